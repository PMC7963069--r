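#' Build the per-sample regressor matrix for the AEI model
#'
#' Forms, for each sample \eqn{j} and cell type \eqn{k}, the regressor
#' \eqn{d_{jk} = m_j \, p_{jk} \, S_k}: library size factor times cell-type
#' proportion times (optional) cell size. When cell sizes are omitted they
#' are absorbed into the slope — the fitted coefficient then estimates
#' \eqn{S_k \theta^k} instead of \eqn{\theta^k} — which leaves the t-test
#' of no cell-type-specific AEI unchanged; \eqn{S_k} is a constant across
#' individuals and acts as a nuisance scale only.
#'
#' @param size_factors Named positive vector of per-sample library size
#'   factors \eqn{m_j} (see [compute_size_factors()]).
#' @param proportions Samples-by-cell-types proportion matrix with sample
#'   row names.
#' @param cell_sizes Optional named positive vector of cell sizes
#'   \eqn{S_k}; default treats all sizes as 1.
#' @return Samples-by-cell-types regressor matrix (no intercept column;
#'   the fitting functions add it).
#' @export
build_design <- function(size_factors, proportions, cell_sizes = NULL) {
  if (is.null(rownames(proportions)))
    stop_ctaei("proportions must have sample row names")
  missing <- setdiff(rownames(proportions), names(size_factors))
  if (length(missing))
    stop_ctaei("no size factor for sample(s): ",
               paste(utils::head(missing, 3L), collapse = ", "))
  m <- size_factors[rownames(proportions)]
  if (any(!is.finite(m)) || any(m <= 0))
    stop_ctaei("size factors must be positive and finite")
  D <- proportions * m
  if (!is.null(cell_sizes)) {
    if (is.null(names(cell_sizes)))
      cell_sizes <- stats::setNames(cell_sizes, colnames(proportions))
    missing_ct <- setdiff(colnames(proportions), names(cell_sizes))
    if (length(missing_ct))
      stop_ctaei("no cell size for cell type(s): ",
                 paste(missing_ct, collapse = ", "))
    s <- cell_sizes[colnames(proportions)]
    if (any(!is.finite(s)) || any(s <= 0))
      stop_ctaei("cell sizes must be positive and finite")
    D <- sweep(D, 2L, s, "*")
  }
  D
}
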