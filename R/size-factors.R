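#' Median-of-ratios library size factors
#'
#' Computes per-sample library size factors with the median-of-ratios
#' estimator: for each gene with strictly positive counts in every sample,
#' form the ratio of the sample's count to the gene's geometric mean across
#' samples; the sample's factor is the median of those ratios. The factors
#' serve as the per-individual sequencing-depth surrogate \eqn{m_j} that
#' scales cell-type proportions in the AEI design (standing in for the
#' unobserved number of cells in the bulk sample). Factors are returned
#' unnormalized; identical samples get factor 1.
#'
#' @param bulk Genes-by-samples matrix of non-negative counts with dimnames.
#' @return Named positive numeric vector of size factors, one per sample.
#' @export
compute_size_factors <- function(bulk) {
  check_matrix_ids(bulk, "expression matrix")
  if (!is.numeric(bulk) || any(bulk < 0) || any(!is.finite(bulk)))
    stop_ctaei("expression matrix must contain non-negative finite counts")
  qualifying <- rowSums(bulk > 0) == ncol(bulk)
  if (!any(qualifying))
    stop_ctaei("no gene has positive counts in every sample; ",
               "supply size factors directly")
  logm <- log(bulk[qualifying, , drop = FALSE])
  loggeo <- rowMeans(logm)
  factors <- apply(logm, 2L, function(col) exp(stats::median(col - loggeo)))
  stats::setNames(factors, colnames(bulk))
}
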