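#' Estimate cell-type proportions by non-negative least squares
#'
#' Deconvolution step: models each bulk sample's expression profile as a
#' weighted sum of cell-type-specific expression,
#' \eqn{X_{jg} = m_j \sum_k p_{jk} S_k \theta_{gk}}, and recovers the
#' mixing weights per sample by (optionally weighted) non-negative least
#' squares of the bulk profile on the size-scaled signature columns
#' \eqn{S_k \theta_{gk}}. Weights are normalized to proportions summing
#' to 1. The per-gene weight hook allows variance-based weighting schemes;
#' the default is unweighted.
#'
#' @param bulk Genes-by-samples count matrix with dimnames.
#' @param reference An [sc_reference][build_reference] object.
#' @param weights Optional named (or signature-ordered) positive per-gene
#'   weights.
#' @param marker_genes Optional subset of gene ids to restrict the fit to;
#'   default uses all genes shared between `bulk` and the reference.
#' @param normalize_bulk Normalize each bulk column to relative abundance
#'   before fitting (default `TRUE`); the fit is then invariant to scaling
#'   a sample's counts.
#' @return Samples-by-cell-types matrix of proportions, each row
#'   non-negative and summing to 1. A sample whose NNLS solution is all
#'   zero yields a row of `NA` with a warning.
#' @export
estimate_proportions <- function(bulk, reference, weights = NULL,
                                 marker_genes = NULL, normalize_bulk = TRUE) {
  check_matrix_ids(bulk, "bulk matrix")
  validate_sc_reference(reference)
  genes <- intersect(rownames(bulk), reference$gene_ids)
  if (!is.null(marker_genes)) genes <- intersect(genes, marker_genes)
  K <- length(reference$cell_types)
  if (length(genes) < K)
    stop_ctaei("only ", length(genes), " genes shared between bulk and ",
               "reference; need at least ", K)
  basis <- sweep(reference$signature[genes, , drop = FALSE], 2L,
                 reference$cell_sizes, "*")
  if (is.null(weights)) {
    w <- rep(1, length(genes))
  } else {
    w <- if (!is.null(names(weights))) weights[genes] else weights
    if (length(w) != length(genes) || any(!is.finite(w)) || any(w <= 0))
      stop_ctaei("weights must be finite positive values for every ",
                 "fitted gene")
  }
  sw <- sqrt(w)
  A <- basis * sw

  P <- matrix(NA_real_, nrow = ncol(bulk), ncol = K,
              dimnames = list(colnames(bulk), reference$cell_types))
  for (j in seq_len(ncol(bulk))) {
    x <- as.numeric(bulk[genes, j])
    tot <- sum(x)
    if (tot <= 0)
      stop_ctaei("bulk sample has zero total counts: ", colnames(bulk)[j])
    if (normalize_bulk) x <- x / tot
    fit <- pracma::lsqnonneg(A, x * sw)
    if (sum(fit$x) <= 0) {
      warning("NNLS returned the all-zero solution for sample ",
              colnames(bulk)[j], "; proportions set to NA")
      next
    }
    P[j, ] <- fit$x / sum(fit$x)
  }
  P
}

#' Multiplicative Gaussian perturbation of a proportion matrix
#'
#' Emulates deconvolution uncertainty by setting
#' \eqn{\hat p_{jk} = p_{jk}(1 + \epsilon_{jk})} with independent
#' \eqn{\epsilon_{jk} \sim N(0, \mathrm{sd}^2)}. Negative results are
#' clamped to zero; rows are deliberately not renormalized, and the result
#' carries attribute `unnormalized = TRUE`.
#'
#' @param P Samples-by-cell-types proportion matrix.
#' @param sd Standard deviation of the multiplicative noise (default 0.2).
#' @param seed Optional integer seed for reproducibility.
#' @return Perturbed matrix of the same shape.
#' @export
perturb_proportions <- function(P, sd = 0.2, seed = NULL) {
  if (!is.numeric(sd) || length(sd) != 1L || sd < 0)
    stop_ctaei("sd must be a single non-negative number")
  with_seed(seed, {
    eps <- matrix(stats::rnorm(length(P), mean = 0, sd = sd), nrow = nrow(P))
    out <- pmax(P * (1 + eps), 0)
    dimnames(out) <- dimnames(P)
    attr(out, "unnormalized") <- TRUE
    out
  })
}

#' Drop rare cell types from a proportion matrix
#'
#' Removes cell types whose mean proportion falls below a threshold and
#' renormalizes the remaining proportions per sample. With a limited number
#' of individuals per SNP, removing rare cell types reduces the parameter
#' count of the AEI regression and improves power.
#'
#' @param P Samples-by-cell-types proportion matrix.
#' @param threshold Mean-proportion cutoff (default 0.02).
#' @return Renormalized matrix over the retained cell types.
#' @export
drop_rare_cell_types <- function(P, threshold = 0.02) {
  keep <- colMeans(P, na.rm = TRUE) >= threshold
  if (!any(keep)) stop_ctaei("all cell types fall below the threshold")
  out <- P[, keep, drop = FALSE]
  out / rowSums(out)
}

#' Write / read a proportion matrix as TSV
#'
#' Rows are samples (first column `sample_id`), columns are cell types.
#'
#' @param P Samples-by-cell-types matrix.
#' @param path File path.
#' @return `path` (write) or the matrix (read).
#' @export
write_proportions <- function(P, path) {
  out <- data.frame(sample_id = rownames(P), P, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_proportions
#' @export
read_proportions <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                           check.names = FALSE)
  as.matrix(tab)
}
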