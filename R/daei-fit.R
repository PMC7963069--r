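#' Test for covariate effects on cell-type-specific AEI
#'
#' Extends the AEI regression with covariate-by-proportion interactions,
#' \deqn{X_{jT} - X_{jt} = \alpha + \sum_k d_{jk}(\theta^k +
#'   V_j\,\theta_\Delta^k) + \epsilon_j,}
#' where \eqn{V_j} is the per-individual covariate (e.g. disease status
#' coded 0/1, or a continuous biomarker). \eqn{\theta^k} is the cell-type
#' AEI term controlling for the covariate; the interaction coefficient
#' \eqn{\theta_\Delta^k} is the change in population-level AEI for cell
#' type \eqn{k} per unit increase of the covariate (differential AEI). Each
#' interaction is tested with a t statistic on \eqn{n - (2K+1)} degrees of
#' freedom; the main-effect tests are reported alongside.
#'
#' Running this model is best reserved for SNPs that already show evidence
#' of cell-type-specific AEI: the `prefilter` argument accepts an
#' [aei_fit][test_aei] object and restricts the fit to SNPs with at least
#' one cell type below `prefilter_level` in that fit.
#'
#' @inheritParams test_aei
#' @param covariate Named numeric vector mapping sample ids to covariate
#'   values; individuals without a value are excluded per SNP.
#' @param center,scale Center/scale the covariate before fitting
#'   (default off).
#' @param prefilter Optional `aei_fit`; only SNPs with `q < prefilter_level`
#'   for some cell type are fitted.
#' @param prefilter_level FDR level for the prefilter (default 0.05).
#' @return An object of class `daei_fit` (inherits `aei_fit`). `results`
#'   has one row per SNP x cell type with the main effect (`theta`,
#'   `theta_se`, `theta_statistic`, `theta_p`) and the interaction
#'   (`estimate`, `se`, `statistic`, `df`, `p`, `q`); `q` adjusts the
#'   interaction p-values.
#' @export
test_daei <- function(table, design, covariate,
                      fdr_scope = c("joint", "per_celltype"),
                      center = FALSE, scale = FALSE,
                      prefilter = NULL, prefilter_level = 0.05,
                      cond_tol = 1e10) {
  fdr_scope <- match.arg(fdr_scope)
  table <- validate_allele_counts(table)
  check_matrix_ids(design, "design matrix")
  if (is.null(names(covariate)))
    stop_ctaei("covariate must be a named vector (names = sample ids)")
  if (any(!is.finite(covariate)))
    stop_ctaei("covariate values must be finite")
  if (center) covariate <- covariate - mean(covariate)
  if (scale) {
    s <- stats::sd(covariate)
    if (s == 0) stop_ctaei("cannot scale a constant covariate")
    covariate <- covariate / s
  }
  cell_types <- colnames(design)
  K <- length(cell_types)

  if (!is.null(prefilter)) {
    stopifnot(inherits(prefilter, "aei_fit"))
    hits <- unique(prefilter$results$snp_id[
      !is.na(prefilter$results$q) & prefilter$results$q < prefilter_level])
    table <- table[table$snp_id %in% hits, , drop = FALSE]
    if (nrow(table) == 0L)
      stop_ctaei("prefilter left no SNPs to test")
  }

  idx <- snp_rows(table)
  snp_ids <- names(idx)
  gene_ids <- table$gene_id[vapply(idx, `[`, 0L, 1L)]

  res_list <- vector("list", length(idx))
  snp_alpha <- snp_sigma2 <- rep(NA_real_, length(idx))
  snp_n <- integer(length(idx))
  snp_code <- character(length(idx))
  for (i in seq_along(idx)) {
    rows <- idx[[i]]
    samples <- table$sample_id[rows]
    keep <- samples %in% rownames(design) & samples %in% names(covariate)
    rows <- rows[keep]
    samples <- samples[keep]
    y <- as.numeric(table$ref_count[rows] - table$alt_count[rows])
    D <- design[samples, , drop = FALSE]
    V <- covariate[samples]
    inter <- D * V
    colnames(inter) <- paste0(cell_types, ":V")
    X <- cbind(`(Intercept)` = 1, D, inter)
    fit <- fit_ols_snp(y, X, cond_tol)
    main_idx <- 1L + seq_len(K)
    int_idx <- 1L + K + seq_len(K)
    snp_alpha[i] <- fit$coef[1L]
    snp_sigma2[i] <- fit$sigma2
    snp_n[i] <- fit$n
    snp_code[i] <- fit$code
    res_list[[i]] <- data.frame(
      snp_id = snp_ids[i], gene_id = gene_ids[i], cell_type = cell_types,
      n = fit$n,
      theta = fit$coef[main_idx], theta_se = fit$se[main_idx],
      theta_statistic = fit$t[main_idx], theta_p = fit$pval[main_idx],
      estimate = fit$coef[int_idx], se = fit$se[int_idx],
      statistic = fit$t[int_idx], df = fit$df, p = fit$pval[int_idx],
      code = fit$code, stringsAsFactors = FALSE, row.names = NULL
    )
  }
  results <- do.call(rbind, res_list)
  results$q <- scoped_fdr(results$p, results$cell_type, fdr_scope)
  results <- results[, c("snp_id", "gene_id", "cell_type", "n",
                         "theta", "theta_se", "theta_statistic", "theta_p",
                         "estimate", "se", "statistic", "df", "p", "q",
                         "code")]
  structure(list(
    results = results,
    snp = data.frame(snp_id = snp_ids, gene_id = gene_ids, n = snp_n,
                     alpha = snp_alpha, sigma2 = snp_sigma2, code = snp_code,
                     stringsAsFactors = FALSE),
    cell_types = cell_types, K = K, fdr_scope = fdr_scope,
    call = match.call()
  ), class = c("daei_fit", "aei_fit"))
}

#' @export
print.daei_fit <- function(x, ...) {
  ok <- x$results$code == "ok"
  cat("Cell-type-specific differential AEI fit\n")
  cat("  SNPs:", nrow(x$snp), " cell types:", x$K,
      " interaction tests:", sum(ok), "of", nrow(x$results), "\n")
  if (any(ok))
    cat("  significant at q < 0.05:",
        sum(x$results$q[ok] < 0.05, na.rm = TRUE), "\n")
  invisible(x)
}
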