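## Shared per-SNP OLS engine for the AEI and differential-AEI models.
## Fits y = X beta + eps by QR, returns estimates, SEs from (X'X)^{-1},
## t statistics and two-sided p from the t distribution on n - ncol(X) df.
## Degenerate situations are reported with a reason code instead of a fit:
##   low_n      too few eligible individuals
##   collinear  condition number of X above `cond_tol`
##   degenerate zero residual variance (p undefined, estimates kept)
fit_ols_snp <- function(y, X, cond_tol = 1e10) {
  n <- length(y)
  p <- ncol(X)
  out <- list(coef = rep(NA_real_, p), se = rep(NA_real_, p),
              t = rep(NA_real_, p), pval = rep(NA_real_, p),
              df = n - p, sigma2 = NA_real_, n = n, code = "ok")
  if (n < p + 1L) {
    out$code <- "low_n"
    return(out)
  }
  if (kappa(X, exact = TRUE) > cond_tol) {
    out$code <- "collinear"
    return(out)
  }
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    out$code <- "collinear"
    return(out)
  }
  beta <- qr.coef(qr_x, y)
  res <- y - as.numeric(X %*% beta)
  rss <- sum(res^2)
  df <- n - p
  sigma2 <- rss / df
  out$coef <- beta
  out$sigma2 <- sigma2
  xtx_inv <- chol2inv(qr.R(qr_x))
  scale <- mean(y^2) + 1
  if (sigma2 <= scale * 1e-20) {
    out$code <- "degenerate"
    return(out)
  }
  out$se <- sqrt(diag(xtx_inv) * sigma2)
  out$t <- beta / out$se
  out$pval <- 2 * stats::pt(-abs(out$t), df)
  out
}

## Assemble y and the (sample-subset) design rows for one SNP.
snp_rows <- function(table) split(seq_len(nrow(table)), table$snp_id)

#' Test for cell-type-specific allelic expression imbalance
#'
#' The core fitting function. For each transcribed SNP it regresses the
#' allelic read-count difference \eqn{y_j = X_{jT} - X_{jt}} on the
#' size-factor-scaled cell-type proportions,
#' \deqn{X_{jT} - X_{jt} = \alpha + \sum_k d_{jk}\,\theta^k + \epsilon_j,
#'   \quad d_{jk} = m_j p_{jk} S_k,}
#' and tests \eqn{H_0: \theta^k = 0} per cell type with a t statistic on
#' \eqn{n - (K+1)} degrees of freedom. A nonzero \eqn{\theta^k} means the
#' two alleles are unequally expressed in cell type \eqn{k}; the intercept
#' \eqn{\alpha} absorbs allelic differences not explained by the selected
#' cell types. p-values are adjusted by Benjamini-Hochberg FDR, by default
#' jointly across all SNP-by-cell-type tests.
#'
#' @param table Allele-count table (see [read_allele_counts()]); only
#'   individuals present in both the table and the design enter a SNP's fit.
#' @param design Samples-by-cell-types regressor matrix from
#'   [build_design()].
#' @param fdr_scope `"joint"` (default) adjusts all SNP-by-cell-type
#'   p-values together; `"per_celltype"` adjusts within each cell type.
#' @param cond_tol Condition-number threshold above which a SNP's design is
#'   flagged `collinear` (default `1e10`).
#' @return An object of class `aei_fit` with components `results` (one row
#'   per SNP x cell type: estimate, se, statistic, df, p, q, code) and
#'   `snp` (per-SNP intercept \eqn{\hat\alpha}, residual variance
#'   \eqn{\hat\sigma^2}, sample size, code). Methods: `print`, `summary`,
#'   `coef`, `as.data.frame`.
#' @seealso [test_daei()] for the covariate-interaction extension,
#'   [bulk_glm_test()] for the bulk-level comparator.
#' @export
test_aei <- function(table, design, fdr_scope = c("joint", "per_celltype"),
                     cond_tol = 1e10) {
  fdr_scope <- match.arg(fdr_scope)
  table <- validate_allele_counts(table)
  check_matrix_ids(design, "design matrix")
  cell_types <- colnames(design)
  K <- length(cell_types)

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
    keep <- samples %in% rownames(design)
    rows <- rows[keep]
    samples <- samples[keep]
    y <- as.numeric(table$ref_count[rows] - table$alt_count[rows])
    X <- cbind(`(Intercept)` = 1, design[samples, , drop = FALSE])
    fit <- fit_ols_snp(y, X, cond_tol)
    snp_alpha[i] <- fit$coef[1L]
    snp_sigma2[i] <- fit$sigma2
    snp_n[i] <- fit$n
    snp_code[i] <- fit$code
    res_list[[i]] <- data.frame(
      snp_id = snp_ids[i], gene_id = gene_ids[i], cell_type = cell_types,
      n = fit$n, estimate = fit$coef[-1L], se = fit$se[-1L],
      statistic = fit$t[-1L], df = fit$df, p = fit$pval[-1L],
      code = fit$code, stringsAsFactors = FALSE, row.names = NULL
    )
  }
  results <- do.call(rbind, res_list)
  results$q <- scoped_fdr(results$p, results$cell_type, fdr_scope)
  results <- results[, c("snp_id", "gene_id", "cell_type", "n", "estimate",
                         "se", "statistic", "df", "p", "q", "code")]
  structure(list(
    results = results,
    snp = data.frame(snp_id = snp_ids, gene_id = gene_ids, n = snp_n,
                     alpha = snp_alpha, sigma2 = snp_sigma2, code = snp_code,
                     stringsAsFactors = FALSE),
    cell_types = cell_types, K = K, fdr_scope = fdr_scope,
    call = match.call()
  ), class = "aei_fit")
}

scoped_fdr <- function(p, group, scope) {
  if (scope == "joint") return(adjust_fdr(p))
  q <- rep(NA_real_, length(p))
  for (g in unique(group)) {
    sel <- group == g
    q[sel] <- adjust_fdr(p[sel])
  }
  q
}

#' Benjamini-Hochberg FDR adjustment with NA propagation
#'
#' Step-up FDR adjustment over the supplied p-values; `NA` entries are
#' excluded from the adjustment (they do not count towards the number of
#' tests) and propagated as `NA`.
#'
#' @param p Numeric vector of p-values in `[0,1]`, `NA` allowed.
#' @return Vector of q-values of the same length.
#' @export
adjust_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop_ctaei("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' @export
print.aei_fit <- function(x, ...) {
  ok <- x$results$code == "ok"
  cat("Cell-type-specific AEI fit\n")
  cat("  SNPs:", nrow(x$snp), " cell types:", x$K,
      " tests:", sum(ok), "of", nrow(x$results), "\n")
  if (any(ok))
    cat("  significant at q < 0.05:",
        sum(x$results$q[ok] < 0.05, na.rm = TRUE), "\n")
  bad <- table(x$results$code[!ok])
  if (length(bad))
    cat("  untested:", paste(names(bad), bad, sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
summary.aei_fit <- function(object, fdr_level = 0.05, ...) {
  r <- object$results
  per_ct <- do.call(rbind, lapply(split(r, r$cell_type), function(d) {
    data.frame(cell_type = d$cell_type[1L],
               tested = sum(!is.na(d$p)),
               significant = sum(d$q < fdr_level, na.rm = TRUE),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(per_cell_type = per_ct, fdr_level = fdr_level,
                 n_snps = nrow(object$snp)), class = "summary.aei_fit")
}

#' @export
print.summary.aei_fit <- function(x, ...) {
  cat("AEI tests across", x$n_snps, "SNPs (FDR level", x$fdr_level, ")\n")
  print(x$per_cell_type, row.names = FALSE)
  invisible(x)
}

#' @export
coef.aei_fit <- function(object, ...) {
  r <- object$results
  est <- matrix(NA_real_, nrow = nrow(object$snp), ncol = object$K,
                dimnames = list(object$snp$snp_id, object$cell_types))
  est[cbind(r$snp_id, r$cell_type)] <- r$estimate
  est
}

#' @export
as.data.frame.aei_fit <- function(x, ...) x$results

#' Write the per-test results of an AEI or differential-AEI fit as TSV
#'
#' @param fit An `aei_fit` or `daei_fit` object, or a plain results
#'   `data.frame` (e.g. from [bulk_glm_test()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(fit, path) {
  tab <- if (is.data.frame(fit)) fit else fit$results
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
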