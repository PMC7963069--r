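#' Bulk-level AEI test (binomial GLM comparator)
#'
#' The traditional cell-type-agnostic analysis: per SNP, the
#' reference-allele read counts across individuals are modelled with an
#' intercept-only binomial GLM with logit link (successes = reference
#' reads, trials = total reads), and AEI is assessed by a Wald test of the
#' intercept. The intercept MLE equals the logit of the pooled
#' reference-allele fraction, so a SNP whose alleles balance out at the
#' bulk level (pooled fraction 0.5) shows no signal here even when
#' individual cell types are imbalanced in opposite directions.
#'
#' @param table Allele-count table.
#' @return `data.frame` with one row per SNP: `snp_id`, `gene_id`, `n`,
#'   `estimate` (intercept on the logit scale), `se`, `z`, `p`, `q`
#'   (BH-adjusted), `code` (`"ok"`, `"no_reads"`, or `"separation"` when
#'   the pooled fraction is exactly 0 or 1).
#' @export
bulk_glm_test <- function(table) {
  table <- validate_allele_counts(table)
  per_snp(table, function(snp_tab) {
    tot <- snp_tab$ref_count + snp_tab$alt_count
    use <- tot > 0
    if (!any(use)) return(glm_row(0L, code = "no_reads"))
    ref <- snp_tab$ref_count[use]
    alt <- snp_tab$alt_count[use]
    if (sum(ref) == 0L || sum(alt) == 0L)
      return(glm_row(sum(use), code = "separation"))
    fit <- stats::glm(cbind(ref, alt) ~ 1, family = stats::binomial(),
                      control = stats::glm.control(epsilon = 1e-12))
    s <- summary(fit)$coefficients
    glm_row(sum(use), estimate = s[1L, 1L], se = s[1L, 2L], z = s[1L, 3L],
            p = s[1L, 4L])
  })
}

#' Bulk-level covariate association test (binomial GLM comparator)
#'
#' Per SNP, regresses the reference-allele fraction on the covariate with a
#' binomial logit GLM and Wald-tests the covariate coefficient: the
#' bulk-level analogue of the differential-AEI test, blind to cell types.
#'
#' @param table Allele-count table.
#' @param covariate Named numeric vector mapping sample ids to covariate
#'   values.
#' @return `data.frame` as in [bulk_glm_test()] with the covariate
#'   coefficient in `estimate`; `code` `"collinear"` flags SNPs whose
#'   eligible individuals share a single covariate value.
#' @export
bulk_glm_covariate_test <- function(table, covariate) {
  table <- validate_allele_counts(table)
  if (is.null(names(covariate)))
    stop_ctaei("covariate must be a named vector (names = sample ids)")
  per_snp(table, function(snp_tab) {
    keep <- snp_tab$sample_id %in% names(covariate)
    snp_tab <- snp_tab[keep, , drop = FALSE]
    tot <- snp_tab$ref_count + snp_tab$alt_count
    use <- tot > 0
    if (!any(use)) return(glm_row(0L, code = "no_reads"))
    ref <- snp_tab$ref_count[use]
    alt <- snp_tab$alt_count[use]
    V <- covariate[snp_tab$sample_id[use]]
    if (length(unique(V)) < 2L)
      return(glm_row(sum(use), code = "collinear"))
    if (sum(ref) == 0L || sum(alt) == 0L)
      return(glm_row(sum(use), code = "separation"))
    fit <- suppressWarnings(
      stats::glm(cbind(ref, alt) ~ V, family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-12)))
    s <- summary(fit)$coefficients
    if (nrow(s) < 2L || !is.finite(s["V", 2L]))
      return(glm_row(sum(use), code = "separation"))
    glm_row(sum(use), estimate = s["V", 1L], se = s["V", 2L],
            z = s["V", 3L], p = s["V", 4L])
  })
}

glm_row <- function(n, estimate = NA_real_, se = NA_real_, z = NA_real_,
                    p = NA_real_, code = "ok") {
  data.frame(n = n, estimate = estimate, se = se, z = z, p = p, code = code,
             stringsAsFactors = FALSE)
}

per_snp <- function(table, fn) {
  idx <- snp_rows(table)
  out <- do.call(rbind, lapply(seq_along(idx), function(i) {
    snp_tab <- table[idx[[i]], , drop = FALSE]
    row <- fn(snp_tab)
    cbind(data.frame(snp_id = names(idx)[i],
                     gene_id = snp_tab$gene_id[1L],
                     stringsAsFactors = FALSE), row)
  }))
  out$q <- adjust_fdr(out$p)
  out[, c("snp_id", "gene_id", "n", "estimate", "se", "z", "p", "q", "code")]
}

#' Resampling-based gene-set enrichment test
#'
#' Assesses whether the genes flagged by the AEI analysis overlap a
#' reference gene set (e.g. eGenes from an eQTL study) more than chance.
#' Repeatedly draws `|hit_genes|` genes without replacement from the
#' background (genes analysed but not flagged) and records the fraction
#' overlapping the reference set; the enrichment p-value is the fraction
#' of resamples whose overlap is at least the observed one.
#'
#' @param hit_genes Character vector of flagged genes.
#' @param background_genes Character vector of non-flagged analysed genes
#'   (disjoint from `hit_genes`, at least as many).
#' @param reference_set Character vector of reference genes.
#' @param n_resamples Number of resamples (default 10000).
#' @param seed Optional integer seed.
#' @return List with `observed` (overlap fraction of the hits), `p`, and
#'   `resampled` (vector of resampled overlap fractions).
#' @export
enrichment_resampling <- function(hit_genes, background_genes, reference_set,
                                  n_resamples = 10000L, seed = NULL) {
  hit_genes <- unique(hit_genes)
  background_genes <- unique(background_genes)
  if (length(intersect(hit_genes, background_genes)))
    stop_ctaei("hit and background gene sets must be disjoint")
  if (length(background_genes) < length(hit_genes))
    stop_ctaei("background must contain at least as many genes as hits")
  observed <- mean(hit_genes %in% reference_set)
  with_seed(seed, {
    resampled <- vapply(seq_len(n_resamples), function(i) {
      mean(sample(background_genes, length(hit_genes)) %in% reference_set)
    }, 0)
    list(observed = observed,
         p = mean(resampled >= observed),
         resampled = resampled)
  })
}
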