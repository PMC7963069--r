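#' Read a table of allele-specific read counts
#'
#' Reads per-individual allele-specific read counts at transcribed SNPs from
#' a delimited text file (gzip-transparent). The table must provide, for each
#' (SNP, individual) pair, the read counts supporting the reference and the
#' alternative allele of the transcribed SNP; counts are assumed to come from
#' heterozygous carriers only, with alleles oriented consistently across
#' individuals (reference vs alternative).
#'
#' @param path Path to a delimited text file with a header row.
#' @param sep Field delimiter (default tab).
#' @param col_map Named character vector mapping the required column names
#'   (`snp_id`, `gene_id`, `sample_id`, `ref_count`, `alt_count`) to the
#'   names used in the file, e.g. `c(ref_count = "refReads")`. Columns not
#'   mentioned are looked up under their canonical name.
#' @return A validated `data.frame` with columns `snp_id`, `gene_id`,
#'   `sample_id`, `ref_count`, `alt_count`.
#' @seealso [filter_allele_counts()], [write_allele_counts()]
#' @export
read_allele_counts <- function(path, sep = "\t", col_map = NULL) {
  if (!file.exists(path)) stop_ctaei("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("snp_id", "gene_id", "sample_id", "ref_count", "alt_count")
  lookup <- stats::setNames(required, required)
  if (!is.null(col_map)) {
    bad <- setdiff(names(col_map), required)
    if (length(bad))
      stop_ctaei("unknown column mapping target(s): ",
                 paste(bad, collapse = ", "))
    lookup[names(col_map)] <- unname(col_map)
  }
  missing <- lookup[!(lookup %in% names(raw))]
  if (length(missing))
    stop_ctaei("missing required column(s): ",
               paste(missing, collapse = ", "))
  tab <- data.frame(
    snp_id = as.character(raw[[lookup["snp_id"]]]),
    gene_id = as.character(raw[[lookup["gene_id"]]]),
    sample_id = as.character(raw[[lookup["sample_id"]]]),
    ref_count = raw[[lookup["ref_count"]]],
    alt_count = raw[[lookup["alt_count"]]],
    stringsAsFactors = FALSE
  )
  validate_allele_counts(tab)
}

#' Validate an allele-count table
#'
#' Checks the structural invariants of a per-SNP allele-count table:
#' non-negative integer counts, unique (SNP, individual) pairs, and a single
#' gene per SNP.
#'
#' @param table A `data.frame` with columns `snp_id`, `gene_id`, `sample_id`,
#'   `ref_count`, `alt_count`.
#' @return The table, invisibly unchanged, or an error describing the first
#'   violated invariant (with the offending row number for count errors).
#' @export
validate_allele_counts <- function(table) {
  required <- c("snp_id", "gene_id", "sample_id", "ref_count", "alt_count")
  missing <- setdiff(required, names(table))
  if (length(missing))
    stop_ctaei("missing required column(s): ", paste(missing, collapse = ", "))
  for (col in c("ref_count", "alt_count")) {
    x <- table[[col]]
    if (!is.numeric(x))
      stop_ctaei(col, " is not numeric")
    bad <- which(!is.finite(x) | x < 0 | x != round(x))
    if (length(bad))
      stop_ctaei(col, " must be a non-negative integer (row ", bad[1L], ")")
    table[[col]] <- as.integer(round(x))
  }
  key <- paste(table$snp_id, table$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- table[duplicated(key), , drop = FALSE][1L, ]
    stop_ctaei("duplicated (snp_id, sample_id) pair: ",
               dup$snp_id, ", ", dup$sample_id)
  }
  genes_per_snp <- tapply(table$gene_id, table$snp_id,
                          function(g) length(unique(g)))
  if (length(genes_per_snp) && any(genes_per_snp > 1L))
    stop_ctaei("snp_id maps to more than one gene_id: ",
               names(genes_per_snp)[which(genes_per_snp > 1L)[1L]])
  rownames(table) <- NULL
  table
}

#' Write an allele-count table
#'
#' @param table A validated allele-count table.
#' @param path Output path; a `.gz` suffix writes gzip-compressed text.
#' @param sep Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(table, path, sep = "\t") {
  table <- validate_allele_counts(table)
  utils::write.table(table, file = path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter allele counts by per-individual and per-SNP coverage rules
#'
#' Applies the standard eligibility rules for cross-individual AEI analysis.
#' An individual's row at a SNP is kept when its minor allele count
#' (`min(ref, alt)`) is at least `min_minor`, its total count is at least
#' `min_total`, and the minor count is at least `min_minor_frac` of the
#' total. A SNP is then retained only when at least `min_individuals` rows
#' survive. Rules are applied in that order, so the removal attribution in
#' the report is deterministic. The minor allele is defined per
#' (SNP, individual) row.
#'
#' @param table An allele-count table.
#' @param min_minor Minimum minor-allele read count per individual (default 5).
#' @param min_total Minimum total read count per individual (default 20).
#' @param min_minor_frac Minimum minor-allele fraction of the total
#'   (default 0.05).
#' @param min_individuals Minimum number of surviving individuals per SNP
#'   (default 20).
#' @return The filtered table. Attribute `report` holds the row counts
#'   removed by each rule; attribute `retention` holds a per-SNP
#'   `data.frame` with the number of rows before/after filtering and whether
#'   the SNP was kept.
#' @export
filter_allele_counts <- function(table, min_minor = 5L, min_total = 20L,
                                 min_minor_frac = 0.05,
                                 min_individuals = 20L) {
  table <- validate_allele_counts(table)
  n_in <- nrow(table)
  if (n_in == 0L) warning("empty allele-count table; nothing to filter")
  minor <- pmin(table$ref_count, table$alt_count)
  total <- table$ref_count + table$alt_count
  frac <- ifelse(total > 0, minor / total, 0)

  pass_minor <- minor >= min_minor
  pass_total <- pass_minor & total >= min_total
  pass_frac <- pass_total & frac >= min_minor_frac
  removed_minor <- sum(!pass_minor)
  removed_total <- sum(pass_minor & !(total >= min_total))
  removed_frac <- sum(pass_total & !(frac >= min_minor_frac))

  kept_rows <- table[pass_frac, , drop = FALSE]
  n_by_snp_in <- table(table$snp_id)
  n_by_snp <- table(kept_rows$snp_id)
  snp_ok <- names(n_by_snp)[n_by_snp >= min_individuals]
  removed_snp <- sum(!(kept_rows$snp_id %in% snp_ok))
  out <- kept_rows[kept_rows$snp_id %in% snp_ok, , drop = FALSE]
  rownames(out) <- NULL

  all_snps <- sort(unique(table$snp_id))
  retention <- data.frame(
    snp_id = all_snps,
    n_in = as.integer(n_by_snp_in[all_snps]),
    n_kept = as.integer(ifelse(is.na(n_by_snp[all_snps]), 0L,
                               n_by_snp[all_snps])),
    kept = all_snps %in% snp_ok,
    stringsAsFactors = FALSE
  )
  attr(out, "retention") <- retention
  attr(out, "report") <- c(
    rows_in = n_in,
    removed_min_minor = removed_minor,
    removed_min_total = removed_total,
    removed_min_minor_frac = removed_frac,
    removed_min_individuals = removed_snp,
    rows_kept = nrow(out)
  )
  out
}
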