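#' Build a cell-type signature from labelled single-cell counts
#'
#' Summarises a labelled single-cell count matrix into the three quantities
#' the downstream steps need per cell type \eqn{k}: the relative abundance
#' \eqn{\theta_{gk}} of each gene (mean count across cells of the type,
#' normalized to sum to 1 over genes), the cell size \eqn{S_k} (mean total
#' count per cell of the type), and the expressed-cell fraction (share of
#' the type's cells with a nonzero count for the gene).
#'
#' @param cell_counts Cells-by-genes count matrix with cell row names and
#'   gene column names.
#' @param labels Cell-type label per cell: a named character vector (names =
#'   cell ids) or an unnamed vector aligned with the rows of `cell_counts`.
#' @return An object of class `sc_reference`: a list with `signature`
#'   (genes x cell types, columns summing to 1), `cell_sizes` (named
#'   positive vector), `expressed_fraction` (genes x cell types in `[0,1]`),
#'   `cell_types` and `gene_ids`.
#' @export
build_reference <- function(cell_counts, labels) {
  check_matrix_ids(cell_counts, "single-cell count matrix")
  if (!is.null(names(labels))) {
    missing <- setdiff(rownames(cell_counts), names(labels))
    if (length(missing))
      stop_ctaei("unlabeled cell(s): ", paste(utils::head(missing, 3L),
                                              collapse = ", "))
    labels <- labels[rownames(cell_counts)]
  } else if (length(labels) != nrow(cell_counts)) {
    stop_ctaei("labels must cover every cell")
  }
  labels <- as.character(labels)
  if (anyNA(labels)) stop_ctaei("unlabeled cell(s): NA label")
  types <- sort(unique(labels))
  if (length(types) < 1L) stop_ctaei("no cell types in labels")

  means <- sapply(types, function(k) {
    colMeans(cell_counts[labels == k, , drop = FALSE])
  })
  sizes <- sapply(types, function(k) {
    mean(rowSums(cell_counts[labels == k, , drop = FALSE]))
  })
  if (any(sizes <= 0))
    stop_ctaei("cell type with zero total counts: ",
               types[which(sizes <= 0)[1L]])
  fractions <- sapply(types, function(k) {
    colMeans(cell_counts[labels == k, , drop = FALSE] > 0)
  })
  signature <- sweep(means, 2L, colSums(means), "/")
  new_sc_reference(signature, stats::setNames(sizes, types), fractions)
}

new_sc_reference <- function(signature, cell_sizes, expressed_fraction) {
  stopifnot(is.matrix(signature), is.matrix(expressed_fraction),
            identical(dim(signature), dim(expressed_fraction)))
  obj <- structure(list(
    signature = signature,
    cell_sizes = cell_sizes,
    expressed_fraction = expressed_fraction,
    cell_types = colnames(signature),
    gene_ids = rownames(signature)
  ), class = "sc_reference")
  validate_sc_reference(obj)
}

validate_sc_reference <- function(ref, tol = 1e-9) {
  cs <- colSums(ref$signature)
  if (any(abs(cs - 1) > tol))
    stop_ctaei("signature columns must sum to 1")
  if (any(ref$cell_sizes <= 0)) stop_ctaei("cell sizes must be positive")
  ef <- ref$expressed_fraction
  if (any(ef < 0 | ef > 1)) stop_ctaei("expressed fractions must be in [0,1]")
  ref
}

#' @export
print.sc_reference <- function(x, ...) {
  cat("Single-cell reference:", length(x$gene_ids), "genes,",
      length(x$cell_types), "cell types\n")
  cat("Cell types:", paste(x$cell_types, collapse = ", "), "\n")
  cat("Cell sizes:", paste(sprintf("%.1f", x$cell_sizes), collapse = ", "),
      "\n")
  invisible(x)
}

#' Serialize / load a single-cell reference as a directory of TSVs
#'
#' @param ref An `sc_reference` object.
#' @param dir Directory to write to (created if needed).
#' @return `dir` (write) or the `sc_reference` (read).
#' @export
write_reference <- function(ref, dir) {
  validate_sc_reference(ref)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ref_matrix <- function(m, file) {
    out <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    utils::write.table(out, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_ref_matrix(ref$signature, "signature.tsv")
  write_ref_matrix(ref$expressed_fraction, "expressed_fraction.tsv")
  utils::write.table(
    data.frame(cell_type = names(ref$cell_sizes),
               cell_size = unname(ref$cell_sizes)),
    file.path(dir, "cell_sizes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' @rdname write_reference
#' @export
read_reference <- function(dir) {
  read_ref_matrix <- function(file) {
    tab <- utils::read.table(file.path(dir, file), header = TRUE, sep = "\t",
                             row.names = 1L, check.names = FALSE)
    as.matrix(tab)
  }
  signature <- read_ref_matrix("signature.tsv")
  fractions <- read_ref_matrix("expressed_fraction.tsv")
  sizes <- utils::read.table(file.path(dir, "cell_sizes.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  new_sc_reference(signature,
                   stats::setNames(sizes$cell_size, sizes$cell_type),
                   fractions)
}
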