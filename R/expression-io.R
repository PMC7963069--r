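#' Read a bulk expression count matrix
#'
#' Reads a genes-by-samples matrix of non-negative integer counts either
#' from a delimited text file (genes as rows, first column gene ids, header
#' row of sample ids) or from a MatrixMarket triplet file with sidecar gene
#' and sample id lists (one id per line).
#'
#' @param path Path to the expression table (TSV) or `.mtx` file.
#' @param format `"tsv"` or `"mtx"`; guessed from the file extension by
#'   default.
#' @param gene_file,sample_file Sidecar id files, required for
#'   `format = "mtx"`.
#' @param sep Field delimiter for `format = "tsv"`.
#' @return A base integer matrix with gene row names and sample column names.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "mtx"),
                            gene_file = NULL, sample_file = NULL,
                            sep = "\t") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx(\\.gz)?$", path)) "mtx" else "tsv"
  if (format == "mtx") {
    if (!requireNamespace("Matrix", quietly = TRUE))
      stop_ctaei("reading MatrixMarket files requires the Matrix package")
    if (is.null(gene_file) || is.null(sample_file))
      stop_ctaei("mtx input needs gene_file and sample_file sidecars")
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(gene_file)
    colnames(m) <- readLines(sample_file)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                             check.names = FALSE)
    m <- as.matrix(tab)
  }
  validate_expression(m)
}

validate_expression <- function(m) {
  check_matrix_ids(m, "expression matrix")
  if (!is_count_vector(as.vector(m)))
    stop_ctaei("expression matrix must contain non-negative integer counts")
  storage.mode(m) <- "integer"
  m
}

#' Write a bulk expression count matrix as TSV
#'
#' @param m Genes-by-samples count matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  check_matrix_ids(m, "expression matrix")
  out <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
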