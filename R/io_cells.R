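#' Read a sparse single-cell count matrix (Matrix Market + TSVs)
#'
#' Reads the standard triplet layout: a `.mtx` file of counts (genes x
#' cells), a gene file (one symbol per line, first column used) and a
#' barcode file.
#'
#' @param mtx_path Path to the Matrix Market counts file.
#' @param genes_path Path to the gene TSV.
#' @param barcodes_path Path to the barcode TSV.
#' @return A `dgCMatrix` with gene row names and cell column names.
#' @export
read_cell_counts <- function(mtx_path, genes_path, barcodes_path) {
  for (p in c(mtx_path, genes_path, barcodes_path)) {
    if (!file.exists(p)) abort(sprintf("File not found: %s", p))
  }
  m <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  genes <- readr::read_tsv(genes_path, col_names = FALSE, show_col_types = FALSE)[[1]]
  cells <- readr::read_tsv(barcodes_path, col_names = FALSE, show_col_types = FALSE)[[1]]
  if (length(genes) != nrow(m)) abort("Gene file length does not match the matrix rows.")
  if (length(cells) != ncol(m)) abort("Barcode file length does not match the matrix columns.")
  dimnames(m) <- list(genes, cells)
  m
}

#' Write a single-cell count matrix as Matrix Market + TSVs
#'
#' @param counts Genes-by-cells matrix (dense or sparse) with dimnames.
#' @param dir Output directory (created if needed); writes `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv`.
#' @return The directory, invisibly.
#' @export
write_cell_counts <- function(counts, dir) {
  counts <- check_counts_matrix(counts)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sparse <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"),
                        "CsparseMatrix")
  Matrix::writeMM(sparse, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}
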