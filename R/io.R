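# Readers and writers for the standard on-disk formats: Matrix Market
# sparse triplets with gene/barcode TSVs, dense CSV/TSV, marker maps as
# JSON or two-column CSV, and label tables as CSV.

#' Read an expression matrix
#'
#' Two layouts are supported:
#' * a 10x-style directory containing `matrix.mtx` (Matrix Market triplet,
#'   genes in rows), `genes.tsv` (gene ids in the first column) and
#'   `barcodes.tsv`;
#' * a dense CSV/TSV file with gene rows and cell columns, gene ids in the
#'   first column and cell ids in the header.
#'
#' @param path Directory (MTX layout) or file (dense layout).
#'
#' @return A dense numeric matrix, genes x cells, with dimnames.
#' @export
read_expression <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    genes <- file.path(path, "genes.tsv")
    barcodes <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, genes, barcodes)) {
      if (!file.exists(f)) abort(sprintf("Expected file not found: %s", f))
    }
    rlang::check_installed("Matrix")
    x <- as.matrix(Matrix::readMM(mtx))
    gene_ids <- read.delim(genes, header = FALSE)[[1]]
    cell_ids <- read.delim(barcodes, header = FALSE)[[1]]
    dimnames(x) <- list(as.character(gene_ids), as.character(cell_ids))
  } else {
    if (!file.exists(path)) abort(sprintf("File not found: %s", path))
    sep <- if (grepl("\\.tsv$", path)) "\t" else ","
    df <- read.csv(path, sep = sep, check.names = FALSE, row.names = 1)
    x <- as.matrix(df)
  }
  storage.mode(x) <- "double"
  check_expr(x)
  x
}

#' Write an expression matrix
#'
#' @param x Matrix, genes x cells, with dimnames.
#' @param path Target: a directory for the MTX layout (`format = "mtx"`)
#'   or a file for dense CSV.
#' @param format `"mtx"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("mtx", "csv")) {
  check_expr(x)
  format <- match.arg(format)
  if (format == "mtx") {
    rlang::check_installed("Matrix")
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(x, sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(x), file.path(path, "genes.tsv"))
    writeLines(colnames(x), file.path(path, "barcodes.tsv"))
  } else {
    write.csv(as.data.frame(x), path, row.names = TRUE)
  }
  invisible(path)
}

#' Read a marker map
#'
#' JSON (`{"type": ["GENE1", ...]}`) or a two-column CSV with header
#' `cell_type,gene`.
#'
#' @param path File path ending in `.json` or `.csv`.
#' @return Named list mapping cell types to character vectors of gene ids.
#' @export
read_markers <- function(path) {
  if (!file.exists(path)) abort(sprintf("Markers file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    markers <- jsonlite::read_json(path, simplifyVector = TRUE)
    markers <- lapply(markers, as.character)
  } else {
    df <- read.csv(path)
    if (!all(c("cell_type", "gene") %in% names(df))) {
      abort("Marker CSV must have columns cell_type and gene.")
    }
    markers <- split(as.character(df$gene), as.character(df$cell_type))
  }
  check_marker_map(markers)
}

#' Write a marker map as JSON
#'
#' @param markers Named list mapping cell types to gene ids.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path) {
  check_marker_map(markers)
  jsonlite::write_json(markers, path, pretty = TRUE)
  invisible(path)
}

#' Read a cell-label table
#'
#' CSV with header `cell_id,cell_type`.
#'
#' @param path File path.
#' @return A tibble with columns `cell_id`, `cell_type`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort(sprintf("Labels file not found: %s", path))
  df <- read.csv(path, colClasses = "character")
  check_label_table(df)
  as_tibble(df[, c("cell_id", "cell_type")])
}
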