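# Internal validation helpers shared across modules.

# An expression matrix is a plain numeric matrix, genes in rows and cells in
# columns, with unique dimnames. Kept as base matrices (not a class): every
# operation in the package is a plain matrix transform, as in limma.
check_expr <- function(x, arg = "x", require_nonneg = FALSE) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix (genes x cells).", arg))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort(sprintf("`%s` must have gene rownames and cell colnames.", arg))
  }
  if (anyDuplicated(rownames(x))) {
    abort(sprintf("`%s` has duplicated gene ids.", arg))
  }
  if (anyDuplicated(colnames(x))) {
    abort(sprintf("`%s` has duplicated cell ids.", arg))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` contains NA or non-finite values.", arg))
  }
  if (require_nonneg && any(x < 0)) {
    abort(sprintf("`%s` must be elementwise non-negative.", arg))
  }
  invisible(x)
}

check_marker_map <- function(markers) {
  if (!is.list(markers) || is.null(names(markers)) ||
      any(!nzchar(names(markers)))) {
    abort("`markers` must be a named list mapping cell types to gene ids.")
  }
  if (anyDuplicated(names(markers))) {
    abort("`markers` has duplicated cell-type names.")
  }
  invisible(markers)
}

check_label_table <- function(labels) {
  if (!is.data.frame(labels) ||
      !all(c("cell_id", "cell_type") %in% names(labels))) {
    abort("`labels` must be a data frame with columns cell_id and cell_type.")
  }
  if (anyDuplicated(labels$cell_id)) {
    abort("`labels` has duplicated cell ids.")
  }
  invisible(labels)
}

check_count <- function(value, arg, min = 0) {
  if (!is.numeric(value) || length(value) != 1 || is.na(value) ||
      value < min || value != round(value)) {
    abort(sprintf("`%s` must be a single integer >= %d.", arg, min))
  }
  invisible(as.integer(value))
}

check_fraction <- function(value, arg) {
  if (!is.numeric(value) || length(value) != 1 || is.na(value) ||
      value < 0 || value > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1].", arg))
  }
  invisible(as.numeric(value))
}

# Run `expr` under a fixed seed when one is supplied, leaving the global RNG
# untouched; otherwise use the current RNG state.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# Row-wise argmax with lowest-index tie-break; rows of all equal values are
# still resolved to column 1 by max.col(ties.method = "first").
argmax_rows <- function(m) max.col(m, ties.method = "first")
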