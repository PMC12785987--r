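#' Build marker and label constraint matrices
#'
#' Encodes the two prior-knowledge constraints of the factorization as
#' binary matrices aligned with the feature matrix:
#'
#' * `M` (genes x types): for a marker gene, `M[i, k] = 1` iff gene i marks
#'   type k; rows of non-marker genes are all ones so those genes are
#'   unconstrained. The penalty `alpha * ||U (1 - M)||_1` (Hadamard product)
#'   then vanishes exactly on non-marker genes.
#' * `P` (cells x types): a labeled cell's row is one-hot on its type;
#'   unlabeled cells are all ones (unconstrained). The penalty
#'   `beta * ||V (1 - P)||_1` vanishes exactly on unlabeled cells.
#'
#' The number of factors `p` is the cardinality of the union of cell types
#' appearing in the marker map and the label table; factor columns are
#' ordered by lexicographic sort of the merged type names, and this order is
#' reused by the model and all metrics.
#'
#' @param markers Named list mapping cell types to marker gene ids.
#' @param labels Optional data frame with columns `cell_id`, `cell_type`
#'   giving known types for a subset of cells; `NULL` for no supervision.
#' @param feature_genes Ordered gene ids of the feature matrix rows.
#' @param cells Ordered cell ids of the feature matrix columns.
#'
#' @return A list of class `cellnmf_priors` with elements `M`, `P`,
#'   `cell_types`, `marker_genes` (genes with at least one annotation that
#'   are present in `feature_genes`), `labeled_cells`, `genes`, `cells`.
#' @export
#' @examples
#' markers <- list(A = c("g1", "g2"), B = "g3")
#' labels <- data.frame(cell_id = "c1", cell_type = "A")
#' pri <- build_priors(markers, labels, feature_genes = paste0("g", 1:4),
#'                     cells = paste0("c", 1:3))
#' pri$M
build_priors <- function(markers, labels = NULL, feature_genes, cells) {
  check_marker_map(markers)
  if (!is.null(labels)) check_label_table(labels)
  if (anyDuplicated(feature_genes) || anyDuplicated(cells)) {
    abort("`feature_genes` and `cells` must be unique.")
  }

  cell_types <- sort(unique(c(names(markers),
                              if (!is.null(labels)) as.character(labels$cell_type))))
  p <- length(cell_types)
  if (p == 0) {
    abort("Empty cell-type union: supply markers and/or labels for >= 1 type.")
  }

  m <- length(feature_genes)
  n <- length(cells)

  M <- matrix(1, m, p, dimnames = list(feature_genes, cell_types))
  marker_genes <- character(0)
  for (k in seq_along(cell_types)) {
    type <- cell_types[k]
    genes_k <- intersect(markers[[type]] %||% character(0), feature_genes)
    if (length(genes_k) == 0) next
    marker_genes <- union(marker_genes, genes_k)
  }
  if (length(marker_genes) > 0) {
    M[marker_genes, ] <- 0
    for (k in seq_along(cell_types)) {
      genes_k <- intersect(markers[[cell_types[k]]] %||% character(0),
                           feature_genes)
      M[genes_k, k] <- 1
    }
  }
  # preserve feature-matrix row order for the marker block
  marker_genes <- feature_genes[feature_genes %in% marker_genes]

  P <- matrix(1, n, p, dimnames = list(cells, cell_types))
  labeled_cells <- character(0)
  if (!is.null(labels) && nrow(labels) > 0) {
    ids <- as.character(labels$cell_id)
    unknown <- setdiff(ids, cells)
    if (length(unknown) > 0) {
      abort(sprintf("Labeled cell id(s) not found in the matrix: %s%s",
                    paste(head(unknown, 5), collapse = ", "),
                    if (length(unknown) > 5) ", ..." else ""))
    }
    P[ids, ] <- 0
    P[cbind(ids, as.character(labels$cell_type))] <- 1
    labeled_cells <- ids
  }

  structure(
    list(M = M, P = P, cell_types = cell_types, marker_genes = marker_genes,
         labeled_cells = labeled_cells, genes = feature_genes, cells = cells),
    class = "cellnmf_priors"
  )
}

#' @export
print.cellnmf_priors <- function(x, ...) {
  cat(sprintf("<cellnmf_priors> %d genes x %d cells, %d factor(s)\n",
              length(x$genes), length(x$cells), length(x$cell_types)))
  cat(sprintf("  cell types:    %s\n", paste(x$cell_types, collapse = ", ")))
  cat(sprintf("  marker genes:  %d\n", length(x$marker_genes)))
  cat(sprintf("  labeled cells: %d\n", length(x$labeled_cells)))
  invisible(x)
}

# Return a copy of the priors with supervision removed for `hide` cell ids
# (their P rows reset to all ones). Used by cross-validation in tuning.
hide_labels <- function(priors, hide) {
  stopifnot(inherits(priors, "cellnmf_priors"))
  hide <- intersect(hide, priors$labeled_cells)
  priors$P[hide, ] <- 1
  priors$labeled_cells <- setdiff(priors$labeled_cells, hide)
  priors
}
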