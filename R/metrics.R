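#' Annotation accuracy
#'
#' Percentage of cells whose predicted type equals the truth:
#' `100 * n_correct / n_all`.
#'
#' @param pred,truth Equal-length character vectors of predicted and true
#'   cell types.
#'
#' @return Accuracy as a percentage in `[0, 100]`.
#' @export
#' @examples
#' annotation_accuracy(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
annotation_accuracy <- function(pred, truth) {
  if (length(pred) == 0 || length(pred) != length(truth)) {
    abort("`pred` and `truth` must be non-empty vectors of equal length.")
  }
  100 * mean(as.character(pred) == as.character(truth))
}

per_class_stats <- function(pred, truth) {
  pred <- as.character(pred); truth <- as.character(truth)
  classes <- sort(unique(truth))
  res <- lapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    precision <- if (tp + fp == 0) {
      inform(sprintf("Class '%s' was never predicted; precision set to 0.", cl))
      0
    } else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    tibble(cell_type = cl, n = sum(truth == cl), precision = precision,
           recall = recall, f1 = f1)
  })
  dplyr::bind_rows(res)
}

#' Class-size-weighted F1 score
#'
#' Per-class F1 scores from one-vs-rest TP/FP/FN counts, averaged with
#' weights `n_i / sum(n_i)` (class sizes in the truth). Classes absent from
#' the truth carry zero weight; a class never predicted gets precision 0
#' (logged).
#'
#' @inheritParams annotation_accuracy
#' @return Weighted F1 in `[0, 1]`.
#' @export
weighted_f1 <- function(pred, truth) {
  if (length(pred) == 0 || length(pred) != length(truth)) {
    abort("`pred` and `truth` must be non-empty vectors of equal length.")
  }
  stats <- per_class_stats(pred, truth)
  sum(stats$f1 * stats$n) / sum(stats$n)
}

#' Full classification report
#'
#' Accuracy, per-class precision/recall/F1, weighted F1, and the confusion
#' matrix (truth in rows, prediction in columns).
#'
#' @inheritParams annotation_accuracy
#' @return A list of class `cellnmf_eval`: `accuracy` (percentage),
#'   `weighted_f1`, `per_class` (tibble), `confusion` (table).
#' @export
evaluation_report <- function(pred, truth) {
  if (length(pred) == 0 || length(pred) != length(truth)) {
    abort("`pred` and `truth` must be non-empty vectors of equal length.")
  }
  pred <- as.character(pred); truth <- as.character(truth)
  levels <- sort(unique(c(pred, truth)))
  confusion <- table(truth = factor(truth, levels),
                     pred = factor(pred, levels))
  stats <- per_class_stats(pred, truth)
  structure(
    list(accuracy = annotation_accuracy(pred, truth),
         weighted_f1 = sum(stats$f1 * stats$n) / sum(stats$n),
         per_class = stats, confusion = confusion),
    class = "cellnmf_eval"
  )
}

#' @export
print.cellnmf_eval <- function(x, ...) {
  cat(sprintf("<cellnmf_eval> accuracy %.2f%%, weighted F1 %.4f\n",
              x$accuracy, x$weighted_f1))
  print(x$per_class)
  invisible(x)
}

#' @method tidy cellnmf_eval
#' @export
tidy.cellnmf_eval <- function(x, ...) x$per_class

#' @method glance cellnmf_eval
#' @export
glance.cellnmf_eval <- function(x, ...) {
  tibble(accuracy = x$accuracy, weighted_f1 = x$weighted_f1,
         n = sum(x$per_class$n))
}

#' Marker-gene factor-consistency analysis
#'
#' Checks whether the learned gene-factor loadings recapitulate the known
#' marker structure. For each marker gene i, its dominant factor is
#' `k*(i) = argmax_k U[i, k]`. Counting, per cell type c, how many of its
#' markers dominate on each factor gives `n_{c->k}`; normalizing by the
#' type's marker count gives the cell-type-normalized proportion matrix
#' `P_{c->k}` (rows sum to 1). Each factor k is assigned the type
#' `c*(k) = argmax_c n_{c->k}` (unassigned when no marker dominates on k),
#' and the marker-gene accuracy is the fraction of annotated marker genes
#' whose dominant factor's assigned type is among the gene's annotated
#' types. Genes marking several types contribute weight `1/|C_i|` per
#' annotated type (reported in `weights`). Argmax ties break to the lowest
#' index.
#'
#' @param U Gene-factor loading matrix with gene rownames and factor
#'   (cell-type) colnames, e.g. `fit$U` from [cellnmf_fit()].
#' @param markers Named list mapping cell types to marker gene ids; genes
#'   absent from `rownames(U)` are ignored.
#'
#' @return A list of class `marker_consistency`: `P_ck` (type x factor
#'   proportion matrix), `factor_assignment` (named character vector
#'   `c*(k)`, `NA` for unassigned factors), `accuracy_marker` in `[0, 1]`,
#'   `dominant_factor` (tibble `gene`, `factor`, `correct`), `weights`
#'   (tibble `gene`, `cell_type`, `weight`).
#' @export
marker_consistency <- function(U, markers) {
  if (inherits(U, "cellnmf_fit")) U <- U$U
  if (!is.matrix(U) || is.null(rownames(U)) || is.null(colnames(U))) {
    abort("`U` must be a matrix with gene rownames and factor colnames.")
  }
  check_marker_map(markers)
  factors <- colnames(U)
  types <- names(markers)
  markers <- lapply(markers, function(g) intersect(g, rownames(U)))

  marker_genes <- unique(unlist(markers, use.names = FALSE))
  if (length(marker_genes) == 0) {
    abort("No marker gene is present among the rows of `U`.")
  }
  # annotated type set C_i per gene
  C <- lapply(setNames(marker_genes, marker_genes), function(g) {
    types[vapply(markers, function(set) g %in% set, logical(1))]
  })

  k_star <- setNames(
    factors[argmax_rows(U[marker_genes, , drop = FALSE])],
    marker_genes
  )

  n_ck <- matrix(0L, length(types), length(factors),
                 dimnames = list(types, factors))
  for (c in types) {
    for (g in markers[[c]]) {
      n_ck[c, k_star[g]] <- n_ck[c, k_star[g]] + 1L
    }
  }
  sizes <- vapply(markers, length, integer(1))
  P_ck <- sweep(n_ck, 1, pmax(sizes, 1), "/")

  factor_assignment <- apply(n_ck, 2, function(col) {
    if (all(col == 0)) NA_character_ else types[which.max(col)]
  })

  assigned_type <- setNames(unname(factor_assignment[k_star]), marker_genes)
  correct <- vapply(marker_genes, function(g) {
    at <- assigned_type[[g]]
    !is.na(at) && at %in% C[[g]]
  }, logical(1))
  accuracy_marker <- mean(correct)

  weights <- dplyr::bind_rows(lapply(marker_genes, function(g) {
    tibble(gene = g, cell_type = C[[g]], weight = 1 / length(C[[g]]))
  }))

  structure(
    list(P_ck = P_ck, factor_assignment = factor_assignment,
         accuracy_marker = accuracy_marker,
         dominant_factor = tibble(gene = marker_genes,
                                  factor = unname(k_star),
                                  correct = unname(correct)),
         weights = weights),
    class = "marker_consistency"
  )
}

#' @export
print.marker_consistency <- function(x, ...) {
  cat(sprintf("<marker_consistency> marker-gene accuracy %.4f\n",
              x$accuracy_marker))
  cat("P_{c->k} (rows: cell types, columns: factors):\n")
  print(round(x$P_ck, 3))
  invisible(x)
}

#' @describeIn marker_consistency Heatmap of the `P_{c->k}` matrix.
#' @param object A `marker_consistency` object.
#' @param ... Ignored.
#' @method autoplot marker_consistency
#' @export
autoplot.marker_consistency <- function(object, ...) {
  df <- as.data.frame.table(object$P_ck, responseName = "proportion")
  names(df)[1:2] <- c("cell_type", "factor")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$cell_type,
                                   fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "Latent factor", y = "Cell type",
                  fill = expression(P[c %->% k])) +
    ggplot2::theme_minimal()
}
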