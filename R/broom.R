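# broom-style accessors and diagnostic plots for fitted models.

#' Tidy a fitted factorization
#'
#' @param x A `cellnmf_fit`.
#' @param matrix Which component to tidy: `"assignments"` (default; the
#'   per-cell annotation, as from [annotate_cells()]), `"u"` (gene-factor
#'   loadings, long form) or `"v"` (cell-factor coefficients, long form).
#' @param ... Ignored.
#'
#' @return A tibble.
#' @method tidy cellnmf_fit
#' @export
tidy.cellnmf_fit <- function(x, matrix = c("assignments", "u", "v"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "assignments") return(annotate_cells(x))
  m <- if (matrix == "u") x$U else x$V
  id_col <- if (matrix == "u") "gene" else "cell_id"
  val_col <- if (matrix == "u") "loading" else "coefficient"
  df <- as.data.frame.table(m, responseName = val_col)
  names(df)[1:2] <- c(id_col, "cell_type")
  as_tibble(lapply(df, function(col) if (is.factor(col)) as.character(col) else col))
}

#' One-row summary of a fitted factorization
#'
#' @param x A `cellnmf_fit`.
#' @param ... Ignored.
#' @return A tibble with columns `n_genes`, `n_cells`, `n_factors`,
#'   `n_iter`, `converged`, `objective`.
#' @method glance cellnmf_fit
#' @export
glance.cellnmf_fit <- function(x, ...) {
  tibble(
    n_genes = nrow(x$U), n_cells = nrow(x$V), n_factors = ncol(x$U),
    n_iter = x$n_iter, converged = x$converged,
    objective = x$objective_trace[length(x$objective_trace)]
  )
}

#' Objective-trace diagnostic plot
#'
#' @param object A `cellnmf_fit`.
#' @param ... Ignored.
#' @return A ggplot of the objective value per iteration (iteration 0 is
#'   the initialization).
#' @method autoplot cellnmf_fit
#' @export
autoplot.cellnmf_fit <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$objective_trace) - 1,
               objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Iteration", y = "Objective") +
    ggplot2::theme_minimal()
}
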