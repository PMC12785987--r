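#' Mutual K-nearest-neighbor edges between cells
#'
#' Computes Euclidean distances between cells (columns) in the preprocessed
#' expression space and keeps an undirected edge (j1, j2) only when each
#' endpoint is among the K nearest neighbors of the other. Ties at the K-th
#' neighbor distance are all included; self-edges are excluded.
#'
#' @param x Preprocessed expression matrix (genes x cells).
#' @param k Neighbor count, `1 <= k < ncol(x)`. Default
#'   `min(floor(n/3), 1000)` where n is the number of cells.
#'
#' @return A tibble with columns `cell_i`, `cell_j` (cell ids, each
#'   undirected edge once), and `distance`; the full ordered cell-id vector
#'   is attached as attribute `"cells"` and `k` as attribute `"k"`.
#' @export
mutual_knn_edges <- function(x, k = NULL) {
  check_expr(x)
  n <- ncol(x)
  k <- k %||% max(1L, min(floor(n / 3), 1000L))
  check_count(k, "k", min = 1)
  if (k >= n) abort(sprintf("`k` (%d) must be smaller than the number of cells (%d).", k, n))

  d <- as.matrix(dist(t(x)))
  nn <- matrix(FALSE, n, n)
  for (j in seq_len(n)) {
    dj <- d[, j]
    dj[j] <- Inf
    kth <- sort(dj, partial = k)[k]
    nn[dj <= kth, j] <- TRUE  # ties at the K-th distance all included
  }
  mutual <- nn & t(nn)
  idx <- which(mutual & upper.tri(mutual), arr.ind = TRUE)
  cells <- colnames(x)
  edges <- tibble(
    cell_i = cells[idx[, 1]],
    cell_j = cells[idx[, 2]],
    distance = d[idx]
  )
  attr(edges, "cells") <- cells
  attr(edges, "k") <- as.integer(k)
  edges
}

#' Gaussian edge weights and graph Laplacian
#'
#' Converts mutual-KNN edge distances into affinities
#' `w = exp(-d^2 / (2 sigma^2))` and assembles the symmetric affinity matrix
#' W, the degree matrix D and the unnormalized Laplacian `L = D - W`. The
#' bandwidth `sigma` defaults to the median of the retained edge distances
#' (each undirected edge counted once); if that median is zero because of
#' duplicated cells but positive distances exist, the median of the positive
#' distances is used instead (with a warning).
#'
#' @param edges Edge tibble from [mutual_knn_edges()].
#' @param sigma Optional bandwidth override (> 0).
#' @param cells Ordered cell ids; defaults to the `"cells"` attribute of
#'   `edges`.
#'
#' @return A list of class `cell_graph` with elements `W` (n x n matrix),
#'   `D` (degree vector), `L` (Laplacian matrix), `k`, `sigma`, `cells`.
#' @export
gaussian_weights <- function(edges, sigma = NULL, cells = attr(edges, "cells")) {
  if (!is.data.frame(edges) ||
      !all(c("cell_i", "cell_j", "distance") %in% names(edges))) {
    abort("`edges` must have columns cell_i, cell_j, distance.")
  }
  if (is.null(cells)) abort("`cells` must be supplied (or present as an attribute of `edges`).")
  if (nrow(edges) == 0) {
    abort("The mutual-KNN graph has no edges; increase `k`.")
  }
  if (is.null(sigma)) {
    sigma <- median(edges$distance)
    if (sigma == 0) {
      pos <- edges$distance[edges$distance > 0]
      if (length(pos) == 0) {
        abort("All edge distances are zero (duplicated cells); supply `sigma` explicitly.")
      }
      warn("Median edge distance is zero; using the median of positive distances as `sigma`.")
      sigma <- median(pos)
    }
  }
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    abort("`sigma` must be a single positive number.")
  }

  n <- length(cells)
  W <- matrix(0, n, n, dimnames = list(cells, cells))
  i <- match(edges$cell_i, cells)
  j <- match(edges$cell_j, cells)
  if (anyNA(i) || anyNA(j)) abort("Edge cell ids not found in `cells`.")
  w <- exp(-edges$distance^2 / (2 * sigma^2))
  W[cbind(i, j)] <- w
  W[cbind(j, i)] <- w
  D <- rowSums(W)
  L <- diag(D, n) - W
  dimnames(L) <- dimnames(W)
  structure(
    list(W = W, D = D, L = L, k = attr(edges, "k"), sigma = sigma, cells = cells),
    class = "cell_graph"
  )
}

#' Build the cell graph in one step
#'
#' Convenience wrapper: [mutual_knn_edges()] followed by
#' [gaussian_weights()].
#'
#' @inheritParams mutual_knn_edges
#' @inheritParams gaussian_weights
#' @return A `cell_graph` (see [gaussian_weights()]).
#' @export
build_cell_graph <- function(x, k = NULL, sigma = NULL) {
  gaussian_weights(mutual_knn_edges(x, k = k), sigma = sigma)
}

#' @export
print.cell_graph <- function(x, ...) {
  n_edges <- sum(x$W > 0) / 2
  cat(sprintf("<cell_graph> %d cells, %d mutual-KNN edges (k = %s, sigma = %.4g)\n",
              length(x$cells), n_edges, x$k %||% "?", x$sigma))
  cat(sprintf("  isolated cells: %d\n", sum(x$D == 0)))
  invisible(x)
}

#' Graph smoothness penalty Tr(V' L V)
#'
#' Evaluates the Laplacian quadratic form over cell-factor coefficients,
#' equal to `1/2 * sum_{j1,j2} w_{j1j2} ||V[j1,] - V[j2,]||^2`.
#'
#' @param V Numeric matrix with one row per cell (cells x factors).
#' @param graph A `cell_graph`.
#'
#' @return A single number, `Tr(V' L V)`.
#' @export
laplacian_quadratic <- function(V, graph) {
  stopifnot(inherits(graph, "cell_graph"))
  if (!is.matrix(V)) V <- as.matrix(V)
  if (nrow(V) != length(graph$cells)) {
    abort(sprintf("`V` has %d rows but the graph has %d cells.",
                  nrow(V), length(graph$cells)))
  }
  sum(V * (graph$L %*% V))
}

#' Export graph edges for inspection
#'
#' @param graph A `cell_graph`.
#' @return A tibble with columns `cell_i`, `cell_j`, `weight`.
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "cell_graph"))
  idx <- which(graph$W > 0 & upper.tri(graph$W), arr.ind = TRUE)
  tibble(
    cell_i = graph$cells[idx[, 1]],
    cell_j = graph$cells[idx[, 2]],
    weight = graph$W[idx]
  )
}
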