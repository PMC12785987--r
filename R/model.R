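#' Model configuration
#'
#' Weights and optimizer settings for the regularized factorization. The
#' defaults are the within-dataset settings: marker weight `alpha = 1e4`,
#' label weight `beta = 1e4`, graph weight `gamma = 10`, and sparsity weight
#' `alpha0 = 50`.
#'
#' @param alpha0 Sparsity weight on `||U||_1` (stabilizes the scale of U).
#' @param alpha Marker-constraint weight on `||U (1 - M)||_1`.
#' @param beta Label-supervision weight on `||V (1 - P)||_1`.
#' @param gamma Graph-regularization weight on `Tr(V' L V)`.
#' @param max_iter Maximum number of update iterations (one iteration = one
#'   U update followed by one V update). Default 50.
#' @param rel_tol Relative objective-change convergence tolerance. Default
#'   `1e-4`.
#' @param seed Optional RNG seed for the random initialization.
#' @param eps Small positive guard added to update denominators. Default
#'   `1e-12`.
#' @param init Initialization: `"random"` (uniform on (0, 1], the default)
#'   or `"nndsvd"` (SVD-based).
#'
#' @return A list of class `cellnmf_config`.
#' @export
cellnmf_config <- function(alpha0 = 50, alpha = 1e4, beta = 1e4, gamma = 10,
                           max_iter = 50, rel_tol = 1e-4, seed = NULL,
                           eps = 1e-12, init = c("random", "nndsvd")) {
  for (w in c("alpha0", "alpha", "beta", "gamma")) {
    val <- get(w)
    if (!is.numeric(val) || length(val) != 1 || is.na(val) || val < 0) {
      abort(sprintf("`%s` must be a single non-negative number.", w))
    }
  }
  check_count(max_iter, "max_iter", min = 1)
  if (!is.numeric(rel_tol) || rel_tol <= 0) abort("`rel_tol` must be > 0.")
  if (!is.numeric(eps) || eps <= 0) abort("`eps` must be > 0.")
  structure(
    list(alpha0 = alpha0, alpha = alpha, beta = beta, gamma = gamma,
         max_iter = as.integer(max_iter), rel_tol = rel_tol, seed = seed,
         eps = eps, init = match.arg(init)),
    class = "cellnmf_config"
  )
}

#' @export
print.cellnmf_config <- function(x, ...) {
  cat(sprintf(paste0("<cellnmf_config> alpha0 = %g, alpha = %g, beta = %g, ",
                     "gamma = %g\n  max_iter = %d, rel_tol = %g, init = %s, seed = %s\n"),
              x$alpha0, x$alpha, x$beta, x$gamma, x$max_iter, x$rel_tol,
              x$init, if (is.null(x$seed)) "NULL" else format(x$seed)))
  invisible(x)
}

check_model_dims <- function(x, U, V, priors, graph = NULL) {
  m <- nrow(x); n <- ncol(x)
  p <- length(priors$cell_types)
  if (!all(dim(U) == c(m, p))) abort("`U` must be genes x factors.")
  if (!all(dim(V) == c(n, p))) abort("`V` must be cells x factors.")
  if (!all(dim(priors$M) == c(m, p))) abort("Prior matrix M does not match the data dimensions.")
  if (!all(dim(priors$P) == c(n, p))) abort("Prior matrix P does not match the data dimensions.")
  if (!is.null(graph) && length(graph$cells) != n) {
    abort("The graph was built on a different number of cells.")
  }
  if (anyNA(U) || anyNA(V) || any(!is.finite(U)) || any(!is.finite(V))) {
    abort("`U`/`V` contain NA or non-finite values.")
  }
  invisible(NULL)
}

#' Regularized factorization objective
#'
#' Evaluates the full objective
#' `||X - U V'||_F^2 + alpha0 ||U||_1 + alpha ||U (1-M)||_1 +
#'  beta ||V (1-P)||_1 + gamma Tr(V' L V)`
#' (Hadamard products inside the L1 norms; all factors non-negative so the
#' L1 norms are plain sums).
#'
#' @param x Non-negative expression matrix (genes x cells).
#' @param U Gene-factor loadings (genes x factors), non-negative.
#' @param V Cell-factor coefficients (cells x factors), non-negative.
#' @param priors A `cellnmf_priors`.
#' @param graph A `cell_graph`, required when `gamma > 0`.
#' @param config A [cellnmf_config()].
#'
#' @return The objective value (single number).
#' @export
cellnmf_objective <- function(x, U, V, priors, graph = NULL,
                              config = cellnmf_config()) {
  check_expr(x, require_nonneg = TRUE)
  check_model_dims(x, U, V, priors, graph)
  r <- x - U %*% t(V)
  obj <- sum(r * r) +
    config$alpha0 * sum(U) +
    config$alpha * sum(U * (1 - priors$M)) +
    config$beta * sum(V * (1 - priors$P))
  if (config$gamma > 0) {
    if (is.null(graph)) abort("`graph` is required when gamma > 0.")
    obj <- obj + config$gamma * laplacian_quadratic(V, graph)
  }
  obj
}

#' Multiplicative update of the gene-factor loadings
#'
#' One step of
#' `u <- u * (2 X V) / (2 U V'V + alpha0 + alpha (1-M))`,
#' with the denominator guarded below by `eps`. Zero entries are fixed
#' points, and non-negativity is preserved.
#'
#' @inheritParams cellnmf_objective
#' @return Updated U.
#' @export
update_u <- function(x, U, V, priors, config = cellnmf_config()) {
  num <- 2 * (x %*% V)
  den <- 2 * U %*% crossprod(V) + config$alpha0 + config$alpha * (1 - priors$M)
  U * num / pmax(den, config$eps)
}

#' Multiplicative update of the cell-factor coefficients
#'
#' One step of
#' `v <- v * 2(X'U + gamma W V) / (2 V U'U + beta (1-P) + 2 gamma D V)`,
#' with the denominator guarded below by `eps`.
#'
#' @inheritParams cellnmf_objective
#' @return Updated V.
#' @export
update_v <- function(x, U, V, priors, graph = NULL,
                     config = cellnmf_config()) {
  num <- 2 * crossprod(x, U)
  den <- 2 * V %*% crossprod(U) + config$beta * (1 - priors$P)
  if (config$gamma > 0) {
    if (is.null(graph)) abort("`graph` is required when gamma > 0.")
    num <- num + 2 * config$gamma * (graph$W %*% V)
    den <- den + 2 * config$gamma * (graph$D * V)
  }
  V * num / pmax(den, config$eps)
}

# NNDSVD initialization (Boutsidis & Gallopoulos 2008), with zeros replaced
# by a small positive fill so multiplicative updates are not locked.
init_nndsvd <- function(x, p) {
  s <- svd(x, nu = p, nv = p)
  U <- matrix(0, nrow(x), p)
  V <- matrix(0, ncol(x), p)
  U[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  V[, 1] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (p > 1) {
    for (k in 2:p) {
      u <- s$u[, k]; v <- s$v[, k]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
      nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
      if (npos >= nneg && npos > 0) {
        U[, k] <- sqrt(s$d[k] * npos) * up / sqrt(sum(up^2))
        V[, k] <- sqrt(s$d[k] * npos) * vp / sqrt(sum(vp^2))
      } else if (nneg > 0) {
        U[, k] <- sqrt(s$d[k] * nneg) * un / sqrt(sum(un^2))
        V[, k] <- sqrt(s$d[k] * nneg) * vn / sqrt(sum(vn^2))
      }
    }
  }
  fill <- 1e-6 * mean(x)
  U[U <= 0] <- fill
  V[V <= 0] <- fill
  list(U = U, V = V)
}

#' Fit the regularized factorization
#'
#' Alternates the multiplicative U and V updates from a strictly positive
#' random initialization (uniform on (0, 1]) until the relative change in
#' the objective falls below `rel_tol` or `max_iter` iterations are reached.
#' The number of factors equals the number of cell types in `priors`.
#' Reproducible given `config$seed`.
#'
#' @param x Preprocessed non-negative matrix (genes x cells), with gene and
#'   cell order matching `priors`.
#' @param priors A `cellnmf_priors` built on the same genes and cells.
#' @param graph A `cell_graph` over the same cells; required when
#'   `config$gamma > 0`.
#' @param config A [cellnmf_config()].
#'
#' @return An object of class `cellnmf_fit` with elements `U`, `V`
#'   (dimnamed by gene/cell ids and cell types), `objective_trace` (the
#'   initial objective followed by one value per iteration), `converged`,
#'   `n_iter`, `cell_types`, `labeled_cells`, `marker_genes`, `config`.
#' @export
#' @examples
#' sim <- simulate_cells(sim_config(n_cells = 60, n_types = 2,
#'                                  markers_per_type = 5,
#'                                  n_background_genes = 20, seed = 1))
#' pri <- build_priors(sim$markers, head(sim$labels, 10),
#'                     feature_genes = rownames(sim$matrix),
#'                     cells = colnames(sim$matrix))
#' g <- build_cell_graph(sim$matrix, k = 10)
#' fit <- cellnmf_fit(sim$matrix, pri, g, cellnmf_config(seed = 1))
#' fit
cellnmf_fit <- function(x, priors, graph = NULL, config = cellnmf_config()) {
  check_expr(x, require_nonneg = TRUE)
  if (nrow(x) == 0 || ncol(x) == 0) abort("`x` is empty.")
  if (!inherits(priors, "cellnmf_priors")) abort("`priors` must come from build_priors().")
  if (!identical(rownames(x), priors$genes) ||
      !identical(colnames(x), priors$cells)) {
    abort("Gene/cell order of `x` does not match `priors`.")
  }
  m <- nrow(x); n <- ncol(x); p <- length(priors$cell_types)

  init <- with_seed_if(config$seed, {
    if (config$init == "nndsvd") {
      init_nndsvd(x, p)
    } else {
      list(U = matrix(runif(m * p), m, p), V = matrix(runif(n * p), n, p))
    }
  })
  U <- init$U; V <- init$V

  obj <- cellnmf_objective(x, U, V, priors, graph, config)
  trace <- numeric(config$max_iter + 1)
  trace[1] <- obj
  converged <- FALSE
  n_iter <- 0L
  for (t in seq_len(config$max_iter)) {
    U <- update_u(x, U, V, priors, config)
    V <- update_v(x, U, V, priors, graph, config)
    obj_new <- cellnmf_objective(x, U, V, priors, graph, config)
    trace[t + 1] <- obj_new
    n_iter <- t
    if (obj == 0 || abs(obj_new - obj) / obj < config$rel_tol) {
      converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }

  dimnames(U) <- list(priors$genes, priors$cell_types)
  dimnames(V) <- list(priors$cells, priors$cell_types)
  structure(
    list(U = U, V = V, objective_trace = trace[seq_len(n_iter + 1)],
         converged = converged, n_iter = n_iter,
         cell_types = priors$cell_types, labeled_cells = priors$labeled_cells,
         marker_genes = priors$marker_genes, config = config),
    class = "cellnmf_fit"
  )
}

#' @export
print.cellnmf_fit <- function(x, ...) {
  cat(sprintf("<cellnmf_fit> %d genes x %d cells, %d factor(s)\n",
              nrow(x$U), nrow(x$V), ncol(x$U)))
  cat(sprintf("  %d iteration(s), %s (final objective %.6g)\n", x$n_iter,
              if (x$converged) "converged" else "max_iter reached",
              x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

#' Annotate cells from a fitted model
#'
#' Assigns each cell the type of the factor with the largest coefficient in
#' its row of V, ties broken by lowest factor index. A cell whose V row is
#' all zeros gets the sentinel `"unassigned"` (with a warning).
#'
#' @param fit A `cellnmf_fit`.
#'
#' @return A tibble with columns `cell_id`, `cell_type`, `score` (the
#'   winning coefficient).
#' @export
annotate_cells <- function(fit) {
  stopifnot(inherits(fit, "cellnmf_fit"))
  V <- fit$V
  best <- argmax_rows(V)
  type <- fit$cell_types[best]
  score <- V[cbind(seq_len(nrow(V)), best)]
  zero_rows <- rowSums(V) == 0
  if (any(zero_rows)) {
    warn(sprintf("%d cell(s) have all-zero coefficients; marked 'unassigned'.",
                 sum(zero_rows)))
    type[zero_rows] <- "unassigned"
  }
  tibble(cell_id = rownames(V), cell_type = type, score = score)
}

#' Hyperparameter grid search by cross-validated accuracy
#'
#' Evaluates every combination of the supplied weight grids by k-fold
#' cross-validation over the labeled cells: each fold's labels are hidden
#' from P, the model is refit, and annotation accuracy is scored on the
#' held-out labeled cells. Folds are stratified by cell type. The
#' combination with the highest mean CV accuracy wins; ties go to the
#' smallest weights (grid evaluated in ascending `(gamma, beta, alpha)`
#' order).
#'
#' @inheritParams cellnmf_fit
#' @param alpha,beta,gamma Numeric vectors of candidate weights. Defaults
#'   are the two-stage search grids `alpha, beta in {1e2, 1e3, 1e4, 1e5}`
#'   and `gamma in {0.1, 1, 10, 100}`.
#' @param folds Number of CV folds. Default 5.
#' @param config Base configuration supplying `alpha0`, optimizer settings
#'   and the seed; the searched weights override its `alpha`, `beta`,
#'   `gamma`.
#'
#' @return A list of class `cellnmf_tune`: `best_config` (a
#'   [cellnmf_config()]) and `cv` (tibble with columns `alpha`, `beta`,
#'   `gamma`, `mean_accuracy`, `se_accuracy`).
#' @export
cellnmf_tune <- function(x, priors, graph = NULL,
                         alpha = 10^(2:5), beta = 10^(2:5),
                         gamma = c(0.1, 1, 10, 100),
                         folds = 5, config = cellnmf_config()) {
  check_count(folds, "folds", min = 2)
  labeled <- priors$labeled_cells
  if (length(labeled) < folds) {
    abort(sprintf(paste("Only %d labeled cell(s) for %d folds; supply more labels",
                        "or reduce `folds`."), length(labeled), folds))
  }
  truth <- priors$cell_types[argmax_rows(priors$P[labeled, , drop = FALSE])]
  names(truth) <- labeled

  # stratified fold assignment, reproducible under config$seed
  fold_of <- with_seed_if(config$seed, {
    f <- integer(length(labeled))
    names(f) <- labeled
    for (type in unique(truth)) {
      ids <- sample(labeled[truth == type])
      f[ids] <- rep_len(seq_len(folds), length(ids))
    }
    f
  })

  grid <- expand.grid(alpha = sort(alpha), beta = sort(beta),
                      gamma = sort(gamma))
  grid <- grid[order(grid$gamma, grid$beta, grid$alpha), , drop = FALSE]

  acc <- matrix(NA_real_, nrow(grid), folds)
  for (g in seq_len(nrow(grid))) {
    cfg <- config
    cfg$alpha <- grid$alpha[g]; cfg$beta <- grid$beta[g]
    cfg$gamma <- grid$gamma[g]
    for (f in seq_len(folds)) {
      held <- labeled[fold_of == f]
      if (length(held) == 0) next
      fit <- cellnmf_fit(x, hide_labels(priors, held), graph, cfg)
      pred <- annotate_cells(fit)
      pred_held <- pred$cell_type[match(held, pred$cell_id)]
      acc[g, f] <- mean(pred_held == truth[held])
    }
  }
  mean_acc <- rowMeans(acc, na.rm = TRUE)
  se_acc <- apply(acc, 1, function(a) {
    a <- a[!is.na(a)]
    if (length(a) > 1) sd(a) / sqrt(length(a)) else NA_real_
  })
  best <- which.max(mean_acc)  # first max = smallest weights in grid order
  best_config <- config
  best_config$alpha <- grid$alpha[best]
  best_config$beta <- grid$beta[best]
  best_config$gamma <- grid$gamma[best]

  structure(
    list(
      best_config = best_config,
      cv = tibble(alpha = grid$alpha, beta = grid$beta, gamma = grid$gamma,
                  mean_accuracy = mean_acc, se_accuracy = se_acc)
    ),
    class = "cellnmf_tune"
  )
}

#' @export
print.cellnmf_tune <- function(x, ...) {
  b <- x$best_config
  cat(sprintf("<cellnmf_tune> best: alpha = %g, beta = %g, gamma = %g (CV accuracy %.4f)\n",
              b$alpha, b$beta, b$gamma, max(x$cv$mean_accuracy)))
  invisible(x)
}
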