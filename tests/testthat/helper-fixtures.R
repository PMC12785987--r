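# Fixtures built in code: toy matrices, random model instances, and
# independent (loop-based) oracles used to cross-check the vectorized
# implementation.

named_matrix <- function(values, nrow, ncol, gene_prefix = "g", cell_prefix = "c") {
  matrix(values, nrow, ncol,
         dimnames = list(sprintf("%s%02d", gene_prefix, seq_len(nrow)),
                         sprintf("%s%02d", cell_prefix, seq_len(ncol))))
}

# Random non-negative problem instance with priors and graph, for
# property-style tests over the optimizer.
random_instance <- function(m = 8, n = 12, p = 3, seed = 1) {
  withr::with_seed(seed, {
    x <- named_matrix(runif(m * n, 0, 5), m, n)
    types <- paste0("T", seq_len(p))
    n_mark <- min(2 * p, m)
    markers <- split(sample(rownames(x), n_mark),
                     rep(types, length.out = n_mark))
    n_lab <- max(2, n %/% 4)
    labels <- data.frame(cell_id = sample(colnames(x), n_lab),
                         cell_type = sample(types, n_lab, replace = TRUE))
    priors <- build_priors(markers, labels, rownames(x), colnames(x))
    graph <- build_cell_graph(x, k = max(2, n %/% 3))
    list(x = x, priors = priors, graph = graph, markers = markers,
         labels = labels)
  })
}

# Term-by-term loop recomputation of the objective; deliberately naive and
# independent of the package's vectorized code path.
oracle_objective <- function(x, U, V, M, P, W, alpha0, alpha, beta, gamma) {
  m <- nrow(x); n <- ncol(x); p <- ncol(U)
  recon <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    fit_ij <- 0
    for (k in seq_len(p)) fit_ij <- fit_ij + U[i, k] * V[j, k]
    recon <- recon + (x[i, j] - fit_ij)^2
  }
  pen_u0 <- 0; pen_u <- 0
  for (i in seq_len(m)) for (k in seq_len(p)) {
    pen_u0 <- pen_u0 + abs(U[i, k])
    pen_u <- pen_u + abs(U[i, k]) * (1 - M[i, k])
  }
  pen_v <- 0
  for (j in seq_len(n)) for (k in seq_len(p)) {
    pen_v <- pen_v + abs(V[j, k]) * (1 - P[j, k])
  }
  graph_term <- 0
  for (j1 in seq_len(n)) for (j2 in seq_len(n)) {
    d2 <- sum((V[j1, ] - V[j2, ])^2)
    graph_term <- graph_term + W[j1, j2] * d2
  }
  recon + alpha0 * pen_u0 + alpha * pen_u + beta * pen_v +
    gamma * graph_term / 2
}

# Pairwise-sum form of the Laplacian quadratic (the identity the Laplacian
# must satisfy), computed with explicit loops.
oracle_pairwise_quadratic <- function(V, W) {
  n <- nrow(V)
  total <- 0
  for (j1 in seq_len(n)) for (j2 in seq_len(n)) {
    total <- total + W[j1, j2] * sum((V[j1, ] - V[j2, ])^2)
  }
  total / 2
}

# Textbook multiplicative-update NMF (reconstruction term only), used as
# the independent reference for the unregularized limit.
reference_nmf <- function(x, U, V, n_iter) {
  for (t in seq_len(n_iter)) {
    U <- U * (x %*% V) / (U %*% crossprod(V) + 1e-9)
    V <- V * (crossprod(x, U)) / (V %*% crossprod(U) + 1e-9)
  }
  list(U = U, V = V, err = sum((x - U %*% t(V))^2))
}

# Small simulated benchmark (fast variant of the default configuration).
small_sim <- function(seed = 1, ...) {
  simulate_cells(sim_config(n_cells = 120, n_types = 3, markers_per_type = 5,
                            n_background_genes = 30, seed = seed, ...))
}
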