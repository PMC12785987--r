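test_that("objective matches a term-by-term loop recomputation", {
  inst <- random_instance(m = 5, n = 8, p = 2, seed = 3)
  cfg <- cellnmf_config(alpha0 = 7, alpha = 11, beta = 13, gamma = 3)
  withr::local_seed(4)
  U <- matrix(runif(5 * 2), 5, 2)
  V <- matrix(runif(8 * 2), 8, 2)
  expect_equal(
    cellnmf_objective(inst$x, U, V, inst$priors, inst$graph, cfg),
    oracle_objective(inst$x, U, V, inst$priors$M, inst$priors$P,
                     inst$graph$W, 7, 11, 13, 3),
    tolerance = 1e-10
  )

  # all weights zero: objective collapses to the reconstruction term
  cfg0 <- cellnmf_config(alpha0 = 0, alpha = 0, beta = 0, gamma = 0)
  expect_equal(
    cellnmf_objective(inst$x, 0 * U, 0 * V, inst$priors, NULL, cfg0),
    sum(inst$x^2)
  )
  # exact factorization with zero weights: objective 0
  Ue <- matrix(1, 5, 2); Ve <- matrix(1, 8, 2)
  xe <- Ue %*% t(Ve)
  dimnames(xe) <- dimnames(inst$x)
  expect_equal(cellnmf_objective(xe, Ue, Ve, inst$priors, NULL, cfg0), 0)

  bad <- inst$x; bad[1, 1] <- NA
  expect_error(cellnmf_objective(bad, U, V, inst$priors, inst$graph, cfg))
})

test_that("multiplicative updates keep zeros fixed and reduce the objective", {
  inst <- random_instance(m = 8, n = 10, p = 3, seed = 8)
  cfg <- cellnmf_config(alpha0 = 5, alpha = 20, beta = 20, gamma = 2)
  withr::local_seed(5)
  U <- matrix(runif(8 * 3), 8, 3); U[2, 1] <- 0
  V <- matrix(runif(10 * 3), 10, 3); V[4, 2] <- 0

  U2 <- update_u(inst$x, U, V, inst$priors, cfg)
  expect_equal(unname(U2[2, 1]), 0)
  expect_true(all(U2 >= 0))
  obj_before <- cellnmf_objective(inst$x, U, V, inst$priors, inst$graph, cfg)
  obj_mid <- cellnmf_objective(inst$x, U2, V, inst$priors, inst$graph, cfg)
  expect_lte(obj_mid, obj_before * (1 + 1e-12))

  V2 <- update_v(inst$x, U2, V, inst$priors, inst$graph, cfg)
  expect_equal(unname(V2[4, 2]), 0)
  expect_true(all(V2 >= 0))
  obj_after <- cellnmf_objective(inst$x, U2, V2, inst$priors, inst$graph, cfg)
  expect_lte(obj_after, obj_mid * (1 + 1e-12))
})

test_that("with all penalties off the updates are the plain Lee-Seung rule", {
  inst <- random_instance(m = 6, n = 7, p = 2, seed = 12)
  cfg0 <- cellnmf_config(alpha0 = 0, alpha = 0, beta = 0, gamma = 0)
  withr::local_seed(6)
  U <- matrix(runif(6 * 2), 6, 2)
  V <- matrix(runif(7 * 2), 7, 2)
  U_ls <- U * (inst$x %*% V) / (U %*% crossprod(V))
  expect_equal(update_u(inst$x, U, V, inst$priors, cfg0), U_ls,
               tolerance = 1e-10)
  V_ls <- V * crossprod(inst$x, U) / (V %*% crossprod(U))
  expect_equal(update_v(inst$x, U, V, inst$priors, NULL, cfg0), V_ls,
               tolerance = 1e-10)
})

test_that("unregularized solver matches an independent NMF reference", {
  inst <- random_instance(m = 10, n = 14, p = 3, seed = 21)
  cfg0 <- cellnmf_config(alpha0 = 0, alpha = 0, beta = 0, gamma = 0,
                         max_iter = 80, rel_tol = 1e-12, seed = 99)
  fit <- cellnmf_fit(inst$x, inst$priors, NULL, cfg0)
  init <- withr::with_seed(99, {
    list(U = matrix(runif(10 * 3), 10, 3), V = matrix(runif(14 * 3), 14, 3))
  })
  ref <- reference_nmf(inst$x, init$U, init$V, n_iter = fit$n_iter)
  err_fit <- sum((inst$x - fit$U %*% t(fit$V))^2)
  expect_equal(err_fit, ref$err, tolerance = 1e-6)
})

test_that("fitting is deterministic given a seed and records a monotone trace", {
  inst <- random_instance(m = 9, n = 12, p = 3, seed = 31)
  cfg <- cellnmf_config(max_iter = 25, seed = 7)
  f1 <- cellnmf_fit(inst$x, inst$priors, inst$graph, cfg)
  f2 <- cellnmf_fit(inst$x, inst$priors, inst$graph, cfg)
  expect_identical(f1$U, f2$U)
  expect_identical(f1$V, f2$V)

  tr <- f1$objective_trace
  expect_true(all(is.finite(tr)))
  expect_true(all(diff(tr) <= 1e-8 * tr[-length(tr)]))
  expect_true(all(f1$U >= 0) && all(f1$V >= 0))
})

test_that("near-stationarity holds at convergence (KKT surface)", {
  inst <- random_instance(m = 8, n = 10, p = 2, seed = 17)
  cfg <- cellnmf_config(alpha0 = 1, alpha = 10, beta = 10, gamma = 1,
                        max_iter = 500, rel_tol = 1e-10, seed = 2)
  fit <- cellnmf_fit(inst$x, inst$priors, inst$graph, cfg)
  grad_u <- -2 * inst$x %*% fit$V + 2 * fit$U %*% crossprod(fit$V) +
    cfg$alpha0 + cfg$alpha * (1 - inst$priors$M)
  stat <- abs(fit$U * grad_u)
  expect_lt(max(stat) / max(abs(grad_u) * max(fit$U)), 1e-2)
})

test_that("planted noiseless structure is recovered exactly", {
  sim <- simulate_cells(sim_config(n_cells = 150, n_types = 3,
                                   markers_per_type = 6,
                                   n_background_genes = 30, pi0 = 0,
                                   sigma_hetero = 0, sigma_homo = 0,
                                   seed = 41))
  lab <- corrupt_labels(sim$labels, retain_fraction = 0.1, seed = 42)
  pri <- build_priors(sim$markers, lab, rownames(sim$matrix),
                      colnames(sim$matrix))
  g <- suppressWarnings(build_cell_graph(sim$matrix))
  fit <- cellnmf_fit(sim$matrix, pri, g, cellnmf_config(seed = 43))
  ann <- annotate_cells(fit)
  ids <- setdiff(sim$labels$cell_id, lab$cell_id)
  acc <- annotation_accuracy(
    ann$cell_type[match(ids, ann$cell_id)],
    sim$labels$cell_type[match(ids, sim$labels$cell_id)]
  )
  expect_equal(acc, 100)
})

test_that("annotation takes the row argmax with deterministic tie-breaks", {
  fit <- structure(
    list(V = matrix(c(0.1, 0.5, 0, 0.9, 0.5, 0, 0, 0, 0), 3, 3,
                    dimnames = list(c("x", "y", "z"), c("A", "B", "C"))),
         cell_types = c("A", "B", "C")),
    class = "cellnmf_fit"
  )
  expect_warning(ann <- annotate_cells(fit), "unassigned")
  expect_identical(ann$cell_type, c("B", "A", "unassigned"))  # tie row -> A
  expect_equal(ann$score, c(0.9, 0.5, 0))
})

test_that("grid search evaluates folds and prefers informative weights", {
  sim <- small_sim(seed = 51)
  lab <- corrupt_labels(sim$labels, retain_fraction = 0.25, seed = 52)
  pri <- build_priors(sim$markers, lab, rownames(sim$matrix),
                      colnames(sim$matrix))
  g <- build_cell_graph(sim$matrix)
  base <- cellnmf_config(max_iter = 30, seed = 53)

  # single grid point is returned unchanged
  single <- cellnmf_tune(sim$matrix, pri, g, alpha = 1e4, beta = 1e4,
                         gamma = 10, folds = 3, config = base)
  expect_equal(single$best_config$alpha, 1e4)
  expect_identical(nrow(single$cv), 1L)

  # default within-dataset weights are evaluable, and beat the
  # unregularized model in CV accuracy
  tuned <- cellnmf_tune(sim$matrix, pri, g, alpha = c(0, 1e4),
                        beta = c(0, 1e4), gamma = c(0, 10), folds = 3,
                        config = base)
  cv <- tuned$cv
  acc_default <- cv$mean_accuracy[cv$alpha == 1e4 & cv$beta == 1e4 &
                                    cv$gamma == 10]
  acc_null <- cv$mean_accuracy[cv$alpha == 0 & cv$beta == 0 & cv$gamma == 0]
  expect_gte(acc_default, acc_null)

  expect_error(
    cellnmf_tune(sim$matrix, pri, g, folds = 1000),
    "labeled"
  )
})
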