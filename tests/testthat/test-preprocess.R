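test_that("filter_cells applies the detected-gene and mito-fraction rules", {
  # 3 cells: 150 detected genes (removed), 500 detected (kept), and a
  # clean cell; plus mito-fraction cases {0.1, 0.25, 0.05} at threshold 0.2
  x <- named_matrix(0, 600, 3)
  x[1:150, 1] <- 1
  x[1:500, 2] <- 1
  x[1:300, 3] <- 1
  kept <- filter_cells(x, qc_config(min_genes_per_cell = 200))
  expect_identical(colnames(kept), c("c02", "c03"))

  y <- named_matrix(1, 4, 3)
  rownames(y)[1] <- "MT-CO1"
  y[1, ] <- c(1, 3, 0.5)   # mito fractions 1/4, 3/6? -> set explicitly
  y[2:4, 1] <- 3           # cell 1: mito 1/10 = 0.1
  y[2:4, 2] <- 3           # cell 2: mito 3/12 = 0.25
  y[2:4, 3] <- 3           # cell 3: mito 0.5/9.5 ~= 0.053
  frac <- y[1, ] / colSums(y)
  expect_equal(unname(round(frac, 2)), c(0.1, 0.25, 0.05))
  kept <- filter_cells(y, qc_config(min_genes_per_cell = 1,
                                    max_mito_fraction = 0.20))
  expect_identical(ncol(kept), 2L)
  expect_false("c02" %in% colnames(kept))

  expect_error(filter_cells(y, qc_config(min_genes_per_cell = 100)),
               "All cells")
})

test_that("filter_genes keeps genes detected in enough cells", {
  # per-gene nonzero cell counts {0, 1, 3, 4, 2} at threshold 3 -> 2 kept
  x <- named_matrix(0, 5, 4)
  x[2, 1] <- 1
  x[3, 1:3] <- 1
  x[4, 1:4] <- 1
  x[5, 1:2] <- 1
  kept <- filter_genes(x, qc_config(min_cells_per_gene = 3))
  expect_identical(rownames(kept), c("g03", "g04"))
  kept1 <- filter_genes(x, qc_config(min_cells_per_gene = 1))
  expect_false("g01" %in% rownames(kept1))  # all-zero gene removed
})

test_that("normalize_log matches the closed form and conserves library size", {
  # cell counts [1, 3], s = 4: gene 1 -> log(2501), gene 2 -> log(7501)
  x <- named_matrix(c(1, 3), 2, 1)
  out <- normalize_log(x, scale = 1e4)
  expect_equal(out["g01", "c01"], log(2501))
  expect_equal(out["g02", "c01"], log(7501))

  # single-gene cell: x0 = 5, s = 5 -> log(1e4 + 1); zeros stay zero
  y <- named_matrix(c(5, 0), 2, 1)
  expect_equal(normalize_log(y)["g01", 1], log(1e4 + 1))
  expect_equal(normalize_log(y)["g02", 1], 0)

  # back-transformed columns sum to `scale` exactly by construction
  withr::local_seed(1)
  z <- named_matrix(rpois(60, 5) + 1, 6, 10)
  nz <- normalize_log(z, scale = 100)
  expect_equal(unname(colSums(expm1(nz))), rep(100, 10))

  z[, 3] <- 0
  expect_error(normalize_log(z), "c03")
})

test_that("select_hvgs ranks by standardized variance with deterministic ties", {
  withr::local_seed(1)
  # planted genes with inflated variance around a common mean
  n <- 200
  base <- matrix(rnorm(100 * n, 5, 1), 100, n)
  base[1:10, ] <- matrix(rnorm(10 * n, 5, sqrt(5)), 10, n)  # 5x variance
  base <- pmax(base, 0)
  dimnames(base) <- list(sprintf("g%03d", 1:100), sprintf("c%03d", 1:n))
  top <- select_hvgs(base, n_top_genes = 10)
  expect_setequal(top, sprintf("g%03d", 1:10))

  # identical rows: tie broken by gene id order
  flat <- named_matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  expect_identical(select_hvgs(flat, 2), c("g01", "g02"))

  # same mean, variances 4 vs 1: higher variance ranks first
  two <- rbind(c(0, 4, 2, 2), c(1, 3, 2, 2))
  dimnames(two) <- list(c("hi", "lo"), paste0("c", 1:4))
  expect_identical(select_hvgs(two, 1), "hi")

  expect_warning(res <- select_hvgs(two, 5), "only 2")
  expect_length(res, 2)
})

test_that("select_hvgs is permutation-equivariant in gene order", {
  withr::local_seed(42)
  x <- named_matrix(rgamma(50 * 40, 2, 1), 50, 40)
  perm <- sample(nrow(x))
  expect_setequal(select_hvgs(x, 12), select_hvgs(x[perm, ], 12))
})

test_that("standardize_genes centers, scales, clips and handles flat genes", {
  x <- named_matrix(c(0, 5, 2, 5, 4, 5), 2, 3)  # row 2 constant
  expect_warning(out <- standardize_genes(x), "zero-variance")
  expect_equal(unname(out[2, ]), c(0, 0, 0))
  expect_true(all(out >= 0))

  # row [0, 2]: standardized to -1/sd, 1/sd then clipped
  y <- named_matrix(c(0, 2), 1, 2)
  out <- standardize_genes(y)
  expect_equal(unname(out[1, ]), c(0, 1 / sd(c(0, 2))))

  withr::local_seed(3)
  z <- named_matrix(runif(60), 6, 10)
  expect_true(all(standardize_genes(z) >= 0))
})

test_that("assemble_feature_matrix takes the marker/HVG union, markers first", {
  withr::local_seed(7)
  x <- named_matrix(runif(200), 20, 10)
  markers <- list(A = c("g01", "g02"), B = c("g02", "g03", "ZZZ"))
  hvgs <- c("g03", "g10", "g11")
  expect_warning(out <- assemble_feature_matrix(x, hvgs, markers), "ZZZ")
  expect_identical(rownames(out), c("g01", "g02", "g03", "g10", "g11"))
  expect_identical(attr(out, "marker_genes"), c("g01", "g02", "g03"))

  # markers subset of HVGs: row count equals |HVGs|
  out2 <- assemble_feature_matrix(x, c("g01", "g02", "g03", "g04"),
                                  list(A = "g01", B = "g02"))
  expect_identical(nrow(out2), 4L)

  expect_error(
    suppressWarnings(assemble_feature_matrix(x, hvgs, list(A = "NOPE"))),
    "symbol conventions"
  )
})

test_that("build_priors encodes marker and label constraints exactly", {
  feature_genes <- paste0("g", 1:5)
  cells <- paste0("c", 1:4)
  markers <- list(A = c("g1", "g2"), B = c("g2", "g3"))
  labels <- data.frame(cell_id = c("c1", "c3"), cell_type = c("B", "A"))
  pri <- build_priors(markers, labels, feature_genes, cells)

  expect_identical(pri$cell_types, c("A", "B"))
  # gene marking both types: M0 row has ones on both columns
  expect_equal(unname(pri$M["g2", ]), c(1, 1))
  expect_equal(unname(pri$M["g1", ]), c(1, 0))
  # non-marker genes unconstrained (all ones)
  expect_equal(unname(pri$M["g4", ]), c(1, 1))
  expect_true(all(rowSums(pri$M[c("g1", "g2", "g3"), ]) >= 1))
  # labeled cells one-hot, unlabeled all ones
  expect_equal(unname(pri$P["c1", ]), c(0, 1))
  expect_equal(unname(pri$P["c3", ]), c(1, 0))
  expect_equal(unname(pri$P["c2", ]), c(1, 1))

  # union cardinality: marker-only + label-only types
  pri3 <- build_priors(list(A = "g1", B = "g2"),
                       data.frame(cell_id = "c1", cell_type = "C"),
                       feature_genes, cells)
  expect_identical(pri3$cell_types, c("A", "B", "C"))

  expect_error(build_priors(markers,
                            data.frame(cell_id = "zz", cell_type = "A"),
                            feature_genes, cells),
               "not found")
})

test_that("prior penalties vanish exactly where priors are uninformative", {
  inst <- random_instance(m = 10, n = 12, p = 3, seed = 5)
  pri <- inst$priors
  # (1 - M) rows are zero exactly for non-marker genes
  non_marker <- setdiff(pri$genes, pri$marker_genes)
  expect_true(all(rowSums(1 - pri$M)[non_marker] == 0))
  expect_true(all(rowSums(1 - pri$M)[pri$marker_genes] > 0))
  # (1 - P) rows are zero exactly for unlabeled cells
  unlabeled <- setdiff(pri$cells, pri$labeled_cells)
  expect_true(all(rowSums(1 - pri$P)[unlabeled] == 0))
  expect_true(all(rowSums(1 - pri$P)[pri$labeled_cells] > 0))
})
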