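#' Simulation configuration
#'
#' Parameters of the synthetic single-cell expression generator. Genes are
#' split into disjoint per-type marker sets and shared background genes.
#' Shared means are drawn as `m_i ~ N(mu0, sigma0^2)`; the type-specific
#' mean of gene i in type k is `a * m_i` when i is a marker of k and
#' `m_i - delta` otherwise (`a > 1`, `delta > 0`). Observed expression adds
#' Gaussian noise with variance `sigma_hetero * mu + sigma_homo^2`
#' (heteroscedastic + homoscedastic components), truncates negatives at
#' zero, and finally zeroes entries independently with dropout probability
#' `pi0`. Optional fixed `batch_shifts` are added to the gene means of
#' predefined, equally sized cell groups.
#'
#' The default sizes (1200 cells, 4 types, 20 markers per type, 100
#' background genes, equal proportions) reproduce the simulated benchmark
#' used throughout the package's robustness experiments; the distribution
#' parameter defaults are the package's calibration (see the methods
#' vignette).
#'
#' @param n_cells Number of cells. Default 1200.
#' @param n_types Number of cell types. Default 4.
#' @param markers_per_type Marker genes per type (disjoint sets). Default 20.
#' @param n_background_genes Shared background genes. Default 100.
#' @param mu0,sigma0 Mean and sd of the shared gene-mean distribution.
#'   Defaults 5 and 1.
#' @param a Marker fold factor (> 1). Default 3.
#' @param delta Depression of non-marker means (> 0). Default 1.
#' @param pi0 Dropout probability in `[0, 1]`. Default 0.3.
#' @param sigma_hetero Heteroscedastic noise coefficient (variance grows
#'   linearly with the mean). Default 0.2.
#' @param sigma_homo Homoscedastic noise sd. Default 0.5.
#' @param batch_shifts Optional numeric vector of additive mean offsets, one
#'   per batch; cells are split into `length(batch_shifts)` contiguous
#'   equally sized groups. `NULL` (default) for no batch structure.
#' @param type_proportions Per-type cell fractions summing to 1; default
#'   equal.
#' @param seed Optional RNG seed.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 1200, n_types = 4, markers_per_type = 20,
                       n_background_genes = 100, mu0 = 5, sigma0 = 1,
                       a = 3, delta = 1, pi0 = 0.3, sigma_hetero = 0.2,
                       sigma_homo = 0.5, batch_shifts = NULL,
                       type_proportions = NULL, seed = NULL) {
  check_count(n_cells, "n_cells", min = 1)
  check_count(n_types, "n_types", min = 1)
  check_count(markers_per_type, "markers_per_type", min = 1)
  check_count(n_background_genes, "n_background_genes")
  check_fraction(pi0, "pi0")
  if (a <= 1) abort("`a` must be > 1.")
  if (delta <= 0) abort("`delta` must be > 0.")
  if (sigma0 < 0 || sigma_hetero < 0 || sigma_homo < 0) {
    abort("`sigma0`, `sigma_hetero`, `sigma_homo` must be >= 0.")
  }
  type_proportions <- type_proportions %||% rep(1 / n_types, n_types)
  if (length(type_proportions) != n_types ||
      abs(sum(type_proportions) - 1) > 1e-8 || any(type_proportions <= 0)) {
    abort("`type_proportions` must be positive, length n_types, and sum to 1.")
  }
  structure(
    list(n_cells = as.integer(n_cells), n_types = as.integer(n_types),
         markers_per_type = as.integer(markers_per_type),
         n_background_genes = as.integer(n_background_genes),
         mu0 = mu0, sigma0 = sigma0, a = a, delta = delta, pi0 = pi0,
         sigma_hetero = sigma_hetero, sigma_homo = sigma_homo,
         batch_shifts = batch_shifts, type_proportions = type_proportions,
         seed = seed),
    class = "sim_config"
  )
}

#' Simulate a single-cell expression dataset
#'
#' Generates a gene-by-cell matrix with planted cell-type structure,
#' ground-truth labels and disjoint marker sets, following the generative
#' model described in [sim_config()]. Stage order: type-specific means
#' (plus batch shifts) -> Gaussian noise -> truncation of negatives at
#' zero -> Bernoulli dropout.
#'
#' @param config A [sim_config()].
#'
#' @return A list of class `cellnmf_sim`: `matrix` (genes x cells,
#'   non-negative), `labels` (tibble `cell_id`, `cell_type` for every
#'   cell — the ground truth), `markers` (named list of per-type marker
#'   gene ids), `batch` (per-cell batch index or `NULL`), `config`.
#' @export
#' @examples
#' sim <- simulate_cells(sim_config(n_cells = 40, n_types = 2,
#'                                  markers_per_type = 3,
#'                                  n_background_genes = 10, seed = 7))
#' dim(sim$matrix)
#' table(sim$labels$cell_type)
simulate_cells <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n_marker <- cfg$n_types * cfg$markers_per_type
  m <- n_marker + cfg$n_background_genes
  n <- cfg$n_cells

  gene_ids <- sprintf("gene%04d", seq_len(m))
  cell_ids <- sprintf("cell%04d", seq_len(n))
  types <- sprintf("type%d", seq_len(cfg$n_types))

  markers <- split(gene_ids[seq_len(n_marker)],
                   rep(types, each = cfg$markers_per_type))
  markers <- markers[types]

  # per-type cell counts from the proportions, remainder to the last type
  counts <- floor(cfg$type_proportions * n)
  counts[cfg$n_types] <- n - sum(counts[-cfg$n_types])
  label_vec <- rep(types, times = counts)

  batch <- NULL
  if (!is.null(cfg$batch_shifts)) {
    batch <- rep(seq_along(cfg$batch_shifts), length.out = n)
    batch <- sort(batch)
  }

  mat <- with_seed_if(cfg$seed, {
    m_i <- rnorm(m, cfg$mu0, cfg$sigma0)
    mu <- matrix(m_i - cfg$delta, m, cfg$n_types,
                 dimnames = list(gene_ids, types))
    for (k in seq_len(cfg$n_types)) {
      mu[markers[[k]], k] <- cfg$a * m_i[match(markers[[k]], gene_ids)]
    }
    mu_cells <- mu[, label_vec, drop = FALSE]
    if (!is.null(batch)) {
      mu_cells <- sweep(mu_cells, 2, cfg$batch_shifts[batch], "+")
    }
    noise_var <- cfg$sigma_hetero * mu_cells + cfg$sigma_homo^2
    if (any(noise_var < 0)) {
      abort(paste("Negative noise variance (sigma_hetero * mu + sigma_homo^2 < 0)",
                  "for some gene; reduce sigma_hetero or delta."))
    }
    x <- mu_cells + rnorm(m * n, 0, sqrt(noise_var))
    x <- pmax(x, 0)
    if (cfg$pi0 > 0) {
      x[runif(m * n) < cfg$pi0] <- 0
    }
    dimnames(x) <- list(gene_ids, cell_ids)
    x
  })

  structure(
    list(matrix = mat,
         labels = tibble(cell_id = cell_ids, cell_type = label_vec),
         markers = markers, batch = batch, config = cfg),
    class = "cellnmf_sim"
  )
}

#' @export
print.cellnmf_sim <- function(x, ...) {
  cat(sprintf("<cellnmf_sim> %d genes x %d cells, %d type(s), %d marker(s)/type\n",
              nrow(x$matrix), ncol(x$matrix), x$config$n_types,
              x$config$markers_per_type))
  cat(sprintf("  zero fraction: %.3f\n", mean(x$matrix == 0)))
  invisible(x)
}

#' Subsample and/or corrupt a cell-label table
#'
#' Two corruption modes for robustness experiments, applied in order:
#' first a uniformly random fraction `retain_fraction` of the labels is
#' kept (`round(retain_fraction * n)` rows, exact count); then
#' `round(error_rate * n_retained)` of the retained labels are reassigned
#' to a uniformly random *different* type drawn from the types present in
#' the input table. Exact-count (not Bernoulli) corruption, reproducible
#' given `seed`.
#'
#' @param labels Data frame with columns `cell_id`, `cell_type`.
#' @param retain_fraction Fraction of labels to keep, in `[0, 1]`. Default 1.
#' @param error_rate Fraction of retained labels to flip, in `[0, 1]`.
#'   Default 0.
#' @param seed Optional RNG seed.
#'
#' @return A tibble with the same columns, `round(retain_fraction * n)`
#'   rows, in the original row order.
#' @export
corrupt_labels <- function(labels, retain_fraction = 1, error_rate = 0,
                           seed = NULL) {
  check_label_table(labels)
  check_fraction(retain_fraction, "retain_fraction")
  check_fraction(error_rate, "error_rate")
  types <- unique(as.character(labels$cell_type))
  with_seed_if(seed, {
    n <- nrow(labels)
    keep <- sort(sample.int(n, round(retain_fraction * n)))
    out <- as_tibble(labels[keep, c("cell_id", "cell_type"), drop = FALSE])
    n_err <- round(error_rate * nrow(out))
    if (n_err > 0) {
      if (length(types) < 2) {
        abort("Cannot inject label errors: only one cell type present.")
      }
      flip <- sample.int(nrow(out), n_err)
      out$cell_type[flip] <- vapply(out$cell_type[flip], function(ct) {
        sample(setdiff(types, ct), 1)
      }, character(1))
    }
    out
  })
}

#' Corrupt marker-gene assignments
#'
#' Replaces `round(error_rate * |G_k|)` markers in each type's set with
#' genes drawn (without replacement) from `gene_pool` excluding the genes
#' currently marking that type. Per-type set sizes are preserved;
#' reproducible given `seed`.
#'
#' @param markers Named list mapping cell types to marker gene ids.
#' @param error_rate Fraction of each set to replace, in `[0, 1]`.
#' @param gene_pool Character vector of candidate replacement gene ids
#'   (typically all genes in the matrix).
#' @param seed Optional RNG seed.
#'
#' @return A named list with the same types and per-type set sizes.
#' @export
corrupt_markers <- function(markers, error_rate, gene_pool, seed = NULL) {
  check_marker_map(markers)
  check_fraction(error_rate, "error_rate")
  with_seed_if(seed, {
    lapply(markers, function(genes) {
      n_swap <- round(error_rate * length(genes))
      if (n_swap == 0) return(genes)
      candidates <- setdiff(gene_pool, genes)
      if (length(candidates) < n_swap) {
        abort("Gene pool exhausted: not enough non-marker genes to swap in.")
      }
      swap_idx <- sample.int(length(genes), n_swap)
      genes[swap_idx] <- sample(candidates, n_swap)
      genes
    })
  })
}
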