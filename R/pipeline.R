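# End-to-end pipelines: preprocess -> priors -> graph -> fit -> annotate ->
# evaluate, plus the robustness and ablation experiment drivers.

# Fit a model on a simulated dataset without count-style preprocessing (the
# generator emits a model-ready non-negative matrix on a homogeneous scale).
fit_simulated <- function(sim, labels, markers, config) {
  priors <- build_priors(markers, labels,
                         feature_genes = rownames(sim$matrix),
                         cells = colnames(sim$matrix))
  graph <- if (config$gamma > 0) build_cell_graph(sim$matrix) else NULL
  fit <- cellnmf_fit(sim$matrix, priors, graph, config)
  list(fit = fit, priors = priors, graph = graph,
       annotations = annotate_cells(fit))
}

score_annotations <- function(annotations, truth, exclude = character(0),
                              include_labeled = FALSE) {
  check_label_table(truth)
  eval_ids <- if (include_labeled) truth$cell_id else
    setdiff(truth$cell_id, exclude)
  if (length(eval_ids) == 0) {
    abort("No unlabeled cells left to evaluate; set include_labeled = TRUE.")
  }
  pred <- annotations$cell_type[match(eval_ids, annotations$cell_id)]
  tru <- truth$cell_type[match(eval_ids, truth$cell_id)]
  evaluation_report(pred, tru)
}

#' Run the full annotation pipeline
#'
#' Composes the package end to end: (optional) preprocessing of raw counts
#' (QC filtering, log-normalization, HVG selection, union with marker
#' genes, gene-wise standardization), prior construction, mutual-KNN graph,
#' model fitting, annotation, and — when ground truth is supplied —
#' evaluation. By default evaluation excludes the supervised (labeled)
#' cells, i.e. it scores the remaining unlabeled cells.
#'
#' @param x A raw count matrix (genes x cells) or a `cellnmf_sim` from
#'   [simulate_cells()] (then `markers`/`truth` default to the simulated
#'   ones and `preprocess` defaults to `FALSE`).
#' @param markers Named list mapping cell types to marker gene ids.
#' @param labels Optional partial label table (`cell_id`, `cell_type`).
#' @param truth Optional full ground-truth table for evaluation.
#' @param config A [cellnmf_config()].
#' @param qc A [qc_config()] (used when `preprocess = TRUE`).
#' @param n_hvgs Number of highly variable genes (when preprocessing).
#' @param graph_k Neighbor count for the cell graph; default
#'   `min(floor(n/3), 1000)`.
#' @param preprocess Logical; run the count preprocessing chain. Default
#'   `TRUE` for matrices, `FALSE` for simulated datasets.
#' @param include_labeled Include supervised cells in the evaluation.
#'   Default `FALSE`.
#' @param outdir Optional directory: writes `annotations.csv`,
#'   `report.json` (when truth is given) and `config.json`.
#'
#' @return A list of class `cellnmf_run`: `annotations` (tibble), `fit`,
#'   `priors`, `graph`, `report` (a `cellnmf_eval` or `NULL`), `config`.
#' @export
run_pipeline <- function(x, markers = NULL, labels = NULL, truth = NULL,
                         config = cellnmf_config(), qc = qc_config(),
                         n_hvgs = 1000, graph_k = NULL, preprocess = NULL,
                         include_labeled = FALSE, outdir = NULL) {
  if (inherits(x, "cellnmf_sim")) {
    markers <- markers %||% x$markers
    truth <- truth %||% x$labels
    preprocess <- preprocess %||% FALSE
    x <- x$matrix
  }
  preprocess <- preprocess %||% TRUE
  if (is.null(markers)) abort("`markers` are required.")
  check_expr(x)

  if (preprocess) {
    x <- filter_cells(x, qc)
    x <- filter_genes(x, qc)
    x <- normalize_log(x)
    hvgs <- select_hvgs(x, n_top_genes = min(n_hvgs, nrow(x)))
    x <- assemble_feature_matrix(x, hvgs, markers)
    x <- standardize_genes(x)
  }
  if (!is.null(labels)) {
    check_label_table(labels)
    labels <- labels[labels$cell_id %in% colnames(x), , drop = FALSE]
  }

  priors <- build_priors(markers, labels, feature_genes = rownames(x),
                         cells = colnames(x))
  graph <- if (config$gamma > 0) build_cell_graph(x, k = graph_k) else NULL
  fit <- cellnmf_fit(x, priors, graph, config)
  annotations <- annotate_cells(fit)

  report <- NULL
  if (!is.null(truth)) {
    truth_here <- truth[truth$cell_id %in% colnames(x), , drop = FALSE]
    report <- score_annotations(annotations, truth_here,
                                exclude = priors$labeled_cells,
                                include_labeled = include_labeled)
  }

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write.csv(annotations, file.path(outdir, "annotations.csv"),
              row.names = FALSE)
    jsonlite::write_json(unclass(config), file.path(outdir, "config.json"),
                         auto_unbox = TRUE, null = "null")
    if (!is.null(report)) {
      jsonlite::write_json(
        list(accuracy = report$accuracy, weighted_f1 = report$weighted_f1,
             per_class = report$per_class),
        file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA
      )
    }
  }

  structure(
    list(annotations = annotations, fit = fit, priors = priors,
         graph = graph, report = report, config = config),
    class = "cellnmf_run"
  )
}

#' @export
print.cellnmf_run <- function(x, ...) {
  cat("<cellnmf_run>\n")
  print(x$fit)
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

# Derive one sub-seed per (level, replicate) cell from a master seed,
# keeping everything below .Machine$integer.max.
draw_subseeds <- function(seed, n) {
  with_seed_if(seed, sample.int(2147483646L, n))
}

#' Robustness of annotation to degraded prior knowledge
#'
#' For each corruption level and replicate, simulates a dataset, degrades
#' the priors according to `scenario`, refits the model with the default
#' within-dataset weights, and scores accuracy and weighted F1 on the
#' unlabeled cells. Scenarios:
#' * `"retain"` — only `level` of the ground-truth labels are kept (clean).
#' * `"label_noise"` — `base_retain` of the labels are kept, then `level`
#'   of those are flipped to a random different type.
#' * `"marker_noise"` — `base_retain` clean labels; `level` of each type's
#'   marker genes are swapped for random other genes.
#'
#' @param scenario One of `"retain"`, `"label_noise"`, `"marker_noise"`.
#' @param levels Numeric vector of corruption levels in `[0, 1]`.
#' @param replicates Replicate simulations per level. Default 5.
#' @param sim A [sim_config()] describing the simulated benchmark.
#' @param config A [cellnmf_config()].
#' @param base_retain Label fraction supplied in the noise scenarios.
#'   Default 0.2.
#' @param seed Master seed; per-run seeds are derived from it.
#'
#' @return A tibble of class `cellnmf_robustness` with columns `scenario`,
#'   `level`, `replicate`, `accuracy` (fraction in `[0, 1]`),
#'   `weighted_f1`.
#' @export
run_robustness <- function(scenario = c("retain", "label_noise", "marker_noise"),
                           levels, replicates = 5, sim = sim_config(),
                           config = cellnmf_config(), base_retain = 0.2,
                           seed = NULL) {
  scenario <- match.arg(scenario)
  check_count(replicates, "replicates", min = 1)
  for (lv in levels) check_fraction(lv, "levels")
  seeds <- matrix(draw_subseeds(seed, length(levels) * replicates),
                  length(levels), replicates)

  rows <- list()
  for (i in seq_along(levels)) {
    for (r in seq_len(replicates)) {
      s <- seeds[i, r]
      cfg_sim <- sim
      cfg_sim$seed <- s
      data <- simulate_cells(cfg_sim)
      markers <- data$markers
      labels <- switch(
        scenario,
        retain = corrupt_labels(data$labels, retain_fraction = levels[i],
                                seed = s + 1L),
        label_noise = corrupt_labels(data$labels,
                                     retain_fraction = base_retain,
                                     error_rate = levels[i], seed = s + 1L),
        marker_noise = corrupt_labels(data$labels,
                                      retain_fraction = base_retain,
                                      seed = s + 1L)
      )
      if (scenario == "marker_noise") {
        markers <- corrupt_markers(markers, error_rate = levels[i],
                                   gene_pool = rownames(data$matrix),
                                   seed = s + 2L)
      }
      res <- fit_simulated(data, labels, markers, config)
      report <- score_annotations(res$annotations, data$labels,
                                  exclude = labels$cell_id)
      rows[[length(rows) + 1]] <- tibble(
        scenario = scenario, level = levels[i], replicate = r,
        accuracy = report$accuracy / 100, weighted_f1 = report$weighted_f1
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cellnmf_robustness", class(out))
  out
}

#' Summarize a robustness table
#'
#' @param results A `cellnmf_robustness` tibble.
#' @return A tibble with mean and standard error of accuracy and weighted
#'   F1 per scenario and level.
#' @export
summarize_robustness <- function(results) {
  results |>
    dplyr::group_by(.data$scenario, .data$level) |>
    dplyr::summarise(
      mean_accuracy = mean(.data$accuracy),
      se_accuracy = sd(.data$accuracy) / sqrt(dplyr::n()),
      mean_weighted_f1 = mean(.data$weighted_f1),
      se_weighted_f1 = sd(.data$weighted_f1) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

#' @describeIn run_robustness Accuracy-vs-level plot with standard-error
#'   bars.
#' @param object A `cellnmf_robustness` tibble.
#' @param ... Ignored.
#' @method autoplot cellnmf_robustness
#' @export
autoplot.cellnmf_robustness <- function(object, ...) {
  sm <- summarize_robustness(object)
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$level, y = .data$mean_accuracy,
                                   color = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_accuracy - .data$se_accuracy,
                   ymax = .data$mean_accuracy + .data$se_accuracy),
      width = 0.02
    ) +
    ggplot2::labs(x = "Corruption level", y = "Mean annotation accuracy") +
    ggplot2::theme_minimal()
}

ablation_variants <- list(
  full         = c(alpha = NA, beta = NA, gamma = NA),
  marker_only  = c(alpha = NA, beta = 0,  gamma = 0),
  label_only   = c(alpha = 0,  beta = NA, gamma = 0),
  marker_label = c(alpha = NA, beta = NA, gamma = 0),
  label_graph  = c(alpha = 0,  beta = NA, gamma = NA),
  marker_graph = c(alpha = NA, beta = 0,  gamma = NA)
)

#' Ablation study over the three prior-knowledge components
#'
#' Runs the named model variants on replicated simulations by zeroing the
#' corresponding penalty weights (`NA` entries keep the value from
#' `config`): `full`, `marker_only` (beta = gamma = 0), `label_only`
#' (alpha = gamma = 0), `marker_label` (gamma = 0), `label_graph`
#' (alpha = 0), `marker_graph` (beta = 0). Labels are a clean random
#' `retain` fraction; evaluation is on the unlabeled cells.
#'
#' @param variants Character vector of variant names (see above).
#' @param replicates Replicate simulations per variant. Default 5.
#' @inheritParams run_robustness
#' @param retain Clean label fraction supplied to every variant. Default
#'   0.2.
#'
#' @return A tibble with columns `variant`, `replicate`, `accuracy`
#'   (fraction), `weighted_f1`.
#' @export
run_ablation <- function(variants = names(ablation_variants), replicates = 5,
                         sim = sim_config(), config = cellnmf_config(),
                         retain = 0.2, seed = NULL) {
  bad <- setdiff(variants, names(ablation_variants))
  if (length(bad) > 0) {
    abort(sprintf("Unknown variant(s): %s. Choose from: %s",
                  paste(bad, collapse = ", "),
                  paste(names(ablation_variants), collapse = ", ")))
  }
  check_count(replicates, "replicates", min = 1)
  seeds <- draw_subseeds(seed, replicates)

  rows <- list()
  for (r in seq_len(replicates)) {
    cfg_sim <- sim
    cfg_sim$seed <- seeds[r]
    data <- simulate_cells(cfg_sim)
    labels <- corrupt_labels(data$labels, retain_fraction = retain,
                             seed = seeds[r] + 1L)
    for (v in variants) {
      cfg <- config
      variant_weights <- ablation_variants[[v]]
      for (w in names(variant_weights)) {
        if (!is.na(variant_weights[[w]])) cfg[[w]] <- variant_weights[[w]]
      }
      res <- fit_simulated(data, labels, data$markers, cfg)
      report <- score_annotations(res$annotations, data$labels,
                                  exclude = labels$cell_id)
      rows[[length(rows) + 1]] <- tibble(
        variant = v, replicate = r, accuracy = report$accuracy / 100,
        weighted_f1 = report$weighted_f1
      )
    }
  }
  dplyr::bind_rows(rows)
}
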