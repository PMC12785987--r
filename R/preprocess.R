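#' Quality-control configuration
#'
#' Thresholds for cell- and gene-level filtering of raw count matrices.
#'
#' @param min_genes_per_cell Minimum number of detected (nonzero) genes a
#'   cell must express to be retained. Default 200.
#' @param max_mito_fraction Maximum tolerated fraction of a cell's counts
#'   coming from mitochondrial genes, in `[0, 1]`. Default 0.20.
#' @param min_cells_per_gene Minimum number of cells in which a gene must be
#'   detected to be retained. Default 3.
#' @param mito_prefixes Gene-symbol prefixes identifying mitochondrial
#'   transcripts. Defaults cover human (`"MT-"`) and mouse (`"mt-"`).
#'
#' @return A list of class `qc_config`.
#' @export
#' @examples
#' qc_config(min_genes_per_cell = 100)
qc_config <- function(min_genes_per_cell = 200,
                      max_mito_fraction = 0.20,
                      min_cells_per_gene = 3,
                      mito_prefixes = c("MT-", "mt-")) {
  check_count(min_genes_per_cell, "min_genes_per_cell")
  check_count(min_cells_per_gene, "min_cells_per_gene")
  check_fraction(max_mito_fraction, "max_mito_fraction")
  structure(
    list(
      min_genes_per_cell = as.integer(min_genes_per_cell),
      max_mito_fraction = as.numeric(max_mito_fraction),
      min_cells_per_gene = as.integer(min_cells_per_gene),
      mito_prefixes = as.character(mito_prefixes)
    ),
    class = "qc_config"
  )
}

mito_gene_mask <- function(gene_ids, prefixes) {
  if (length(prefixes) == 0) return(rep(FALSE, length(gene_ids)))
  pattern <- paste0("^(", paste(gsub("([^[:alnum:]])", "\\\\\\1", prefixes),
                                collapse = "|"), ")")
  grepl(pattern, gene_ids)
}

#' Filter low-quality cells
#'
#' Removes cells expressing fewer than `min_genes_per_cell` genes or whose
#' mitochondrial count fraction exceeds `max_mito_fraction`. Cell order is
#' preserved.
#'
#' @param x Raw count matrix, genes in rows, cells in columns, with gene
#'   symbols as rownames and cell barcodes as colnames.
#' @param qc A [qc_config()].
#'
#' @return The filtered matrix.
#' @export
filter_cells <- function(x, qc = qc_config()) {
  check_expr(x, require_nonneg = TRUE)
  detected <- colSums(x > 0)
  mito <- mito_gene_mask(rownames(x), qc$mito_prefixes)
  lib <- colSums(x)
  mito_frac <- ifelse(lib > 0, colSums(x[mito, , drop = FALSE]) / pmax(lib, 1), 0)
  keep <- detected >= qc$min_genes_per_cell & mito_frac <= qc$max_mito_fraction
  if (!any(keep)) {
    abort("All cells were removed by QC filtering; relax the thresholds.")
  }
  x[, keep, drop = FALSE]
}

#' Filter rarely detected genes
#'
#' Keeps genes detected (nonzero) in at least `min_cells_per_gene` cells.
#'
#' @inheritParams filter_cells
#' @return The filtered matrix.
#' @export
filter_genes <- function(x, qc = qc_config()) {
  check_expr(x, require_nonneg = TRUE)
  keep <- rowSums(x > 0) >= qc$min_cells_per_gene
  if (!any(keep)) {
    abort("All genes were removed by QC filtering; relax the thresholds.")
  }
  x[keep, , drop = FALSE]
}

#' Library-size log-normalization
#'
#' Scales each cell's counts to a common library size and applies a natural
#' log transform: `x' = log(count / libsize * scale + 1)`.
#'
#' @inheritParams filter_cells
#' @param scale Target library size. Default `1e4`.
#'
#' @return Matrix of log-normalized expression.
#' @export
normalize_log <- function(x, scale = 1e4) {
  check_expr(x, require_nonneg = TRUE)
  s <- colSums(x)
  if (any(s == 0)) {
    bad <- colnames(x)[s == 0][1]
    abort(sprintf("Cell '%s' has zero library size; filter cells first.", bad))
  }
  log1p(sweep(x, 2, s, "/") * scale)
}

#' Select highly variable genes
#'
#' Ranks genes by standardized variance `v_i = var_i / f(mean_i)`, where `f`
#' is a mean-variance trend fitted by local polynomial regression of log
#' variance on log mean across all expressed genes, and returns the top
#' `n_top_genes` gene ids. Ties are broken deterministically by
#' (-v, gene id).
#'
#' @param x Log-normalized expression matrix.
#' @param n_top_genes Number of genes to select. Default 1000.
#' @param span Loess span for the trend fit. Default 0.3.
#'
#' @return Character vector of selected gene ids.
#' @export
select_hvgs <- function(x, n_top_genes = 1000, span = 0.3) {
  check_expr(x)
  check_count(n_top_genes, "n_top_genes", min = 1)
  n <- ncol(x)
  mu <- rowMeans(x)
  sigma2 <- if (n > 1) rowSums((x - mu)^2) / (n - 1) else rep(0, nrow(x))
  v <- standardized_variance(mu, sigma2, span)
  ord <- order(-v, rownames(x), method = "radix")
  if (n_top_genes >= nrow(x)) {
    warn(sprintf("Requested %d HVGs but only %d genes available; returning all.",
                 n_top_genes, nrow(x)))
    return(rownames(x)[ord])
  }
  rownames(x)[ord][seq_len(n_top_genes)]
}

# Standardized variance against a fitted mean-variance trend. Genes with zero
# variance get v = 0. With too few informative genes for a local fit, the
# trend degenerates to the mean variance (a flat trend), which preserves the
# variance ranking.
standardized_variance <- function(mu, sigma2, span = 0.3) {
  v <- numeric(length(mu))
  ok <- sigma2 > 0 & mu > 0
  if (!any(ok)) return(v)
  if (sum(ok) < 10 || length(unique(mu[ok])) < 5) {
    v[ok] <- sigma2[ok] / mean(sigma2[ok])
    return(v)
  }
  fit <- tryCatch(
    loess(log(sigma2[ok]) ~ log(mu[ok]), span = span, degree = 2,
          family = "gaussian"),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    v[ok] <- sigma2[ok] / mean(sigma2[ok])
  } else {
    f <- exp(predict(fit))
    f[!is.finite(f) | f <= 0] <- mean(sigma2[ok])
    v[ok] <- sigma2[ok] / f
  }
  v
}

#' Gene-wise standardization with non-negativity repair
#'
#' Centers and scales each gene row to mean 0 and unit variance, then clips
#' negative values to 0 so the result satisfies the factorization model's
#' non-negativity requirement. Zero-variance genes become all-zero rows (with
#' a warning): they carry no signal.
#'
#' @param x Log-normalized (typically HVG/marker-subset) matrix.
#'
#' @return Standardized, clipped matrix (elementwise `>= 0`).
#' @export
standardize_genes <- function(x) {
  check_expr(x)
  mu <- rowMeans(x)
  sdev <- apply(x, 1, sd)
  flat <- sdev == 0
  if (any(flat)) {
    warn(sprintf("%d zero-variance gene(s) set to all-zero rows.", sum(flat)))
    sdev[flat] <- 1
  }
  z <- (x - mu) / sdev
  z[flat, ] <- 0
  pmax(z, 0)
}

#' Assemble the model feature matrix
#'
#' Subsets the matrix to the union of selected HVGs and surviving marker
#' genes, placing marker genes in the leading rows so that the marker
#' constraint matrix aligns with the gene order. Marker genes absent from
#' the matrix are dropped with a warning.
#'
#' @param x Expression matrix (log-normalized).
#' @param hvgs Character vector of HVG ids (from [select_hvgs()]).
#' @param markers Named list mapping cell types to marker gene ids.
#'
#' @return Matrix whose first rows are the marker genes, followed by the
#'   remaining HVGs; the marker gene ids are attached as attribute
#'   `"marker_genes"`.
#' @export
assemble_feature_matrix <- function(x, hvgs, markers) {
  check_expr(x)
  check_marker_map(markers)
  all_markers <- unique(unlist(markers, use.names = FALSE))
  present <- all_markers[all_markers %in% rownames(x)]
  missing <- setdiff(all_markers, present)
  if (length(missing) > 0) {
    warn(sprintf("%d marker gene(s) absent from the matrix were excluded: %s%s",
                 length(missing), paste(head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) ", ..." else ""))
  }
  if (length(present) == 0) {
    abort(paste("No marker gene is present in the expression matrix;",
                "check gene symbol conventions (e.g. case, aliases)."))
  }
  hvgs <- hvgs[hvgs %in% rownames(x)]
  feature_genes <- c(present, setdiff(hvgs, present))
  out <- x[feature_genes, , drop = FALSE]
  attr(out, "marker_genes") <- present
  out
}
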