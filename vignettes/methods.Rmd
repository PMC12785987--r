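---
title: "Model and methods behind cellnmf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind cellnmf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellnmf)
```

## The annotation problem

Cell-type annotation assigns a biological identity (T cell, beta cell,
astrocyte, ...) to every cell of a single-cell RNA-seq experiment. In
practice the available prior knowledge is heterogeneous and imperfect: a
curated list of marker genes per type, a small subset of cells whose
identity is known, or neither in full. `cellnmf` treats annotation as a
constrained matrix-factorization problem that can absorb all three kinds of
evidence at once and degrade gracefully when any of them is noisy or
missing.

## The model

Let $X \in \mathbb{R}^{m \times n}_{\ge 0}$ be the preprocessed gene-by-cell
matrix. We factorize $X \approx U V^\top$ with $U \in
\mathbb{R}^{m \times p}_{\ge 0}$ (gene–factor loadings) and $V \in
\mathbb{R}^{n \times p}_{\ge 0}$ (cell–factor coefficients), where the
number of factors $p$ equals the number of distinct cell types named by the
priors — each factor is intended to represent one type. The fitted
objective is

$$
O \;=\; \lVert X - U V^\top \rVert_F^2
\;+\; \alpha_0 \lVert U \rVert_1
\;+\; \alpha \lVert U \odot (1 - M) \rVert_1
\;+\; \beta \lVert V \odot (1 - P) \rVert_1
\;+\; \gamma\, \mathrm{Tr}(V^\top L V),
$$

with all factors non-negative. The three knowledge terms are:

* **Marker constraint** ($\alpha$). $M$ is a binary genes $\times$ types
  matrix: for a marker gene, $M_{ik} = 1$ iff gene $i$ marks type $k$;
  rows of non-marker genes are all ones. The penalty charges marker genes
  for loading on factors of *other* types and vanishes identically on
  non-marker genes, leaving them data-driven.
* **Label supervision** ($\beta$). $P$ is a binary cells $\times$ types
  matrix: a labeled cell's row is one-hot, an unlabeled cell's row is all
  ones. Off-type coefficients of labeled cells are penalized; unlabeled
  cells are untouched.
* **Graph smoothness** ($\gamma$). $L = D - W$ is the unnormalized
  Laplacian of a mutual K-nearest-neighbor cell graph with Gaussian edge
  weights $w = \exp(-d^2 / 2\sigma^2)$, so
  $\mathrm{Tr}(V^\top L V) = \tfrac12 \sum_{j_1 j_2} w_{j_1 j_2}
  \lVert V_{j_1} - V_{j_2} \rVert^2$ pulls transcriptionally similar cells
  toward similar factor coefficients.

$\alpha_0$ is a plain L1 sparsity weight on $U$ that stabilizes the scale
of the factorization. A cell is annotated with the type of the largest
entry in its row of $V$ (ties to the lowest factor index; an all-zero row
is reported as `unassigned`).

Note that marker-consistent entries of $U$ are still charged by
$\alpha_0$: the sparsity and marker terms are deliberately independent, so
setting $\alpha = 0$ leaves a conventionally L1-regularized NMF.

## Optimization

The objective is non-convex jointly but each factor has a closed-form
multiplicative update derived from the KKT conditions:

$$
u_{ik} \leftarrow u_{ik}\,
\frac{(2 X V)_{ik}}{(2 U V^\top V + \alpha_0 \mathbf{1} + \alpha(1 - M))_{ik}},
\qquad
v_{jk} \leftarrow v_{jk}\,
\frac{2 (X^\top U + \gamma W V)_{jk}}{(2 V U^\top U + \beta(1 - P) + 2\gamma D V)_{jk}}.
$$

Numerical choices, each of which is load-bearing:

* **Denominator guard.** Every denominator is floored at
  `eps = 1e-12`; the update rules themselves never divide by zero on
  strictly positive iterates, but exact zeros in $U^\top U$ can occur on
  degenerate inputs.
* **Initialization.** $U, V \sim \mathrm{Uniform}(0, 1]$ — strictly
  positive, because a multiplicative update can never revive an exact
  zero. An SVD-based (NNDSVD) initialization is available behind
  `init = "nndsvd"` but is off by default: on this model class it does not
  improve annotation and random restarts are cheap.
* **Convergence.** One iteration is a U update followed by a V update;
  the fit stops when $|O^{(t)} - O^{(t-1)}| / O^{(t-1)} < 10^{-4}$
  (absolute value taken, so an anomalous increase also terminates rather
  than loops) or after `max_iter = 50` iterations. The full objective
  trace is stored and tested to be non-increasing to within $10^{-8}$
  relative — the testable surface of the KKT derivation.
* **Determinism.** All randomness flows through the configuration seed;
  the same seed reproduces $U$ and $V$ bit for bit.

Default weights are the within-dataset setting $\alpha = \beta = 10^4$,
$\gamma = 10$, $\alpha_0 = 50$. `cellnmf_tune()` searches
$\alpha, \beta \in \{10^2, \dots, 10^5\}$, $\gamma \in \{0.1, 1, 10, 100\}$
by stratified five-fold cross-validation over the labeled cells, breaking
accuracy ties toward the smallest weights.

## The cell graph

Distances are Euclidean in the preprocessed expression space (after HVG
selection and standardization); an embedding-space graph (e.g. PCA) is a
scalability extension we deliberately left out to keep distances
interpretable at the scales this package targets. The defaults:

* $K = \min(\lfloor n/3 \rfloor, 1000)$, user-overridable.
* An edge survives only if each endpoint is within the other's $K$ nearest
  neighbors (mutual rule); ties at the $K$-th distance are all included
  rather than cut arbitrarily, so the graph is invariant to cell order.
* $\sigma$ is the median of the retained edge distances, each undirected
  edge counted once. Degenerate case: when more than half of the edges
  have distance zero (duplicated or noiseless cells) the median is zero,
  and the bandwidth falls back to the median of the *positive* distances
  with a warning; if every distance is zero, an explicit `sigma` is
  required. Isolated cells are allowed (zero degree, zero Laplacian row).

## Preprocessing

The count-to-feature chain is the standard single-cell recipe: cells with
fewer than 200 detected genes or more than 20% mitochondrial counts (gene
symbols prefixed `MT-`/`mt-`, configurable) are removed; genes detected in
fewer than 3 cells are removed; counts are library-size normalized to
$10^4$ and log-transformed with the natural log,
$x' = \log(x\,/\,s \cdot 10^4 + 1)$. Highly variable genes are ranked by
standardized variance $v_i = \sigma_i^2 / f(\mu_i)$ where $f$ is a loess
fit (span 0.3, degree 2) of log variance on log mean — the common
variance-stabilizing trend; with too few informative genes for a local
fit the trend degenerates to a flat (mean-variance-constant) trend, which
preserves the variance ranking. Ties rank by gene id, so selection is
deterministic and permutation-equivariant.

The model consumes the union of the top 1000 HVGs and all marker genes
present in the matrix, marker genes first so the marker block of $M$
aligns with the leading rows. Rows are then standardized to mean 0,
variance 1. Standardization conflicts with the model's non-negativity, and
we repair it by **clipping negatives to zero**: it is the minimal
intervention, it preserves the sparsity of below-average entries, and the
retained positive part is exactly the "expressed above average" signal
that the factors should explain. The alternative — shifting each gene by
its minimum — densifies the matrix and was rejected. Zero-variance genes
become all-zero rows (with a warning) rather than errors: they carry no
signal either way.

## The simulator

`simulate_cells()` generates the benchmark used throughout the package's
tests. Genes split into disjoint per-type marker sets and shared
background genes; shared means are $m_i \sim N(\mu_0, \sigma_0^2)$; the
mean of gene $i$ in type $k$ is $a\,m_i$ for its own markers and
$m_i - \delta$ otherwise; observed values add Gaussian noise with variance
$\sigma_{hetero}\,\mu + \sigma_{homo}^2$, are truncated at zero, and are
then zeroed independently with dropout probability $\pi_0$. Optional batch
shifts add fixed offsets to the gene means of predefined cell groups.
Stage order is means → noise → truncation → dropout, so that observed
zeros decompose into dropout plus truncation.

The benchmark configuration is 1200 cells, 4 equally frequent types, 20
markers per type, 100 background genes. The distribution defaults
($\mu_0 = 5$, $\sigma_0 = 1$, $a = 3$, $\delta = 1$, $\pi_0 = 0.3$,
$\sigma_{hetero} = 0.2$, $\sigma_{homo} = 0.5$) put roughly 30% zeros,
a 3-fold marker elevation and noise of the same order as the between-gene
spread — a regime we consider representative of a well-separated sorted
population. All parameters are exposed; none are revisited by the tests.

What the simulator does **not** emulate: count statistics (no negative
binomial or UMI sampling — values are truncated Gaussians), ambient RNA,
doublets, or realistic batch structure beyond additive mean shifts. Tests
that pass on this generator therefore certify the optimizer and the
pipeline logic, not performance on real tissue atlases.

### Prior corruption

Robustness experiments degrade the priors with exact counts rather than
i.i.d. coin flips, so the corruption level on the x-axis is exact:
`corrupt_labels()` keeps `round(f * n)` labels and flips
`round(e * n_kept)` of them to a uniformly random *different* type;
`corrupt_markers()` swaps `round(e * |G_k|)` markers per type for random
genes not currently marking that type. In the label-noise and marker-noise
scenarios of `run_robustness()` the supervision fraction is held at 20% of
cells (the midpoint of the 10–30% range exercised by the label-sparsity
scenario); each scenario varies one knob at a time.

## Evaluation conventions

Accuracy is reported as a percentage of correctly annotated cells;
weighted F1 averages one-vs-rest per-class F1 scores with class-size
weights. By default both are computed on the cells that carried **no**
supervision, since labeled cells are pinned by construction; a flag
includes them. A class never predicted receives precision 0 (logged, not
an error).

The marker-consistency analysis asks whether $U$ recapitulates the marker
structure: each marker gene's dominant factor is its row argmax, per-type
counts are normalized into the proportion matrix $P_{c \to k}$ (rows sum
to 1), each factor is assigned the type contributing most of its dominant
markers, and the marker-gene accuracy is the fraction of annotated marker
genes whose dominant factor's type is among the gene's annotated types —
a gene marking several types is correct if any of them matches. Ties
always resolve to the lowest index; a factor on which no marker dominates
is reported unassigned and counts against accuracy. Multi-type genes also
carry weights $1/|C_i|$, exposed for downstream weighting although the
headline accuracy follows the unweighted count definition.

## Problem sizes used by the test suite

The suite exercises the full benchmark (1200 cells) for the headline
robustness and noiseless-recovery checks — about 30 runs of the complete
simulate/graph/fit cycle — and drops to 120–300 cells for pipeline,
tuning and property tests, with randomized-instance sweeps (dimensions up
to 50, factors up to 5, 100 instances) for optimizer invariants. These
sizes are the package's own choice of a thorough-but-quick default; every
driver scales to larger runs by changing `sim_config()` and `replicates`.

## Known limitations

* Factors are fixed one-per-type; cell types absent from both priors
  cannot be discovered (a cell of an unseen type is forced onto the
  nearest known factor, though it often separates visibly in $V$).
* The dense Laplacian and distance matrix make memory quadratic in cells;
  beyond a few tens of thousands of cells a sparse graph and an
  embedding-space KNN would be needed.
* Clipping after standardization discards the below-average half of each
  gene's signal by design; genes whose information is predominantly
  *down*-regulation are weakly represented.
* Weight defaults were chosen for matrices standardized as above; on
  unstandardized inputs the penalty scales change meaning and should be
  retuned via `cellnmf_tune()`.
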