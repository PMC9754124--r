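---
title: "Reference-anchored bipartite-graph clustering: model and methods"
author: "lfsc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-anchored bipartite-graph clustering: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`lfsc` clusters single cells by learning how each cell decomposes over a
small dictionary of reference transcriptomes, instead of by comparing
cells with each other. Given log-normalized expression
$X \in \mathbb{R}^{m \times n}$ over $m$ highly variable genes and $n$
cells, and a reference panel $R' \in \mathbb{R}^{m \times d'}$
($d' \ll n$), the anchor graph $A \in \mathbb{R}^{d' \times n}$ is fit by

$$
\min_{A \ge 0,\; \mathbf{1}^\top a_i = 1}\;
\|X - R'A\|_F^2 + \delta \|A\|_F^2 + \beta\,\mathrm{Tr}(F^\top L F),
\qquad F^\top F = I,
$$

where $L = I - D^{-1/2} B D^{-1/2}$ is the normalized Laplacian of the
bipartite adjacency $B = \begin{bmatrix} 0 & A \\ A^\top & 0\end{bmatrix}$
and $F \in \mathbb{R}^{(d'+n) \times k}$ collects the eigenvectors of the
$k$ smallest eigenvalues of $L$. Because the multiplicity of $L$'s zero
eigenvalue equals the number of connected components of $B$, driving the
bottom-$k$ eigenvalue sum to zero forces the graph into exactly $k$
components: the partition is part of the model, not a post-hoc cut.

Assumptions worth stating explicitly:

* each cell is approximately a convex combination of reference profiles
  on the shared highly-variable-gene space (the simplex constraint makes
  the coefficients interpretable as affinities and fixes every cell's
  graph degree at exactly 1);
* the reference panel covers the populations present — a population with
  no nearby reference is still separated (connectivity does the work) but
  is annotated "Unknown type";
* log-scale expression is comparable between the cell matrix and the
  panel (see *Bulk panel scale* below).

## Alternating optimization

The objective is biconvex in $(A, F)$, and both blocks have exact
updates:

* **F-update.** With degree-normalized graph
  $\bar A = D_a^{-1/2} A D_c^{-1/2}$, every singular triplet
  $(\sigma, u, v)$ of $\bar A$ gives a Laplacian eigenpair
  $\bigl(1-\sigma, (u, v)/\sqrt{2}\bigr)$, so the bottom-$k$ eigenspace
  comes from a thin SVD of a $d' \times n$ matrix — never from the
  $(d'+n) \times (d'+n)$ Laplacian, which the solver never materializes.
* **A-update.** $\mathrm{Tr}(F^\top L F)$ couples cells only through the
  degrees. Freezing the degrees at the previous iterate (standard in
  constrained-Laplacian-rank methods) makes the penalty separable:
  with $v_{ji} = \tfrac12 \| f_{a_j}/\sqrt{d_j} - f_{c_i}/\sqrt{d_i}\|^2$
  each cell solves the strictly convex quadratic program
  $\min_{a \in \Delta} \|x_i - R'a\|^2 + \delta\|a\|^2 + \beta v_i^\top a$
  over the probability simplex. A primal active-set method (compiled,
  RcppArmadillo) solves each QP exactly, so the update provably never
  increases the frozen-degree objective — a property the test suite
  checks against an exhaustive simplex-grid oracle and across 30
  alternations.

$\beta$ is adapted toward the connectivity target after every iteration:
doubled while the graph has fewer than $k$ components, halved while it
has more, held once the count is exactly $k$. The fit stops when the
relative objective change falls below `tol` with exactly $k$ components,
or at `maxIter` (returning the best iterate with `converged = FALSE` and
a warning). The initial graph is the $\beta = 0$ solution.

Per-iteration cost is $O(md'n + d'^2 n + d'^3 n)$ — linear in cells —
and all solver state is $O(d'n)$.

# Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `delta` | 1 | ridge on A; keeps each per-cell QP strictly convex and spreads affinity over similar references. Clustering is flat across 0.1–100 on synthetic data (the suite checks a 5 × 8 grid), so the default sits mid-range. |
| `beta0` | 0.01 | initial spectral weight; only the starting point of the doubling/halving schedule, which typically travels several orders of magnitude, so its value matters little (same grid check, 1e-4 to 100). |
| `k` | `"auto"` | cluster count; `estimateK()` when not given. The target of the connectivity constraint, so it must be ≤ d′. |
| `maxIter`, `tol` | 30, 1e-6 | outer iterations and relative objective tolerance; 30 iterations accommodate the β schedule even from a tiny `beta0`. |
| `nHvg` | 2000 | highly variable genes kept; the common single-cell default, capped by the gene count. |
| `lowFrac`, `highFrac` | 0.05, 0.95 | QC band on the fraction of cells expressing a gene; removal requires being strictly outside the band, so boundary genes stay. |
| `threshold` | 0.6 | annotation correlation cut; strictly greater assigns a type, otherwise "Unknown type". |
| `downsampleRatio` | 1 | fraction of each labeled type's cells averaged into its reference (ceiling, so every type keeps ≥ 1 cell even at 0.05). |

# Preprocessing and reference panels

Gene QC and normalization run on raw counts: each entry becomes
$\log(m_{ij} \cdot 10^4 / s_j + 1)$ (natural log; $s_j$ = cell total).
Highly variable genes are ranked by a variance-stabilizing criterion:
per-gene variance of standardized counts, after standardizing by the
standard deviation a loess trend of log-variance on log-mean predicts
(degree-2 polynomial fallback when fewer than 30 genes are available),
with standardized values clipped at $\sqrt{n}$. HVG selection happens on
raw counts of QC-passed genes; normalization is applied before the
downstream stages, and both modalities are then restricted to the
intersection of the selected genes with the panel's genes.

Three panel constructions are supported:

* **bulk-selected** — each cell votes for its Pearson-argmax bulk sample;
  exactly the samples that win at least one vote are retained. Irrelevant
  samples (decoys in the synthetic benchmark) are discarded by
  construction.
* **sc-averaged** — per-type means of labeled cells, optionally from a
  seeded subsample of each type.
* **kmeans** — unsupervised centroids, the ablation mode: no labels, so
  no annotation.

**Bulk panel scale.** Whether a bulk panel should pass through the same
log transform as the cells is not determined by the model; `lfsc` applies
`log1p` to bulk values by default (`bulkLog = "log1p"`) so both
modalities are on a log scale, and exposes `bulkLog = "none"` for panels
that are already log-scale — the synthetic generator's panels are, since
they are built from mean log-normalized profiles.

# Choosing k

`estimateK()` scores each candidate $k$ by replicate stability: seeded
K-means on the top-20 principal components, several seeds per $k$, and
instability = 1 − mean pairwise adjusted Rand index between replicate
partitions; the largest $k$ with instability ≤ 0.05 wins. Rationale:
above the true cluster number K-means must split homogeneous groups
arbitrarily, so replicate partitions stop agreeing. A child-overlap rule
(flagging clusters that split into two substantial children at $k+1$) was
considered and rejected: genuine structure also splits cleanly below the
true $k$, so overlap-based instability cannot separate real from
arbitrary splits — on $c$ copies of $c$ distinct points it flags every
level and cannot return $c$, while the replicate rule returns $c$
exactly (this is a unit test). Cluster-tree stability tools in the field
are visual diagnostics with no single numeric read-off; this rule is one
operationalization, its knobs (`instabilityBudget`, `nReps`, `nPcs`) are
exposed, and an explicit `k` always bypasses it.

# Numerical choices

* **Simplex orientation.** The constraint binds each *cell's* coefficient
  column of $A$ (columns sum to 1): reconstruction $X \approx R'A$ is
  column-wise, and unit columns make every cell degree exactly 1.
* **Degenerate degrees.** Anchor degrees below 1e-12 are floored at
  1e-12 before $D^{-1/2}$ (isolated anchors otherwise produce infinities).
* **Component counting.** Support threshold 1e-8 on entries of A; counted
  by graph traversal (igraph), cross-checked in tests against the
  zero-eigenvalue multiplicity of the explicit Laplacian on 50 random
  graphs.
* **Correlation conventions.** Any zero-variance vector correlates 0 with
  everything; argmax ties break to the lowest index. Both matter for
  degenerate clusters and duplicated references.
* **K-means.** k-means++ seeding, best of `restarts` runs by
  within-cluster sum of squares, Lloyd iterations with *randomized*
  tie-breaking in the assignment step. Randomized tie-breaking makes
  exact-duplicate points (which arise in the `estimateK` stability probe)
  behave as a genuinely random split rather than erroring or collapsing
  deterministically; on non-degenerate data ties have measure zero and
  the iteration is ordinary Lloyd (cross-checked against `stats::kmeans`
  on separated data).
* **Embedding ambiguity.** $F$ is defined up to sign/rotation within
  eigenspaces; downstream use (K-means on rows) is invariant, and tests
  compare subspace projectors, never signed vectors.
* **Seeding.** Every stochastic stage takes an explicit seed
  (`withr::with_seed`, so the caller's RNG state is untouched); the
  pipeline threads one seed through all stages, and the solver itself is
  deterministic.
* **ACC metric.** Optimal cluster-class matching via an in-package
  Hungarian algorithm on the zero-padded confusion matrix, verified
  against brute-force permutation enumeration.

# The synthetic generator

`makeClusters()` emulates the features the method actually consumes:
cluster-specific expression programs (disjoint marker blocks elevated by
`separation` on the log scale over a shared baseline — disjointness makes
identifiability a function of `separation` alone), realistic count noise
(negative binomial, dispersion 0.3), broad library-size variation
(log-normal, meanlog 9.2 / sdlog 0.3, median ≈ 10k counts) and dropout
(i.i.d. zeroing). `makeBulkFromTruth()` derives a matched panel: per-type
mean log-normalized profiles plus Gaussian noise, and optional decoy
samples (permuted global mean profiles, uncorrelated with every cell)
that exercise the bulk-selection step.

It does **not** emulate batch effects, doublets, ambient RNA,
gene–gene correlation beyond the marker blocks, count-depth-dependent
dropout, or continuous trajectories. Passing tests therefore show the
machinery is correct under the stated generative model, not that real
tissues reach any particular accuracy: separation 5 is essentially
noiseless structure (the perfect-recovery benchmark), separation 2 the
moderate regime used for the robustness checks.

Test problem sizes: the end-to-end benchmark runs 300 cells × 500 genes;
the hyperparameter grid and downsampling sweep 200 × 300 (30 seeds per
ratio); the timing property compares fits at 2,000 and 8,000 cells at
fixed d′ — sizes chosen so the whole suite completes in a few minutes on
one core while every regime (stochastic sweep, scaling, oracles up to
d′+n = 60 dense eigendecompositions) stays covered.

# Known limitations

* The annotation unit is the cluster: per-cell typing of mixed clusters
  is out of scope, as are hierarchical label ontologies.
* d′ must be ≥ k — you cannot ask for more clusters than reference
  samples; with bulk-selected panels, d′ is data-driven and may come out
  smaller than hoped if few samples win argmax votes.
* The β schedule guarantees progress toward k components but not a
  monotone full objective across iterations (β itself changes); the
  monotone quantity is the frozen-degree objective within each A-update.
* Reference panels whose types are transcriptionally close produce
  correlation near-ties; annotation then depends on the tie-break order.
* Cell-level QC (doublets, mitochondrial fraction) and batch correction
  are deliberately out of scope; run them upstream if needed.
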