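---
title: "Hierarchical cell-type deconvolution: model, choices, and limits"
author: "hideconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical cell-type deconvolution: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical model behind `hideconv`, the
assumptions it makes, the tunable parameters and their defaults, the
numerical choices taken where the method leaves room, and what the
package's simulation-based validation does and does not establish about
real data.

## The model

A bulk expression profile is modeled as a non-negative linear combination
of cell-type reference profiles: for genes $p$, cell types $q$, samples
$n$,
$$ Y = X C, \qquad X \in \mathbb{R}_+^{p\times q},\; C \in
\mathbb{R}_+^{q\times n}, $$
where a column of $C$ holds one bulk's cellular proportions. The core
estimator is weighted non-negative least squares,
$$ \hat C(g) = \arg\min_{C \succeq 0} \lVert \mathrm{diag}(g)\,(Y - XC)
\rVert_F^2, $$
with per-gene weights $g$ learned from training mixtures of known
composition by minimizing
$$ L(g) = -\sum_{j=1}^{q} \mathrm{cor}\!\left(C_{j,\cdot},\,
\hat C_{j,\cdot}(g)\right), \qquad \lVert g\rVert_2 = 1 . $$
Genes that help ranking samples by a type's abundance are up-weighted;
genes dominated by technical or within-type biological noise are
down-weighted. Effective weights enter as $g^2$, so signs are immaterial,
and because the ridge term below scales with $g$, the loss is *exactly*
invariant to positive rescaling of $g$ — the unit norm is a normalization,
not a restriction.

The hierarchy is a rooted forest of cell types plus an ordered list of
*levels*: antichains covering every leaf once. A type with no subdivision
at some level stands for itself there, so the same name may appear at
several levels without phantom nodes. Depth is unlimited; the packaged
trees have three levels because that is the resolution at which annotated
references are commonly published.

Fitting walks the levels coarse to fine:

* **Step 0 (root).** Learn weights against the truth aggregated to the
  root types; at prediction, solve, recalibrate each type affinely
  ($\theta \hat C_{j,\cdot} + \Delta$, fitted by ordinary least squares of
  truth on estimate over the training mixtures, negatives clipped), and
  normalize columns to sum one.
* **Step 1 (residual bulks).** For parent type $k$ at level $\ell$:
  $Y_k = Y - X_{P\setminus k}\hat C_{P\setminus k}$, clipped at zero,
  using the *finalized* level-$\ell$ estimates. What remains approximates
  the expression contributed by $k$ alone.
* **Step 2 (child weighting).** Learn fresh weights for $k$'s children on
  the residual bulks — the loss now only involves the children, so the
  weights specialize in separating sibling subtypes.
* **Step 3 (normalization).** Per-child affine recalibration and clipping
  as at the root, then per-sample factors
  $\xi_i = \hat C_{\text{parent},i} / \sum_{k'} \hat C_{k',i}$ (set to 0
  when the denominator is 0) scale the children so they sum exactly to the
  parent.

Consequences, all of them exact algebraic properties rather than empirical
tendencies: every level's columns sum to one; children sum to their parent
at every depth; a zero parent silences its whole subtree; and training or
predicting deeper levels never changes coarser outputs, so refinement can
be stopped at any level.

## Scales and units

Consensus references are arithmetic means of depth-normalized
(counts-per-10k) cell profiles, so every reference column sums to
$10^4$ and the reference is invariant to global sequencing-depth changes.
Pseudo-bulks, in contrast, are raw sums of cell count vectors. To make the
two commensurate — in particular so that proportion-scale parent estimates
can be multiplied onto reference columns and subtracted from bulks in the
residual step — `hideFit()` and `hidePredict()` scale every bulk column to
a fixed total of $10^4$ on entry. With that convention a column of
$X\hat C$ and a bulk column carry the same unit, residual columns total
approximately $10^4 \cdot \hat C_{k}$, and raw solver outputs land near
the proportion scale, leaving the affine recalibration with slopes close
to one. This normalization is internal to the model: data files and the
pseudo-bulk generator are untouched by it.

The affine recalibration itself deserves a caveat: it is a regression of
truth on estimate fitted over the *training* composition distribution.
Its slope absorbs the attenuation caused by estimation noise
(errors-in-variables), which makes it optimal for mixtures distributed
like the training ones and slightly shrinking for compositions far outside
that distribution.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `topK` (`genes.top_k`) | 5000 | genes kept, ranked by variance across the leaf-level reference columns (ties broken by input order); one shared gene index for the whole model |
| `cellsPerBulk` | 100 | cells summed per pseudo-bulk; truth entries are multiples of `1/cellsPerBulk` |
| `nTrainBulks` / `nTestBulks` × batches | 20000 / 1000 × 10 | training and evaluation design of the full-scale protocol |
| `trainOptions()$maxIters` | 1000 | gradient-descent budget per node |
| `trainOptions()$tol` | 1e-6 | stop when the relative loss improvement falls below this |
| `trainOptions()$ridge` | 1e-8 | relative ridge jitter, $\varepsilon = \text{ridge}\cdot\mathrm{tr}(X^\top \Gamma X)/q$ |
| `hidePredict()$maxMissing` | 0.05 | tolerated fraction of model genes absent from new bulks |

Pseudo-bulk cells are drawn uniformly from the whole annotated pool —
without replacement within a mixture, with replacement across mixtures —
so mixture compositions follow the pool's marginal type frequencies with
multinomial variation.

## Numerical choices

* **Training-time estimator.** Weight learning differentiates through the
  *unconstrained* ridge-regularized closed form
  $(X^\top\Gamma X+\varepsilon I)^{-1}X^\top\Gamma Y$, $\Gamma =
  \mathrm{diag}(g^2)$, with an analytic gradient; the cone-constrained
  solver is used at inference. The constraint's treatment during training
  is genuinely open; the differentiable route keeps each iteration cheap
  and, empirically, constrained and unconstrained solutions coincide
  wherever the optimum is interior. `trainOptions(constrainedGradient =
  TRUE)` trains against the constrained solver with numerical gradients
  for small gene counts.
* **Optimizer.** Start at $g_i = 1/\sqrt{p}$; gradient descent with a
  doubling/halving backtracking line search; renormalize to unit norm
  after every accepted step; accept only strict decreases, so the loss
  trace is monotone and the result can never be worse than uniform
  weights.
* **Constrained solves.** The $p$-dimensional weighted problem is reduced
  to $q$ dimensions via the Cholesky factor of the weighted Gram matrix
  and solved with the Lawson–Hanson active-set algorithm; a rank-deficient
  weighted design falls back to a small ridge jitter with a warning.
* **Degenerate inputs.** Truth-constant cell types are excluded from the
  loss (the Pearson correlation is undefined; rare types can be absent
  from every mixture at small $n$). A constant estimate row makes the
  recalibration fall back to $\theta = 1, \Delta = 0$. All-zero proportion
  columns at the root normalize to equal shares. Single-child nodes bypass
  fitting entirely — the child inherits the parent row, which the $\xi$
  step would force anyway.
* **Residuals from own estimates.** Residual bulks are built from the
  model's own (finalized) parent-level training estimates, not from the
  ground truth — the same information available at deployment, so
  training matches the prediction-time data flow.

## The simulator: what it emulates, what it does not

`simulateCells()` emulates a lineage-annotated single-cell compendium:
every tree node perturbs a random marker subset of its parent's mean
profile in log space, so siblings share most of their transcriptome and
separation decays with depth; counts are negative binomial around
per-cell library sizes. Defaults — 1000 genes, marker fractions
(0.20, 0.05, 0.02) and natural-log effects (1.5, 1.0, 0.8) by depth, NB
dispersion 0.5, mean depth 2000 — mirror the broad structure of real
annotated data: major populations differ in hundreds of genes, subtypes
in a few dozen, with substantial overdispersion.

The simulator does *not* emulate platform shifts between single-cell and
bulk measurements, ambient RNA, doublets, unequal per-type abundances, or
cell types present in bulks but missing from the reference. Passing
simulation benchmarks therefore demonstrates the algorithm's correctness
and its hierarchy guarantees, not immunity to those real-data
complications; the gene-wise rescaling (`computeRescaleFactors()`)
addresses the platform-mean component only.

Two regimes are used in validation, chosen once:

* the *default* regime above, at reduced scale (2000 training mixtures,
  200-sample test batches, 600 kept genes on a 4/7/10-type tree) for the
  benchmark and ablation comparisons;
* a *well-separated* regime — marker fractions (0.35, 0.2, 0.15), effects
  (3, 2.5, 2.5), dispersion 0.05, depth 4000 — for parameter-recovery
  checks, where the method should and does recover truth closely
  (per-type correlation above 0.9 at all levels; noise-free mixtures with
  training-law compositions recovered to ~0.02 per entry). An earlier,
  weaker instantiation of this regime left sibling consensus profiles
  correlated up to 0.95 for some marker draws, which is not
  "well separated"; the regime was strengthened to deserve its name.

## Ablations

`hideAblation()` provides the two reduced models used to attribute
performance: `"flat"` learns one weight set directly at the finest level
and aggregates upward (no per-node machinery), and `"no_residual"` keeps
the root model and per-node weight learning but solves children on the
original bulks and reports them raw (no residuals, no recalibration, no
$\xi$). On the packaged benchmark the full model's NMAE is lowest at the
major and minor levels; the raw variant's estimates are strongly inflated
because missing sibling contributions are absorbed into the types being
fitted — the residual and normalization steps are what make the estimates
quantitatively accurate, not just well correlated.

## Metrics

Per-type Pearson correlation is computed across samples; undefined
(constant) rows are reported missing and excluded from level means, with
the exclusion count carried alongside. NMAE is the mean absolute error
divided by the type's mean true proportion — the normalizer is a
convention (a `"range"` switch is provided); absolute NMAE values are
therefore comparable only within one convention, while orderings between
methods are stable.

## Limitations

Estimates inherit the reference's biases: cell types absent from the
reference are redistributed over the types present; background or
tumor-specific expression not spanned by the references is not modeled.
The correlation loss optimizes ranking, not calibration — the affine
recalibration restores scale only as far as the training composition
distribution reaches. And the hierarchy constraint transfers, rather than
removes, estimation error: a biased parent bounds all of its children.
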