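---
title: "Methods: the Pf2 model, its fitting algorithm, and the package's design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Pf2 model, its fitting algorithm, and the package's design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parafac2sc)
```

## The model and its assumptions

A multi-condition single-cell experiment yields one cells-by-genes matrix
per condition, `X_i` of shape `J_i × K`, with the cell counts `J_i`
varying across the `I` conditions. Pf2 (PARAFAC2) models the collection as

$$X_i \approx P_i\, B\, \mathrm{diag}(a_i)\, C^\top,
\qquad P_i^\top P_i = I \;\; \forall i,$$

minimizing the summed squared Frobenius error. The orthonormal-column
projections `P_i` align each condition's cells onto a shared rank-`R`
eigen-state frame; `B` couples eigen-states to components; row `a_i` of
the condition factor matrix `A` scales components per condition; `C`
carries gene loadings. The key assumptions are (i) every condition's
expression is well approximated inside a common `R`-dimensional gene-space
frame, (ii) conditions differ mainly by how strongly they express each
component (the classical parallel proportional profiles idea), and (iii)
residual variation is unstructured. Inputs are assumed to be
depth-normalized, variance-stabilized and gene-centered (see
preprocessing below); the model itself is scale-free.

## The fitting algorithm

The direct alternating algorithm is used:

1. **Initialization.** The condition matrices are row-concatenated into a
   pooled `(ΣJ_i) × K` matrix and its truncated SVD is taken (exact LAPACK
   by default, or seeded randomized SVD with oversampling 10 and two power
   iterations). The first `R` right singular vectors initialize `C`; `B`
   starts as the identity and `A` as all ones. This is the only
   shape-consistent assignment of the pooled SVD to the three factor
   matrices, and it makes the first projection update operate against the
   dominant gene subspace.
2. **Projection update.** With factors fixed, each `P_i` is the orthogonal
   Procrustes minimizer of `‖X_i − P_i M_i‖` with
   `M_i = B diag(a_i) Cᵀ`: from the SVD `M_i X_iᵀ = U Σ Vᵀ`, set
   `P_i = V Uᵀ`. If `M_i X_iᵀ` is identically zero (an all-zero condition,
   or factors that assign it nothing) the update has no well-defined
   direction and the fit stops with an error rather than returning an
   arbitrary orthonormal basis that would silently poison downstream
   factors.
3. **CP sub-step.** The aligned tensor `T` with slices `T_i = P_iᵀ X_i`
   (shape `I × R × K`) is decomposed by 20 alternating-least-squares
   sweeps of CP (canonical polyadic) decomposition, warm-started from the
   previous iteration's factors. Scale is carried inside the factor
   matrices during fitting; rank-deficient normal equations fall back to
   the Moore–Penrose pseudoinverse and are flagged on the result object.
4. **Convergence.** R2X — one minus the ratio of residual to total squared
   Frobenius norm, computed against the *original* ragged data — is
   tracked each iteration; fitting stops when its absolute change drops
   below `tol` (default `1e-6`) or after `max_iter` (default 200)
   iterations. Because the projection update is exact and ALS sweeps never
   increase the residual, the unaccelerated R2X sequence is monotone
   non-decreasing, which the test suite asserts.

### Acceleration

An optional all-at-once Nesterov-like extrapolation (default on) jointly
extrapolates `A`, `B`, `C` after each iteration by a momentum coefficient
β (seeded at 0.05). An extrapolated point is evaluated through a full
projection update; if it improves R2X it is accepted and β grows by the
factor γ = 1.1 up to a running bound (seeded at 1, grown by γ̄ = 1.03),
otherwise it is rejected and β shrinks by η = 1.5. Rejecting worsening
steps preserves the monotone-convergence guarantee of the plain
alternation, which is why every correctness test also runs unaccelerated.
The published description of this scheme leaves the exact accept/reject
bookkeeping open; the restart rule above is one faithful-in-spirit
realization.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `rank` | — | components `R`; must satisfy `R ≤ min(K, min_i J_i)` |
| `tol` | `1e-6` | convergence threshold on |ΔR2X| (dimensionless) |
| `max_iter` | 200 | outer iteration cap |
| `cpd_iter` | 20 | CP-ALS sweeps per outer iteration |
| `accelerate` | `TRUE` | Nesterov-like extrapolation with safe restart |
| `svd_method` | `"exact"` | `"randomized"` trades determinism class for speed on wide data |
| `seed` | 0 | controls every random draw; exact-SVD fits are bit-reproducible |

## Preprocessing

`preprocess_dataset()` implements the pipeline the model expects, in
order: (1) drop genes whose mean raw count pooled over *all* cells falls
below `min_gene_mean` (0.01 by default; a stricter 0.1 suits
million-cell cohorts); (2) scale each cell to `cpm_scale` total
(counts-per-million, `1e6`); (3) optionally divide each gene by its pooled
total rescaled by the cell count, so a uniformly expressed gene keeps unit
magnitude; (4) transform entries by the delta-method
variance-stabilizer `g(y) = log(y + 100)` (natural log; the additive
constant tempers the variance of low counts); (5) center each gene to
pooled mean zero.

Two deliberate choices: *gene-sum scaling* is interpreted as division by
the gene's pooled total (kept at unit scale via the cell count) and is
switchable (`gene_sum_scale`), since "scale each gene by its sum" admits
several readings and the choice interacts with the log pseudocount; and
*centering is pooled across conditions*, never per-condition — per-condition
centering would delete exactly the condition-level differences the
condition factors exist to capture. Cells with zero total count are an
error, not silently dropped: CPM is undefined for them and they indicate
upstream QC problems.

## Post-factorization conventions

A CP-type solution is unique only up to scale, sign and order of
components. `pf2_standardize()` fixes all three: factor columns are
normalized to unit Euclidean norm with the scale collected in per-component
weights; signs are flipped so condition- and eigen-state-factor column
means are nonnegative, with the compensating flips absorbed by the gene
factors (two flips cancel there); and components are sorted by ascending
Gini coefficient of the absolute condition loadings, ties broken by
original index. The Gini index is computed on absolute values because
condition loadings may be negative and the quantity of interest is
association inequality; ascending order puts broadly shared components
first. All of this is a re-parameterization: reconstruction is unchanged
to machine precision, and the operation is idempotent.

`weighted_projections()` returns `W_i = P_i B`, giving every cell an
association score per component; these scores color external embeddings
of the concatenated projections.

## Factor match score and its two deviations from the obvious reading

`fms()` scores two decompositions of the same conditions and genes as the
mean, over optimally matched component pairs (linear sum assignment,
solved by a Hungarian algorithm implemented in the package and tested
against brute-force enumeration), of

$$\Big(1 - \frac{|w_r - w_s|}{\max(w_r, w_s)}\Big)\;
  |\cos(A_{\cdot r}, A_{\cdot s})|\; |\cos(C_{\cdot r}, C_{\cdot s})|.$$

Eigen-state factors are excluded: their rows describe cell eigen-states
whose identity shifts with the cells present. Two details deserve
justification because the naive alternatives fail:

- **Cosines are compared in magnitude.** The eigen-state frame carries an
  orthogonal gauge freedom — replacing `P_i → P_i Q`, `B → QᵀB` for any
  orthogonal `Q` leaves every reconstruction unchanged — so the sign
  convention applied to `B` columns cannot propagate a consistent sign
  into `C` across two independent fits. Empirically, signed cosines score
  a perfectly recovered component at −1 whenever the two fits landed in
  different gauges; magnitudes are the gauge-invariant comparison.
- **Weights are compared as relative shares** (each weight vector is
  normalized to unit sum before the penalty). Absolute component
  magnitudes grow with the number of cells, so comparing a fit on the full
  dataset against a fit on half the cells would incur a
  `1 − sqrt(1/2) ≈ 0.29` penalty per component from data size alone, even
  with identical factors. Relative shares penalize what the score is
  meant to detect — redistribution of weight among components.

Self-comparison scores 1, and the score is invariant to component
permutation and to standardization of either argument.

## Stability protocols and ablation experiments

`stability_curve()` implements two protocols. *Subsample*: fit the full
data once, refit on copies with each condition's cells subsampled without
replacement to a fraction (drawn cells keep their original order so
projection rows stay reproducible), and record FMS against the full fit —
probing dependence on data size at fixed rank. *Bootstrap*: at each rank,
fit the original data and one per-condition bootstrap replicate of equal
shape and record their FMS — probing stability across ranks.

`ablate_cell_type()` removes (or thins to a `keep_fraction`) a labeled
cell type within a single condition, emulating an experiment in which
that population is absent. `compare_condition_weights()` then matches
components between the reference and ablated fits (same matching as FMS,
with a 0.5 gene-cosine floor to refuse nonsense matches) and reports the
per-condition drop in standardized condition weight; on data where a
labeled block drives a component, the drop is positive and largest in the
ablated condition, which the tests assert.

## The synthetic-data generator

`pf2_sim()` draws data from the model class itself:
`X_i = P_i B diag(a_i) Cᵀ + σ ε` with random column-orthonormal `P_i`
(polar factors of Gaussian matrices), orthonormalized Gaussian `C`,
near-identity `B` (identity plus Gaussian of sd 0.1 — keeping eigen-states
interpretable and the Procrustes subproblem well-conditioned; `hard = TRUE`
switches to a dense random `B` for stress tests), and condition factors
from a uniform, lognormal or block law. The planted signal is rescaled to
unit per-entry root-mean-square, so `noise_sd` reads directly as a
noise-to-signal amplitude ratio (`noise_sd = 1` puts roughly half the
variance in noise). Labeled cell blocks emulate a cell type driving a
component: block cells receive a strong loading (default boost 3) on the
chosen component while the remaining cells' loading on that component is
damped to 20% — a component that *is* a cell-type program is, by
definition, barely expressed by other cells. Ground truth is returned
standardized, with the block-to-component mapping resolved through the
standardization reordering.

What the generator does **not** emulate: counts, dropout, library-size
variation, batch effects, or gene–gene correlation beyond the planted
components. Passing recovery tests therefore demonstrates correctness of
the estimator on model-true data, not robustness to the full messiness of
real scRNA-seq; the preprocessing pipeline exists precisely to bring real
data closer to the model's assumptions.

## Association workflow

`classify_conditions()` regresses a binary per-condition label on the rows
of `A` with L1-penalized logistic regression (glmnet; convergence
threshold `1e-4`, iteration cap 10,000) under a deliberately conservative
cross-validation: each processing batch serves once as the *training* set
with all remaining batches pooled as test, so the model must transfer out
of its batch. The regularization strength is chosen by grid search (10
log-spaced values over `[1e-3, 1e2]`) on pooled held-out AUC, ties broken
by held-out accuracy and then by sparsity. Factor columns are z-scored
before fitting (penalized coefficients are scale-sensitive; switchable via
`scale_factors`). Training folds lacking two classes — or with a class too
small for the optimizer — are skipped with a warning. AUC is the
Mann–Whitney rank statistic, cross-checked against an independent ROC
implementation in the tests. `pairwise_component_scan()` repeats the
scheme with unpenalized two-component models over all component pairs, and
`rank_selection_curve()` traces pooled AUC across ranks to guide the
choice of `R`.

## Numerical choices and degenerate inputs

- Exact SVD everywhere by default; fits are bit-reproducible given
  (data, config, seed). The randomized SVD (oversampling 10, two power
  iterations) is seeded and deterministic for a fixed seed.
- Rank-deficient least-squares systems inside CP-ALS use the
  pseudoinverse and set `pinv_used` on the result.
- `rank > min(K, min_i J_i)`, all-zero datasets, zero-total cells,
  zero-norm factor columns and degenerate Procrustes systems all raise
  validation errors rather than returning arbitrary results.
- Gini ordering ties break by original component index; assignment
  problems are solved exactly, not greedily.
- Decomposition bundles round-trip floats through 17 significant digits
  (full double precision) in plain-text CSV/JSON.

## Problem sizes used by the tests

The suite validates contracts on generated data at desk scale, chosen to
exercise every code path while keeping the default run fast: recovery and
stability checks use 6–8 conditions with 20–80 cells each and 30–50
genes at ranks 2–3; the null-calibration checks fit 40 small pure-noise
datasets; the association checks use 40 synthetic conditions in 4
batches. At these sizes the full suite completes in well under a minute.

## Known limitations

- No non-negativity or other constraints on factors; no coupled
  multi-omic or supervised variants.
- The fitting objective is non-convex: different seeds can land in
  different local optima, which is exactly what the FMS protocols are for.
- No HDF5-based I/O: datasets travel as Matrix Market + TSV bundles and
  decompositions as plain-text bundles.
- Out-of-core fitting is not supported; per-condition matrices are
  densified where dense algebra requires it.
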