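---
title: "Hybrid nearest-neighbour and fuzzy-clustering imputation: models, parameters, design"
author: "fcki authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid nearest-neighbour and fuzzy-clustering imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the imputation procedures and their assumptions, the parameters that
matter, the numerical choices behind them, what the synthetic benchmark
does and does not show, and the known limitations.

## The imputation problem

A numeric table `D` (N records × M attributes) has missing cells. The goal
is a completed table `D'` whose filled-in values are close to the unknown
truth, judged — in benchmark mode, where missingness is injected into a
complete table — by RMSE, range-normalised RMSE and MAE over exactly the
masked cells. Both imputers here are hot-deck hybrids: donors (similar
records) supply the local neighbourhood, and a regression over that
neighbourhood supplies the value, so record similarity and inter-feature
correlation are both exploited.

The methods assume attributes are numeric and on scales comparable enough
for Euclidean distance to be meaningful. The benchmark harness therefore
min–max scales each column to [0, 1] by default before masking; the core
imputers never rescale, so a user imputing raw data should scale first if
the columns have wildly different units.

## KI: automatic-k donors plus round-robin regression

For each incomplete record `R_i` (ascending row order, for determinism;
each imputed record rejoins `D` immediately and may donate to later
records):

1. **Donor pool.** `P` is every other record observed on all of `R_i`'s
   missing attributes `A_mis`. Donors may be missing elsewhere — distances
   are partial (see below) and estimates use observed values only — so the
   method works even when the dataset has no fully complete record.
2. **Self-probe k selection.** One observed attribute `z` of `R_i` is drawn
   uniformly at random (this is the only stochastic step; it consumes the
   seeded stream) and its value `AV` withheld. For every `k` from 2 to
   `N_p − 1` (`N_p` counts the pool plus `R_i`), the withheld value is
   re-estimated as the mean of attribute `z` over `R_i`'s `k` nearest
   donors, and scored by `|AV − estimate|` (the RMSE of a single value).
   The smallest `k` attaining the minimal error wins. One distance sort
   serves all `k`: the per-`k` estimates are running means over the sorted
   donor order.
3. **Subset regression.** The best-`k` donors plus `R_i` form `S`, which is
   completed by round-robin regression (below); only `R_i`'s cells are
   accepted.

When the pool cannot support the probe search (`N_p < 3`, a record with no
observed attribute, or a probe attribute observed in no donor), the record
is filled with observed column means and the fallback is logged. The
algorithm itself has no branch for these inputs, and guaranteed
imputability requires one.

## The regression stage

Missing cells of `S` start at their column's observed mean. Each round
visits every incomplete column — fewest missing cells first, ties by index
— regresses it on all other columns over the rows where it is observed,
and replaces its missing entries with predictions. Iteration stops when the
largest change of any imputed cell, relative to its column's observed
range, drops below `tol` (default 1e-3) or after `maxRounds` (default 10).
Observed cells are returned bit-identical; the stage has no randomness.

The per-column regressor is ridge with the penalty chosen by generalised
cross-validation (GCV) over a logarithmic grid floored at `ridgeLambda`
(default 1e-6). This choice is deliberate and matters:

* Donor subsets routinely have about as many rows as the table has
  attributes. A flat near-zero penalty then interpolates the donors and can
  extrapolate wildly at the query record — single-cell errors several
  within-cluster standard deviations large, bad enough to make the hybrid
  worse than plain kNNI. GCV raises the penalty exactly in that regime,
  shrinking the prediction towards the donor mean (which is the kNNI
  estimate, a sensible worst case), while on clean, exactly collinear
  subsets it selects the floor and reproduces the least-squares prediction.
  Penalties whose effective degrees of freedom would come within 0.5 of the
  row count are excluded, so the degenerate GCV limit at full interpolation
  is never scored.
* Predictors are standardised inside the fit so one isotropic penalty is
  meaningful — but the *scale* is taken over all rows of the subset,
  prediction rows included. The training rows are nearest neighbours whose
  spread can be arbitrarily small; scaling by it would turn a query sitting
  just outside that spread into an extreme standardised point and amplify
  the extrapolation it was meant to prevent. Centring stays on the training
  rows so the unpenalised intercept absorbs their mean exactly.
* Predictions are not clipped to the observed range by default
  (`clipToObservedRange` turns it on): clipping would silently bias
  extrapolation-legitimate cases, and the GCV penalty already handles the
  pathological ones.

## FCKI: fuzzy cluster routing

FCKI runs fuzzy c-means on the incomplete data, hard-assigns each record to
its highest-membership cluster (ties to the lowest cluster index), and runs
KI within each cluster. Soft clustering is preferred to k-means because
records near cluster frontiers — common under missingness — retain graded
membership in several clusters, and only the strongest association routes
the record.

FCM details and choices, where the procedure is conventionally
underspecified:

* **Objective and updates.** Alternating minimisation of
  `Σ_i Σ_k δ_ik^{m'} d²(R_i, c_k)`: closed-form membership update
  `δ_ik = 1 / Σ_j (d_ik/d_ij)^{2/(m'−1)}`, weighted-mean centroid update.
* **Missing cells** enter through the partial-distance strategy: squared
  distances over co-observed cells rescaled by `M/m_obs`, centroid averages
  over observed cells only. The per-record rescale is carried into the
  centroid weights, so each half-step exactly minimises the rescaled
  objective and the objective trace is provably non-increasing (a validity
  invariant of the fitted object). On complete data the factor is 1 and the
  procedure is standard FCM. A record observing nothing gets uniform
  membership and zero weight.
* **Fuzzifier** `m' = 2`, the near-universal default in (1, ∞);
  configurable. Larger values blur the partition, values near 1 approach
  k-means.
* **Initialisation**: membership rows drawn from a flat Dirichlet under the
  seed — reproducible, and immune to the coincident-centroid degeneracy of
  point seeding. Convergence: largest membership change below `tol = 1e-4`
  or 100 iterations.
* **Cluster count** by the elbow rule: fit each `c` in `[cMin, cMax]`
  (default `cMax = min(10, floor(sqrt(N/2)))`, bounding the sweep on small
  tables), and take the interior `c` maximising the discrete second
  difference `J(c−1) − 2J(c) + J(c+1)` of the converged objectives — the
  sharpest bend of the curve, which is what reading an elbow off a plot
  formalises. A curve with no positive second difference has no elbow and
  yields `cMin`. With a fixed `c = 1`, clustering is bypassed entirely and
  FCKI is bit-identical to KI under the same seed — a reduction the test
  suite checks.
* **Fallback ladder.** A record whose within-cluster pool is too small
  retries against the whole dataset, then takes column means; both are
  logged per record.

## Missingness generators

All three generators mask a complete table until the achieved ratio of
missing cells first reaches the requested `mdr` percent of the `V = N·M`
cells, record the truth, mask and provenance, and are bit-reproducible from
their seed.

* **MCAR** samples `ceiling(mdr·V/100)` distinct cells without replacement
  — the same distribution as redrawing random coordinates until the ratio
  is reached, without the unbounded loop at high ratios.
* **MAR** draws a causative attribute and `nAttrs` distinct dependent
  attributes uniformly (the causative may be drawn as a dependent, unless
  `excludeCausative`; note that masking the causative makes those cells
  effectively MNAR), then masks the records holding the smallest causative
  values — ties to the lowest row index, for deterministic replay — adding
  records until the ratio is reached. The masked rows are exactly the
  argmin-prefix of the causative column, a property the tests verify by an
  independent sort.
* **MNAR** is MAR with the record selection replaced by uniform random
  draws: the driver of missingness is unobservable by construction.
* A requested ratio of 0 is rejected rather than producing one missing
  cell; `mdr` must lie strictly in (0, 100). The achieved ratio exceeds
  `mdr` by less than one step's share (one cell for MCAR, `nAttrs` cells
  for MAR/MNAR).

## The benchmark harness and the synthetic generator

`runBenchmark()` crosses mechanisms {MCAR, MAR, MNAR} with ratios
{1, 5, 10, 20}% — twelve conditions per dataset per method — masking with
replicate seeds derived deterministically from the master seed, and scoring
each method over exactly the masked cells. NRMSE normalises by the range of
the masked cells' true values, the observed vector actually entering the
metric. Columns are min–max scaled to [0, 1] before masking by default, so
errors are comparable across features and datasets. MAR/MNAR need a number
of attributes losing values; the harness defaults to `nAttrs = 2` (capped
at M), a small value that keeps the ratio overshoot negligible on the grid
above.

`makeSynthetic()` draws each cluster from a multivariate Gaussian with the
equicorrelation covariance `noiseSigma² ((1−ρ)I + ρJ)` — every feature pair
at the target correlation ρ — with centroids `separation · noiseSigma`
apart along the alternating-sign unit direction `(1, −1, …)/√m`. That
direction is a deliberate geometric choice: it gives every feature a share
of the cluster separation (so a record missing any one feature can still be
routed from the rest, as in real clustered tables where groups differ
across many variables), and it stays clear of the equicorrelation
structure's leading principal axis (the all-ones direction), so the nominal
separation-to-spread ratio holds at any correlation instead of silently
collapsing as ρ grows.

What the generator emulates: inter-feature correlation (what the
regression stage exploits), cluster structure (what the routing exploits),
and exact reproducibility. What it does not: heavy tails, skewness, mixed
measurement scales, discrete or bounded attributes, and correlation
structure that varies across features. Passing tests on it show the
algorithms work as specified under their favourable assumptions; they do
not certify performance on any particular real dataset.

## Problem sizes and numerical tolerances in the test suite

The suite exercises the oracle comparisons at small sizes where exhaustive
enumeration is exact (pools of 4–12 records, 2–6 attributes; hundreds of
replicates), and the end-to-end ordering claim — mean masked-cell RMSE of
FCKI ≤ KI < global kNNI (k = 5) < mean imputation — on the 300 × 8,
three-cluster, ρ = 0.9 fixture at 10% MCAR over ten seeds, allowing an
FCKI/KI tie within one standard error of their difference. Collinear
recovery is asserted to 0.1 absolute; FCM membership row sums to 1e-9;
objective monotonicity to 1e-9; the symmetric-point membership split to
1e-3 (finite convergence tolerance).

## Known limitations

* Quadratic-ish cost: KI scans the whole dataset (FCKI: the cluster) per
  incomplete record; the per-record probe search sorts the pool once. Very
  large tables will be slow in plain R.
* Numeric attributes only; no categorical distances, no mixed types.
* Single imputation: no between-imputation variance, no posterior draws.
* The probe-based k selection scores a single withheld value, so the
  selected k is noisy by construction; the regression stage's adaptive
  penalty is what keeps occasional poor k choices harmless.
* MAR generation masks the globally smallest causative values, a stylised
  mechanism; real MAR processes are rarely this sharp.
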