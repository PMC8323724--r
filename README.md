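# fcki

Hybrid nearest-neighbour and fuzzy-clustering imputation of missing values
in numeric tabular data, for anyone who needs a complete matrix before
downstream modelling — epidemiological registries, clinical measurement
panels, sensor tables — and wants the fill-in values to respect both the
similarity between records and the correlation between features.

## The methods

Given an incomplete dataset *D* of *N* records and *M* numeric attributes,
**KI** imputes each incomplete record *Rᵢ* in turn:

1. Build the donor pool *P*: every other record observed on all of *Rᵢ*'s
   missing attributes *A_mis* (donors may be missing elsewhere, so KI runs
   even when no record is fully complete).
2. Choose *k* automatically by self-probing: withhold one observed value
   *AV = r_iz* of *Rᵢ*, and for each *k* in 2…(N_p − 1) re-estimate it as
   the mean of the probe attribute over *Rᵢ*'s *k* nearest donors
   (missing-aware Euclidean distance, rescaled by *M/m_obs*). The *k*
   minimising |AV − estimate| wins, smallest *k* on ties.
3. Form *S = d_k ∪ Rᵢ* from the best-*k* nearest donors and impute *S* by
   round-robin regression — each incomplete attribute regressed on the
   others (ridge with a GCV-chosen penalty), iterated to convergence — and
   accept only *Rᵢ*'s cells. The imputed record immediately rejoins *D* and
   may donate to later records.

**FCKI** adds a first level of similarity: fuzzy c-means soft clustering of
the incomplete data (partial distances; the cluster count picked by the
elbow of the objective curve, memberships δ_ik row-normalised to 1), each
record hard-assigned to its highest-membership cluster, and KI run within
each cluster. Records whose within-cluster pool is too small fall back to a
whole-dataset pass, then to column means; every fallback is logged.

The package also ships the three seeded missingness generators used to
build benchmarks — MCAR (uniform random cells), MAR (records holding the
smallest values of a random causative attribute lose a random attribute
set), MNAR (random records lose a fixed attribute set), each stopping at
the first count whose ratio reaches the requested MDR — plus mean and
global-kNNI baselines, masked-cell RMSE / NRMSE / MAE scoring, a
mechanism-by-ratio benchmark harness, and a correlated Gaussian-mixture
synthetic data generator.

## Worked example

```r
library(fcki)

syn <- makeSynthetic(n = 150, m = 6, nClusters = 2, separation = 8,
                     correlation = 0.8, seed = 7)
md  <- generateMCAR(syn$data, mdr = 10, seed = 7)
md
#> MaskedDataset: 150 x 6, MCAR, requested 10%, achieved 10% (90 cells), seed 7

res <- fckiImpute(maskedValues(md), seed = 7)
res
#> ImputationResult: 150 x 6 complete matrix, 69 records imputed by 'fcki'

evaluateMasked(md, imputed = res)
#> MetricsReport over 90 masked cells: RMSE 0.551466, NRMSE 0.0494826, MAE 0.410332 (range 11.1447)

evaluateMasked(md, imputed = meanImpute(maskedValues(md)))
#> MetricsReport over 90 masked cells: RMSE 2.01903, NRMSE 0.181166, MAE 1.78535 (range 11.1447)

head(recordLog(res), 3)
#>   record bestK poolSize clusterId fallback
#> 1      2     2       35         2     none
#> 2      6    13       31         2     none
#> 3     10    6        35         1     none
```

Masking 10% of a two-cluster, strongly correlated 150 × 6 table and
imputing with FCKI leaves an RMSE of 0.55 over the 90 masked cells —
roughly a quarter of mean imputation's 2.02, because the regression stage
exploits the feature correlation and the cluster routing keeps donors
local. The log shows, per record, the automatically selected *k*, the donor
pool size and the routed cluster.

A command-line front end wraps the same functions:

```sh
Rscript inst/scripts/fcki generate --mechanism mcar --ratio 10 --seed 1 --in d.csv --out dm.csv
Rscript inst/scripts/fcki impute   --method fcki --seed 1 --in dm.csv --out di.csv --log run.jsonl
Rscript inst/scripts/fcki benchmark --in d.csv --methods mean,knni,ki,fcki --seed 1 --out table.csv
```

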