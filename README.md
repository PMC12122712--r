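# parashift

Host-conditioned species distribution modelling (SDM) and climate-change
range-shift analysis in R.

`parashift` is built for the hierarchical niche-modelling situation that
arises with host-dependent organisms such as the mistletoe *Loranthus
europaeus* on oaks (*Quercus* spp.): the parasite's climatic niche cannot be
modelled from climate alone, because its distribution is constrained by
where its host can live. The package fits a maximum-entropy niche model for
the host, injects the host's predicted suitability as a biotic predictor
into the parasite's model, projects both under future climate scenario
ensembles, and classifies each grid cell's range change.

## What it implements

* **Maximum-entropy SDM core.** The presence/background Gibbs model
  `q(x) = exp(β'f(x)) / Z` over background cells, fitted by maximizing the
  L1-penalized log-likelihood

  `mean_presence(β'f) − log mean_background(exp(β'f)) − Σ_j λ_j |β_j|`

  with MaxEnt-style feature expansion (linear, quadratic, product and hinge
  features on min-max scaled variables, hinge knots on an even grid) and a
  sample-size-dependent regularization schedule. The logistic output is
  `r·e^H / (1 + r·e^H)` with `r` the raw (normalized) density and `H` the
  entropy of the fitted background distribution. Projection clamps
  variables into the training range.
* **Occurrence handling.** CSV reading, exact-duplicate removal, half-open
  extent clipping, spatial thinning to one record per species per 0.25°
  cell (seeded), and uniform background sampling (default 10,000 points).
* **Predictor screening.** Pairwise Pearson correlations over valid cells
  and greedy elimination of variables with `|r| > 0.7` (strict), with a
  `protected` list for variables that must stay.
* **Evaluation.** Seeded 80/20 train/validation split, rank-based AUC, the
  max(sensitivity + specificity) threshold, binary range maps (`≥ τ*`),
  and range saturation.
* **Scenario ensembles.** Projection under SSP × GCM × timeline stacks,
  cellwise averaging of suitability across GCMs within each SSP × timeline.
* **Range change.** The `current − 2·future` encoding on binary maps —
  `0` still unsuitable, `−2` expansion, `1` contraction, `−1` persistence —
  with expansion/contraction percentages relative to the current range
  size (optionally cos-latitude area-weighted).
* **Synthetic world.** Gaussian-random-field climate layers, known logistic
  niches (host, and host-conditioned parasite), biased presence-only
  sampling, and additive latitude-graded warming offsets per scenario, so
  the whole pipeline can be validated against ground truth offline.

Rasters are held as plain matrices bound to a `grid_spec` georeference and
are read/written as ESRI ASCII grids (plain text, diff-friendly);
occurrences travel as CSV.

## Worked example

```r
library(parashift)

cfg <- demo_config(master_seed = 1)   # 60 x 60 grid, 5 climate layers
res <- run_all(cfg)

res$host$eval
#> <evaluation_report> AUC 0.746, threshold 0.407 (sens 0.819, spec 0.562)
#>   confusion: TP 118 FP 1313 TN 1687 FN 26

res$parasite$contribution
#>           variable contribution
#> 1             bio1          4.7
#> 2             bio2         29.3
#> 3             bio3          2.1
#> 4             bio4          4.2
#> 5             bio5          1.0
#> 6 host_suitability         58.6

subset(res$report, metric == "expansion_pct")
#>     ssp  timeline        metric value
#>  SSP126 2041-2060 expansion_pct  15.8
#>  SSP126 2061-2080 expansion_pct  27.2
#>  SSP245 2041-2060 expansion_pct  26.1
#>  SSP245 2061-2080 expansion_pct  43.4
#>  SSP370 2041-2060 expansion_pct  36.6
#>  SSP370 2061-2080 expansion_pct  52.9
#>  SSP585 2041-2060 expansion_pct  45.3
#>  SSP585 2061-2080 expansion_pct  56.8
```

The host model is fitted on all five climate layers; its predicted
suitability dominates the parasite model's permutation contributions
(`host_suitability` at 58.6%), exactly the hierarchical dependence the
demo world generates. Expansion percentages grow monotonically from the
mildest scenario (SSP126, 15.8% in the near timeline) to the strongest
warming (SSP585, 56.8% in the late timeline), and expansion cells sit at
higher latitudes than contraction cells — the poleward shift the encoding
is designed to quantify. (Numbers above were printed by this exact run
with `master_seed = 1` and vary with the seed.)

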