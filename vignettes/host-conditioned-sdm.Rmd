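---
title: "Host-conditioned species distribution modelling with parashift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host-conditioned species distribution modelling with parashift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parashift)
```

## The problem

Obligate host-dependent organisms — hemiparasitic plants like mistletoes
are the motivating case — cannot be modelled from climate alone: wherever
the host genus is climatically excluded, the parasite is absent no matter
how favourable the climate. `parashift` operationalizes the two-stage
design used in host–parasite distribution studies: fit a climatic niche
model for the host on the full candidate predictor set, then feed the
host's *predicted suitability* into the parasite's model as one more
predictor alongside a collinearity-screened climate set. Both models are
projected under future climate scenario ensembles and per-cell range
change is classified and accounted.

## The model

The niche model is the presence/background maximum-entropy model: over the
background cells the species' distribution is the Gibbs density
$q(x) \propto \exp(\beta^\top f(x))$, and $\beta$ maximizes the penalized
log-likelihood

$$\frac{1}{m}\sum_{i \in \text{presence}} \beta^\top f(x_i)
  \;-\; \log \frac{1}{n}\sum_{b \in \text{background}} e^{\beta^\top f(x_b)}
  \;-\; \sum_j \lambda_j |\beta_j|.$$

This is the maximum-entropy dual, equivalent to an infinitely-weighted
L1-penalized logistic regression of presence against background. The
features $f$ are the classic MaxEnt expansion of the min-max scaled
variables: linear, quadratic, pairwise product, and hinge
($\max(0,(s-k)/(1-k))$ and $\max(0,(k-s)/k)$ on an even knot grid,
50 knots per variable by default). Feature classes are chosen by presence
sample size: linear + quadratic below 80 presences, plus hinge and product
at 80 or more.

**Regularization.** $\lambda_j = c \cdot \beta_{\text{class}}(m) \cdot
\mathrm{sd}_{\text{presence}}(f_j) / \sqrt{m}$, where $m$ is the presence
count, $c$ the user multiplier (default 1), and $\beta_{\text{class}}$
interpolates from 1.0 at $m \le 10$ to 0.05 at $m \ge 100$ for
linear/quadratic/product features and is fixed at 0.5 for hinge features.
The presence standard deviation is floored at 0.05 so no feature is ever
unpenalized.

**Optimization.** Working-set accelerated proximal gradient descent with
backtracking: the solver repeatedly tightens the fit on the features that
violate the KKT conditions, declaring convergence when the maximum
violation is at most $10^{-5}$ (hard cap 10,000 iterations; exceeding it
raises an error carrying the residual gradient norm). The fit is
deterministic given its inputs. In tests the coefficients agree with an
independent L1-penalized logistic solver (glmnet under the infinite-weight
correspondence) to well under $10^{-3}$.

**Outputs.** The raw output is the Gibbs density normalized so it sums to
1 over the training background. The reported suitability is the logistic
transform $r e^H / (1 + r e^H)$ with $H$ the entropy of the fitted
background distribution; it maps a typical background cell to about 0.5
and is the scale on which occurrence-probability thresholds are usually
quoted. Projection onto new conditions clamps each variable into its
training range first, so extrapolated cells predict as at the training
envelope boundary.

## Protocol parameters

| Parameter | Default | Meaning |
|---|---|---|
| thinning cell | 0.25° | one record per species per cell, seeded choice |
| background | 10,000 points | uniform over valid cells, at cell centers |
| split | 80 / 20 | seeded random train/validation split |
| collinearity cutoff | \|r\| > 0.7 (strict) | greedy elimination, max-mean-\|r\| drop rule |
| threshold | max(sens + spec) | scanned over score midpoints, ties to the smaller τ |
| binarization | suitability ≥ τ | cells exactly at τ are inside the range |
| ensemble | mean over GCMs | continuous suitability averaged *before* thresholding |

Notable conventions, chosen where the field's practice is genuinely open:

* **Specificity on background.** True absences do not exist in
  presence-only data; specificity is computed against the background
  sample, the convention of the standard SDM evaluation stacks.
* **Thinning grid origin** is anchored at the study-extent lower-left
  corner, making thinning reproducible from the configuration alone.
* **Greedy collinearity elimination** drops, within the worst offending
  pair, the variable with the larger mean absolute correlation to the
  retained set (ties: the later variable in input order). A `protected`
  list pins variables that must survive screening — the host-suitability
  layer is always exempt in the pipeline.
* **Host handling under scenarios.** By default the host model is
  re-projected under each scenario and its future suitability feeds the
  parasite model (`host_mode = "reprojected"`); `"static"` holds the host
  at current suitability. Re-projection is the default because a parasite
  cannot persist where its host has moved away.
* **Percentages relative to the current range.** Expansion % =
  100 · n_expansion / (n_contraction + n_persistence), and likewise for
  contraction; this makes expansion > 100% possible and is the convention
  under which published range-shift figures in this literature read
  naturally. A cos-latitude weighting flag approximates area weighting on
  the geographic grid.

## The range-change encoding

Binary maps (current, future) are combined as `current − 2·future`:

| current | future | code | class |
|---|---|---|---|
| 0 | 0 | 0 | still unsuitable |
| 0 | 1 | −2 | expansion |
| 1 | 0 | 1 | contraction |
| 1 | 1 | −1 | persistence |

The encoding is lossless (both inputs are recoverable from the code) and
its counts satisfy `n_contraction + n_persistence = current range size`
and `n_expansion + n_persistence = future range size` — identities the
test suite asserts on every generated instance.

## The synthetic world

Because the real inputs of such analyses (occurrence archives, gridded
climatologies, CMIP6 scenario layers) are external downloads, the package
ships a generator that emulates their statistical structure with known
ground truth:

* **Climate layers** are Gaussian random fields — white noise convolved
  with an isotropic Gaussian kernel (correlation length in cells) on a
  torus, standardized to mean 0 / sd 1 — reproducing the smooth spatial
  autocorrelation of bioclimatic surfaces. One layer (the "temperature"
  proxy, `bio1` by default) is mixed with a north–south gradient so that
  latitude means something.
* **Niches** are logistic in the layers (with optional quadratic terms);
  the parasite niche adds `host_coefficient ×` host suitability.
* **Occurrences** are drawn cell-wise proportional to suitability × a
  collection-bias surface (default: one region over-sampled 5×, so
  thinning has a measurable effect), then placed uniformly within the
  cell, exercising the point-to-cell arithmetic downstream.
* **Future scenarios** are additive offsets on the gradient layer, scaled
  per SSP (0.5–1.4 sd of the field by default), per timeline (0.6 / 1.0)
  and per GCM (0.85–1.15), and graded with latitude (+50% at the northern
  edge) to emulate stronger high-latitude warming. Offsets move the
  temperature optimum poleward, which is what produces the
  expansion-north / contraction-south signal the pipeline must detect.

What the generator deliberately does *not* emulate: realistic correlation
structure among the 19 bioclimatic variables, coastlines and elevation,
temporally varying sampling effort, or any GCM physics. Passing tests
therefore demonstrate that the statistical machinery recovers known
structure under the stated assumptions — not that any particular real
species behaves this way.

## Validation harnesses and problem sizes

* **Niche recovery**: a specialist truth (intercept −6, coefficients +5
  and −4 on two layers, three zero-coefficient noise layers, smoothness 4)
  on a 60 × 60 quarter-degree window, 500 presences, 10,000 background.
  The specialist setting is used because a generalist niche caps the
  achievable discrimination of *any* model — with these settings the
  generating truth itself scores AUC ≈ 0.90, leaving headroom for the
  fitted model's held-out AUC ≥ 0.85 and Spearman ≥ 0.8 bars.
* **Range-shift direction**: a reduced two-scenario pipeline (weakest and
  strongest SSP, later timeline, two GCMs, 40 × 40 grid, 2,000
  background) run across seeds, asserting expansion cells lie poleward of
  contraction cells and expansion % is ordered weakest → strongest.
* The bundled `demo_config()` (60 × 60 grid, 3,000 background) runs the
  full 4 SSP × 2 timeline × 4 GCM analysis end-to-end in a few minutes on
  one CPU.

## Numerical choices and degenerate inputs

* Seeded operations restore the caller's RNG state; every stage seed is a
  deterministic hash of the master seed and the stage name, so adding a
  stage never perturbs another.
* A constant predictor is excluded from features with a warning; a
  constant layer's correlations are reported as `NA` and flagged.
* All-zero sampling weights (suitability × bias) and stacks without valid
  cells raise errors rather than returning empty sets.
* Nodata propagation is strict everywhere: masked cells stay `NA` through
  niche evaluation, prediction, scenario shifts, ensemble averaging
  (any-member rule) and change encoding.
* An empty current range makes change percentages `NA` (undefined) while
  the counts remain valid.

## Known limitations

* No spatially blocked cross-validation; the split is random, as in the
  package defaults this protocol follows.
* No extrapolation diagnostics (MESS-style) beyond hard clamping.
* Percent contribution is permutation importance, not the original
  solver-path gain accounting, which is solver-order-dependent and not
  reproducible across implementations.
* The ASCII-grid raster I/O targets reproducibility and portability, not
  throughput; continent-scale 2.5′ stacks fit comfortably, but this is
  not a general raster engine.
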