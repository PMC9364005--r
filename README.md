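# divekin

Kinematic dive features and environmental models for multi-sensor
biologging data.

## What problem this solves

Air-breathing marine "surfacers" — sea turtles, sea snakes, many
cetaceans — stay submerged at sea and surface only briefly, packing
several behaviours into a single dive. Classifying their dives into a few
"dive types" from time–depth profiles, the standard playbook developed for
pinnipeds and seabirds, tends to fail on such animals: the extra kinematic
detail available from modern tags (tri-axial acceleration, magnetometer
heading, 1 Hz depth) makes dives *less* clusterable, not more. `divekin`
implements the alternative: describe every dive with a rich set of
kinematic variables, let a correlation-matrix PCA condense the collinear
description into a few orthogonal dive features, and model those features
against the environment (season, time of day, tide) with penalized
additive mixed models. The package is aimed at movement ecologists working
with high-resolution tag deployments on diving animals.

## The analysis in brief

1. **Kinematics** (per deployment, 1 Hz): zero-offset-corrected depth;
   static/dynamic acceleration split by a centred 4 s box smoother;
   activity as ODBA = |Dx| + |Dy| + |Dz| (VeDBA, its Euclidean
   counterpart, proxies speed for dead-reckoning); pitch
   = arctan(Ax / sqrt(Ay² + Az²)) · 180/π, corrected for a tag-mounting
   offset estimated from level swimming; tilt-compensated magnetic
   heading; per-phase path tortuosity as circular variance
   V = 1 − ‖mean unit heading vector‖ ∈ [0, 1].
2. **Dives**: depth ≥ 1 m for > 30 s defines a dive; the bottom phase
   spans first-to-last crossing of 80% of maximum depth; each dive yields
   16 variables (phase durations incl. the post-dive surface interval,
   bottom-depth statistics, per-phase mean ODBA, mean pitch, circular
   variance), pooled across animals and standardized.
3. **Diagnostics and ordination**: k-means and hierarchical cluster scans
   (k = 1..10, elbow + mean silhouette) test for discrete dive types; PCA
   on the 16 × 16 correlation matrix condenses the variables, retaining
   components with eigenvalue > 1, orienting each so its strongest
   loading is positive, interpreting loadings at the ±0.4 cutoff, and
   checking stability with a bootstrap (components matched by absolute
   cosine similarity across 1000 resamples).
4. **Environmental models**: each retained component's scores ~
   s(hour, cyclic) + s(tide height) + s(tide rate), each optionally by
   season, + season + a per-animal random intercept; Gaussian identity
   link; two-stage AR(1) residual whitening within animals; all 35
   candidate term sets ranked by AICc with the two-unit
   fewest-variables rule.

A multi-sensor deployment simulator (semidiurnal 10 m tides, planted
trapezoid/V dives, wingbeat-modulated dynamic acceleration, planted
seasonal/diel/tidal effect functions, per-deployment mounting offsets)
provides ground truth for every stage.

## A worked example

Simulate per-dive component scores with known environmental structure
(by-season diel timing, by-season tide effects, animal intercepts, AR(1)
residuals with rho = 0.5 at n = 2000 dives) and let model selection find
it:

```r
library(divekin)

d <- simulate_dive_scores(seed = 11)
sel <- select_model(d, d$score)
sel
#> AICc model selection over 35 candidates
#> # A tibble: 35 x 9
#>    label        n_variables   edf loglik  aicc   rho de_full de_fixed delta_aicc
#>  1 s(hour x se…           4 31.8  -1111. 2286. 0.469    89.6     86.9        0
#>  2 s(hour x se…           4 30.2  -1154. 2369. 0.508    88.5     85.8       83.4
#>  ...
#> winner: s(hour x season) + s(tide_height x season) + s(tide_diff x season) + season
```

The winner is the data-generating term set; its AR(1) coefficient
(`rho = 0.469`, true 0.5), deviance explained by the full model (89.6%)
and by fixed effects alone (86.9%) are reported by
`glance(sel$winner)`, and `predict_effects(sel$winner)` (or
`autoplot(sel$winner)`) returns the centred effect curves with pointwise
standard errors — the fitted diel curve correlates > 0.99 with the
planted one.

The full pipeline — simulation, kinematics, dive segmentation, cluster
scan, PCA with bootstrap, per-component model selection, CSV/JSON outputs
plus a run manifest — is one call:

```r
cfg <- pipeline_config(
  sim = sim_config(seed = 4, n_deployments = 4, deployment_hours = 3),
  bootstrap_B = 200
)
res <- run_pipeline(cfg, out_dir = "divekin-run")
glance(res$pca)
#> # A tibble: 1 x 4
#>       n     p n_retained retained_var
#> 1    70    16          4        0.876
```

Here 70 dives were detected in the four simulated records and four
principal components with eigenvalue > 1 carry 87.6% of the variance of
the 16 dive variables.

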