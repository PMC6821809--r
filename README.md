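# defaunate

Quantifying defaunation of tropical mammal and bird communities from
systematic camera-trap surveys.

Camera-trap grids are the standard tool for monitoring ground-dwelling
vertebrates in tropical forest, but raw detection counts confound how many
species persist with how detectable they are. This package implements, as a
tested and reusable pipeline, the three tiers of a defaunation analysis used
to compare landscapes facing different pressures (e.g. indiscriminate snaring
vs logging-driven habitat degradation):

1. **Historical defaunation** — a weighted presence/absence defaunation
   index against a historical reference assemblage, with a
   functional-extinction rule for "present but no longer ecologically
   functional" species;
2. **Community occupancy modelling** — a hierarchical Bayesian multispecies
   occupancy model that separates occurrence from imperfect detection, with
   habitat (canopy closure) and hunting-pressure (village density)
   covariates on occupancy and survey effort on detection;
3. **Occupancy-based defaunation** — Monte-Carlo propagation of the
   occupancy posteriors through the defaunation index, giving a distribution
   of defaunation values per site with credible intervals.

A synthetic-data generator emulates the underlying survey design (two
landscapes × three sites, ~80 stations/site spaced ~2.5 km, two cameras per
station collapsed to station level, ≥60-day deployments pooled into 10-day
occasions), so every stage can be exercised and validated end-to-end without
field data.

## The statistics

**Defaunation index.** For focal assemblage *f* and reference assemblage
*r* over aligned species (or analysis units) *k* with importance weights
ω<sub>k</sub>:

```
D(r, f) = Σ_k ω_k (N_k,r − N_k,f)  /  Σ_k ω_k (N_k,r + N_k,f)
```

with N ∈ {0, 1} for the historical index, or N = ψ (occupancy probability)
for the occupancy-based variant. D ∈ [−1, 1]; positive values mean the focal
assemblage is more defaunated. Weights: equal; IUCN category (LC = 1 … CR =
5, DD = 2.5); body mass<sup>3/4</sup>; or body-mass rank. A unit is
*functionally extinct* at a site if recorded at strictly fewer than 2.5% of
the site's camera stations.

**Community occupancy model.** For unit *i*, station *j*, occasion *k*:

```
z_ij  ~ Bernoulli(ψ_ij)        logit(ψ_ij)  = α_{i,site[j]} + β1_i·canopy_j + β2_i·village_j
y_ijk ~ Bernoulli(z_ij·p_ijk)  logit(p_ijk) = α.p_i + β.e_i·Effort_jk
```

with every species-level parameter drawn from a community-level normal
distribution (means μ, sds σ). Covariates are z-scored within landscape;
effort is the number of active camera-days in the occasion, z-scored over
active cells. Fitting is by a built-in Metropolis-within-Gibbs sampler
(latent z from its exact full conditional); convergence is assessed by the
Gelman-Rubin statistic (R̂ < 1.1).

## Worked example

The landmark index values are direct evaluations of the formula. A hunted
landscape with 25 of 45 reference units functionally extinct, and a degraded
landscape with 4 of 36, give:

```r
library(defaunate)
defaunation_index(rep(1, 45), rep(c(1, 0), c(20, 25)))  # 0.3846154 -> 0.38
defaunation_index(rep(1, 36), rep(c(1, 0), c(32, 4)))   # 0.05882353 -> 0.06
```

A full synthetic analysis of one landscape, from records to the
occupancy-based index:

```r
bundle   <- paper_scale_fixture(seed = 42)    # 2 landscapes x 3 sites x 80 stations
stations <- normalize_covariates(bundle$stations)
hunted   <- stations[stations$landscape_id == "L2", ]   # village-driven landscape

history <- build_detection_history(
  bundle$records[bundle$records$station_id %in% hunted$station_id, ],
  hunted, occasion_length = 10, units = bundle$traits$unit_id)
history
#> <detection_history> 30 units x 240 stations x 7 occasions (10-day)
#>   detections: 7453 cells; effort: 15661 camera-days

fit <- fit_community_occupancy(history, hunted, mcmc = mcmc_config(seed = 1))
glance(fit)
#>   n_units n_stations n_sites chains draws_per_chain max_rhat converged
#> 1      30        240       3      3            1500     1.01 TRUE

dplyr::filter(tidy(fit), parameter %in% c("mu.b1", "mu.b2"))
#>   parameter    mean     sd lower75 upper75 lower95 upper95
#> 1 mu.b1      0.0226 0.0534 -0.0377  0.0826 -0.0873   0.124
#> 2 mu.b2     -1.04   0.139  -1.20   -0.890  -1.32    -0.773
```

The community-mean village-density effect `mu.b2` is sharply negative
(generating value −1) while the canopy effect `mu.b1` straddles zero
(generating value 0): occupancy in this landscape is driven by hunting
pressure, not habitat. Propagating the occupancy posteriors through the
index, with the first site as reference:

```r
psi  <- species_site_occupancy(fit)
occd <- occupancy_defaunation(psi, reference_site = "L2-S1",
                              n_draws = 30000, seed = 1)
occd
#>   site_id   mean     sd lower95 upper95 n_draws is_reference
#> 1 L2-S1    0     0        0       0       30000 TRUE
#> 2 L2-S2   -0.370 0.0160  -0.401  -0.338   30000 FALSE
#> 3 L2-S3   -0.354 0.0163  -0.387  -0.322   30000 FALSE
```

Negative values: both focal sites have *higher* occupancy than this
reference site (it has the highest surrounding village density in the
fixture). `run_pipeline(pipeline_config(...))` chains all stages, writes
every table as CSV plus a JSON run manifest, and `plot_defaunation()`,
`plot_effect_sizes()` and `autoplot()` methods draw the standard figures.

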