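# martendyn

Population dynamics of pine martens (*Martes martes*) from volunteer
snow-track surveys: density-dependence diagnosis and Bayesian mixed models
for growth rate and abundance, with a fully synthetic study system for
verification.

## The problem

Boreal mustelid monitoring often rests on winter snow-transect counts:
volunteers walk fixed transects each January and tally track crossings.
Two questions drive the analysis here:

1. **Are the populations cyclic or directly density-dependent?** Counts are
   converted to an effort-corrected abundance index,

   ```
   index = tracks / (length_km × days_since_snowfall)
   ```

   averaged within proximity clusters of transects, and each cluster's
   annual series is diagnosed with the **partial rate correlation function
   (PRCF)**: with X_t = ln N_t and realized growth rate R_t = X_t − X_{t−1},
   PRCF(d) is the partial correlation of R_t with X_{t−d} controlling for
   the intermediate lags. The first significantly negative lag (by
   Bartlett's ±2/√n criterion) estimates the feedback order — lag 1 means
   direct density dependence, lag ≥ 2 the delayed feedback typical of
   cycles.

2. **What drives growth and abundance?** Two Bayesian GLMMs:

   * growth model — R_gt ~ Normal(β0 + β·z_gt + u_g, σ²) with a transect-group
     random intercept;
   * abundance model — tracks_it ~ NegBin(μ_it, θ) with
     log μ = log(length) + log(days) + δ0 + δ·z_it + v_year,
     i.e. survey effort enters as an offset and year as a random intercept.

   Covariates (z-standardized): a microtine-rodent prey index interpolated
   from municipality-level presence proportions by inverse distance
   weighting (IDW, power 2), elevation averaged over home-range-sized
   (7.17 km²) grid cells, a rodent × elevation interaction, snow depth, and
   size-weighted Gaussian kernel densities of mature-spruce and
   agricultural patches. Priors are Normal(0, 2²) on intercepts and slopes;
   models run 4 chains × 6000 iterations (3000 warmup) under an adaptive
   random-walk Metropolis sampler with split-R-hat and bulk-ESS
   diagnostics, 80% credible intervals, and posterior predictive checks.

A synthetic-world generator (`sim_config()` / `build_world()`) emulates the
whole design — south–north elevation gradient, municipality-structured
cyclic rodent dynamics with elevation-dependent amplitude, a 593-transect
network with truncated-normal survey effort, negative-binomial track counts
with known coefficients — so every stage can be verified against ground
truth without any external data.

## Worked example

```r
library(martendyn)

world <- build_world(sim_config(seed = 1))
res <- run_all(world, seed = 1, chains = 2, iterations = 1500, warmup = 750)
print(res)
```

which prints (abbreviated):

```
Feedback diagnosis: 51 of 59 series with most negative PRCF at lag 1
Rodent index validation: r^2 = 0.763 (p = 0.00462)
Abundance model coefficients (80% CRI):
          parameter   mean cri_lower cri_upper excludes_zero
        (Intercept) -3.144    -3.412    -2.872          TRUE
             rodent  0.234     0.132     0.354          TRUE
          elevation  0.477     0.411     0.540          TRUE
 rodent_x_elevation  0.235     0.185     0.293          TRUE
               snow  0.499     0.452     0.551          TRUE
             spruce  0.412     0.369     0.451          TRUE
               agri -0.247    -0.301    -0.194          TRUE
```

Reading: the large majority of cluster series show their most negative rate
correlation at lag 1 (direct density dependence, no cycle signature); the
rodent presence-proportion index validates strongly against the synthetic
snap-trap series; and the abundance model recovers the signs of every
generating effect — positive for prey, elevation, snow and mature spruce,
negative for agricultural land — with all 80% credible intervals excluding
zero. The rodent slope is attenuated relative to its generating value
because the fitted covariate is the interpolated presence *proportion*, a
saturating transform of the log abundance that generated the counts — the
same measurement gap a real monitoring analysis faces. (Numbers come from
the reduced two-chain run shown; `run_all(world, seed = 1)` at the default
four chains gives the same picture.)

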