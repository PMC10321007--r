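# orgssm

State-space modelling of directional organelle movement from tracked
time-lapse trajectories.

## The problem

In many cells, organelles move directionally in response to a localised
stimulus. The motivating system is the chloroplast accumulation response:
when a small region of a plant cell is irradiated with a weak blue
microbeam, an unknown intracellular signal propagates outward and, after a
distance-dependent lag, each chloroplast starts moving toward the irradiated
area. Because organelles also wander by a random walk (cytoplasmic
streaming), deciding *when* directed movement begins from a noisy
distance-vs-time trace is the hard part — historically done by eye, which is
slow and analyst-dependent.

`orgssm` provides objective estimators for tracked distance series
`d[0..T]` (µm from the stimulus edge, one frame per minute, stimulus
switched on at a known frame):

* **Bayesian individual model** — for the velocity `y[t] = d[t] − d[t−1]`,

  ```
  y[t]    ~ N(α[t], σ_y²)
  α[t]    = w[t]                      (t < t₀)
  α[t]    = w[t] + β[t]               (t ≥ t₀)
  w[t]    ~ N(0, σ_w²)
  β[t₀]   ~ N(0, σ_β²),  β[t] ~ N(β[t−1], σ_β²)
  ```

  where `β[t]` is the time-varying regression coefficient of the stimulus
  (negative while the organelle approaches). Posterior sampling is by a
  Gibbs sampler (exact multivariate-Gaussian state draws, slice-sampled
  log-SDs with half-Normal priors); no compiled sampler is needed. The
  movement **start time** is the first `t ≥ t₀` at which the 99% credible
  upper bound of `β[t]` is negative, falling back to 95% then 90%, else
  infinity.
* **Kalman-filter variant** — the same model without `w`, fitted by exact
  maximum likelihood (Kalman filter) and smoothed (RTS); the same interval
  rule runs on Gaussian bounds.
* **Model-free heuristic** — three criteria on the raw distances
  (3 consecutive decreases; negative 9-point trailing mean change; a
  13-point look-ahead decrease exceeding 1.5× the track's mean decrease),
  with a grid-search tuner against visual annotations.

Downstream, per-cell **signal-transfer speed** is the repeated-median
(Siegel) regression slope of distance-at-onset (µm) on start time (min);
transfer time = distance/speed is compared with the total reaction time by
an exact one-sided Wilcoxon signed-rank test; pairwise speeds and a
geometric alignment judgement feed an exact Fisher test; and a hierarchical
**common model** estimates, per cell, the dynamics of an imaginary organelle
at distance zero that every real organelle follows after its own lag.

A trajectory simulator with known ground truth (`simulate_accumulation()`,
`simulate_escape()`) generates data with exactly the structure the models
assume and drives the test suite.

## Worked example

```r
library(orgssm)

sim <- simulate_accumulation(sim_params(organelles_per_cell = 6, seed = 42))
g   <- sim$tracks$grid           # 120 frames, stimulus ON from velocity index 30
sim$truth$per_organelle
#>     cell organelle       d0 true_start_min signal_speed
#> 1 cell01     org01 12.80206             16          0.8
#> 2 cell01     org02 16.49913             21          0.8
#> 3 cell01     org03 11.29525             14          0.8
#> 4 cell01     org04 21.75135             27          0.8
#> 5 cell01     org05 10.53661             13          0.8
#> 6 cell01     org06 14.71747             18          0.8

tr <- sim$tracks$tracks[[1]]     # true lag 16 min (d0 12.8 um / 0.8 um/min)
detect_start_heuristic(tr, g)
#> <start_time_estimate> 23 min after onset (method heuristic, threshold criteria)

detect_start_kalman(compute_velocity(tr, g), g)$start
#> <start_time_estimate> 22 min after onset (method kalman, threshold 99)

dr <- fit_individual(compute_velocity(tr, g), individual_model_spec(g),
                     mcmc_config(seed = 1))
estimate_start_from_intervals(summarize_posterior(dr), g)
#> <start_time_estimate> 22 min after onset (method bayes, threshold 99)
```

All three detectors place the start a few minutes after the true lag: the
rules fire once directed movement is *evident*, so they trail the generative
onset by the ramp of the drift pulse plus the evidence the rule needs (see
the methods vignette for the exact accounting).

Per-cell signal-transfer speed from the heuristic starts:

```r
starts <- vapply(sim$tracks$tracks, function(t) detect_start_heuristic(t, g)$start_min, numeric(1))
d0s    <- vapply(sim$tracks$tracks, function(t) t$distances[g$onset], numeric(1))
fit_signal_speed(starts, d0s, "cell01", seed = 1)
#> <regression_fit> slope 0.6403 [-0.08176, 1.022], intercept 0.1438, R2 0.857, p 0.07898, n 6
```

The slope (0.64 µm/min here, true 0.8 with only 6 organelles and
detection-delay noise) is the cell's signal-transfer speed; the bracket is a
seeded case-resampling bootstrap 95% CI.

The full pipeline (load → detect → kinetics → pairwise → common model) runs
from one call or the CLI:

```sh
Rscript exec/orgssm simulate --out simdir --organelles 8 --seed 7
Rscript exec/orgssm run-all --input simdir/tracks.csv --out results --detector heuristic --seed 7
```

writing `start_times.csv`, `signal_speeds.csv`, per-cell `common_*.csv`,
JSON test results and a reproducibility manifest.

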