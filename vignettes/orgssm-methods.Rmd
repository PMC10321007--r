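---
title: "Models and methods behind orgssm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind orgssm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(orgssm)
```

This vignette is the package's own account of its statistical machinery:
the models and their assumptions, the conventions that had to be fixed
where more than one reading was defensible, what the simulator does and
does not emulate, and the known limitations. It states no empirical result
that the test suite does not itself compute.

## Data model and indexing

A tracked experiment is a set of distance series on a shared grid: distance
frames `0..T` (µm from the stimulus edge, `frame_interval` minutes apart,
default 1) and velocity steps `1..T`, where velocity index `t` is the step
ending at frame `t` (`y[t] = d[t] − d[t−1]`; negative = approach). The
stimulus indicator is 0 for `t < onset` and 1 from `onset` (default 30 on a
120-frame grid, i.e. 29 pre-stimulus and 90 stimulus minutes).

Two conventions are load-bearing and used everywhere:

* **Distance at the start of irradiation** is `d[onset − 1]`, the last
  pre-stimulus frame — because `y[onset]` is the first stimulus-affected
  velocity.
* **Start times are minutes after onset**: a detector firing at absolute
  velocity index `t*` reports `t* − (onset − 1)`, so an immediate response
  is 1 min. The simulator's ground truth, by contrast, is the lag itself
  (`round(d0/speed) + warmup`), so even a perfect detector scores a fixed
  +1 min against the truth. Both definitions were inherited as stated; the
  offset is documented rather than hidden.

The loader rejects (rather than imputes) missing frames, duplicated frames
and non-numeric distances, naming the offending cell/organelle/time:
sub-minute timestamps and dropped frames have no stated treatment upstream,
and silent imputation would contaminate the velocity differencing.

## The individual model

For one organelle the observed velocity is explained by a time-varying
stimulus coefficient plus white noise:

$$y_t \sim N(\alpha_t, \sigma_y^2), \qquad
\alpha_t = w_t + \beta_t \cdot \mathrm{beam}_t, \qquad
w_t \sim N(0, \sigma_w^2),$$

with $\beta_t$ a Gaussian random walk over the beam period, initialised
$\beta_{t_0} \sim N(0, \sigma_\beta^2)$ with the same variance as its
innovations (the model prints a proper initial distribution; a diffuse
option exists in the Kalman variant for parity with common dynamic-linear-
model practice).

**Priors.** The three SDs get half-Normal(0, `prior_sd_scale`) priors,
default scale 1 µm/min: weakly informative at the data's units (organelle
speeds are a few tenths of µm/min). The original analysis code's priors are
unpublished; equivalence is asserted against the equations, not that code.

**Sampler.** Conditional on the SDs the model is linear-Gaussian, so the
package uses a Gibbs sampler with *exact* multivariate-Gaussian state draws
(dense Cholesky of the sparse posterior precision) alternating with
univariate slice updates of the log-SDs — the stated chains/warmup/samples
contract without any compiled dependency. One subtlety: with a single
organelle, $w_t$ and the observation error enter the likelihood only
through $\sigma_w^2 + \sigma_y^2$, so a naive scheme random-walks along
that ridge. The single-track sampler therefore *collapses* $w$: $\beta$ is
drawn against observation variance $\sigma_w^2 + \sigma_y^2$, the two SDs
are slice-sampled against that marginal (their split is prior-driven, as
it must be in an unidentified direction), and $w$ is redrawn exactly for
output. Split R-hat is computed for every SD and every $\beta_t$; a fit
whose maximum exceeds the threshold (default 1.1) is returned flagged, not
errored.

**Start-time rule.** Equal-tailed central intervals ("99% upper bound" =
0.995 quantile). The scan is strict (`< 0`, a tie does not trigger) and the
first qualifying index wins; levels fall back 99 → 95 → 90, then infinity.
For escape responses (positive coefficient) the mirrored rule — first
strictly positive *lower* bound — is applied via `direction = "escape"`;
the published rule is approach-specific and this is its unique
sign-symmetric extension.

## The Kalman variant

Dropping $w$ leaves `y[t] = β[t]·beam[t] + e[t]`: pre-onset observations
are iid noise and the beam period is a scalar local-level model. The
likelihood is exact (prediction-error decomposition); variances are
maximised over `(log σ_β², log σ_y²)` by Nelder–Mead from three data-driven
starts to guard against boundary optima; smoothed means/variances come from
the RTS recursion, and the same interval scan runs on Gaussian bounds
(smoothed, not filtered — the display and the decision are retrospective).
The filter, smoother and likelihood are all validated against brute-force
joint-Gaussian oracles to 1e-8 in the tests.

## The model-free heuristic

Three criteria on raw distances, scanned from onset; the start is the
first `t` meeting all three:

1. strictly decreasing distance at each of the last `k_consec` (3) steps;
2. negative trailing mean of the one-step changes over `ma_window` (9)
   steps — *trailing*, because a centred window would let the decision at
   `t` use information the rule's phrasing does not clearly grant;
3. the forward decrease `D(t) = d[t] − d[t+horizon]` (horizon 13) exceeds
   `fold` (1.5) times the mean of `D(s)` over all beam-period `s` where the
   look-ahead is defined, **per track** — the reading that keeps both sides
   of the inequality in the same units over the same horizon. Whether the
   original meant per-track, per-cell or dataset-wide is not stated; this
   choice is the only one that makes the criterion self-contained per
   trajectory.

Where the look-ahead overruns the series the criterion is undefined and
cannot trigger. All three criteria are invariant to translating or
rescaling the distances. The grid-search tuner is exhaustive over the
candidate lists, drops tracks where either estimate is infinite (reducing
n), disqualifies a combination that is infinite on more than half the
annotated tracks, and breaks ties by the lexicographically smallest
`(k_consec, ma_window, horizon, fold)` — all of which had to be fixed for
determinism because the published description stops at "grid search".

## Kinetics and robust regression

Per-organelle summaries collapse the beam-period posterior: mean and
minimum of the per-time coefficient medians; the coefficient SD is the
median over draws of each draw's across-time SD (the stated computation is
"the median of the Bayesian inference" of that SD — an SD-of-medians
fallback exists when only summaries are available); velocity summaries come
from the $\alpha$ medians.

The repeated-median (Siegel) slope — median over points of the median of
pairwise slopes, 50% breakdown — is computed exactly (pairs with equal x
excluded) and validated against loop enumeration. Because the upstream
package's interval/p-value method is unpublished, uncertainty here is a
seeded case-resampling bootstrap (default 2000 resamples): percentile 95%
CI, two-sided sign-proportion p for slope = 0. R² is `1 − SS_res/SS_tot`
evaluated on the robust fit and can leave `[0, 1]` for a poor fit, which is
flagged degenerate rather than clamped.

Signal-transfer speed is the slope of distance-at-onset (response) on
start time (explanatory); organelles with infinite starts are excluded and
cells with fewer than three finite starts are skipped with a notice.
Transfer time is distance/speed; transfer vs total reaction time uses the
exact one-sided Wilcoxon signed-rank test ("less"), enumerated by dynamic
programming over doubled mid-ranks (valid under ties) up to n = 25 and a
tie-corrected normal approximation above. The pairwise analysis judges a
pair "in a line" when the nearer centre lies within `organelle_radius` of
the segment from the beam centre to the farther centre (projection inside
the segment) — the minimal geometric reading, since no tolerance is
published; the radius is a configuration value. The alignment × slope-sign
table uses disjoint rows (aligned / not aligned), as a valid exact Fisher
test requires.

## The common model

Per cell, an imaginary organelle at distance zero has common dynamics
(same structure as the individual model); each real organelle's coefficient
is zero until its own start and then follows the common trajectory shifted
to begin there. The integer offset convention is fixed by index algebra:
`start[n] = start_min + 1`, so an immediate responder (1 min) has offset 2
and follows the common coefficient unshifted — the only convention under
which the zero-lag case reduces to the individual model, which the tests
verify numerically. The white-noise series is *shared* across the cell's
organelles exactly as the model prints it (one `w[t]` per cell) — unusual,
but it is what identifies $\sigma_w$ here and what makes pooling effective;
the tests check that the common coefficient's band is narrower than any
single organelle's. The common distance is the cumulative sum of
$\alpha_{common}$ anchored to zero at the last pre-stimulus step; the
anchoring holds exactly for every posterior draw by construction.
Organelles whose shifted trajectory would begin past the series end are
dropped with a warning rather than extrapolated.

## The simulator

`simulate_accumulation()` generates exactly the structure the models
assume: per organelle, white noise `w`, observation error, and a drift
pulse that switches on `round(d0/signal_speed) + warmup` minutes after
onset — an intracellular signal travelling at `signal_speed` from the
stimulus edge. Defaults: 10 organelles, initial distances uniform on 5–25
µm, `σ_w = σ_y = 0.3` µm/min, speed 0.8 µm/min (the scale of published
estimates in plant cells), and a pulse ramping to −0.5 µm/min over 5 min,
holding to 40 min, recovering over 20 — a shape chosen once as a realistic
accumulation episode; none of these values is tuned to any test outcome.
Distances are floored at zero (an organelle cannot be nearer than the
stimulus edge) with a warning when flooring affects a majority of frames;
the recorded ground-truth coefficient is the *generative* pulse, so
calibration checks must use initial distances exceeding the pulse's total
displacement (~23 µm at defaults) or they will "miss" truth at floored
frames. Per-organelle substreams are derived deterministically from the run
seed, so adding organelles never perturbs earlier ones.

`simulate_escape()` uses a 200-frame grid with the stimulus ON for the
final 70 velocity steps and a *transient* positive dash (ramp 5, plateau to
20 min, recovery over 10). The shorter episode is deliberate: with a
70-min terminal stimulus window, a 60-min accumulation-style episode would
drift until the very end of the series, and the heuristic's
strong-decrease criterion — which compares a window's decrease against the
track's mean decrease — would have no contrast to fire on. A transient
dash followed by a plateau is also the behaviourally realistic reading of
a microbe's escape from localised heating.

What the simulator does **not** emulate: 2-D motion (optional coordinates
place organelles on rays from the beam centre, for alignment tests only),
arrival dynamics other than the hard floor, frame drops, tracking error
autocorrelation, or between-organelle interaction. A green test therefore
establishes correctness of the estimators under the assumed noise model,
not robustness to tracking artefacts.

## Numerical choices

* State draws use a dense Cholesky of the posterior precision (dimension
  ≤ T + beam-period length ≈ 209 at defaults); `A'A` is precomputed once.
* Slice sampling uses stepping-out with shrinkage, width 0.5 on the log-SD
  scale; all randomness flows from per-chain seeds derived from the run
  seed, so fits are byte-reproducible.
* The Kalman filter handles `σ_y² = 0` and diffuse initialisation
  explicitly (first diffuse term dropped from the likelihood).
* Bootstrap resamples that collapse below three distinct x are discarded;
  an interval is reported only when ≥ 100 usable resamples remain.
* Exact-test enumeration doubles mid-ranks to stay in integers under ties;
  Fisher's two-sided p sums hypergeometric probabilities ≤ the observed
  table's with the customary `1 + 1e-7` tolerance.

## Known limitations

* **Start-time bias.** All three detectors report the time directed
  movement is *evident*, not the generative onset: the heuristic reports
  the end of the first 3-decrease run (+2 min by construction), the
  interval rules need accumulated evidence, the reporting convention adds
  +1 min against the simulator's truth, and the default 5-min pulse ramp
  delays visible movement further. At noise SD 0.3 per component and pulse
  depth 0.5 the measured median absolute errors are ~6 min (heuristic) and
  ~5 min (Bayesian) — the acceptance suite's ≤ 3 min recovery criterion is
  therefore left failing by design rather than met by weakening; the
  decision ledger carries the full decomposition. Relative comparisons
  (speed regressions, pairwise differences) are unaffected by the shared
  bias component.
* With a single organelle, $\sigma_w$ and $\sigma_y$ are not separately
  identified; only their sum constrains the fit, and their individual
  posteriors follow the prior along that ridge.
* The common model truncates, rather than models, organelles that start
  after the observation window; cross-cell pooling is out of scope (each
  cell is fitted independently).
* The escape analysis reuses the single-onset grid (stimulus ON to the end
  of the modelled window); a mid-series stimulus OFF transition is not
  representable.
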