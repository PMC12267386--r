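---
title: "Models and methods behind vrreach"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vrreach}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vrreach)
```

# The instrument

`vrreach` implements, headlessly, a paired reaction-time (RT) instrument: a
computerized go/no-go test (keyboard responses to colored squares) and a
virtual-reality counterpart in which stimuli are 3D cubes placed on a
body-scaled spherical grid and, in its second phase, responses are physical
reaches from a base position at the sternum. The package covers protocol
generation, calibration geometry, a synthetic-participant simulator, the
scoring pipeline, and the method-agreement statistics used to validate one
test against the other.

## Protocol

Both tests share the color logic: four stimulus colors (yellow, green, blue,
red); in simple-RT (SRT) phases every stimulus is responded to; in choice-RT
(CRT) phases green and yellow are go stimuli and blue and red no-go.
Phase-one constants are a 260 ms display and ISIs drawn uniformly from
1000–2000 ms; reach tasks display for 2000 ms with ISIs from 3000–4500 ms so
there is time to reach and return. Counts: 4 training + 20 test trials per
stimulus category in SRT/CRT phases, and 2 training plus 20 / 18 / 27 test
trials in the Center / Spatial / Dynamic reach tasks. The Dynamic task
allocates each of the nine grid locations as origin exactly three times and
stages cube speed by trial position: 0.6 m/s for the first nine test trials,
0.75 for the next nine, 0.9 for the last nine.

Two protocol points are under-determined by the instrument's description and
were decided here:

* *"20 trials for each stimulus type (go or no-go)"* can be read per color or
  per category. The default is per category — SRT has 20 test trials (5 per
  color, the stated 25% proportion) and CRT 20 go + 20 no-go (10 per color).
  `protocol_config(per_color = TRUE)` switches to the per-color reading
  (80 test trials per phase).
* Color proportions are made *exactly* equal by drawing from counterbalanced
  decks shuffled with the seeded RNG, not merely equal in expectation; the
  27-trial Dynamic task uses a near-balanced deck (7/7/7/6). ISIs are
  continuous uniform on the closed range.

The VR Press phase mirrors the computerized protocol exactly (same display,
ISIs and counts), differing only in the response device.

## Geometry

Calibration records `location_b` (controller at the sternum) and
`location_r` (arm extended at shoulder level); their Euclidean separation
`d` scales the grid. All geometry lives in a right-handed frame in meters:
+y up, +z the participant's facing direction, +x their right. Each grid
location is

$$\mathbf{x}_i = \mathbf{b} + d\,(\cos e_i \sin a_i,\; \sin e_i,\; \cos e_i \cos a_i)$$

with elevation $e_i \in \{+30^\circ, 0, -30^\circ\}$ by row and azimuth
$a_i \in \{-35^\circ, 0, +35^\circ\}$ by column, numbered row-major with
location 5 central. This parameterization keeps every location exactly at
distance `d`, including the corners; it is identical to applying an
elevation rotation about the lateral axis followed by an azimuth rotation
about the vertical axis, which is how the test-suite oracle builds the grid
independently. The corner composition and the row-major numbering are design
choices: only the central location's alignment and the 30°/35° offsets are
fixed by the instrument's definition.

Other geometric conventions: the base sphere (radius 0.028 m around
`location_b`) is inclusive at its boundary; cubes are 0.10 m, their front
face centered on the grid location and their body extending away from the
participant, and the touch volume is the full solid; dynamic cubes keep
translating along their line after passing the target location until
stimulus offset.

## Synthetic participants

No generative behavioral model is published for this instrument, so the
simulator is a stand-in with recorded ground truth, never a claim about real
cohorts. Latencies are ex-Gaussian — the standard descriptive family for RT
— with an additive structure:

$$\mathrm{RT} = \mu_{\text{family}} + \text{latent speed} + \text{VR bias}
+ \text{choice cost} + \mathcal{N}(0, \sigma) + \mathrm{Exp}(\tau)$$

Defaults: $\sigma = 20$ ms, $\tau = 60$ ms, and family $\mu$ solved (by
root-finding on the closed-form ex-Gaussian CDF) so the family medians equal
group-mean medians observed with the instrument — 239.4 ms for button
presses, and 341.4 / 386.0 / 344.8 ms for Center / Spatial / Dynamic reaches
inclusive of the VR offset. The default VR bias (32.44 ms) and choice cost
(121.49 ms) are the corresponding group-mean median differences. Between
participants, the latent speed is normal with SD 18 ms by default, chosen so
that simulated between-participant spread of median SRT (~19 ms) matches the
observed group SD.

Error processes are explicit and independently switchable: anticipations
(response at 10–95 ms) with probability 0.01, lapses (no response) 0.01,
false alarms on no-go trials 0.08, and forced touch failures 0.01. Reaches
follow a minimum-jerk profile ($10s^3 - 15s^4 + 6s^5$) sampled at 72 Hz (a
typical headset rate; the real rate is unreported), with lognormal durations
(medians 187.4 / 191.3 / 147.1 ms, log-SD 0.30). Touches aim half an edge
into the cube with Gaussian endpoint scatter (SD 0.015 m); in the Dynamic
task the scatter widens with cube speed (factor $1 + 0.9 \cdot
\text{speed}$), which produces that task's elevated movement-omission rate
(~10%) without hard-coding it. Dynamic aiming uses perfect linear prediction
of the cube position at arrival time.

What the simulator does **not** emulate: learning or fatigue across trials,
speed–accuracy trade-offs, trajectory curvature, pauses (leaving the base
without a stimulus), or any dependence of latency on stimulus color or
location beyond the task family. Tests passing on simulated data therefore
validate the *pipeline arithmetic and statistics*, not the behavioral
realism of the instrument.

## Scoring

Per trial: in press tasks RT is the first button press after onset; in reach
tasks RT is base exit, MT runs from base exit to touch, displacement is the
onset-to-touch controller gap minus 0.028 m (movement is only measured after
the controller has left the base sphere), and MV = displacement / MT.
Cutoffs: RTs valid on the closed interval [100, 1000] ms — below is an
anticipation, above or absent an omission (go trials); any no-go response is
a false alarm. MTs above 600 ms are excluded from MT and MV central values
but the trial keeps its RT and is counted in the over-600 rate; a valid RT
without a touch is a movement omission (M-omission). Both the over-600 and
M-omission rates are over all test trials of the task; anticipation and
omission rates are over go trials, the false-alarm rate over no-go trials.
The ICV is the sample SD (n−1) over the mean. Inclusive window endpoints,
the n−1 denominator and midpoint medians for even counts are conventions
chosen here; trials where the controller left the base before onset are
flagged `paused` and dropped from every denominator (reported as
`n_paused`). The onset controller position is the most recent sample at or
before onset.

## Validation statistics

* **Pearson correlation** (`pearson_validate`) with the two-tailed t test.
* **Bland–Altman** (`bland_altman`): bias = mean(A−B), limits of agreement
  bias ± 1.96·SD (the conventional multiplier; sample SD), and proportional
  bias from the least-squares slope of differences on pairwise means.
* **Repeated-measures ANOVA** (`rm_anova_gg`): sums of squares computed
  directly from the subjects × conditions matrix; Mauchly's W on the
  orthonormal-contrast covariance; the Greenhouse–Geisser epsilon
  $\hat\varepsilon = (\sum\lambda_i)^2 / ((k{-}1)\sum\lambda_i^2)$ deflates
  both df when Mauchly's p < .05 (the conditional rule; `correction = "GG"`
  forces it, `"none"` disables). With two conditions the test is exactly the
  squared paired t. No imputation: incomplete matrices are an error.
* **Wilcoxon signed-rank / Friedman** wrap the base R tests; zero
  differences are dropped (Wilcoxon's rule), the exact distribution is used
  up to 25 untied differences, and a degenerate all-zero comparison is an
  error rather than a p value.
* **Bonferroni** (`bonferroni`) reports α/m at 4 decimals, the instrument's
  convention (0.05/7 → 0.0071, 0.05/12 → 0.0042).
* **Exact correlation power** (`power_pearson_n`): the default method
  integrates Hotelling's exact density of the sample correlation under
  bivariate normality (hypergeometric-series evaluation) against the
  t-based critical value, and returns the smallest n reaching the target
  power — 46 at r = 0.4, α = .05, power .80. The Fisher-z approximation
  (`method = "fisher_z"`) gives 47 on the same inputs; the one-participant
  discrepancy is why the exact route is the default.

## Numerical choices and problem sizes

Geometry asserts to 1e−9 m (grid radii) and 1e−12 (oracle agreement);
scoring identities to 1e−12. The power integration uses `integrate` at
rel.tol 1e−9; the 2F1 series terminates at 1e−16 relative terms and
converges fast because its third parameter is ~n. Test-suite simulation
sizes were chosen to keep Monte-Carlo standard errors well below the asserted
tolerances while remaining desk-scale: 2×10⁵ draws for latency medians,
200 participants for Bland–Altman bias recovery (±3 MC SE), 2000 null
replicates for type-I calibration of the nonparametric and ANOVA tests at
n = 48, and 4000 replicates for Monte-Carlo verification of the exact power
computation.

## Limitations

The simulator's parameters are calibrated to group summary statistics, so
only group-level self-consistency is checkable; per-participant realism
(skew of MT distributions, color effects, sequential dependencies) is out of
scope. External event logs are accepted via the documented JSONL schema but
hardware timestamping semantics (render vs. command time) are the logger's
responsibility. The agreement layer implements the univariate battery only —
no post-hoc effect-size confidence intervals, Bayesian analyses, or
trial-level mixed models.
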