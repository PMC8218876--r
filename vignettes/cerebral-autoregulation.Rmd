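---
title: "Steady-state cerebral autoregulation analysis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state cerebral autoregulation analysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbfautoreg)
```

## The measurement problem

Cerebral autoregulation keeps cerebral blood flow (CBF) roughly constant
while systemic blood pressure varies. Characterising it in mice combines
two instruments with complementary blind spots:

* **Laser-Doppler flowmetry** tracks CBF continuously while mean arterial
  pressure (MAP) is swept pharmacologically (phenylephrine) and by
  phlebotomy — but only in *arbitrary units* (a.u.), with a gain that
  differs between animals and probe placements. Curves from different
  animals cannot be compared on this scale.
* **Fluorescent microspheres** give a one-shot *absolute* perfusion
  measurement (ml/100 g tissue/min): beads injected into the left
  ventricle lodge in capillaries in proportion to flow, and a reference
  arterial withdrawal at a known rate anchors the scale,

  $$Q \;=\; \frac{F_{\text{tissue}}}{F_{\text{ref}}}\times r \times
  \frac{100}{w},$$

  with $F$ the fluorescence intensities, $r$ the withdrawal rate (ml/min)
  and $w$ the tissue wet weight (g). `compute_blood_flow()` implements
  exactly this; weights are carried in mg throughout the package's tables
  (matching how they are recorded at dissection) and converted to g at
  this single audited site.

The analysis fuses the two: each animal's MAP–CBF sweep is fitted with a
third-order polynomial (`fit_curve()`), then rescaled so that the curve's
value at the group's resting MAP equals the group's microsphere perfusion
mean (`calibrate()`). Autoregulation is operationalised as CBF within
±20% of that baseline; the pressures where the calibrated cubic crosses
80% and 120% of baseline are the lower and upper autoregulatory limits
(`compute_thresholds()`, `find_limits()`), and their difference is the
autoregulation range in mmHg (`autoreg_range()`). Group statistics are
mean ± SEM with one-way ANOVA and Tukey's multiple comparisons
(`summarize_group()`, `compare_groups()`).

## Why a cubic, and how the roots are picked

A cubic is the lowest-degree polynomial that can express the triphasic
shape — falling limb, plateau, rising limb — with its two bends. The fit
is ordinary least squares on the raw samples; no time-averaging or
weighting is applied.

Numerical choices in `find_limits()`:

* Crossings are obtained from the polynomial analytically (`polyroot`),
  supplemented by bracketed bisection over sign changes on a 512-point
  grid; the two agree to well below 0.01 mmHg on every instance the test
  suite scans, and the bisection path also covers degenerate
  (effectively lower-degree) coefficient vectors.
* A cubic can cross a horizontal line up to three times. The
  disambiguation rule is *first crossing walking away from baseline*: the
  lower limit is the largest root below the resting MAP on the 80% line,
  the upper limit the smallest root above it on the 120% line.
* **No extrapolation.** Roots are only accepted inside the fitted
  pressure span (`fit_domain`). A curve that never reaches a threshold
  within the measured range has that limit *censored* at the domain edge
  and flagged; censored limits propagate as an undefined range
  (`NA`), never as a number, and are excluded from group summaries with a
  logged count.
* Calibration is refused when the resting MAP lies outside the fitted
  span or the fitted curve is non-positive there, rather than silently
  producing a negative scale factor.

Fitting eligibility gates — at least 8 samples, a MAP span of at least
60 mmHg, at least 4 distinct pressures — are the package's own guards: a
cubic fitted to a narrow pressure window cannot express a triphasic shape
and its threshold crossings would be extrapolation in disguise.

The baseline anchor is *group-level* (resting MAP paired with the group's
ipsilateral-cortex microsphere mean) because the microsphere and sweep
cohorts are separately instrumented animals; per-animal anchors can be
supplied through the same interface. Summaries default to per-animal
fitting (each animal contributes one set of limits, matching n-per-group
statistics); a pooled mode concatenates a group's samples into one
display-style curve.

## What the synthetic generator emulates

The package ships a generator (`autoreg_model()`, `simulate_trace()`,
`simulate_microsphere_experiment()`, `default_study_design()`) so that
every stage can be validated against known ground truth.

The generating pressure–flow curve is piecewise linear in *fractional*
flow: slope $s_b$ per mmHg below the lower plateau knee, flat at the
plateau, slope $s_a$ above the upper knee, with each kink optionally
smoothed over a `blend_width` (default 5 mmHg) by ramping the slope with
a cosine profile — a smoothed hinge that keeps the curve continuously
differentiable and non-decreasing. The published work reports the
empirical triphasic shape but no generating functional form; piecewise
linear with smoothing is the simplest shape a cubic can approximate well
while preserving a genuinely flat plateau.

Default study conditions (`default_study_design()`):

* **Group plateaus and knees** sit at the published group means: plateau
  flows 174.8 / 180.5 / 116.9 ml/100 g/min and knee pressures 77.3–135.0 /
  78.2–137.0 / 80.5–122.2 mmHg for control / sham / SAH; resting MAPs
  110.5 / 103.7 / 101.8 mmHg; 5 / 4 / 6 sweep animals and 6 / 6 / 7
  microsphere animals per group.
* **Limb slopes** $s_b = 0.015$, $s_a = 0.020$ per mmHg (fractional) are
  chosen from the visual shape of the published group curves: flow falls
  to roughly 45% of plateau at 40 mmHg and roughly doubles by 190 mmHg.
* **Sweeps** cover 40–190 mmHg with 50 points, visited
  descending-then-ascending to mimic a phlebotomy-then-pressor session.
* **Trace noise** is additive Gaussian on the a.u. scale, SD 5% of the
  plateau signal; per-animal gains are lognormal (sdlog 0.3) around 1.
* **Microsphere dispersion** is lognormal (mean-preserving) with
  per-group CVs 0.259 / 0.121 / 0.179 back-computed from the published
  SEMs ($\mathrm{CV} = \mathrm{SEM}\sqrt{n}/\text{mean}$).
* Spleen (250) and kidney (600 ml/100 g/min) flows are
  literature-typical placeholders, equal across groups; they are
  synthetic, not published means.
* All randomness flows from one integer seed; identical seeds give
  bit-identical outputs, and the simulators restore the caller's RNG
  state.

An important bookkeeping point: because the measurement procedure defines
limits as ±20% *crossings*, the generator's ground-truth limits are the
crossings of the true curve itself (`true_autoreg_limits()`), which lie
outside the plateau knees by about $0.2/s$ mmHg — not the knee positions.
All recovery checks compare against these crossings; with the default
slopes the control-like truth is 64.0–145.0 mmHg.

What the generator does **not** emulate: within-sweep autocorrelation and
hysteresis (pressure history, drug kinetics), probe drift,
heteroscedastic noise, intracranial-pressure dynamics, cortical spreading
depolarisation, or any biophysics of vessel walls. Passing recovery tests
therefore shows the *estimator* is sound under clean triphasic truth with
independent Gaussian trace noise — not that real sweeps satisfy those
assumptions.

## Validation scale and expected accuracy

The test suite exercises (sizes chosen to keep the default run in
seconds):

* exact round-trips of the blood-flow equation on dispersion-free
  records (relative error below $10^{-9}$);
* agreement of the analytic root solver with a 0.01 mmHg grid scan on
  100 randomly generated calibrated cubics;
* limit recovery on 100 simulated sweeps per group at the default noise
  (mean absolute error ≈ 2.3 mmHg against the generating crossings,
  dominated by the cubic's approximation bias near the upper bend;
  the error shrinks monotonically as noise → 0, to ≈ 1 mmHg, the pure
  approximation floor);
* invariance of calibrated limits to the arbitrary-unit gain over two
  orders of magnitude (differences below $10^{-9}$ mmHg);
* equality of the two-group ANOVA F with the squared pooled t, and a
  hand studentized-range (Tukey–Kramer) recomputation of the adjusted
  p-values.

For the across-group power check, the three-group microsphere fixture
(n = 6/6/7, distinct true flows) uses a measurement CV of 0.12 — the
sham group's own back-computed CV, at the low end of the plausible range
for the method. This value was fixed by an a priori power analysis: at
CV 0.12 the Tukey SAH-vs-control contrast detects the ≈58 ml/100 g/min
difference in essentially every seeded replicate, whereas at the
control group's CV of 0.26 per-replicate power drops to roughly 50–80%,
so a detection-rate check would measure dispersion, not correctness of
the statistics.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `autoreg_fraction` | 0.20 | — | flow band half-width defining the limits |
| `fit_degree` | 3 | — | polynomial degree (sensitivity checks only) |
| `mode` | `per_animal` | — | per-animal limits vs pooled display curve |
| `alpha` | 0.05 | — | significance level for ANOVA/Tukey |
| `min_span` | 60 | mmHg | eligibility gate on the sweep's pressure span |
| `blend_width` | 5 | mmHg | knee smoothing of the generating curve |
| `noise_frac` | 0.05 | — | trace noise SD as a fraction of plateau |
| `microsphere_cv` | 0.259/0.121/0.179 | — | per-group microsphere dispersion |

## Known limitations

* The method is steady-state only; dynamic indices (transfer function,
  phase shift) are out of scope.
* A cubic has one inflection, so it systematically rounds the two bends
  of a sharply triphasic curve; the ≈1 mmHg noise-free bias of the
  recovered limits is intrinsic to the published procedure, not a solver
  error. Wider blend zones or gentler limbs reduce it.
* Group-level calibration transfers the group's mean perfusion to every
  animal in the sweep cohort; between-animal variation in true baseline
  CBF therefore appears as limit variation, exactly as in the original
  design.
* Censoring at the domain edge makes limit estimates conservative when
  the sweep does not reach a threshold; summaries report how many animals
  were excluded for that reason.
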