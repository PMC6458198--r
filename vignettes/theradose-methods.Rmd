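---
title: "Methods: dosimetry and tumor response after intratumoral PET-tracer infusion"
author: "theradose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosimetry and tumor response after intratumoral PET-tracer infusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(theradose)
```

## The problem

Targeted radionuclide therapy (TRT) delivered by direct intratumoral
infusion of a positron emitter (e.g. a fluorine-18-labelled thymidine
analog) poses three quantitative questions that this package answers from
dynamic PET and caliper data:

1. **Where does the activity go?**  Region-of-interest (ROI) quantification
   of a 4D dynamic acquisition into time-activity curves (TACs), expressed
   as percent injected activity per gram (%IA/g).
2. **How much dose does each tissue absorb?**  Residence times and
   time-integrated activities from the decay-uncorrected TACs, converted to
   gray through a calibration factor measured against a ferrous-sulfate
   (Fricke) chemical dosimeter.
3. **Did the tumor respond?**  Fivefold growth time (5Td), tumor growth
   delay (TGD) and enhancement factor (EF) from caliper growth curves, with
   one-way ANOVA and Dunnett/Tukey multiple comparisons.

No animal data ship with the package.  Every stage is exercised against
seeded synthetic generators with known ground truth, so the correctness of
each computation is testable without downloads.

## Time-activity curves and quantification

A 4D image stores activity-rate concentrations (cps/mL) per frame; a scanner
calibration factor converts to MBq/mL.  For a mask $M$ with volume $V_M$
(mL), the ROI activity in frame $f$ is

$$A_f = \overline{c}_{f,M} \cdot \kappa \cdot V_M \quad \text{(MBq)},$$

with $\overline{c}$ the voxel mean over the mask and $\kappa$ the
calibration.  Samples are placed at **frame midpoints** — the standard
convention for frame-averaged activity; the residual error this introduces
is covered by the integration tests below.  The default schedule is
10 × 1 min, 10 × 5 min and 4 × 15 min frames covering 0–120 min, so the
last sample sits at 112.5 min.

Decay correction references $t = 0$ (start of infusion):
$A_\mathrm{corr}(t) = A(t)\,e^{+\lambda t}$ with
$\lambda = \ln 2 / T_{1/2}$ and $T_{1/2} = 109.77$ min for fluorine-18
(configurable via `radionuclide()`).  The correction state is an explicit
flag on every curve and can only change through `decay_correct()`, which
rejects wrong-direction calls; the round trip is the identity to machine
precision.

Percent injected activity per gram is
$100\,A(t) / (A_0\, m)$ with $m$ the ROI mass (volume × density, default
1 g/mL).  Two operationalizations of the reference activity $A_0$ are
supported, because whole-body PET counts and the nominal syringe activity
are both defensible normalizations and are not generally identical: the
default takes the maximum of the whole-body curve over the first three
post-infusion frames (`estimate_a0()`); a nominal activity can be supplied
instead everywhere that matters.  The manifest of every pipeline run
records which mode was in effect.

## Residence time and time-integrated activity

For a decay-**uncorrected** curve the residence time in hours is

$$\tau = \frac{\int_0^{T}\mathrm{TAC}(t)\,dt \;+\;
\mathrm{TAC}(T)/\lambda}{A_0},$$

where $T$ is the last frame midpoint.  The measured window is integrated
with the trapezoidal rule after prepending the point $(0, 0)$ — there is no
activity in the body before the infusion starts — and the tail beyond $T$
is the analytic integral of $\mathrm{TAC}(T)\,e^{-\lambda (t - T)}$, i.e.
physical decay with no further biological clearance.

Two numerical choices deserve comment:

* **Tail reading.**  A literal product
  $\mathrm{TAC}(T)\int_T^\infty e^{-\lambda t}dt$ would multiply the decay
  already present in $\mathrm{TAC}(T)$ by a second decay factor
  $e^{-\lambda T}$, and a fully trapped tracer would then *not* attain the
  physical limit $\tau = 1/\lambda$ (2.640 h for fluorine-18).  The
  package therefore uses the physically consistent tail
  $\mathrm{TAC}(T)/\lambda$ by default and keeps the literal reading behind
  `tail = "literal"` for comparison.
* **Window end.**  $T$ is the last frame *midpoint* (112.5 min on the
  default schedule), consistent with the midpoint sampling convention, not
  the nominal 120-min end of acquisition.  For curves that clear faster
  than physical decay this makes $\tau$ slightly larger than a 120-min
  window would (the slower tail starts earlier); the difference is about
  2–3% for a biological half-life of 60 min and is documented rather than
  hidden.

Accuracy: against dense numerical quadrature (0.01-min step) of the same
integrand, the frame-schedule trapezoid agrees to better than 0.5% for all
analytic curve families in the test suite (trapped, mono- and
bi-exponential clearance, uptake–washout, plateau, infusion-ramp shapes).
The discretization error grows with the clearance rate — at a biological
clearance of 0.03/min the 1-min early frames no longer resolve the initial
drop to better than ~0.5% — so the guarantee is stated for curves within
the acquisition protocol's design range.  Two identities are enforced
exactly: $\tau A_0 = $ `auc_to_infinity()` (up to float rounding), and
$\tau \le 1/\lambda$ whenever the decay-corrected activity never exceeds
$A_0$ (the property test draws random bounded washout curves at 99% of
$A_0$, leaving headroom for the trapezoid's ~2·10⁻⁴ systematic error on
convex integrands).

Tumor-to-tissue ratios are evaluated at 30, 60 and 120 min by
nearest-frame-midpoint lookup.  A requested time matches when it falls
inside the nearest frame, so "120 min" resolves to the final 105–120 min
frame; with no schedule attached a fixed ±2.5 min tolerance applies.  A
fixed midpoint-distance rule alone would leave the 120-min column of the
ratio table permanently missing on the default schedule, which is why the
frame-containment rule is the default.  Zero-valued reference tissue yields
a missing ratio, never infinity.

## Fricke calibration and absorbed dose

The calibration interface is the measured relationship itself: paired
(cumulated activity, dose) points.  The raw ferrous-dosimetry chain
(G-value, molar absorptivity, path length) is deliberately out of scope —
the calibration data enter as activity/dose pairs, and the fit is a
least-squares line **through the origin** (zero cumulated activity deposits
zero dose):

$$\hat{C} = \frac{\sum_i x_i y_i}{\sum_i x_i^2} \quad
\text{(Gy per MBq·h)}.$$

`fit_conversion_factor()` delegates to `stats::lm(y ~ 0 + x)` and keeps the
residual SD and $n$ as diagnostics; the default when no series is supplied
is $C = 0.09$ Gy/MBq·h.  The absorbed dose identity is

$$D\,(\mathrm{Gy}) = \breve{A}\,(\mathrm{MBq\cdot h/g}) \times M\,(\mathrm{g})
\times C\,(\mathrm{Gy/MBq\cdot h}),$$

with $\breve{A}$ the time-integrated activity per gram from the kinetics
stage.  Whether $\breve{A}$ includes the extrapolated tail or only the
measured 0–120 min window is exposed as `include_tail` and recorded in the
dose table; the default includes the tail.

## Tumor growth and response

Caliper volumes use the ellipsoid formula $V = \pi/6 \cdot a b^2$ with $a
\ge b$ the perpendicular diameters.  5Td is the first crossing of
$5 V_0$ ($V_0$ = volume on the first follow-up day), located by **linear
interpolation in log-volume** between the bracketing measurements — exact
for exponential growth between samples.  Curves that never reach fivefold
are censored at the last day and excluded from group means (the count is
always reported); the censored value is a lower bound.

Group metrics follow the conventional definitions, computed on per-animal
5Td values (not on the mean curve, so the per-animal variance survives into
SDs and tests): $\mathrm{TGD} = \overline{5Td}_\mathrm{grp} -
\overline{5Td}_\mathrm{ctl}$ and $\mathrm{EF} =
\overline{5Td}_\mathrm{grp} / \overline{5Td}_\mathrm{ctl}$, positive TGD
and EF > 1 for effective treatment.  Both are invariant to rescaling all
volumes.

Statistics: one-way ANOVA via `stats::aov`.  Dunnett-adjusted p-values
(each group vs control) come from a seeded Monte Carlo over the joint null
of the comparison t statistics (shared control mean and pooled variance;
10⁵ draws by default), which reduces analytically to the ordinary
two-sample t for a single comparison — that closed form is used there.
Tukey all-pairs p-values use the studentized-range distribution
(`stats::ptukey`, Tukey–Kramer for unequal n); the test suite checks them
against an independent 10⁶-draw Monte Carlo of the studentized range.
Stars follow the conventional thresholds (ns > 0.05 down to **** ≤ 1e-4).
Degenerate all-equal inputs return $F = 0$, $p = 1$ by convention instead
of 0/0.

## What the synthetic generators emulate

`simulate_tacs()` produces decay-corrected %IA/g curves per ROI for a
5-MBq, 10-min intratumoral infusion:

* **Injected (primary) tumor**: linear ramp over the infusion to a peak
  fraction (default 0.90 of injected activity), then biexponential washout
  (weights 0.75/0.25, rates 0.05/0.012 per min) — the curve peaks at the
  end of infusion and falls to ~8% of its maximum by 120 min.
* **Contralateral (distant) tumor**: mono-exponential saturation
  $B(1 - e^{-kt})$; the FLT-like preset ($B = 9$ %IA/g, $k = 0.018$/min)
  reaches ~8 %IA/g at 120 min, the FDG-like preset ($B = 1.6$, $k =
  0.10$/min) plateaus by 40 min at one fifth of that.
* **Organs** (kidneys, liver, brain, heart, bone, muscle): uptake–washout
  $U(1-e^{-k_u t})e^{-k_w t}$ as fractions of injected activity, with the
  FDG-like preset spilling more into heart, brain and kidneys.  Organ
  masses (0.15–8 g) are field-plausible values for a ~25 g mouse.
* The **whole-body** curve is the sum of the organ curves, so %IA
  conservation holds by construction; the noise-free fractions are
  validated to never exceed the injected activity.
* Measurement noise is multiplicative lognormal per sample (default 2%).

These are minimal shape families, not fits to any measured curve: they
reproduce the qualitative kinetics (peak time, late-time fractions,
plateau behaviour) a real study prints, and nothing else.  Passing tests
therefore demonstrate that the *computations* are correct on curves of
realistic shape — not that the generator reproduces any animal's
biodistribution, and not that the pipeline would be robust to
reconstruction artefacts, motion, spill-over or partial-volume effects,
which are out of scope.

`simulate_dynamic_image()` paints each ROI as a uniform ellipsoid on a
reduced 40 × 40 × 40 grid (0.5 × 0.5 × 0.6 mm voxels, a reduced version of
a 120 × 120 × 128 small-animal matrix) with non-overlap enforced; ROI
means reproduce the input curves exactly in noise-free mode, making the
simulate → paint → extract round trip a strong end-to-end oracle (< 2% RMS
is the acceptance bound; the observed error is at machine precision).
Optional Gaussian voxel noise exists but reconstruction noise modelling is
a non-goal.

`simulate_growth()` draws $V(t) = V_0 e^{g \max(0, t - d)}$ with
multiplicative lognormal noise, sampled twice weekly — the simplest family
in which 5Td has the closed form $d + \ln 5 / g$, so recovery is exactly
checkable.  The default group set (control, doubling time 3 d, plus three
arms with lags giving true EFs 1.8, 2.1, 3.7; n = 4; σ = 0.1) defines the
conditions under which EF recovery is tested: the mean estimate over 50
replicate experiments sits within 10% of truth per group.  Onset-lag
growth is a phenomenological stand-in; mechanistic regrowth models are a
non-goal.

`simulate_fricke_series()` draws $y_i = C x_i + \mathcal{N}(0, \sigma)$
with $C = 0.09$ Gy/MBq·h, ten activity points 5–50 MBq·h and
$\sigma = 0.005$ Gy; 200-replicate recovery keeps the mean within 1% and
every estimate within 5%, and the empirical SD matches the least-squares
sampling formula $\sigma / \sqrt{\sum x_i^2}$ within 20%.

## Problem sizes and runtime

The test suite and the acceptance script run on the reduced phantom
(40³ voxels × 24 frames), 200 calibration replicates, 50 growth-experiment
replicates, 1,000 random TACs for the physical-bound property and a single
10⁶-draw studentized-range Monte Carlo; the whole suite completes in well
under a minute on one core.  Larger grids and draw counts are plain
function arguments.

## Known limitations

* No partial-volume, motion, attenuation or scatter handling; images are
  assumed reconstructed and corrected upstream.
* A0 ambiguity (whole-body PET vs syringe activity) is surfaced, not
  resolved; results scale accordingly.
* Censored growth curves contribute bounds, not likelihood-based
  estimates; survival-style analysis is out of scope.
* The Dunnett adjustment is Monte Carlo (seeded, so reproducible); its
  p-values carry ~10⁻³ simulation noise at the default draw count.
* Compartmental modelling (Patlak/Logan), voxel-level S-value dosimetry
  and external-beam physics are non-goals.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(out_dir = "run1", seed = 1)
bundle <- run_pipeline(cfg)
bundle$response          # 5Td / TGD / EF table
bundle$dose              # per-organ absorbed doses
cat(render_report(bundle), sep = "\n")
```

The bundle directory then contains the TAC, residence-time, ratio, dose,
response and statistics tables as CSV, a `report.txt`, and a
`manifest.json` recording the seed and every flag in effect; re-running
the same config is byte-identical.
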