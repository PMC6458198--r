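# theradose

Quantitative analysis of preclinical **targeted radionuclide therapy (TRT)
by intratumoral infusion of a positron-emitting radiotracer** — for
researchers who have a dynamic small-animal PET acquisition, caliper
follow-up of tumor growth, and a Fricke-dosimeter calibration, and need the
numbers a therapy study reports: time-activity curves in %IA/g, residence
times, absorbed doses in gray, and growth-delay response metrics.

The package covers the full chain:

* **Quantification** — 4D dynamic image + ROI masks → calibrated
  time-activity curves (TACs); explicit decay-correction state; percent
  injected activity per gram, `%IA/g(t) = 100·A(t)/(A₀·m)`.
* **Kinetics** — residence time from the decay-uncorrected TAC,

  τ = [ ∫₀ᵀ TAC(t) dt + TAC(T)/λ ] / A₀,

  trapezoidal over the measured frames plus an analytic physical-decay tail
  (λ = ln2/109.77 min⁻¹ for ¹⁸F); time-integrated activity (MBq·h);
  tumor-to-tissue uptake ratios at 30/60/120 min.
* **Dosimetry** — through-origin least-squares calibration of the
  activity→dose conversion factor from Fricke data (Ĉ = Σxy/Σx², default
  0.09 Gy/MBq·h) and the dose identity **D (Gy) = Ă (MBq·h/g) × M (g) ×
  C (Gy/MBq·h)**.
* **Tumor response** — caliper volumes V = π/6·a·b², fivefold growth time
  (5Td) by log-linear interpolation, TGD = 5Td(treated) − 5Td(control),
  EF = 5Td(treated)/5Td(control); one-way ANOVA with Dunnett (seeded
  Monte Carlo) or Tukey (studentized range) multiple comparisons; Ki67
  index arithmetic.
* **Synthetic data** — seeded generators for infusion-kinetics TACs, 4D
  ellipsoid phantoms, exponential-with-lag growth tables and linear Fricke
  series, with known ground truth, so the entire pipeline is testable with
  no animal data.
* **Pipeline** — `run_pipeline()` ties the stages together from a single
  config, writes CSV tables + a text report + a manifest, and is
  byte-reproducible under a fixed seed.  A thin CLI lives at
  `inst/cli/theradose.R`.

## Worked example

```r
library(theradose)

# synthetic study: 5 MBq intratumoral infusion, FLT-like kinetics
s <- simulate_tacs(tracer_kinetics_spec("FLT-like"), seed = 1)
s
#> <tac_set> 9 ROIs (primary tumor, contralateral tumor, kidneys, liver,
#>           brain, heart, bone, muscle, whole body); A0 = 5 MBq

# distant-tumor uptake at the end of the 2 h acquisition
ct <- s[["contralateral tumor"]]
ct$values[length(ct$values)]
#> 7.93        # %IA/g

# residence time of the injected tumor (decay-uncorrected curve)
unc <- decay_correct(to_megabecquerel(s[["primary tumor"]]), f18(),
                     "to-uncorrected")
residence_time(unc, A0 = attr(s, "A0"))
#> <residence_time> 'primary tumor': tau = 0.5114 h
#>   (window 2.122 + tail 0.4349 MBq.h, A0 = 5 MBq)

# Fricke calibration and absorbed dose
cal <- fit_conversion_factor(simulate_fricke_series(seed = 1))
cal
#> <conversion_factor> C = 0.0900306 Gy/MBq.h (n = 10, residual SD = 0.00384 Gy)
absorbed_dose(5.114, 0.5, cal)
#> <dose_estimate> D = 0.2302 Gy (A = 5.114 MBq.h/g, M = 0.5 g, C = 0.09003)

# tumor response on simulated caliper data (true EFs 1.8 / 2.1 / 3.7)
rs <- response_summary(simulate_growth(default_growth_specs(), seed = 1),
                       "Control")
rs
#>             group n n_censored mean_5td_days sd_5td_days tgd_days    ef
#>           Control 4          0         7.501      0.4430    0.000 1.000
#>        TRT 15 MBq 4          0        13.059      0.6471    5.558 1.741
#>        TRT 25 MBq 4          0        14.203      0.3520    6.702 1.894
#>  5FU + TRT 15 MBq 4          0        25.789      0.5972   18.288 3.438
```

Reading the output: the injected tumor holds τ = 0.51 h of the 5 MBq
infusion (a fully trapped tracer would give the physical maximum
1/λ = 2.640 h); the distant tumor accumulates ~8 %IA/g by 120 min; the
recovered conversion factor matches the generating 0.09 Gy/MBq·h; and the
estimated enhancement factors track the generating 1.8/2.1/3.7 within the
noise of n = 4 animals per group.

The one-call version:

```r
bundle <- run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
cat(render_report(bundle), sep = "\n")
```

writes residence-time, ratio, dose, response and statistics tables (CSV),
`report.txt` and `manifest.json` under `run1/`.

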