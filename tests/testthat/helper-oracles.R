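# Shared fixtures and independent oracles.

# dense-quadrature oracle for the residence-time integral: trapezoid of the
# continuous uncorrected curve at a fine step over [0, T_last] plus the
# analytic physical tail; independent of the frame-schedule code path
dense_tau_oracle <- function(f_uncorrected, lambda_per_min, T_last_min,
                             A0 = 1, step_min = 0.01) {
  t <- seq(0, T_last_min, by = step_min)
  v <- f_uncorrected(t)
  window <- sum(diff(t) * (v[-length(v)] + v[-1]) / 2)
  (window + v[length(v)] / lambda_per_min) / 60 / A0
}

# sample an uncorrected analytic curve on a schedule's frame midpoints
sampled_uncorrected_tac <- function(f, schedule = default_frame_schedule(),
                                    roi = "test") {
  tm <- frame_midpoints(schedule)
  tac(tm, f(tm), roi = roi, units = "MBq", decay_corrected = FALSE,
      schedule = schedule)
}

# analytic uncorrected TAC families with closed-form behaviour; each entry
# is f(t) in MBq for A0 = 1
analytic_tac_families <- function(lambda) {
  list(
    trapped   = function(t) exp(-lambda * t),
    monoexp   = function(t) exp(-(lambda + log(2) / 60) * t),
    plateau_decay = function(t) (0.3 + 0.7 * exp(-0.02 * t)) *
                                exp(-lambda * t),
    biexp     = function(t) (0.6 * exp(-0.04 * t) + 0.4 * exp(-0.005 * t)) *
                            exp(-lambda * t),
    uptake_washout = function(t) (1 - exp(-0.2 * t)) * exp(-0.01 * t) *
                                 exp(-lambda * t),
    ramp_washout = function(t) pmin(t / 10, 1) *
      ifelse(t <= 10, 1, 0.7 * exp(-0.05 * (t - 10)) +
                          0.3 * exp(-0.008 * (t - 10))) * exp(-lambda * t)
  )
}

# through-origin least-squares slope, the hand formula sum(xy)/sum(x^2)
slope_through_origin <- function(x, y) sum(x * y) / sum(x^2)

# minimal noise-free two-tracer spec used where tests need exact values
noisefree_spec <- function(tracer = "FLT-like")
  tracer_kinetics_spec(tracer, noise_sd = 0)
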