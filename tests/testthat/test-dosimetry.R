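test_that("conversion-factor fit matches the through-origin formula", {
  # single point
  expect_equal(fit_conversion_factor(calibration_series(1, 0.09))$C, 0.09)
  # exact line, ten points
  act <- seq(5, 50, by = 5)
  cf <- fit_conversion_factor(calibration_series(act, 0.09 * act))
  expect_equal(cf$C, 0.09, tolerance = 1e-12)
  expect_equal(cf$n, 10L)
  # noisy series vs the hand formula sum(xy)/sum(x^2)
  s <- simulate_fricke_series(fricke_series_spec(), seed = 5)
  cf2 <- fit_conversion_factor(s)
  expect_equal(cf2$C,
               slope_through_origin(s$cumulated_activity_MBq_h, s$dose_Gy),
               tolerance = 1e-12)
  expect_lt(abs(cf2$C - 0.09) / 0.09, 0.05)
  expect_equal(unname(predict(cf2, 10)), cf2$C * 10)
})

test_that("conversion-factor fit is scale-equivariant", {
  s <- simulate_fricke_series(fricke_series_spec(), seed = 8)
  c1 <- fit_conversion_factor(s)$C
  s2 <- calibration_series(s$cumulated_activity_MBq_h, 3 * s$dose_Gy)
  expect_equal(fit_conversion_factor(s2)$C, 3 * c1, tolerance = 1e-12)
})

test_that("repeated calibrations recover the slope and its sampling spread", {
  act <- seq(5, 50, by = 5)
  Chat <- vapply(1:200, function(i)
    fit_conversion_factor(simulate_fricke_series(fricke_series_spec(),
                                                 seed = 1000 + i))$C,
    numeric(1))
  expect_lt(abs(mean(Chat) - 0.09) / 0.09, 0.01)
  # least-squares sampling SD: sigma / sqrt(sum x^2)
  expect_equal(stats::sd(Chat), 0.005 / sqrt(sum(act^2)), tolerance = 0.2)
})

test_that("the dose identity D = A.M.C holds exactly and is linear", {
  d <- absorbed_dose(2, 0.5, 0.09)
  expect_equal(d$D_Gy, 0.09, tolerance = 1e-12)
  expect_equal(absorbed_dose(0, 0.5, 0.09)$D_Gy, 0)
  base <- absorbed_dose(1.7, 0.3, 0.09)$D_Gy
  expect_equal(absorbed_dose(2 * 1.7, 0.3, 0.09)$D_Gy, 2 * base,
               tolerance = 1e-12)
  expect_equal(absorbed_dose(1.7, 2 * 0.3, 0.09)$D_Gy, 2 * base,
               tolerance = 1e-12)
  expect_equal(absorbed_dose(1.7, 0.3, 2 * 0.09)$D_Gy, 2 * base,
               tolerance = 1e-12)
  expect_error(absorbed_dose(-1, 1, 0.09), ">= 0")
  expect_error(absorbed_dose(1, -1, 0.09), ">= 0")
})

test_that("end-to-end trapped-tracer dose matches the closed form", {
  nuc <- f18()
  x <- sampled_uncorrected_tac(function(t) 15 * exp(-nuc$lambda_per_min * t))
  auc <- as.numeric(auc_to_infinity(x, nuc))          # 15 MBq x 2.640 h
  d <- absorbed_dose(auc / 1, 1, 0.09)
  expect_equal(d$D_Gy, 0.09 * 15 / nuc$lambda_per_min / 60, tolerance = 0.01)
  expect_equal(d$D_Gy, 3.56, tolerance = 0.01)
})

test_that("dose table is ordered, linear in mass and validated", {
  nuc <- f18()
  sch <- default_frame_schedule()
  tm <- frame_midpoints(sch)
  mk <- function(roi, scale) tac(tm, scale * exp(-nuc$lambda_per_min * tm),
                                 roi, units = "MBq", decay_corrected = FALSE,
                                 schedule = sch)
  tacs <- tac_set(list(mk("brain", 0.1), mk("tumor", 2), mk("heart", 0.3)))
  masses <- c(brain = 0.4, tumor = 0.5, heart = 0.15)
  tab <- dose_table(tacs, masses, C = 0.09, nuclide = nuc)
  expect_equal(tab$roi, c("tumor", "heart", "brain"))
  expect_equal(tab$D_Gy, tab$A_per_g_MBq_h * tab$M_g * tab$C_Gy_per_MBq_h,
               tolerance = 1e-12)
  # doubling masses doubles doses (A per gram halves, M doubles twice over)
  tab2 <- dose_table(tacs, 2 * masses, C = 0.09, nuclide = nuc)
  expect_equal(tab2$D_Gy, tab$D_Gy, tolerance = 1e-12)  # total AUC unchanged
  expect_equal(tab2$A_per_g_MBq_h, tab$A_per_g_MBq_h / 2, tolerance = 1e-12)
  # zero activity -> zero dose
  z <- tac_set(list(tac(tm, rep(0, 24), "tumor", units = "MBq",
                        decay_corrected = FALSE, schedule = sch)))
  expect_equal(dose_table(z, masses, C = 0.09, nuclide = nuc)$D_Gy, 0)
  expect_error(dose_table(tacs, c(brain = 0.4), C = 0.09, nuclide = nuc),
               "tumor")
})

test_that("synthetic-phantom doses match analytic generator integrals", {
  nuc <- f18(); lambda <- nuc$lambda_per_min
  spec <- noisefree_spec("FDG-like")
  s <- simulate_tacs(spec, seed = 1)
  A0 <- attr(s, "A0")
  unc <- tac_set(lapply(s[spec$organ_params$roi], function(tc)
    decay_correct(to_megabecquerel(tc), nuc, "to-uncorrected")))
  masses <- spec$masses_g[spec$organ_params$roi]
  tab <- dose_table(unc, masses, C = 0.09, nuclide = nuc)
  # closed-form integral of U (1 - e^{-ku t}) e^{-(kw+lambda) t} + tail
  T_last <- max(frame_midpoints(default_frame_schedule()))
  for (i in seq_len(nrow(spec$organ_params))) {
    p <- spec$organ_params[i, ]
    a <- p$kw + lambda; b <- p$ku + p$kw + lambda
    window <- p$U * ((1 - exp(-a * T_last)) / a - (1 - exp(-b * T_last)) / b)
    tail <- p$U * (1 - exp(-p$ku * T_last)) * exp(-p$kw * T_last) *
      exp(-lambda * T_last) / lambda
    D_true <- 0.09 * A0 * (window + tail) / 60
    expect_equal(tab$D_Gy[tab$roi == p$roi], D_true, tolerance = 0.01,
                 label = p$roi)
  }
})
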