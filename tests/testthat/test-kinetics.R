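nuc <- f18()
lambda <- nuc$lambda_per_min

test_that("frame-schedule trapezoid + tail matches dense quadrature", {
  sch <- default_frame_schedule()
  T_last <- max(frame_midpoints(sch))
  for (nm in names(analytic_tac_families(lambda))) {
    f <- analytic_tac_families(lambda)[[nm]]
    x <- sampled_uncorrected_tac(f, sch, roi = nm)
    tau <- residence_time(x, A0 = 1, nuc)$tau_h
    oracle <- dense_tau_oracle(f, lambda, T_last)
    expect_lt(abs(tau - oracle) / oracle, 0.005, label = nm)
  }
})

test_that("a fully trapped tracer attains the physical limit 1/lambda", {
  x <- sampled_uncorrected_tac(function(t) 5 * exp(-lambda * t))
  tau <- residence_time(x, A0 = 5, nuc)$tau_h
  expect_equal(tau, 1 / lambda / 60, tolerance = 0.005)  # 2.640 h
  expect_equal(tau, 2.640, tolerance = 0.005)
})

test_that("mono-exponential clearance matches its closed form", {
  k <- log(2) / 60
  closed_form <- function(T) {
    ((1 - exp(-(lambda + k) * T)) / (lambda + k) +
       exp(-(lambda + k) * T) / lambda) / 60
  }
  # default schedule: window ends at the last frame midpoint
  x <- sampled_uncorrected_tac(function(t) exp(-(lambda + k) * t))
  expect_equal(residence_time(x, A0 = 1, nuc)$tau_h, closed_form(112.5),
               tolerance = 0.005)
  # a 1-min schedule out to 120 min reproduces the ~1.133 h closed form
  sch2 <- frame_schedule(seq(0, 119, 1), rep(1, 120))
  x2 <- sampled_uncorrected_tac(function(t) exp(-(lambda + k) * t), sch2)
  expect_equal(residence_time(x2, A0 = 1, nuc)$tau_h, 1.133,
               tolerance = 0.005)
})

test_that("degenerate and invalid inputs are handled", {
  sch <- default_frame_schedule()
  zero <- tac(frame_midpoints(sch), rep(0, 24), "z", units = "MBq",
              decay_corrected = FALSE, schedule = sch)
  expect_equal(residence_time(zero, A0 = 1, nuc)$tau_h, 0)
  expect_equal(as.numeric(auc_to_infinity(zero, nuc)), 0)
  corrected <- tac(1, 1, "c", units = "MBq", decay_corrected = TRUE)
  expect_error(residence_time(corrected, A0 = 1, nuc), "uncorrected")
  expect_error(auc_to_infinity(corrected, nuc), "uncorrected")
  unc <- tac(1, 1, "u", units = "MBq", decay_corrected = FALSE)
  expect_error(residence_time(unc, A0 = 0, nuc), "> 0")
})

test_that("literal tail reading under-counts by exp(-lambda T)", {
  x <- sampled_uncorrected_tac(function(t) exp(-lambda * t))
  phys <- residence_time(x, A0 = 1, nuc, tail = "physical")
  lit <- residence_time(x, A0 = 1, nuc, tail = "literal")
  T_last <- max(x$times)
  expect_equal(lit$tail_MBq_h / phys$tail_MBq_h, exp(-lambda * T_last),
               tolerance = 1e-12)
  expect_lt(lit$tau_h, phys$tau_h)
})

test_that("residence time x A0 equals the AUC exactly, and AUC is linear", {
  f <- analytic_tac_families(lambda)$biexp
  x <- sampled_uncorrected_tac(f)
  A0 <- 7.3
  expect_equal(residence_time(x, A0 = A0, nuc)$tau_h * A0,
               as.numeric(auc_to_infinity(x, nuc)), tolerance = 1e-14)
  x3 <- x; x3$values <- 3 * x$values
  expect_equal(as.numeric(auc_to_infinity(x3, nuc)),
               3 * as.numeric(auc_to_infinity(x, nuc)), tolerance = 1e-12)
})

test_that("tau never exceeds 1/lambda for physically realizable curves", {
  # decay-corrected activity bounded by A0 (fractions <= 0.99), random
  # biexponential washout with non-negative clearance
  sch <- default_frame_schedule()
  tm <- frame_midpoints(sch)
  bound <- 1 / lambda / 60
  set.seed(42)
  for (i in 1:200) {
    w <- stats::runif(1)
    rates <- stats::runif(2, 0, 0.1)
    frac <- 0.99 * stats::runif(1)
    corrected <- frac * (w * exp(-rates[1] * tm) +
                           (1 - w) * exp(-rates[2] * tm))
    x <- tac(tm, corrected * exp(-lambda * tm), "r", units = "MBq",
             decay_corrected = FALSE, schedule = sch)
    expect_lte(residence_time(x, A0 = 1, nuc)$tau_h, bound)
  }
})

test_that("faster biological clearance strictly decreases tau", {
  taus <- vapply(c(0, 0.002, 0.005, 0.01, 0.02, 0.05), function(k) {
    x <- sampled_uncorrected_tac(function(t) exp(-(lambda + k) * t))
    residence_time(x, A0 = 1, nuc)$tau_h
  }, numeric(1))
  expect_true(all(diff(taus) < 0))
})

test_that("tumor-to-tissue ratios behave as documented", {
  sch <- default_frame_schedule()
  tm <- frame_midpoints(sch)
  a <- tac(tm, seq(2, 4, length.out = 24), "a", units = "%IA/g", A0 = 5,
           schedule = sch)
  b <- a; b$roi <- "b"; b$values <- 2 * a$values
  zero <- tac(tm, rep(0, 24), "z", units = "%IA/g", A0 = 5, schedule = sch)
  s <- tac_set(list(a, b, zero))
  expect_equal(tumor_to_tissue_ratio(s, "a", "a")$ratio, rep(1, 3))
  expect_equal(tumor_to_tissue_ratio(s, "b", "a")$ratio, rep(2, 3))
  expect_true(all(is.na(tumor_to_tissue_ratio(s, "a", "z")$ratio)))
  # no frame within tolerance -> missing, not an error
  expect_true(is.na(tumor_to_tissue_ratio(s, "a", "b",
                                          times_min = 300)$ratio))
  expect_error(tumor_to_tissue_ratio(s, "a", "nope"), "no TAC")
})

test_that("contralateral-to-brain ratio increases over 30/60/120 min", {
  s <- simulate_tacs(noisefree_spec("FLT-like"), seed = 1)
  r <- tumor_to_tissue_ratio(s, "contralateral tumor", "brain")
  expect_equal(r$time_min, c(30, 60, 120))
  expect_true(all(diff(r$ratio) > 0))
  # direct evaluation of the generator formulas as the oracle
  spec <- noisefree_spec("FLT-like")
  t3 <- r$matched_time_min
  ct <- spec$contralateral_plateau * (1 - exp(-spec$contralateral_uptake_rate * t3))
  p <- spec$organ_params[spec$organ_params$roi == "brain", ]
  br <- 100 * p$U * (1 - exp(-p$ku * t3)) * exp(-p$kw * t3) /
    spec$masses_g[["brain"]]
  expect_equal(r$ratio, ct / br, tolerance = 1e-9)
})

test_that("AUC group comparison reproduces the textbook t statistics", {
  # zero-variance group equal to the reference
  ht0 <- compare_auc_groups(c(5, 5, 5), 5)
  expect_equal(unname(ht0$statistic), 0)
  expect_equal(ht0$p.value, 1)
  # mean 5.12, sd 1.37, n 3 against a single reference 6.7
  x <- c(5.12 - 1.37, 5.12, 5.12 + 1.37)
  ht <- compare_auc_groups(x, 6.7)
  t_hand <- (5.12 - 6.7) / (1.37 / sqrt(3))
  expect_equal(unname(ht$statistic), t_hand, tolerance = 1e-9)
  expect_equal(ht$p.value, 2 * stats::pt(-abs(t_hand), df = 2),
               tolerance = 1e-9)
  expect_equal(unname(ht$parameter), 2)
  # swapping the two sides negates t (two-sample mode)
  y <- c(6.1, 6.9, 7.3)
  expect_equal(unname(compare_auc_groups(x, y)$statistic),
               -unname(compare_auc_groups(y, x)$statistic), tolerance = 1e-12)
})
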