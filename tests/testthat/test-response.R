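test_that("caliper volume formula and its edge cases", {
  expect_equal(volume_from_calipers(6, 5), 78.54, tolerance = 1e-4)
  expect_equal(volume_from_calipers(7, 5), pi / 6 * 7 * 25, tolerance = 1e-12)
  expect_equal(volume_from_calipers(7, 5), 91.63, tolerance = 1e-4)
  d <- 4.2  # a sphere when both diameters agree
  expect_equal(volume_from_calipers(d, d), pi * d^3 / 6, tolerance = 1e-12)
  expect_error(volume_from_calipers(5, 6), "swapped")
})

test_that("five_td interpolates in log volume and censors correctly", {
  # exact exponential with doubling time 3 d
  g <- log(2) / 3
  day <- seq(0, 21, by = 3.5)
  v <- 100 * exp(g * day)
  ft <- five_td(day, v)
  expect_equal(ft$five_td_days, log(5) / g, tolerance = 1e-9)
  expect_false(ft$censored)
  # endpoint crossing
  ft2 <- five_td(c(0, 7), c(100, 500))
  expect_equal(ft2$five_td_days, 7)
  # never reaches fivefold: censored at last day
  ft3 <- five_td(c(0, 15, 30), c(100, 300, 490))
  expect_true(ft3$censored)
  expect_equal(ft3$five_td_days, 30)
  expect_error(five_td(0, 100), "two time points")
})

test_that("response summary computes TGD and EF per the footnote definitions", {
  mk <- function(id, group, t5) {
    g <- log(5) / t5
    day <- seq(0, 40, by = 2)
    data.frame(animal_id = id, group = group, day = day,
               volume_mm3 = 100 * exp(g * day))
  }
  growth <- rbind(mk("c1", "Control", 5), mk("c2", "Control", 5),
                  mk("t1", "Treated", 10), mk("t2", "Treated", 10))
  rs <- response_summary(growth, "Control")
  tr <- rs[rs$group == "Treated", ]
  expect_equal(tr$tgd_days, 5, tolerance = 1e-9)
  expect_equal(tr$ef, 2, tolerance = 1e-9)
  expect_equal(rs$ef[rs$group == "Control"], 1)
  expect_equal(rs$tgd_days[rs$group == "Control"], 0)
})

test_that("5Td, TGD and EF are invariant to volume rescaling", {
  specs <- list(Control = growth_model_spec(noise_sigma = 0.05),
                Treated = growth_model_spec(noise_sigma = 0.05,
                                            lag_days = 6))
  g <- simulate_growth(specs, seed = 5)
  rs1 <- response_summary(g, "Control")
  g2 <- g; g2$volume_mm3 <- 17 * g$volume_mm3
  g2$a_mm <- NULL; g2$b_mm <- NULL
  rs2 <- response_summary(g2, "Control")
  expect_equal(rs2$mean_5td_days, rs1$mean_5td_days, tolerance = 1e-9)
  expect_equal(rs2$ef, rs1$ef, tolerance = 1e-9)
})

test_that("uniformly faster growth never increases 5Td", {
  day <- seq(0, 30, by = 3.5)
  for (g1 in c(0.1, 0.2, 0.3)) {
    v1 <- 100 * exp(g1 * day)
    v2 <- 100 * exp((g1 + 0.05) * day)
    expect_lte(five_td(day, v2)$five_td_days, five_td(day, v1)$five_td_days)
  }
})

test_that("censored animals are excluded from group means but counted", {
  day <- c(0, 10, 20)
  growth <- rbind(
    data.frame(animal_id = "c1", group = "Control", day = day,
               volume_mm3 = 100 * exp(log(5) / 8 * day)),
    data.frame(animal_id = "t1", group = "Treated", day = day,
               volume_mm3 = 100 * exp(log(5) / 10 * day)),
    data.frame(animal_id = "t2", group = "Treated", day = day,
               volume_mm3 = c(100, 120, 150)))  # never reaches 500
  rs <- response_summary(growth, "Control")
  tr <- rs[rs$group == "Treated", ]
  expect_equal(tr$n_censored, 1L)
  expect_equal(tr$mean_5td_days, 10, tolerance = 1e-9)
})

test_that("EF estimates recover the generator's true enhancement factors", {
  g <- log(2) / 3
  base <- log(5) / g
  efs <- c(1.8, 2.1, 3.7)
  specs <- c(list(Control = growth_model_spec(growth_rate = g,
                                              noise_sigma = 0.1)),
             lapply(efs, function(ef)
               growth_model_spec(growth_rate = g, lag_days = (ef - 1) * base,
                                 noise_sigma = 0.1)))
  names(specs) <- c("Control", paste0("EF", efs))
  est <- sapply(1:25, function(i) {
    rs <- response_summary(simulate_growth(specs, seed = 2000 + i), "Control")
    rs$ef[match(paste0("EF", efs), rs$group)]
  })
  expect_equal(rowMeans(est), efs, tolerance = 0.1)
})

test_that("one-way ANOVA handles the degenerate all-equal case", {
  gt <- group_tests(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_equal(gt$anova$F, 0)
  expect_equal(gt$anova$p, 1)
  expect_true(all(gt$comparisons$p_adj == 1))
  expect_true(all(gt$comparisons$stars == "ns"))
})

test_that("Dunnett with a single comparison is the two-sample t test", {
  x <- list(Control = c(5.1, 6.2, 5.8, 5.5), Treated = c(7.9, 8.4, 7.2, 8.8))
  gt <- group_tests(x, control = "Control", comparisons = "dunnett")
  tt <- stats::t.test(x$Treated, x$Control, var.equal = TRUE)
  expect_equal(gt$comparisons$p_adj, tt$p.value, tolerance = 1e-12)
  expect_equal(gt$comparisons$statistic, unname(tt$statistic),
               tolerance = 1e-12)
})

test_that("Monte Carlo Dunnett agrees with the multivariate-t reference", {
  skip_if_not_installed("multcomp")
  set.seed(10)
  x <- list(Control = rnorm(5, 10), A = rnorm(5, 11.5), B = rnorm(5, 10.4))
  gt <- group_tests(x, control = "Control", comparisons = "dunnett",
                    nsim = 2e5, seed = 3)
  d <- data.frame(y = unlist(x),
                  g = factor(rep(names(x), lengths(x)), levels = names(x)))
  mc <- summary(multcomp::glht(stats::aov(y ~ g, d),
                               linfct = multcomp::mcp(g = "Dunnett")))
  expect_lt(max(abs(gt$comparisons$p_adj - as.numeric(mc$test$pvalues))),
            0.01)
})

test_that("Tukey adjustment matches base R's TukeyHSD", {
  set.seed(11)
  x <- list(a = rnorm(6, 0), b = rnorm(6, 1), c = rnorm(6, 0.5))
  gt <- group_tests(x, comparisons = "tukey")
  d <- data.frame(y = unlist(x),
                  g = factor(rep(names(x), lengths(x)), levels = names(x)))
  th <- TukeyHSD(stats::aov(y ~ g, d))$g
  expect_equal(sort(gt$comparisons$p_adj), sort(unname(th[, "p adj"])),
               tolerance = 1e-9)
})

test_that("groups of size one are dropped with a warning", {
  expect_warning(
    gt <- group_tests(list(a = c(1, 2, 3), b = 5, c = c(2, 3, 4))),
    "n = 1")
  expect_equal(gt$anova$df1, 1L)
})

test_that("Ki67 index is the percentage of positive cells", {
  expect_equal(ki67_index(0, 100), 0)
  expect_equal(ki67_index(41, 100), 41)
  expect_equal(ki67_index(74, 1000), 7.4)
  expect_error(ki67_index(5, 0), "> 0")
  expect_error(ki67_index(11, 10), "exceeds")
})
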