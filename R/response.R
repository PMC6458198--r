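#' Tumor volume from caliper diameters
#'
#' `V (mm^3) = pi/6 * a * b^2` with `a` the largest and `b` the smallest
#' perpendicular diameter.  Vectorized; swapped diameters (b > a) are
#' rejected.
#'
#' @param a_mm Largest diameter(s), mm.
#' @param b_mm Smallest perpendicular diameter(s), mm.
#' @return Volume(s) in mm^3.
#' @examples
#' volume_from_calipers(6, 5)  # 78.54
#' @export
volume_from_calipers <- function(a_mm, b_mm) {
  a_mm <- as.numeric(a_mm); b_mm <- as.numeric(b_mm)
  if (length(a_mm) != length(b_mm))
    stop("a_mm and b_mm must have equal length", call. = FALSE)
  if (any(!is.finite(a_mm)) || any(!is.finite(b_mm)) || any(b_mm <= 0))
    stop("diameters must be finite and > 0", call. = FALSE)
  if (any(b_mm > a_mm))
    stop("b > a: diameters appear swapped", call. = FALSE)
  pi / 6 * a_mm * b_mm^2
}

#' Time to fivefold volume (5Td) of one growth curve
#'
#' First crossing of five times the baseline volume (the volume on the first
#' day of follow-up), located by linear interpolation in log-volume between
#' the bracketing measurements - exact for exponential growth.  Curves that
#' never reach the threshold are censored at the last day: the returned
#' value is then a lower bound and `censored` is `TRUE`.
#'
#' @param day Measurement days, increasing; >= 2 points.
#' @param volume_mm3 Volumes (mm^3), > 0, same length.
#' @return `list(five_td_days, censored, V0)`.
#' @export
five_td <- function(day, volume_mm3) {
  day <- as.numeric(day); v <- as.numeric(volume_mm3)
  if (length(day) < 2L) stop("need at least two time points", call. = FALSE)
  if (length(day) != length(v)) stop("length mismatch", call. = FALSE)
  if (is.unsorted(day, strictly = TRUE))
    stop("days must be strictly increasing", call. = FALSE)
  if (any(v <= 0) || any(!is.finite(v)))
    stop("volumes must be finite and > 0", call. = FALSE)
  V0 <- v[1L]
  target <- 5 * V0
  hit <- which(v >= target)
  if (length(hit) == 0L)
    return(list(five_td_days = day[length(day)], censored = TRUE, V0 = V0))
  i <- hit[1L]
  if (i == 1L)
    return(list(five_td_days = day[1L], censored = FALSE, V0 = V0))
  lt <- log(target); l0 <- log(v[i - 1L]); l1 <- log(v[i])
  t5 <- day[i - 1L] + (day[i] - day[i - 1L]) * (lt - l0) / (l1 - l0)
  list(five_td_days = t5, censored = FALSE, V0 = V0)
}

#' Group response summary: 5Td, TGD and enhancement factor
#'
#' Per-animal fivefold growth times are computed with [five_td()]; group
#' statistics are taken over the uncensored animals (censored counts are
#' reported).  Tumor growth delay `TGD = mean 5Td(group) - mean 5Td(control)`
#' (positive for effective treatment) and enhancement factor
#' `EF = mean 5Td(group) / mean 5Td(control)`.
#'
#' @param growth Data frame with columns `animal_id`, `group`, `day` and
#'   either `volume_mm3` or the caliper pair `a_mm`, `b_mm`.
#' @param control_group Name of the untreated control group; must be present
#'   with at least one uncensored animal.
#' @return Data frame of class `response_summary`: `group`, `n`,
#'   `n_censored`, `mean_5td_days`, `sd_5td_days`, `tgd_days`, `ef`, plus
#'   attribute `"per_animal"` (animal-level 5Td table).  For groups whose
#'   animals are all censored the metrics are lower bounds and `all_censored`
#'   is `TRUE`.
#' @export
response_summary <- function(growth, control_group) {
  stopifnot(is.data.frame(growth),
            all(c("animal_id", "group", "day") %in% names(growth)))
  if (!"volume_mm3" %in% names(growth)) {
    if (!all(c("a_mm", "b_mm") %in% names(growth)))
      stop("growth table needs volume_mm3 or a_mm/b_mm columns", call. = FALSE)
    growth$volume_mm3 <- volume_from_calipers(growth$a_mm, growth$b_mm)
  }
  if (!control_group %in% growth$group)
    stop("control group '", control_group, "' not found", call. = FALSE)
  per <- do.call(rbind, lapply(split(growth, growth$animal_id), function(d) {
    d <- d[order(d$day), ]
    ft <- five_td(d$day, d$volume_mm3)
    data.frame(animal_id = d$animal_id[1L], group = d$group[1L],
               five_td_days = ft$five_td_days, censored = ft$censored,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  summarize <- function(d) {
    unc <- d[!d$censored, , drop = FALSE]
    if (nrow(unc) == 0L) {
      # all censored: report the bound given by the last observed day
      data.frame(group = d$group[1L], n = nrow(d), n_censored = nrow(d),
                 mean_5td_days = mean(d$five_td_days), sd_5td_days = NA_real_,
                 all_censored = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(group = d$group[1L], n = nrow(d),
                 n_censored = sum(d$censored),
                 mean_5td_days = mean(unc$five_td_days),
                 sd_5td_days = stats::sd(unc$five_td_days),
                 all_censored = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, lapply(split(per, per$group), summarize))
  rownames(out) <- NULL
  ctrl <- out[out$group == control_group, ]
  if (ctrl$all_censored)
    stop("control group has no uncensored animal", call. = FALSE)
  out$tgd_days <- out$mean_5td_days - ctrl$mean_5td_days
  out$ef <- out$mean_5td_days / ctrl$mean_5td_days
  # control first, then by increasing effect
  out <- out[order(out$group != control_group, out$mean_5td_days), ]
  rownames(out) <- NULL
  attr(out, "per_animal") <- per
  attr(out, "control_group") <- control_group
  class(out) <- c("response_summary", "data.frame")
  out
}

#' @export
print.response_summary <- function(x, ...) {
  cat("Tumor response summary (control: ",
      attr(x, "control_group"), ")\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

signif_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", "ns"))
}

#' One-way ANOVA with Dunnett or Tukey multiple comparisons
#'
#' Stacks the per-group values, fits a one-way ANOVA ([stats::aov()]), and
#' adjusts the post-hoc comparisons: Dunnett (each group vs control) via a
#' seeded Monte Carlo over the joint null distribution of the comparison t
#' statistics (exact closed form `2 pt()` when there is a single
#' comparison), or all-pairs Tukey via the studentized-range distribution
#' ([stats::ptukey()], Tukey-Kramer for unequal n).  Significance stars use
#' the conventional thresholds (ns > 0.05, * <= 0.05, ** <= 0.01,
#' *** <= 0.001, **** <= 0.0001).
#'
#' Groups with a single observation cannot contribute a variance estimate
#' and are dropped with a warning.  If every observation is identical the
#' ANOVA is degenerate; `F = 0` and all p = 1 are returned by convention.
#'
#' @param values Named list of numeric vectors (one per group).
#' @param control Control-group name (required for Dunnett; defaults to the
#'   first group).
#' @param comparisons `"dunnett"` or `"tukey"`.
#' @param nsim Monte Carlo draws for the Dunnett null (default 1e5).
#' @param seed Seed for the Monte Carlo.
#' @return Object of class `group_tests`: `anova` (F, df, p),
#'   `comparisons` data frame (`comparison`, `estimate`, `statistic`,
#'   `p_adj`, `stars`), `method`.
#' @export
group_tests <- function(values, control = NULL,
                        comparisons = c("dunnett", "tukey"),
                        nsim = 1e5, seed = 1L) {
  comparisons <- match.arg(comparisons)
  stopifnot(is.list(values), !is.null(names(values)), length(values) >= 2L)
  sizes <- lengths(values)
  if (any(sizes < 2L)) {
    warning("dropping group(s) with n = 1: ",
            paste(names(values)[sizes < 2L], collapse = ", "), call. = FALSE)
    values <- values[sizes >= 2L]
    sizes <- lengths(values)
  }
  if (length(values) < 2L)
    stop("need at least two groups with n >= 2", call. = FALSE)
  if (is.null(control)) control <- names(values)[1L]
  if (comparisons == "dunnett" && !control %in% names(values))
    stop("control group '", control, "' not present", call. = FALSE)
  g <- factor(rep(names(values), sizes), levels = names(values))
  y <- unlist(values, use.names = FALSE)
  k <- length(values)
  N <- length(y)
  df_err <- N - k
  degenerate <- stats::var(y) == 0
  if (degenerate) {
    an <- data.frame(F = 0, df1 = k - 1L, df2 = df_err, p = 1)
  } else {
    fit <- stats::aov(y ~ g)
    s <- summary(fit)[[1L]]
    an <- data.frame(F = s$`F value`[1L], df1 = s$Df[1L], df2 = s$Df[2L],
                     p = s$`Pr(>F)`[1L])
  }
  means <- vapply(values, mean, numeric(1))
  mse <- if (degenerate) 0 else
    sum(unlist(lapply(values, function(v) (v - mean(v))^2))) / df_err
  sp <- sqrt(mse)
  if (comparisons == "dunnett") {
    others <- setdiff(names(values), control)
    se <- sp * sqrt(1 / sizes[others] + 1 / sizes[[control]])
    est <- means[others] - means[[control]]
    tstat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf * sign(est)))
    p_adj <- if (degenerate) rep(1, length(others))
    else dunnett_padj(abs(tstat), sizes[others], sizes[[control]], df_err,
                      nsim = nsim, seed = seed)
    cmp <- data.frame(comparison = paste(others, "-", control),
                      estimate = unname(est), statistic = unname(tstat),
                      p_adj = unname(p_adj), stringsAsFactors = FALSE)
  } else {
    pairs <- utils::combn(names(values), 2L)
    est <- means[pairs[2L, ]] - means[pairs[1L, ]]
    se_q <- sp * sqrt((1 / sizes[pairs[1L, ]] + 1 / sizes[pairs[2L, ]]) / 2)
    q <- ifelse(se_q > 0, abs(est) / se_q, ifelse(est == 0, 0, Inf))
    p_adj <- if (degenerate) rep(1, ncol(pairs))
    else stats::ptukey(q, nmeans = k, df = df_err, lower.tail = FALSE)
    cmp <- data.frame(comparison = paste(pairs[2L, ], "-", pairs[1L, ]),
                      estimate = unname(est), statistic = unname(q),
                      p_adj = unname(p_adj), stringsAsFactors = FALSE)
  }
  cmp$stars <- as.character(signif_stars(cmp$p_adj))
  structure(list(anova = an, comparisons = cmp, method = comparisons,
                 control = if (comparisons == "dunnett") control else NA),
            class = "group_tests")
}

# two-sided Dunnett adjusted p-values: P(max_j |T_j| >= |t_i|) under the
# joint null of the comparison statistics (common error variance, shared
# control mean).  Closed form for a single comparison; seeded Monte Carlo
# over the multivariate-t null otherwise.
dunnett_padj <- function(abs_t, n_groups, n_control, df, nsim = 1e5,
                         seed = 1L) {
  k <- length(abs_t)
  if (k == 1L) return(2 * stats::pt(abs_t, df, lower.tail = FALSE))
  set.seed(as.integer(seed))
  z0 <- stats::rnorm(nsim, 0, sqrt(1 / n_control))
  s <- sqrt(stats::rchisq(nsim, df) / df)
  maxT <- rep(0, nsim)
  for (j in seq_len(k)) {
    zj <- stats::rnorm(nsim, 0, sqrt(1 / n_groups[[j]]))
    Tj <- abs(zj - z0) / (s * sqrt(1 / n_groups[[j]] + 1 / n_control))
    maxT <- pmax(maxT, Tj)
  }
  vapply(abs_t, function(t0) mean(maxT >= t0), numeric(1))
}

#' @export
print.group_tests <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  cat(sprintf("%s multiple comparisons:\n",
              if (x$method == "dunnett") "Dunnett" else "Tukey"))
  print.data.frame(x$comparisons, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Ki67 proliferation index
#'
#' Percentage of Ki67-positive cells among all counted tumor cells
#' (conventionally counted over ten consecutive 20x fields).
#'
#' @param positive Count of Ki67-positive cells (<= total).
#' @param total Total counted cells, > 0.
#' @return Index in percent.
#' @examples
#' ki67_index(41, 100)  # 41
#' @export
ki67_index <- function(positive, total) {
  stop_if_not_scalar_num(positive, "positive", nonneg = TRUE)
  stop_if_not_scalar_num(total, "total", positive = TRUE)
  if (positive > total) stop("positive exceeds total", call. = FALSE)
  100 * positive / total
}
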