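#' Area under a decay-uncorrected TAC, extrapolated to infinity
#'
#' Numerator of the residence-time calculation: the trapezoidal integral of
#' the decay-uncorrected curve over the measured window (a point (0, 0) is
#' prepended - no activity before the infusion starts) plus an analytic tail
#' beyond the last sample, which decays with the physical half-life.
#'
#' Two tail readings are provided.  The default, `"physical"`, takes the
#' tail as `TAC(T) * exp(-lambda (t - T))` integrated to infinity, i.e.
#' `TAC(T)/lambda`; for a fully trapped tracer this reproduces the exact
#' total `A0/lambda`.  The `"literal"` reading multiplies the last value by
#' `integral_T^inf exp(-lambda t) dt = exp(-lambda T)/lambda`, which
#' double-counts the decay already present in `TAC(T)`; it is kept only for
#' comparison.
#'
#' @param x A decay-uncorrected [tac()] in MBq (or MBq/g for the per-gram
#'   variant; the result is then MBq.h/g).
#' @param nuclide A [radionuclide()].
#' @param tail `"physical"` (default) or `"literal"`.
#' @param include_tail Set `FALSE` to integrate the measured window only
#'   (no extrapolation beyond the last frame).
#' @return Area in MBq.h (attributes `window_MBq_h` and `tail_MBq_h` carry
#'   the two components).
#' @seealso [residence_time()]
#' @export
auc_to_infinity <- function(x, nuclide = f18(),
                            tail = c("physical", "literal"),
                            include_tail = TRUE) {
  stopifnot(inherits(x, "tac"))
  tail <- match.arg(tail)
  nuclide <- as_radionuclide(nuclide)
  if (x$decay_corrected)
    stop("AUC requires a decay-uncorrected TAC; call decay_correct() first",
         call. = FALSE)
  if (!x$units %in% c("MBq", "MBq/g"))
    stop("TAC must be in MBq or MBq/g", call. = FALSE)
  t <- x$times; v <- x$values
  if (t[1L] > 0) { t <- c(0, t); v <- c(0, v) }
  lambda <- nuclide$lambda_per_min
  T_last <- t[length(t)]
  window <- trapz(t, v) / 60                       # MBq.min -> MBq.h
  tail_val <- if (!include_tail) 0
  else if (tail == "physical") v[length(v)] / lambda / 60
  else v[length(v)] * exp(-lambda * T_last) / lambda / 60
  structure(window + tail_val, window_MBq_h = window, tail_MBq_h = tail_val,
            T_last_min = T_last, tail_mode = tail)
}

#' Residence time of a region
#'
#' `tau (h) = [ trapezoid(TAC, 0 -> T_last) + TAC(T_last)/lambda ] / A0`
#' computed on the decay-uncorrected curve, with the analytic physical-decay
#' tail of [auc_to_infinity()].  `T_last` is the last frame midpoint.  The
#' identity `tau * A0 = auc_to_infinity(tac)` holds exactly.
#'
#' For a fully trapped tracer (uncorrected `TAC(t) = A0 exp(-lambda t)`) the
#' residence time equals `1/lambda` - 2.640 h for fluorine-18 - which is the
#' physical upper bound whenever the decay-corrected activity never exceeds
#' `A0`.
#'
#' @param x A decay-uncorrected [tac()] in MBq.
#' @param A0 Injected (reference) activity in MBq, > 0.
#' @inheritParams auc_to_infinity
#' @return Object of class `residence_time` with fields `roi`, `tau_h`,
#'   `window_MBq_h`, `tail_MBq_h`, `A0`, `tail_mode`.
#' @export
residence_time <- function(x, A0, nuclide = f18(),
                           tail = c("physical", "literal"),
                           include_tail = TRUE) {
  stopifnot(inherits(x, "tac"))
  stop_if_not_scalar_num(A0, "A0", positive = TRUE)
  if (x$units != "MBq")
    stop("residence time requires a TAC in MBq", call. = FALSE)
  auc <- auc_to_infinity(x, nuclide = nuclide, tail = tail,
                         include_tail = include_tail)
  structure(list(roi = x$roi, tau_h = as.numeric(auc) / A0,
                 window_MBq_h = attr(auc, "window_MBq_h"),
                 tail_MBq_h = attr(auc, "tail_MBq_h"),
                 A0 = A0, tail_mode = attr(auc, "tail_mode")),
            class = "residence_time")
}

#' @export
print.residence_time <- function(x, ...) {
  cat(sprintf(
    "<residence_time> '%s': tau = %.4g h (window %.4g + tail %.4g MBq.h, A0 = %.4g MBq)\n",
    x$roi, x$tau_h, x$window_MBq_h, x$tail_MBq_h, x$A0))
  invisible(x)
}

#' Residence-time table for a set of curves
#'
#' @param tacs A [tac_set()] of decay-uncorrected MBq curves.
#' @param A0 Reference activity (MBq).
#' @inheritParams auc_to_infinity
#' @return Data frame: `roi`, `tau_h`, `window_MBq_h`, `tail_MBq_h`, `A0`.
#' @export
residence_time_table <- function(tacs, A0, nuclide = f18(),
                                 tail = c("physical", "literal"),
                                 include_tail = TRUE) {
  stopifnot(inherits(tacs, "tac_set"))
  tail <- match.arg(tail)
  rows <- lapply(tacs, function(tc) {
    rt <- residence_time(tc, A0 = A0, nuclide = nuclide, tail = tail,
                         include_tail = include_tail)
    data.frame(roi = rt$roi, tau_h = rt$tau_h,
               window_MBq_h = rt$window_MBq_h, tail_MBq_h = rt$tail_MBq_h,
               A0 = rt$A0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tumor-to-tissue uptake ratios at fixed times
#'
#' Ratio of the tumor to the reference-tissue value at each requested time,
#' matched to the nearest frame midpoint.  A requested time matches when it
#' falls inside the nearest frame (so "120 min" resolves to the final
#' 105-120 min frame); when the curves carry no schedule, a fixed midpoint
#' tolerance `tol_min` is used instead.  A zero tissue value, or no frame
#' within tolerance, yields `NA` (never infinity).
#'
#' @param tacs A [tac_set()] of decay-corrected `%IA/g` curves.
#' @param tumor,tissue ROI names.
#' @param times_min Requested times post injection (min).
#' @param tol_min Matching tolerance around frame midpoints (min) when no
#'   schedule is attached; also the minimum tolerance otherwise.
#' @return Data frame: `tumor`, `tissue`, `time_min`, `matched_time_min`,
#'   `ratio`.
#' @export
tumor_to_tissue_ratio <- function(tacs, tumor, tissue,
                                  times_min = c(30, 60, 120), tol_min = 2.5) {
  stopifnot(inherits(tacs, "tac_set"))
  for (r in c(tumor, tissue))
    if (!r %in% names(tacs)) stop("no TAC for ROI '", r, "'", call. = FALSE)
  tu <- tacs[[tumor]]; ti <- tacs[[tissue]]
  tol_at <- function(tc, i) {
    if (!is.null(tc$schedule))
      max(tol_min, tc$schedule$frame_durations[i] / 2)
    else tol_min
  }
  rows <- lapply(times_min, function(tm) {
    i <- which.min(abs(tu$times - tm))
    j <- which.min(abs(ti$times - tm))
    matched <- tu$times[i]
    ratio <- if (abs(tu$times[i] - tm) > tol_at(tu, i) ||
                 abs(ti$times[j] - tm) > tol_at(ti, j)) NA_real_
    else if (ti$values[j] == 0) NA_real_
    else tu$values[i] / ti$values[j]
    data.frame(tumor = tumor, tissue = tissue, time_min = tm,
               matched_time_min = matched, ratio = ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare AUC (or any summary) groups with a t test
#'
#' One-sample mode when the reference side is a single value (the group mean
#' is compared to it, df = n - 1); Welch two-sample otherwise.  This mirrors
#' the one-sample t contrast used when only one reference animal is
#' available.
#'
#' @param aucs_a Numeric vector (>= 1 value).
#' @param aucs_b Numeric vector; a single value triggers one-sample mode.
#' @return The `htest` object from [stats::t.test()] (fields `statistic`,
#'   `p.value`, `parameter` = df).
#' @export
compare_auc_groups <- function(aucs_a, aucs_b) {
  stopifnot(is.numeric(aucs_a), is.numeric(aucs_b),
            length(aucs_a) >= 1L, length(aucs_b) >= 1L)
  # degenerate zero-variance groups: t = 0, p = 1 when means agree,
  # |t| = Inf, p = 0 when they differ (t.test itself refuses constant data)
  one_sample_safe <- function(x, mu, flip = FALSE) {
    if (stats::sd(x) == 0) {
      delta <- mean(x) - mu
      t0 <- if (delta == 0) 0 else sign(delta) * Inf
      if (flip) t0 <- -t0
      return(structure(list(statistic = c(t = t0),
                            parameter = c(df = length(x) - 1),
                            p.value = if (delta == 0) 1 else 0,
                            method = "One Sample t-test (degenerate)"),
                       class = "htest"))
    }
    ht <- stats::t.test(x, mu = mu)
    if (flip) ht$statistic <- -ht$statistic
    ht
  }
  if (length(aucs_b) == 1L) {
    if (length(aucs_a) < 2L)
      stop("one-sample mode needs >= 2 values in the group", call. = FALSE)
    one_sample_safe(aucs_a, aucs_b)
  } else if (length(aucs_a) == 1L) {
    one_sample_safe(aucs_b, aucs_a, flip = TRUE)
  } else {
    stats::t.test(aucs_a, aucs_b)
  }
}
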