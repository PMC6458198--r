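#' Fit the activity-to-dose conversion factor
#'
#' Least-squares line through the origin of Fricke-measured dose versus
#' PET-measured cumulated activity: `dose = C * activity`.  The intercept is
#' fixed at zero because zero cumulated activity deposits zero dose.  Fit via
#' [stats::lm()]; residual SD and n are kept as diagnostics.
#'
#' @param series A [calibration_series()] (or data frame with columns
#'   `cumulated_activity_MBq_h`, `dose_Gy`).
#' @return Object of class `conversion_factor`: fields `C` (Gy per MBq.h),
#'   `residual_sd`, `n`, and the underlying `lm` fit (`NULL` for n = 1).
#' @examples
#' fit_conversion_factor(calibration_series(1, 0.09))
#' @export
fit_conversion_factor <- function(series) {
  if (is.data.frame(series))
    series <- calibration_series(series$cumulated_activity_MBq_h,
                                 series$dose_Gy)
  stopifnot(inherits(series, "calibration_series"))
  x <- series$cumulated_activity_MBq_h
  y <- series$dose_Gy
  if (all(x == 0)) stop("all activities are zero", call. = FALSE)
  if (length(x) == 1L) {
    C <- y / x
    fit <- NULL
    rsd <- NA_real_
  } else {
    fit <- stats::lm(y ~ 0 + x)
    C <- unname(stats::coef(fit)[1L])
    rsd <- sqrt(sum(stats::residuals(fit)^2) / (length(x) - 1L))
  }
  if (!is.finite(C) || C <= 0)
    warning("fitted conversion factor is not positive", call. = FALSE)
  structure(list(C = C, residual_sd = rsd, n = length(x), fit = fit,
                 true_C = series$true_C),
            class = "conversion_factor")
}

#' @export
print.conversion_factor <- function(x, ...) {
  cat(sprintf("<conversion_factor> C = %.6g Gy/MBq.h (n = %d, residual SD = %.3g Gy)\n",
              x$C, x$n, x$residual_sd))
  invisible(x)
}

#' @export
coef.conversion_factor <- function(object, ...) c(C = object$C)

#' @export
predict.conversion_factor <- function(object, cumulated_activity_MBq_h, ...) {
  object$C * cumulated_activity_MBq_h
}

#' @export
plot.conversion_factor <- function(x, ...) {
  if (is.null(x$fit)) stop("nothing to plot for a single-point fit")
  d <- x$fit$model
  graphics::plot(d$x, d$y, xlab = "Cumulated activity (MBq.h)",
                 ylab = "Dose (Gy)", ...)
  graphics::abline(0, x$C)
  invisible(x)
}

#' Default conversion factor
#'
#' The study's calibration, 0.09 Gy per MBq.h, used when no Fricke series is
#' supplied.
#' @return A `conversion_factor` with C = 0.09 and no fit diagnostics.
#' @export
default_conversion_factor <- function() {
  structure(list(C = 0.09, residual_sd = NA_real_, n = 0L, fit = NULL,
                 true_C = NA_real_),
            class = "conversion_factor")
}

as_C <- function(C) {
  if (inherits(C, "conversion_factor")) C$C
  else { stop_if_not_scalar_num(C, "C", positive = TRUE); C }
}

#' Absorbed dose from time-integrated activity
#'
#' `D (Gy) = A_per_g (MBq.h/g) x M (g) x C (Gy/MBq.h)`: the time-integrated
#' activity per gram of tissue, the tissue mass and the calibration factor
#' multiply to the mean absorbed dose.
#'
#' @param A_per_g Time-integrated activity per gram (MBq.h/g), >= 0.
#' @param M Tissue mass (g), >= 0.
#' @param C A [fit_conversion_factor()] result or a positive number
#'   (Gy per MBq.h).
#' @param roi Optional region label.
#' @return Object of class `dose_estimate` with fields `roi`, `A_per_g`,
#'   `M_g`, `C`, `D_Gy`.
#' @examples
#' absorbed_dose(2, 0.5, 0.09)  # 0.09 Gy
#' @export
absorbed_dose <- function(A_per_g, M, C = default_conversion_factor(),
                          roi = NA_character_) {
  stop_if_not_scalar_num(A_per_g, "A_per_g", nonneg = TRUE)
  stop_if_not_scalar_num(M, "M", nonneg = TRUE)
  Cv <- as_C(C)
  structure(list(roi = as.character(roi), A_per_g = A_per_g, M_g = M,
                 C = Cv, D_Gy = A_per_g * M * Cv),
            class = "dose_estimate")
}

#' @export
print.dose_estimate <- function(x, ...) {
  cat(sprintf("<dose_estimate> %s: D = %.4g Gy (A = %.4g MBq.h/g, M = %.4g g, C = %.4g Gy/MBq.h)\n",
              if (is.na(x$roi)) "(unnamed)" else x$roi,
              x$D_Gy, x$A_per_g, x$M_g, x$C))
  invisible(x)
}

# canonical reporting order for the organ dose table
dose_table_order <- c("tumor", "primary tumor", "contralateral tumor",
                      "heart", "liver", "kidney", "kidneys", "bladder",
                      "brain")

#' Per-organ absorbed dose table
#'
#' For every curve: time-integrated activity via [auc_to_infinity()]
#' (decay-uncorrected, trapezoid + analytic tail), divided by the organ mass
#' to give MBq.h/g, then the dose identity.  Rows are ordered tumor first,
#' then heart, liver, kidney, bladder, brain, then any remaining ROIs.
#'
#' @param tacs A [tac_set()] of decay-uncorrected MBq curves.
#' @param masses_g Named vector of organ masses (g); every ROI must be
#'   present (an informative error names the missing one).
#' @param C Conversion factor (object or number).
#' @param nuclide A [radionuclide()].
#' @param include_tail Whether to extrapolate beyond the measured window
#'   (default) or integrate the 0-120 min window only; recorded in the
#'   table attribute `"include_tail"`.
#' @return Data frame: `roi`, `A_per_g_MBq_h`, `M_g`, `C_Gy_per_MBq_h`,
#'   `D_Gy`.
#' @export
dose_table <- function(tacs, masses_g, C = default_conversion_factor(),
                       nuclide = f18(), include_tail = TRUE) {
  stopifnot(inherits(tacs, "tac_set"))
  Cv <- as_C(C)
  missing <- setdiff(names(tacs), names(masses_g))
  if (length(missing))
    stop("no mass supplied for ROI: ", paste(missing, collapse = ", "),
         call. = FALSE)
  rows <- lapply(names(tacs), function(roi) {
    auc <- auc_to_infinity(tacs[[roi]], nuclide = nuclide,
                           include_tail = include_tail)
    M <- masses_g[[roi]]
    A_per_g <- as.numeric(auc) / M
    data.frame(roi = roi, A_per_g_MBq_h = A_per_g, M_g = M,
               C_Gy_per_MBq_h = Cv, D_Gy = A_per_g * M * Cv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  key <- match(tolower(out$roi), dose_table_order)
  key[is.na(key)] <- length(dose_table_order) + rank(out$roi[is.na(key)])
  out <- out[order(key), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "include_tail") <- include_tail
  out
}
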