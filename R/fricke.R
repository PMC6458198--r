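#' Fricke calibration series
#'
#' Paired (cumulated activity, measured dose) points relating PET-measured
#' time-integrated activity to absorbed dose measured by a ferrous-sulfate
#' (Fricke) chemical dosimeter.
#'
#' @param cumulated_activity_MBq_h Cumulated activities (MBq.h), all > 0.
#' @param dose_Gy Measured doses (Gy), same length.
#' @param true_C Optional known slope (Gy per MBq.h) when the series is
#'   synthetic; recorded as metadata only.
#' @return Object of class `calibration_series`.
#' @export
calibration_series <- function(cumulated_activity_MBq_h, dose_Gy,
                               true_C = NULL) {
  x <- as.numeric(cumulated_activity_MBq_h); y <- as.numeric(dose_Gy)
  if (length(x) < 1L) stop("need at least one calibration point", call. = FALSE)
  if (length(x) != length(y))
    stop("activity and dose vectors differ in length", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite calibration values", call. = FALSE)
  if (any(x <= 0)) stop("cumulated activities must be > 0", call. = FALSE)
  structure(list(cumulated_activity_MBq_h = x, dose_Gy = y,
                 true_C = if (is.null(true_C)) NA_real_ else as.numeric(true_C)),
            class = "calibration_series")
}

#' @export
print.calibration_series <- function(x, ...) {
  cat(sprintf("<calibration_series> %d points, %.3g-%.3g MBq.h\n",
              length(x$dose_Gy), min(x$cumulated_activity_MBq_h),
              max(x$cumulated_activity_MBq_h)))
  invisible(x)
}

#' @export
as.data.frame.calibration_series <- function(x, ...) {
  data.frame(cumulated_activity_MBq_h = x$cumulated_activity_MBq_h,
             dose_Gy = x$dose_Gy)
}

#' Specification for a synthetic Fricke series
#'
#' Linear dose-activity relation through the origin with additive Gaussian
#' dose noise: `dose_i = true_C * activity_i + N(0, noise_sigma)`.  Defaults
#' reproduce the study's calibration: slope 0.09 Gy/MBq.h, dose noise
#' 0.005 Gy, ten activity points.
#'
#' @param true_C True slope (Gy per MBq.h), > 0.
#' @param activity_points Cumulated activities (MBq.h), all > 0.
#' @param noise_sigma SD of the dose noise (Gy), >= 0.
#' @return Object of class `fricke_series_spec`.
#' @export
fricke_series_spec <- function(true_C = 0.09,
                               activity_points = seq(5, 50, by = 5),
                               noise_sigma = 0.005) {
  stop_if_not_scalar_num(true_C, "true_C", positive = TRUE)
  if (length(activity_points) < 1L || any(activity_points <= 0))
    stop("activity_points must be positive", call. = FALSE)
  stop_if_not_scalar_num(noise_sigma, "noise_sigma", nonneg = TRUE)
  structure(list(true_C = true_C,
                 activity_points = as.numeric(activity_points),
                 noise_sigma = noise_sigma),
            class = "fricke_series_spec")
}

#' Simulate a Fricke calibration series
#'
#' @param spec A [fricke_series_spec()].
#' @param seed Integer seed for the dose noise.
#' @return A [calibration_series()] with `true_C` recorded.
#' @export
simulate_fricke_series <- function(spec = fricke_series_spec(), seed = 1L) {
  stopifnot(inherits(spec, "fricke_series_spec"))
  set.seed(as.integer(seed))
  dose <- spec$true_C * spec$activity_points +
    stats::rnorm(length(spec$activity_points), 0, spec$noise_sigma)
  calibration_series(spec$activity_points, dose, true_C = spec$true_C)
}
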