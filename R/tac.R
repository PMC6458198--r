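#' Time-activity curve (TAC)
#'
#' The central kinetic object: sampled activity of one region of interest
#' versus time post injection.  Values carry a unit tag (`"MBq"` for total
#' ROI activity, `"MBq/g"` for concentration, `"%IA/g"` for percent injected
#' activity per gram) and a decay-correction flag.  The flag may only change
#' through [decay_correct()]; unit conversions go through
#' [to_percent_ia_per_gram()] and [to_megabecquerel()].
#'
#' @param times Sample times in minutes (frame midpoints), strictly
#'   increasing, >= 0.
#' @param values Non-negative activity values, same length as `times`.
#' @param roi Region name.
#' @param units One of `"MBq"`, `"MBq/g"`, `"%IA/g"`.
#' @param decay_corrected Logical; has physical decay been removed?
#' @param A0 Injected / whole-body reference activity (MBq); required
#'   (positive) when `units = "%IA/g"`.
#' @param mass_g Optional ROI mass in grams (volume x density for
#'   image-derived curves).
#' @param schedule Optional [frame_schedule()] the samples came from; kept
#'   for lossless CSV round trips.
#'
#' @return An object of class `tac`.
#' @examples
#' tac(c(0.5, 1.5), c(1, 0.9), roi = "tumor")
#' @export
tac <- function(times, values, roi, units = c("MBq", "MBq/g", "%IA/g"),
                decay_corrected = TRUE, A0 = NA_real_, mass_g = NA_real_,
                schedule = NULL) {
  units <- match.arg(units)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) == 0L) stop("empty TAC", call. = FALSE)
  if (length(times) != length(values))
    stop("times and values must have equal length", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("TAC contains non-finite values", call. = FALSE)
  if (any(times < 0)) stop("TAC times must be >= 0", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("TAC times must be strictly increasing", call. = FALSE)
  if (any(values < 0)) stop("TAC values must be >= 0", call. = FALSE)
  if (units == "%IA/g" && (!is.finite(A0) || A0 <= 0))
    stop("%IA/g values require A0 > 0", call. = FALSE)
  if (!is.null(schedule)) stopifnot(inherits(schedule, "frame_schedule"))
  structure(list(times = times, values = values, roi = as.character(roi)[1L],
                 units = units, decay_corrected = isTRUE(decay_corrected),
                 A0 = as.numeric(A0), mass_g = as.numeric(mass_g),
                 schedule = schedule),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> roi '%s': %d samples over %.4g-%.4g min, %s (%s)\n",
              x$roi, length(x$times), min(x$times), max(x$times), x$units,
              if (x$decay_corrected) "decay-corrected" else "decay-uncorrected"))
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  data.frame(roi = x$roi, time_min = x$times, value = x$values,
             units = x$units, decay_corrected = x$decay_corrected,
             stringsAsFactors = FALSE)
}

#' @export
plot.tac <- function(x, ..., xlab = "Time post injection (min)",
                     ylab = x$units, type = "b") {
  graphics::plot(x$times, x$values, type = type, xlab = xlab, ylab = ylab,
                 main = x$roi, ...)
  invisible(x)
}

#' Apply or remove physical decay correction
#'
#' Decay correction references t = 0 (start of infusion):
#' `corrected(t) = uncorrected(t) * exp(+lambda t)`.  The call direction must
#' match the curve's current state; correcting an already-corrected curve is
#' an error.  `to-corrected` followed by `to-uncorrected` is the identity.
#'
#' @param x A [tac()].
#' @param nuclide A [radionuclide()].
#' @param direction `"to-corrected"` or `"to-uncorrected"`.
#' @return The converted `tac`, with its flag toggled.
#' @export
decay_correct <- function(x, nuclide = f18(),
                          direction = c("to-corrected", "to-uncorrected")) {
  stopifnot(inherits(x, "tac"))
  direction <- match.arg(direction)
  nuclide <- as_radionuclide(nuclide)
  if (direction == "to-corrected" && x$decay_corrected)
    stop("TAC is already decay-corrected", call. = FALSE)
  if (direction == "to-uncorrected" && !x$decay_corrected)
    stop("TAC is already decay-uncorrected", call. = FALSE)
  sgn <- if (direction == "to-corrected") 1 else -1
  x$values <- x$values * exp(sgn * nuclide$lambda_per_min * x$times)
  x$decay_corrected <- !x$decay_corrected
  x
}

#' Convert an activity TAC to percent injected activity per gram
#'
#' `%IA/g(t) = 100 * A(t) / (A0 * m)` with `A` the ROI activity (MBq), `A0`
#' the injected (reference) activity and `m` the ROI mass.
#'
#' @param x A [tac()] in MBq.
#' @param A0 Reference activity (MBq), > 0.  See [estimate_a0()] for the
#'   whole-body-derived default used by the pipeline.
#' @param roi_mass_g ROI mass in grams, > 0; defaults to the mass recorded
#'   on the curve.
#' @return A `tac` in `%IA/g`.
#' @export
to_percent_ia_per_gram <- function(x, A0, roi_mass_g = x$mass_g) {
  stopifnot(inherits(x, "tac"))
  if (x$units != "MBq")
    stop("input TAC must be in MBq (got ", x$units, ")", call. = FALSE)
  stop_if_not_scalar_num(A0, "A0", positive = TRUE)
  stop_if_not_scalar_num(roi_mass_g, "roi_mass_g", positive = TRUE)
  x$values <- 100 * x$values / (A0 * roi_mass_g)
  x$units <- "%IA/g"
  x$A0 <- A0
  x$mass_g <- roi_mass_g
  x
}

#' Convert a %IA/g TAC back to total ROI activity in MBq
#'
#' Inverse of [to_percent_ia_per_gram()], using the `A0` and mass stored on
#' the curve unless overridden.
#'
#' @inheritParams to_percent_ia_per_gram
#' @return A `tac` in MBq.
#' @export
to_megabecquerel <- function(x, A0 = x$A0, roi_mass_g = x$mass_g) {
  stopifnot(inherits(x, "tac"))
  if (x$units != "%IA/g")
    stop("input TAC must be in %IA/g (got ", x$units, ")", call. = FALSE)
  stop_if_not_scalar_num(A0, "A0", positive = TRUE)
  stop_if_not_scalar_num(roi_mass_g, "roi_mass_g", positive = TRUE)
  x$values <- x$values * A0 * roi_mass_g / 100
  x$units <- "MBq"
  x$A0 <- A0
  x$mass_g <- roi_mass_g
  x
}

#' Estimate the reference activity A0 from a whole-body curve
#'
#' Operationalizes "whole-body radioactivity measured by PET": the maximum of
#' the whole-body activity over the first `n_frames` frames after the end of
#' infusion, before appreciable excretion.  Supply a nominal syringe activity
#' instead wherever that normalization is preferred.
#'
#' @param whole_body A [tac()] in MBq for the whole-body ROI.
#' @param infusion_end_min End of the infusion (min); frames at or after this
#'   time are considered.  Default 10 (a 10-min slow infusion).
#' @param n_frames Number of post-infusion frames scanned for the maximum.
#' @return A0 in MBq.
#' @export
estimate_a0 <- function(whole_body, infusion_end_min = 10, n_frames = 3L) {
  stopifnot(inherits(whole_body, "tac"))
  if (whole_body$units != "MBq")
    stop("whole-body TAC must be in MBq", call. = FALSE)
  idx <- which(whole_body$times >= infusion_end_min)
  if (length(idx) == 0L) idx <- seq_along(whole_body$times)
  idx <- idx[seq_len(min(n_frames, length(idx)))]
  max(whole_body$values[idx])
}

#' A named collection of TACs
#'
#' @param tacs Named list of [tac()] objects (names = ROI names).
#' @param A0 Reference activity (MBq) shared by the set, if known.
#' @param tracer Optional tracer label.
#' @return A `tac_set` (named list with attributes).
#' @export
tac_set <- function(tacs, A0 = NA_real_, tracer = NA_character_) {
  stopifnot(is.list(tacs), length(tacs) > 0L,
            all(vapply(tacs, inherits, logical(1), "tac")))
  names(tacs) <- vapply(tacs, function(t) t$roi, character(1))
  structure(tacs, A0 = as.numeric(A0), tracer = as.character(tracer),
            class = "tac_set")
}

#' @export
print.tac_set <- function(x, ...) {
  cat(sprintf("<tac_set> %d ROIs (%s); A0 = %.4g MBq\n", length(x),
              paste(names(x), collapse = ", "), attr(x, "A0")))
  invisible(x)
}

#' @export
`[.tac_set` <- function(x, i) {
  tac_set(unclass(x)[i], A0 = attr(x, "A0"), tracer = attr(x, "tracer"))
}
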