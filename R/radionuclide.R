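#' Radionuclide physical-decay description
#'
#' A radionuclide is described by its physical half-life; the decay constant
#' \eqn{\lambda = \ln 2 / T_{1/2}} (per minute) is derived and stored with it.
#' All decay corrections and analytic tail integrals in the package take one
#' of these objects.
#'
#' @param name Character label, e.g. `"F-18"`.
#' @param half_life_min Physical half-life in minutes; must be positive.
#'
#' @return An object of class `radionuclide` with fields `name`,
#'   `half_life_min` and `lambda_per_min`.
#' @examples
#' f18()
#' radionuclide("Cu-64", 12.7 * 60)
#' @export
radionuclide <- function(name, half_life_min) {
  stop_if_not_scalar_num(half_life_min, "half_life_min", positive = TRUE)
  structure(
    list(name = as.character(name)[1L],
         half_life_min = half_life_min,
         lambda_per_min = log(2) / half_life_min),
    class = "radionuclide")
}

#' @describeIn radionuclide Fluorine-18, half-life 109.77 min (the default
#'   positron emitter throughout the package; override by constructing your
#'   own `radionuclide`).
#' @export
f18 <- function() radionuclide("F-18", 109.77)

#' @export
print.radionuclide <- function(x, ...) {
  cat(sprintf("<radionuclide> %s: T1/2 = %.4g min, lambda = %.6g /min\n",
              x$name, x$half_life_min, x$lambda_per_min))
  invisible(x)
}

as_radionuclide <- function(x) {
  if (inherits(x, "radionuclide")) return(x)
  if (is.numeric(x)) return(radionuclide("custom", x))
  if (is.character(x) && toupper(gsub("[^A-Z0-9]", "", toupper(x))) %in%
      c("F18", "18F")) return(f18())
  stop("cannot interpret 'nuclide'; supply a radionuclide() object",
       call. = FALSE)
}
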