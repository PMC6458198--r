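#' Tracer kinetics specification for the TAC generator
#'
#' Shape parameters for the synthetic intratumoral-infusion kinetics.  The
#' injected (primary) tumor curve is a linear ramp over the infusion followed
#' by biexponential washout of the peak fraction of injected activity; the
#' contralateral (distant, untreated) tumor follows a mono-exponential
#' saturation `B (1 - exp(-k t))` in %IA/g; organs follow
#' `U (1 - exp(-ku t)) exp(-kw t)` as fractions of injected activity.  All
#' curves are decay-corrected fractions; the whole-body curve is their sum.
#'
#' Defaults encode the study conditions the generator emulates: the primary
#' tumor peaks at the end of the 10-min infusion and falls below 10% of its
#' maximum by 120 min; with the FLT-like preset the contralateral tumor
#' reaches ~8 %IA/g at 120 min, while the FDG-like preset plateaus by 40 min
#' at one fifth of that level, with higher heart/brain/kidney spill.
#'
#' @param tracer `"FLT-like"` or `"FDG-like"`; selects the preset.
#' @param infusion_duration_min Infusion length (min), > 0.
#' @param peak_fraction Fraction of injected activity in the primary tumor at
#'   the end of infusion (0-1).
#' @param primary_weights,primary_rates Biexponential washout weights
#'   (summing to 1) and clearance rates (1/min, >= 0) of the primary tumor.
#' @param contralateral_plateau Contralateral saturation level (%IA/g).
#' @param contralateral_uptake_rate Saturation rate (1/min, >= 0).
#' @param organ_params Data frame with columns `roi`, `U` (peak fraction of
#'   injected activity), `ku`, `kw` (1/min, >= 0).
#' @param masses_g Named vector of ROI masses (g) covering both tumors and
#'   every organ in `organ_params`.
#' @param noise_sd SD of multiplicative lognormal measurement noise applied
#'   to each sampled value (0 disables noise).
#' @return An object of class `tracer_kinetics_spec`.
#' @export
tracer_kinetics_spec <- function(tracer = c("FLT-like", "FDG-like"),
                                 infusion_duration_min = 10,
                                 peak_fraction = 0.90,
                                 primary_weights = c(0.75, 0.25),
                                 primary_rates = c(0.05, 0.012),
                                 contralateral_plateau = NULL,
                                 contralateral_uptake_rate = NULL,
                                 organ_params = NULL,
                                 masses_g = NULL,
                                 noise_sd = 0.02) {
  tracer <- match.arg(tracer)
  if (is.null(contralateral_plateau))
    contralateral_plateau <- if (tracer == "FLT-like") 9.0 else 1.6
  if (is.null(contralateral_uptake_rate))
    contralateral_uptake_rate <- if (tracer == "FLT-like") 0.018 else 0.10
  if (is.null(organ_params)) {
    organ_params <- if (tracer == "FLT-like") {
      data.frame(
        roi = c("kidneys", "liver", "brain", "heart", "bone", "muscle"),
        U  = c(0.030, 0.050, 0.002, 0.004, 0.040, 0.060),
        ku = c(0.030, 0.025, 0.020, 0.025, 0.015, 0.020),
        kw = c(0.0020, 0.0015, 0.0010, 0.0015, 0.0005, 0.0010),
        stringsAsFactors = FALSE)
    } else {
      data.frame(
        roi = c("kidneys", "liver", "brain", "heart", "bone", "muscle"),
        U  = c(0.060, 0.040, 0.050, 0.060, 0.020, 0.060),
        ku = c(0.060, 0.040, 0.060, 0.080, 0.030, 0.040),
        kw = c(0.0020, 0.0015, 0.0002, 0.0005, 0.0005, 0.0010),
        stringsAsFactors = FALSE)
    }
  }
  if (is.null(masses_g))
    masses_g <- c("primary tumor" = 0.5, "contralateral tumor" = 0.5,
                  kidneys = 0.3, liver = 1.3, brain = 0.4, heart = 0.15,
                  bone = 2.0, muscle = 8.0)
  stop_if_not_scalar_num(infusion_duration_min, "infusion_duration_min",
                         positive = TRUE)
  stop_if_not_scalar_num(peak_fraction, "peak_fraction", positive = TRUE)
  if (peak_fraction > 1) stop("peak_fraction must be <= 1", call. = FALSE)
  if (abs(sum(primary_weights) - 1) > 1e-9)
    stop("primary_weights must sum to 1", call. = FALSE)
  if (any(primary_weights < 0)) stop("weights must be >= 0", call. = FALSE)
  if (length(primary_weights) != length(primary_rates))
    stop("weights/rates length mismatch", call. = FALSE)
  rates <- c(primary_rates, contralateral_uptake_rate,
             organ_params$ku, organ_params$kw)
  if (any(rates < 0)) stop("all rates must be >= 0", call. = FALSE)
  if (contralateral_plateau < 0)
    stop("contralateral_plateau must be >= 0", call. = FALSE)
  stop_if_not_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  need <- c("primary tumor", "contralateral tumor", organ_params$roi)
  if (!all(need %in% names(masses_g)))
    stop("masses_g must name every ROI", call. = FALSE)
  structure(list(tracer = tracer,
                 infusion_duration_min = infusion_duration_min,
                 peak_fraction = peak_fraction,
                 primary_weights = as.numeric(primary_weights),
                 primary_rates = as.numeric(primary_rates),
                 contralateral_plateau = contralateral_plateau,
                 contralateral_uptake_rate = contralateral_uptake_rate,
                 organ_params = organ_params,
                 masses_g = masses_g,
                 noise_sd = noise_sd),
            class = "tracer_kinetics_spec")
}

# decay-corrected fraction of injected activity in each ROI at times t (min);
# returns a matrix [time, roi] including both tumors and all organs
kinetic_fractions <- function(spec, t) {
  Tin <- spec$infusion_duration_min
  ramp <- pmin(t / Tin, 1)
  washout <- vapply(t, function(ti) {
    if (ti <= Tin) 1
    else sum(spec$primary_weights * exp(-spec$primary_rates * (ti - Tin)))
  }, numeric(1))
  primary <- spec$peak_fraction * ramp * washout
  ct_mass <- spec$masses_g[["contralateral tumor"]]
  contral <- (spec$contralateral_plateau * ct_mass / 100) *
    (1 - exp(-spec$contralateral_uptake_rate * t))
  organs <- sapply(seq_len(nrow(spec$organ_params)), function(i) {
    p <- spec$organ_params[i, ]
    p$U * (1 - exp(-p$ku * t)) * exp(-p$kw * t)
  })
  if (is.null(dim(organs))) organs <- matrix(organs, nrow = length(t))
  m <- cbind(primary, contral, organs)
  colnames(m) <- c("primary tumor", "contralateral tumor",
                   spec$organ_params$roi)
  m
}

#' Simulate decay-corrected time-activity curves
#'
#' Samples the kinetic model of a [tracer_kinetics_spec()] at the frame
#' midpoints of `schedule`, applies multiplicative lognormal measurement
#' noise (seeded), and returns one `%IA/g` curve per ROI plus a whole-body
#' curve equal to the sum of the organ curves (so whole-body %IA is
#' consistent with the organ set by construction).  Noise-free fractions must
#' never exceed the injected activity; the generator rejects parameter sets
#' that break this.
#'
#' @param spec A [tracer_kinetics_spec()].
#' @param schedule A [frame_schedule()]; must reach at least 60 min so the
#'   late kinetics are observable (default covers 0-120 min).
#' @param nuclide A [radionuclide()] recorded with the set (used downstream
#'   when uncorrecting).
#' @param seed Integer seed for the measurement noise.
#' @param A0 Injected activity (MBq); 5 MBq is the imaging study condition.
#' @return A [tac_set()] of decay-corrected `%IA/g` curves (ROIs + `"whole
#'   body"`), each with `A0` and its mass attached.
#' @export
simulate_tacs <- function(spec = tracer_kinetics_spec(),
                          schedule = default_frame_schedule(),
                          nuclide = f18(), seed = 1L, A0 = 5) {
  stopifnot(inherits(spec, "tracer_kinetics_spec"),
            inherits(schedule, "frame_schedule"))
  stop_if_not_scalar_num(A0, "A0", positive = TRUE)
  t <- frame_midpoints(schedule)
  if (max(schedule$frame_starts + schedule$frame_durations) < 60)
    stop("schedule must cover at least 0-60 min", call. = FALSE)
  frac <- kinetic_fractions(spec, t)
  tot <- rowSums(frac)
  if (any(tot > 1 + 1e-9))
    stop("kinetic fractions exceed the injected activity; reduce uptake ",
         "parameters", call. = FALSE)
  if (spec$noise_sd > 0) {
    set.seed(as.integer(seed))
    frac <- frac * exp(matrix(stats::rnorm(length(frac), 0, spec$noise_sd),
                              nrow = nrow(frac)))
  }
  masses <- spec$masses_g
  curves <- lapply(colnames(frac), function(roi) {
    tac(t, 100 * frac[, roi] / masses[[roi]], roi = roi, units = "%IA/g",
        decay_corrected = TRUE, A0 = A0, mass_g = masses[[roi]],
        schedule = schedule)
  })
  wb_mass <- sum(masses[colnames(frac)])
  wb <- tac(t, 100 * rowSums(frac) / wb_mass, roi = "whole body",
            units = "%IA/g", decay_corrected = TRUE, A0 = A0,
            mass_g = wb_mass, schedule = schedule)
  out <- tac_set(c(curves, list(wb)), A0 = A0, tracer = spec$tracer)
  attr(out, "nuclide") <- as_radionuclide(nuclide)
  out
}
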