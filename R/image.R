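#' 4D dynamic PET image
#'
#' Voxel values are activity-rate concentrations (cps/mL) per frame, as
#' produced by a reconstructed small-animal PET acquisition.  A scanner
#' calibration factor converts cps/mL to MBq/mL.
#'
#' @param data 4D numeric array (x, y, z, frame), non-negative; the fourth
#'   dimension must match the schedule.
#' @param voxel_mm Voxel size in mm, length 3, all > 0.
#' @param schedule A [frame_schedule()].
#' @param calibration Scanner calibration, (MBq/mL) per (cps/mL); > 0.
#' @param decay_corrected Logical; whether the reconstruction already removed
#'   physical decay (typical).
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(data, voxel_mm, schedule, calibration = 1,
                          decay_corrected = TRUE) {
  stopifnot(is.array(data), length(dim(data)) == 4L,
            inherits(schedule, "frame_schedule"))
  if (dim(data)[4L] != n_frames(schedule))
    stop("number of image frames does not match the schedule", call. = FALSE)
  if (length(voxel_mm) != 3L || any(voxel_mm <= 0))
    stop("voxel_mm must be three positive sizes", call. = FALSE)
  if (any(data < 0)) stop("image values must be >= 0", call. = FALSE)
  stop_if_not_scalar_num(calibration, "calibration", positive = TRUE)
  structure(list(data = data, voxel_mm = as.numeric(voxel_mm),
                 schedule = schedule, calibration = calibration,
                 decay_corrected = isTRUE(decay_corrected)),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_image> %dx%dx%d voxels (%gx%gx%g mm), %d frames\n",
              d[1], d[2], d[3], x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3],
              d[4]))
  invisible(x)
}

#' Region-of-interest mask
#'
#' @param name ROI name.
#' @param voxels Logical 3D array marking member voxels; at least one TRUE.
#' @param density_g_per_ml Tissue density used to turn ROI volume into mass;
#'   default 1.0 g/mL (soft tissue).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(name, voxels, density_g_per_ml = 1.0) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  storage.mode(voxels) <- "logical"
  if (!any(voxels)) stop("ROI mask '", name, "' is empty", call. = FALSE)
  stop_if_not_scalar_num(density_g_per_ml, "density_g_per_ml", positive = TRUE)
  structure(list(name = as.character(name)[1L], voxels = voxels,
                 density_g_per_ml = density_g_per_ml),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s': %d voxels\n", x$name, sum(x$voxels)))
  invisible(x)
}

mask_volume_ml <- function(mask, voxel_mm) {
  sum(mask$voxels) * prod(voxel_mm) / 1000  # mm^3 -> mL
}

#' Extract time-activity curves from a dynamic image
#'
#' For every mask and frame:
#' `activity (MBq) = mean(cps/mL over mask) x calibration x ROI volume (mL)`.
#' Sample times are frame midpoints; the decay-correction flag is inherited
#' from the image metadata, and the ROI mass (volume x density) is recorded
#' on each curve.
#'
#' @param image A [dynamic_image()].
#' @param masks A list of [roi_mask()] objects (dimensions must match the
#'   image grid).
#' @return A [tac_set()] of curves in MBq.
#' @export
extract_tacs <- function(image, masks) {
  stopifnot(inherits(image, "dynamic_image"), is.list(masks))
  if (inherits(masks, "roi_mask")) masks <- list(masks)
  d <- dim(image$data)
  nf <- d[4L]
  flat <- image$data
  dim(flat) <- c(prod(d[1:3]), nf)
  mids <- frame_midpoints(image$schedule)
  out <- lapply(masks, function(m) {
    stopifnot(inherits(m, "roi_mask"))
    if (!identical(dim(m$voxels), d[1:3]))
      stop("mask '", m$name, "' does not match the image grid", call. = FALSE)
    idx <- which(m$voxels)
    vol_ml <- mask_volume_ml(m, image$voxel_mm)
    vals <- colMeans(flat[idx, , drop = FALSE]) * image$calibration * vol_ml
    tac(mids, vals, roi = m$name, units = "MBq",
        decay_corrected = image$decay_corrected,
        mass_g = vol_ml * m$density_g_per_ml, schedule = image$schedule)
  })
  tac_set(out)
}

#' Total image activity per frame
#'
#' Whole-image activity (MBq) per frame; on a phantom with no activity
#' outside the ROI blobs this equals the sum of the ROI curves.
#'
#' @param image A [dynamic_image()].
#' @return Numeric vector, one value per frame.
#' @export
image_total_activity <- function(image) {
  stopifnot(inherits(image, "dynamic_image"))
  d <- dim(image$data)
  flat <- image$data
  dim(flat) <- c(prod(d[1:3]), d[4L])
  colSums(flat) * image$calibration * prod(image$voxel_mm) / 1000
}
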