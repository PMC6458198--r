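#' Phantom geometry for the 4D image generator
#'
#' Lays out one ellipsoidal blob per ROI on a voxel grid.  The default grid
#' is 40 x 40 x 40 voxels of 0.5 x 0.5 x 0.6 mm (a reduced version of a
#' 120 x 120 x 128 small-animal reconstruction matrix, same voxel size);
#' pass `dim` to use a larger grid.
#'
#' @param rois Character vector of ROI names to place.
#' @param dim Grid size (3 integers).
#' @param voxel_mm Voxel size in mm (3 values).
#' @param radii_vox Ellipsoid semi-axes in voxels (3 values) used for every
#'   blob.
#' @return Object of class `phantom_geometry`: the grid description plus a
#'   data frame of blob centres and semi-axes (voxel units, 1-based centres).
#' @export
phantom_geometry <- function(rois, dim = c(40L, 40L, 40L),
                             voxel_mm = c(0.5, 0.5, 0.6),
                             radii_vox = c(4, 4, 3)) {
  stopifnot(length(rois) >= 1L, length(dim) == 3L, length(voxel_mm) == 3L,
            all(dim >= 8L), all(voxel_mm > 0), all(radii_vox >= 1))
  # centres on a coarse lattice, filled in order; lattice spacing keeps
  # blobs separated by construction
  nx <- max(1L, floor(dim[1] / (2 * radii_vox[1] + 3)))
  ny <- max(1L, floor(dim[2] / (2 * radii_vox[2] + 3)))
  nz <- max(1L, floor(dim[3] / (2 * radii_vox[3] + 3)))
  cx <- round(seq(radii_vox[1] + 2, dim[1] - radii_vox[1] - 1,
                  length.out = nx))
  cy <- round(seq(radii_vox[2] + 2, dim[2] - radii_vox[2] - 1,
                  length.out = ny))
  cz <- round(seq(radii_vox[3] + 2, dim[3] - radii_vox[3] - 1,
                  length.out = nz))
  slots <- expand.grid(cx = cx, cy = cy, cz = cz)
  if (nrow(slots) < length(rois))
    stop("grid too small to place ", length(rois), " non-overlapping blobs",
         call. = FALSE)
  blobs <- data.frame(roi = rois,
                      cx = slots$cx[seq_along(rois)],
                      cy = slots$cy[seq_along(rois)],
                      cz = slots$cz[seq_along(rois)],
                      rx = radii_vox[1], ry = radii_vox[2], rz = radii_vox[3],
                      stringsAsFactors = FALSE)
  structure(list(dim = as.integer(dim), voxel_mm = as.numeric(voxel_mm),
                 blobs = blobs),
            class = "phantom_geometry")
}

ellipsoid_voxels <- function(geom, blob) {
  d <- geom$dim
  x <- seq_len(d[1]); y <- seq_len(d[2]); z <- seq_len(d[3])
  dx2 <- ((x - blob$cx) / blob$rx)^2
  dy2 <- ((y - blob$cy) / blob$ry)^2
  dz2 <- ((z - blob$cz) / blob$rz)^2
  arr <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
  arr
}

#' Paint time-activity curves into a 4D phantom image
#'
#' Each ROI's activity is spread uniformly over its ellipsoidal blob:
#' voxel value (cps/mL) = activity (MBq) / blob volume (mL) / calibration.
#' The ROI-mean of a painted blob therefore reproduces the input curve
#' exactly in noise-free mode, and [extract_tacs()] closes the round trip.
#'
#' @param tacs A [tac_set()]; `%IA/g` curves are converted to MBq using
#'   their stored `A0` and mass.  A `"whole body"` member, if present, is
#'   not painted (it is the sum of the others) but its mask (union of all
#'   blobs) is returned.
#' @param geometry A [phantom_geometry()]; every blob must have a matching
#'   TAC and vice versa (the whole-body curve excepted).
#' @param seed Integer seed for voxel noise.
#' @param noise_sd Relative SD of additive Gaussian voxel noise (0 = off,
#'   the default; reconstruction noise is out of scope).
#' @param calibration Scanner calibration, (MBq/mL) per (cps/mL).
#' @return `list(image = dynamic_image, masks = list of roi_mask)`; masks
#'   include `"whole body"` (union of all blobs).
#' @export
simulate_dynamic_image <- function(tacs, geometry = NULL, seed = 1L,
                                   noise_sd = 0, calibration = 1e-3) {
  stopifnot(inherits(tacs, "tac_set"))
  rois <- setdiff(names(tacs), "whole body")
  if (is.null(geometry)) geometry <- phantom_geometry(rois)
  stopifnot(inherits(geometry, "phantom_geometry"))
  if (!setequal(geometry$blobs$roi, rois))
    stop("geometry blobs and TAC ROIs do not match: [",
         paste(union(setdiff(geometry$blobs$roi, rois),
                     setdiff(rois, geometry$blobs$roi)), collapse = ", "),
         "]", call. = FALSE)
  schedule <- tacs[[rois[1L]]]$schedule
  if (is.null(schedule))
    stop("TACs carry no frame schedule", call. = FALSE)
  nf <- n_frames(schedule)
  d <- geometry$dim
  vox_ml <- prod(geometry$voxel_mm) / 1000
  img <- array(0, dim = c(d, nf))
  occupied <- array(FALSE, dim = d)
  masks <- list()
  for (i in seq_len(nrow(geometry$blobs))) {
    blob <- geometry$blobs[i, ]
    vox <- ellipsoid_voxels(geometry, blob)
    if (any(vox & occupied))
      stop("blobs overlap at ROI '", blob$roi, "'", call. = FALSE)
    occupied <- occupied | vox
    curve <- tacs[[blob$roi]]
    if (curve$units == "%IA/g") curve <- to_megabecquerel(curve)
    if (curve$units != "MBq")
      stop("TAC units must be MBq or %IA/g", call. = FALSE)
    if (length(curve$values) != nf)
      stop("TAC '", blob$roi, "' does not match the schedule", call. = FALSE)
    conc <- curve$values / (sum(vox) * vox_ml) / calibration  # cps/mL
    idx <- which(vox)
    for (f in seq_len(nf)) {
      frame <- img[, , , f]
      frame[idx] <- conc[f]
      img[, , , f] <- frame
    }
    masks[[blob$roi]] <- roi_mask(blob$roi, vox)
  }
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    img <- pmax(0, img * (1 + stats::rnorm(length(img), 0, noise_sd)))
    dim(img) <- c(d, nf)
  }
  masks[["whole body"]] <- roi_mask("whole body", occupied)
  decay_flag <- tacs[[rois[1L]]]$decay_corrected
  list(image = dynamic_image(img, geometry$voxel_mm, schedule,
                             calibration = calibration,
                             decay_corrected = decay_flag),
       masks = masks)
}
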