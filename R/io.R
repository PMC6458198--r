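#' Write a TAC set to CSV
#'
#' Schema: `roi, frame_start_min, frame_duration_min, value, units,
#' decay_corrected`.  Numbers are printed with 17 significant digits so that
#' write -> read -> write is byte-stable and values round-trip at full double
#' precision.
#'
#' @param tacs A [tac_set()] whose members carry a frame schedule.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tac_csv <- function(tacs, path) {
  stopifnot(inherits(tacs, "tac_set"))
  lines <- "roi,frame_start_min,frame_duration_min,value,units,decay_corrected"
  for (tc in tacs) {
    if (is.null(tc$schedule))
      stop("TAC '", tc$roi, "' carries no frame schedule", call. = FALSE)
    sch <- tc$schedule
    lines <- c(lines, sprintf("%s,%s,%s,%s,%s,%s",
                              tc$roi, fmt_num(sch$frame_starts),
                              fmt_num(sch$frame_durations),
                              fmt_num(tc$values), tc$units,
                              ifelse(tc$decay_corrected, "true", "false")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a TAC set from CSV
#'
#' Inverse of [write_tac_csv()].  Rows are grouped by ROI; malformed content
#' is rejected with the offending line number: unknown units, non-monotone
#' frame starts within an ROI, or mixed decay-correction flags within an
#' ROI.
#'
#' @param path CSV file in the TAC schema.
#' @param A0 Optional reference activity attached to the set.
#' @return A [tac_set()].
#' @export
read_tac_csv <- function(path, A0 = NA_real_) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop("no curves in '", path, "'", call. = FALSE)
  need <- c("roi", "frame_start_min", "frame_duration_min", "value",
            "units", "decay_corrected")
  if (!all(need %in% names(d)))
    stop("TAC CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  d$.line <- seq_len(nrow(d)) + 1L  # header is line 1
  bad <- which(!d$units %in% c("MBq", "MBq/g", "%IA/g"))
  if (length(bad))
    stop("unknown units '", d$units[bad[1L]], "' at line ", d$.line[bad[1L]],
         call. = FALSE)
  dc <- tolower(as.character(d$decay_corrected))
  bad <- which(!dc %in% c("true", "false"))
  if (length(bad))
    stop("decay_corrected must be true/false at line ", d$.line[bad[1L]],
         call. = FALSE)
  d$decay_corrected <- dc == "true"
  # preserve first-appearance ROI order so write -> read -> write is stable
  curves <- lapply(split(d, factor(d$roi, levels = unique(d$roi))),
                   function(dd) {
    dd <- dd[order(dd$.line), ]
    if (any(diff(dd$frame_start_min) <= 0)) {
      i <- which(diff(dd$frame_start_min) <= 0)[1L] + 1L
      stop("non-increasing frame starts for roi '", dd$roi[1L],
           "' at line ", dd$.line[i], call. = FALSE)
    }
    if (length(unique(dd$decay_corrected)) > 1L)
      stop("mixed decay_corrected flags for roi '", dd$roi[1L],
           "' (line ", dd$.line[which(dd$decay_corrected !=
                                        dd$decay_corrected[1L])[1L]], ")",
           call. = FALSE)
    if (length(unique(dd$units)) > 1L)
      stop("mixed units for roi '", dd$roi[1L], "'", call. = FALSE)
    sch <- frame_schedule(dd$frame_start_min, dd$frame_duration_min)
    tac(frame_midpoints(sch), dd$value, roi = dd$roi[1L],
        units = dd$units[1L], decay_corrected = dd$decay_corrected[1L],
        A0 = if (dd$units[1L] == "%IA/g") A0 else NA_real_,
        schedule = sch)
  })
  tac_set(curves, A0 = A0)
}

#' Read a caliper growth table
#'
#' Expects columns `animal_id`, `group`, `day` and either `volume_mm3` or
#' the caliper pair `a_mm`, `b_mm` (volumes are then computed with
#' [volume_from_calipers()]).
#'
#' @param path CSV file.
#' @return Data frame ready for [response_summary()].
#' @export
read_growth_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "day")
  if (!all(need %in% names(d)))
    stop("growth CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"volume_mm3" %in% names(d)) {
    if (!all(c("a_mm", "b_mm") %in% names(d)))
      stop("growth CSV needs volume_mm3 or a_mm/b_mm", call. = FALSE)
    d$volume_mm3 <- volume_from_calipers(d$a_mm, d$b_mm)
  }
  d
}

#' Read a Fricke calibration CSV
#'
#' Columns `cumulated_activity_MBq_h`, `dose_Gy`.
#'
#' @param path CSV file.
#' @return A [calibration_series()].
#' @export
read_calibration_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cumulated_activity_MBq_h", "dose_Gy")
  if (!all(need %in% names(d)))
    stop("calibration CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  calibration_series(d$cumulated_activity_MBq_h, d$dose_Gy)
}

#' Write a dynamic image (plus sidecar) and masks to disk
#'
#' The image goes to NIfTI-1 (`<prefix>.nii.gz`), the acquisition metadata
#' to a JSON sidecar (`<prefix>.json`: frame starts/durations, calibration,
#' decay flag, nuclide), and the masks to a NIfTI label image
#' (`<prefix>_labels.nii.gz`) with the label-name mapping in the sidecar.
#'
#' @param sim Result of [simulate_dynamic_image()], or a list with `image`
#'   and `masks`.
#' @param prefix Output path prefix.
#' @param nuclide A [radionuclide()] recorded in the sidecar.
#' @return The sidecar path, invisibly.
#' @export
write_dynamic_image <- function(sim, prefix, nuclide = f18()) {
  image <- sim$image; masks <- sim$masks
  stopifnot(inherits(image, "dynamic_image"))
  nuclide <- as_radionuclide(nuclide)
  RNifti::writeNifti(RNifti::asNifti(image$data,
                                     pixdim = c(image$voxel_mm, 1)),
                     paste0(prefix, ".nii.gz"))
  labels <- array(0L, dim = dim(image$data)[1:3])
  label_names <- character(0)
  i <- 0L
  for (m in masks) {
    if (m$name == "whole body") next
    i <- i + 1L
    labels[m$voxels] <- i
    label_names[i] <- m$name
  }
  RNifti::writeNifti(RNifti::asNifti(labels, pixdim = c(image$voxel_mm, 1)),
                     paste0(prefix, "_labels.nii.gz"))
  sidecar <- list(frame_starts_min = image$schedule$frame_starts,
                  frame_durations_min = image$schedule$frame_durations,
                  calibration_MBq_per_mL_per_cps_per_mL = image$calibration,
                  decay_corrected = image$decay_corrected,
                  nuclide = nuclide$name,
                  half_life_min = nuclide$half_life_min,
                  voxel_mm = image$voxel_mm,
                  labels = as.list(stats::setNames(seq_along(label_names),
                                                   label_names)))
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paste0(prefix, ".json"))
}

#' Read a dynamic image written by [write_dynamic_image()]
#'
#' @param prefix Path prefix used when writing.
#' @return `list(image, masks)` as produced by [simulate_dynamic_image()].
#' @export
read_dynamic_image <- function(prefix) {
  sidecar <- jsonlite::read_json(paste0(prefix, ".json"),
                                 simplifyVector = TRUE)
  arr <- as.array(RNifti::readNifti(paste0(prefix, ".nii.gz")))
  sch <- frame_schedule(sidecar$frame_starts_min,
                        sidecar$frame_durations_min)
  image <- dynamic_image(arr, sidecar$voxel_mm, sch,
                         calibration = sidecar$calibration_MBq_per_mL_per_cps_per_mL,
                         decay_corrected = isTRUE(sidecar$decay_corrected))
  labels <- as.array(RNifti::readNifti(paste0(prefix, "_labels.nii.gz")))
  masks <- lapply(names(sidecar$labels), function(nm) {
    roi_mask(nm, labels == sidecar$labels[[nm]])
  })
  names(masks) <- names(sidecar$labels)
  masks[["whole body"]] <- roi_mask("whole body", labels > 0)
  list(image = image, masks = masks)
}
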