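#' Per-class volumes and trabecular volume percentage
#'
#' Sums per-label pixel counts over all slices and converts them to mm^3
#' using the voxel volume `pixel_spacing_x * pixel_spacing_y *
#' (slice_thickness + slice_gap)` when geometry is present (raw pixel
#' counts when `use_geometry = FALSE`). The trabecular volume percentage is
#'
#' \deqn{VT\% = 100 \cdot V_{TZ} / (V_{TZ} + V_{EL})}
#'
#' i.e. trabecular over trabecular-plus-compacted volume; the internal
#' cavity is reported but excluded from the ratio. Being a ratio, VT% is
#' invariant to any uniform scaling of the voxel geometry.
#'
#' @param stack a [segmentation_stack()].
#' @param use_geometry convert counts to mm^3 (default `TRUE`).
#' @return an object of class `volume_breakdown` with fields `el_volume`,
#'   `ic_volume`, `tz_volume` (mm^3 or pixels) and `vt_percent`.
#' @export
compute_volumes <- function(stack, use_geometry = TRUE) {
  if (!inherits(stack, "segmentation_stack"))
    stop("stack must be a segmentation_stack", call. = FALSE)
  counts <- c(el = 0, ic = 0, tz = 0)
  for (sl in stack$slices) {
    counts["el"] <- counts["el"] + sum(sl == LABEL_EL)
    counts["ic"] <- counts["ic"] + sum(sl == LABEL_IC)
    counts["tz"] <- counts["tz"] + sum(sl == LABEL_TZ)
  }
  vox <- if (use_geometry) {
    g <- stack$geometry
    g$pixel_spacing_x * g$pixel_spacing_y * slice_pitch(g)
  } else 1
  vols <- counts * vox
  denom <- vols[["tz"]] + vols[["el"]]
  vt <- if (denom > 0) 100 * vols[["tz"]] / denom else 0
  structure(list(el_volume = vols[["el"]], ic_volume = vols[["ic"]],
                 tz_volume = vols[["tz"]], vt_percent = vt,
                 units = if (use_geometry) "mm^3" else "pixels"),
            class = "volume_breakdown")
}

#' @export
print.volume_breakdown <- function(x, ...) {
  cat(sprintf("volumes (%s): EL %.1f, IC %.1f, TZ %.1f; VT%% = %.2f\n",
              x$units, x$el_volume, x$ic_volume, x$tz_volume, x$vt_percent))
  invisible(x)
}

#' LVNC decision rule
#'
#' A patient is called LVNC-positive when the trabecular volume percentage
#' strictly exceeds the threshold; a value exactly at the threshold is
#' negative. The default threshold is 27.4 percent.
#'
#' @param vt_percent trabecular volume percentage in \[0, 100\].
#' @param threshold decision threshold in percent (default 27.4).
#' @return logical: `TRUE` for an LVNC-positive call.
#' @export
diagnose <- function(vt_percent, threshold = 27.4) {
  if (any(vt_percent < 0 | vt_percent > 100))
    stop("vt_percent must lie in [0, 100]", call. = FALSE)
  vt_percent > threshold
}

#' Diagnosis record for one patient
#'
#' @param patient_id identifier.
#' @param vt_percent trabecular volume percentage.
#' @param threshold decision threshold in percent (default 27.4).
#' @return an object of class `diagnosis_record` with the VT%, the binary
#'   LVNC call and the threshold used.
#' @export
diagnosis_record <- function(patient_id, vt_percent, threshold = 27.4) {
  structure(list(patient_id = as.character(patient_id),
                 vt_percent = vt_percent,
                 lvnc_positive = diagnose(vt_percent, threshold),
                 threshold_used = threshold),
            class = "diagnosis_record")
}

#' @export
print.diagnosis_record <- function(x, ...) {
  cat(sprintf("patient %s: VT%% = %.2f (threshold %.1f) -> %s\n",
              x$patient_id, x$vt_percent, x$threshold_used,
              if (x$lvnc_positive) "LVNC" else "no LVNC"))
  invisible(x)
}

#' Normalised slice position within a patient's stack
#'
#' Maps a slice index to \[0, 1\] by `(slice - min) / (max - min)` over the
#' patient's slice indices; a slice is at an end of the stack iff the
#' result is 0 or 1. Used to relate segmentation quality to position along
#' the ventricle.
#'
#' @param slice_index slice index (must occur in `patient_slice_indices`).
#' @param patient_slice_indices all slice indices of the patient.
#' @return a real in \[0, 1\].
#' @export
normalized_slice <- function(slice_index, patient_slice_indices) {
  lo <- min(patient_slice_indices); hi <- max(patient_slice_indices)
  if (hi == lo)
    stop(sprintf(
      "normalised slice undefined: max - min of slice indices is 0 (all = %s)",
      lo), call. = FALSE)
  if (!slice_index %in% patient_slice_indices)
    stop("slice_index not among the patient's slice indices", call. = FALSE)
  (slice_index - lo) / (hi - lo)
}
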