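#' Validate a label map
#'
#' A label map is one short-axis slice of integer class labels:
#' 0 = background, 1 = external layer (EL), 2 = internal cavity (IC),
#' 3 = trabecular zone (TZ).
#'
#' @param pixels integer matrix of class labels.
#' @param slice optional slice identifier used in error messages.
#' @return the validated integer matrix (invisibly identical content).
#' @export
label_map <- function(pixels, slice = NULL) {
  if (!is.matrix(pixels))
    stop("label map must be a matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("label map must have positive dimensions", call. = FALSE)
  storage.mode(pixels) <- "integer"
  bad <- setdiff(unique(as.vector(pixels)), LABEL_VALUES)
  if (length(bad) > 0L) {
    where <- if (is.null(slice)) "" else sprintf(" in slice %s", slice)
    stop(sprintf("invalid label value(s) %s%s; allowed labels are 0,1,2,3",
                 paste(bad, collapse = ", "), where), call. = FALSE)
  }
  pixels
}

#' Voxel geometry of a short-axis stack
#'
#' Pixel spacings and slice geometry in millimetres. The effective slice
#' pitch used for volume computation is `slice_thickness + slice_gap`.
#' Defaults (1.5, 1.5, 8, 2) mm correspond to a typical cine b-SSFP
#' short-axis acquisition.
#'
#' @param pixel_spacing_x,pixel_spacing_y in-plane pixel spacing, mm.
#' @param slice_thickness slice thickness, mm.
#' @param slice_gap inter-slice gap, mm.
#' @return an object of class `voxel_geometry`.
#' @export
voxel_geometry <- function(pixel_spacing_x = 1.5, pixel_spacing_y = 1.5,
                           slice_thickness = 8, slice_gap = 2) {
  vals <- c(pixel_spacing_x, pixel_spacing_y, slice_thickness)
  if (any(!is.finite(c(vals, slice_gap))) || any(vals <= 0) || slice_gap < 0)
    stop("voxel geometry fields must be positive (slice_gap may be 0)",
         call. = FALSE)
  structure(list(pixel_spacing_x = pixel_spacing_x,
                 pixel_spacing_y = pixel_spacing_y,
                 slice_thickness = slice_thickness,
                 slice_gap = slice_gap),
            class = "voxel_geometry")
}

#' Effective slice pitch (thickness + gap) in mm
#' @param geometry a [voxel_geometry()].
#' @export
slice_pitch <- function(geometry) {
  geometry$slice_thickness + geometry$slice_gap
}

#' Construct a segmentation stack
#'
#' An ordered stack of label maps for one patient (apex-to-base or
#' base-to-apex; the post-processing algorithms are direction-symmetric)
#' plus voxel geometry.
#'
#' @param slices list of label-map matrices, all the same size.
#' @param patient_id identifier string.
#' @param geometry a [voxel_geometry()]; defaults apply when omitted.
#' @return an object of class `segmentation_stack`.
#' @export
segmentation_stack <- function(slices, patient_id = "patient",
                               geometry = voxel_geometry()) {
  if (!is.list(slices) || length(slices) == 0L)
    stop("a segmentation stack needs at least one slice", call. = FALSE)
  slices <- lapply(seq_along(slices), function(i)
    label_map(slices[[i]], slice = i - 1L))
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all slices must share identical height and width", call. = FALSE)
  if (!inherits(geometry, "voxel_geometry"))
    stop("geometry must be a voxel_geometry object", call. = FALSE)
  structure(list(patient_id = as.character(patient_id),
                 slices = slices, geometry = geometry),
            class = "segmentation_stack")
}

#' @export
print.segmentation_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("segmentation_stack '%s': %d slices of %d x %d px, pitch %.1f mm\n",
              x$patient_id, length(x$slices), d[1], d[2],
              slice_pitch(x$geometry)))
  invisible(x)
}

#' Number of slices in a stack
#' @param stack a [segmentation_stack()].
#' @export
n_slices <- function(stack) length(stack$slices)

guess_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else "png_dir"
}

#' Read a segmentation stack
#'
#' Reads either a NIfTI integer label volume (slices along the third axis)
#' or a directory of RGB PNG slices named `<patient>_s<index>.png`, coloured
#' with the package's fixed four-colour palette. For PNG directories an
#' optional `geometry.json` sidecar supplies the voxel geometry.
#'
#' @param path file (NIfTI) or directory (PNG) location.
#' @param format `"nifti"`, `"png_dir"`, or `"auto"` (from the path).
#' @return a [segmentation_stack()].
#' @export
read_stack <- function(path, format = c("auto", "nifti", "png_dir")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format == "nifti") read_stack_nifti(path) else read_stack_png(path)
}

read_stack_nifti <- function(path) {
  if (!file.exists(path))
    stop(sprintf("no such file: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L)
    stop("label volume must be 2- or 3-dimensional", call. = FALSE)
  if (any(arr != round(arr)))
    stop("label volume contains non-integer values", call. = FALSE)
  pd <- RNifti::pixdim(img)
  geom <- if (length(pd) >= 3 && all(pd[1:3] > 0)) {
    # NIfTI has no slice-gap field: pixdim[3] is the effective pitch
    voxel_geometry(pd[1], pd[2], slice_thickness = pd[3], slice_gap = 0)
  } else voxel_geometry()
  slices <- lapply(seq_len(dim(arr)[3]), function(k)
    label_map(matrix(as.integer(arr[, , k]), dim(arr)[1], dim(arr)[2]),
              slice = k - 1L))
  pid <- sub("\\.nii(\\.gz)?$", "", basename(path))
  segmentation_stack(slices, patient_id = pid, geometry = geom)
}

label_to_rgb <- function(map) {
  h <- nrow(map); w <- ncol(map)
  arr <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) arr[, , ch] <- LABEL_PALETTE[map + 1L, ch] / 255
  arr
}

rgb_to_label <- function(arr, slice, file) {
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  h <- dim(arr)[1]; w <- dim(arr)[2]
  nch <- dim(arr)[3]
  rgb <- if (nch >= 3) arr[, , 1:3, drop = FALSE]
         else array(arr[, , 1], dim = c(h, w, 3))
  code <- round(rgb[, , 1] * 255) * 65536 +
          round(rgb[, , 2] * 255) * 256 + round(rgb[, , 3] * 255)
  pal_code <- LABEL_PALETTE[, 1] * 65536 + LABEL_PALETTE[, 2] * 256 +
              LABEL_PALETTE[, 3]
  idx <- match(as.vector(code), pal_code)
  if (anyNA(idx)) {
    bad <- code[which(is.na(idx))[1]]
    stop(sprintf(
      "unrecognised pixel colour #%06X in slice %s (%s); not in the label palette",
      bad, slice, file), call. = FALSE)
  }
  matrix(as.integer(idx - 1L), h, w)
}

read_stack_png <- function(path) {
  if (!dir.exists(path))
    stop(sprintf("no such directory: %s", path), call. = FALSE)
  files <- list.files(path, pattern = "^.+_s[0-9]+\\.png$")
  if (length(files) == 0L)
    stop(sprintf("no '<patient>_s<index>.png' slices found in %s", path),
         call. = FALSE)
  idx <- as.integer(sub("^.+_s([0-9]+)\\.png$", "\\1", files))
  pid <- unique(sub("_s[0-9]+\\.png$", "", files))
  if (length(pid) != 1L)
    stop("PNG directory mixes slices from several patients", call. = FALSE)
  ord <- order(idx)
  slices <- lapply(seq_along(ord), function(i) {
    f <- files[ord[i]]
    rgb_to_label(png::readPNG(file.path(path, f)), slice = idx[ord[i]], f)
  })
  geom_file <- file.path(path, "geometry.json")
  geom <- if (file.exists(geom_file)) {
    g <- jsonlite::read_json(geom_file, simplifyVector = TRUE)
    voxel_geometry(g$pixel_spacing_x, g$pixel_spacing_y,
                   g$slice_thickness, g$slice_gap)
  } else voxel_geometry()
  segmentation_stack(slices, patient_id = pid, geometry = geom)
}

#' Write a segmentation stack
#'
#' Inverse of [read_stack()]: pixel values, slice order and dimensions
#' round-trip exactly. NIfTI output stores pixel spacings and the effective
#' slice pitch in the header's pixel-dimension fields; PNG output writes one
#' palette-coloured RGB image per slice plus a `geometry.json` sidecar.
#'
#' @param stack a [segmentation_stack()].
#' @param path target file (NIfTI) or directory (PNG; created if absent).
#' @param format `"nifti"`, `"png_dir"`, or `"auto"` (from the path).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, format = c("auto", "nifti", "png_dir")) {
  if (!inherits(stack, "segmentation_stack"))
    stop("stack must be a segmentation_stack", call. = FALSE)
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format == "nifti") write_stack_nifti(stack, path)
  else write_stack_png(stack, path)
  invisible(path)
}

write_stack_nifti <- function(stack, path) {
  d <- dim(stack$slices[[1]])
  arr <- array(0L, dim = c(d[1], d[2], n_slices(stack)))
  for (k in seq_len(n_slices(stack))) arr[, , k] <- stack$slices[[k]]
  g <- stack$geometry
  img <- RNifti::asNifti(arr, datatype = "uint8")
  img <- RNifti::asNifti(img, list(pixdim = c(
    -1, g$pixel_spacing_x, g$pixel_spacing_y, slice_pitch(g), 0, 0, 0, 0)))
  RNifti::writeNifti(img, path)
}

write_stack_png <- function(stack, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  n <- n_slices(stack)
  width <- max(2L, nchar(as.character(n - 1L)))
  for (k in seq_len(n)) {
    f <- file.path(path, sprintf("%s_s%0*d.png", stack$patient_id,
                                 width, k - 1L))
    png::writePNG(label_to_rgb(stack$slices[[k]]), f)
  }
  g <- stack$geometry
  jsonlite::write_json(list(pixel_spacing_x = g$pixel_spacing_x,
                            pixel_spacing_y = g$pixel_spacing_y,
                            slice_thickness = g$slice_thickness,
                            slice_gap = g$slice_gap),
                       file.path(path, "geometry.json"),
                       auto_unbox = TRUE, digits = NA)
}
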