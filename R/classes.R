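#' Image volume container
#'
#' One contrast timepoint: a 3D grid of Hounsfield-unit values with
#' per-axis physical spacing. The third array axis is the slice (axial)
#' direction; the first two axes span the axial plane.
#'
#' @param values 3D numeric array of HU values.
#' @param spacing_mm length-3 positive numeric, physical voxel spacing in mm
#'   along the three array axes.
#' @param timepoint_id character scalar identifying the scan timepoint.
#' @param phase contrast-enhancement phase label, one of `"NCE"`, `"E-AP"`,
#'   `"L-AP"`, `"PVP"`, or `NA` if supplied later via a label table.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing_mm, timepoint_id = "T01", phase = NA_character_) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_cect("measure", "volume values must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop_cect("measure", "spacing_mm must be 3 strictly positive values")
  rng <- range(values, finite = TRUE)
  if (rng[1] < -1024 || rng[2] > 3071)
    stop_cect("measure", "HU values outside [-1024, 3071]")
  if (!is.na(phase)) phase <- match.arg(phase, PHASES)
  structure(
    list(values = values, spacing_mm = spacing_mm,
         timepoint_id = as.character(timepoint_id), phase = phase),
    class = "image_volume"
  )
}

#' Binary segmentation mask
#'
#' A binary grid aligned to an [image_volume()], tagged with lesion, reader
#' and timepoint identifiers.
#'
#' @param values 3D logical (or 0/1) array; `TRUE` marks lesion voxels.
#' @param spacing_mm length-3 positive numeric, voxel spacing in mm.
#' @param lesion_id,reader_id,timepoint_id character identifiers.
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(values, spacing_mm, lesion_id = "L01", reader_id = "R1",
                     timepoint_id = "T01") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_cect("measure", "mask values must be a 3D array")
  if (!is.logical(values)) {
    if (!all(values %in% c(0, 1)))
      stop_cect("measure", "mask values must be binary")
    values <- array(values > 0, dim(values))
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop_cect("measure", "spacing_mm must be 3 strictly positive values")
  structure(
    list(values = values, spacing_mm = spacing_mm,
         lesion_id = as.character(lesion_id), reader_id = as.character(reader_id),
         timepoint_id = as.character(timepoint_id)),
    class = "seg_mask"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s phase=%s dim=%s spacing=%s mm>\n",
              x$timepoint_id, x$phase %||% NA,
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing_mm, 3), collapse = "x")))
  invisible(x)
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask %s/%s/%s dim=%s voxels=%d>\n",
              x$lesion_id, x$reader_id, x$timepoint_id,
              paste(dim(x$values), collapse = "x"), sum(x$values)))
  invisible(x)
}

check_aligned <- function(volume, mask) {
  if (!identical(dim(volume$values), dim(mask$values)))
    stop_cect("measure", sprintf(
      "mask %s/%s/%s grid (%s) does not match volume %s grid (%s)",
      mask$lesion_id, mask$reader_id, mask$timepoint_id,
      paste(dim(mask$values), collapse = "x"),
      volume$timepoint_id, paste(dim(volume$values), collapse = "x")))
  if (max(abs(volume$spacing_mm - mask$spacing_mm)) > 1e-6)
    stop_cect("measure", "mask and volume voxel spacing differ")
  invisible(TRUE)
}
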