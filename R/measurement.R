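# Maximal in-plane (Feret) diameter and mean-density extraction.
#
# RECIST-style calipers measure the longest straight-line extent of the
# lesion cross-section within an axial slice. On a binary raster that is the
# largest pairwise distance among the physical-coordinate corners of the
# foreground pixels ("corner" convention: pixels are closed unit rectangles),
# maximised over slices. The corner maximum is attained on the convex hull
# of boundary-pixel corners, so we take the hull and scan its vertex pairs
# (equivalent to rotating calipers for the diameter; hulls are tiny).

# Corner coordinates (mm) of the boundary pixels of one slice.
# Interior pixels cannot carry the extreme corners, so they are dropped
# before the hull for speed; the result is unchanged.
slice_corner_points <- function(sl, sx, sy, convention = "corner") {
  fg <- which(sl, arr.ind = TRUE)
  if (nrow(fg) == 0L) return(NULL)
  nx <- nrow(sl); ny <- ncol(sl)
  pad <- matrix(FALSE, nx + 2L, ny + 2L)
  pad[2:(nx + 1L), 2:(ny + 1L)] <- sl
  interior <- pad[2:(nx + 1L), 2:(ny + 1L)] &
    pad[1:nx, 2:(ny + 1L)] & pad[3:(nx + 2L), 2:(ny + 1L)] &
    pad[2:(nx + 1L), 1:ny] & pad[2:(nx + 1L), 3:(ny + 2L)]
  bnd <- which(sl & !interior, arr.ind = TRUE)
  i <- bnd[, 1L]; j <- bnd[, 2L]
  if (convention == "center") {
    pts <- cbind((i - 0.5) * sx, (j - 0.5) * sy)
  } else {
    pts <- cbind(c(i - 1L, i, i - 1L, i) * sx,
                 c(j - 1L, j - 1L, j, j) * sy)
  }
  unique(pts)
}

max_pairwise_dist <- function(pts) {
  n <- nrow(pts)
  if (n == 1L) return(0)
  if (n > 8L) {
    h <- grDevices::chull(pts)
    pts <- pts[h, , drop = FALSE]
    n <- nrow(pts)
  }
  max(stats::dist(pts))
}

#' Maximal in-plane diameter of a segmentation mask
#'
#' For each axial slice containing foreground, computes the maximal Feret
#' diameter as the largest pairwise distance among the physical-coordinate
#' corners of the foreground pixels, and returns the maximum over slices.
#' Anisotropic in-plane spacing is applied before distances are taken.
#' Multi-component slices are measured over the union of components.
#'
#' @param mask a [seg_mask()].
#' @param convention `"corner"` (pixels as closed rectangles; the default,
#'   matching edge-to-edge radiologic calipers) or `"center"` (pixel-center
#'   distances).
#' @return Diameter in mm, with attribute `"slice"` giving the 1-based index
#'   of the slice attaining the maximum.
#' @export
#' @examples
#' m <- array(FALSE, c(3, 3, 1)); m[2, 2, 1] <- TRUE
#' max_inplane_diameter(seg_mask(m, c(1, 1, 5)))  # sqrt(2) for one pixel
max_inplane_diameter <- function(mask, convention = c("corner", "center")) {
  convention <- match.arg(convention)
  stopifnot(inherits(mask, "seg_mask"))
  if (!any(mask$values)) stop_cect("measure", "mask is empty")
  sx <- mask$spacing_mm[1]; sy <- mask$spacing_mm[2]
  best <- -Inf; best_slice <- NA_integer_
  dims <- dim(mask$values)
  for (k in seq_len(dims[3])) {
    sl <- array(mask$values[, , k], dims[1:2])
    if (!any(sl)) next
    d <- max_pairwise_dist(slice_corner_points(sl, sx, sy, convention))
    if (d > best) { best <- d; best_slice <- k }
  }
  structure(best, slice = best_slice)
}

#' Mean density (HU) within a mask
#'
#' Arithmetic mean of the Hounsfield-unit values over all foreground voxels
#' of the mask, across all slices.
#'
#' @param volume an [image_volume()].
#' @param mask a [seg_mask()] on the same grid.
#' @return Mean HU, a scalar.
#' @export
mean_density <- function(volume, mask) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "seg_mask"))
  check_aligned(volume, mask)
  if (!any(mask$values)) stop_cect("measure", "mask is empty")
  mean(volume$values[mask$values])
}

#' Measure a whole study
#'
#' Extracts one measurement record per (lesion, reader, timepoint): maximal
#' in-plane diameter (mm) and mean density (HU). Each mask is matched to its
#' volume by `timepoint_id`; phase labels come from the volumes or from a
#' `phase_labels` table with columns `timepoint_id`, `phase`.
#'
#' @param volumes list of [image_volume()] objects.
#' @param masks list of [seg_mask()] objects.
#' @param phase_labels optional data frame mapping `timepoint_id` to `phase`;
#'   required when volumes carry no phase.
#' @param convention diameter convention, see [max_inplane_diameter()].
#' @return A data frame with columns `lesion_id`, `reader_id`,
#'   `timepoint_id`, `phase`, `diameter_mm`, `mean_density_hu`, ordered by
#'   lesion, reader, timepoint.
#' @export
measure_study <- function(volumes, masks, phase_labels = NULL,
                          convention = c("corner", "center")) {
  convention <- match.arg(convention)
  vol_ids <- vapply(volumes, function(v) v$timepoint_id, "")
  if (anyDuplicated(vol_ids))
    stop_cect("measure", "duplicated volume timepoint_id")
  names(volumes) <- vol_ids
  lab <- NULL
  if (!is.null(phase_labels)) {
    stopifnot(all(c("timepoint_id", "phase") %in% names(phase_labels)))
    lab <- stats::setNames(as.character(phase_labels$phase),
                           phase_labels$timepoint_id)
  }
  rows <- lapply(masks, function(m) {
    v <- volumes[[m$timepoint_id]]
    if (is.null(v))
      stop_cect("measure", "no volume for mask timepoint ", m$timepoint_id)
    phase <- if (!is.null(lab)) unname(lab[m$timepoint_id]) else v$phase
    data.frame(lesion_id = m$lesion_id, reader_id = m$reader_id,
               timepoint_id = m$timepoint_id, phase = phase,
               diameter_mm = as.numeric(max_inplane_diameter(m, convention)),
               mean_density_hu = mean_density(v, m),
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  missing <- unique(rec$timepoint_id[is.na(rec$phase) | !(rec$phase %in% PHASES)])
  if (length(missing))
    stop_cect("measure", "missing or invalid phase label for timepoints: ",
              paste(missing, collapse = ", "))
  rec <- rec[order(rec$lesion_id, rec$reader_id, rec$timepoint_id), ]
  rownames(rec) <- NULL
  rec
}

#' Write / read measurement records as CSV
#'
#' Lossless round-trip of the measurement table (full double precision).
#'
#' @param records data frame from [measure_study()].
#' @param path file path.
#' @return `read_records()` returns the records data frame.
#' @export
write_records <- function(records, path) {
  utils::write.csv(format(records, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(lesion_id = "character",
                                        reader_id = "character",
                                        timepoint_id = "character",
                                        phase = "character"))
  rec$diameter_mm <- as.numeric(rec$diameter_mm)
  rec$mean_density_hu <- as.numeric(rec$mean_density_hu)
  rec
}

# ---- NIfTI I/O -------------------------------------------------------------

# Reject volumes whose stored orientation is oblique: "in-plane" is only
# well defined when the slice axis is aligned with the third grid axis.
assert_axis_aligned <- function(img, path) {
  x <- RNifti::xform(img)
  rot <- x[1:3, 1:3]
  scal <- sqrt(colSums(rot^2))
  axes <- abs(sweep(rot, 2, scal, "/"))
  if (any(abs(axes[axes > 0.5] - 1) > 1e-3) || any(axes[axes <= 0.5] > 1e-3))
    stop_cect("io", "oblique acquisition in ", path,
              ": slice axis is not grid-aligned; resample upstream")
  invisible(TRUE)
}

#' Read a CT volume or mask from NIfTI
#'
#' Voxel spacing is taken from the NIfTI header. Oblique acquisitions are
#' rejected rather than silently resampled.
#'
#' @param path NIfTI file path.
#' @param timepoint_id,phase metadata for the volume.
#' @param lesion_id,reader_id metadata for the mask.
#' @return An [image_volume()] / [seg_mask()].
#' @export
read_volume_nifti <- function(path, timepoint_id = basename(path),
                              phase = NA_character_) {
  img <- RNifti::readNifti(path)
  assert_axis_aligned(img, path)
  image_volume(array(as.numeric(img), dim(img)), RNifti::pixdim(img)[1:3],
               timepoint_id = timepoint_id, phase = phase)
}

#' @rdname read_volume_nifti
#' @export
read_mask_nifti <- function(path, lesion_id = "L01", reader_id = "R1",
                            timepoint_id = basename(path)) {
  img <- RNifti::readNifti(path)
  assert_axis_aligned(img, path)
  seg_mask(array(as.numeric(img) > 0.5, dim(img)), RNifti::pixdim(img)[1:3],
           lesion_id = lesion_id, reader_id = reader_id,
           timepoint_id = timepoint_id)
}

#' Write a volume or mask to NIfTI
#'
#' @param x an [image_volume()] or [seg_mask()].
#' @param path destination file (`.nii` or `.nii.gz`).
#' @export
write_nifti <- function(x, path) {
  vals <- if (inherits(x, "seg_mask")) array(as.integer(x$values), dim(x$values))
          else x$values
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- x$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
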