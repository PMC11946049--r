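# Analytic lesion shapes and contour perturbation.
#
# Lesions are super-ellipsoids with a hard boundary (no partial-volume
# blur): a pixel is foreground when its center lies inside the shape after
# an inset of 0.4 x in-plane pixel. The inset compensates the outward bias
# of the pixel-corner Feret convention so that the measured diameter of the
# digitized shape stays within one in-plane voxel of the nominal diameter.
RASTER_INSET_PX <- 0.4

# Low-order angular boundary perturbation R(theta) = 1 + sum a_k cos(k theta + phi_k).
harmonics_field <- function(theta, amps, phases, ks = seq_along(amps) + 1L) {
  r <- rep(1, length(theta))
  for (i in seq_along(amps))
    r <- r + amps[i] * cos(ks[i] * theta + phases[i])
  r
}

# Rasterize one lesion onto a grid.
#   a, b  : in-plane semi-axes (mm), a = semi-major (x), b (y)
#   c_z   : through-plane semi-axis (mm)
#   scale : global radial scale (reader jitter), applied in-plane
#   rough : list(amps, phases) angular harmonics, or NULL
#   center_mm : lesion center in grid physical coordinates
#   exponent  : super-ellipsoid exponent (2 = ellipsoid)
rasterize_lesion <- function(dim3, spacing, a, b, c_z, center_mm,
                             scale = 1, rough = NULL, exponent = 2) {
  sx <- spacing[1]; sy <- spacing[2]; sz <- spacing[3]
  inset <- RASTER_INSET_PX * (sx + sy) / 2
  xc <- (seq_len(dim3[1]) - 0.5) * sx - center_mm[1]
  yc <- (seq_len(dim3[2]) - 0.5) * sy - center_mm[2]
  out <- array(FALSE, dim3)
  DX <- matrix(xc, dim3[1], dim3[2])
  DY <- matrix(yc, dim3[1], dim3[2], byrow = TRUE)
  # angle and directional ellipse radius are slice-independent
  theta <- atan2(DY / b, DX / a)
  r_dir <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  R <- if (is.null(rough)) 1 else harmonics_field(theta, rough$amps, rough$phases)
  e <- exponent
  n_r <- (abs(DX / a)^e + abs(DY / b)^e)^(1 / e)
  for (k in seq_len(dim3[3])) {
    zc <- (k - 0.5) * sz - center_mm[3]
    w <- abs(zc / c_z)^e
    if (w >= 1) next
    s_z <- (1 - w)^(1 / e)
    out[, , k] <- n_r <= scale * R * s_z - inset / r_dir
  }
  out
}

#' Generate a synthetic lesion mask
#'
#' Rasterizes an approximately ellipsoidal lesion of the requested maximal
#' in-plane diameter onto a grid with the given voxel spacing. With
#' `roughness = 0` the shape is a smooth (super-)ellipsoid and the measured
#' pixel-corner Feret diameter is within one in-plane voxel of
#' `diameter_mm`; positive `roughness` adds seeded low-order angular
#' irregularity to the boundary.
#'
#' @param diameter_mm nominal maximal in-plane diameter (mm); must exceed
#'   twice the largest in-plane voxel dimension.
#' @param spacing_mm `(x, y, z)` voxel spacing in mm.
#' @param roughness angular perturbation amplitude (fraction of radius).
#' @param seed integer seed for the roughness harmonics.
#' @param axial_ratio in-plane minor/major axis ratio, in `(0, 1]`.
#' @param z_ratio through-plane semi-axis as a fraction of the in-plane
#'   semi-major axis.
#' @param exponent super-ellipsoid exponent (2 gives an ellipsoid).
#' @param lesion_id,reader_id,timepoint_id identifiers for the returned mask.
#' @return A [seg_mask()]; the lesion center sits at the grid center, on a
#'   slice center, so the equatorial cross-section is always sampled.
#' @export
#' @examples
#' m <- generate_lesion_mask(30, c(0.7, 0.7, 5))
#' max_inplane_diameter(m)  # within [29.3, 30.7]
generate_lesion_mask <- function(diameter_mm, spacing_mm, roughness = 0,
                                 seed = 1, axial_ratio = 1, z_ratio = 0.8,
                                 exponent = 2, lesion_id = "L01",
                                 reader_id = "R1", timepoint_id = "T01") {
  spacing_mm <- as.numeric(spacing_mm)
  stopifnot(length(spacing_mm) == 3, all(spacing_mm > 0),
            axial_ratio > 0, axial_ratio <= 1, z_ratio > 0)
  if (diameter_mm <= 2 * max(spacing_mm[1:2]))
    stop_cect("phantom", sprintf(
      "diameter %.2f mm is below the resolvable size for %.2f x %.2f mm pixels",
      diameter_mm, spacing_mm[1], spacing_mm[2]))
  a <- diameter_mm / 2
  b <- a * axial_ratio
  c_z <- a * z_ratio
  rough <- with_seed(seed, list(
    amps = roughness * stats::rnorm(3) / sqrt(3),
    phases = stats::runif(3, 0, 2 * pi)))
  if (roughness == 0) rough <- NULL
  dims <- lesion_grid_dim(diameter_mm, c_z, spacing_mm)
  center <- grid_center_mm(dims, spacing_mm)
  vals <- rasterize_lesion(dims, spacing_mm, a, b, c_z, center,
                           rough = rough, exponent = exponent)
  if (!any(vals)) stop_cect("phantom", "rasterized lesion is empty")
  seg_mask(vals, spacing_mm, lesion_id = lesion_id, reader_id = reader_id,
           timepoint_id = timepoint_id)
}

# Grid large enough for the lesion plus jitter/motion margin.
lesion_grid_dim <- function(diameter_mm, c_z, spacing, margin_mm = 4) {
  nx <- ceiling((diameter_mm + 2 * margin_mm) / spacing[1])
  ny <- ceiling((diameter_mm + 2 * margin_mm) / spacing[2])
  nz <- 2L * ceiling((c_z + 2) / spacing[3]) + 1L
  c(as.integer(nx), as.integer(ny), as.integer(nz))
}

# Physical center of the grid, snapped so the middle slice center is the
# lesion equator.
grid_center_mm <- function(dims, spacing) {
  c(dims[1] / 2 * spacing[1], dims[2] / 2 * spacing[2],
    (floor(dims[3] / 2) + 0.5) * spacing[3])
}

#' Perturb a contour as a simulated reader edit
#'
#' Scales each in-plane contour's radial profile about the slice centroid by
#' a factor `1 + eps`, with `eps` drawn once per call (one radial draw per
#' timepoint), optionally adding smooth angular roughness. Works on
#' arbitrary star-shaped masks via a binned radial boundary profile; with
#' zero jitter and zero roughness the input mask is returned unchanged.
#'
#' @param mask a [seg_mask()], nonempty.
#' @param model a [reader_model()]; its `radial_jitter_cv` (or
#'   `radial_jitter_sd_mm`) and `boundary_roughness` drive the perturbation.
#' @param seed integer seed for this draw.
#' @return A perturbed [seg_mask()]. Errors rather than returning an empty
#'   mask.
#' @export
perturb_contour <- function(mask, model = reader_model(), seed = 1) {
  stopifnot(inherits(mask, "seg_mask"), inherits(model, "reader_model"))
  if (!any(mask$values)) stop_cect("phantom", "mask is empty")
  cv <- model$radial_jitter_cv
  sd_mm <- model$radial_jitter_sd_mm
  roughness <- model$boundary_roughness
  if ((is.null(sd_mm) && cv == 0 || !is.null(sd_mm) && sd_mm == 0) &&
      roughness == 0)
    return(mask)
  draws <- with_seed(seed, list(
    eps = stats::rnorm(1, 0, if (is.null(sd_mm)) cv else 1),
    amps = roughness * stats::rnorm(3) / sqrt(3),
    phases = stats::runif(3, 0, 2 * pi)))
  sx <- mask$spacing_mm[1]; sy <- mask$spacing_mm[2]
  dims <- dim(mask$values)
  out <- array(FALSE, dims)
  nb <- 72L
  for (k in seq_len(dims[3])) {
    sl <- array(mask$values[, , k], dims[1:2])
    if (!any(sl)) next
    fg <- which(sl, arr.ind = TRUE)
    cx <- mean((fg[, 1] - 0.5) * sx)
    cy <- mean((fg[, 2] - 0.5) * sy)
    px <- (matrix(seq_len(dims[1]), dims[1], dims[2]) - 0.5) * sx - cx
    py <- (matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE) - 0.5) * sy - cy
    r <- sqrt(px^2 + py^2)
    th <- atan2(py, px)
    bin <- pmin(nb, 1L + floor((th + pi) / (2 * pi) * nb))
    # binned outer boundary radius (pixel centers + half-pixel edge)
    rb <- rep(NA_real_, nb)
    rfg <- r[sl]; bfg <- bin[sl]
    agg <- tapply(rfg, bfg, max)
    rb[as.integer(names(agg))] <- agg + 0.5 * (sx + sy) / 2
    # fill unobserved bins by circular interpolation, then smooth
    if (anyNA(rb)) {
      idx <- which(!is.na(rb))
      rb <- stats::approx(x = c(idx - nb, idx, idx + nb),
                          y = rep(rb[idx], 3), xout = seq_len(nb))$y
    }
    rb <- (rb + rb[c(nb, 1:(nb - 1))] + rb[c(2:nb, 1)] * 1) / 3
    scale_th <- harmonics_field(th, draws$amps, draws$phases)
    lim <- if (is.null(sd_mm)) (1 + draws$eps) * scale_th * rb[bin]
           else scale_th * rb[bin] + draws$eps * sd_mm
    out[, , k] <- r <= lim
  }
  if (!any(out))
    stop_cect("phantom", "perturbation emptied the mask (jitter too large for lesion size)")
  seg_mask(out, mask$spacing_mm, lesion_id = mask$lesion_id,
           reader_id = mask$reader_id, timepoint_id = mask$timepoint_id)
}
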