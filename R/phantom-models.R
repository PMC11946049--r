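# Parameterization of the synthetic dynamic-CECT phantom.

#' Lesion enhancement model
#'
#' Controls the mean Hounsfield-unit density a lesion takes in each contrast
#' phase. Two modes:
#'
#' * `"piecewise"` — each phase has a mean HU and an SD. The defaults are
#'   phase-level summary values observed in a 51-patient HCC dynamic-CECT
#'   cohort (NCE 45.03, E-AP 44.25, L-AP 77.96, PVP 88.01 HU, with SDs
#'   9.73, 10.59, 18.93, 16.68). The late arterial phase carries the
#'   largest SD, reflecting contrast inflow through the hepatic artery.
#'   Each phase SD is split into a between-lesion component (drawn once per
#'   lesion and phase) and a within-phase temporal component (drawn per
#'   timepoint); `between_lesion_frac` is the fraction of the *variance*
#'   assigned to the between-lesion component.
#' * `"gamma"` — a gamma-variate enhancement curve
#'   `HU(t) = baseline + A (t/tp)^a exp(a (1 - t/tp))` sampled at a random
#'   time inside each phase's acquisition window.
#'
#' @param mode `"piecewise"` or `"gamma"`.
#' @param phase_means,phase_sds named numeric vectors over
#'   `c("NCE","E-AP","L-AP","PVP")`, in HU.
#' @param between_lesion_frac fraction of variance that is between-lesion
#'   (piecewise mode), in `[0, 1]`.
#' @param baseline_hu,amplitude_hu,time_to_peak_s,shape gamma-variate
#'   parameters.
#' @param phase_windows_s named list of `(start, end)` acquisition windows in
#'   seconds post-injection (gamma mode).
#' @return An object of class `enhancement_model`.
#' @export
enhancement_model <- function(mode = c("piecewise", "gamma"),
                              phase_means = c("NCE" = 45.03, "E-AP" = 44.25,
                                              "L-AP" = 77.96, "PVP" = 88.01),
                              phase_sds = c("NCE" = 9.73, "E-AP" = 10.59,
                                            "L-AP" = 18.93, "PVP" = 16.68),
                              between_lesion_frac = 0.5,
                              baseline_hu = 45, amplitude_hu = 50,
                              time_to_peak_s = 35, shape = 3,
                              phase_windows_s = list("NCE" = c(0, 0),
                                                     "E-AP" = c(15, 25),
                                                     "L-AP" = c(30, 45),
                                                     "PVP" = c(60, 80))) {
  mode <- match.arg(mode)
  stopifnot(setequal(names(phase_means), PHASES),
            setequal(names(phase_sds), PHASES),
            all(phase_sds >= 0),
            between_lesion_frac >= 0, between_lesion_frac <= 1,
            time_to_peak_s > 0, shape > 0)
  structure(list(mode = mode,
                 phase_means = phase_means[PHASES], phase_sds = phase_sds[PHASES],
                 between_lesion_frac = between_lesion_frac,
                 baseline_hu = baseline_hu, amplitude_hu = amplitude_hu,
                 time_to_peak_s = time_to_peak_s, shape = shape,
                 phase_windows_s = phase_windows_s[PHASES]),
            class = "enhancement_model")
}

#' Reader (contour) model
#'
#' Emulates two radiologists who each draw a lesion contour once, copy it
#' across all timepoints, and edit per timepoint. Each reader's base contour
#' is a correlated copy of the true boundary carrying reader-specific smooth
#' angular roughness; per (reader, timepoint) the whole radial profile is
#' additionally scaled by `1 + eps`, with `eps` drawn once per timepoint.
#' One global radial draw per timepoint (rather than per boundary point)
#' makes the induced diameter CV equal the configured radial jitter CV, so
#' variability parameters are recoverable analytically.
#'
#' Jitter can be relative (`radial_jitter_cv`, fractional SD of the radius;
#' the default 0.05 emulates the ~5% diameter CV seen in repeat HCC
#' measurements) or absolute (`radial_jitter_sd_mm`, SD of the radius in mm,
#' identical for every lesion size) — the absolute mode is what makes small
#' lesions show larger *percent* variability.
#'
#' @param n_readers number of readers (>= 1).
#' @param radial_jitter_cv fractional SD of the per-timepoint radius scale.
#' @param radial_jitter_sd_mm absolute radius SD in mm; when non-`NULL`
#'   overrides `radial_jitter_cv`.
#' @param boundary_roughness amplitude of the reader-specific low-order
#'   angular perturbation (fraction of radius).
#' @param seed_offset integer folded into every reader RNG stream.
#' @return An object of class `reader_model`.
#' @export
reader_model <- function(n_readers = 2, radial_jitter_cv = 0.05,
                         radial_jitter_sd_mm = NULL,
                         boundary_roughness = 0.01, seed_offset = 0) {
  stopifnot(n_readers >= 1, radial_jitter_cv >= 0, boundary_roughness >= 0,
            is.null(radial_jitter_sd_mm) || radial_jitter_sd_mm >= 0)
  structure(list(n_readers = as.integer(n_readers),
                 radial_jitter_cv = radial_jitter_cv,
                 radial_jitter_sd_mm = radial_jitter_sd_mm,
                 boundary_roughness = boundary_roughness,
                 seed_offset = as.integer(seed_offset)),
            class = "reader_model")
}

#' Phantom study specification
#'
#' Full parameterization of a synthetic dynamic-CECT study. The defaults
#' mirror the design of the repeat-measurement cohort the analysis modules
#' target: 51 lesions of 1-7 cm, two readers, and per-lesion timepoint
#' counts of 5/2/16/17 across NCE / E-AP / L-AP / PVP (proportional to the
#' cohort's 236/127/818/874 scans over 51 patients), on a 0.7 x 0.7 x 5 mm
#' grid.
#'
#' @param n_lesions number of lesions (one per simulated patient).
#' @param diameter_range_mm `(low, high)` true diameter range, mm.
#' @param voxel_spacing_mm `(x, y, z)` grid spacing, mm.
#' @param timepoints_per_phase named integer vector of per-lesion scan counts
#'   for `c("NCE","E-AP","L-AP","PVP")`; phases with count 0 are omitted.
#' @param enhancement an [enhancement_model()].
#' @param readers a [reader_model()].
#' @param motion_sd_mm SD of the per-timepoint in-plane translation (mm)
#'   applied jointly to the lesion and its contours (contours are edited to
#'   track motion; the residual effect is grid re-alignment).
#' @param image_noise_sd_hu additive Gaussian image noise SD, HU.
#' @param liver_background_hu constant background parenchyma density, HU.
#' @param seed integer master seed; every stream derives from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_lesions = 51,
                         diameter_range_mm = c(10, 70),
                         voxel_spacing_mm = c(0.7, 0.7, 5),
                         timepoints_per_phase = c("NCE" = 5, "E-AP" = 2,
                                                  "L-AP" = 16, "PVP" = 17),
                         enhancement = enhancement_model(),
                         readers = reader_model(),
                         motion_sd_mm = 1,
                         image_noise_sd_hu = 10,
                         liver_background_hu = 60,
                         seed = 1) {
  stopifnot(n_lesions >= 1,
            length(diameter_range_mm) == 2, all(diameter_range_mm > 0),
            diameter_range_mm[1] < diameter_range_mm[2],
            length(voxel_spacing_mm) == 3, all(voxel_spacing_mm > 0),
            all(names(timepoints_per_phase) %in% PHASES),
            all(timepoints_per_phase >= 0), sum(timepoints_per_phase) >= 1,
            motion_sd_mm >= 0, image_noise_sd_hu >= 0)
  used <- timepoints_per_phase[timepoints_per_phase > 0]
  if (!length(used)) stop_cect("phantom", "no phase has timepoints")
  if (!inherits(enhancement, "enhancement_model"))
    stop_cect("phantom", "enhancement must be an enhancement_model")
  if (!inherits(readers, "reader_model"))
    stop_cect("phantom", "readers must be a reader_model")
  structure(list(n_lesions = as.integer(n_lesions),
                 diameter_range_mm = as.numeric(diameter_range_mm),
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 timepoints_per_phase = timepoints_per_phase,
                 enhancement = enhancement, readers = readers,
                 motion_sd_mm = motion_sd_mm,
                 image_noise_sd_hu = image_noise_sd_hu,
                 liver_background_hu = liver_background_hu,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec: %d lesions %.0f-%.0f mm, %d readers, %d timepoints (%s), seed %d>\n",
              x$n_lesions, x$diameter_range_mm[1], x$diameter_range_mm[2],
              x$readers$n_readers, sum(x$timepoints_per_phase),
              paste(sprintf("%s=%d", names(x$timepoints_per_phase),
                            x$timepoints_per_phase), collapse = " "),
              x$seed))
  invisible(x)
}

#' Save / load a phantom specification as YAML
#'
#' Round-trips every field of the spec, including the nested enhancement and
#' reader models.
#'
#' @param spec a [phantom_spec()].
#' @param path YAML file path.
#' @return `read_phantom_spec()` returns the reconstructed [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  x <- unclass(spec)
  x$enhancement <- unclass(x$enhancement)
  x$enhancement$phase_means <- as.list(x$enhancement$phase_means)
  x$enhancement$phase_sds <- as.list(x$enhancement$phase_sds)
  x$readers <- unclass(x$readers)
  x$timepoints_per_phase <- as.list(x$timepoints_per_phase)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  enh <- x$enhancement
  rdm <- x$readers
  phantom_spec(
    n_lesions = x$n_lesions,
    diameter_range_mm = unlist(x$diameter_range_mm),
    voxel_spacing_mm = unlist(x$voxel_spacing_mm),
    timepoints_per_phase = unlist(x$timepoints_per_phase),
    enhancement = enhancement_model(
      mode = enh$mode,
      phase_means = unlist(enh$phase_means),
      phase_sds = unlist(enh$phase_sds),
      between_lesion_frac = enh$between_lesion_frac,
      baseline_hu = enh$baseline_hu, amplitude_hu = enh$amplitude_hu,
      time_to_peak_s = enh$time_to_peak_s, shape = enh$shape,
      phase_windows_s = lapply(enh$phase_windows_s, unlist)),
    readers = reader_model(
      n_readers = rdm$n_readers,
      radial_jitter_cv = rdm$radial_jitter_cv,
      radial_jitter_sd_mm = rdm$radial_jitter_sd_mm,
      boundary_roughness = rdm$boundary_roughness,
      seed_offset = rdm$seed_offset),
    motion_sd_mm = x$motion_sd_mm,
    image_noise_sd_hu = x$image_noise_sd_hu,
    liver_background_hu = x$liver_background_hu,
    seed = x$seed)
}
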