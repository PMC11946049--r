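# Synthetic dynamic-CECT study generation.

#' Draw a lesion density for a contrast phase
#'
#' In piecewise mode, draws from the configured per-phase normal
#' distribution (with SD 0 the phase mean is returned exactly). In gamma
#' mode, samples an acquisition time uniformly inside the phase window and
#' evaluates the gamma-variate enhancement curve
#' `HU(t) = baseline + A (t/tp)^a exp(a (1 - t/tp))`.
#'
#' Draws consume the current RNG state; seed beforehand for reproducibility.
#'
#' @param phase one of `"NCE"`, `"E-AP"`, `"L-AP"`, `"PVP"`.
#' @param model an [enhancement_model()].
#' @param n number of draws.
#' @return Numeric vector of `n` HU values.
#' @export
#' @examples
#' m <- enhancement_model(phase_sds = c("NCE" = 0, "E-AP" = 0, "L-AP" = 0, "PVP" = 0))
#' enhancement_value("NCE", m)  # exactly 45.03
enhancement_value <- function(phase, model = enhancement_model(), n = 1) {
  stopifnot(inherits(model, "enhancement_model"))
  if (!is.character(phase) || length(phase) != 1 || !(phase %in% PHASES))
    stop_cect("phantom", "unknown phase label: ", paste(phase, collapse = ","))
  if (model$mode == "piecewise") {
    mu <- model$phase_means[[phase]]
    sd <- model$phase_sds[[phase]]
    if (sd == 0) rep(mu, n) else stats::rnorm(n, mu, sd)
  } else {
    w <- model$phase_windows_s[[phase]]
    t <- stats::runif(n, w[1], w[2])
    gamma_variate_hu(t, model)
  }
}

gamma_variate_hu <- function(t, model) {
  tp <- model$time_to_peak_s; a <- model$shape
  rel <- pmax(t / tp, 0)
  model$baseline_hu + model$amplitude_hu * rel^a * exp(a * (1 - rel))
}

# Deterministic per-lesion shape and density parameters.
lesion_params <- function(spec, l) {
  enh <- spec$enhancement
  with_seed(derive_seed(spec$seed, l), {
    diameter <- stats::runif(1, spec$diameter_range_mm[1], spec$diameter_range_mm[2])
    axial_ratio <- stats::runif(1, 0.85, 1)
    z_ratio <- stats::runif(1, 0.7, 0.95)
    sd_b <- enh$phase_sds * sqrt(enh$between_lesion_frac)
    offs <- stats::rnorm(4, 0, 1) * sd_b
    names(offs) <- PHASES
    list(diameter = diameter, a = diameter / 2,
         b = diameter / 2 * axial_ratio, c_z = diameter / 2 * z_ratio,
         phase_offsets = offs)
  })
}

# Reader-specific base-contour roughness (the "copied" contour edit field).
reader_params <- function(spec, l, r) {
  rd <- spec$readers
  with_seed(derive_seed(spec$seed, l, r + rd$seed_offset), list(
    amps = rd$boundary_roughness * stats::rnorm(3) / sqrt(3),
    phases = stats::runif(3, 0, 2 * pi)))
}

# Timepoint table: per-lesion scan sequence interleaving the phases in
# proportion to their counts (so early timepoints sample every phase).
timepoint_table <- function(spec) {
  counts <- spec$timepoints_per_phase[spec$timepoints_per_phase > 0]
  df <- do.call(rbind, lapply(names(counts), function(p) {
    n <- counts[[p]]
    data.frame(phase = p, pos = (seq_len(n) - 0.5) / n, stringsAsFactors = FALSE)
  }))
  df <- df[order(df$pos, match(df$phase, PHASES)), ]
  df$timepoint_id <- sprintf("T%02d", seq_len(nrow(df)))
  rownames(df) <- NULL
  df[, c("timepoint_id", "phase")]
}

# Per-timepoint draws: density (within-phase component), in-plane motion.
timepoint_draws <- function(spec, l, les, tp) {
  enh <- spec$enhancement
  with_seed(derive_seed(spec$seed, l, 0, tp$idx), {
    if (enh$mode == "piecewise") {
      sd_w <- enh$phase_sds[[tp$phase]] * sqrt(1 - enh$between_lesion_frac)
      dens <- enh$phase_means[[tp$phase]] + les$phase_offsets[[tp$phase]] +
        stats::rnorm(1, 0, sd_w)
    } else {
      dens <- enhancement_value(tp$phase, enh, 1)
    }
    motion <- stats::rnorm(2, 0, spec$motion_sd_mm)
    list(density = dens, motion = c(motion, 0))
  })
}

# Per (reader, timepoint) radial jitter: one draw per timepoint.
reader_scale <- function(spec, l, r, tp_idx, a_mm) {
  rd <- spec$readers
  with_seed(derive_seed(spec$seed, l, r, tp_idx), {
    if (!is.null(rd$radial_jitter_sd_mm))
      (a_mm + stats::rnorm(1, 0, rd$radial_jitter_sd_mm)) / a_mm
    else
      1 + stats::rnorm(1, 0, rd$radial_jitter_cv)
  })
}

#' Generate a complete synthetic study
#'
#' Produces volumes, per-reader masks, phase labels and a ground-truth
#' table for a [phantom_spec()]. Each lesion lives on its own cropped grid
#' (one simulated patient per lesion); each timepoint of a lesion gets a
#' volume with the lesion rendered at its drawn density on a constant liver
#' background plus Gaussian noise, and one mask per reader. All randomness
#' derives from the spec seed via per-(lesion, reader, timepoint) streams,
#' so a fixed spec reproduces the dataset exactly and adding lesions does
#' not perturb earlier ones.
#'
#' For study-sized specs prefer [simulate_measurements()], which measures
#' each timepoint as it is generated instead of materializing every volume.
#'
#' @param spec a [phantom_spec()].
#' @param render_volumes if `FALSE`, skip HU volumes (masks and truth only).
#' @return An object of class `phantom_dataset`: list with `volumes`,
#'   `masks`, `phase_labels` (data frame `timepoint_id`, `phase`),
#'   `truth_diameter` (`lesion_id`, `true_diameter_mm`), `truth_density`
#'   (`lesion_id`, `timepoint_id`, `phase`, `true_density_hu`), and `spec`.
#' @export
generate_study <- function(spec, render_volumes = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  tt <- timepoint_table(spec)
  volumes <- list(); masks <- list()
  labels <- list(); t_diam <- list(); t_dens <- list()
  for (l in seq_len(spec$n_lesions)) {
    lesion_id <- sprintf("L%02d", l)
    les <- lesion_params(spec, l)
    rps <- lapply(seq_len(spec$readers$n_readers), function(r) reader_params(spec, l, r))
    t_diam[[l]] <- data.frame(lesion_id = lesion_id,
                              true_diameter_mm = les$diameter,
                              stringsAsFactors = FALSE)
    for (t in seq_len(nrow(tt))) {
      tp <- list(idx = t, phase = tt$phase[t])
      tpid <- paste0(lesion_id, "_", tt$timepoint_id[t])
      g <- render_timepoint(spec, l, les, rps, tp, tpid, lesion_id,
                            render_volume = render_volumes)
      if (render_volumes) volumes[[tpid]] <- g$volume
      masks <- c(masks, g$masks)
      labels[[tpid]] <- data.frame(timepoint_id = tpid, phase = tp$phase,
                                   stringsAsFactors = FALSE)
      t_dens[[tpid]] <- data.frame(lesion_id = lesion_id, timepoint_id = tpid,
                                   phase = tp$phase, true_density_hu = g$density,
                                   stringsAsFactors = FALSE)
    }
  }
  structure(list(volumes = volumes, masks = masks,
                 phase_labels = do.call(rbind, unname(labels)),
                 truth_diameter = do.call(rbind, t_diam),
                 truth_density = do.call(rbind, unname(t_dens)),
                 spec = spec),
            class = "phantom_dataset")
}

# Build one timepoint of one lesion: the (optional) volume, the per-reader
# masks, and the drawn true density.
render_timepoint <- function(spec, l, les, rps, tp, tpid, lesion_id,
                             render_volume = TRUE) {
  sp <- spec$voxel_spacing_mm
  dims <- lesion_grid_dim(les$diameter, les$c_z, sp,
                          margin_mm = 4 + 3 * spec$motion_sd_mm)
  td <- timepoint_draws(spec, l, les, tp)
  center <- grid_center_mm(dims, sp) + td$motion
  true_mask <- rasterize_lesion(dims, sp, les$a, les$b, les$c_z, center)
  volume <- NULL
  if (render_volume) {
    arr <- with_seed(derive_seed(spec$seed, l, 99, tp$idx), {
      v <- array(spec$liver_background_hu, dims)
      if (spec$image_noise_sd_hu > 0)
        v <- v + stats::rnorm(length(v), 0, spec$image_noise_sd_hu)
      v[true_mask] <- td$density +
        if (spec$image_noise_sd_hu > 0)
          stats::rnorm(sum(true_mask), 0, spec$image_noise_sd_hu) else 0
      pmin(pmax(v, -1024), 3071)
    })
    volume <- image_volume(arr, sp, timepoint_id = tpid, phase = tp$phase)
  }
  mlist <- lapply(seq_len(spec$readers$n_readers), function(r) {
    sc <- reader_scale(spec, l, r, tp$idx, les$a)
    vals <- rasterize_lesion(dims, sp, les$a, les$b, les$c_z, center,
                             scale = sc, rough = rps[[r]])
    if (!any(vals))
      stop_cect("phantom", "reader jitter emptied mask for ", tpid)
    seg_mask(vals, sp, lesion_id = lesion_id, reader_id = sprintf("R%d", r),
             timepoint_id = tpid)
  })
  list(volume = volume, masks = mlist, density = td$density)
}

#' Simulate and measure a study without materializing it
#'
#' Streams through the phantom: each (lesion, timepoint) is generated on its
#' cropped grid, measured with the measurement module, and discarded, so
#' memory stays bounded at study scale (51 lesions x 2 readers x 40
#' timepoints). Numerically identical to [generate_study()] followed by
#' [measure_study()].
#'
#' @param spec a [phantom_spec()].
#' @param measure_density if `FALSE`, skip volume rendering and report `NA`
#'   densities (diameter-only studies run several times faster).
#' @param convention diameter convention, see [max_inplane_diameter()].
#' @return List with `records` (the measurement data frame), and the
#'   `truth_diameter` / `truth_density` tables.
#' @export
simulate_measurements <- function(spec, measure_density = TRUE,
                                  convention = "corner") {
  stopifnot(inherits(spec, "phantom_spec"))
  tt <- timepoint_table(spec)
  recs <- vector("list", spec$n_lesions * nrow(tt) * spec$readers$n_readers)
  t_diam <- vector("list", spec$n_lesions)
  t_dens <- vector("list", spec$n_lesions * nrow(tt))
  i <- 0L
  for (l in seq_len(spec$n_lesions)) {
    lesion_id <- sprintf("L%02d", l)
    les <- lesion_params(spec, l)
    rps <- lapply(seq_len(spec$readers$n_readers), function(r) reader_params(spec, l, r))
    t_diam[[l]] <- data.frame(lesion_id = lesion_id,
                              true_diameter_mm = les$diameter,
                              stringsAsFactors = FALSE)
    for (t in seq_len(nrow(tt))) {
      tp <- list(idx = t, phase = tt$phase[t])
      tpid <- paste0(lesion_id, "_", tt$timepoint_id[t])
      g <- render_timepoint(spec, l, les, rps, tp, tpid, lesion_id,
                            render_volume = measure_density)
      t_dens[[(l - 1L) * nrow(tt) + t]] <-
        data.frame(lesion_id = lesion_id, timepoint_id = tpid, phase = tp$phase,
                   true_density_hu = g$density, stringsAsFactors = FALSE)
      for (m in g$masks) {
        i <- i + 1L
        recs[[i]] <- data.frame(
          lesion_id = lesion_id, reader_id = m$reader_id, timepoint_id = tpid,
          phase = tp$phase,
          diameter_mm = as.numeric(max_inplane_diameter(m, convention)),
          mean_density_hu = if (measure_density) mean_density(g$volume, m)
                            else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  list(records = records,
       truth_diameter = do.call(rbind, t_diam),
       truth_density = do.call(rbind, t_dens))
}

#' Write a phantom dataset to disk
#'
#' Volumes and masks as NIfTI (spacing in the header), truth tables and
#' phase labels as CSV, and the generating spec as YAML.
#'
#' @param dataset a `phantom_dataset` from [generate_study()].
#' @param dir output directory (created if needed).
#' @export
write_phantom <- function(dataset, dir) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  dir.create(file.path(dir, "volumes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (v in dataset$volumes)
    write_nifti(v, file.path(dir, "volumes", paste0(v$timepoint_id, ".nii.gz")))
  for (m in dataset$masks)
    write_nifti(m, file.path(dir, "masks",
                             sprintf("%s_%s.nii.gz", m$timepoint_id, m$reader_id)))
  utils::write.csv(dataset$phase_labels, file.path(dir, "phase_labels.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$truth_diameter, file.path(dir, "truth_diameter.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$truth_density, file.path(dir, "truth_density.csv"),
                   row.names = FALSE)
  write_phantom_spec(dataset$spec, file.path(dir, "phantom_spec.yaml"))
  invisible(dir)
}
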