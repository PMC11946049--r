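# Synthetic phantom: lesion masks, enhancement draws, contour perturbation,
# study generation.

test_that("generated lesion masks hit the requested diameter and are deterministic", {
  m <- generate_lesion_mask(30, c(0.7, 0.7, 5), roughness = 0, seed = 1)
  d <- as.numeric(max_inplane_diameter(m))
  expect_gte(d, 29.3)
  expect_lte(d, 30.7)
  expect_true(sum(m$values) > 0)

  # roughness 0 leaves nothing random: different seeds, identical masks
  m2 <- generate_lesion_mask(30, c(0.7, 0.7, 5), roughness = 0, seed = 2)
  expect_identical(m$values, m2$values)

  # roughness reshapes the boundary reproducibly
  r1 <- generate_lesion_mask(30, c(0.7, 0.7, 5), roughness = 0.05, seed = 3)
  r1b <- generate_lesion_mask(30, c(0.7, 0.7, 5), roughness = 0.05, seed = 3)
  r2 <- generate_lesion_mask(30, c(0.7, 0.7, 5), roughness = 0.05, seed = 4)
  expect_identical(r1$values, r1b$values)
  expect_false(identical(r1$values, r2$values))

  # below the resolvable size
  expect_error(generate_lesion_mask(1, c(1, 1, 5)), "below the resolvable size")
})

test_that("masks stay within one voxel of truth across sizes and spacings", {
  for (d_mm in c(12, 21, 33.5, 47, 66)) {
    m <- generate_lesion_mask(d_mm, c(0.7, 0.7, 5), axial_ratio = 0.9)
    expect_lt(abs(as.numeric(max_inplane_diameter(m)) - d_mm), 0.7,
              label = sprintf("diameter %.1f", d_mm))
  }
  m1 <- generate_lesion_mask(25, c(1, 1, 2.5))
  expect_lt(abs(as.numeric(max_inplane_diameter(m1)) - 25), 1)
})

test_that("enhancement draws follow the configured phase distributions", {
  flat <- enhancement_model(phase_sds = c("NCE" = 0, "E-AP" = 0, "L-AP" = 0, "PVP" = 0))
  expect_identical(enhancement_value("NCE", flat), 45.03)
  expect_identical(enhancement_value("PVP", flat), 88.01)
  expect_identical(enhancement_value("E-AP", flat), 44.25)
  expect_error(enhancement_value("arterial", flat), "unknown phase")

  # Monte-Carlo: sample mean of the L-AP draw within 3 SE of the
  # configured mean under its configured SD
  mdl <- enhancement_model()
  set.seed(123)
  x <- enhancement_value("L-AP", mdl, n = 10000)
  se <- 18.93 / sqrt(10000)
  expect_lt(abs(mean(x) - 77.96), 3 * se)
  expect_lt(abs(sd(x) - 18.93), 3 * 18.93 / sqrt(2 * 9999))

  # L-AP carries the largest default SD (contrast inflow phase)
  expect_identical(names(which.max(mdl$phase_sds)), "L-AP")

  # gamma-variate mode peaks at the configured time-to-peak
  g <- enhancement_model(mode = "gamma")
  ts <- seq(1, 120, by = 1)
  hu <- cectvar:::gamma_variate_hu(ts, g)
  expect_equal(ts[which.max(hu)], g$time_to_peak_s, tolerance = 0.05)
})

test_that("perturb_contour scales contours by one radial draw per call", {
  base <- generate_lesion_mask(40, c(1, 1, 5))

  # zero jitter and roughness: identity
  still <- reader_model(radial_jitter_cv = 0, boundary_roughness = 0)
  expect_identical(perturb_contour(base, still, seed = 10), base)

  # 5% radial jitter induces ~5% diameter CV (Monte-Carlo, 3 SE band)
  md <- reader_model(radial_jitter_cv = 0.05, boundary_roughness = 0)
  d <- vapply(1:250, function(s)
    as.numeric(max_inplane_diameter(perturb_contour(base, md, seed = s))), 0)
  cv <- 100 * sd(d) / mean(d)
  se_cv <- 5 / sqrt(2 * (length(d) - 1))
  expect_lt(abs(cv - 5), 3 * se_cv)

  # degenerate tiny mask: either an explicit error or a nonempty mask,
  # never a silently empty one
  tiny <- array(FALSE, c(7, 7, 1)); tiny[3:5, 4, 1] <- TRUE
  tm <- seg_mask(tiny, c(1, 1, 5))
  wild <- reader_model(radial_jitter_cv = 0.99, boundary_roughness = 0)
  for (s in 1:20) {
    res <- tryCatch(perturb_contour(tm, wild, seed = s), error = function(e) e)
    if (!inherits(res, "error")) expect_gt(sum(res$values), 0)
  }
  expect_error(perturb_contour(seg_mask(array(FALSE, c(3, 3, 1)), c(1, 1, 5)),
                               md, seed = 1), "empty")
})

test_that("study generation is seed-deterministic with stable per-lesion streams", {
  spec <- phantom_spec(n_lesions = 2, timepoints_per_phase = c("NCE" = 1, "L-AP" = 2),
                       seed = 7)
  a <- generate_study(spec)
  b <- generate_study(spec)
  expect_identical(a, b)

  # adding a lesion leaves earlier lesions' data untouched
  spec3 <- phantom_spec(n_lesions = 3, timepoints_per_phase = c("NCE" = 1, "L-AP" = 2),
                        seed = 7)
  rec2 <- sort_records(measure_study(a$volumes, a$masks, a$phase_labels))
  rec3 <- simulate_measurements(spec3)$records
  rec3 <- sort_records(rec3[rec3$lesion_id %in% c("L01", "L02"), ])
  expect_equal(rec2, rec3)
})

test_that("phantom truth is recovered with jitter and noise off", {
  spec <- phantom_spec(
    n_lesions = 6, diameter_range_mm = c(12, 60),
    timepoints_per_phase = c("NCE" = 1, "E-AP" = 1, "L-AP" = 2, "PVP" = 2),
    readers = reader_model(radial_jitter_cv = 0, boundary_roughness = 0),
    image_noise_sd_hu = 0, seed = 5)
  sim <- simulate_measurements(spec)

  expect_true(all(sim$truth_diameter$true_diameter_mm >= 12 &
                    sim$truth_diameter$true_diameter_mm <= 60))

  jd <- merge(sim$records, sim$truth_diameter, by = "lesion_id")
  expect_lt(max(abs(jd$diameter_mm - jd$true_diameter_mm)), 0.7)

  # with exact masks and no noise, measured mean density equals the
  # configured enhancement value exactly
  jdens <- merge(sim$records, sim$truth_density,
                 by = c("lesion_id", "timepoint_id", "phase"))
  expect_equal(jdens$mean_density_hu, jdens$true_density_hu, tolerance = 1e-12)
})

test_that("phantom spec round-trips through YAML", {
  spec <- phantom_spec(n_lesions = 5, seed = 99,
                       readers = reader_model(radial_jitter_sd_mm = 0.8),
                       enhancement = enhancement_model(between_lesion_frac = 0.3))
  f <- tempfile(fileext = ".yaml")
  write_phantom_spec(spec, f)
  back <- read_phantom_spec(f)
  expect_equal(back, spec)
})
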