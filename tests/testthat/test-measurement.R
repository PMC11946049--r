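# Maximal in-plane diameter and mean density extraction.

test_that("corner-convention diameter is exact on hand-checkable masks", {
  # one pixel: the unit square's diagonal
  m <- array(FALSE, c(3, 3, 1)); m[2, 2, 1] <- TRUE
  expect_equal(as.numeric(max_inplane_diameter(seg_mask(m, c(1, 1, 5)))), sqrt(2))

  # two pixels in one row at columns 0 and 3: corners (0,0)-(4,1)
  m2 <- array(FALSE, c(1, 5, 1)); m2[1, c(1, 4), 1] <- TRUE
  expect_equal(as.numeric(max_inplane_diameter(seg_mask(m2, c(1, 1, 5)))), sqrt(17))

  # anisotropic spacing is applied before distances
  expect_equal(as.numeric(max_inplane_diameter(seg_mask(m2, c(2, 0.5, 5)))),
               sqrt(2^2 + (4 * 0.5)^2))

  # center convention: single pixel has zero extent, two pixels their
  # center distance
  expect_equal(as.numeric(max_inplane_diameter(seg_mask(m, c(1, 1, 5)), "center")), 0)
  expect_equal(as.numeric(max_inplane_diameter(seg_mask(m2, c(1, 1, 5)), "center")), 3)

  expect_error(max_inplane_diameter(seg_mask(array(FALSE, c(2, 2, 1)), c(1, 1, 5))),
               "empty")
})

test_that("hull-based diameter equals the brute-force corner-pair oracle", {
  for (s in 1:60) {
    msk <- random_blob_mask(s)
    expect_identical(as.numeric(max_inplane_diameter(msk)),
                     brute_force_feret(msk$values, 1, 1),
                     label = sprintf("seed %d", s))
  }
  # anisotropic in-plane spacing
  for (s in 61:80) {
    msk <- random_blob_mask(s, spacing = c(0.8, 1.3, 5))
    expect_identical(as.numeric(max_inplane_diameter(msk)),
                     brute_force_feret(msk$values, 0.8, 1.3),
                     label = sprintf("aniso seed %d", s))
  }
  # digital disk, anisotropy-free
  d <- disk_mask(32, c(0.8, 0.8, 5))
  expect_identical(as.numeric(max_inplane_diameter(d)),
                   brute_force_feret(d$values, 0.8, 0.8))
})

test_that("diameter is invariant under rotation/translation and monotone under dilation", {
  msk <- random_blob_mask(7)
  d0 <- as.numeric(max_inplane_diameter(msk))

  # 90-degree in-plane rotation
  rot <- msk$values[, rev(seq_len(dim(msk$values)[2])), , drop = FALSE]
  rot <- aperm(rot, c(2, 1, 3))
  expect_equal(as.numeric(max_inplane_diameter(seg_mask(rot, c(1, 1, 5)))), d0)

  # integer translation inside a larger grid
  n <- dim(msk$values)[1]
  big <- array(FALSE, c(n + 10, n + 10, 1))
  big[6:(n + 5), 4:(n + 3), 1] <- msk$values[, , 1]
  expect_equal(as.numeric(max_inplane_diameter(seg_mask(big, c(1, 1, 5)))), d0)

  # isotropic spacing scales the diameter linearly
  expect_equal(as.numeric(max_inplane_diameter(seg_mask(msk$values, c(2.5, 2.5, 5)))),
               2.5 * d0)

  # dilation (superset) can only grow the diameter
  dil <- msk$values
  dil[, , 1] <- msk$values[, , 1] |
    rbind(msk$values[-1, , 1], FALSE) | rbind(FALSE, msk$values[-n, , 1])
  expect_gte(as.numeric(max_inplane_diameter(seg_mask(dil, c(1, 1, 5)))), d0)
})

test_that("mean density matches direct summation and stays within the masked range", {
  vol <- image_volume(array(50, c(4, 4, 2)), c(1, 1, 5))
  msk <- seg_mask(array(c(rep(TRUE, 5), rep(FALSE, 27)), c(4, 4, 2)), c(1, 1, 5))
  expect_equal(mean_density(vol, msk), 50)

  v2 <- array(0, c(2, 2, 1)); v2[1, 1, 1] <- 40; v2[2, 1, 1] <- 60
  m2 <- array(FALSE, c(2, 2, 1)); m2[1:2, 1, 1] <- TRUE
  expect_equal(mean_density(image_volume(v2, c(1, 1, 1)), seg_mask(m2, c(1, 1, 1))), 50)

  set.seed(9)
  vals <- array(rnorm(500, 50, 20), c(10, 10, 5))
  sel <- array(runif(500) < 0.3, c(10, 10, 5))
  sel[1, 1, 1] <- TRUE
  vol3 <- image_volume(vals, c(1, 1, 1)); msk3 <- seg_mask(sel, c(1, 1, 1))
  expect_identical(mean_density(vol3, msk3), sum(vals[sel]) / sum(sel))
  expect_gte(mean_density(vol3, msk3), min(vals[sel]))
  expect_lte(mean_density(vol3, msk3), max(vals[sel]))

  expect_error(mean_density(vol3, seg_mask(array(FALSE, c(10, 10, 5)), c(1, 1, 1))),
               "empty")
  expect_error(mean_density(vol, seg_mask(array(TRUE, c(3, 3, 1)), c(1, 1, 5))),
               "does not match")
})

test_that("measure_study yields one record per (lesion, reader, timepoint) and round-trips CSV", {
  spec <- phantom_spec(n_lesions = 1, timepoints_per_phase = c("NCE" = 1, "L-AP" = 2),
                       seed = 3)
  ds <- generate_study(spec)
  rec <- measure_study(ds$volumes, ds$masks, ds$phase_labels)
  expect_equal(nrow(rec), 1 * 2 * 3)
  expect_setequal(rec$phase, c("NCE", "L-AP"))

  f <- tempfile(fileext = ".csv")
  write_records(rec, f)
  expect_equal(read_records(f), rec)

  # a timepoint without a phase label is reported by id
  bad <- ds$phase_labels[-1, ]
  expect_error(measure_study(ds$volumes, ds$masks, bad),
               ds$phase_labels$timepoint_id[1], fixed = TRUE)
})

test_that("NIfTI round-trip preserves grids and spacing", {
  spec <- phantom_spec(n_lesions = 1, timepoints_per_phase = c("PVP" = 1), seed = 2)
  ds <- generate_study(spec)
  v <- ds$volumes[[1]]; m <- ds$masks[[1]]
  fv <- tempfile(fileext = ".nii.gz"); fm <- tempfile(fileext = ".nii.gz")
  write_nifti(v, fv); write_nifti(m, fm)
  v2 <- read_volume_nifti(fv, timepoint_id = v$timepoint_id, phase = v$phase)
  m2 <- read_mask_nifti(fm, lesion_id = m$lesion_id, reader_id = m$reader_id,
                        timepoint_id = m$timepoint_id)
  expect_equal(v2$spacing_mm, v$spacing_mm, tolerance = 1e-6)
  expect_equal(v2$values, v$values, tolerance = 1e-4, ignore_attr = TRUE)
  expect_identical(m2$values, m$values)
  # header spacing is stored as float32, so allow that precision
  expect_equal(as.numeric(max_inplane_diameter(m2)),
               as.numeric(max_inplane_diameter(m)), tolerance = 1e-5)
})
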