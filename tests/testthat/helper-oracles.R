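# Independent oracles and fixture builders, kept deliberately naive.

# Brute-force maximal Feret diameter: largest pairwise distance over the
# physical corners of ALL foreground pixels of each slice (no hull, no
# boundary pruning), maximised over slices.
brute_force_feret <- function(mask_values, sx, sy, convention = "corner") {
  best <- -Inf
  for (k in seq_len(dim(mask_values)[3])) {
    sl <- mask_values[, , k]
    fg <- which(sl, arr.ind = TRUE)
    if (nrow(fg) == 0L) next
    i <- fg[, 1]; j <- fg[, 2]
    if (convention == "center") {
      pts <- cbind((i - 0.5) * sx, (j - 0.5) * sy)
    } else {
      pts <- cbind(c(i - 1L, i, i - 1L, i) * sx,
                   c(j - 1L, j - 1L, j, j) * sy)
    }
    pts <- unique(pts)
    d <- if (nrow(pts) == 1L) 0 else max(stats::dist(pts))
    if (d > best) best <- d
  }
  best
}

# Random blob masks: union of 1-4 random ellipses on one slice, any size
# from a single pixel up to several thousand.
random_blob_mask <- function(seed, max_px = 60, spacing = c(1, 1, 5)) {
  set.seed(seed)
  n <- sample(4:max_px, 1)
  m <- matrix(FALSE, n, n)
  for (b in seq_len(sample(1:4, 1))) {
    cx <- runif(1, 1, n); cy <- runif(1, 1, n)
    ax <- runif(1, 0.5, n / 2); by <- runif(1, 0.5, n / 2)
    th <- runif(1, 0, pi)
    xs <- matrix(seq_len(n) - 0.5, n, n) - cx
    ys <- matrix(seq_len(n) - 0.5, n, n, byrow = TRUE) - cy
    u <- xs * cos(th) + ys * sin(th)
    v <- -xs * sin(th) + ys * cos(th)
    m <- m | ((u / ax)^2 + (v / by)^2 <= 1)
  }
  if (!any(m)) m[sample(n, 1), sample(n, 1)] <- TRUE
  if (any(spacing[1:2] != 1)) {
    # keep anisotropic cases in the pool
  }
  seg_mask(array(m, c(n, n, 1)), spacing)
}

# A single-slice digital disk mask.
disk_mask <- function(diameter_mm, spacing = c(1, 1, 5)) {
  generate_lesion_mask(diameter_mm, spacing)
}

# Small fully in-memory study for pipeline tests: every stratum populated.
small_test_spec <- function(seed = 42, n_lesions = 8, jitter = 0.03) {
  phantom_spec(
    n_lesions = n_lesions,
    diameter_range_mm = c(11, 68),
    timepoints_per_phase = c("NCE" = 2, "E-AP" = 2, "L-AP" = 3, "PVP" = 3),
    readers = reader_model(radial_jitter_cv = jitter),
    seed = seed)
}

sort_records <- function(d) {
  d <- d[order(d$lesion_id, d$reader_id, d$timepoint_id), ]
  rownames(d) <- NULL
  d
}
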