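# Repeatability statistics: percent differences, CVs, CIs, strata,
# waterfall maxima, correlations.

test_that("percent difference follows the growth-positive convention", {
  expect_equal(percent_difference(100, 110), 10)
  expect_equal(percent_difference(50, 40), -20)
  expect_equal(percent_difference(37.2, 37.2), 0)
  expect_error(percent_difference(0, 10), "zero baseline")

  # role swap flips the sign around the ratio: the product is never positive
  set.seed(4)
  a <- runif(200, 5, 80); b <- runif(200, 5, 80)
  expect_true(all(percent_difference(a, b) * percent_difference(b, a) <= 0))
  expect_true(all((percent_difference(a, b) == 0) == (a == b)))
})

test_that("pairing modes produce the expected pairs deterministically", {
  vals <- data.frame(lesion_id = "L01", timepoint_id = c("T01", "T02", "T03"),
                     value = c(30, 33, 27))
  fx <- pair_changes(vals, "fixed")
  expect_equal(nrow(fx), 2)
  expect_true(all(fx$baseline_tp == "T01"))
  expect_equal(fx$percent_difference, c(10, -10))
  expect_equal(fx$absolute_difference, c(3, -3))

  rd <- pair_changes(vals, "random", seed = 11)
  expect_equal(nrow(rd), choose(3, 2))
  expect_identical(rd, pair_changes(vals, "random", seed = 11))
  expect_false(identical(rd$baseline_tp,
                         pair_changes(vals, "random", seed = 12)$baseline_tp))

  # single-timepoint lesions are skipped with a warning naming them
  one <- rbind(vals, data.frame(lesion_id = "L02", timepoint_id = "T01", value = 20))
  expect_warning(out <- pair_changes(one, "fixed"), "L02")
  expect_equal(unique(out$lesion_id), "L01")
})

test_that("per-lesion CV matches hand computation and is scale invariant", {
  expect_equal(lesion_cv(c(8, 12)), 100 * 2 * sqrt(2) / 10)
  expect_equal(lesion_cv(c(5, 5, 5)), 0)
  x <- c(28, 31, 30, 33)
  expect_equal(lesion_cv(3.7 * x), lesion_cv(x))
  expect_error(lesion_cv(7), "at least 2")
  expect_error(lesion_cv(c(-2, 2)), "non-positive mean")
})

test_that("pooled CV confidence interval uses the normal approximation", {
  p <- pooled_cv_ci(c(4, 6))
  expect_equal(p$cv, 5)
  expect_equal(p$ci_low, 5 - 1.96, tolerance = 1e-12)
  expect_equal(p$ci_high, 5 + 1.96, tolerance = 1e-12)

  z <- pooled_cv_ci(rep(5.2, 10))
  expect_equal(c(z$ci_low, z$ci_high), c(5.2, 5.2))

  # CI half-width shrinks as 1/sqrt(n) under replication
  cvs <- c(3, 4, 5, 6, 7)
  w1 <- with(pooled_cv_ci(cvs), ci_high - ci_low)
  w4 <- with(pooled_cv_ci(rep(cvs, 4)), ci_high - ci_low)
  w16 <- with(pooled_cv_ci(rep(cvs, 16)), ci_high - ci_low)
  expect_lt(w4, w1 / 1.8)
  expect_lt(w16, w4 / 1.8)
})

test_that("phase-mean confidence intervals reproduce the published intervals", {
  ref <- reference_density_by_phase()
  expected <- list("NCE" = c(42.4, 47.7), "E-AP" = c(41.3, 47.2),
                   "L-AP" = c(72.8, 83.2), "PVP" = c(83.4, 92.6))
  for (p in names(expected)) {
    row <- ref[ref$phase == p, ]
    expect_equal(phase_mean_ci(row$mean_hu, row$sd_hu, 51), expected[[p]],
                 label = p)
  }
  expect_equal(phase_mean_ci(10, 0, 5), c(10, 10))
})

test_that("limits of agreement and half-range percent are consistent", {
  expect_equal(limits_of_agreement(10, 2), c(6.08, 13.92))
  expect_equal(limits_of_agreement(7, 0, k = 3), c(7, 7))
  expect_equal(limits_of_agreement(77.96, 18.93), c(40.8572, 115.0628),
               tolerance = 1e-10)
  expect_equal(half_range_percent(77.96, 114.4), 47L)
  expect_equal(half_range_percent(76.41, 118.0), 54L)
  expect_equal(half_range_percent(50, 50), 0L)
})

test_that("waterfall maxima keep the signed value of maximal magnitude", {
  ch <- data.frame(
    lesion_id = c("A", "A", "A", "B", "B", "C"),
    percent_difference = c(-5, 12, 3, -15, 12, 0))
  w <- max_change_waterfall(ch)
  expect_equal(w$max_percent_change[w$lesion_id == "A"], 12)
  expect_equal(w$max_percent_change[w$lesion_id == "B"], -15)
  expect_equal(w$max_percent_change[w$lesion_id == "C"], 0)
  # sorted descending for plotting
  expect_true(!is.unsorted(rev(w$max_percent_change)))
})

test_that("size strata use half-open 1/2/3/5/7 cm bins", {
  s <- stratify_by_size(c(1.5, 2.5, 4.0, 5.4))
  expect_equal(s$n, c(1, 1, 1, 1))
  expect_equal(s$mean_size_cm, c(1.5, 2.5, 4.0, 5.4))

  # boundary 2.0 cm belongs to the 2-3 stratum; 7.0 closes the last bin
  b <- stratify_by_size(c(2.0, 7.0))
  expect_equal(b$n, c(0, 1, 0, 1))

  expect_warning(o <- stratify_by_size(c(0.8, 7.6)), "nearest stratum")
  expect_equal(o$n, c(1, 0, 0, 1))

  # pooled CVs per stratum
  s2 <- stratify_by_size(c(1.2, 1.8, 5.5), cvs = c(4, 6, 7))
  expect_equal(s2$cv[1], 5)
  expect_equal(s2$cv[4], 7)
  expect_true(is.na(s2$cv[2]))
})

test_that("size-change correlation matches the textbook formula", {
  x <- c(1.3, 2.1, 2.8, 3.9, 5.2, 6.0)
  y <- c(21, 14, 11, 8, 6, 5)
  out <- size_change_correlation(x, y)
  # independent oracle: covariance formula + t transform
  r0 <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t0 <- r0 * sqrt((6 - 2) / (1 - r0^2))
  p0 <- 2 * pt(-abs(t0), df = 4)
  expect_equal(out$r, r0, tolerance = 1e-12)
  expect_equal(out$p, p0, tolerance = 1e-12)

  expect_equal(size_change_correlation(1:5, 2 * (1:5) + 3)$r, 1)
  expect_equal(size_change_correlation(1:5, -(1:5))$r, -1)
  expect_error(size_change_correlation(rep(2, 5), 1:5), "zero variance")
})

test_that("fraction_within counts magnitudes against the threshold", {
  expect_equal(fraction_within(c(-5, 3, 12), 10), 2 / 3)
  expect_equal(fraction_within(c(-5, 3, 12), Inf), 1)
  expect_equal(fraction_within(c(-5, 3, 12), 1), 0)
  expect_equal(fraction_within(c(-10, 10), 10), 1)  # closed at the boundary
  expect_error(fraction_within(numeric(), 10), "no changes")
})

test_that("pooled CV of identically variable lesions concentrates on the common value", {
  # lesions with the same per-lesion CV: the pooled estimate is that CV
  # and the CI tightens as lesions are added
  set.seed(21)
  mk <- function(n_lesions) {
    cvs <- replicate(n_lesions, {
      x <- rnorm(40, 100, 5)   # population CV 5%
      lesion_cv(x)
    })
    pooled_cv_ci(cvs)
  }
  p <- mk(120)
  expect_lt(abs(p$cv - 5), 0.3)
  expect_lt(p$ci_high - p$ci_low, 1)
})
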