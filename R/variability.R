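# Core repeatability statistics: percent differences, coefficients of
# variance, pooled confidence intervals, limits of agreement, waterfall
# maxima, size strata and size-variability correlation.

#' Percent difference between a baseline and a repeat measurement
#'
#' Growth-positive convention: `100 * (repeat - baseline) / baseline`, so a
#' +20% value is an increase (progression side) and -30% a decrease
#' (response side), matching how waterfall plots and RECIST thresholds are
#' read.
#'
#' @param baseline,repeat_ numeric; baseline must be nonzero.
#' @return Percent difference (vectorized).
#' @export
#' @examples
#' percent_difference(100, 110)  # +10
#' percent_difference(50, 40)    # -20
percent_difference <- function(baseline, repeat_) {
  if (any(baseline == 0)) stop_cect("variability", "zero baseline value")
  100 * (repeat_ - baseline) / baseline
}

#' Pair repeat measurements within lesions
#'
#' Builds baseline/repeat pairs per lesion (optionally within phase) from a
#' table of per-timepoint values. Two pairing modes:
#' * `"fixed"` — the baseline is the first (initial) timepoint; every later
#'   timepoint is compared to it (`n - 1` pairs per lesion).
#' * `"random"` — all `C(n, 2)` unordered pairs, with the baseline role
#'   assigned by a seeded coin flip within each pair.
#'
#' Lesions with a single timepoint are skipped with a warning.
#'
#' @param values data frame with columns `lesion_id`, `timepoint_id`,
#'   `value`, and optionally `phase`.
#' @param mode `"fixed"` or `"random"`.
#' @param seed integer seed for the random baseline assignment.
#' @param by_phase if `TRUE`, pair within each (lesion, phase) block and
#'   report the phase; otherwise pair across all timepoints (`phase "all"`).
#' @return Data frame of paired changes: `lesion_id`, `phase`,
#'   `baseline_tp`, `repeat_tp`, `baseline_value`, `repeat_value`,
#'   `absolute_difference`, `percent_difference`.
#' @export
pair_changes <- function(values, mode = c("fixed", "random"), seed = 1,
                         by_phase = FALSE) {
  mode <- match.arg(mode)
  stopifnot(all(c("lesion_id", "timepoint_id", "value") %in% names(values)))
  if (by_phase && !("phase" %in% names(values)))
    stop_cect("variability", "by_phase pairing needs a phase column")
  values <- values[order(values$lesion_id, values$timepoint_id), ]
  key <- if (by_phase) interaction(values$lesion_id, values$phase, drop = TRUE)
         else values$lesion_id
  groups <- split(values, key)
  skipped <- character()
  out <- with_seed(seed, lapply(groups, function(g) {
    n <- nrow(g)
    if (n < 2) {
      skipped <<- c(skipped, sprintf("%s (%s)", g$lesion_id[1],
                                     if (by_phase) g$phase[1] else "all"))
      return(NULL)
    }
    ph <- if (by_phase) g$phase[1] else "all"
    if (mode == "fixed") {
      i <- rep(1L, n - 1L); j <- 2:n
    } else {
      cmb <- utils::combn(n, 2)
      flip <- stats::runif(ncol(cmb)) < 0.5
      i <- ifelse(flip, cmb[2, ], cmb[1, ])
      j <- ifelse(flip, cmb[1, ], cmb[2, ])
    }
    data.frame(lesion_id = g$lesion_id[1], phase = ph,
               baseline_tp = g$timepoint_id[i], repeat_tp = g$timepoint_id[j],
               baseline_value = g$value[i], repeat_value = g$value[j],
               absolute_difference = g$value[j] - g$value[i],
               percent_difference = percent_difference(g$value[i], g$value[j]),
               stringsAsFactors = FALSE)
  }))
  if (length(skipped))
    warning("skipped single-timepoint lesion groups: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(lesion_id = character(), phase = character(),
                      baseline_tp = character(), repeat_tp = character(),
                      baseline_value = numeric(), repeat_value = numeric(),
                      absolute_difference = numeric(),
                      percent_difference = numeric())
  rownames(res) <- NULL
  res
}

#' Coefficient of variance of a series of repeat measurements
#'
#' `100 * sample SD / mean` (n - 1 denominator), in percent.
#'
#' @param values numeric vector, `n >= 2`, positive mean.
#' @return CV in percent.
#' @export
#' @examples
#' lesion_cv(c(8, 12))  # 100 * 2*sqrt(2) / 10
lesion_cv <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop_cect("variability", "CV needs at least 2 values")
  m <- mean(values)
  if (m <= 0) stop_cect("variability", "CV undefined for non-positive mean")
  100 * stats::sd(values) / m
}

#' Pooled CV across lesions with a 95% confidence interval
#'
#' The cohort-level variability is the mean of the per-lesion CVs; its 95%
#' CI is the normal approximation `mean +/- 1.96 * SD / sqrt(n)` over
#' lesions.
#'
#' @param per_lesion_cvs numeric vector of per-lesion CVs (percent).
#' @return List with `cv`, `ci_low`, `ci_high`, `n`.
#' @export
pooled_cv_ci <- function(per_lesion_cvs) {
  x <- as.numeric(per_lesion_cvs)
  n <- length(x)
  if (n < 2) stop_cect("variability", "pooled CV needs at least 2 lesions")
  m <- mean(x)
  half <- 1.96 * stats::sd(x) / sqrt(n)
  list(cv = m, ci_low = m - half, ci_high = m + half, n = n)
}

#' 95% confidence interval for a phase mean
#'
#' `mean +/- 1.96 * sd / sqrt(n)`, with the bounds rounded half-up to one
#' decimal for report display (set `digits = NULL` for unrounded bounds).
#'
#' @param mean,sd,n summary statistics of the per-lesion phase means.
#' @param digits decimals for display rounding, or `NULL`.
#' @return `c(low, high)`.
#' @export
#' @examples
#' phase_mean_ci(45.03, 9.73, 51)  # c(42.4, 47.7)
phase_mean_ci <- function(mean, sd, n, digits = 1) {
  stopifnot(n >= 2, sd >= 0)
  half <- 1.96 * sd / sqrt(n)
  out <- c(mean - half, mean + half)
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Limits of agreement
#'
#' The `mean +/- k * sd` interval (default `k = 1.96`) describing the
#' plausible spread of repeat measurements.
#'
#' @param mean,sd summary statistics; `sd >= 0`.
#' @param k multiplier.
#' @return `c(low, high)`.
#' @export
limits_of_agreement <- function(mean, sd, k = 1.96) {
  stopifnot(sd >= 0)
  c(mean - k * sd, mean + k * sd)
}

#' Half-range as a percent of the mean
#'
#' Expresses the upper limit of a variability range as a symmetric
#' percent change (`+/-x%`): `100 * (upper - mean) / mean`, rounded half-up
#' to an integer.
#'
#' @param mean central value (> 0).
#' @param upper upper range limit (`>= mean`).
#' @return Integer percent.
#' @export
#' @examples
#' half_range_percent(77.96, 114.4)  # 47
half_range_percent <- function(mean, upper) {
  stopifnot(upper >= mean, mean > 0)
  as.integer(round_half_up(100 * (upper - mean) / mean))
}

#' Per-lesion maximum change for waterfall plotting
#'
#' For each lesion, the percent change of maximal magnitude (the signed
#' value is kept), sorted descending for plotting. With tied magnitudes the
#' positive value is reported.
#'
#' @param changes data frame from [pair_changes()] (needs `lesion_id`,
#'   `percent_difference`).
#' @return Data frame `lesion_id`, `max_percent_change`, sorted descending.
#' @export
max_change_waterfall <- function(changes) {
  stopifnot(all(c("lesion_id", "percent_difference") %in% names(changes)))
  sp <- split(changes$percent_difference, changes$lesion_id)
  mx <- vapply(sp, function(v) {
    cand <- v[abs(v) == max(abs(v))]
    max(cand)
  }, 0)
  out <- data.frame(lesion_id = names(mx), max_percent_change = unname(mx),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$max_percent_change), ]
  rownames(out) <- NULL
  out
}

SIZE_BREAKS_CM <- c(1, 2, 3, 5, 7)
SIZE_LABELS <- c("1-2", "2-3", "3-5", "5-7")

#' Stratify lesions by average size
#'
#' Bins per-lesion average diameters (cm) into the standard strata
#' `[1,2) [2,3) [3,5) [5,7]` (half-open on the left, so a 2.0 cm lesion is
#' in the 2-3 stratum). Diameters outside 1-7 cm are assigned to the
#' nearest bin with a warning. Per stratum, reports the lesion count, mean
#' and SD of size, and (when per-lesion CVs are supplied) the pooled CV
#' with its 95% CI.
#'
#' @param sizes_cm numeric vector of per-lesion average diameters, cm.
#' @param cvs optional per-lesion CVs (percent), same order.
#' @return Data frame with one row per stratum: `stratum`, `n`,
#'   `mean_size_cm`, `sd_size_cm`, `cv`, `cv_ci_low`, `cv_ci_high`.
#' @export
stratify_by_size <- function(sizes_cm, cvs = NULL) {
  stopifnot(all(sizes_cm > 0))
  out_of_range <- sizes_cm < SIZE_BREAKS_CM[1] | sizes_cm > SIZE_BREAKS_CM[5]
  if (any(out_of_range))
    warning(sum(out_of_range),
            " lesion(s) outside 1-7 cm assigned to the nearest stratum",
            call. = FALSE)
  idx <- findInterval(sizes_cm, SIZE_BREAKS_CM, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), 4L)
  rows <- lapply(seq_along(SIZE_LABELS), function(s) {
    in_s <- idx == s
    n <- sum(in_s)
    cv <- ci_lo <- ci_hi <- NA_real_
    if (!is.null(cvs) && n >= 2) {
      p <- pooled_cv_ci(cvs[in_s])
      cv <- p$cv; ci_lo <- p$ci_low; ci_hi <- p$ci_high
    } else if (!is.null(cvs) && n == 1) {
      cv <- cvs[in_s]
    }
    data.frame(stratum = SIZE_LABELS[s], n = n,
               mean_size_cm = if (n) mean(sizes_cm[in_s]) else NA_real_,
               sd_size_cm = if (n >= 2) stats::sd(sizes_cm[in_s]) else NA_real_,
               cv = cv, cv_ci_low = ci_lo, cv_ci_high = ci_hi,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlation between lesion size and measurement change
#'
#' Pearson correlation with a two-sided p-value from the t distribution on
#' `n - 2` degrees of freedom, as implemented in [stats::cor.test()].
#'
#' @param sizes per-lesion sizes.
#' @param changes per-lesion change magnitudes (same length).
#' @return List with `r`, `p`, `n`.
#' @export
size_change_correlation <- function(sizes, changes) {
  stopifnot(length(sizes) == length(changes), length(sizes) >= 3)
  if (stats::sd(sizes) == 0 || stats::sd(changes) == 0)
    stop_cect("variability", "zero variance: correlation undefined")
  ct <- stats::cor.test(sizes, changes, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(sizes))
}

#' Fraction of changes within a symmetric threshold
#'
#' @param changes numeric vector of percent changes.
#' @param threshold positive percent threshold.
#' @return Proportion with `|change| <= threshold`.
#' @export
#' @examples
#' fraction_within(c(-5, 3, 12), 10)  # 2/3
fraction_within <- function(changes, threshold) {
  stopifnot(threshold > 0)
  if (!length(changes)) stop_cect("variability", "no changes supplied")
  mean(abs(changes) <= threshold)
}

#' Relative SD of summed diameters for k lesions
#'
#' Monte-Carlo illustration of the sum-of-target-lesions property: when `k`
#' independent lesions each carry the same absolute measurement SD, the SD
#' of the summed diameter grows as `sqrt(k)` while the sum grows as `k`, so
#' the *relative* SD of the sum falls as `1 / sqrt(k)`.
#'
#' @param k_values integer vector of lesion counts.
#' @param diameter_mm common true diameter per lesion.
#' @param sd_mm absolute per-lesion measurement SD, mm.
#' @param n_sim Monte-Carlo replicates per `k`.
#' @param seed integer seed.
#' @return Data frame `k`, `relative_sd`, and `expected` (= `rsd(k=1)/sqrt(k)`
#'   scaling reference computed from the k = 1 entry when present).
#' @export
summed_diameter_rsd <- function(k_values, diameter_mm = 30, sd_mm = 1.5,
                                n_sim = 20000, seed = 1) {
  stopifnot(all(k_values >= 1))
  rsd <- with_seed(seed, vapply(k_values, function(k) {
    sums <- colSums(matrix(stats::rnorm(k * n_sim, diameter_mm, sd_mm), nrow = k))
    stats::sd(sums) / mean(sums)
  }, 0))
  ref <- if (1 %in% k_values) rsd[match(1, k_values)] else sd_mm / diameter_mm
  data.frame(k = k_values, relative_sd = rsd, expected = ref / sqrt(k_values))
}
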