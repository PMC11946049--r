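# Study-level analysis: turns a measurement table into the variability
# report (cohort summaries, per-phase blocks, strata, waterfall values,
# correlations) and response-criteria calls.

reader_average <- function(records, value_col) {
  agg <- stats::aggregate(records[[value_col]],
                          by = list(lesion_id = records$lesion_id,
                                    timepoint_id = records$timepoint_id,
                                    phase = records$phase),
                          FUN = mean)
  names(agg)[4] <- "value"
  agg[order(agg$lesion_id, agg$timepoint_id), ]
}

per_lesion_cvs <- function(records, value_col, phase = NULL) {
  r <- if (is.null(phase)) records else records[records$phase == phase, ]
  sp <- split(r[[value_col]], r$lesion_id)
  sp <- sp[vapply(sp, length, 0L) >= 2]
  vapply(sp, lesion_cv, 0)
}

cohort_block <- function(records, value_col, phase = NULL) {
  r <- if (is.null(phase)) records else records[records$phase == phase, ]
  lesion_means <- vapply(split(r[[value_col]], r$lesion_id), mean, 0)
  cvs <- per_lesion_cvs(records, value_col, phase)
  p <- pooled_cv_ci(cvs)
  list(phase = phase %||% "all", n_lesions = length(lesion_means),
       mean = mean(lesion_means), sd = stats::sd(lesion_means),
       cv = p$cv, cv_ci_low = p$ci_low, cv_ci_high = p$ci_high)
}

#' Analyze the variability of a measured study
#'
#' The statistical core of the package. From a measurement table (one row
#' per lesion, reader, timepoint), computes:
#'
#' * paired percent/absolute changes of the reader-averaged diameter and
#'   density (overall and within phase), under fixed-baseline or
#'   random-baseline pairing;
#' * per-lesion CVs (computed on the pooled set of both readers'
#'   measurements) and pooled cohort CVs with 95% CIs, overall and per
#'   phase, for diameter and density;
#' * per-phase density summaries: mean over lesions, SD, 95% CI of the
#'   mean, limits of agreement and the half-range percent;
#' * per-lesion maximum changes (waterfall values), overall and per phase;
#' * fractions of diameter changes within +/-5/10/20%;
#' * size strata over the per-lesion average diameter, and the Pearson
#'   correlation between lesion size and change magnitude (absolute and
#'   relative).
#'
#' @param records measurement data frame (see [measure_study()]).
#' @param pairing `"fixed"` (baseline = initial timepoint) or `"random"`
#'   (all pairs, seeded random baseline role).
#' @param seed integer seed for random pairing.
#' @return An object of class `cect_report` (a list; see Details).
#' @export
analyze_study <- function(records, pairing = c("fixed", "random"), seed = 1) {
  pairing <- match.arg(pairing)
  needed <- c("lesion_id", "reader_id", "timepoint_id", "phase",
              "diameter_mm", "mean_density_hu")
  if (!all(needed %in% names(records)))
    stop_cect("analyze", "records must have columns: ",
              paste(needed, collapse = ", "))
  bad <- setdiff(unique(records$phase), PHASES)
  if (length(bad))
    stop_cect("analyze", "unknown phase labels: ", paste(bad, collapse = ", "))
  has_density <- !all(is.na(records$mean_density_hu))

  d_avg <- reader_average(records, "diameter_mm")
  d_changes <- pair_changes(d_avg, pairing, seed, by_phase = FALSE)
  d_changes_phase <- pair_changes(d_avg, pairing, seed, by_phase = TRUE)

  diameter <- list(
    overall = cohort_block(records, "diameter_mm"),
    by_phase = do.call(rbind, lapply(intersect(PHASES, unique(records$phase)),
      function(p) as.data.frame(cohort_block(records, "diameter_mm", p)))),
    fraction_within = c(
      "5" = fraction_within(d_changes$percent_difference, 5),
      "10" = fraction_within(d_changes$percent_difference, 10),
      "20" = fraction_within(d_changes$percent_difference, 20)),
    changes = d_changes,
    changes_by_phase = d_changes_phase,
    waterfall = max_change_waterfall(d_changes),
    waterfall_by_phase = do.call(rbind, lapply(
      split(d_changes_phase, d_changes_phase$phase), function(ch) {
        w <- max_change_waterfall(ch); w$phase <- ch$phase[1]; w
      }))
  )
  rownames(diameter$waterfall_by_phase) <- NULL

  density <- NULL
  if (has_density) {
    dens_avg <- reader_average(records, "mean_density_hu")
    dens_changes <- pair_changes(dens_avg, pairing, seed, by_phase = FALSE)
    dens_changes_phase <- pair_changes(dens_avg, pairing, seed, by_phase = TRUE)
    # per-lesion mean density within each phase, summarized across lesions
    phase_rows <- lapply(intersect(PHASES, unique(records$phase)), function(p) {
      r <- records[records$phase == p, ]
      lm <- vapply(split(r$mean_density_hu, r$lesion_id), mean, 0)
      m <- mean(lm); s <- stats::sd(lm); n <- length(lm)
      ci <- phase_mean_ci(m, s, n)
      loa <- limits_of_agreement(m, s)
      cvs <- per_lesion_cvs(records, "mean_density_hu", p)
      pc <- pooled_cv_ci(cvs)
      data.frame(phase = p, n_lesions = n, mean_hu = m, sd_hu = s,
                 ci_low = ci[1], ci_high = ci[2],
                 loa_low = loa[1], loa_high = loa[2],
                 half_range_pct = half_range_percent(m, loa[2]),
                 cv = pc$cv, cv_ci_low = pc$ci_low, cv_ci_high = pc$ci_high,
                 stringsAsFactors = FALSE)
    })
    by_phase <- do.call(rbind, phase_rows)
    density <- list(
      overall = cohort_block(records, "mean_density_hu"),
      by_phase = by_phase,
      most_variable_phase = by_phase$phase[which.max(by_phase$cv)],
      changes = dens_changes,
      changes_by_phase = dens_changes_phase)
  }

  # size stratification and size-variability correlation on per-lesion
  # average diameter (cm) across all phases
  lesion_size_cm <- vapply(split(records$diameter_mm, records$lesion_id),
                           mean, 0) / 10
  d_cvs <- per_lesion_cvs(records, "diameter_mm")
  common <- intersect(names(lesion_size_cm), names(d_cvs))
  strata <- stratify_by_size(lesion_size_cm[common], d_cvs[common])
  mean_abs <- vapply(split(abs(d_changes$absolute_difference), d_changes$lesion_id),
                     mean, 0)
  mean_rel <- vapply(split(abs(d_changes$percent_difference), d_changes$lesion_id),
                     mean, 0)
  sz <- lesion_size_cm[names(mean_rel)]
  correlation <- list(
    absolute = tryCatch(size_change_correlation(sz, mean_abs),
                        error = function(e) NULL),
    relative = tryCatch(size_change_correlation(sz, mean_rel),
                        error = function(e) NULL))

  structure(list(n_lesions = length(unique(records$lesion_id)),
                 n_records = nrow(records),
                 pairing = pairing, seed = seed,
                 diameter = diameter, density = density,
                 strata = strata, correlation = correlation),
            class = "cect_report")
}

#' @export
print.cect_report <- function(x, ...) {
  d <- x$diameter$overall
  cat(sprintf("Variability report: %d lesions, %d records (pairing: %s)\n",
              x$n_lesions, x$n_records, x$pairing))
  cat(sprintf("  diameter: mean %.1f +/- %.2f mm, CV %.2f%% (95%% CI %.2f-%.2f%%)\n",
              d$mean, d$sd, d$cv, d$cv_ci_low, d$cv_ci_high))
  cat(sprintf("  diameter changes within +/-10%%: %.0f%%\n",
              100 * x$diameter$fraction_within[["10"]]))
  if (!is.null(x$density)) {
    dd <- x$density$overall
    cat(sprintf("  density: CV %.2f%% (95%% CI %.2f-%.2f%%); most variable phase: %s\n",
                dd$cv, dd$cv_ci_low, dd$cv_ci_high, x$density$most_variable_phase))
  }
  if (!is.null(x$correlation$relative))
    cat(sprintf("  size vs relative change: r = %.3f (p = %.3f)\n",
                x$correlation$relative$r, x$correlation$relative$p))
  invisible(x)
}

#' Classify a report's per-lesion maximum changes
#'
#' Applies the three response criteria to each lesion's maximal-magnitude
#' diameter change within each phase. The matching density change (same
#' baseline/repeat pair) feeds the modified Choi call; the mRECIST
#' enhancement gate marks a lesion enhancing when its mean arterial-phase
#' (L-AP) density exceeds its NCE density by at least `enhance_delta_hu`
#' (lesions lacking either phase are treated as enhancing).
#'
#' @param report a `cect_report` from [analyze_study()].
#' @param records the measurement table the report was built from.
#' @param thresholds a [criteria_thresholds()].
#' @param enhance_delta_hu HU increase (L-AP over NCE) defining "enhancing".
#' @return List with `calls` (one row per lesion x phase x criteria) and
#'   `crossings` (per-phase PD/PR counts from [count_crossings()]).
#' @export
classify_study <- function(report, records, thresholds = criteria_thresholds(),
                           enhance_delta_hu = 10) {
  stopifnot(inherits(report, "cect_report"))
  ch <- report$diameter$changes_by_phase
  if (!nrow(ch)) stop_cect("classify", "report has no paired changes")
  # maximal-magnitude diameter change per (lesion, phase), keeping the pair
  key <- interaction(ch$lesion_id, ch$phase, drop = TRUE)
  top <- do.call(rbind, lapply(split(ch, key), function(g) {
    g[order(-abs(g$percent_difference), -g$percent_difference), ][1, ]
  }))
  dens_ch <- if (!is.null(report$density)) report$density$changes_by_phase else NULL
  if (!is.null(dens_ch)) {
    m <- merge(top, dens_ch[, c("lesion_id", "phase", "baseline_tp", "repeat_tp",
                                "percent_difference")],
               by = c("lesion_id", "phase", "baseline_tp", "repeat_tp"),
               all.x = TRUE, suffixes = c("", "_density"))
  } else {
    m <- top; m$percent_difference_density <- NA_real_
  }
  enhancing <- rep(TRUE, nrow(m))
  if (!is.null(report$density)) {
    bp <- report$density$by_phase
    lap <- records[records$phase == "L-AP", ]
    nce <- records[records$phase == "NCE", ]
    if (nrow(lap) && nrow(nce)) {
      lap_m <- vapply(split(lap$mean_density_hu, lap$lesion_id), mean, 0)
      nce_m <- vapply(split(nce$mean_density_hu, nce$lesion_id), mean, 0)
      common <- intersect(names(lap_m), names(nce_m))
      enh <- stats::setNames(lap_m[common] - nce_m[common] >= enhance_delta_hu,
                             common)
      hit <- m$lesion_id %in% names(enh)
      enhancing[hit] <- enh[m$lesion_id[hit]]
    }
  }
  calls <- data.frame(
    lesion_id = m$lesion_id, phase = m$phase,
    diameter_change = m$percent_difference,
    absolute_change_mm = m$absolute_difference,
    density_change = m$percent_difference_density,
    enhancing = enhancing,
    recist11 = classify_recist11(m$percent_difference, m$absolute_difference,
                                 thresholds),
    mrecist = as.character(classify_mrecist(m$percent_difference, enhancing,
                                            thresholds)),
    mchoi = ifelse(is.na(m$percent_difference_density), NA_character_,
                   as.character(classify_mchoi(
                     m$percent_difference,
                     ifelse(is.na(m$percent_difference_density), 0,
                            m$percent_difference_density),
                     thresholds))),
    stringsAsFactors = FALSE)
  calls <- calls[order(calls$lesion_id, match(calls$phase, PHASES)), ]
  rownames(calls) <- NULL
  wf <- report$diameter$waterfall_by_phase
  list(calls = calls, crossings = count_crossings(wf, thresholds))
}

#' Write a report bundle to disk
#'
#' Emits `report.json` (the full report, bare numbers at full precision)
#' plus CSVs for the per-phase blocks, strata, waterfall values and paired
#' changes.
#'
#' @param report a `cect_report`.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cect_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  utils::write.csv(report$diameter$by_phase,
                   file.path(dir, "diameter_by_phase.csv"), row.names = FALSE)
  if (!is.null(report$density))
    utils::write.csv(report$density$by_phase,
                     file.path(dir, "density_by_phase.csv"), row.names = FALSE)
  utils::write.csv(report$strata, file.path(dir, "size_strata.csv"),
                   row.names = FALSE)
  utils::write.csv(report$diameter$waterfall_by_phase,
                   file.path(dir, "waterfall.csv"), row.names = FALSE)
  utils::write.csv(report$diameter$changes, file.path(dir, "changes.csv"),
                   row.names = FALSE)
  invisible(dir)
}
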