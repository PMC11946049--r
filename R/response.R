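# Tumor response classification: RECIST 1.1, mRECIST, modified Choi.

#' Response-criteria thresholds
#'
#' Percent and absolute thresholds for the three rule sets. Boundary
#' inclusivity follows the wording of each criterion: RECIST-style
#' thresholds are "at least"/"or more" (closed, `>=` / `<=`), while the
#' modified Choi conditions are "more than" (strict, `<` on the reduction
#' side).
#'
#' @param pd_diameter_increase percent increase qualifying as progressive
#'   disease (default +20).
#' @param pr_diameter_decrease percent decrease qualifying as partial
#'   response (default -30).
#' @param pd_min_absolute_mm minimum absolute increase (mm) for RECIST 1.1
#'   progression (default 5).
#' @param mchoi_density_decrease,mchoi_diameter_decrease modified-Choi
#'   partial-response conditions (defaults -15 and -10, strict).
#' @return An object of class `criteria_thresholds`.
#' @export
criteria_thresholds <- function(pd_diameter_increase = 20,
                                pr_diameter_decrease = -30,
                                pd_min_absolute_mm = 5,
                                mchoi_density_decrease = -15,
                                mchoi_diameter_decrease = -10) {
  stopifnot(pd_diameter_increase >= 0, pr_diameter_decrease <= 0,
            pd_min_absolute_mm >= 0,
            mchoi_density_decrease <= 0, mchoi_diameter_decrease <= 0)
  structure(list(pd_diameter_increase = pd_diameter_increase,
                 pr_diameter_decrease = pr_diameter_decrease,
                 pd_min_absolute_mm = pd_min_absolute_mm,
                 mchoi_density_decrease = mchoi_density_decrease,
                 mchoi_diameter_decrease = mchoi_diameter_decrease),
            class = "criteria_thresholds")
}

response_factor <- function(x) factor(x, levels = c("PR", "SD", "PD"))

#' Classify a diameter change under RECIST 1.1
#'
#' PD requires both a percent increase of at least the PD threshold *and*
#' an absolute increase of at least 5 mm; PR requires a decrease of at
#' least the PR threshold; anything else is SD.
#'
#' @param diameter_change percent change(s) in diameter.
#' @param absolute_change_mm absolute change(s) in mm.
#' @param thresholds a [criteria_thresholds()].
#' @return Factor with levels `PR`, `SD`, `PD` (vectorized).
#' @export
#' @examples
#' classify_recist11(25, 8)   # PD
#' classify_recist11(22, 3)   # SD: fails the 5 mm minimum
#' classify_recist11(-35, -12)  # PR
classify_recist11 <- function(diameter_change, absolute_change_mm,
                              thresholds = criteria_thresholds()) {
  stopifnot(inherits(thresholds, "criteria_thresholds"),
            is.finite(diameter_change), is.finite(absolute_change_mm))
  out <- rep("SD", length(diameter_change))
  out[diameter_change >= thresholds$pd_diameter_increase &
        absolute_change_mm >= thresholds$pd_min_absolute_mm] <- "PD"
  out[diameter_change <= thresholds$pr_diameter_decrease] <- "PR"
  response_factor(out)
}

#' Classify a diameter change under mRECIST
#'
#' Same percent thresholds as RECIST (here without the 5 mm minimum, which
#' can be switched on via `apply_min_mm`), but the change must occur in a
#' lesion that enhances in the arterial phase: a non-enhancing lesion is
#' returned as SD, flagged in the `"gated"` attribute.
#'
#' @param diameter_change percent change(s).
#' @param enhancing logical flag(s): does the lesion enhance arterially?
#' @param thresholds a [criteria_thresholds()].
#' @param apply_min_mm also require the RECIST 5 mm minimum for PD.
#' @param absolute_change_mm needed when `apply_min_mm = TRUE`.
#' @return Factor with levels `PR`, `SD`, `PD`; attribute `gated` marks
#'   calls forced to SD by the enhancement gate.
#' @export
classify_mrecist <- function(diameter_change, enhancing,
                             thresholds = criteria_thresholds(),
                             apply_min_mm = FALSE, absolute_change_mm = NULL) {
  stopifnot(inherits(thresholds, "criteria_thresholds"),
            is.finite(diameter_change), is.logical(enhancing))
  enhancing <- rep_len(enhancing, length(diameter_change))
  out <- rep("SD", length(diameter_change))
  pd <- diameter_change >= thresholds$pd_diameter_increase
  if (apply_min_mm) {
    stopifnot(!is.null(absolute_change_mm))
    pd <- pd & absolute_change_mm >= thresholds$pd_min_absolute_mm
  }
  out[pd] <- "PD"
  out[diameter_change <= thresholds$pr_diameter_decrease] <- "PR"
  gated <- out != "SD" & !enhancing
  out[!enhancing] <- "SD"
  structure(response_factor(out), gated = gated)
}

#' Classify paired diameter and density changes under modified Choi
#'
#' PR requires *both* a density reduction of more than 15% and a diameter
#' reduction of more than 10% (strict). PD requires a diameter increase at
#' or above the PD threshold, and is vetoed whenever the density
#' partial-response condition is met.
#'
#' @param diameter_change,density_change percent changes (vectorized).
#' @param thresholds a [criteria_thresholds()].
#' @return Factor with levels `PR`, `SD`, `PD`.
#' @export
#' @examples
#' classify_mchoi(-12, -20)  # PR
#' classify_mchoi(-12, -10)  # SD: density condition fails
#' classify_mchoi(25, -30)   # SD: density response vetoes PD
classify_mchoi <- function(diameter_change, density_change,
                           thresholds = criteria_thresholds()) {
  stopifnot(inherits(thresholds, "criteria_thresholds"),
            is.finite(diameter_change), is.finite(density_change))
  dens_pr <- density_change < thresholds$mchoi_density_decrease
  out <- rep("SD", length(diameter_change))
  out[diameter_change >= thresholds$pd_diameter_increase & !dens_pr] <- "PD"
  out[dens_pr & diameter_change < thresholds$mchoi_diameter_decrease] <- "PR"
  response_factor(out)
}

#' Count threshold crossings of per-lesion maximum changes
#'
#' For each phase, counts the lesions whose maximum percent change crosses
#' the PD (increase) or PR (decrease) threshold, with fractions over the
#' per-phase lesion count and a `count/n` display label.
#'
#' @param waterfall data frame with `lesion_id`, `max_percent_change`, and
#'   optionally `phase`.
#' @param thresholds a [criteria_thresholds()].
#' @return Data frame with one row per phase: `phase`, `n`, `pd_count`,
#'   `pd_fraction`, `pd_label`, `pd_percent`, and the PR equivalents.
#'   `pd_percent` is rounded half-up to one decimal (8/51 displays 15.7).
#' @export
count_crossings <- function(waterfall, thresholds = criteria_thresholds()) {
  stopifnot(all(c("lesion_id", "max_percent_change") %in% names(waterfall)))
  if (!("phase" %in% names(waterfall))) waterfall$phase <- "all"
  rows <- lapply(split(waterfall, waterfall$phase), function(w) {
    n <- nrow(w)
    pd <- sum(w$max_percent_change >= thresholds$pd_diameter_increase)
    pr <- sum(w$max_percent_change <= thresholds$pr_diameter_decrease)
    data.frame(phase = w$phase[1], n = n,
               pd_count = pd, pd_fraction = pd / n,
               pd_label = sprintf("%d/%d", pd, n),
               pd_percent = round_half_up(100 * pd / n, 1),
               pr_count = pr, pr_fraction = pr / n,
               pr_label = sprintf("%d/%d", pr, n),
               pr_percent = round_half_up(100 * pr / n, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(match(out$phase, c(PHASES, "all"))), , drop = FALSE]
}

#' Sum-of-target-lesions aggregate helper
#'
#' RECIST-style trials sum the diameters of several target lesions before
#' applying the percent thresholds. Given per-lesion baseline and repeat
#' diameters for one patient, returns the percent and absolute change of
#' the summed diameter.
#'
#' @param baseline_mm,repeat_mm per-lesion diameters (mm), same length.
#' @return List with `baseline_sum`, `repeat_sum`, `percent_change`,
#'   `absolute_change_mm`.
#' @export
sum_target_lesions <- function(baseline_mm, repeat_mm) {
  stopifnot(length(baseline_mm) == length(repeat_mm), all(baseline_mm > 0))
  b <- sum(baseline_mm); r <- sum(repeat_mm)
  list(baseline_sum = b, repeat_sum = r,
       percent_change = percent_difference(b, r),
       absolute_change_mm = r - b)
}
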