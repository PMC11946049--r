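# RECIST 1.1 / mRECIST / modified Choi classification logic.

test_that("RECIST 1.1 applies the percent thresholds with the 5 mm minimum", {
  expect_equal(as.character(classify_recist11(25, 8)), "PD")
  expect_equal(as.character(classify_recist11(22, 3)), "SD")  # fails 5 mm
  expect_equal(as.character(classify_recist11(-35, -12)), "PR")
  # closed boundaries: exactly +20% with exactly +5 mm is PD, exactly -30% is PR
  expect_equal(as.character(classify_recist11(20, 5)), "PD")
  expect_equal(as.character(classify_recist11(-30, -9)), "PR")
  expect_equal(as.character(classify_recist11(19.99, 10)), "SD")
})

test_that("mRECIST gates calls on arterial enhancement", {
  expect_equal(as.character(classify_mrecist(20, TRUE)), "PD")
  expect_equal(as.character(classify_mrecist(-30, TRUE)), "PR")
  g <- classify_mrecist(40, FALSE)
  expect_equal(as.character(g), "SD")
  expect_true(attr(g, "gated"))
  # no 5 mm minimum by default; available on request
  expect_equal(as.character(classify_mrecist(25, TRUE)), "PD")
  expect_equal(as.character(classify_mrecist(25, TRUE, apply_min_mm = TRUE,
                                             absolute_change_mm = 3)), "SD")
})

test_that("modified Choi requires the density-and-diameter conjunction", {
  expect_equal(as.character(classify_mchoi(-12, -20)), "PR")
  expect_equal(as.character(classify_mchoi(-12, -10)), "SD")  # density fails
  expect_equal(as.character(classify_mchoi(25, -30)), "SD")   # density vetoes PD
  expect_equal(as.character(classify_mchoi(25, 5)), "PD")
  # strict "more than" boundaries: exactly -15/-10 do not qualify
  expect_equal(as.character(classify_mchoi(-10, -15)), "SD")
  expect_equal(as.character(classify_mchoi(-10.01, -15.01)), "PR")
})

test_that("classification is monotone in the diameter change", {
  thr <- criteria_thresholds()
  grid <- seq(-60, 60, by = 0.5)
  lv <- function(f) as.integer(f)  # PR=1 < SD=2 < PD=3
  r <- lv(classify_recist11(grid, grid))  # abs change large enough throughout
  expect_true(all(diff(r) >= 0))
  m <- lv(classify_mrecist(grid, TRUE, thr))
  expect_true(all(diff(m) >= 0))
  ch <- lv(classify_mchoi(grid, rep(0, length(grid)), thr))
  expect_true(all(diff(ch) >= 0))
})

test_that("threshold boundary audit: infinite thresholds give SD, zero thresholds never do", {
  inf_thr <- criteria_thresholds(pd_diameter_increase = Inf,
                                 pr_diameter_decrease = -Inf,
                                 mchoi_density_decrease = -Inf,
                                 mchoi_diameter_decrease = -Inf)
  x <- c(-80, -5, 0, 5, 80)
  expect_true(all(classify_recist11(x, x, inf_thr) == "SD"))
  expect_true(all(classify_mrecist(x, TRUE, inf_thr) == "SD"))
  expect_true(all(classify_mchoi(x, x, inf_thr) == "SD"))

  zero_thr <- criteria_thresholds(pd_diameter_increase = 0,
                                  pr_diameter_decrease = 0,
                                  pd_min_absolute_mm = 0)
  expect_true(all(classify_recist11(x, x, zero_thr) != "SD"))
  expect_true(all(classify_mrecist(x, TRUE, zero_thr) != "SD"))
})

test_that("crossing counts report disjoint PD/PR sets with display fractions", {
  wf <- data.frame(lesion_id = sprintf("L%02d", 1:3),
                   max_percent_change = c(25, 5, -35))
  cc <- count_crossings(wf)
  expect_equal(cc$pd_count, 1)
  expect_equal(cc$pr_count, 1)

  none <- data.frame(lesion_id = sprintf("L%02d", 1:5),
                     max_percent_change = c(-29, -10, 0, 10, 19.9))
  cc0 <- count_crossings(none)
  expect_equal(cc0$pd_count + cc0$pr_count, 0)

  # a cohort built so 8 of 51 lesions exceed +20%: the label and percent
  # match the count/n display convention
  maxima <- c(rep(25, 8), rep(5, 43))
  wf51 <- data.frame(lesion_id = sprintf("L%02d", 1:51),
                     max_percent_change = maxima)
  cc51 <- count_crossings(wf51)
  expect_equal(cc51$pd_label, "8/51")
  expect_equal(cc51$pd_percent, 15.7)
  expect_lte(cc51$pd_count + cc51$pr_count, 51)
})

test_that("summed target-lesion changes use the summed diameters", {
  s <- sum_target_lesions(c(20, 30), c(26, 34))
  expect_equal(s$baseline_sum, 50)
  expect_equal(s$percent_change, 20)
  expect_equal(s$absolute_change_mm, 10)
})
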