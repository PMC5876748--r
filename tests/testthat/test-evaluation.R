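## build a phase sequence carrying given event times on a 200 Hz grid
seq_from_events <- function(events, dur = 5, rate = 200) {
  labels_from_events(events, n = dur * rate, rate = rate)
}

ev <- function(...) {
  d <- data.frame(...)
  names(d) <- c("type", "time")
  d
}

base_events <- data.frame(
  type = rep(c("HS", "TS", "HO", "TO"), 4),
  time = as.vector(t(outer(0:3, c(0.1, 0.2, 0.6, 0.8), "+"))),
  stringsAsFactors = FALSE)

test_that("transitions inside the tolerance window are true positives", {
  ref <- seq_from_events(base_events)
  shifted <- base_events
  shifted$time[shifted$type == "HS"] <- shifted$time[shifted$type == "HS"] +
    0.025
  pred <- seq_from_events(shifted)
  cnt <- match_transitions(ref, pred, tolerance_ms = 60)
  expect_equal(cnt$FP, 0)
  expect_equal(cnt$FN, 0)
  ## 25 ms <= the 30 ms half window; every event is a label change
  ## (the pre-event samples carry the cycle predecessor phase)
  expect_equal(cnt$TP, nrow(base_events))
})

test_that("a transition outside the window is both FP and FN", {
  ref <- seq_from_events(base_events)
  off <- base_events
  off$time[off$type == "HO"] <- off$time[off$type == "HO"] + 0.040
  pred <- seq_from_events(off)
  cnt <- match_transitions(ref, pred, tolerance_ms = 60)
  expect_equal(cnt$FP, 4)
  expect_equal(cnt$FN, 4)
})

test_that("identity comparison gives perfect rates and zero goodness", {
  ref <- seq_from_events(base_events)
  cnt <- match_transitions(ref, ref)
  expect_equal(cnt$FP, 0); expect_equal(cnt$FN, 0)
  r <- rates(cnt)
  expect_equal(unname(r), c(1, 1))
  g <- goodness(r["TPR"], r["TNR"])
  expect_equal(g$G, 0)
  expect_equal(g$performance_class, "optimum")
})

test_that("swapping reference and prediction swaps FP and FN", {
  ref <- seq_from_events(base_events)
  off <- base_events[-c(3, 7), ]                # drop two events
  pred <- seq_from_events(off)
  a <- match_transitions(ref, pred)
  b <- match_transitions(pred, ref)
  expect_equal(a$FP, b$FN)
  expect_equal(a$FN, b$FP)
  expect_equal(a$TP, b$TP)
})

test_that("TP + FN equals the number of reference transitions", {
  f <- healthy_trial()
  pred <- s_method(sagittal_gyro(f$trial$imu))
  cnt <- match_transitions(f$ref, pred)
  n_ref <- nrow(gaitphase:::transitions_of(f$ref))
  expect_equal(cnt$TP + cnt$FN, n_ref)
})

test_that("rates are exact ratios and demand positive denominators", {
  expect_equal(unname(rates(list(TP = 9, FN = 1, TN = 7, FP = 3))),
               c(0.9, 0.7))
  expect_error(rates(list(TP = 0, FN = 0, TN = 5, FP = 1)), "denominator")
})

test_that("the goodness index follows the ROC-distance formula and bands", {
  expect_equal(goodness(1, 1)$G, 0)
  expect_equal(goodness(0, 0)$G, sqrt(2))
  expect_equal(goodness(0, 0)$performance_class, "random")
  g <- goodness(0.8, 0.7)
  expect_equal(g$G, sqrt(0.3^2 + 0.2^2))
  expect_equal(round(g$G, 1), 0.4)
  expect_equal(g$performance_class, "good")
  expect_equal(goodness(0.9, 0.9)$performance_class, "optimum")
})

test_that("goodness is monotone non-increasing in each rate", {
  grid <- seq(0, 1, by = 0.1)
  for (tnr in c(0.3, 0.7, 1)) {
    gs <- vapply(grid, function(tpr) goodness(tpr, tnr)$G, numeric(1))
    expect_true(all(diff(gs) <= 1e-12))
  }
  for (tpr in c(0.3, 0.7, 1)) {
    gs <- vapply(grid, function(tnr) goodness(tpr, tnr)$G, numeric(1))
    expect_true(all(diff(gs) <= 1e-12))
  }
})

test_that("phase errors compare trial-mean percentages", {
  one <- c(rep("LR", 14), rep("FF", 80), rep("PS", 32), rep("Sw", 74))
  ref <- segment_strides(phase_sequence(c(rep(one, 8), "LR"), 200),
                         discard_ends = 0)
  expect_equal(unname(phase_errors(ref, ref)), rep(0, 5))
  two <- c(rep("LR", 14), rep("FF", 84), rep("PS", 28), rep("Sw", 74))
  prd <- segment_strides(phase_sequence(c(rep(two, 8), "LR"), 200),
                         discard_ends = 0)
  e <- phase_errors(ref, prd)
  expect_equal(unname(e[c("FF_e", "PS_e")]), c(2, 2))
  expect_equal(unname(e[c("LR_e", "Sw_e")]), c(0, 0))
  expect_error(phase_errors(ref[0, ], prd), "empty")
})

test_that("AUC matches the rank-sum identity and its boundary cases", {
  expect_equal(roc_auc(c(5, 6, 7), c(1, 2, 3)), 100)
  expect_equal(roc_auc(2, 2), 50)
  set.seed(10)
  a <- rnorm(40, 1); b <- rnorm(35)
  w <- wilcox.test(a, b, exact = FALSE)$statistic  # independent oracle
  expect_equal(roc_auc(a, b), 100 * unname(w) / (40 * 35), tolerance = 1e-12)
  set.seed(11)
  expect_equal(roc_auc(rnorm(200), rnorm(200)), 50, tolerance = 5)
  expect_error(roc_auc(numeric(0), 1), "empty")
})
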