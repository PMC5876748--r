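mk_fsw <- function(heel, mt1, mt5, toe, rate = 200) {
  fsw_recording("right", cbind(heel, mt1, mt5, toe), rate)
}

test_that("contact rules map switch states to the four phases", {
  n <- 60
  fsw <- mk_fsw(heel = c(rep(1, 15), rep(1, 15), rep(0, 15), rep(0, 15)),
                mt1 = c(rep(0, 15), rep(1, 15), rep(1, 15), rep(0, 15)),
                mt5 = c(rep(0, 15), rep(1, 15), rep(1, 15), rep(0, 15)),
                toe = c(rep(0, 15), rep(1, 15), rep(1, 15), rep(0, 15)))
  seq <- label_phases(fsw)
  lab <- as.character(seq$labels)
  expect_equal(lab[1:15], rep("LR", 15))    # only heel pressed
  expect_equal(lab[16:30], rep("FF", 15))   # all pressed: FF beats PS
  expect_equal(lab[31:45], rep("PS", 15))   # forefoot only
  expect_equal(lab[46:60], rep("Sw", 15))   # none pressed
})

test_that("heel plus partial forefoot counts as pre-swing, not loading", {
  fsw <- mk_fsw(heel = rep(1, 20), mt1 = rep(1, 20),
                mt5 = rep(0, 20), toe = rep(0, 20))
  expect_equal(as.character(label_phases(fsw)$labels), rep("PS", 20))
})

test_that("binarization thresholds at a fraction of the robust maximum", {
  ramp <- seq(0, 1, length.out = 100)
  fsw <- mk_fsw(ramp, ramp, ramp, ramp)
  b <- binarize_footswitch(fsw, 0.5)
  expect_true(all(b$channels %in% c(0, 1)))
  step <- which(diff(b$channels[, 1]) == 1)
  expect_equal(step, 48, tolerance = 2)     # 0.5 x 95th percentile
  already <- mk_fsw(rep(c(0, 1), 50), rep(0:1, 50), rep(0:1, 50),
                    rep(0:1, 50))
  expect_equal(binarize_footswitch(already)$channels, already$channels)
  dead <- mk_fsw(rep(0, 100), rep(1, 100), rep(1, 100), rep(1, 100))
  expect_warning(binarize_footswitch(dead), "never closes")
})

test_that("binarized generator forces equal the contact truth without chatter", {
  tr <- generate_trial(gait_preset("healthy"), 8, seed = 13)
  b <- binarize_footswitch(tr$fsw)
  ev <- tr$truth$events
  tf <- tr$fsw$t0 + (seq_len(nrow(b$channels)) - 1) / tr$fsw$rate
  hs <- ev$time[ev$type == "HS"]; ho <- ev$time[ev$type == "HO"]
  truth_heel <- rep(0, length(tf))
  for (k in seq_along(ho)) truth_heel[tf >= hs[k] & tf < ho[k]] <- 1
  truth_heel[tf >= hs[length(hs)]] <- 1
  expect_lt(mean(b$channels[, "heel"] != truth_heel), 1e-3)
})

test_that("debouncing removes chatter-induced spurious events", {
  p <- gait_profile(chatter_prob = 0.5)
  tr <- generate_trial(p, 10, seed = 17)
  seq <- reference_sequence(tr$fsw, debounce_ms = 20)
  n_truth <- sum(tr$truth$events$type %in% gait_events())
  expect_equal(nrow(seq$events), n_truth, tolerance = 2)
})

test_that("stride segmentation computes percentages and discards ends", {
  ## 1000 ms stride: LR 70, FF 400, PS 160, Sw 370 -> (7, 40, 16, 37) %
  one <- c(rep("LR", 14), rep("FF", 80), rep("PS", 32), rep("Sw", 74))
  lab <- c(rep(one, 8), "LR")
  seq <- phase_sequence(lab, 200)
  st <- segment_strides(seq, discard_ends = 0)
  expect_equal(nrow(st), 8)
  expect_equal(unname(unlist(st[1, c("LR", "FF", "PS", "Sw")])),
               c(7, 40, 16, 37))
  expect_equal(rowSums(st[, c("LR", "FF", "PS", "Sw")]),
               rep(100, 8), ignore_attr = TRUE)
  st3 <- segment_strides(seq, discard_ends = 3)
  expect_equal(nrow(st3), 2)
  expect_error(segment_strides(seq, discard_ends = 4), "stride")
})

test_that("strides with non-canonical phase order are excluded but counted", {
  one <- c(rep("LR", 14), rep("FF", 80), rep("PS", 32), rep("Sw", 74))
  bad <- c(rep("LR", 14), rep("FF", 40), rep("LR", 40), rep("PS", 32),
           rep("Sw", 74))
  lab <- c(rep(one, 3), bad, rep(one, 3), "LR")
  st <- segment_strides(phase_sequence(lab, 200), discard_ends = 1)
  expect_equal(attr(st, "n_excluded"), 1L)
  expect_equal(nrow(st), 4)
})

test_that("labeling is idempotent on its own output re-encoded as contacts", {
  f <- healthy_trial()
  seq1 <- f$ref
  lab <- as.character(seq1$labels)
  enc <- cbind(heel = as.numeric(lab %in% c("LR", "FF")),
               mt1 = as.numeric(lab %in% c("FF", "PS")),
               mt5 = as.numeric(lab %in% c("FF", "PS")),
               toe = as.numeric(lab %in% c("FF", "PS")))
  seq2 <- label_phases(fsw_recording("right", enc, seq1$rate))
  expect_equal(as.character(seq2$labels), lab)
})

test_that("reference percentages track the generator ground truth", {
  f <- healthy_trial()
  st <- segment_strides(f$ref)
  truth <- f$trial$truth$fractions
  kept <- st$stride
  for (j in 1:4)
    expect_lt(max(abs(st[[gait_phases()[j]]] - truth[kept, j])), 1.5)
})
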