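ref <- healthy_reference()

test_that("GPQI is zero exactly at the reference distribution", {
  expect_equal(gpqi(ref$means, ref$means, ref)$gpqi, 0)
})

test_that("GPQI hand-computed examples", {
  d <- c(3, 4, -4, -3)
  r <- gpqi(ref$means + d, ref$means + d, ref)
  expect_equal(r$gpqi, 2 * sqrt(50), tolerance = 1e-12)
  one <- gpqi(ref$means, ref$means + c(1, 0, 0, -1), ref)
  expect_equal(one$gpqi, sqrt(2), tolerance = 1e-12)
  expect_equal(unname(one$per_side_distance), c(0, sqrt(2)))
})

test_that("GPQI is symmetric in sides and scales linearly in deviations", {
  d <- c(2, -1, -2, 1)
  a <- gpqi(ref$means + d, ref$means - d, ref)$gpqi
  b <- gpqi(ref$means - d, ref$means + d, ref)$gpqi
  expect_equal(a, b)
  twice <- gpqi(ref$means + 2 * d, ref$means - 2 * d, ref)$gpqi
  expect_equal(twice, 2 * a, tolerance = 1e-12)
})

test_that("malformed side vectors are rejected", {
  expect_error(gpqi(c(50, 50, 0.5, 0.5), ref$means, ref), "sum")
  expect_error(gpqi(c(1, 2, 3), ref$means, ref), "4-vector")
  expect_error(reference_distribution(c(10, 20, 30, 60)), "100")
})

test_that("trial GPQI bases agree for a single stride and differ sensibly", {
  one <- c(rep("LR", 14), rep("FF", 80), rep("PS", 32), rep("Sw", 74))
  st <- segment_strides(phase_sequence(c(one, one, "LR"), 200),
                        discard_ends = 0)
  single <- st[1, , drop = FALSE]
  class(single) <- class(st)
  a <- gpqi_trial(single, single, ref, basis = "trial_mean")
  b <- gpqi_trial(single, single, ref, basis = "per_stride")
  expect_equal(a$gpqi, b$gpqi)
  expect_warning(gpqi_trial(st, single, ref, basis = "per_stride"),
                 "truncating")
})

test_that("healthy cohorts score lower GPQI than severe parkinsonian ones", {
  vals <- function(preset, n = 6) vapply(seq_len(n), function(i) {
    bi <- generate_bilateral(gait_preset(preset), 9, seed = 700 + i)
    gpqi_trial(segment_strides(reference_sequence(bi$left$fsw)),
               segment_strides(reference_sequence(bi$right$fsw)), ref)$gpqi
  }, numeric(1))
  h <- vals("healthy"); s <- vals("pd_severe")
  expect_lt(mean(h), mean(s))
  expect_equal(roc_auc(s, h), 100, tolerance = 10)
})

test_that("a computed control reference recovers the generator fractions", {
  p <- gait_preset("healthy")
  tabs <- lapply(1:6, function(s) {
    tr <- generate_trial(p, 15, seed = 800 + s)
    segment_strides(reference_sequence(tr$fsw))
  })
  cr <- control_reference(tabs)
  expect_equal(cr$source, "computed")
  ## grand means within 3 SE of the per-trial spread
  per_trial <- t(vapply(tabs, phase_means, numeric(4)))
  for (j in 1:4) {
    se <- sd(per_trial[, j]) / sqrt(nrow(per_trial))
    expect_lt(abs(cr$means[j] - p$phase_fractions[j] / 100.2 * 100),
              3 * se + 0.2)
  }
  ## single trial equal to its own mean
  single <- control_reference(tabs[1])
  expect_equal(unname(single$means), unname(phase_means(tabs[[1]])))
})

test_that("ICC(3,k) matches an aov-based oracle and handles edge cases", {
  expect_icc_aov <- function(m) {
    got <- icc_3k(m)
    d <- data.frame(y = as.vector(m),
                    subj = factor(rep(seq_len(nrow(m)), ncol(m))),
                    trial = factor(rep(seq_len(ncol(m)), each = nrow(m))))
    tab <- summary(stats::aov(y ~ subj + trial, d))[[1]]
    msr <- tab["subj", "Mean Sq"]; mse <- tab["Residuals", "Mean Sq"]
    expect_equal(got$icc, (msr - mse) / msr, tolerance = 1e-10)
    got
  }
  set.seed(5)
  m <- matrix(rnorm(30, rep(1:10, 3), 0.5), 10, 3)
  r <- expect_icc_aov(m)
  expect_equal(r$mdc95, 1.96 * sqrt(2) * r$sem, tolerance = 1e-12)

  ## zero within-subject variance
  perfect <- matrix(rep(1:3, each = 3), 3, 3, byrow = TRUE)
  rp <- icc_3k(perfect)
  expect_equal(rp$icc, 1)
  expect_equal(rp$mdc95, 0)

  ## pure noise: ICC near zero
  set.seed(6)
  noise <- matrix(rnorm(600), 200, 3)
  expect_lt(abs(icc_3k(noise)$icc), 0.2)

  expect_error(icc_3k(matrix(1:3, 1, 3)), "2 subjects")
  expect_error(icc_3k(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("reliability classes follow the stated bands", {
  ## strong between-subject spread, small trial noise: excellent (ICC ~0.96+)
  set.seed(9)
  m <- matrix(rnorm(60, rep(seq(0, 20, length.out = 20), 3), 0.8), 20, 3)
  r <- icc_3k(m)
  expect_gt(r$icc, 0.75)
  expect_equal(r$reliability_class, "excellent")
  ## pure noise: poor
  set.seed(12)
  expect_equal(icc_3k(matrix(rnorm(150), 50, 3))$reliability_class, "poor")
})
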