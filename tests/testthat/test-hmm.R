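test_that("supervised initialization matches the moment formulas", {
  lab <- rep(rep(gait_phases(), 4), each = 50)
  x <- rep(rep(c(10, 0, -20, 40), 4), each = 50)
  m <- gait_hmm(x, lab, n_mix = 1, sd_floor = 1)
  mu <- vapply(m$emissions, `[[`, numeric(1), "mu")
  expect_equal(mu, c(10, 0, -20, 40))
  ## mean dwell of 50 samples -> self-transition 0.98
  expect_equal(unname(diag(m$A)), rep(0.98, 4))
  expect_equal(m$pi, rep(0.25, 4))
  ## SD floor engaged on constant segments
  expect_true(all(vapply(m$emissions, function(e) min(e$sd), numeric(1)) >= 1))
})

test_that("initialization refuses labels missing a phase", {
  expect_error(gait_hmm(rnorm(100), rep(c("LR", "FF", "PS"), length.out = 100)),
               "Sw")
})

test_that("Baum-Welch log-likelihood is non-decreasing and tol=Inf stops after one step", {
  f <- healthy_trial()
  m0 <- gait_hmm(f$obs, f$labels)
  m <- baum_welch(m0, f$obs, max_iter = 12)
  ll <- m$train$log_likelihood
  expect_true(all(diff(ll) > -1e-8))
  m1 <- baum_welch(m0, f$obs, tol = Inf)
  expect_equal(m1$train$n_iter, 1)
})

test_that("training preserves the left-right cyclic structure", {
  f <- healthy_trial()
  m <- baum_welch(gait_hmm(f$obs, f$labels), f$obs, max_iter = 8)
  mask <- gaitphase:::hmm_mask(4)
  expect_equal(unname(rowSums(m$A)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(m$A[mask == 0] == 0))
  for (e in m$emissions) {
    expect_equal(sum(e$w), 1, tolerance = 1e-9)
    expect_true(all(e$sd >= m$sd_floor))
  }
})

test_that("Baum-Welch recovers emission means of a known model within 5%", {
  set.seed(123)
  true <- random_gait_hmm(sep = 80)
  sim <- simulate(true, nsim = 6000, seed = 99)
  m0 <- gait_hmm(sim$samples, as.character(sim$states), n_mix = 1,
                 sd_floor = 1)
  m <- baum_welch(m0, sim$samples, max_iter = 50)
  mu_true <- vapply(true$emissions, `[[`, numeric(1), "mu")
  mu_est <- vapply(m$emissions, `[[`, numeric(1), "mu")
  expect_lt(max(abs(mu_est - mu_true) / pmax(abs(mu_true), 20)), 0.05)
  ## self-transitions recovered too
  expect_lt(max(abs(diag(m$A) - diag(true$A))), 0.05)
})

test_that("Viterbi equals exhaustive path enumeration on short sequences", {
  set.seed(42)
  for (rep in 1:25) {
    m <- random_gait_hmm(sep = runif(1, 10, 80))
    x <- rnorm(8, sample(c(-80, -40, 0, 40, 80), 8, replace = TRUE), 30)
    got <- as.integer(viterbi(m, x, rate = 200)$labels)
    want <- unname(viterbi_exhaustive(m, x))
    expect_equal(got, want)
  }
})

test_that("decoded paths never move backward through the cycle", {
  f <- healthy_trial()
  m <- trained_spt()
  path <- as.integer(viterbi(m, f$obs)$labels)
  step <- diff(path) %% 4
  expect_true(all(step %in% c(0, 1)))
})

test_that("Viterbi decoding matches the ground truth on a clean trial", {
  quiet <- gait_profile(gyro_noise_sd = 0, accel_noise_sd = 0,
                        fraction_jitter_sd = 0, stride_time_jitter_sd = 0)
  tr <- generate_trial(quiet, 10, seed = 77)
  ref <- reference_sequence(tr$fsw)
  obs <- hmm_observation(tr$imu)
  n <- min(length(obs$samples), length(ref$labels))
  obs$samples <- obs$samples[seq_len(n)]
  lab <- ref; lab$labels <- lab$labels[seq_len(n)]
  m <- baum_welch(gait_hmm(obs, lab), obs, max_iter = 10)
  dec <- viterbi(m, obs)
  agree <- mean(as.character(dec$labels) == as.character(lab$labels))
  ## boundaries may shift by a few samples (emission geometry); the bulk
  ## of every phase must agree and the event-level score stay optimum
  expect_gt(agree, 0.92)
  expect_lt(evaluate_segmentation(lab, dec)$G, 0.15)
})

test_that("online decoding approximates Viterbi with normalized posteriors", {
  f <- healthy_trial()
  m <- trained_spt()
  on <- decode_online(m, f$obs)
  vit <- viterbi(m, f$obs)
  expect_gt(mean(as.character(on$phases) == as.character(vit$labels)), 0.95)
  expect_equal(rowSums(on$posterior), rep(1, nrow(on$posterior)),
               tolerance = 1e-9)
})

test_that("a signal starting mid-swing is first decoded as swing", {
  f <- healthy_trial()
  ms <- which(f$obs$samples > 300)[1]           # inside the swing plateau
  tail_sig <- f$obs$samples[ms:(ms + 400)]
  on <- decode_online(trained_spt(), tail_sig)
  expect_equal(as.character(on$phases[1]), "Sw")
})

test_that("subject-specific training uses two trials and rotates three folds", {
  trials <- lapply(1:3, function(k) {
    f <- healthy_trial(200 + k)
    list(signal = f$obs, labels = f$labels)
  })
  folds <- train_sst(trials, max_iter = 10)
  expect_length(folds, 3)
  expect_equal(vapply(folds, `[[`, integer(1), "held_out"), 1:3)
  one <- train_sst(trials, held_out = 2, max_iter = 10)
  expect_s3_class(one$model, "gait_hmm")
  expect_s3_class(one$decoded, "phase_sequence")
  expect_error(train_sst(trials[1:2]), "3 trials")
})

test_that("the pooled control-group model decodes unseen trials accurately", {
  m <- trained_spt()
  f <- healthy_trial(300)
  g <- evaluate_segmentation(f$ref, viterbi(m, f$obs))$G
  expect_lte(g, 0.25)
})

test_that("model JSON persistence round-trips", {
  m <- trained_spt()
  path <- tempfile(fileext = ".json")
  write_gait_hmm(m, path)
  m2 <- read_gait_hmm(path)
  expect_equal(m2$A, m$A, tolerance = 1e-12)
  expect_equal(m2$pi, m$pi)
  for (i in 1:4) {
    expect_equal(m2$emissions[[i]]$mu, m$emissions[[i]]$mu, tolerance = 1e-12)
    expect_equal(m2$emissions[[i]]$sd, m$emissions[[i]]$sd, tolerance = 1e-12)
  }
  x <- healthy_trial(301)$obs
  expect_equal(as.character(viterbi(m2, x)$labels),
               as.character(viterbi(m, x)$labels))
})
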