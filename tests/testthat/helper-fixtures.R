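# Shared fixtures, built once per test run. All are seeded so the suite is
# deterministic.

fixture_env <- new.env(parent = emptyenv())

# one healthy 12-stride trial with derived reference and HMM observation
healthy_trial <- function(seed = 42) {
  key <- paste0("trial_", seed)
  if (is.null(fixture_env[[key]])) {
    tr <- generate_trial(gait_preset("healthy"), 12, seed = seed)
    ref <- reference_sequence(tr$fsw)
    obs <- hmm_observation(tr$imu)
    n <- min(length(obs$samples), length(ref$labels))
    obs$samples <- obs$samples[seq_len(n)]
    lab <- ref
    lab$labels <- lab$labels[seq_len(n)]
    fixture_env[[key]] <- list(trial = tr, ref = ref, obs = obs, labels = lab)
  }
  fixture_env[[key]]
}

# cross-subject HMM trained on a small healthy pool
trained_spt <- function() {
  if (is.null(fixture_env$spt)) {
    pool <- lapply(1:3, function(i) {
      f <- healthy_trial(100 + i)
      list(signal = f$obs, labels = f$labels)
    })
    fixture_env$spt <- train_spt(pool, max_iter = 20)
  }
  fixture_env$spt
}

# small random cyclic 4-state model for oracle comparisons
random_gait_hmm <- function(sep = 60) {
  A <- matrix(0, 4, 4)
  for (i in 1:4) {
    a <- runif(1, 0.7, 0.95)
    A[i, i] <- a
    A[i, i %% 4 + 1] <- 1 - a
  }
  structure(list(n_states = 4L, A = A, pi = rep(0.25, 4),
                 emissions = lapply(1:4, function(i)
                   list(w = 1, mu = (i - 2.5) * sep,
                        sd = runif(1, 5, 20))),
                 n_mix = 1L, sd_floor = 1, train = NULL),
            class = "gait_hmm")
}

# brute-force most-likely path by enumerating all 4^T state sequences
viterbi_exhaustive <- function(model, x) {
  Tn <- length(x)
  B <- log(gaitphase:::emission_probs(model, x))
  logA <- log(model$A)
  paths <- as.matrix(expand.grid(rep(list(1:4), Tn)))
  score <- log(model$pi[paths[, 1]]) + B[cbind(1, paths[, 1])]
  if (Tn > 1) for (t in 2:Tn) {
    score <- score + logA[cbind(paths[, t - 1], paths[, t])] +
      B[cbind(t, paths[, t])]
  }
  paths[which.max(score), ]
}
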