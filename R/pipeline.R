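## End-to-end harness on synthetic cohorts: simulate -> reference label ->
## segment with all four methods -> evaluate -> GPQI group report.

#' Reference phase sequence of a footswitch recording
#'
#' Standard conditioning chain: binarize the analog channels, zero-order
#' hold resample onto the common evaluation grid, apply the four-phase
#' contact rules with debouncing.
#'
#' @param fsw An \code{\link{fsw_recording}}.
#' @param target_rate Common grid, Hz. Default 200.
#' @param threshold_frac Binarization threshold fraction. Default 0.10.
#' @param debounce_ms Debounce window, ms. Default 20.
#' @return A \code{\link{phase_sequence}} at \code{target_rate}.
#' @export
reference_sequence <- function(fsw, target_rate = 200, threshold_frac = 0.10,
                               debounce_ms = 20) {
  b <- binarize_footswitch(fsw, threshold_frac)
  ch <- vapply(seq_len(4L), function(j)
    resample_series(uniform_series(b$channels[, j], b$rate, b$t0),
                    target_rate, "hold")$samples,
    numeric(length(resample_series(uniform_series(b$channels[, 1], b$rate,
                                                  b$t0),
                                   target_rate, "hold")$samples)))
  label_phases(fsw_recording(b$side, ch, target_rate, b$t0), debounce_ms)
}

#' HMM observation signal from an IMU recording
#'
#' The scalar input of both HMM segmenters: sagittal angular velocity on
#' the common grid, low-pass filtered (2nd order Butterworth, 17 Hz).
#'
#' @param imu An \code{\link{imu_recording}}.
#' @param target_rate Common grid, Hz. Default 200.
#' @param cutoff_hz Low-pass cutoff, Hz. Default 17.
#' @param axis Gyroscope axis, see \code{\link{sagittal_gyro}}.
#' @return A \code{\link{uniform_series}}.
#' @export
hmm_observation <- function(imu, target_rate = 200, cutoff_hz = 17,
                            axis = "auto") {
  lowpass(sagittal_gyro(imu, axis = axis, target_rate = target_rate),
          cutoff_hz)
}

## derive a stream of sub-seeds from the master seed, kept within the
## 32-bit integer range (multiplication done in double precision)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483647)
}

## truncate a signal / label pair to a common length
align_lengths <- function(signal, labels) {
  n <- min(length(signal$samples), length(labels$labels))
  signal$samples <- signal$samples[seq_len(n)]
  labels$labels <- labels$labels[seq_len(n)]
  list(signal = signal, labels = labels)
}

## one simulated trial plus everything derived from it
prepare_trial <- function(preset, n_strides, seed, side = "right") {
  tr <- generate_trial(gait_preset(preset), n_strides, side, seed = seed)
  ref <- reference_sequence(tr$fsw)
  obs <- hmm_observation(tr$imu)
  al <- align_lengths(obs, ref)
  list(trial = tr, ref = ref, obs = al$signal, labels = al$labels,
       preset = preset, seed = seed)
}

#' Run the full synthetic benchmark pipeline
#'
#' Simulates cohorts for each preset, produces the footswitch reference,
#' runs all four partitioning methods (gyroscope threshold, accelerometer
#' threshold, subject-specific HMM, control-group HMM), evaluates them
#' against the reference with the 60 ms tolerance window, and computes
#' per-phase percentage errors. Separately, bilateral trials per preset
#' give a GPQI group report with AUC against the healthy cohort.
#' Deterministic for a fixed \code{seed}.
#'
#' Each preset cohort has \code{n_subjects} subjects with 3 trials each
#' (the subject-specific HMM rotates leave-one-trial-out folds within a
#' subject); the control-group HMM is trained once on \code{n_train}
#' extra healthy trials.
#'
#' @param seed Master seed; all trial seeds derive from it.
#' @param n_subjects Subjects per preset. Default 2.
#' @param n_strides Strides per trial. Default 18.
#' @param n_train Healthy trials in the control-group training pool.
#' @param n_gpqi Bilateral trials per preset for the GPQI report.
#' @param presets Character vector of preset names.
#' @param tolerance_ms Evaluation tolerance window, ms. Default 60.
#' @return Object of class \code{"gait_pipeline"}: \code{accuracy} (one
#'   row per method x preset with mean TPR, TNR, G, class and phase
#'   errors), \code{per_trial} (trial-level results), \code{gpqi}
#'   (per-trial GPQI by preset), \code{auc} (GPQI discrimination of each
#'   parkinsonian preset from healthy), \code{spt_model}.
#' @export
run_gait_pipeline <- function(seed = 1, n_subjects = 2, n_strides = 18,
                              n_train = 6, n_gpqi = 8,
                              presets = c("healthy", "pd_mild", "pd_severe"),
                              tolerance_ms = 60) {
  seed <- as.integer(seed)
  ## control-group training pool for the cross-subject HMM
  pool <- lapply(seq_len(n_train), function(i)
    prepare_trial("healthy", n_strides, derive_seed(seed, i)))
  spt <- train_spt(lapply(pool, function(p)
    list(signal = p$obs, labels = p$labels)), max_iter = 25)

  per_trial <- list()
  for (pi in seq_along(presets)) {
    preset <- presets[pi]
    for (s in seq_len(n_subjects)) {
      trials <- lapply(1:3, function(k)
        prepare_trial(preset, n_strides,
                      derive_seed(seed, 100L * pi + 10L * s + k)))
      folds <- train_sst(lapply(trials, function(p)
        list(signal = p$obs, labels = p$labels)), max_iter = 25)
      for (k in 1:3) {
        p <- trials[[k]]
        ref_str <- segment_strides(p$ref)
        preds <- list(
          s_method = s_method(sagittal_gyro(p$trial$imu)),
          r_method = r_method(p$trial$imu),
          hmm_sst = folds[[k]]$decoded,
          hmm_spt = viterbi(spt, p$obs))
        for (m in names(preds)) {
          ev <- evaluate_segmentation(p$ref, preds[[m]], tolerance_ms)
          pe <- tryCatch(
            phase_errors(ref_str, segment_strides(preds[[m]])),
            error = function(e) c(LR_e = NA, FF_e = NA, PS_e = NA,
                                  Sw_e = NA, GPQI_e = NA))
          per_trial[[length(per_trial) + 1L]] <- data.frame(
            preset = preset, subject = s, trial = k, method = m,
            TPR = ev$TPR, TNR = ev$TNR, G = ev$G,
            t(pe), stringsAsFactors = FALSE)
        }
      }
    }
  }
  per_trial <- do.call(rbind, per_trial)

  acc <- do.call(rbind, lapply(split(per_trial,
                                     per_trial[c("method", "preset")]),
    function(d) data.frame(
      preset = d$preset[1], method = d$method[1],
      TPR = mean(d$TPR), TNR = mean(d$TNR), G = mean(d$G),
      performance_class = goodness(mean(d$TPR),
                                   mean(d$TNR))$performance_class,
      LR_e = mean(d$LR_e, na.rm = TRUE), FF_e = mean(d$FF_e, na.rm = TRUE),
      PS_e = mean(d$PS_e, na.rm = TRUE), Sw_e = mean(d$Sw_e, na.rm = TRUE),
      GPQI_e = mean(d$GPQI_e, na.rm = TRUE), stringsAsFactors = FALSE)))
  acc <- acc[order(match(acc$preset, presets), acc$method), ]
  rownames(acc) <- NULL

  ## GPQI group report on bilateral trials (reference labels only)
  ref_dist <- healthy_reference()
  gp <- do.call(rbind, lapply(presets, function(preset) {
    vals <- vapply(seq_len(n_gpqi), function(i) {
      bi <- generate_bilateral(gait_preset(preset), n_strides,
                               seed = derive_seed(seed, 500L +
                                 50L * match(preset, presets) + i))
      sl <- segment_strides(reference_sequence(bi$left$fsw))
      sr <- segment_strides(reference_sequence(bi$right$fsw))
      gpqi_trial(sl, sr, ref_dist)$gpqi
    }, numeric(1))
    data.frame(preset = preset, trial = seq_len(n_gpqi), gpqi = vals,
               stringsAsFactors = FALSE)
  }))
  auc <- NULL
  if ("healthy" %in% presets && length(presets) > 1L) {
    h <- gp$gpqi[gp$preset == "healthy"]
    auc <- vapply(setdiff(presets, "healthy"), function(preset)
      roc_auc(gp$gpqi[gp$preset == preset], h), numeric(1))
  }
  structure(list(accuracy = acc, per_trial = per_trial, gpqi = gp,
                 auc = auc, spt_model = spt, seed = seed),
            class = "gait_pipeline")
}

#' @export
print.gait_pipeline <- function(x, ...) {
  cat("synthetic gait benchmark (seed", x$seed, ")\n\n")
  cat("Accuracy by method and preset (means over trials):\n")
  d <- x$accuracy
  d[c("TPR", "TNR", "G")] <- lapply(d[c("TPR", "TNR", "G")], round, 3)
  d[c("LR_e", "FF_e", "PS_e", "Sw_e", "GPQI_e")] <-
    lapply(d[c("LR_e", "FF_e", "PS_e", "Sw_e", "GPQI_e")], round, 2)
  print(d, row.names = FALSE)
  cat("\nGPQI group means [%]:\n")
  agg <- stats::aggregate(gpqi ~ preset, x$gpqi, mean)
  print(agg, row.names = FALSE)
  if (!is.null(x$auc)) {
    cat("\nGPQI AUC vs healthy [%]:\n")
    print(round(x$auc, 1))
  }
  invisible(x)
}

#' Healthy-cohort benchmark of the four partitioning methods
#'
#' The standard synthetic benchmark: a seeded cohort of healthy-preset
#' trials. The cross-subject HMM is trained on the first
#' \code{n_train} trials and decodes the remaining test trials; the
#' gyroscope and accelerometer threshold detectors run on the same test
#' trials; the subject-specific HMM uses \code{n_subjects_sst} separate
#' synthetic subjects with 3 trials each under leave-one-trial-out
#' rotation. All methods are scored against the footswitch reference
#' with the centered 60 ms tolerance window.
#'
#' @param seed Master seed.
#' @param n_trials Cohort size (training + test). Default 20.
#' @param n_train Trials used to train the cross-subject HMM. Default 10.
#' @param n_strides Strides per trial. Default 30.
#' @param n_subjects_sst Subjects for the leave-one-trial-out HMM.
#' @param tolerance_ms Tolerance window, ms. Default 60.
#' @return List with \code{mean_G} (named: s_method, r_method, hmm_sst,
#'   hmm_spt), \code{per_trial_G}, and the number of test trials.
#' @export
benchmark_healthy_cohort <- function(seed = 1, n_trials = 20, n_train = 10,
                                     n_strides = 30, n_subjects_sst = 5,
                                     tolerance_ms = 60) {
  seed <- as.integer(seed)
  cohort <- lapply(seq_len(n_trials), function(i)
    prepare_trial("healthy", n_strides, derive_seed(seed, i)))
  spt <- train_spt(lapply(cohort[seq_len(n_train)], function(p)
    list(signal = p$obs, labels = p$labels)), max_iter = 25)
  test <- cohort[(n_train + 1L):n_trials]
  g_spt <- vapply(test, function(p)
    evaluate_segmentation(p$ref, viterbi(spt, p$obs), tolerance_ms)$G,
    numeric(1))
  g_s <- vapply(test, function(p)
    evaluate_segmentation(p$ref, s_method(sagittal_gyro(p$trial$imu)),
                          tolerance_ms)$G, numeric(1))
  g_r <- vapply(test, function(p)
    evaluate_segmentation(p$ref, r_method(p$trial$imu), tolerance_ms)$G,
    numeric(1))
  g_sst <- unlist(lapply(seq_len(n_subjects_sst), function(s) {
    trials <- lapply(1:3, function(k)
      prepare_trial("healthy", n_strides, derive_seed(seed, 400L + 10L * s + k)))
    folds <- train_sst(lapply(trials, function(p)
      list(signal = p$obs, labels = p$labels)), max_iter = 25)
    vapply(1:3, function(k)
      evaluate_segmentation(trials[[k]]$ref, folds[[k]]$decoded,
                            tolerance_ms)$G, numeric(1))
  }))
  list(mean_G = c(s_method = mean(g_s), r_method = mean(g_r),
                  hmm_sst = mean(g_sst), hmm_spt = mean(g_spt)),
       per_trial_G = list(s_method = g_s, r_method = g_r,
                          hmm_sst = g_sst, hmm_spt = g_spt),
       n_test = length(test))
}
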