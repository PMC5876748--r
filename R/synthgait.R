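## Synthetic gait trials with exact ground truth.
##
## One stride is laid out as HS -> TS -> HO -> TO -> next HS with phase
## durations drawn per stride. The sagittal (pitch) angular velocity is a
## superposition of asymmetric Gaussian bumps per stride: a negative trough
## at heel strike, a negative trough at toe off and a positive mid-swing
## peak, with near-zero angular velocity during flat foot. Bump widths are
## solved so that |w| crosses the 30 deg/s stasis level at the true toe
## strike and heel off instants, which is what the gyroscope threshold
## detector keys on. Footswitch channels follow the contact logic of the
## four-phase model exactly (heel closed during LR+FF, forefoot during
## FF+PS, nothing during swing) before optional chatter noise.

#' Gait profile for the synthetic generator
#'
#' Describes the statistical gait pattern a synthetic trial is drawn from.
#' The default values are the healthy preset; see \code{\link{gait_preset}}.
#'
#' @param phase_fractions Mean phase percentages (LR, FF, PS, Sw), must sum
#'   to 100.
#' @param stride_time_s Mean stride duration, seconds.
#' @param fraction_jitter_sd Per-stride SD of the phase percentages; length
#'   1 or 4 (percent).
#' @param stride_time_jitter_sd Per-stride SD of stride duration, seconds.
#' @param gyro_noise_sd White noise SD added to gyroscope channels, deg/s.
#' @param accel_noise_sd White noise SD on accelerometer channels, m/s^2.
#' @param tremor_amp Amplitude of an additive tremor sinusoid, deg/s.
#' @param tremor_hz Tremor frequency, Hz (parkinsonian rest tremor band).
#' @param peak_amps Named amplitudes (HS, TO, MS) of the heel-strike trough,
#'   toe-off trough and mid-swing peak, deg/s; each must exceed 30 deg/s.
#' @param chatter_prob Probability that a footswitch contact edge picks up
#'   chatter (brief spurious flips within 3 samples of the edge).
#' @param seed Default RNG seed used by \code{\link{generate_trial}}.
#' @return Object of class \code{"gait_profile"}.
#' @export
gait_profile <- function(phase_fractions = c(LR = 6.9, FF = 39.4,
                                             PS = 16.2, Sw = 37.7),
                         stride_time_s = 1.1,
                         fraction_jitter_sd = c(0.7, 2.3, 1.8, 0.9),
                         stride_time_jitter_sd = 0.03,
                         gyro_noise_sd = 5,
                         accel_noise_sd = 0.08,
                         tremor_amp = 0,
                         tremor_hz = 5,
                         peak_amps = c(HS = 100, TO = 200, MS = 400),
                         chatter_prob = 0,
                         seed = NULL) {
  phase_fractions <- as.numeric(phase_fractions)
  if (length(phase_fractions) != 4L || any(phase_fractions <= 0))
    stop("'phase_fractions' must be 4 positive percentages")
  ## printed phase distributions carry rounding; tolerate it and
  ## renormalize when durations are drawn
  if (abs(sum(phase_fractions) - 100) > 0.25)
    stop("'phase_fractions' must sum to 100")
  if (stride_time_s <= 0) stop("'stride_time_s' must be positive")
  fraction_jitter_sd <- rep_len(as.numeric(fraction_jitter_sd), 4L)
  sds <- c(fraction_jitter_sd, stride_time_jitter_sd, gyro_noise_sd,
           accel_noise_sd, tremor_amp)
  if (any(sds < 0)) stop("jitter/noise parameters must be >= 0")
  peak_amps <- as.numeric(peak_amps)
  if (length(peak_amps) != 3L || any(peak_amps <= 30))
    stop("'peak_amps' must be 3 amplitudes above the 30 deg/s stasis level")
  if (chatter_prob < 0 || chatter_prob > 1) stop("invalid 'chatter_prob'")
  structure(list(phase_fractions = phase_fractions,
                 stride_time_s = stride_time_s,
                 fraction_jitter_sd = fraction_jitter_sd,
                 stride_time_jitter_sd = stride_time_jitter_sd,
                 gyro_noise_sd = gyro_noise_sd,
                 accel_noise_sd = accel_noise_sd,
                 tremor_amp = tremor_amp, tremor_hz = tremor_hz,
                 peak_amps = peak_amps, chatter_prob = chatter_prob,
                 seed = seed),
            class = "gait_profile")
}

#' Named gait profile presets
#'
#' \code{"healthy"} uses the control-group phase distribution
#' (6.9, 39.4, 16.2, 37.7)\%. The parkinsonian presets shift mass from
#' swing and pre-swing into flat foot, the hallmark of hobbling/shuffling
#' gait: \code{"pd_mild"} moves 4 points into FF; \code{"pd_severe"} uses
#' (8, 48, 12, 32)\% with slower strides, weaker angular-velocity peaks and
#' a 5 Hz tremor component. The parkinsonian numbers are plausibility
#' choices for synthetic benchmarking, not measured patient values.
#'
#' @param name One of \code{"healthy"}, \code{"pd_mild"}, \code{"pd_severe"}.
#' @return A \code{\link{gait_profile}}.
#' @examples
#' gait_preset("healthy")$phase_fractions
#' @export
gait_preset <- function(name = c("healthy", "pd_mild", "pd_severe")) {
  name <- match.arg(name)
  switch(name,
    healthy = gait_profile(),
    pd_mild = gait_profile(
      phase_fractions = c(LR = 6.9, FF = 43.4, PS = 14.2, Sw = 35.7),
      stride_time_s = 1.15),
    pd_severe = gait_profile(
      phase_fractions = c(LR = 8, FF = 48, PS = 12, Sw = 32),
      stride_time_s = 1.25,
      peak_amps = c(HS = 70, TO = 140, MS = 280),
      tremor_amp = 15, tremor_hz = 5,
      gyro_noise_sd = 6))
}

## asymmetric generalized-Gaussian bump: width and shape exponent may
## differ left and right of the center; p > 2 flattens the core and
## steepens the tail (used where a threshold crossing must be sharp)
asym_bump <- function(t, center, amp, sl, sr, pl = 2, pr = 2) {
  d <- t - center
  s <- ifelse(d < 0, sl, sr)
  p <- ifelse(d < 0, pl, pr)
  amp * exp(-0.5 * abs(d / s)^p)
}

## width so that |bump| = level at distance d from the center
bump_sigma <- function(d, amp, level = 30, p = 2)
  d / (2 * log(amp / level))^(1 / p)

#' Generate one synthetic walking trial
#'
#' Draws per-stride phase durations from the profile, builds the gyroscope
#' and accelerometer channels from the stride template, renders the four
#' footswitch contact channels, and returns the exact ground truth. The
#' trial starts at the first heel strike and ends on a flat foot 0.5 s
#' after the last one. All randomness comes from \code{seed} (falling back
#' to \code{profile$seed}); a fixed seed gives identical output.
#'
#' @param profile A \code{\link{gait_profile}}.
#' @param n_strides Number of complete strides (>= 1).
#' @param side \code{"left"} or \code{"right"}.
#' @param seed RNG seed; overrides \code{profile$seed} when given.
#' @param imu_rate IMU sampling rate, Hz (nominal hardware rate 50).
#' @param fsw_rate Footswitch sampling rate, Hz (nominal 2000).
#' @param truth_rate Grid for the ground-truth label sequence, Hz.
#' @return List with elements \code{imu} (\code{\link{imu_recording}}),
#'   \code{fsw} (\code{\link{fsw_recording}}) and \code{truth}, itself a
#'   list with the exact \code{events} table, the per-sample
#'   \code{\link{phase_sequence}} \code{phases}, and the per-stride drawn
#'   \code{fractions} matrix.
#' @export
generate_trial <- function(profile, n_strides, side = "right",
                           seed = profile$seed,
                           imu_rate = 50, fsw_rate = 2000,
                           truth_rate = 200) {
  stopifnot(inherits(profile, "gait_profile"), n_strides >= 1)
  side <- match.arg(side, c("left", "right"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  p <- profile
  ## per-stride stride times and phase fractions
  st <- stats::rnorm(n_strides, p$stride_time_s, p$stride_time_jitter_sd)
  st <- pmax(st, 0.5 * p$stride_time_s)
  fr <- matrix(stats::rnorm(4L * n_strides, rep(p$phase_fractions,
                                                each = n_strides),
                            rep(p$fraction_jitter_sd, each = n_strides)),
               n_strides, 4L)
  fr <- pmax(fr, 1)                       # phases never vanish
  fr <- fr / rowSums(fr) * 100            # renormalize after jitter
  colnames(fr) <- gait_phases()

  hs <- c(0, cumsum(st))                  # n_strides + 1 heel strikes
  dur <- fr / 100 * st                    # per-stride phase durations, s
  ts_t <- hs[seq_len(n_strides)] + dur[, 1]
  ho_t <- ts_t + dur[, 2]
  to_t <- ho_t + dur[, 3]
  ## terminal partial cycle: last HS then toe strike, flat to the end
  last_ts <- hs[n_strides + 1L] + p$phase_fractions[1] / 100 * p$stride_time_s
  t_end <- hs[n_strides + 1L] + 0.5

  events <- data.frame(
    type = c(rep(gait_events(), n_strides), "HS", "TS"),
    time = c(as.vector(rbind(hs[seq_len(n_strides)], ts_t, ho_t, to_t)),
             hs[n_strides + 1L], last_ts),
    stringsAsFactors = FALSE)
  events$side <- side

  amps <- p$peak_amps                     # (HS, TO, MS)
  template <- function(t) {
    w <- numeric(length(t))
    for (k in seq_len(n_strides)) {
      lr <- dur[k, 1]; ps <- dur[k, 3]; sw <- dur[k, 4]
      ## HS trough: peak foot-slap velocity lags initial contact by
      ## a few ms; fast onset on the left, steep-tailed right side whose
      ## 30 deg/s crossing falls at toe strike
      w <- w + asym_bump(t, hs[k] + 0.005, -amps[1], 0.012,
                         bump_sigma(lr - 0.005, amps[1], p = 4), 2, 4)
      ## TO trough: V-shaped, left width solved so the 30 deg/s
      ## crossing falls at heel off
      w <- w + asym_bump(t, to_t[k] - 0.005, -amps[2],
                         bump_sigma(ps - 0.005, amps[2]), 0.015, 2, 2)
      ## swing: rise starts right at toe off, the plateau holds until
      ## late swing and collapses just before the next contact
      w <- w + asym_bump(t, to_t[k] + 0.5 * sw, amps[3], 0.2 * sw,
                         (0.5 * sw - 0.02) /
                           (2 * log(amps[3] / 50))^0.25, 2, 4)
    }
    lr_f <- p$phase_fractions[1] / 100 * p$stride_time_s
    w + asym_bump(t, hs[n_strides + 1L] + 0.005, -amps[1], 0.012,
                  bump_sigma(lr_f - 0.005, amps[1], p = 4), 2, 4)
  }
  accel_norm <- function(t) {
    a <- rep(9.81, length(t))
    for (k in seq_len(n_strides)) {
      sw <- dur[k, 4]
      a <- a + asym_bump(t, hs[k] + 0.01, 8, 0.012, 0.02) +    # impact spike
        asym_bump(t, ho_t[k] + 0.03, 1.8, 0.04, 0.05) +        # heel-off rise
        asym_bump(t, to_t[k] - 0.02, 5, 0.05, 0.04) +          # push-off
        asym_bump(t, to_t[k] + 0.5 * sw, -1.6, sw / 6, sw / 6) # swing dip
    }
    a + asym_bump(t, hs[n_strides + 1L] + 0.01, 8, 0.012, 0.02)
  }

  ## IMU channels
  ti <- seq(0, t_end, by = 1 / imu_rate)
  gz <- template(ti)
  if (p$tremor_amp > 0)
    gz <- gz + p$tremor_amp * sin(2 * pi * p$tremor_hz * ti +
                                    stats::runif(1, 0, 2 * pi))
  gz <- gz + stats::rnorm(length(ti), 0, p$gyro_noise_sd)
  gx <- 0.1 * gz + stats::rnorm(length(ti), 0, p$gyro_noise_sd)
  gy <- stats::rnorm(length(ti), 0, p$gyro_noise_sd)
  nrm <- accel_norm(ti)
  tilt <- 0.25 * template(ti) / max(abs(template(ti)))  # smooth pitch proxy
  ax <- nrm * sin(tilt) + stats::rnorm(length(ti), 0, p$accel_noise_sd)
  az <- nrm * cos(tilt) + stats::rnorm(length(ti), 0, p$accel_noise_sd)
  ay <- stats::rnorm(length(ti), 0, p$accel_noise_sd)
  imu <- imu_recording(side, cbind(gx, gy, gz), cbind(ax, ay, az), imu_rate)

  ## footswitch contact logic: heel closed on [HS, HO), forefoot on [TS, TO)
  tf <- seq(0, t_end, by = 1 / fsw_rate)
  heel <- fore <- logical(length(tf))
  for (k in seq_len(n_strides)) {
    heel <- heel | (tf >= hs[k] & tf < ho_t[k])
    fore <- fore | (tf >= ts_t[k] & tf < to_t[k])
  }
  heel <- heel | tf >= hs[n_strides + 1L]
  fore <- fore | tf >= last_ts
  contacts <- cbind(heel = heel, mt1 = fore, mt5 = fore, toe = fore)
  if (p$chatter_prob > 0) contacts <- apply(contacts, 2L, add_chatter,
                                            prob = p$chatter_prob)
  ## analog force: closed contact near 1, open near 0
  force <- contacts * (1 + stats::rnorm(length(contacts), 0, 0.03)) +
    (!contacts) * abs(stats::rnorm(length(contacts), 0, 0.02))
  fsw <- fsw_recording(side, force, fsw_rate)

  n_truth <- floor(t_end * truth_rate) + 1L
  phases <- labels_from_events(events, n_truth, truth_rate)
  list(imu = imu, fsw = fsw,
       truth = list(events = events, phases = phases, fractions = fr,
                    stride_times = st))
}

## flip short bursts around contact edges; each edge independently chattered
add_chatter <- function(contact, prob) {
  edges <- which(diff(contact) != 0)
  n <- length(contact)
  for (e in edges) {
    if (stats::runif(1) < prob) {
      off <- sample(-3:3, 1L)
      len <- sample(1:3, 1L)
      i <- (e + off):(e + off + len - 1L)
      i <- i[i >= 1L & i <= n]
      contact[i] <- !contact[i]
    }
  }
  contact
}

#' Generate a bilateral trial
#'
#' Generates the two feet of one walking trial: independent stride draws
#' per side, with the left foot's events offset by half a stride so the
#' feet alternate as in real gait.
#'
#' @inheritParams generate_trial
#' @param seed RNG seed; the two sides use derived sub-seeds.
#' @return List with elements \code{left} and \code{right}, each as
#'   returned by \code{\link{generate_trial}}.
#' @export
generate_bilateral <- function(profile, n_strides, seed = profile$seed, ...) {
  if (is.null(seed)) seed <- 0L
  right <- generate_trial(profile, n_strides, "right", seed = seed, ...)
  left <- generate_trial(profile, n_strides, "left", seed = seed + 1L, ...)
  shift <- profile$stride_time_s / 2
  left$truth$events$time <- left$truth$events$time + shift
  left$truth$phases$t0 <- left$truth$phases$t0 + shift
  left$truth$phases$events$time <- left$truth$phases$events$time + shift
  left$imu$t0 <- left$imu$t0 + shift
  left$fsw$t0 <- left$fsw$t0 + shift
  list(left = left, right = right)
}
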