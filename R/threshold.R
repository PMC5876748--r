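## Threshold-based gait partitioning.
##
## S-method: the foot is near-still during flat foot, so |sagittal angular
## velocity| staying under a 30 deg/s stasis level marks the flat-foot
## core; heel off / toe strike are the crossings out of / into stasis, toe
## off and heel strike are the two clockwise (negative) troughs flanking
## the mid-swing peak.
##
## R-method: works on the low-pass filtered resultant acceleration (c50)
## and its first and second derivatives; two moving averages of the
## resultant (long window cA200, short window cA50) act as constraining
## bands that select which turning and inflection points are gait events.

## local maxima above min_height, at least min_dist samples apart
## (greedy from the highest peak down)
find_peaks <- function(x, min_height, min_dist) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand)
    if (!length(keep) || all(abs(keep - i) >= min_dist)) keep <- c(keep, i)
  sort(keep)
}

## runs of TRUE at least min_len long, as a matrix of (start, end) indices
true_runs <- function(flag, min_len = 1L) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values & r$lengths >= min_len
  cbind(start = starts[sel], end = ends[sel])
}

empty_phase_sequence <- function(n, rate, t0) {
  phase_sequence(rep("Sw", n), rate, t0,
                 events = data.frame(type = character(0), time = numeric(0),
                                     stringsAsFactors = FALSE))
}

#' Gyroscope stasis-threshold gait partitioning (S-method)
#'
#' Detects the four gait events from the sagittal angular velocity of the
#' foot. The signal is low-pass filtered (2nd order Butterworth,
#' \code{lowpass_hz}); cycles are anchored at the positive mid-swing
#' peaks. Within each cycle the longest run with
#' \code{|w| < stasis_threshold} is the flat-foot core: heel off is the
#' first sample after it where \code{|w|} exceeds the threshold, toe off
#' the most negative extremum between heel off and the next mid-swing
#' peak, heel strike the negative trough after the mid-swing peak (the
#' second clockwise extremum, counting toe off as the first), and toe
#' strike the first sample after heel strike where \code{|w|} drops below
#' the threshold and stays there for \code{min_phase_ms}.
#'
#' @param gyro_sagittal A \code{\link{uniform_series}} of sagittal angular
#'   velocity in deg/s (positive at the mid-swing peak; see
#'   \code{flip_sign}).
#' @param stasis_threshold Stasis level in deg/s. Default 30.
#' @param lowpass_hz Low-pass cutoff, Hz. Default 15.
#' @param midswing_min_peak Minimum mid-swing peak height, deg/s. Default 50.
#' @param min_phase_ms Minimum sub-threshold dwell for toe strike, ms.
#'   Default 40.
#' @param flip_sign Set TRUE for sensors mounted with the opposite
#'   handedness (negates the signal first).
#' @return A \code{\link{phase_sequence}} on the input grid; empty (all
#'   swing, no events) with a warning when no mid-swing peak is found.
#' @export
s_method <- function(gyro_sagittal, stasis_threshold = 30, lowpass_hz = 15,
                     midswing_min_peak = 50, min_phase_ms = 40,
                     flip_sign = FALSE) {
  stopifnot(inherits(gyro_sagittal, "uniform_series"))
  x <- gyro_sagittal
  if (flip_sign) x$samples <- -x$samples
  w <- lowpass(x, lowpass_hz)$samples
  rate <- x$rate
  n <- length(w)
  min_dwell <- max(1L, round(min_phase_ms * rate / 1000))
  peaks <- find_peaks(w, midswing_min_peak, round(0.3 * rate))
  if (!length(peaks)) {
    warning("no mid-swing peak found; returning empty sequence")
    return(empty_phase_sequence(n, rate, x$t0))
  }
  bounds <- c(1L, peaks, n)
  ev_type <- character(0); ev_idx <- integer(0)
  add <- function(type, idx) { ev_type <<- c(ev_type, type)
                               ev_idx <<- c(ev_idx, idx) }
  for (j in seq_len(length(bounds) - 1L)) {
    a <- bounds[j]; b <- bounds[j + 1L]
    seg <- a:b
    runs <- true_runs(abs(w[seg]) < stasis_threshold, min_dwell)
    if (!nrow(runs)) next
    core <- runs[which.max(runs[, 2] - runs[, 1]), ]
    st_start <- seg[core[1]]; st_end <- seg[core[2]]
    ## heel strike: trough between the left cycle boundary and stasis
    if (st_start - a >= 2L) {
      hs <- a + which.min(w[a:st_start]) - 1L
      if (w[hs] < -stasis_threshold) {
        add("HS", hs)
        ## toe strike: first durable sub-threshold sample after HS
        below <- abs(w[hs:st_end]) < stasis_threshold
        runs_b <- true_runs(below, min_dwell)
        if (nrow(runs_b)) add("TS", hs + runs_b[1, 1] - 1L)
      }
    }
    ## heel off: first crossing above threshold after the stasis core;
    ## toe off: most negative extremum before the next mid-swing peak
    if (st_end < b && j < length(bounds) - 1L) {
      ho <- st_end + 1L
      add("HO", ho)
      to <- ho + which.min(w[ho:b]) - 1L
      if (w[to] < -stasis_threshold) add("TO", to)
    }
  }
  if (!length(ev_idx)) {
    warning("no gait events detected; returning empty sequence")
    return(empty_phase_sequence(n, rate, x$t0))
  }
  ord <- order(ev_idx)
  events <- data.frame(type = ev_type[ord],
                       time = x$t0 + (ev_idx[ord] - 1L) / rate,
                       stringsAsFactors = FALSE)
  labels_from_events(events, n, rate, x$t0)
}

#' R-method configuration
#'
#' @param lowpass_hz Butterworth cutoff on the resultant acceleration, Hz.
#' @param ma_long_s Long moving-average window (cA200), s.
#' @param ma_short_s Short moving-average window (cA50), s.
#' @param quiescence_band Allowed deviation of c50 from cA200 during flat
#'   foot, m/s^2.
#' @param quiescence_min_ms Minimum flat-foot dwell, ms.
#' @param derivative_eps Maximum |d1| during flat foot, m/s^3.
#' @return List of class \code{"r_method_config"}.
#' @export
r_method_config <- function(lowpass_hz = 6, ma_long_s = 1.25,
                            ma_short_s = 0.30, quiescence_band = 1.0,
                            quiescence_min_ms = 100, derivative_eps = 5.0) {
  stopifnot(lowpass_hz > 0, ma_long_s > 0, ma_short_s > 0,
            quiescence_band > 0, quiescence_min_ms > 0, derivative_eps > 0)
  structure(as.list(environment()), class = "r_method_config")
}

#' Reference signals of the accelerometer detector
#'
#' Computes the five working signals of the R-method from the two
#' sagittal-plane accelerometer channels (\code{ax}, \code{az}): the
#' Euclidean resultant filtered at \code{lowpass_hz} (c50), its first and
#' second central-difference derivatives (d1, d2), and the long and short
#' moving averages of the resultant (cA200, cA50).
#'
#' @param accel An \code{\link{imu_recording}}, or an n x 2 matrix of the
#'   two sagittal-plane acceleration channels with an attached rate.
#' @param cfg An \code{\link{r_method_config}}.
#' @param rate Required when \code{accel} is a plain matrix.
#' @param target_rate Common evaluation grid, Hz. Default 200.
#' @return List of \code{uniform_series}: \code{c50}, \code{d1},
#'   \code{d2}, \code{cA200}, \code{cA50}.
#' @export
r_method_signals <- function(accel, cfg = r_method_config(), rate = NULL,
                             target_rate = 200) {
  if (inherits(accel, "imu_recording")) {
    m <- accel$accel[, c("ax", "az")]
    rate <- accel$rate; t0 <- accel$t0
  } else {
    m <- as.matrix(accel); t0 <- 0
    if (is.null(rate)) stop("'rate' required for matrix input")
    if (ncol(m) < 2L) stop("need the two sagittal-plane channels")
  }
  res <- sqrt(m[, 1]^2 + m[, 2]^2)
  s <- uniform_series(res, rate, t0)
  if (rate != target_rate) s <- resample_series(s, target_rate, "linear")
  c50 <- lowpass(s, cfg$lowpass_hz)
  d1 <- central_diff(c50)
  d2 <- central_diff(d1)
  list(c50 = c50, d1 = d1, d2 = d2,
       cA200 = moving_average(s, cfg$ma_long_s),
       cA50 = moving_average(s, cfg$ma_short_s))
}

## central difference derivative, one-sided at the edges
central_diff <- function(x) {
  v <- x$samples; n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) * x$rate / 2
  d[1] <- (v[2] - v[1]) * x$rate
  d[n] <- (v[n] - v[n - 1]) * x$rate
  uniform_series(d, x$rate, x$t0)
}

## indices where v changes sign (reported at the left sample)
zero_crossings <- function(v) {
  s <- sign(v)
  which(s[-length(s)] * s[-1] < 0)
}

## morphological closing on a logical vector: fill FALSE gaps <= max_gap
close_gaps <- function(flag, max_gap) {
  if (max_gap < 1L) return(flag)
  r <- rle(flag)
  fill <- !r$values & r$lengths <= max_gap
  fill[1L] <- FALSE; fill[length(fill)] <- FALSE
  r$values[fill] <- TRUE
  inverse.rle(r)
}

#' Accelerometer turning/inflection-point gait partitioning (R-method)
#'
#' Identifies flat-foot cores as intervals where the filtered resultant
#' acceleration hugs its long moving average (\code{|c50 - cA200| <
#' quiescence_band}) with small first derivative, for at least
#' \code{quiescence_min_ms}. Heel off is the end of a core refined to the
#' nearest inflection point (d2 zero crossing); toe off the first turning
#' point (d1 zero crossing at a local maximum of c50) after heel off; heel
#' strike the largest turning point exceeding the short moving average
#' cA50 before the next core; toe strike the first inflection point after
#' heel strike where c50 falls back below cA50.
#'
#' @inheritParams r_method_signals
#' @return A \code{\link{phase_sequence}} at \code{target_rate}; empty
#'   (all swing, no events) with a warning when no quiescent interval is
#'   found.
#' @export
r_method <- function(accel, cfg = r_method_config(), rate = NULL,
                     target_rate = 200) {
  sig <- r_method_signals(accel, cfg, rate, target_rate)
  c50 <- sig$c50$samples; d1 <- sig$d1$samples; d2 <- sig$d2$samples
  ca200 <- sig$cA200$samples; ca50 <- sig$cA50$samples
  fs <- sig$c50$rate; t0 <- sig$c50$t0
  n <- length(c50)
  min_q <- max(1L, round(cfg$quiescence_min_ms * fs / 1000))
  quiet <- abs(c50 - ca200) < cfg$quiescence_band & abs(d1) < cfg$derivative_eps
  quiet <- close_gaps(quiet, round(0.08 * fs))
  cores <- true_runs(quiet, min_q)
  if (!nrow(cores)) {
    warning("no quiescent interval found; returning empty sequence")
    return(empty_phase_sequence(n, fs, t0))
  }
  infl <- zero_crossings(d2)
  ## turning points that are local maxima: d1 crosses from + to -
  turn_max <- which(d1[-n] > 0 & d1[-1] <= 0)
  ev_type <- character(0); ev_idx <- integer(0)
  add <- function(type, idx) { ev_type <<- c(ev_type, type)
                               ev_idx <<- c(ev_idx, idx) }
  for (j in seq_len(nrow(cores))) {
    q_end <- cores[j, 2]
    nxt <- if (j < nrow(cores)) cores[j + 1L, 1] else n
    ## heel off: the quiescent core ends at the onset of the heel-lift
    ## rise; snap forward to the steepest-rise inflection (d2 zero
    ## crossing with clearly positive slope) within the next 250 ms
    near <- infl[infl > q_end & infl <= q_end + round(0.25 * fs)]
    near <- near[d1[near] > cfg$derivative_eps]
    if (!length(near)) next                 # no heel lift: still standing
    ho <- near[1L]
    add("HO", ho)
    ## push-off: first turning point (local max of c50) after heel off;
    ## toe off is the descent inflection that follows it
    cand <- turn_max[turn_max > ho + 2L & turn_max < nxt]
    cand <- cand[c50[cand] > ca50[cand]]
    if (!length(cand)) next
    push <- cand[1L]
    dsc <- infl[infl > push & infl < nxt]
    to <- if (length(dsc)) dsc[1L] else push
    add("TO", to)
    ## heel strike: largest turning point above cA50 before the next core
    cand <- turn_max[turn_max > to + 2L & turn_max < nxt]
    cand <- cand[c50[cand] > ca50[cand]]
    if (!length(cand)) next
    hs <- cand[which.max(c50[cand])]
    add("HS", hs)
    ## toe strike: impact transient over -- first downward crossing of c50
    ## below the short moving average after heel strike
    cand <- which(c50[-n] >= ca50[-n] & c50[-1] < ca50[-1])
    cand <- cand[cand > hs & cand <= nxt]
    if (length(cand)) add("TS", cand[1L] + 1L)
  }
  if (!length(ev_idx)) {
    warning("no gait events detected; returning empty sequence")
    return(empty_phase_sequence(n, fs, t0))
  }
  ord <- order(ev_idx)
  events <- data.frame(type = ev_type[ord],
                       time = t0 + (ev_idx[ord] - 1L) / fs,
                       stringsAsFactors = FALSE)
  labels_from_events(events, n, fs, t0)
}

#' Sagittal angular velocity on the common grid
#'
#' Extracts one gyroscope axis from an IMU recording and resamples it to
#' the common evaluation rate. By default the axis with the largest
#' variance is taken as sagittal, which holds during straight walking.
#'
#' @param imu An \code{\link{imu_recording}}.
#' @param axis \code{"gx"}, \code{"gy"}, \code{"gz"} or \code{"auto"}
#'   (maximal variance).
#' @param target_rate Hz, default 200.
#' @param flip_sign Negate the channel (opposite-handed mounting).
#' @return A \code{\link{uniform_series}}.
#' @export
sagittal_gyro <- function(imu, axis = "auto", target_rate = 200,
                          flip_sign = FALSE) {
  stopifnot(inherits(imu, "imu_recording"))
  if (axis == "auto") {
    axis <- colnames(imu$gyro)[which.max(apply(imu$gyro, 2L, stats::var))]
  }
  v <- imu$gyro[, axis]
  if (flip_sign) v <- -v
  s <- uniform_series(v, imu$rate, imu$t0)
  if (imu$rate != target_rate) s <- resample_series(s, target_rate, "linear")
  s
}
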