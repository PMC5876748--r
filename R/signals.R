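#' Uniformly sampled scalar series
#'
#' Lightweight container for a uniformly sampled scalar signal: a numeric
#' vector of samples, a sampling rate in Hz and the time of the first sample.
#' All filtering, resampling and detection routines in the package operate on
#' this type.
#'
#' @param samples Numeric vector of finite sample values.
#' @param rate Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds.
#' @return An object of class \code{"uniform_series"}.
#' @examples
#' s <- uniform_series(sin(2 * pi * seq(0, 1, by = 0.02)), rate = 50)
#' series_time(s)[1:3]
#' @export
uniform_series <- function(samples, rate, t0 = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("'rate' must be a single positive number (Hz)")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("samples must be finite")
  structure(list(samples = samples, rate = rate, t0 = t0),
            class = "uniform_series")
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("uniform series: %d samples @ %g Hz, t0 = %g s (%.2f s)\n",
              length(x$samples), x$rate, x$t0,
              length(x$samples) / x$rate))
  invisible(x)
}

#' Sample times of a uniform series
#' @param x A \code{uniform_series}.
#' @return Numeric vector of sample times in seconds.
#' @export
series_time <- function(x) {
  x$t0 + (seq_along(x$samples) - 1) / x$rate
}

#' Per-foot inertial recording
#'
#' Bundles the 3-axis gyroscope (deg/s) and 3-axis accelerometer (m/s^2)
#' channels of one foot-mounted inertial unit. Channels are stored as
#' numeric matrices with columns \code{gx, gy, gz} and \code{ax, ay, az};
#' all channels share the sampling rate and start time.
#'
#' @param side \code{"left"} or \code{"right"}.
#' @param gyro Numeric matrix, n x 3, angular velocity in deg/s.
#' @param accel Numeric matrix, n x 3, acceleration in m/s^2.
#' @param rate Sampling rate in Hz.
#' @param t0 Start time in seconds.
#' @return An object of class \code{"imu_recording"}.
#' @export
imu_recording <- function(side, gyro, accel, rate, t0 = 0) {
  side <- match.arg(side, c("left", "right"))
  gyro <- as.matrix(gyro); accel <- as.matrix(accel)
  if (ncol(gyro) != 3L || ncol(accel) != 3L)
    stop("gyro and accel must each have 3 channels")
  if (nrow(gyro) != nrow(accel))
    stop("gyro and accel must have equal length")
  if (!all(is.finite(gyro)) || !all(is.finite(accel)))
    stop("samples must be finite")
  if (rate <= 0) stop("'rate' must be positive")
  colnames(gyro) <- c("gx", "gy", "gz")
  colnames(accel) <- c("ax", "ay", "az")
  structure(list(side = side, gyro = gyro, accel = accel,
                 rate = rate, t0 = t0),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("IMU recording (%s foot): %d samples @ %g Hz (%.2f s)\n",
              x$side, nrow(x$gyro), x$rate, nrow(x$gyro) / x$rate))
  invisible(x)
}

#' Per-foot footswitch recording
#'
#' Four contact channels per foot — heel, first metatarsophalangeal, fifth
#' metatarsophalangeal, toe — either analog force readings or binary contact
#' states. The reference phase sequence is derived from these channels.
#'
#' @param side \code{"left"} or \code{"right"}.
#' @param channels Numeric matrix, n x 4, columns \code{heel, mt1, mt5, toe}.
#' @param rate Sampling rate in Hz.
#' @param t0 Start time in seconds.
#' @return An object of class \code{"fsw_recording"}.
#' @export
fsw_recording <- function(side, channels, rate, t0 = 0) {
  side <- match.arg(side, c("left", "right"))
  channels <- as.matrix(channels)
  if (ncol(channels) != 4L) stop("footswitch recording needs 4 channels")
  if (!all(is.finite(channels))) stop("samples must be finite")
  if (rate <= 0) stop("'rate' must be positive")
  colnames(channels) <- c("heel", "mt1", "mt5", "toe")
  structure(list(side = side, channels = channels, rate = rate, t0 = t0),
            class = "fsw_recording")
}

#' @export
print.fsw_recording <- function(x, ...) {
  cat(sprintf("footswitch recording (%s foot): %d samples @ %g Hz (%.2f s)\n",
              x$side, nrow(x$channels), x$rate, nrow(x$channels) / x$rate))
  invisible(x)
}

## rate inference shared by the two readers: median time step, 1% jitter limit
infer_rate <- function(time) {
  if (length(time) < 2L) stop("need at least 2 samples to infer a rate")
  dt <- diff(time)
  if (any(dt <= 0)) stop("time column must be strictly increasing")
  med <- stats::median(dt)
  if (any(abs(dt - med) > 0.01 * med))
    stop("non-uniform sampling: time steps deviate more than 1% from median")
  1 / med
}

#' Read an IMU recording from a delimited text file
#'
#' Expects a header row with columns \code{time, gx, gy, gz, ax, ay, az}
#' (seconds, deg/s, m/s^2). The sampling rate is inferred from the median
#' time step; files with more than 1\% timing jitter are rejected.
#'
#' @param path Path to a CSV (or \code{sep}-delimited) file.
#' @param side \code{"left"} or \code{"right"}.
#' @param sep Field separator, default comma.
#' @return An \code{\link{imu_recording}}.
#' @export
read_imu <- function(path, side, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("time", "gx", "gy", "gz", "ax", "ay", "az")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  rate <- infer_rate(d$time)
  imu_recording(side, as.matrix(d[c("gx", "gy", "gz")]),
                as.matrix(d[c("ax", "ay", "az")]), rate, t0 = d$time[1])
}

#' Read a footswitch recording from a delimited text file
#'
#' Expects a header row with columns \code{time, heel, mt1, mt5, toe}.
#' See \code{\link{read_imu}} for rate inference rules.
#'
#' @inheritParams read_imu
#' @return An \code{\link{fsw_recording}}.
#' @export
read_footswitch <- function(path, side, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("time", "heel", "mt1", "mt5", "toe")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  rate <- infer_rate(d$time)
  fsw_recording(side, as.matrix(d[c("heel", "mt1", "mt5", "toe")]),
                rate, t0 = d$time[1])
}

#' Write a recording to a delimited text file
#'
#' Inverse of \code{\link{read_imu}} / \code{\link{read_footswitch}}: writes
#' the time column followed by the channel columns, with a header row.
#'
#' @param x An \code{imu_recording} or \code{fsw_recording}.
#' @param path Output file path.
#' @param sep Field separator, default comma.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(x, path, sep = ",") {
  if (inherits(x, "imu_recording")) {
    n <- nrow(x$gyro)
    d <- data.frame(time = x$t0 + (seq_len(n) - 1) / x$rate, x$gyro, x$accel)
  } else if (inherits(x, "fsw_recording")) {
    n <- nrow(x$channels)
    d <- data.frame(time = x$t0 + (seq_len(n) - 1) / x$rate, x$channels)
  } else stop("unsupported recording type")
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a uniform series onto a new rate
#'
#' \code{mode = "linear"} interpolates between samples (analog channels);
#' \code{mode = "hold"} is a zero-order hold that takes the most recent
#' original sample, so binary-valued inputs stay binary. The output grid
#' starts at \code{t0} and covers the original time span.
#'
#' @param x A \code{uniform_series}.
#' @param target_rate New sampling rate in Hz.
#' @param mode \code{"linear"} or \code{"hold"}.
#' @return A \code{uniform_series} at \code{target_rate}.
#' @export
resample_series <- function(x, target_rate, mode = c("linear", "hold")) {
  mode <- match.arg(mode)
  if (target_rate <= 0) stop("'target_rate' must be positive")
  n <- length(x$samples)
  if (n < 2L) stop("need at least 2 samples to resample")
  t_old <- series_time(x)
  t_end <- t_old[n]
  t_new <- x$t0 + seq.int(0L, floor((t_end - x$t0) * target_rate)) / target_rate
  y <- if (mode == "linear") {
    stats::approx(t_old, x$samples, xout = t_new, rule = 2)$y
  } else {
    stats::approx(t_old, x$samples, xout = t_new, method = "constant",
                  f = 0, rule = 2)$y
  }
  uniform_series(y, target_rate, x$t0)
}

#' Filter specification
#'
#' @param kind \code{"butterworth_lowpass"} or \code{"moving_average"}.
#' @param order Filter order (Butterworth), >= 1.
#' @param cutoff_hz Cutoff frequency in Hz (Butterworth).
#' @param window_s Window length in seconds (moving average).
#' @param zero_phase Apply forward-backward for zero group delay
#'   (Butterworth only). Doubles the effective order.
#' @return A list of class \code{"filter_spec"}.
#' @export
filter_spec <- function(kind = c("butterworth_lowpass", "moving_average"),
                        order = 2, cutoff_hz = NULL, window_s = NULL,
                        zero_phase = TRUE) {
  kind <- match.arg(kind)
  if (kind == "butterworth_lowpass") {
    if (is.null(cutoff_hz) || cutoff_hz <= 0) stop("'cutoff_hz' required")
    if (order < 1) stop("'order' must be >= 1")
  } else {
    if (is.null(window_s) || window_s <= 0) stop("'window_s' required")
  }
  structure(list(kind = kind, order = order, cutoff_hz = cutoff_hz,
                 window_s = window_s, zero_phase = zero_phase),
            class = "filter_spec")
}

#' Apply a filter to a uniform series
#'
#' Butterworth low-pass filtering uses \pkg{signal}; with
#' \code{zero_phase = TRUE} the filter runs forward and backward
#' (\code{filtfilt}), giving zero group delay so event timings are not
#' biased, at the cost of doubling the effective order. The causal variant
#' (\code{zero_phase = FALSE}) suits streaming use.
#'
#' @param x A \code{uniform_series}.
#' @param spec A \code{\link{filter_spec}}.
#' @return Filtered \code{uniform_series} on the same grid.
#' @export
apply_filter <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$kind == "moving_average")
    return(moving_average(x, spec$window_s))
  nyq <- x$rate / 2
  if (spec$cutoff_hz >= nyq)
    stop(sprintf("cutoff %g Hz >= Nyquist %g Hz", spec$cutoff_hz, nyq))
  bf <- signal::butter(spec$order, spec$cutoff_hz / nyq, type = "low")
  y <- if (isTRUE(spec$zero_phase)) {
    ## odd-symmetric end padding suppresses the start-up transient of the
    ## forward-backward pass
    v <- x$samples
    n <- length(v)
    np <- min(n - 1L, max(12L, 3L * ceiling(x$rate / spec$cutoff_hz)))
    pad_l <- 2 * v[1] - v[(np + 1L):2L]
    pad_r <- 2 * v[n] - v[(n - 1L):(n - np)]
    out <- signal::filtfilt(bf, c(pad_l, v, pad_r))
    out[(np + 1L):(np + n)]
  } else as.numeric(signal::filter(bf, x$samples))
  uniform_series(y, x$rate, x$t0)
}

#' Convenience Butterworth low-pass
#'
#' @param x A \code{uniform_series}.
#' @param cutoff_hz Cutoff frequency, Hz.
#' @param order Filter order, default 2.
#' @param zero_phase Zero-phase (forward-backward) filtering, default TRUE.
#' @return Filtered \code{uniform_series}.
#' @export
lowpass <- function(x, cutoff_hz, order = 2, zero_phase = TRUE) {
  apply_filter(x, filter_spec("butterworth_lowpass", order = order,
                              cutoff_hz = cutoff_hz, zero_phase = zero_phase))
}

#' Centered moving average
#'
#' Window of \code{round(window_s * rate)} samples centered on each sample;
#' at the edges the window shrinks to the available samples, so the output
#' has the same length and a constant input passes through unchanged.
#'
#' @param x A \code{uniform_series}.
#' @param window_s Window length in seconds.
#' @return Smoothed \code{uniform_series}.
#' @export
moving_average <- function(x, window_s) {
  w <- round(window_s * x$rate)
  if (w < 1) stop("window shorter than one sample")
  n <- length(x$samples)
  half_lo <- floor((w - 1) / 2)
  half_hi <- w - 1 - half_lo
  cs <- c(0, cumsum(x$samples))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  y <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  uniform_series(y, x$rate, x$t0)
}
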