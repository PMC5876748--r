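## Reference phase sequence from footswitch contacts.
##
## Contact rules for the four phases: loading response = only the heel
## switch closed; flat foot = all four closed; pre-swing = at least one of
## toe / first / fifth metatarsus closed (heel open); swing = none closed.
## Flat foot is checked before pre-swing because its condition ("all
## closed") is the more specific one and logically implies the pre-swing
## condition.

#' Binarize analog footswitch channels
#'
#' Thresholds each channel at \code{threshold_frac} times its own robust
#' maximum (95th percentile), turning analog force readings into contact
#' states. A channel whose robust maximum is zero never closed; it is kept
#' at zero with a warning.
#'
#' @param fsw An \code{\link{fsw_recording}}.
#' @param threshold_frac Fraction of the per-channel robust maximum,
#'   in (0, 1). Default 0.10.
#' @return An \code{fsw_recording} with binary channels.
#' @export
binarize_footswitch <- function(fsw, threshold_frac = 0.10) {
  stopifnot(inherits(fsw, "fsw_recording"))
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("'threshold_frac' must be in (0, 1)")
  ch <- fsw$channels
  for (j in seq_len(ncol(ch))) {
    m <- stats::quantile(ch[, j], 0.95, names = FALSE)
    if (m <= 0) {
      warning(sprintf("channel '%s' never closes", colnames(ch)[j]))
      ch[, j] <- 0
    } else {
      ch[, j] <- as.numeric(ch[, j] >= threshold_frac * m)
    }
  }
  fsw_recording(fsw$side, ch, fsw$rate, fsw$t0)
}

#' Label gait phases from binary footswitch channels
#'
#' Applies the four-phase contact rules per sample, then merges label runs
#' shorter than \code{debounce_ms} into the preceding phase to suppress
#' switch chatter. Events are emitted at the remaining label changes;
#' transitions that do not follow the canonical cycle are flagged, not
#' dropped.
#'
#' @param fsw A binary \code{\link{fsw_recording}} (see
#'   \code{\link{binarize_footswitch}}).
#' @param debounce_ms Minimum accepted run length, milliseconds. Default 20.
#' @return A \code{\link{phase_sequence}} at the recording's rate.
#' @export
label_phases <- function(fsw, debounce_ms = 20) {
  stopifnot(inherits(fsw, "fsw_recording"))
  ch <- fsw$channels
  if (!all(ch %in% c(0, 1))) stop("channels must be binary; binarize first")
  heel <- ch[, "heel"] == 1
  fore <- ch[, "mt1"] == 1 | ch[, "mt5"] == 1 | ch[, "toe"] == 1
  all4 <- heel & ch[, "mt1"] == 1 & ch[, "mt5"] == 1 & ch[, "toe"] == 1
  lab <- ifelse(all4, "FF",
         ifelse(heel & !fore, "LR",
         ifelse(fore, "PS", "Sw")))
  lab <- debounce_labels(lab, debounce_ms * fsw$rate / 1000)
  phase_sequence(lab, fsw$rate, fsw$t0)
}

## merge runs shorter than min_len samples into the previous run,
## repeating until stable (merges can create new short runs)
debounce_labels <- function(lab, min_len) {
  if (min_len <= 1) return(lab)
  repeat {
    r <- rle(lab)
    short <- which(r$lengths < min_len)
    short <- short[short > 1L]
    if (!length(short)) break
    r$values[short[1L]] <- r$values[short[1L] - 1L]
    lab <- inverse.rle(r)
  }
  lab
}

#' Per-stride phase percentages
#'
#' Segments a phase sequence into gait cycles (heel strike to next heel
#' strike), drops \code{discard_ends} cycles at each end to avoid gait
#' initiation/termination effects (default 3), and computes each phase's
#' share of the cycle in percent. Strides whose internal phase order is
#' not the canonical LR, FF, PS, Sw are excluded from the table (their
#' count is kept in the \code{"n_excluded"} attribute) but their events
#' remain available in the input sequence.
#'
#' @param seq A \code{\link{phase_sequence}}.
#' @param discard_ends Cycles discarded at each end. Default 3.
#' @return Data frame of class \code{"stride_phases"} with columns
#'   \code{stride}, \code{t_start}, \code{t_end}, \code{LR}, \code{FF},
#'   \code{PS}, \code{Sw}; attribute \code{n_excluded}.
#' @export
segment_strides <- function(seq, discard_ends = 3) {
  stopifnot(inherits(seq, "phase_sequence"))
  lab <- as.character(seq$labels)
  n <- length(lab)
  ## heel strikes = samples entering LR from Sw
  into_lr <- which(lab[-1L] == "LR" & lab[-n] == "Sw") + 1L
  n_strides <- length(into_lr) - 1L
  ## the label vector may itself start at a heel strike
  if (length(lab) && lab[1L] == "LR" &&
      (length(into_lr) == 0L || into_lr[1L] > 1L)) {
    into_lr <- c(1L, into_lr)
    n_strides <- n_strides + 1L
  }
  if (n_strides < 2L * discard_ends + 1L)
    stop(sprintf("only %d stride(s) detected; need at least %d",
                 max(n_strides, 0L), 2L * discard_ends + 1L))
  keep <- seq.int(discard_ends + 1L, n_strides - discard_ends)
  out <- vector("list", length(keep))
  excluded <- 0L
  for (m in seq_along(keep)) {
    k <- keep[m]
    i0 <- into_lr[k]; i1 <- into_lr[k + 1L] - 1L
    r <- rle(lab[i0:i1])
    if (!identical(r$values, gait_phases())) { excluded <- excluded + 1L; next }
    cnt <- r$lengths
    out[[m]] <- data.frame(
      stride = k,
      t_start = seq$t0 + (i0 - 1L) / seq$rate,
      t_end = seq$t0 + i1 / seq$rate,
      LR = 100 * cnt[1] / sum(cnt), FF = 100 * cnt[2] / sum(cnt),
      PS = 100 * cnt[3] / sum(cnt), Sw = 100 * cnt[4] / sum(cnt))
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) stop("no stride with canonical phase order retained")
  attr(res, "n_excluded") <- excluded
  class(res) <- c("stride_phases", "data.frame")
  res
}

#' Trial-mean phase percentages
#'
#' @param strides A \code{stride_phases} table from
#'   \code{\link{segment_strides}}.
#' @return Named numeric 4-vector (LR, FF, PS, Sw) in percent.
#' @export
phase_means <- function(strides) {
  colMeans(as.data.frame(strides)[, gait_phases(), drop = FALSE])
}
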