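## Four-phase model of the gait cycle.
## Each cycle runs LR -> FF -> PS -> Sw, delimited by the events
## HS (heel strike), TS (toe strike), HO (heel off), TO (toe off):
## entering LR is an HS, entering FF a TS, entering PS an HO, entering Sw a TO.

#' Gait phase and event names
#'
#' \code{gait_phases()} returns the four phase labels in cyclic order
#' (loading response, flat foot, pre-swing, swing); \code{gait_events()}
#' the four delimiting events (heel strike, toe strike, heel off, toe off),
#' ordered so that event k marks entry into phase k.
#'
#' @return Character vector of length 4.
#' @export
gait_phases <- function() c("LR", "FF", "PS", "Sw")

#' @rdname gait_phases
#' @export
gait_events <- function() c("HS", "TS", "HO", "TO")

#' Per-sample gait phase sequence
#'
#' Holds per-sample phase labels on a uniform time grid together with the
#' gait-event list derived from (or defining) the label changes. Events not
#' following the canonical cycle HS -> TS -> HO -> TO -> HS are kept but
#' flagged in the \code{canonical} column.
#'
#' @param labels Character or factor vector of per-sample labels in
#'   \code{c("LR","FF","PS","Sw")}.
#' @param rate Sampling rate in Hz.
#' @param t0 Time of first sample, seconds.
#' @param events Optional data frame with columns \code{type} and
#'   \code{time}; derived from label changes when omitted.
#' @return Object of class \code{"phase_sequence"}.
#' @export
phase_sequence <- function(labels, rate, t0 = 0, events = NULL) {
  labels <- factor(as.character(labels), levels = gait_phases())
  if (anyNA(labels)) stop("labels must all be in LR/FF/PS/Sw")
  if (is.null(events)) events <- events_from_labels(labels, rate, t0)
  events$canonical <- flag_canonical(events$type)
  structure(list(labels = labels, rate = rate, t0 = t0, events = events),
            class = "phase_sequence")
}

## event list from per-sample labels: one event at each label change,
## typed by the phase being entered; an event is also emitted at t0.
events_from_labels <- function(labels, rate, t0) {
  ph <- gait_phases(); ev <- gait_events()
  idx <- c(1L, which(labels[-1L] != labels[-length(labels)]) + 1L)
  data.frame(type = ev[match(as.character(labels[idx]), ph)],
             time = t0 + (idx - 1L) / rate,
             stringsAsFactors = FALSE)
}

## TRUE where the event continues the canonical cycle from its predecessor
flag_canonical <- function(types) {
  ev <- gait_events()
  if (!length(types)) return(logical(0))
  pos <- match(types, ev)
  c(TRUE, diff(pos) %% 4L == 1L)
}

#' @export
print.phase_sequence <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("phase sequence: %d samples @ %g Hz, %d events\n",
              length(x$labels), x$rate, nrow(x$events)))
  cat("  samples per phase: ",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n", sep = "")
  bad <- sum(!x$events$canonical)
  if (bad) cat(sprintf("  %d non-canonical event transition(s)\n", bad))
  invisible(x)
}

#' @export
plot.phase_sequence <- function(x, signal = NULL, ...) {
  t <- x$t0 + (seq_along(x$labels) - 1) / x$rate
  code <- as.integer(x$labels)
  if (is.null(signal)) {
    plot(t, code, type = "s", yaxt = "n", xlab = "time [s]",
         ylab = "phase", ...)
    graphics::axis(2, at = 1:4, labels = gait_phases())
  } else {
    plot(t, signal$samples[seq_along(t)], type = "l", xlab = "time [s]",
         ylab = "signal", ...)
    graphics::abline(v = x$events$time, col = "grey70", lty = 3)
  }
  invisible(x)
}

#' Build per-sample labels from an ordered event list
#'
#' Fills a label vector of \code{n} samples at \code{rate} from gait events:
#' each event switches the current phase to the one it introduces. Samples
#' before the first event get the phase preceding it in the cycle.
#'
#' @param events Data frame with columns \code{type}, \code{time}.
#' @param n Number of samples.
#' @param rate Sampling rate, Hz.
#' @param t0 Time of first sample, seconds.
#' @return A \code{\link{phase_sequence}}.
#' @export
labels_from_events <- function(events, n, rate, t0 = 0) {
  ph <- gait_phases(); ev <- gait_events()
  events <- events[order(events$time), , drop = FALSE]
  lab <- integer(n)
  idx <- pmin(pmax(round((events$time - t0) * rate) + 1, 1L), n)
  phase_of <- match(events$type, ev)
  if (!nrow(events)) stop("empty event list")
  ## phase before the first event = predecessor in the cycle
  cur <- (phase_of[1] - 2L) %% 4L + 1L
  starts <- c(1L, idx)
  phases <- c(cur, phase_of)
  for (k in seq_along(starts)) {
    from <- starts[k]
    to <- if (k < length(starts)) starts[k + 1L] - 1L else n
    if (from <= to) lab[from:to] <- phases[k]
  }
  phase_sequence(ph[lab], rate, t0,
                 events = data.frame(type = events$type, time = events$time,
                                     stringsAsFactors = FALSE))
}

#' Save / load a phase sequence as JSON
#'
#' Stores rate, origin, per-sample labels and the event table.
#'
#' @param x A \code{\link{phase_sequence}}.
#' @param path File path.
#' @return \code{read_phase_sequence} returns a \code{phase_sequence};
#'   \code{write_phase_sequence} returns \code{path} invisibly.
#' @export
write_phase_sequence <- function(x, path) {
  obj <- list(rate = x$rate, t0 = x$t0,
              labels = as.character(x$labels),
              events = x$events[c("type", "time")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phase_sequence
#' @export
read_phase_sequence <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- as.data.frame(obj$events, stringsAsFactors = FALSE)
  if (!nrow(ev)) ev <- data.frame(type = character(0), time = numeric(0),
                                  stringsAsFactors = FALSE)
  phase_sequence(obj$labels, obj$rate, obj$t0, events = ev)
}
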