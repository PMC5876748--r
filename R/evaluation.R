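## Transition-level accuracy against the footswitch reference.
##
## A detected transition counts as a true positive when it falls inside a
## tolerance window (60 ms, centered, i.e. +/- 30 ms) around a reference
## transition of the same event type, with one-to-one matching. True
## negatives are counted at sample level: samples outside every tolerance
## window that carry no predicted transition. The goodness index G is the
## Euclidean distance of (TNR, TPR) from the perfect point (1, 1) of ROC
## space.

## transitions = actual label changes (the phase entered gives the type);
## the state at the first sample is not a transition
transitions_of <- function(seq) {
  lab <- as.character(seq$labels)
  n <- length(lab)
  idx <- which(lab[-1L] != lab[-n]) + 1L
  data.frame(type = gait_events()[match(lab[idx], gait_phases())],
             idx = idx,
             time = seq$t0 + (idx - 1L) / seq$rate,
             stringsAsFactors = FALSE)
}

#' Match predicted to reference transitions
#'
#' Each reference transition opens a window of \code{tolerance_ms}
#' centered on it. Predicted transitions of the same event type are
#' matched one-to-one to reference transitions greedily by ascending time
#' distance (ties to the earlier predicted transition); matches are TP,
#' unmatched predictions FP, unmatched reference windows FN. TN counts
#' the samples that lie outside every window and carry no predicted
#' transition.
#'
#' @param reference,predicted \code{\link{phase_sequence}} objects on the
#'   same grid (equal rate and origin).
#' @param tolerance_ms Full window width, ms (60 means +/- 30 ms).
#' @return List of class \code{"eval_counts"}: \code{TP}, \code{TN},
#'   \code{FP}, \code{FN}, plus a per-event-type breakdown in
#'   \code{by_type}.
#' @export
match_transitions <- function(reference, predicted, tolerance_ms = 60) {
  stopifnot(inherits(reference, "phase_sequence"),
            inherits(predicted, "phase_sequence"))
  if (reference$rate != predicted$rate ||
      abs(reference$t0 - predicted$t0) > 1e-9)
    stop("reference and predicted sequences are on different grids")
  tol <- tolerance_ms / 1000 / 2
  rate <- reference$rate
  rt <- transitions_of(reference)
  pt <- transitions_of(predicted)
  TP <- FP <- FN <- 0L
  by_type <- list()
  for (ty in gait_events()) {
    r <- rt$time[rt$type == ty]
    p <- pt$time[pt$type == ty]
    matched_r <- logical(length(r)); matched_p <- logical(length(p))
    if (length(r) && length(p)) {
      cand <- expand.grid(i = seq_along(r), j = seq_along(p))
      cand$d <- abs(r[cand$i] - p[cand$j])
      cand <- cand[cand$d <= tol + 1e-12, , drop = FALSE]
      cand <- cand[order(cand$d, p[cand$j]), , drop = FALSE]
      for (k in seq_len(nrow(cand))) {
        i <- cand$i[k]; j <- cand$j[k]
        if (!matched_r[i] && !matched_p[j]) {
          matched_r[i] <- TRUE; matched_p[j] <- TRUE
        }
      }
    }
    tp <- sum(matched_r)
    by_type[[ty]] <- c(TP = tp, FP = sum(!matched_p), FN = sum(!matched_r))
    TP <- TP + tp; FP <- FP + sum(!matched_p); FN <- FN + sum(!matched_r)
  }
  ## sample-level true negatives
  n <- min(length(reference$labels), length(predicted$labels))
  in_window <- logical(n)
  half <- round(tol * rate)
  for (i in rt$idx) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    in_window[lo:hi] <- TRUE
  }
  pred_samp <- logical(n)
  pred_samp[pt$idx[pt$idx <= n]] <- TRUE
  TN <- sum(!in_window & !pred_samp)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 by_type = do.call(rbind, by_type)),
            class = "eval_counts")
}

#' Sensitivity and specificity from transition counts
#'
#' True positive rate \code{TP / (TP + FN)} and true negative rate
#' \code{TN / (TN + FP)}.
#'
#' @param counts An \code{eval_counts} (or any list with TP/TN/FP/FN).
#' @return Named numeric vector \code{c(TPR, TNR)}.
#' @export
rates <- function(counts) {
  if (counts$TP + counts$FN <= 0 || counts$TN + counts$FP <= 0)
    stop("undefined rate: zero denominator")
  c(TPR = counts$TP / (counts$TP + counts$FN),
    TNR = counts$TN / (counts$TN + counts$FP))
}

#' Goodness index
#'
#' \code{G = sqrt((1 - TNR)^2 + (1 - TPR)^2)}: the Euclidean distance of
#' the operating point from perfect classification in ROC space, in
#' [0, sqrt(2)]. Performance class: optimum when \code{G <= 0.25}, good
#' when \code{0.25 < G <= 0.7}, random above.
#'
#' @param TPR,TNR Rates in [0, 1].
#' @return List with \code{G} and \code{performance_class}.
#' @examples
#' goodness(0.8, 0.7)   # G = 0.36, "good"
#' @export
goodness <- function(TPR, TNR) {
  stopifnot(TPR >= 0, TPR <= 1, TNR >= 0, TNR <= 1)
  G <- unname(sqrt((1 - TNR)^2 + (1 - TPR)^2))
  cls <- if (G <= 0.25) "optimum" else if (G <= 0.7) "good" else "random"
  list(G = G, performance_class = cls)
}

#' End-to-end accuracy of a predicted phase sequence
#'
#' Convenience wrapper: \code{\link{match_transitions}} then
#' \code{\link{rates}} and \code{\link{goodness}}.
#'
#' @inheritParams match_transitions
#' @return List of class \code{"eval_result"}: counts, TPR, TNR, G,
#'   performance class.
#' @export
evaluate_segmentation <- function(reference, predicted, tolerance_ms = 60) {
  counts <- match_transitions(reference, predicted, tolerance_ms)
  r <- rates(counts)
  g <- goodness(r["TPR"], r["TNR"])
  structure(list(counts = counts, TPR = unname(r["TPR"]),
                 TNR = unname(r["TNR"]), G = g$G,
                 performance_class = g$performance_class),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("TPR %.3f  TNR %.3f  G %.3f (%s)\n",
              x$TPR, x$TNR, x$G, x$performance_class))
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n",
              x$counts$TP, x$counts$FP, x$counts$FN, x$counts$TN))
  invisible(x)
}

#' Per-phase percentage absolute errors
#'
#' Absolute difference between the trial-mean phase percentages of a
#' method and of the reference, per phase, plus the absolute error of the
#' single-side GPQI distance computed against \code{ref_dist}.
#'
#' @param reference,predicted \code{stride_phases} tables
#'   (\code{\link{segment_strides}}).
#' @param ref_dist A \code{\link{reference_distribution}} for the GPQI
#'   error. Default: the bundled healthy reference.
#' @return Named vector \code{LR_e, FF_e, PS_e, Sw_e, GPQI_e} in percent.
#' @export
phase_errors <- function(reference, predicted, ref_dist = healthy_reference()) {
  if (!nrow(as.data.frame(reference)) || !nrow(as.data.frame(predicted)))
    stop("empty stride table")
  mr <- phase_means(reference)
  mp <- phase_means(predicted)
  e <- abs(mp - mr)
  g_ref <- sqrt(sum((mr - ref_dist$means)^2))
  g_prd <- sqrt(sum((mp - ref_dist$means)^2))
  c(LR_e = unname(e[1]), FF_e = unname(e[2]), PS_e = unname(e[3]),
    Sw_e = unname(e[4]), GPQI_e = abs(g_ref - g_prd))
}

#' Area under the ROC curve for two groups of scores
#'
#' AUC via the rank-sum (Mann-Whitney) identity, ties counted one half;
#' the probability that a score from \code{scores_a} exceeds one from
#' \code{scores_b}, in percent. 100 means perfect separation with group a
#' above group b; 50 a worthless classifier.
#'
#' @param scores_a,scores_b Non-empty numeric vectors.
#' @return AUC in percent.
#' @export
roc_auc <- function(scores_a, scores_b) {
  if (!length(scores_a) || !length(scores_b)) stop("empty group")
  na <- length(scores_a); nb <- length(scores_b)
  r <- rank(c(scores_a, scores_b))
  auc <- (sum(r[seq_len(na)]) - na * (na + 1) / 2) / (na * nb)
  100 * auc
}
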