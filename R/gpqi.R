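## Gait Phases Quality Index.
##
## For each body side the subject's phase-percentage 4-vector (LR, FF,
## PS, Sw) is compared to the control-group mean distribution; the index
## is the sum over the two sides of the Euclidean distances in that
## four-dimensional phase space. 0 means a phase distribution identical
## to the healthy average; larger values mean larger deviation from
## healthy gait, in percentage points.

#' Control-group reference phase distribution
#'
#' \code{reference_distribution} wraps a 4-vector of control-group mean
#' phase percentages; \code{healthy_reference} returns the bundled
#' default, the control-group distribution (LR, FF, PS, Sw) =
#' (6.9, 39.4, 16.2, 37.7)\%. Use \code{\link{control_reference}} to
#' compute one from your own control cohort.
#'
#' @param means Numeric 4-vector of mean percentages; must sum to 100
#'   within rounding (98-102 accepted).
#' @param source \code{"default"} or \code{"computed"}.
#' @return Object of class \code{"reference_distribution"}.
#' @export
reference_distribution <- function(means, source = "computed") {
  means <- as.numeric(means)
  if (length(means) != 4L || any(means <= 0))
    stop("'means' must be 4 positive percentages")
  s <- sum(means)
  if (s < 98 || s > 102)
    stop("reference means must sum to ~100 (got ", round(s, 2), ")")
  structure(list(means = stats::setNames(means, gait_phases()),
                 source = source),
            class = "reference_distribution")
}

#' @rdname reference_distribution
#' @export
healthy_reference <- function() {
  reference_distribution(c(6.9, 39.4, 16.2, 37.7), source = "default")
}

#' @export
print.reference_distribution <- function(x, ...) {
  cat("control-group reference distribution (", x$source, "):\n  ",
      paste(sprintf("%s=%.1f%%", names(x$means), x$means), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Gait Phases Quality Index from two side distributions
#'
#' Sum over the left and right side of the Euclidean distance between the
#' side's phase-percentage vector and the control-group reference means.
#'
#' @param left,right Numeric 4-vectors (LR, FF, PS, Sw) in percent,
#'   each summing to 100 (a quarter point of rounding slack is accepted).
#' @param ref A \code{\link{reference_distribution}}.
#' @return List of class \code{"gpqi_result"}: \code{gpqi} (percent),
#'   \code{per_side_distance} (named 2-vector), \code{basis}.
#' @examples
#' ref <- healthy_reference()
#' gpqi(ref$means, ref$means, ref)$gpqi          # 0: healthy-like
#' @export
gpqi <- function(left, right, ref = healthy_reference()) {
  stopifnot(inherits(ref, "reference_distribution"))
  check_side <- function(v, nm) {
    v <- as.numeric(v)
    if (length(v) != 4L || anyNA(v))
      stop("'", nm, "' must be a numeric 4-vector")
    ## printed distributions carry rounding (the bundled reference sums
    ## to 100.2), so a quarter point of slack is accepted
    if (abs(sum(v) - 100) > 0.25)
      stop("'", nm, "' percentages must sum to 100")
    v
  }
  left <- check_side(left, "left"); right <- check_side(right, "right")
  d <- c(left = sqrt(sum((left - ref$means)^2)),
         right = sqrt(sum((right - ref$means)^2)))
  structure(list(gpqi = sum(d), per_side_distance = d, basis = "direct"),
            class = "gpqi_result")
}

#' @export
print.gpqi_result <- function(x, ...) {
  cat(sprintf("GPQI = %.3f%% (left %.3f, right %.3f; basis %s)\n",
              x$gpqi, x$per_side_distance["left"],
              x$per_side_distance["right"], x$basis))
  invisible(x)
}

#' GPQI of a walking trial
#'
#' With \code{basis = "trial_mean"} (default) each side's strides are
#' averaged first and the index computed once from the two mean vectors.
#' With \code{basis = "per_stride"} strides are paired across sides by
#' temporal index, the index computed per pair and averaged; unequal
#' stride counts truncate to the shorter side with a warning.
#'
#' @param strides_left,strides_right \code{stride_phases} tables from
#'   \code{\link{segment_strides}}.
#' @param ref A \code{\link{reference_distribution}}.
#' @param basis \code{"trial_mean"} or \code{"per_stride"}.
#' @return A \code{"gpqi_result"}.
#' @export
gpqi_trial <- function(strides_left, strides_right,
                       ref = healthy_reference(),
                       basis = c("trial_mean", "per_stride")) {
  basis <- match.arg(basis)
  dl <- as.data.frame(strides_left); dr <- as.data.frame(strides_right)
  if (!nrow(dl) || !nrow(dr)) stop("empty stride table for one side")
  if (basis == "trial_mean") {
    res <- gpqi(phase_means(strides_left), phase_means(strides_right), ref)
    res$basis <- "trial_mean"
    return(res)
  }
  n <- min(nrow(dl), nrow(dr))
  if (nrow(dl) != nrow(dr))
    warning(sprintf("unequal stride counts (%d vs %d); truncating to %d",
                    nrow(dl), nrow(dr), n))
  ph <- gait_phases()
  vals <- vapply(seq_len(n), function(i)
    gpqi(as.numeric(dl[i, ph]), as.numeric(dr[i, ph]), ref)$gpqi, numeric(1))
  d <- c(left = mean(vapply(seq_len(n), function(i)
           sqrt(sum((as.numeric(dl[i, ph]) - ref$means)^2)), numeric(1))),
         right = mean(vapply(seq_len(n), function(i)
           sqrt(sum((as.numeric(dr[i, ph]) - ref$means)^2)), numeric(1))))
  structure(list(gpqi = mean(vals), per_side_distance = d,
                 basis = "per_stride"),
            class = "gpqi_result")
}

#' Compute a control-group reference distribution from healthy trials
#'
#' Per subject, trial-mean phase percentages are averaged (sides pooled);
#' the reference is the grand mean over subjects.
#'
#' @param trials List of subjects; each subject is a list of
#'   \code{stride_phases} tables (one per trial and side), or a single
#'   table.
#' @return A \code{\link{reference_distribution}} with source
#'   \code{"computed"}.
#' @export
control_reference <- function(trials) {
  if (!length(trials)) stop("empty control cohort")
  per_subject <- lapply(trials, function(subj) {
    if (inherits(subj, "stride_phases") || is.data.frame(subj))
      subj <- list(subj)
    if (!length(subj)) stop("subject with no trials")
    rowMeans(vapply(subj, phase_means, numeric(4)))
  })
  m <- rowMeans(do.call(cbind, per_subject))
  reference_distribution(m, source = "computed")
}

#' Test-retest reliability: ICC(3,k), SEM and MDC95
#'
#' Two-way mixed, consistency, average-measures intraclass correlation
#' from the subjects x trials ANOVA decomposition:
#' \code{ICC = (MS_subjects - MS_error) / MS_subjects}. The standard
#' error of measurement is \code{SD * sqrt(1 - ICC)} with SD the
#' between-subject standard deviation of the trial means, and
#' \code{MDC95 = 1.96 * sqrt(2) * SEM} is the smallest change
#' distinguishable from measurement error at 95\% confidence.
#' Reliability classes: poor below 0.40, fair to 0.59, good to 0.74,
#' excellent from 0.75.
#'
#' @param measurements Numeric matrix, subjects in rows, the k repeated
#'   trials in columns; no missing cells.
#' @return List of class \code{"reliability_result"}: \code{icc},
#'   \code{sem}, \code{mdc95}, \code{k}, \code{reliability_class}.
#' @export
icc_3k <- function(measurements) {
  m <- as.matrix(measurements)
  if (anyNA(m)) stop("missing cells not supported")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 trials")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  if (ms_rows <= 0) {                     # all values equal
    icc <- 1; sem <- 0
  } else {
    icc <- (ms_rows - ms_err) / ms_rows
    sem <- stats::sd(row_m) * sqrt(max(1 - icc, 0))
  }
  mdc95 <- 1.96 * sqrt(2) * sem
  cls <- if (icc < 0.40) "poor" else if (icc < 0.60) "fair"
         else if (icc < 0.75) "good" else "excellent"
  structure(list(icc = icc, sem = sem, mdc95 = mdc95, k = k,
                 reliability_class = cls),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("ICC(3,%d) = %.3f (%s), SEM = %.3f, MDC95 = %.3f\n",
              x$k, x$icc, x$reliability_class, x$sem, x$mdc95))
  invisible(x)
}
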