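## Scalar continuous hidden Markov model over the four gait phases.
##
## Topology is left-right and cyclic: state i may stay or advance to its
## successor (LR -> FF -> PS -> Sw -> LR), all other transitions are
## structural zeros, so whole multi-stride trials decode continuously.
## Emissions are per-state scalar Gaussian mixtures on the low-pass
## filtered sagittal angular velocity. The initial distribution is kept
## uniform over the four phases and is not re-estimated: a walking trial
## may start anywhere in the cycle.

hmm_mask <- function(n = 4L) {
  m <- diag(n)
  m[cbind(seq_len(n), c(seq_len(n - 1L) + 1L, 1L))] <- 1
  m
}

## emission density matrix: T x n_states, mixture of scalar Gaussians
emission_probs <- function(model, x) {
  B <- matrix(0, length(x), model$n_states)
  for (i in seq_len(model$n_states)) {
    e <- model$emissions[[i]]
    for (k in seq_along(e$w))
      B[, i] <- B[, i] + e$w[k] * stats::dnorm(x, e$mu[k], e$sd[k])
  }
  pmax(B, 1e-300)
}

#' Fit a gait-phase hidden Markov model from labeled data
#'
#' Supervised initialization of the scalar continuous HMM: per-phase
#' emission parameters are moment estimates of the signal within each
#' labeled phase (for \code{n_mix > 1}, a k-means split of the phase's
#' samples provides the mixture components), the self-transition
#' probability of each state is \code{1 - 1/d} with \code{d} the mean
#' phase duration in samples (the geometric dwell-time match), the
#' remaining mass goes to the successor state, and the initial
#' distribution is uniform. Refine with \code{\link{baum_welch}}; decode
#' with \code{\link{viterbi}} or \code{predict}.
#'
#' @param signal A \code{\link{uniform_series}} (sagittal angular
#'   velocity, conventionally low-pass filtered at 17 Hz), or a plain
#'   numeric vector.
#' @param labels A \code{\link{phase_sequence}} aligned to \code{signal},
#'   or a character/factor vector of per-sample labels.
#' @param n_mix Gaussian components per state (1-3). Default 3: the
#'   phase-conditional distributions of the sagittal angular velocity are
#'   strongly multimodal (troughs, plateau, boundary transients), which a
#'   single Gaussian represents poorly.
#' @param sd_floor Lower bound on emission SDs, deg/s. Guards against
#'   variance collapse on the quasi-constant flat-foot segment and encodes
#'   the angular-velocity measurement noise scale; a floor well below the
#'   sensor noise makes the flat-foot state overconfident and biases the
#'   decoded phase boundaries. Default 6.
#' @return Object of class \code{"gait_hmm"}.
#' @examples
#' tr <- generate_trial(gait_preset("healthy"), 10, seed = 1)
#' sig <- lowpass(sagittal_gyro(tr$imu), 17)
#' m <- gait_hmm(sig, tr$truth$phases)
#' m
#' @export
gait_hmm <- function(signal, labels, n_mix = 3, sd_floor = 6) {
  x <- if (inherits(signal, "uniform_series")) signal$samples
       else as.numeric(signal)
  lab <- if (inherits(labels, "phase_sequence")) as.character(labels$labels)
         else as.character(labels)
  if (length(x) != length(lab))
    stop("signal and labels must be aligned (equal length)")
  if (n_mix < 1 || n_mix > 3) stop("'n_mix' must be 1, 2 or 3")
  ph <- gait_phases()
  miss <- setdiff(ph, unique(lab))
  if (length(miss))
    stop("phase(s) absent from labels: ", paste(miss, collapse = ", "))
  emissions <- vector("list", 4L)
  A <- matrix(0, 4L, 4L, dimnames = list(ph, ph))
  r <- rle(lab)
  for (i in seq_len(4L)) {
    xs <- x[lab == ph[i]]
    ctr <- unique(stats::quantile(xs, (seq_len(n_mix) * 2 - 1) / (2 * n_mix),
                                  names = FALSE))
    if (n_mix == 1L || length(ctr) < n_mix) {
      emissions[[i]] <- list(w = 1,
                             mu = mean(xs),
                             sd = max(stats::sd(xs), sd_floor, na.rm = TRUE))
    } else {
      ## deterministic seeding: initial centers spread over the quantiles
      km <- stats::kmeans(xs, centers = ctr)
      emissions[[i]] <- list(w = as.numeric(km$size) / length(xs),
                             mu = as.numeric(km$centers),
                             sd = pmax(sqrt(km$withinss /
                                              pmax(km$size - 1, 1)), sd_floor))
    }
    d <- mean(r$lengths[r$values == ph[i]])
    a_ii <- max(0, 1 - 1 / d)
    A[i, i] <- a_ii
    A[i, i %% 4L + 1L] <- 1 - a_ii
  }
  structure(list(n_states = 4L, A = A, pi = rep(0.25, 4L),
                 emissions = emissions, n_mix = n_mix, sd_floor = sd_floor,
                 train = NULL),
            class = "gait_hmm")
}

#' @export
print.gait_hmm <- function(x, ...) {
  cat(sprintf("gait-phase HMM: 4 states (left-right cyclic), %d mixture component(s)\n",
              x$n_mix))
  mu <- vapply(x$emissions, function(e) e$mu[which.max(e$w)], numeric(1))
  cat("  dominant emission means [deg/s]: ",
      paste(sprintf("%s=%.1f", gait_phases(), mu), collapse = ", "), "\n",
      sep = "")
  cat("  self-transitions: ",
      paste(sprintf("%.3f", diag(x$A)), collapse = ", "), "\n", sep = "")
  if (!is.null(x$train))
    cat(sprintf("  trained: %d EM iteration(s), logLik %.2f, %s\n",
                x$train$n_iter, utils::tail(x$train$log_likelihood, 1),
                if (x$train$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
summary.gait_hmm <- function(object, ...) {
  cat("Transition matrix (structural zeros outside diagonal+successor):\n")
  print(round(object$A, 4))
  cat("\nEmissions (per state):\n")
  for (i in seq_len(4L)) {
    e <- object$emissions[[i]]
    cat(sprintf("  %s: ", gait_phases()[i]))
    cat(paste(sprintf("w=%.2f mu=%.2f sd=%.2f", e$w, e$mu, e$sd),
              collapse = " | "), "\n")
  }
  cat("\nInitial distribution:", paste(round(object$pi, 3), collapse = " "),
      "\n")
  invisible(object)
}

#' @export
coef.gait_hmm <- function(object, ...) {
  list(A = object$A, pi = object$pi,
       emissions = do.call(rbind, lapply(seq_len(4L), function(i) {
         e <- object$emissions[[i]]
         data.frame(state = gait_phases()[i], component = seq_along(e$w),
                    weight = e$w, mean = e$mu, sd = e$sd)
       })))
}

#' @export
logLik.gait_hmm <- function(object, ...) {
  if (is.null(object$train)) return(NA_real_)
  ll <- utils::tail(object$train$log_likelihood, 1)
  structure(ll, class = "logLik", df = NA)
}

## scaled forward pass; returns normalized alpha and scaling constants
forward_scaled <- function(model, B) {
  Tn <- nrow(B); K <- model$n_states
  alpha <- matrix(0, Tn, K)
  cc <- numeric(Tn)
  a <- model$pi * B[1, ]
  cc[1] <- sum(a); alpha[1, ] <- a / cc[1]
  tA <- t(model$A)
  for (t in 2:Tn) {
    a <- (tA %*% alpha[t - 1, ]) * B[t, ]
    cc[t] <- sum(a)
    alpha[t, ] <- a / cc[t]
  }
  list(alpha = alpha, c = cc)
}

backward_scaled <- function(model, B, cc) {
  Tn <- nrow(B); K <- model$n_states
  beta <- matrix(0, Tn, K)
  beta[Tn, ] <- 1
  A <- model$A
  for (t in (Tn - 1):1)
    beta[t, ] <- (A %*% (B[t + 1, ] * beta[t + 1, ])) / cc[t + 1]
  beta
}

#' Baum-Welch training
#'
#' Expectation-maximization over one or more observation sequences with
#' scaled forward-backward recursions (numerically stable for long
#' trials). The left-right cyclic structural zeros of the transition
#' matrix and the emission SD floor are re-imposed at every M-step; the
#' initial distribution stays uniform. Stops when the log-likelihood
#' improves by less than \code{tol} or after \code{max_iter} iterations.
#'
#' @param model A \code{\link{gait_hmm}}.
#' @param signals A \code{uniform_series}, numeric vector, or list of them.
#' @param tol Absolute log-likelihood change for convergence. Default 1e-4.
#' @param max_iter Maximum EM iterations. Default 100.
#' @param freeze_transitions Keep the transition matrix at its initial
#'   values and re-estimate emissions only.
#' @return The trained \code{gait_hmm}; element \code{train} holds the
#'   per-iteration log-likelihood trace, iteration count and convergence
#'   flag.
#' @export
baum_welch <- function(model, signals, tol = 1e-4, max_iter = 100,
                       freeze_transitions = FALSE) {
  stopifnot(inherits(model, "gait_hmm"))
  if (!is.list(signals) || inherits(signals, "uniform_series"))
    signals <- list(signals)
  xs <- lapply(signals, function(s)
    if (inherits(s, "uniform_series")) s$samples else as.numeric(s))
  if (!length(xs)) stop("need at least one training sequence")
  mask <- hmm_mask(model$n_states)
  K <- model$n_states
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    A_num <- matrix(0, K, K)
    g1 <- numeric(K)                      # summed gamma per state
    w_num <- mu_num <- var_num <- vector("list", K)
    for (i in seq_len(K)) {
      nm <- length(model$emissions[[i]]$w)
      w_num[[i]] <- numeric(nm); mu_num[[i]] <- numeric(nm)
      var_num[[i]] <- numeric(nm)
    }
    ll <- 0
    for (x in xs) {
      B <- emission_probs(model, x)
      fw <- forward_scaled(model, B)
      if (anyNA(fw$c) || any(fw$c <= 0))
        stop(sprintf("degenerate likelihood at iteration %d", iter))
      beta <- backward_scaled(model, B, fw$c)
      ll <- ll + sum(log(fw$c))
      gamma <- fw$alpha * beta
      gamma <- gamma / rowSums(gamma)
      Tn <- length(x)
      bbc <- (B * beta) / fw$c
      A_num <- A_num + model$A *
        (t(fw$alpha[-Tn, , drop = FALSE]) %*% bbc[-1, , drop = FALSE])
      g1 <- g1 + colSums(gamma)
      for (i in seq_len(K)) {
        e <- model$emissions[[i]]
        nm <- length(e$w)
        if (nm == 1L) {
          w_num[[i]] <- w_num[[i]] + sum(gamma[, i])
          mu_num[[i]] <- mu_num[[i]] + sum(gamma[, i] * x)
          var_num[[i]] <- var_num[[i]] + sum(gamma[, i] * x^2)
        } else {
          comp <- vapply(seq_len(nm), function(k)
            e$w[k] * stats::dnorm(x, e$mu[k], e$sd[k]), numeric(Tn))
          comp <- comp / pmax(rowSums(comp), 1e-300)
          for (k in seq_len(nm)) {
            r <- gamma[, i] * comp[, k]
            w_num[[i]][k] <- w_num[[i]][k] + sum(r)
            mu_num[[i]][k] <- mu_num[[i]][k] + sum(r * x)
            var_num[[i]][k] <- var_num[[i]][k] + sum(r * x^2)
          }
        }
      }
    }
    ll_trace <- c(ll_trace, ll)
    ## M-step
    if (!freeze_transitions) {
      A_new <- A_num * mask
      rs <- rowSums(A_new)
      rs[rs == 0] <- 1
      model$A <- A_new / rs
    }
    for (i in seq_len(K)) {
      wk <- w_num[[i]]
      tot <- sum(wk)
      mu <- mu_num[[i]] / pmax(wk, 1e-300)
      v <- var_num[[i]] / pmax(wk, 1e-300) - mu^2
      model$emissions[[i]] <- list(w = wk / max(tot, 1e-300), mu = mu,
                                   sd = pmax(sqrt(pmax(v, 0)),
                                             model$sd_floor))
    }
    if (!is.finite(tol) ||
        (is.finite(ll_old) && abs(ll - ll_old) < tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  model$train <- list(log_likelihood = ll_trace, n_iter = length(ll_trace),
                      converged = converged)
  model
}

#' Viterbi decoding
#'
#' Maximum-probability state path in log space; ties break toward the
#' lower state index. The path is mapped to phase labels and gait events.
#'
#' @param model A trained \code{\link{gait_hmm}}.
#' @param signal A \code{uniform_series} or numeric vector.
#' @param rate Sampling rate when \code{signal} is a plain vector.
#' @return A \code{\link{phase_sequence}}.
#' @export
viterbi <- function(model, signal, rate = 200) {
  stopifnot(inherits(model, "gait_hmm"))
  if (inherits(signal, "uniform_series")) {
    x <- signal$samples; rate <- signal$rate; t0 <- signal$t0
  } else { x <- as.numeric(signal); t0 <- 0 }
  B <- log(emission_probs(model, x))
  logA <- log(model$A)
  Tn <- length(x); K <- model$n_states
  delta <- log(model$pi) + B[1, ]
  psi <- matrix(0L, Tn, K)
  for (t in 2:Tn) {
    m <- delta + logA                    # K x K: from-state rows
    psi[t, ] <- max.col(t(m), ties.method = "first")
    delta <- m[cbind(psi[t, ], seq_len(K))] + B[t, ]
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta)
  for (t in (Tn - 1):1) path[t] <- psi[t + 1L, path[t + 1L]]
  phase_sequence(gait_phases()[path], rate, t0)
}

#' @export
predict.gait_hmm <- function(object, newdata, ...) viterbi(object, newdata, ...)

#' Causal online decoding
#'
#' Forward filtering: at each sample the filtered posterior over the four
#' phases is updated and its argmax emitted. This is the real-time
#' approximation to Viterbi decoding (no backward smoothing), suitable
#' for streaming use.
#'
#' @inheritParams viterbi
#' @return List with \code{phases} (factor vector) and \code{posterior}
#'   (T x 4 matrix, rows summing to 1).
#' @export
decode_online <- function(model, signal, rate = 200) {
  if (inherits(signal, "uniform_series")) {
    x <- signal$samples
  } else x <- as.numeric(signal)
  B <- emission_probs(model, x)
  Tn <- length(x); K <- model$n_states
  post <- matrix(0, Tn, K)
  phi <- model$pi * B[1, ]
  post[1, ] <- phi / sum(phi)
  tA <- t(model$A)
  for (t in 2:Tn) {
    phi <- (tA %*% post[t - 1, ]) * B[t, ]
    post[t, ] <- phi / sum(phi)
  }
  list(phases = factor(gait_phases()[max.col(post, ties.method = "first")],
                       levels = gait_phases()),
       posterior = post)
}

#' @export
simulate.gait_hmm <- function(object, nsim = 1000, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  K <- object$n_states
  states <- integer(nsim)
  states[1] <- sample.int(K, 1L, prob = object$pi)
  for (t in seq_len(nsim - 1L))
    states[t + 1L] <- sample.int(K, 1L, prob = object$A[states[t], ])
  x <- vapply(states, function(s) {
    e <- object$emissions[[s]]
    k <- sample.int(length(e$w), 1L, prob = e$w)
    stats::rnorm(1L, e$mu[k], e$sd[k])
  }, numeric(1))
  list(states = factor(gait_phases()[states], levels = gait_phases()),
       samples = x)
}

#' Subject-specific training (leave-one-trial-out)
#'
#' Trains the HMM on two of a subject's three labeled trials and decodes
#' the held-out one; with \code{held_out = NULL} all three folds are
#' rotated. This is the subject-specific deployment: the model sees only
#' the tested subject's own gait in one pharmacological condition.
#'
#' @param trials List of exactly 3 trials, each a list with elements
#'   \code{signal} (\code{uniform_series}) and \code{labels}
#'   (\code{phase_sequence}).
#' @param held_out Index (1-3) of the test trial, or \code{NULL} to
#'   rotate over all folds.
#' @param n_mix,sd_floor Passed to \code{\link{gait_hmm}}.
#' @param ... Passed to \code{\link{baum_welch}}.
#' @return For one fold: list with \code{model}, \code{decoded},
#'   \code{held_out}. For rotation: list of three such lists.
#' @export
train_sst <- function(trials, held_out = NULL, n_mix = 3, sd_floor = 6, ...) {
  if (length(trials) != 3L) stop("subject-specific training needs exactly 3 trials")
  one_fold <- function(h) {
    tr <- trials[-h]
    x <- unlist(lapply(tr, function(t)
      if (inherits(t$signal, "uniform_series")) t$signal$samples
      else as.numeric(t$signal)))
    lab <- unlist(lapply(tr, function(t) as.character(t$labels$labels)))
    m <- gait_hmm(x, lab, n_mix = n_mix, sd_floor = sd_floor)
    m <- baum_welch(m, lapply(tr, `[[`, "signal"), ...)
    list(model = m, decoded = viterbi(m, trials[[h]]$signal), held_out = h)
  }
  if (!is.null(held_out)) return(one_fold(held_out))
  lapply(1:3, one_fold)
}

#' Cross-subject (control-group) training
#'
#' Pools all labeled control-group trials: supervised initialization from
#' the pooled per-phase statistics, then Baum-Welch refinement over the
#' pooled signals. The resulting model is applied to any test trial
#' without retraining — the standard-training-set deployment.
#'
#' @param control_trials Non-empty list of trials (\code{signal} +
#'   \code{labels} as in \code{\link{train_sst}}).
#' @param n_mix,sd_floor Passed to \code{\link{gait_hmm}}.
#' @param ... Passed to \code{\link{baum_welch}}.
#' @return A trained \code{\link{gait_hmm}}.
#' @export
train_spt <- function(control_trials, n_mix = 3, sd_floor = 6, ...) {
  if (!length(control_trials)) stop("empty control-trial pool")
  x <- unlist(lapply(control_trials, function(t)
    if (inherits(t$signal, "uniform_series")) t$signal$samples
    else as.numeric(t$signal)))
  lab <- unlist(lapply(control_trials, function(t) as.character(t$labels$labels)))
  m <- gait_hmm(x, lab, n_mix = n_mix, sd_floor = sd_floor)
  baum_welch(m, lapply(control_trials, `[[`, "signal"), ...)
}

#' Save / load a gait-phase HMM as JSON
#'
#' @param model A \code{gait_hmm}.
#' @param path File path.
#' @return \code{read_gait_hmm} returns a \code{gait_hmm};
#'   \code{write_gait_hmm} returns \code{path} invisibly.
#' @export
write_gait_hmm <- function(model, path) {
  obj <- list(n_states = model$n_states, A = model$A, pi = model$pi,
              emissions = model$emissions, n_mix = model$n_mix,
              sd_floor = model$sd_floor)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_gait_hmm
#' @export
read_gait_hmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(n_states = as.integer(obj$n_states),
                 A = matrix(obj$A, obj$n_states, obj$n_states, byrow = FALSE,
                            dimnames = list(gait_phases(), gait_phases())),
                 pi = as.numeric(obj$pi),
                 emissions = lapply(seq_len(obj$n_states), function(i) {
                   e <- if (is.data.frame(obj$emissions)) obj$emissions[i, ]
                        else obj$emissions[[i]]
                   list(w = as.numeric(unlist(e$w)),
                        mu = as.numeric(unlist(e$mu)),
                        sd = as.numeric(unlist(e$sd)))
                 }),
                 n_mix = as.integer(obj$n_mix),
                 sd_floor = as.numeric(obj$sd_floor), train = NULL),
            class = "gait_hmm")
}
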