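#' Build the observation matrix for gait decoding
#'
#' Slides a 360-ms window (11 bins at the 33.3-ms frame duration) across a
#' binned activity series, stride one bin.  EPSC windows are normalised by
#' the whole-trace mean rate; spike windows have the mean of their first
#' 90 ms (3 bins) subtracted as a baseline.
#'
#' @param activity A [rate_series_obj()] binned at the video frame
#'   duration, or a numeric vector with `bin_s` supplied.
#' @param window_ms Window length, ms.
#' @param mode `"epsc"` (divide by mean) or `"spike"` (subtract early
#'   baseline).
#' @param baseline_ms Baseline portion for spike mode, ms.
#' @param bin_s Bin width when `activity` is a bare vector.
#' @return Matrix (windows x bins) of class `observation_matrix` with
#'   attributes `bin_s` and `mode`.
#' @export
build_observations <- function(activity, window_ms = 360,
                               mode = c("epsc", "spike"), baseline_ms = 90,
                               bin_s = 1 / 30) {
  mode <- match.arg(mode)
  v <- if (inherits(activity, "rate_series")) activity$values else activity
  if (inherits(activity, "rate_series")) bin_s <- 1 / activity$fs
  nb <- max(2L, round(window_ms / 1000 / bin_s))
  if (length(v) < nb) stopf("series shorter than one observation window")
  nbl <- max(1L, round(baseline_ms / 1000 / bin_s))
  nw <- length(v) - nb + 1L
  M <- matrix(0, nw, nb)
  for (j in seq_len(nb)) M[, j] <- v[j:(j + nw - 1L)]
  if (mode == "epsc") {
    mu <- mean(v)
    if (mu == 0) stopf("mean rate is zero; epsc normalisation undefined")
    M <- M / mu
  } else {
    M <- M - rowMeans(M[, seq_len(nbl), drop = FALSE])
  }
  structure(M, bin_s = bin_s, mode = mode,
            class = c("observation_matrix", "matrix", "array"))
}

# --- mixture-of-Gaussians emission helpers (diagonal covariances) ---------

# Per-observation log densities: list(logB = T x S state log-likelihoods,
# logC = T x S x M component log-densities including log weights).
mog_logdens <- function(obs, em) {
  Tn <- nrow(obs); S <- length(em); M <- nrow(em[[1]]$mu)
  D <- ncol(obs)
  logC <- vector("list", S)
  logB <- matrix(0, Tn, S)
  for (s in seq_len(S)) {
    lc <- matrix(0, Tn, M)
    for (m in seq_len(M)) {
      mu <- em[[s]]$mu[m, ]; s2 <- em[[s]]$sigma2[m, ]
      q <- obs - rep(mu, each = Tn)
      lc[, m] <- log(em[[s]]$w[m]) -
        0.5 * (D * log(2 * pi) + sum(log(s2))) -
        0.5 * as.numeric((q * q) %*% (1 / s2))
    }
    mx <- do.call(pmax, as.data.frame(lc))
    logB[, s] <- mx + log(rowSums(exp(lc - mx)))
    logC[[s]] <- lc
  }
  list(logB = logB, logC = logC)
}

# Scaled forward-backward.  Returns log-likelihood, gamma, and transition
# sufficient statistics.
forward_backward <- function(logB, pi0, A) {
  Tn <- nrow(logB); S <- ncol(logB)
  mx <- pmax(logB[, 1], logB[, 2])
  if (S > 2) mx <- do.call(pmax, as.data.frame(logB))
  Bs <- exp(logB - mx)
  alpha <- matrix(0, Tn, S)
  cvec <- numeric(Tn)
  a <- pi0 * Bs[1, ]
  cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
  if (S == 2) {
    a11 <- A[1, 1]; a12 <- A[1, 2]; a21 <- A[2, 1]; a22 <- A[2, 2]
    b1 <- Bs[, 1]; b2 <- Bs[, 2]
    al1 <- alpha[1, 1]; al2 <- alpha[1, 2]
    for (t in 2:Tn) {
      x1 <- (al1 * a11 + al2 * a21) * b1[t]
      x2 <- (al1 * a12 + al2 * a22) * b2[t]
      ct <- x1 + x2
      al1 <- x1 / ct; al2 <- x2 / ct
      cvec[t] <- ct
      alpha[t, 1] <- al1; alpha[t, 2] <- al2
    }
    beta <- matrix(0, Tn, S)
    beta[Tn, ] <- 1
    x11 <- x12 <- x21 <- x22 <- 0
    be1 <- 1; be2 <- 1
    for (t in (Tn - 1):1) {
      nb1 <- b1[t + 1] * be1; nb2 <- b2[t + 1] * be2
      ic <- 1 / cvec[t + 1]
      al1 <- alpha[t, 1]; al2 <- alpha[t, 2]
      x11 <- x11 + al1 * a11 * nb1 * ic
      x12 <- x12 + al1 * a12 * nb2 * ic
      x21 <- x21 + al2 * a21 * nb1 * ic
      x22 <- x22 + al2 * a22 * nb2 * ic
      be1 <- (a11 * nb1 + a12 * nb2) * ic
      be2 <- (a21 * nb1 + a22 * nb2) * ic
      beta[t, 1] <- be1; beta[t, 2] <- be2
    }
    xi <- matrix(c(x11, x21, x12, x22), 2, 2)
  } else {
    for (t in 2:Tn) {
      a <- (alpha[t - 1, ] %*% A)[1, ] * Bs[t, ]
      cvec[t] <- sum(a)
      alpha[t, ] <- a / cvec[t]
    }
    beta <- matrix(0, Tn, S)
    beta[Tn, ] <- 1
    xi <- matrix(0, S, S)
    for (t in (Tn - 1):1) {
      nb <- Bs[t + 1, ] * beta[t + 1, ]
      xi <- xi + (alpha[t, ] %o% nb) * A / cvec[t + 1]
      beta[t, ] <- (A %*% nb) / cvec[t + 1]
    }
  }
  list(loglik = sum(log(cvec)) + sum(mx), gamma = alpha * beta, xi = xi)
}

# Forward log-likelihood only (for scoring and the enumeration check).
hmm_forward_loglik <- function(logB, pi0, A) {
  forward_backward(logB, pi0, A)$loglik
}

#' Log-likelihood of an observation sequence under a fitted gait HMM
#'
#' @param hmm A [gait_hmm()] fit.
#' @param obs Observation matrix (as from [build_observations()]).
#' @return Scalar log-likelihood (forward algorithm).
#' @export
hmm_loglik <- function(hmm, obs) {
  hmm_forward_loglik(mog_logdens(obs, hmm$emission)$logB, hmm$pi, hmm$A)
}

#' Fit a two-state gait HMM by Baum-Welch
#'
#' Unsupervised expectation-maximisation fit of a two-state hidden Markov
#' model with mixture-of-Gaussians emissions (4 components per state,
#' diagonal covariances) over sliding activity windows.  The state priors
#' and transition matrix are initialised from the empirical swing/stance
#' dwell statistics of the step annotation (the annotation is used only for
#' this initialisation, never as a supervision signal); emission parameters
#' start at random.  State 1 is anchored to "swing" through the
#' initialisation and the label is carried through EM.
#'
#' @param obs An [build_observations()] matrix.
#' @param steps Optional [step_annotation()] for the dwell-time
#'   initialisation; without it a generic gait prior (120 ms swing, 200 ms
#'   stance) is used.
#' @param n_mix Mixture components per state.
#' @param max_iter EM iteration cap.
#' @param tol Relative log-likelihood improvement tolerance.
#' @param seed RNG seed for the random emission initialisation.
#' @param var_floor Variance floor (fraction of the data variance).
#' @return An object of class `gait_hmm`: `pi`, `A`, `emission` (per-state
#'   weights/means/variances), `loglik`, `ll_trace`, `state_labels`,
#'   `n_reinit`, `converged`.
#' @export
gait_hmm <- function(obs, steps = NULL, n_mix = 4, max_iter = 50,
                     tol = 1e-4, seed = 1L, var_floor = 1e-4) {
  obs <- unclass(obs)
  stopifnot(is.matrix(obs), nrow(obs) >= 2)
  bin_s <- attr(obs, "bin_s"); if (is.null(bin_s)) bin_s <- 1 / 30
  Tn <- nrow(obs); D <- ncol(obs); S <- 2L

  # dwell-time initialisation of priors and transitions (state 1 = swing)
  dwell <- c(swing = 0.12, stance = 0.2)
  if (!is.null(steps)) {
    iv <- steps$intervals
    for (ph in c("swing", "stance")) {
      dd <- iv$end_s[iv$phase == ph] - iv$start_s[iv$phase == ph]
      if (length(dd)) dwell[ph] <- mean(dd)
    }
  }
  dw_bins <- pmax(1.5, dwell / bin_s)
  A <- rbind(c(1 - 1 / dw_bins[1], 1 / dw_bins[1]),
             c(1 / dw_bins[2], 1 - 1 / dw_bins[2]))
  pi0 <- dwell / sum(dwell)
  names(pi0) <- NULL

  colvar <- pmax(apply(obs, 2, stats::var), 1e-12)
  floorv <- var_floor * colvar
  init_component <- function() {
    list(mu = obs[sample.int(Tn, 1), ] +
           stats::rnorm(D, 0, sqrt(colvar) / 4),
         sigma2 = colvar)
  }
  em <- with_seed(seed, {
    lapply(seq_len(S), function(s) {
      mus <- t(vapply(seq_len(n_mix), function(m) init_component()$mu,
                      numeric(D)))
      list(w = rep(1 / n_mix, n_mix), mu = mus,
           sigma2 = matrix(colvar, n_mix, D, byrow = TRUE))
    })
  })

  ll_trace <- numeric(0)
  n_reinit <- 0L
  converged <- FALSE
  rng_state <- child_seed(seed, 7L)
  for (it in seq_len(max_iter)) {
    dens <- mog_logdens(obs, em)
    fb <- forward_backward(dens$logB, pi0, A)
    ll_trace <- c(ll_trace, fb$loglik)
    if (it > 1) {
      gain <- fb$loglik - ll_trace[it - 1]
      if (abs(gain) < tol * abs(ll_trace[it - 1])) { converged <- TRUE; break }
    }
    g <- fb$gamma
    pi0 <- g[1, ] / sum(g[1, ])
    A <- fb$xi / rowSums(fb$xi)
    for (s in seq_len(S)) {
      # component responsibilities within state s
      r <- exp(dens$logC[[s]] - dens$logB[, s]) * g[, s]
      Ns <- colSums(r)
      bad <- which(Ns < 1e-6 * Tn)
      for (m in seq_len(n_mix)) {
        if (m %in% bad) next
        em[[s]]$w[m] <- Ns[m] / sum(g[, s])
        mu <- colSums(r[, m] * obs) / Ns[m]
        em[[s]]$mu[m, ] <- mu
        v <- colSums(r[, m] * sweep(obs, 2, mu)^2) / Ns[m]
        em[[s]]$sigma2[m, ] <- pmax(v, floorv)
      }
      if (length(bad)) {
        n_reinit <- n_reinit + length(bad)
        if (n_reinit > 20) stopf("EM failed: repeated degenerate components")
        rng_state <- child_seed(rng_state, 13L)
        em[[s]] <- with_seed(rng_state, {
          e <- em[[s]]
          for (m in bad) {
            cm <- init_component()
            e$mu[m, ] <- cm$mu
            e$sigma2[m, ] <- cm$sigma2
            e$w[m] <- 1e-3
          }
          e$w <- e$w / sum(e$w)
          e
        })
      }
      em[[s]]$w <- em[[s]]$w / sum(em[[s]]$w)
    }
  }
  final_ll <- hmm_forward_loglik(mog_logdens(obs, em)$logB, pi0, A)
  structure(list(pi = pi0, A = A, emission = em,
                 loglik = final_ll, ll_trace = ll_trace,
                 state_labels = c("swing", "stance"),
                 bin_s = bin_s, n_mix = n_mix, dim = D,
                 n_reinit = n_reinit, converged = converged,
                 n_obs = Tn),
            class = "gait_hmm")
}

#' @export
print.gait_hmm <- function(x, ...) {
  cat(sprintf(paste0("<gait_hmm> 2 states x %d Gaussians over %d-bin windows; ",
                     "logLik %.1f after %d EM iterations%s\n"),
              x$n_mix, x$dim, x$loglik, length(x$ll_trace),
              if (x$converged) "" else " (iteration cap reached)"))
  cat("Transition matrix (swing, stance):\n")
  print(round(x$A, 3))
  invisible(x)
}

#' @export
logLik.gait_hmm <- function(object, ...) {
  structure(object$loglik, df = NA, class = "logLik")
}

#' @export
simulate.gait_hmm <- function(object, nsim = 100, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  S <- length(object$pi)
  st <- integer(nsim)
  st[1] <- sample.int(S, 1, prob = object$pi)
  for (t in 2:nsim) st[t] <- sample.int(S, 1, prob = object$A[st[t - 1], ])
  D <- object$dim
  obs <- matrix(0, nsim, D)
  for (t in seq_len(nsim)) {
    e <- object$emission[[st[t]]]
    m <- sample.int(length(e$w), 1, prob = e$w)
    obs[t, ] <- stats::rnorm(D, e$mu[m, ], sqrt(e$sigma2[m, ]))
  }
  list(obs = structure(obs, bin_s = object$bin_s), states = st)
}

#' Decode the most likely swing/stance path
#'
#' Viterbi decoding of an observation sequence under a fitted gait HMM.
#' State labels follow the fit's initialisation anchoring (state 1 =
#' swing).
#'
#' @param object A [gait_hmm()] fit.
#' @param newdata Observation matrix.
#' @param ... Unused.
#' @return An object of class `step_prediction`: per-window `state`
#'   (labels), `swing_onsets_s` (stance-to-swing transition times), and
#'   the path log-probability `logp`.
#' @export
predict.gait_hmm <- function(object, newdata, ...) {
  obs <- unclass(newdata)
  logB <- mog_logdens(obs, object$emission)$logB
  Tn <- nrow(logB); S <- ncol(logB)
  lA <- log(object$A)
  delta <- log(object$pi) + logB[1, ]
  psi <- matrix(0L, Tn, S)
  for (t in 2:Tn) {
    cand <- delta + lA  # S x S: cand[i, j] = delta_i + log a_ij
    psi[t, ] <- max.col(t(cand), ties.method = "first")
    delta <- apply(cand, 2, max) + logB[t, ]
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta)
  for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  states <- object$state_labels[path]
  onset_idx <- which(path[-1] == 1L & path[-Tn] == 2L) + 1L
  structure(list(state = states,
                 swing_onsets_s = (onset_idx - 1) * object$bin_s,
                 bin_s = object$bin_s, logp = max(delta)),
            class = "step_prediction")
}

#' @export
print.step_prediction <- function(x, ...) {
  cat(sprintf("<step_prediction> %d windows, %d predicted swing onsets\n",
              length(x$state), length(x$swing_onsets_s)))
  invisible(x)
}

#' Gaussian-kernel similarity between step transition trains
#'
#' Converts predicted and actual step sequences into point trains at the
#' stance-to-swing transitions, convolves both with a Gaussian kernel
#' (sigma = 100 ms), and takes the peak of the normalised, mean-subtracted
#' cross-correlation within the searched lag range.  The score is 1 for
#' identical trains and negative peaks are clamped to 0 so it lies in
#' \[0, 1\]; the unclamped value is attached as attribute `raw`.
#'
#' @param pred A [predict.gait_hmm()] result or numeric vector of
#'   transition times (s).
#' @param actual A [step_annotation()] (swing onsets of `limb`) or numeric
#'   vector of transition times.
#' @param sigma_ms Gaussian kernel SD, ms.
#' @param lag_max_ms Lag search range, ms.
#' @param limb Limb selector when `actual` is an annotation.
#' @param bin_s Time grid for the convolution, s.
#' @param duration Common duration (defaults to covering both trains).
#' @return Similarity in \[0, 1\].
#' @export
similarity_score <- function(pred, actual, sigma_ms = 100, lag_max_ms = 500,
                             limb = NULL, bin_s = 1 / 120, duration = NULL) {
  p <- if (inherits(pred, "step_prediction")) pred$swing_onsets_s else pred
  a <- if (inherits(actual, "step_annotation")) swing_onsets(actual, limb)
       else actual
  if (!length(p) || !length(a)) {
    warnf("a transition train is empty; similarity set to 0")
    return(structure(0, raw = NA_real_))
  }
  if (is.null(duration)) duration <- max(p, a) + 4 * sigma_ms / 1000
  n <- ceiling(duration / bin_s)
  tr <- function(tt) {
    x <- numeric(n)
    i <- pmin(n, pmax(1L, round(tt / bin_s) + 1L))
    for (j in i) x[j] <- x[j] + 1
    x
  }
  half <- ceiling(4 * sigma_ms / 1000 / bin_s)
  k <- stats::dnorm(seq(-half, half) * bin_s, sd = sigma_ms / 1000)
  sm <- function(x) conv_causal(c(x, numeric(half)), k)[(half + 1):(n + half)]
  xs <- sm(tr(p)); ys <- sm(tr(a))
  lag_max <- round(lag_max_ms / 1000 / bin_s)
  # per-lag normalisation over the overlapping segment, so that a pure
  # time shift within the searched range scores exactly 1
  lag_corr <- function(L) {
    if (L >= 0) { xv <- xs[seq_len(n - L)]; yv <- ys[seq_len(n - L) + L] }
    else { xv <- xs[seq_len(n + L) - L]; yv <- ys[seq_len(n + L)] }
    if (stats::sd(xv) == 0 || stats::sd(yv) == 0) return(NA_real_)
    stats::cor(xv, yv)
  }
  cc <- vapply(-lag_max:lag_max, lag_corr, numeric(1))
  raw <- suppressWarnings(max(cc, na.rm = TRUE))
  if (!is.finite(raw)) raw <- 0
  structure(max(0, raw), raw = raw)
}

#' End-to-end gait decoding with shuffle significance
#'
#' Runs the complete decoding pipeline: builds observation windows from the
#' binned activity, fits the two-state HMM `runs` times with independent
#' random emission initialisations, decodes each fit, scores the predicted
#' swing-onset train against each annotated limb (percent similarity), and
#' averages across runs.  The best-predicted limb is reported.
#' Significance comes from re-running the procedure on shuffled versions of
#' the binned activity (z-score against the shuffle null, one-sided normal
#' p, Bonferroni-corrected by `family_size`).
#'
#' @param activity A [rate_series_obj()] binned at the frame duration.
#' @param steps A [step_annotation()] with both forelimbs.
#' @param mode Observation preprocessing, `"epsc"` or `"spike"`.
#' @param runs HMM restarts averaged into the score.
#' @param n_shuffles Shuffle-null replicates.
#' @param shuffle_runs HMM restarts per shuffle replicate.
#' @param seed RNG seed.
#' @param family_size Bonferroni family size.
#' @param sigma_ms,lag_max_ms Similarity-metric parameters.
#' @param ... Passed to [gait_hmm()].
#' @return An object of class `prediction_score`: `score` (percent, best
#'   limb), `per_limb`, `per_run` (runs x limbs), `best_limb`, `z`, `p`,
#'   `p_corrected`, `null_scores`.
#' @export
evaluate_gait_decoding <- function(activity, steps, mode = c("epsc", "spike"),
                                   runs = 10, n_shuffles = 15,
                                   shuffle_runs = 2, seed = 1L,
                                   family_size = 1, sigma_ms = 100,
                                   lag_max_ms = 500, ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(activity, "rate_series"))
  limbs <- sort(unique(steps$intervals$limb))
  if (!length(limbs)) stopf("annotation contains no steps")
  dur <- length(activity$values) / activity$fs

  score_series <- function(values, n_runs, base_seed) {
    obs <- build_observations(
      rate_series_obj(values, activity$fs, kind = activity$kind), mode = mode)
    sc <- matrix(NA_real_, n_runs, length(limbs),
                 dimnames = list(NULL, limbs))
    for (r in seq_len(n_runs)) {
      h <- gait_hmm(obs, steps, seed = child_seed(base_seed, r), ...)
      pr <- predict(h, obs)
      for (li in seq_along(limbs))
        sc[r, li] <- 100 * similarity_score(
          pr, steps, sigma_ms = sigma_ms, lag_max_ms = lag_max_ms,
          limb = limbs[li], duration = dur)
    }
    sc
  }

  per_run <- score_series(activity$values, runs, child_seed(seed, 100L))
  per_limb <- colMeans(per_run)
  best <- which.max(per_limb)
  obs_score <- per_limb[best]

  null_scores <- with_seed(child_seed(seed, 200L), {
    shufs <- lapply(seq_len(n_shuffles), function(k) sample(activity$values))
    vapply(seq_len(n_shuffles), function(k) {
      sc <- score_series(shufs[[k]], shuffle_runs, child_seed(seed, 300L + k))
      max(colMeans(sc))
    }, numeric(1))
  })
  ns <- stats::sd(null_scores)
  z <- if (ns > 0) (obs_score - mean(null_scores)) / ns else NA_real_
  p <- if (is.na(z)) NA_real_ else stats::pnorm(z, lower.tail = FALSE)
  structure(list(score = unname(obs_score), per_limb = per_limb,
                 per_run = per_run, best_limb = limbs[best],
                 z = z, p = p,
                 p_corrected = if (is.na(p)) NA_real_
                               else min(1, p * family_size),
                 null_scores = null_scores, runs = runs,
                 n_shuffles = n_shuffles),
            class = "prediction_score")
}

#' @export
print.prediction_score <- function(x, ...) {
  cat(sprintf("<prediction_score> %.1f%% (best limb: %s; %d runs), z = %.2f, p = %.3g\n",
              x$score, x$best_limb, x$runs, x$z, x$p))
  invisible(x)
}
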