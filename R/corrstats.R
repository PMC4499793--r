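#' Shuffle-bootstrap significance of a series statistic
#'
#' Recomputes a statistic on random permutations of a (binned) activity
#' series, forms `z = (observed - null mean) / null SD`, and converts to a
#' one-sided p-value from the standard normal table, optionally
#' Bonferroni-corrected by a family size.  Full permutation destroys all
#' autocorrelation; a block shuffle is available for a more conservative
#' null.
#'
#' @param stat Function of the series returning a scalar.
#' @param series Numeric vector (the binned activity).
#' @param n Number of shuffles (>= 100).
#' @param seed RNG seed.
#' @param family_size Bonferroni family size.
#' @param block Block length for block shuffling (1 = full permutation).
#' @return An object of class `bootstrap_result`: `observed`, `null_mean`,
#'   `null_sd`, `z`, `p`, `p_corrected`, `n_shuffles`.
#' @export
shuffle_bootstrap <- function(stat, series, n = 1000, seed = 1L,
                              family_size = 1, block = 1) {
  if (n < 100) stopf("need at least 100 shuffles")
  obs <- stat(series)
  with_seed(seed, {
    null <- vapply(seq_len(n), function(b) {
      s <- if (block <= 1) sample(series)
      else {
        nb <- ceiling(length(series) / block)
        idx <- as.vector(outer(seq_len(block),
                               (sample.int(nb) - 1L) * block, "+"))
        series[idx[idx <= length(series)]][seq_along(series)]
      }
      stat(s)
    }, numeric(1))
    nm <- mean(null); ns <- stats::sd(null)
    if (!is.finite(ns) || ns == 0)
      stopf("degenerate null distribution (SD = 0); p undefined")
    z <- (obs - nm) / ns
    p <- stats::pnorm(z, lower.tail = FALSE)
    structure(list(observed = obs, null_mean = nm, null_sd = ns, z = z,
                   p = p, p_corrected = min(1, p * family_size),
                   n_shuffles = n),
              class = "bootstrap_result")
  })
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("observed %.4f vs null %.4f +/- %.4f: z = %.2f, p = %.3g%s\n",
              x$observed, x$null_mean, x$null_sd, x$z, x$p,
              if (x$p_corrected != x$p)
                sprintf(" (corrected %.3g)", x$p_corrected) else ""))
  invisible(x)
}

#' Coarse correlation of neural activity with the motion index
#'
#' Averages both series in coarse bins (default 1.5 s) and computes
#' Pearson's r, with significance from shuffling the binned activity.
#'
#' @param activity A [rate_series_obj()] (any timebase).
#' @param mi A [motion_index()] series or numeric vector with attribute-free
#'   frame values; `mi_fps` gives its rate when a bare vector is passed.
#' @param bin_s Coarse bin width, seconds.
#' @param n_shuffles,seed,family_size Passed to [shuffle_bootstrap()].
#' @param mi_fps Frame rate of `mi` if it is a bare vector.
#' @return List with `r` and a `bootstrap_result`.
#' @export
coarse_correlation <- function(activity, mi, bin_s = 1.5, n_shuffles = 1000,
                               seed = 1L, family_size = 1, mi_fps = 30) {
  av <- activity$values; afs <- activity$fs
  if (inherits(mi, "motion_index_series")) { mv <- mi$values; mfs <- mi$fps }
  else { mv <- as.numeric(mi); mfs <- mi_fps }
  rebin <- function(v, fs) {
    per <- max(1L, round(bin_s * fs))
    nb <- floor(length(v) / per)
    if (nb < 3) stopf("need at least 3 coarse bins")
    colMeans(matrix(v[seq_len(nb * per)], nrow = per))
  }
  a <- rebin(av, afs); m <- rebin(mv, mfs)
  nb <- min(length(a), length(m))
  a <- a[seq_len(nb)]; m <- m[seq_len(nb)]
  if (stats::sd(a) == 0 || stats::sd(m) == 0)
    stopf("zero-variance input; correlation undefined")
  bs <- shuffle_bootstrap(function(x) stats::cor(x, m), a, n = n_shuffles,
                          seed = seed, family_size = family_size)
  list(r = stats::cor(a, m), bootstrap = bs)
}

#' Fine-timescale rolling cross-correlation with significance
#'
#' Rolling normalised cross-correlation (3-s windows by default) between an
#' activity series and a target series on a common fine timebase (33.3 ms
#' bins), averaged across windows, with a shuffle null for the peak.
#'
#' @param activity,target Numeric vectors or [rate_series_obj()] on a
#'   common timebase.
#' @param fs Common sampling rate (Hz) when bare vectors are passed.
#' @param window_s Rolling window, seconds.
#' @param lag_max_s Maximum lag; defaults to half the window.
#' @param n_shuffles,seed,family_size Shuffle-null parameters.
#' @return List with the `xcorr_result` and a `bootstrap_result` for the
#'   peak magnitude.
#' @export
fine_sliding_xcorr <- function(activity, target, fs = 30, window_s = 3,
                               lag_max_s = window_s / 2, n_shuffles = 200,
                               seed = 1L, family_size = 1) {
  a <- if (inherits(activity, "rate_series")) activity$values else activity
  if (inherits(activity, "rate_series")) fs <- activity$fs
  y <- if (inherits(target, "rate_series")) target$values else
       if (inherits(target, "motion_index_series")) target$values else target
  m <- min(length(a), length(y))
  a <- a[seq_len(m)]; y <- y[seq_len(m)]
  xc <- sliding_xcorr(a, y, fs, window_s, lag_max_s)
  bs <- shuffle_bootstrap(function(s) {
    max(abs(sliding_xcorr(s, y, fs, window_s, lag_max_s)$mean_corr))
  }, a, n = max(100, n_shuffles), seed = seed, family_size = family_size)
  list(xcorr = xc, bootstrap = bs)
}

#' Event rates around locomotion onsets and offsets
#'
#' For each locomotion bout, compares a 500-ms window of the rate 1 s
#' before the first swing with the window immediately after onset, and the
#' window immediately before the last swing end with the window 1 s after
#' it.  Bouts lacking context are skipped and counted.
#'
#' @param rate A [rate_series_obj()].
#' @param bouts Data frame with `start_s`, `end_s` (e.g.
#'   [locomotion_bouts()]).
#' @param window_s Comparison window, seconds.
#' @param gap_s Offset of the pre-onset / post-offset windows, seconds.
#' @return List with data frames `onset` and `offset` (per-bout `pre`,
#'   `post` mean rates) and counts of skipped bouts.
#' @export
onset_offset_rates <- function(rate, bouts, window_s = 0.5, gap_s = 1) {
  v <- rate$values; fs <- rate$fs
  dur <- length(v) / fs
  win_mean <- function(a, b) {
    i <- (floor(a * fs) + 1L):ceiling(b * fs)
    if (min(i) < 1 || max(i) > length(v)) return(NA_real_)
    mean(v[i])
  }
  onset <- offset <- data.frame(pre = numeric(0), post = numeric(0))
  sk_on <- sk_off <- 0L
  for (k in seq_len(nrow(bouts))) {
    on <- bouts$start_s[k]; off <- bouts$end_s[k]
    pre <- win_mean(on - gap_s, on - gap_s + window_s)
    post <- win_mean(on, on + window_s)
    if (is.na(pre) || is.na(post)) sk_on <- sk_on + 1L
    else onset <- rbind(onset, data.frame(pre = pre, post = post))
    pre2 <- win_mean(off - window_s, off)
    post2 <- win_mean(off + gap_s, off + gap_s + window_s)
    if (is.na(pre2) || is.na(post2)) sk_off <- sk_off + 1L
    else offset <- rbind(offset, data.frame(pre = pre2, post = post2))
  }
  list(onset = onset, offset = offset, skipped_onset = sk_on,
       skipped_offset = sk_off)
}
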