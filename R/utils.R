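# Internal numerical helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and a small op-specific offset,
# kept inside the 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 101L + offset) %% 2147483647)
}

# Causal discrete convolution: y[i] = sum_j x[j] k[i - j + 1], truncated to
# length(x).  FFT-based; k is the kernel sampled at the same rate as x.
conv_causal <- function(x, k) {
  n <- length(x)
  m <- length(k)
  nfft <- stats::nextn(n + m - 1L, 2L)
  xf <- stats::fft(c(x, rep(0, nfft - n)))
  kf <- stats::fft(c(k, rep(0, nfft - m)))
  y <- Re(stats::fft(xf * kf, inverse = TRUE)) / nfft
  y[seq_len(n)]
}

# Recursive causal exponential filter of a per-sample count vector.
# Discrete kernel fs(1-a) a^k matches (1/tau) exp(-t/tau) as fs -> Inf and
# sums exactly to 1 per event, so the output is a rate in Hz that conserves
# the event count.
exp_rate_filter <- function(counts, fs, tau_s) {
  a <- exp(-1 / (fs * tau_s))
  as.numeric(stats::filter(counts * (1 - a) * fs, a, method = "recursive"))
}

# Bin event times into counts on a regular grid covering [0, duration).
bin_counts <- function(times, duration, bin_s) {
  nb <- max(1L, ceiling(duration / bin_s - 1e-9))
  idx <- floor(times / bin_s) + 1L
  idx <- idx[idx >= 1L & idx <= nb]
  tabulate(idx, nbins = nb)
}

# Mean-subtracted, normalised cross-correlation of two equal-length vectors
# at integer lags -lag_max..lag_max.  Positive lag means y lags x.
norm_xcorr <- function(x, y, lag_max) {
  x <- x - mean(x)
  y <- y - mean(y)
  den <- sqrt(sum(x^2) * sum(y^2))
  lags <- -lag_max:lag_max
  if (den == 0) return(list(lags = lags, corr = rep(NA_real_, length(lags))))
  n <- length(x)
  cc <- vapply(lags, function(L) {
    if (L >= 0) sum(x[seq_len(n - L)] * y[seq_len(n - L) + L])
    else sum(x[seq_len(n + L) - L] * y[seq_len(n + L)])
  }, numeric(1))
  list(lags = lags, corr = cc / den)
}

# Sliding-window averaged normalised cross-correlation (rolling scheme):
# split into windows, mean-subtract and correlate within each, then
# average across windows.  Zero-variance windows are skipped and counted.
sliding_xcorr <- function(x, y, fs, window_s, lag_max_s, stride_s = window_s / 2) {
  stopifnot(length(x) == length(y))
  wlen <- round(window_s * fs)
  if (wlen > length(x)) stop("window longer than the series")
  lag_max <- round(lag_max_s * fs)
  stride <- max(1L, round(stride_s * fs))
  starts <- seq(1L, length(x) - wlen + 1L, by = stride)
  acc <- matrix(NA_real_, nrow = length(starts), ncol = 2 * lag_max + 1)
  skipped <- 0L
  for (i in seq_along(starts)) {
    sel <- starts[i]:(starts[i] + wlen - 1L)
    xs <- x[sel]; ys <- y[sel]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) { skipped <- skipped + 1L; next }
    acc[i, ] <- norm_xcorr(xs, ys, lag_max)$corr
  }
  ok <- rowSums(is.na(acc)) == 0
  if (!any(ok)) stop("no windows with non-zero variance")
  lags <- (-lag_max:lag_max) / fs
  m <- colMeans(acc[ok, , drop = FALSE])
  s <- apply(acc[ok, , drop = FALSE], 2, stats::sd)
  pk <- which.max(abs(m))
  structure(list(lags = lags, mean_corr = m, sd_corr = s,
                 peak_corr = m[pk], peak_lag = lags[pk],
                 n_windows = sum(ok), n_skipped = skipped),
            class = "xcorr_result")
}

#' @export
print.xcorr_result <- function(x, ...) {
  cat(sprintf("Sliding cross-correlation: peak %.3f at lag %+.1f ms (%d windows)\n",
              x$peak_corr, 1000 * x$peak_lag, x$n_windows))
  invisible(x)
}

# Peak time (ms) and peak value of the biexponential kernel; closed form.
biexp_peak <- function(tau_rise, tau_fall) {
  tstar <- log(tau_fall / tau_rise) / (1 / tau_rise - 1 / tau_fall)
  list(t_peak = tstar, peak = zeta(tau_rise, tau_fall, tstar))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
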