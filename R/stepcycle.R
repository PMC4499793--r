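#' Step-triggered average activity
#'
#' Triggers fixed-length episodes of a binned activity series (40 bins of
#' the 33.3-ms frame duration, i.e. 1.32 s) on stance or swing onsets and
#' averages them.  Episodes running past the end of the recording are
#' dropped and counted.
#'
#' @param rate A [rate_series_obj()] binned at the video frame duration.
#' @param steps A [step_annotation()].
#' @param trigger `"stance_start"` or `"swing_start"`.
#' @param limb Limb name (default: first annotated limb).
#' @param n_bins Episode length in bins.
#' @return An object of class `step_triggered_average`: `sigma` (the mean
#'   episode), `episodes` (matrix steps x bins), `n_steps`, `n_dropped`,
#'   `bin_s`, `trigger`.
#' @export
step_triggered_average <- function(rate, steps, trigger = c("stance_start",
                                                            "swing_start"),
                                   limb = NULL, n_bins = 40) {
  trigger <- match.arg(trigger)
  stopifnot(inherits(rate, "rate_series"), inherits(steps, "step_annotation"))
  trig_t <- if (trigger == "stance_start") stance_onsets(steps, limb)
            else swing_onsets(steps, limb)
  if (!length(trig_t)) stopf("no %s triggers in the annotation", trigger)
  v <- rate$values
  bin_s <- 1 / rate$fs
  i0 <- floor(trig_t / bin_s) + 1L
  ok <- i0 >= 1 & (i0 + n_bins - 1L) <= length(v)
  if (!any(ok)) stopf("no trigger followed by %d bins of data", n_bins)
  ep <- t(vapply(i0[ok], function(i) v[i:(i + n_bins - 1L)],
                 numeric(n_bins)))
  structure(list(sigma = colMeans(ep), episodes = ep,
                 n_steps = sum(ok), n_dropped = sum(!ok),
                 bin_s = bin_s, trigger = trigger,
                 limb = if (is.null(limb))
                   sort(unique(steps$intervals$limb))[1] else limb,
                 rate_values = v),
            class = "step_triggered_average")
}

#' @export
print.step_triggered_average <- function(x, ...) {
  cat(sprintf("<step_triggered_average> %s, limb %s: %d steps (%d dropped), %d bins\n",
              x$trigger, x$limb, x$n_steps, x$n_dropped, length(x$sigma)))
  invisible(x)
}

# Raw modulation index of an activity vector.
mod_index <- function(sigma) {
  mx <- max(sigma); mn <- min(sigma)
  if (mx == 0) stopf("modulation index undefined: max(sigma) = 0")
  (mx - mn) / (mx + mn)
}

#' Step-cycle modulation index with bootstrap significance
#'
#' Computes `m = (max sigma - min sigma) / (max sigma + min sigma)` of a
#' step-triggered average and assesses significance against a null built by
#' re-triggering on one random window per real step.
#'
#' @param sta A [step_triggered_average()], or a bare nonnegative vector
#'   (in which case no bootstrap is possible and only `m` is returned).
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed.
#' @param family_size Bonferroni family size.
#' @return An object of class `modulation_result`: `m`, `z`, `p`,
#'   `p_corrected`, `null_mean`, `null_sd`, `limb`.
#' @export
modulation_index <- function(sta, n_boot = 1000, seed = 1L,
                             family_size = 1) {
  if (is.numeric(sta)) {
    if (any(sta < 0)) stopf("sigma must be nonnegative")
    return(structure(list(m = mod_index(sta), z = NA_real_, p = NA_real_,
                          p_corrected = NA_real_, limb = NA_character_),
                     class = "modulation_result"))
  }
  stopifnot(inherits(sta, "step_triggered_average"))
  sigma <- sta$sigma
  if (any(sigma < 0)) stopf("sigma must be nonnegative")
  m <- mod_index(sigma)
  v <- sta$rate_values
  nb <- length(sigma)
  nstep <- sta$n_steps
  with_seed(seed, {
    null <- vapply(seq_len(n_boot), function(b) {
      i0 <- sample.int(length(v) - nb + 1L, nstep, replace = TRUE)
      ep <- vapply(i0, function(i) v[i:(i + nb - 1L)], numeric(nb))
      mod_index(rowMeans(ep))
    }, numeric(1))
    nm <- mean(null); ns <- stats::sd(null)
    z <- if (ns > 0) (m - nm) / ns else NA_real_
    p <- if (is.na(z)) NA_real_ else stats::pnorm(z, lower.tail = FALSE)
    structure(list(m = m, z = z, p = p,
                   p_corrected = if (is.na(p)) NA_real_
                                 else min(1, p * family_size),
                   null_mean = nm, null_sd = ns, limb = sta$limb),
              class = "modulation_result")
  })
}

#' @export
print.modulation_result <- function(x, ...) {
  cat(sprintf("m = %.3f", x$m))
  if (!is.na(x$z)) cat(sprintf(" (z = %.2f, p = %.3g)", x$z, x$p))
  cat("\n")
  invisible(x)
}

#' Polar representation of step-cycle tuning
#'
#' Maps the step-triggered activity vector onto 360 degrees (linear
#' interpolation), takes the absolute deviation from the mean activity as
#' the radius, subtracts the minimum across phases, and divides by the
#' maximum so R lies in \[0, 1\].  Also returns the z-profile
#' `(sigma - mean) / SD` and the phase of maximal modulation.  By
#' convention 0 degrees is the start of the swing phase, so pass an
#' average triggered on swing onsets for figure-style phases.
#'
#' @param sigma Activity vector (e.g. `sta$sigma`), or a
#'   [step_triggered_average()].
#' @return An object of class `polar_modulation`: `theta_deg`, `R`,
#'   `phase_max_deg`, `z_profile`.
#' @export
polar_modulation <- function(sigma) {
  if (inherits(sigma, "step_triggered_average")) sigma <- sigma$sigma
  if (stats::sd(sigma) == 0)
    stopf("zero-variance activity: polar modulation undefined")
  n <- length(sigma)
  theta <- 0:359
  act <- stats::approx(seq(0, 360, length.out = n + 1),
                       c(sigma, sigma[1]), xout = theta)$y
  R <- abs(act - mean(act))
  R <- R - min(R)
  R <- R / max(R)
  structure(list(theta_deg = theta, R = R,
                 phase_max_deg = theta[which.max(R)],
                 z_profile = (act - mean(act)) / stats::sd(act)),
            class = "polar_modulation")
}

#' @export
print.polar_modulation <- function(x, ...) {
  cat(sprintf("<polar_modulation> maximal modulation at %d deg\n",
              x$phase_max_deg))
  invisible(x)
}

#' Low-pass (biexponential) filtering control for step modulation
#'
#' Convolves the binned rate with a unit-integral biexponential kernel
#' (rise 50 ms, decay 100 ms by default) and recomputes the step-triggered
#' average and modulation index, mimicking the temporal filtering a slow
#' synaptic current applies to its driving rate.
#'
#' @param rate A [rate_series_obj()] at the frame duration.
#' @param steps A [step_annotation()].
#' @param rise_ms,decay_ms Kernel time constants, ms.
#' @param ... Passed to [step_triggered_average()] /
#'   [modulation_index()].
#' @return List: `filtered` (the filtered [rate_series_obj()]),
#'   `m_unfiltered`, `m_filtered` ([modulation_index()] results).
#' @export
filtered_rate_control <- function(rate, steps, rise_ms = 50, decay_ms = 100,
                                  ...) {
  stopifnot(inherits(rate, "rate_series"))
  fs <- rate$fs
  k <- sampled_biexp(rise_ms, decay_ms, fs, unit = "integral") / fs
  filt <- rate_series_obj(conv_causal(rate$values, k), fs,
                          kind = sprintf("biexp-filtered %g/%g ms",
                                         rise_ms, decay_ms))
  sta0 <- step_triggered_average(rate, steps, ...)
  sta1 <- step_triggered_average(filt, steps, ...)
  list(filtered = filt,
       m_unfiltered = modulation_index(sta0),
       m_filtered = modulation_index(sta1))
}

#' Interlimb comparison of step-cycle modulation
#'
#' Circular phase difference (reported in \[0, 180\] degrees) between the
#' preferred phases of the two forelimbs, correlation of modulation
#' magnitude across cells, and the signed direction (z) of the maximal
#' modulation per limb.
#'
#' @param left,right Per-cell lists with elements `m` (modulation index),
#'   `phase_deg` (preferred phase) and optionally `z`; or single results.
#' @return List: `phase_diff_deg` per cell, `m_correlation` (across cells,
#'   `NA` with fewer than 3), `direction` data frame of signed z pairs.
#' @export
interlimb_summary <- function(left, right = NULL) {
  if (is.null(right)) {
    warnf("single-limb input: returning partial summary")
    return(list(phase_diff_deg = NULL, m_correlation = NA_real_,
                direction = NULL))
  }
  as_list <- function(x) if (!is.null(x$m)) list(x) else x
  L <- as_list(left); R <- as_list(right)
  stopifnot(length(L) == length(R))
  pd <- vapply(seq_along(L), function(i) {
    d <- (L[[i]]$phase_deg - R[[i]]$phase_deg) %% 360
    min(d, 360 - d)
  }, numeric(1))
  mL <- vapply(L, function(x) x$m, numeric(1))
  mR <- vapply(R, function(x) x$m, numeric(1))
  mc <- if (length(mL) >= 3 && stats::sd(mL) > 0 && stats::sd(mR) > 0)
    stats::cor(mL, mR) else NA_real_
  zL <- vapply(L, function(x) if (is.null(x$z)) NA_real_ else x$z, numeric(1))
  zR <- vapply(R, function(x) if (is.null(x$z)) NA_real_ else x$z, numeric(1))
  list(phase_diff_deg = pd, m_correlation = mc,
       direction = data.frame(z_left = zL, z_right = zR))
}
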