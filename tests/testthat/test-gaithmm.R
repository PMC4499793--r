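test_that("observation windows apply the modality preprocessing", {
  r <- rate_series_obj(rep(6, 120), 30)
  obs <- build_observations(r, mode = "epsc")
  expect_equal(ncol(obs), 11)
  expect_true(all(abs(obs - 1) < 1e-12))
  obs2 <- build_observations(r, mode = "spike")
  expect_true(all(abs(obs2) < 1e-12))
  expect_error(build_observations(rate_series_obj(rep(0, 120), 30),
                                  mode = "epsc"), "mean rate")
  # step-locked rates separate into two clusters
  v <- rep(c(rep(12, 50), rep(2, 50)), 5)
  obs3 <- build_observations(rate_series_obj(v, 30), mode = "epsc")
  km <- kmeans(unclass(obs3), 2, nstart = 5)
  expect_gt(km$betweenss / km$totss, 0.5)
})

test_that("the forward algorithm equals brute-force path enumeration", {
  set.seed(10)
  em <- lapply(1:2, function(s) {
    list(w = c(0.3, 0.2, 0.25, 0.25),
         mu = matrix(rnorm(4 * 3, mean = 2 * s), 4, 3),
         sigma2 = matrix(runif(4 * 3, 0.5, 2), 4, 3))
  })
  pi0 <- c(0.4, 0.6)
  A <- rbind(c(0.7, 0.3), c(0.2, 0.8))
  obs <- matrix(rnorm(5 * 3, 1), 5, 3)

  # independent oracle: sum the joint density over all 2^5 paths
  dens_state <- function(x, s) {
    sum(vapply(1:4, function(m)
      em[[s]]$w[m] * prod(dnorm(x, em[[s]]$mu[m, ],
                                sqrt(em[[s]]$sigma2[m, ]))), numeric(1)))
  }
  total <- 0
  for (path_id in 0:31) {
    path <- as.integer(intToBits(path_id))[1:5] + 1L
    p <- pi0[path[1]] * dens_state(obs[1, ], path[1])
    for (t in 2:5)
      p <- p * A[path[t - 1], path[t]] * dens_state(obs[t, ], path[t])
    total <- total + p
  }
  hmm <- structure(list(pi = pi0, A = A, emission = em, bin_s = 1 / 30,
                        state_labels = c("swing", "stance")),
                   class = "gait_hmm")
  expect_equal(hmm_loglik(hmm, obs), log(total), tolerance = 1e-9)
})

test_that("EM is monotone and deterministic under a fixed seed", {
  rate <- rate_series(fix_session$epsc, bin_s = 1 / 30)
  obs <- build_observations(rate)
  h1 <- gait_hmm(obs, fix_session$steps, seed = 5, max_iter = 25)
  h2 <- gait_hmm(obs, fix_session$steps, seed = 5, max_iter = 25)
  expect_identical(h1$A, h2$A)
  expect_identical(h1$emission, h2$emission)
  expect_true(all(diff(h1$ll_trace) > -1e-9))
  expect_true(all(abs(rowSums(h1$A) - 1) < 1e-12))
  expect_equal(sum(h1$pi), 1, tolerance = 1e-12)
  for (s in 1:2) expect_equal(sum(h1$emission[[s]]$w), 1, tolerance = 1e-12)
})

test_that("parameters of a known mixture HMM are recovered", {
  truth <- structure(list(
    pi = c(0.5, 0.5),
    A = rbind(c(0.75, 0.25), c(0.15, 0.85)),
    emission = lapply(1:2, function(s)
      list(w = rep(0.25, 4),
           mu = matrix(rep(c(3, -3)[s], 4 * 6), 4, 6) +
             matrix(rnorm(24, 0, 0.2), 4, 6),
           sigma2 = matrix(0.8, 4, 6))),
    state_labels = c("swing", "stance"), bin_s = 1 / 30, dim = 6,
    n_mix = 4), class = "gait_hmm")
  set.seed(21)
  sim <- simulate(truth, nsim = 3000)
  fit <- gait_hmm(sim$obs, steps = NULL, seed = 2, max_iter = 40)
  # label-match by emission mean sign
  mu1 <- mean(fit$emission[[1]]$mu)
  ord <- if (mu1 > 0) 1:2 else 2:1
  Ah <- fit$A[ord, ord]
  expect_lt(max(abs(Ah - truth$A)), 0.05)
  # decoding matches the generating states almost everywhere
  pr <- predict(fit, sim$obs)
  dec <- ifelse(pr$state == "swing", ord[1], ord[2])
  expect_gte(mean(dec == sim$states), 0.95)
})

test_that("near-iid observations decode to an almost constant path", {
  set.seed(31)
  obs <- structure(matrix(rnorm(600 * 5), 600, 5), bin_s = 1 / 30)
  fit <- gait_hmm(obs, steps = NULL, seed = 3, max_iter = 20)
  pr <- predict(fit, obs)
  expect_gte(max(table(pr$state)) / 600, 0.5)
  # constant observations: a single-state path
  obsc <- structure(matrix(1, 100, 5), bin_s = 1 / 30)
  fitc <- gait_hmm(obsc, steps = NULL, seed = 3, max_iter = 10)
  prc <- predict(fitc, obsc)
  expect_gte(max(table(prc$state)) / length(prc$state), 0.9)
})

test_that("the Viterbi path outscores random paths", {
  rate <- rate_series(fix_session$epsc, bin_s = 1 / 30)
  obs <- build_observations(rate)
  fit <- gait_hmm(obs, fix_session$steps, seed = 7, max_iter = 20)
  dens <- gaitcode:::mog_logdens(unclass(obs), fit$emission)
  path_lp <- function(path) {
    lp <- log(fit$pi[path[1]]) + dens$logB[1, path[1]]
    for (t in 2:length(path))
      lp <- lp + log(fit$A[path[t - 1], path[t]]) + dens$logB[t, path[t]]
    lp
  }
  pr <- predict(fit, obs)
  vit <- ifelse(pr$state == "swing", 1L, 2L)
  set.seed(12)
  rand_lp <- vapply(1:100, function(r)
    path_lp(sample(1:2, length(vit), replace = TRUE)), numeric(1))
  expect_true(all(path_lp(vit) >= rand_lp))
})

test_that("the similarity metric is 1 for identical trains and clamps", {
  tt <- c(0.5, 1.1, 1.8, 2.6)
  expect_equal(as.numeric(similarity_score(tt, tt)), 1, tolerance = 1e-9)
  # symmetric
  uu <- c(0.4, 1.3, 2.0)
  expect_equal(as.numeric(similarity_score(tt, uu)),
               as.numeric(similarity_score(uu, tt)), tolerance = 1e-9)
  expect_warning(z <- similarity_score(numeric(0), tt), "empty")
  expect_equal(as.numeric(z), 0)
  # constant 300 ms offset: the peak search recovers self-similarity
  expect_equal(as.numeric(similarity_score(tt + 0.3, tt, lag_max_ms = 500)),
               1, tolerance = 1e-6)
  # zero-lag restriction: Gaussian-overlap oracle computed directly
  bin_s <- 1 / 120
  n <- ceiling((max(tt) + 0.3 + 0.4) / bin_s)
  g <- seq_len(n) * bin_s
  smooth <- function(ts) Reduce(`+`, lapply(ts, function(t0)
    dnorm(g, t0, 0.1)))
  xs <- smooth(tt + 0.3); ys <- smooth(tt)
  oracle <- sum((xs - mean(xs)) * (ys - mean(ys))) /
    sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
  got <- similarity_score(tt + 0.3, tt, lag_max_ms = 0, duration = n * bin_s)
  expect_equal(as.numeric(got), max(0, oracle), tolerance = 0.02)
})

test_that("end-to-end decoding is significant only for modulated trains", {
  cfg <- sim_config(seed = 55, duration = 40, ephys_fs = 2000, tau_rise = 2,
                    modulation_depth = 0.8)
  st <- generate_step_sequence(cfg)
  rate <- rate_series(generate_modulated_events(st, cfg, "epsc"),
                      bin_s = 1 / 30)
  ev <- evaluate_gait_decoding(rate, st, "epsc", runs = 5, n_shuffles = 10,
                               shuffle_runs = 1, seed = 2, max_iter = 25)
  expect_lt(ev$p, 0.05)
  expect_true(ev$best_limb %in% c("left", "right"))
  expect_equal(dim(ev$per_run), c(5L, 2L))
  # reproducible under the seed schedule
  ev2 <- evaluate_gait_decoding(rate, st, "epsc", runs = 5, n_shuffles = 10,
                                shuffle_runs = 1, seed = 2, max_iter = 25)
  expect_identical(ev$score, ev2$score)
  expect_identical(ev$null_scores, ev2$null_scores)
})
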