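test_that("background and map recursions match hand-unrolled values", {
  # single-pixel step 0 -> 255 at frame k
  n <- 20; k <- 6
  fr <- array(0L, dim = c(4, 4, n))
  fr[2, 2, k:n] <- 255L
  mm <- compute_motion_map(frame_stack(fr, 30), alpha = 0.3, beta = 0.9)
  # diffim at the step frame: 255 (1 - alpha); then geometric decay by 0.7
  expect_equal(mm$diffim[2, 2, k], 255 * 0.7)
  expect_equal(mm$diffim[2, 2, k + 3], 255 * 0.7^4, tolerance = 1e-9)
  # map recursion on top of the diffim sequence
  expect_equal(mm$map[2, 2, k], 0.9 * 255 * 0.7)
  expect_equal(mm$map[2, 2, k + 1],
               0.9 * 255 * 0.7^2 + 0.1 * 0.9 * 255 * 0.7)
  # all other pixels silent
  expect_equal(max(mm$map[-2, , ]), 0)

  # constant video: map -> 0; alpha = 1: background equals the frame
  cv <- frame_stack(array(37L, dim = c(4, 4, 10)), 30)
  expect_equal(max(compute_motion_map(cv)$map), 0)
  m1 <- compute_motion_map(frame_stack(fr, 30), alpha = 1)
  expect_equal(max(m1$diffim), 0)
  expect_error(compute_motion_map(frame_stack(array(0L, c(2, 2, 1)), 30)),
               "at least 2")
})

test_that("background window size follows the closed form", {
  # cumulative recency weight 1 - (1-alpha)^n >= 0.995 first at n = 15
  expect_identical(background_window_frames(0.3, 0.995), 15L)
  expect_gte(1 - 0.7^15, 0.995)
  expect_lt(1 - 0.7^14, 0.995)
  expect_identical(background_window_frames(0.5, 0.995), 8L)
})

test_that("motion index thresholds, normalises and ignores pixel layout", {
  n <- 10
  mp <- array(0, dim = c(8, 8, n))
  mp[1:5, 1:4, 4] <- 100   # 20 pixels above threshold
  mp[1:5, 1:8, 7] <- 100   # 40 pixels: the max frame
  mm <- structure(list(map = mp, fps = 30), class = "motion_map")
  mi <- motion_index(mm, threshold = 40)
  expect_equal(mi$values[7], 1)
  expect_equal(mi$values[4], 0.5)
  expect_equal(mi$values[1], 0)
  # all below threshold: series identically zero
  mm0 <- structure(list(map = mp * 0 + 30, fps = 30), class = "motion_map")
  expect_equal(motion_index(mm0)$values, rep(0, n))
  # permuting pixels within each frame leaves the index unchanged
  set.seed(5)
  perm <- sample(64)
  mp2 <- mp
  for (i in seq_len(n)) mp2[, , i] <- matrix(mp[, , i][perm], 8, 8)
  mm2 <- structure(list(map = mp2, fps = 30), class = "motion_map")
  expect_equal(motion_index(mm2)$values, mi$values)
})

test_that("epoch classification applies the rate and run-length rules", {
  mk <- function(v) structure(list(values = v, fps = 30),
                              class = "motion_index_series")
  # constant series: one quiet epoch over all (post-warmup) frames
  lab <- classify_epochs(mk(rep(0.3, 120)))
  expect_true(all(lab$label[16:120] == "quiet"))
  # sawtooth with slope 0.05/frame: movement
  saw <- rep(seq(0, 0.95, by = 0.05), length.out = 120)
  lab2 <- classify_epochs(mk(saw))
  expect_true(all(lab2$label[16:120] == "movement"))
  # a 20-frame fast segment inside quiet stays unlabeled (too short)
  v <- rep(0.2, 150)
  v[61:80] <- 0.2 + 0.05 * seq_len(20)
  lab3 <- classify_epochs(mk(v))
  expect_true(all(lab3$label[62:80] == "unlabeled"))
  expect_true(all(lab3$label[100:150] == "quiet"))
})

test_that("activity-triggered maps are rate-weighted frame averages", {
  set.seed(9)
  mp <- array(runif(4 * 4 * 6), dim = c(4, 4, 6))
  mm <- structure(list(map = mp, fps = 30), class = "motion_map")
  # uniform rate: the time-mean of the map
  expect_equal(activity_triggered_map(mm, rep(2, 6)),
               apply(mp, c(1, 2), mean))
  # rate concentrated on one frame: exactly that frame
  w <- c(0, 0, 3, 0, 0, 0)
  expect_equal(activity_triggered_map(mm, w), mp[, , 3])
  expect_error(activity_triggered_map(mm, rep(0, 6)), "all-zero")
})

test_that("motion PCA finds low-rank structure and exact projections", {
  # rank-1 map: one spatial pattern with varying intensity
  set.seed(3)
  pat <- matrix(runif(16 * 16), 16)
  amp <- sin(seq(0, 6 * pi, length.out = 40))^2
  mp <- array(0, dim = c(16, 16, 40))
  for (i in 1:40) mp[, , i] <- pat * amp[i]
  mm <- structure(list(map = mp, fps = 30), class = "motion_map")
  pcs <- suppressWarnings(motion_pca(mm, window = 8, keep = 10,
                                     downsample = 2))
  # a rank-1 spatial pattern with sinusoidal intensity spans two window
  # modes (the 8-sample amplitude subsequences live in a 2-D space)
  expect_gt(sum(pcs$eigenvalues[1:2]) / sum(pcs$all_eigenvalues), 0.95)
  # orthonormality
  v1 <- as.numeric(pcs$components[, , , 1])
  v2 <- as.numeric(pcs$components[, , , 2])
  expect_equal(sum(v1^2), 1, tolerance = 1e-8)
  expect_lt(abs(sum(v1 * v2)), 1e-8)
  # coefficients match brute-force projections of the centred windows
  small <- mp[seq(1, 16, 2), seq(1, 16, 2), ]
  M <- t(vapply(1:33, function(i) as.numeric(small[, , i:(i + 7)]),
                numeric(8 * 8 * 8)))
  Mc <- sweep(M, 2, colMeans(M))
  expect_equal(unname(pcs$coefficients[, 1]), unname(as.numeric(Mc %*% v1)),
               tolerance = 1e-8)
})

test_that("component labelling applies the framewise-Delta rule", {
  # PC alternating +/-1 in a 100-pixel ROI over 8 frames:
  # Delta = 100 * 7 * 2 = 1400 < 3000 -> unlabeled; x3 -> 4200 -> labeled
  pc <- array(0, dim = c(20, 20, 8, 1))
  roi <- as.matrix(expand.grid(1:10, 1:10))
  for (i in 1:8) pc[1:10, 1:10, i, 1] <- (-1)^i
  out <- label_components(pc, list(limb = roi), threshold = 3000)
  expect_equal(unname(out$delta[1, "limb"]), 1400)
  expect_false(out$labels[1, "limb"])
  out3 <- label_components(pc * 3, list(limb = roi), threshold = 3000)
  expect_equal(unname(out3$delta[1, "limb"]), 4200)
  expect_true(out3$labels[1, "limb"])
  # constant PC: Delta 0
  expect_equal(unname(label_components(pc * 0, list(limb = roi))$delta[1, 1]), 0)
  expect_error(roi_delta(pc[, , , 1], roi[0, ]), "empty")
})

test_that("synthetic bout videos recover their epochs through the pipeline", {
  cfg <- sim_config(seed = 14, duration = 30, ephys_fs = 2000, tau_rise = 2)
  st <- generate_step_sequence(cfg)
  fr <- generate_motion_frames(st, cfg)
  mi <- motion_index(compute_motion_map(fr))
  lab <- classify_epochs(mi)
  mv <- attr(fr, "moving")
  gt <- ifelse(mv, "movement", "quiet")
  mask <- rep(TRUE, length(gt))
  mask[seq_len(lab$warmup + lab$min_frames)] <- FALSE
  for (b in which(diff(mv) != 0))
    mask[max(1, b - 5):min(length(gt), b + 5 + lab$min_frames)] <- FALSE
  expect_true(all(lab$label[mask] == gt[mask]))
  # index strictly greater during bouts than in quiet
  expect_gt(min(mi$values[mv]), max(mi$values[!mv & mask]))
})
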