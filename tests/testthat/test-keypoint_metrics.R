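test_that("t-scores match hand computation and zero-variance conventions", {
  slice <- matrix(0, 4, 132)
  slice[, 1] <- c(1, 2, 3, 4)
  slice[, 2] <- c(-1, 1, -2, 2)
  t <- t_scores(slice)
  expect_equal(t[1], 3.872983, tolerance = 1e-6)  # mean 2.5, s = sqrt(5/3)
  expect_equal(t[2], 0)
  expect_equal(t[3], 0)          # all-zero samples
  # zero variance, nonzero mean: signed cap
  slice[, 4] <- -2
  expect_equal(t_scores(slice)[4], -1e6)

  expect_error(t_scores(matrix(0, 1, 132)), class = "crm_sample_error")
})

test_that("avg_t / max_t follow their definitions and scaling options", {
  t <- c(3, -1, 2, rep(0, 129))
  expect_equal(avg_t(t), 6 / 132)
  expect_equal(max_t(t), 3)
  expect_equal(max_t(t, literal_scaling = TRUE), 3 / 132)
  expect_equal(avg_t(sample(t)), avg_t(t))
  expect_gte(max_t(t), avg_t(t))
  expect_equal(avg_t(rep(1.7, 132)), 1.7)
})

test_that("per-keypoint Hotelling matches the hand-solved 2x2 case", {
  slice <- matrix(0, 4, 132)
  slice[, 1] <- c(1, 0, 2, 1)    # keypoint 0: x
  slice[, 67] <- c(0, 1, 1, 2)   # keypoint 0: y
  t2 <- hotelling_t2_per_keypoint(slice)
  expect_equal(t2[1], 12)        # mean (1,1), cov diag(2/3), t2 = 12
  expect_equal(t2[2], 0)         # all-zero keypoint

  # samples symmetric about the origin: zero mean, t2 = 0
  sym <- matrix(0, 4, 132)
  sym[, 5] <- c(1, -1, 2, -2)
  sym[, 71] <- c(1, -1, -2, 2)
  expect_equal(hotelling_t2_per_keypoint(sym)[5], 0)

  expect_error(hotelling_t2_per_keypoint(matrix(0, 2, 132)),
               class = "crm_sample_error")
})

test_that("Hotelling t2 is invariant under a common rotation of the samples", {
  set.seed(10)
  for (rep in 1:5) {
    r <- matrix(rnorm(12, 1), 6, 2)
    th <- runif(1, -pi, pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    slice <- matrix(0, 6, 132)
    slice[, 1] <- r[, 1]; slice[, 67] <- r[, 2]
    rot <- r %*% t(R)
    slice_rot <- matrix(0, 6, 132)
    slice_rot[, 1] <- rot[, 1]; slice_rot[, 67] <- rot[, 2]
    expect_equal(hotelling_t2_per_keypoint(slice)[1],
                 hotelling_t2_per_keypoint(slice_rot)[1], tolerance = 1e-9)
  }
})

test_that("avg_t2 / max_t2 follow their definitions", {
  t2 <- c(12, rep(0, 65))
  expect_equal(avg_t2(t2), 12 / 66)
  expect_equal(max_t2(t2), 12)
  expect_equal(max_t2(t2, literal_scaling = TRUE), 12 / 66)
  expect_equal(avg_t2(rep(3, 66)), 3)
  expect_gte(max_t2(t2), avg_t2(t2))
})

test_that("library implementations match naive oracles on random slices", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(3:10, 1)
    slice <- random_slice_conditioned(n)
    expect_equal(t_scores(slice), naive_t_scores(slice), tolerance = 1e-10)
    expect_equal(hotelling_t2_per_keypoint(slice),
                 naive_hotelling_per_keypoint(slice), tolerance = 1e-10)
    # unconstrained draws: agreement limited only by cov conditioning
    u <- random_slice(n)
    expect_equal(hotelling_t2_per_keypoint(u),
                 naive_hotelling_per_keypoint(u), tolerance = 1e-6)
  }
  # spot check against stats::t.test as a fully independent oracle
  slice <- random_slice(8)
  for (j in c(1, 70, 132)) {
    expect_equal(t_scores(slice)[j],
                 unname(t.test(slice[, j])$statistic), tolerance = 1e-10)
  }
})

test_that("uncentered PCA reconstructs low-rank data and orders variance", {
  set.seed(1)
  P0 <- qr.Q(qr(matrix(rnorm(132 * 2), 132, 2)))
  Y <- P0 %*% matrix(rnorm(2 * 50, 0, 3), 2, 50)   # exact rank 2
  model <- pca_reduce(Y, k = 2)
  expect_lt(max(abs(model$P %*% model$Q - Y)), 1e-9)
  expect_equal(crossprod(model$P), diag(2), tolerance = 1e-10)
  expect_true(all(diff(model$explained_all) <= 1e-12))
  expect_equal(sum(model$explained), 1, tolerance = 1e-10)

  # variance_target selects the smallest sufficient k
  expect_equal(pca_reduce(Y, variance_target = 0.99)$k, 2L)
  expect_error(pca_reduce(Y, k = 132), class = "crm_dimension_error")

  full <- matrix(rnorm(132 * 20), 132, 20)
  m19 <- pca_reduce(full, k = 19)
  expect_lt(sum(m19$explained), 1)
  resid <- full - m19$P %*% m19$Q
  sv <- svd(full, nu = 0, nv = 0)$d
  expect_equal(sum(resid^2), sum(sv[20:length(sv)]^2), tolerance = 1e-8)
})

test_that("pca_t2 equals squared Student t for k = 1 and errors when n <= k", {
  scores <- matrix(c(1, 2, 3, 4), 4, 1)
  expect_equal(pca_t2(scores), 3.872983^2, tolerance = 1e-5)
  expect_equal(pca_t2(matrix(c(-1, 1, -2, 2), 4, 1)), 0)
  expect_error(pca_t2(matrix(rnorm(9), 3, 3)), class = "crm_singular_error")
})

test_that("metric_timeseries matches the per-slice functions frame by frame", {
  sim <- simulate_cohort(simulation_config(
    n_subjects = 5, n_frames = 12, seed = 8, noise_sd = 0.5,
    pose = list(rot_deg = 0, scale_dev = 0, trans_px = 0),
    epochs = list(list(au = 12, start = 3, end = 9, p = 1, amp_mean = 4,
                       amp_sd = 0.3))))
  kpm <- raw_kpm(sim)
  X <- lapply(kpm, `[[`, "X")
  savg <- metric_timeseries(kpm, "avg_t")
  smax <- metric_timeseries(kpm, "max_t")
  s2avg <- metric_timeseries(kpm, "avg_t2")
  s2max <- metric_timeseries(kpm, "max_t2")
  for (tt in c(1, 5, 8, 12)) {
    slice <- do.call(rbind, lapply(X, function(x) x[tt, ]))
    expect_equal(savg$value[tt], avg_t(t_scores(slice)), tolerance = 1e-10)
    expect_equal(smax$value[tt], max_t(t_scores(slice)), tolerance = 1e-10)
    t2 <- hotelling_t2_per_keypoint(slice)
    expect_equal(s2avg$value[tt], avg_t2(t2), tolerance = 1e-10)
    expect_equal(s2max$value[tt], max_t2(t2), tolerance = 1e-10)
  }
  # pca route agrees with explicitly projecting onto the pooled model
  spca <- metric_timeseries(kpm, "pca_t2", k = 3)
  model <- pca_reduce(t(do.call(rbind, X)), k = 3)
  tt <- 7
  sl <- do.call(rbind, lapply(X, function(x) pca_scores(model, x[tt, , drop = FALSE])))
  expect_equal(spca$value[tt], pca_t2(sl), tolerance = 1e-8)
})

test_that("metric series handle degenerate cohorts and bad options", {
  zero <- lapply(1:3, function(i)
    structure(list(subject_id = paste0("s", i), X = matrix(0, 4, 132),
                   frames = 0:3, neutral_frame_index = 0L),
              class = "kpm_series"))
  s <- metric_timeseries(zero, "avg_t")
  expect_equal(s$value, rep(0, 4))
  expect_equal(nrow(metric_timeseries(zero[1:2], "avg_t")), 4)

  one_frame <- lapply(zero, function(z) { z$X <- z$X[1, , drop = FALSE]; z$frames <- 0L; z })
  expect_equal(nrow(metric_timeseries(one_frame, "avg_t")), 1)

  expect_error(metric_timeseries(zero, "not_a_metric"), class = "crm_usage_error")
  expect_error(metric_timeseries(zero, "pca_t2", k = 5), class = "crm_singular_error")
})

test_that("metrics are invariant to subject relabeling and keypoint reordering", {
  set.seed(9)
  kpm <- lapply(1:4, function(i)
    structure(list(subject_id = paste0("s", i),
                   X = matrix(rnorm(6 * 132), 6, 132),
                   frames = 0:5, neutral_frame_index = 0L),
              class = "kpm_series"))
  for (m in c("avg_t", "max_t", "avg_t2", "max_t2", "pca_t2")) {
    a <- metric_timeseries(kpm, m, k = 2)
    b <- metric_timeseries(rev(kpm), m, k = 2)
    expect_equal(a$value, b$value, tolerance = 1e-9)
  }
  # keypoint permutation: permute (x_i, y_i) blocks consistently
  perm <- sample(66)
  kpm_p <- lapply(kpm, function(s) { s$X <- s$X[, c(perm, perm + 66)]; s })
  for (m in c("avg_t", "max_t", "avg_t2", "max_t2")) {
    expect_equal(metric_timeseries(kpm, m)$value,
                 metric_timeseries(kpm_p, m)$value, tolerance = 1e-10)
  }
})

test_that("null Hotelling rejection rates respect the F critical value", {
  # small, fast version of the distributional identity (the full-size
  # calibration lives in the acceptance suite)
  set.seed(14)
  n <- 10
  t2 <- replicate(4000, {
    x <- matrix(rnorm(n * 2), n, 2)
    n * drop(crossprod(colMeans(x), solve(cov(x), colMeans(x))))
  })
  for (alpha in c(0.05, 0.01)) {
    rate <- mean(t2 > hotelling_critical(n, 2, alpha))
    expect_lt(abs(rate - alpha), 2.6 * sqrt(alpha * (1 - alpha) / 4000) + 1e-12)
  }
})
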