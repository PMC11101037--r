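# Shared fixtures and independent oracle implementations.

# A static cohort: every subject shows the template face (optionally under a
# per-subject affine) at every frame.
static_cohort <- function(n = 3, T = 4, affines = NULL) {
  tmpl <- face_template()
  recs <- lapply(seq_len(n), function(i) {
    xy <- tmpl
    if (!is.null(affines)) {
      a <- affines[[i]]
      xy <- sweep(xy %*% t(a$A), 2, a$b, `+`)
    }
    row <- c(xy[, 1], xy[, 2])
    subject_recording(matrix(rep(row, each = T), nrow = T),
                      subject_id = sprintf("S%02d", i))
  })
  cohort_dataset(recs)
}

# Naive, from-the-formula re-implementations used as oracles.
naive_t_scores <- function(slice, zero_cap = 1e6) {
  vapply(seq_len(ncol(slice)), function(j) {
    x <- slice[, j]
    m <- mean(x)
    s <- sqrt(sum((x - m)^2) / (length(x) - 1))
    if (s == 0) {
      if (m == 0) 0 else sign(m) * zero_cap
    } else {
      m / (s / sqrt(length(x)))
    }
  }, numeric(1))
}

naive_hotelling_per_keypoint <- function(slice) {
  n <- nrow(slice)
  vapply(1:66, function(i) {
    r <- cbind(slice[, i], slice[, i + 66])
    m <- colMeans(r)
    S <- cov(r)
    drop(t(m) %*% solve(S / n) %*% m)  # m' (S/n)^-1 m
  }, numeric(1))
}

# Random KPM slice (n x 132), unconstrained Gaussian draws.
random_slice <- function(n) {
  matrix(rnorm(n * 132, mean = rnorm(132, 0, 0.5)), n, 132, byrow = FALSE) +
    matrix(rnorm(n * 132), n, 132)
}

# Random slice whose per-keypoint 2x2 sample covariances are well-posed by
# construction (singular values in [0.5, 2], random orientation and means):
# keeps the Hotelling statistic's condition number bounded so implementation
# agreement at 1e-10 is numerically meaningful.
random_slice_conditioned <- function(n) {
  slice <- matrix(0, n, 132)
  # orthonormal n x 2 basis orthogonal to the intercept => exactly centered
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 2), n, 2))))[, 2:3, drop = FALSE]
  for (kp in 1:66) {
    mu <- rnorm(2, 0, 2)
    th <- runif(1, -pi, pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    D <- Q %*% diag(runif(2, 0.5, 2) * sqrt(n - 1)) %*% t(R)
    slice[, kp] <- mu[1] + D[, 1]
    slice[, kp + 66] <- mu[2] + D[, 2]
  }
  slice
}

expect_recording_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a$coords - b$coords)), tol)
}

apply_similarity_to_recording <- function(rec, tfs) {
  for (tt in seq_len(nrow(rec$coords))) {
    xy <- cbind(rec$coords[tt, 1:66], rec$coords[tt, 67:132])
    xy <- apply_similarity(tfs[[tt]], xy)
    rec$coords[tt, ] <- c(xy[, 1], xy[, 2])
  }
  rec
}

random_similarity <- function(max_rot_deg = 15, scale_range = c(0.8, 1.2),
                              max_trans = 30) {
  structure(list(s = runif(1, scale_range[1], scale_range[2]),
                 theta = runif(1, -max_rot_deg, max_rot_deg) * pi / 180,
                 t = runif(2, -max_trans, max_trans)),
            class = "similarity_transform")
}

# Apply independent random per-frame similarity nuisance to a whole cohort.
with_pose_nuisance <- function(cohort, seed = 1) {
  set.seed(seed)
  cohort$recordings <- lapply(cohort$recordings, function(rec) {
    tfs <- replicate(nrow(rec$coords), random_similarity(), simplify = FALSE)
    apply_similarity_to_recording(rec, tfs)
  })
  cohort
}
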