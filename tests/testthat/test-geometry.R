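template_recording <- function(T = 3) {
  tmpl <- face_template()
  subject_recording(matrix(rep(c(tmpl[, 1], tmpl[, 2]), each = T), nrow = T),
                    subject_id = "tmpl")
}

test_that("frontalization fixes symmetric faces and inverts in-plane roll", {
  rec <- template_recording()
  out <- frontalize(rec)
  expect_recording_equal(out, rec, 1e-9)

  # rotate 10 degrees about the eye midpoint, frontalize, expect the original
  tmpl <- face_template()
  m <- (tmpl[37, ] + tmpl[46, ]) / 2
  th <- 10 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- sweep(sweep(tmpl, 2, m) %*% t(R), 2, m, `+`)
  rec_rot <- subject_recording(matrix(c(rot[, 1], rot[, 2]), 1, 132))
  out <- frontalize(rec_rot)
  expect_lt(max(abs(out$coords[1, ] - c(tmpl[, 1], tmpl[, 2]))), 1e-9)

  expect_identical(frontalize(rec, "none"), rec)

  degen <- rec
  degen$coords[1, ] <- 0  # all points coincide: zero-length eye axis
  expect_error(frontalize(degen), class = "crm_geometry_error")
})

test_that("fit_affine solves the 3-pair system exactly and flags degeneracy", {
  src <- rbind(c(0, 0), c(1, 0), c(0, 1))
  id <- fit_affine(src, src)
  expect_equal(id$A, diag(2), tolerance = 1e-12)
  expect_equal(id$b, c(0, 0), tolerance = 1e-12)

  dst <- rbind(c(1, 2), c(3, 2), c(1, 5))
  tf <- fit_affine(src, dst)
  expect_equal(tf$A, matrix(c(2, 0, 0, 3), 2, 2), tolerance = 1e-12)
  expect_equal(tf$b, c(1, 2), tolerance = 1e-12)
  expect_equal(apply_affine(tf, src), dst, tolerance = 1e-12)

  expect_error(fit_affine(rbind(c(0, 0), c(1, 1), c(2, 2)), dst),
               class = "crm_singular_fit_error")
})

test_that("fit_similarity recovers exact two-point transforms", {
  src <- rbind(c(0, 0), c(1, 0))
  id <- fit_similarity(src, src)
  expect_equal(c(id$s, id$theta, id$t), c(1, 0, 0, 0), tolerance = 1e-12)

  tf <- fit_similarity(src, rbind(c(0, 0), c(0, 2)))
  expect_equal(tf$s, 2, tolerance = 1e-12)
  expect_equal(tf$theta, pi / 2, tolerance = 1e-12)
  expect_equal(tf$t, c(0, 0), tolerance = 1e-12)

  one <- fit_similarity(rbind(c(1, 1)), rbind(c(4, 5)))
  expect_equal(c(one$s, one$theta), c(1, 0))
  expect_equal(one$t, c(3, 4))

  expect_error(fit_similarity(rbind(c(1, 1), c(1, 1)), rbind(c(0, 0), c(1, 0))),
               class = "crm_singular_fit_error")
})

test_that("least-squares similarity is invariant to exchanging noisy pairs", {
  set.seed(7)
  src <- matrix(rnorm(10, 0, 5), 5, 2)
  dst <- apply_similarity(
    structure(list(s = 1.3, theta = 0.4, t = c(2, -1)),
              class = "similarity_transform"), src) + matrix(rnorm(10, 0, 0.1), 5, 2)
  tf1 <- fit_similarity(src, dst)
  perm <- c(3, 1, 5, 2, 4)
  tf2 <- fit_similarity(src[perm, ], dst[perm, ])
  expect_equal(tf1$s, tf2$s, tolerance = 1e-12)
  expect_equal(tf1$theta, tf2$theta, tolerance = 1e-12)
})

test_that("affine registration recovers known per-frame distortions and is idempotent", {
  tmpl <- face_template()
  ref <- as_reference_face(tmpl)
  rec <- template_recording(T = 4)
  same <- affine_register(rec, ref)
  expect_recording_equal(same, rec, 1e-9)

  # distort each frame by a known affine; registration must restore the face
  set.seed(3)
  dist <- rec
  for (tt in 1:4) {
    A <- diag(2) + matrix(runif(4, -0.2, 0.2), 2, 2)
    b <- runif(2, -20, 20)
    xy <- sweep(tmpl %*% t(A), 2, b, `+`)
    dist$coords[tt, ] <- c(xy[, 1], xy[, 2])
  }
  back <- affine_register(dist, ref)
  expect_recording_equal(back, rec, 1e-8)

  twice <- affine_register(back, ref)
  expect_recording_equal(twice, back, 1e-9)
})

test_that("part-wise similarity restores scaled parts and never touches lips", {
  tmpl <- face_template()
  ref <- as_reference_face(tmpl)
  parts <- face_part_map()

  # scale the left brow+eye part by 1.5 about the anchor midpoint
  mod <- tmpl
  members <- parts$left_brow_eye$members + 1L
  center <- colMeans(tmpl[parts$left_brow_eye$anchors + 1L, ])
  mod[members, ] <- sweep(sweep(mod[members, ], 2, center) * 1.5, 2, center, `+`)
  rec <- subject_recording(matrix(c(mod[, 1], mod[, 2]), 1, 132))
  out <- partwise_similarity_register(rec, ref, parts)
  expect_lt(max(abs(out$coords[1, ] - c(tmpl[, 1], tmpl[, 2]))), 1e-9)

  # translate the lips arbitrarily: the stage must leave them alone
  mod2 <- tmpl
  lips <- parts$lips$members + 1L
  mod2[lips, ] <- mod2[lips, ] + matrix(c(7, -4), length(lips), 2, byrow = TRUE)
  rec2 <- subject_recording(matrix(c(mod2[, 1], mod2[, 2]), 1, 132))
  out2 <- partwise_similarity_register(rec2, ref, parts)
  expect_equal(out2$coords[1, c(lips, lips + 66)],
               rec2$coords[1, c(lips, lips + 66)])
})

test_that("KPM vectors follow the definition and are linear", {
  rec <- template_recording(T = 3)
  rec$coords[2, ] <- rec$coords[1, ] + rep(c(1, 2), each = 66)
  rec$coords[3, ] <- rec$coords[1, ] + rep(c(4, -2), each = 66)
  kpm <- compute_kpm(rec, neutral_frame = 0)
  expect_equal(kpm$X[1, ], setNames(rep(0, 132), colnames(rec$coords)))
  expect_equal(unname(kpm$X[2, ]), rep(c(1, 2), each = 66))
  # linearity: KPM of the midpoint frame equals the mean of the frames' KPMs
  mid <- rec
  mid$coords[2, ] <- (rec$coords[2, ] + rec$coords[3, ]) / 2
  kmid <- compute_kpm(mid, neutral_frame = 0)
  expect_equal(kmid$X[2, ], (kpm$X[2, ] + kpm$X[3, ]) / 2)

  expect_error(compute_kpm(rec, neutral_frame = 99), class = "crmface_error")
})

test_that("preprocessing removes per-subject global affines and static cohorts give zero KPM", {
  cohort <- static_cohort(n = 3, T = 3)
  kpm <- preprocess_cohort(cohort)
  expect_lt(max(abs(kpm[[1]]$X)), 1e-9)

  set.seed(5)
  affines <- lapply(1:3, function(i)
    list(A = diag(2) + matrix(runif(4, -0.1, 0.1), 2, 2), b = runif(2, -10, 10)))
  cohort2 <- static_cohort(n = 3, T = 3, affines = affines)
  kpm2 <- preprocess_cohort(cohort2)
  for (s in kpm2) expect_lt(max(abs(s$X)), 1e-8)
})

test_that("registration invariance: per-frame similarity nuisance leaves KPM unchanged", {
  sim <- simulate_cohort(simulation_config(
    n_subjects = 4, n_frames = 8, seed = 21, noise_sd = 0.4,
    pose = list(rot_deg = 0, scale_dev = 0, trans_px = 0),
    epochs = list(list(au = 1, start = 2, end = 6, p = 1, amp_mean = 4,
                       amp_sd = 0.2))))
  clean <- preprocess_cohort(sim$cohort)
  noisy <- preprocess_cohort(with_pose_nuisance(sim$cohort, seed = 9))
  for (i in seq_along(clean)) {
    expect_lt(max(abs(clean[[i]]$X - noisy[[i]]$X)), 1e-6)
  }
})

test_that("the registration stage order is fixed: swapping stages changes output", {
  tmpl <- face_template()
  ref <- as_reference_face(tmpl)
  set.seed(12)
  A <- diag(2) + matrix(runif(4, -0.15, 0.15), 2, 2)
  xy <- sweep(tmpl %*% t(A), 2, c(4, -6), `+`)
  rec <- subject_recording(matrix(c(xy[, 1], xy[, 2]), 1, 132))
  canonical <- partwise_similarity_register(affine_register(rec, ref), ref)
  swapped <- affine_register(partwise_similarity_register(rec, ref), ref)
  expect_gt(max(abs(canonical$coords - swapped$coords)), 1e-3)
})

test_that("reference faces require non-collinear anchors", {
  bad <- matrix(c(seq_len(66), seq_len(66) * 2), 66, 2)  # all collinear
  expect_error(as_reference_face(bad), class = "crm_geometry_error")
})
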