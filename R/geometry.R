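# Geometric normalization: frontalization, affine registration to a
# reference face, part-wise similarity registration, and keypoint-movement
# (KPM) vectors relative to a neutral frame.

#' Fit a six-parameter affine transform by least squares
#'
#' Minimizes \eqn{\sum_j \|A s_j + b - d_j\|^2} over the 2x2 linear part `A`
#' and translation `b`; exact when three non-collinear pairs are given.
#'
#' @param src,dst Numeric matrices of matching (x, y) rows, at least 3 pairs.
#' @return An `affine_transform`: list with elements `A` (2x2) and `b`
#'   (length 2).
#' @export
fit_affine <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  crm_assert(nrow(src) >= 3 && nrow(src) == nrow(dst),
             "affine fit needs at least 3 matching point pairs")
  M <- cbind(src, 1)
  qrM <- qr(M)
  if (qrM$rank < 3) {
    crm_stop("affine fit is singular: source points are collinear or coincident",
             "crm_singular_fit_error")
  }
  beta <- qr.coef(qrM, dst)           # 3 x 2
  tf <- structure(list(A = t(beta[1:2, , drop = FALSE]), b = as.numeric(beta[3, ])),
                  class = "affine_transform")
  if (abs(det(tf$A)) <= 1e-12) {
    crm_stop("fitted affine transform is degenerate (|det A| ~ 0)",
             "crm_singular_fit_error")
  }
  tf
}

#' @rdname fit_affine
#' @param tf An `affine_transform`.
#' @param xy A 66 x 2 (or n x 2) coordinate matrix.
#' @export
apply_affine <- function(tf, xy) {
  sweep(as.matrix(xy) %*% t(tf$A), 2, tf$b, `+`)
}

#' Fit a four-parameter similarity transform by least squares
#'
#' Scale + rotation + translation fit of `src` onto `dst`. With a single
#' point pair only the translation is identifiable; by convention the fit is
#' then translation-only (scale 1, angle 0).
#'
#' @param src,dst Matching (x, y) matrices, at least 1 pair.
#' @return A `similarity_transform`: list with `s` (scale), `theta`
#'   (radians), `t` (translation).
#' @export
fit_similarity <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  crm_assert(nrow(src) >= 1 && nrow(src) == nrow(dst),
             "similarity fit needs at least 1 matching point pair")
  if (nrow(src) == 1) {
    return(structure(list(s = 1, theta = 0, t = as.numeric(dst - src)),
                     class = "similarity_transform"))
  }
  sc <- colMeans(src); dc <- colMeans(dst)
  s0 <- sweep(src, 2, sc); d0 <- sweep(dst, 2, dc)
  denom <- sum(s0^2)
  if (denom <= 1e-24) {
    crm_stop("similarity fit is degenerate: source points coincide",
             "crm_singular_fit_error")
  }
  a <- sum(s0 * d0) / denom                       # s cos(theta)
  b <- sum(s0[, 1] * d0[, 2] - s0[, 2] * d0[, 1]) / denom  # s sin(theta)
  s <- sqrt(a^2 + b^2)
  theta <- atan2(b, a)
  R <- matrix(c(a, b, -b, a), 2, 2)               # s * rotation matrix
  t <- dc - as.numeric(R %*% sc)
  structure(list(s = s, theta = theta, t = as.numeric(t)),
            class = "similarity_transform")
}

#' @rdname fit_similarity
#' @param tf A `similarity_transform`.
#' @param xy Coordinate matrix to transform.
#' @export
apply_similarity <- function(tf, xy) {
  a <- tf$s * cos(tf$theta); b <- tf$s * sin(tf$theta)
  R <- matrix(c(a, b, -b, a), 2, 2)
  sweep(as.matrix(xy) %*% t(R), 2, tf$t, `+`)
}

rotate_about <- function(xy, theta, center) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(sweep(xy, 2, center) %*% t(R), 2, center, `+`)
}

# Roll-correct one frame: rotate so the outer eye-corner axis (36 -> 45) is
# horizontal, pivoting about the eye-corner midpoint.
level_eye_axis <- function(xy) {
  e1 <- xy[EYE_CORNER_R + 1L, ]
  e2 <- xy[EYE_CORNER_L + 1L, ]
  v <- e2 - e1
  if (sum(v^2) <= 1e-18) {
    crm_stop("degenerate eye axis: outer eye corners coincide", "crm_geometry_error")
  }
  rotate_about(xy, -atan2(v[2], v[1]), (e1 + e2) / 2)
}

# Bilateral symmetrization about the vertical midline through the nose
# bridge (landmark 27): each left/right pair is replaced by the average of
# the point and its mirrored partner; midline landmarks are projected onto
# the midline. Assumes the frame is already roll-corrected.
symmetrize_frame <- function(xy) {
  cx <- xy[27 + 1L, 1]
  out <- xy
  for (r in seq_len(nrow(FACE_PAIRS))) {
    i <- FACE_PAIRS[r, 1] + 1L
    j <- FACE_PAIRS[r, 2] + 1L
    mirror_j <- c(2 * cx - xy[j, 1], xy[j, 2])
    new_i <- (xy[i, ] + mirror_j) / 2
    out[i, ] <- new_i
    out[j, ] <- c(2 * cx - new_i[1], new_i[2])
  }
  out[FACE_MIDLINE + 1L, 1] <- cx
  out
}

#' Frontalize a recording
#'
#' Default method `"symmetrize"`: per frame, (i) estimate the in-plane roll
#' from the outer eye-corner axis and rotate it level, then (ii) symmetrize
#' bilaterally about the facial midline through the nose bridge. This removes
#' in-plane head roll and the asymmetric component of residual out-of-plane
#' pose; it is a 2D stand-in for full 3D frontalization, adequate for
#' near-frontal recordings. Method `"none"` passes coordinates through.
#'
#' @param recording A [subject_recording()].
#' @param method `"symmetrize"` (default) or `"none"`.
#' @return A frontalized [subject_recording()].
#' @export
frontalize <- function(recording, method = c("symmetrize", "none")) {
  method <- match.arg(method)
  if (method == "none") return(recording)
  coords <- recording$coords
  for (i in seq_len(nrow(coords))) {
    xy <- row_to_xy(coords[i, ])
    xy <- symmetrize_frame(level_eye_axis(xy))
    coords[i, ] <- xy_to_row(xy)
  }
  recording$coords <- coords
  recording
}

# Canonical similarity pose: eye-corner midpoint at the origin, eye axis
# horizontal, inter-ocular (outer corner) distance rescaled to `scale_to`.
# Used to pool neutral frames into a nuisance-free reference face.
canonical_pose <- function(xy, scale_to = 100) {
  xy <- level_eye_axis(xy)
  e1 <- xy[EYE_CORNER_R + 1L, ]
  e2 <- xy[EYE_CORNER_L + 1L, ]
  m <- (e1 + e2) / 2
  d <- sqrt(sum((e2 - e1)^2))
  sweep(xy, 2, m) * (scale_to / d)
}

#' Build a reference face from a cohort
#'
#' Mean of the subjects' frontalized neutral frames, each first brought into
#' a canonical similarity pose (eye axis level, inter-ocular distance 100,
#' eye midpoint at the origin) so that per-subject pose and scale do not leak
#' into the reference.
#'
#' @param cohort A [cohort_dataset()].
#' @param config A [registration_config()].
#' @return A `reference_face`: 66 x 2 matrix with a `provenance` attribute.
#' @export
reference_face <- function(cohort, config = registration_config()) {
  acc <- matrix(0, KEYPOINT_N, 2)
  for (rec in cohort$recordings) {
    fr <- frontalize(rec, config$frontalization)
    ni <- resolve_neutral(fr, config$neutral_frame)
    acc <- acc + canonical_pose(row_to_xy(fr$coords[ni, ]))
  }
  ref <- acc / cohort$n
  as_reference_face(ref, provenance = "cohort-mean")
}

#' @rdname reference_face
#' @param xy A 66 x 2 coordinate matrix to use verbatim as the registration
#'   target.
#' @param provenance Provenance tag stored on the object.
#' @export
as_reference_face <- function(xy, provenance = "supplied") {
  xy <- as.matrix(xy)
  crm_assert(nrow(xy) == KEYPOINT_N && ncol(xy) == 2,
             "a reference face must be a 66 x 2 matrix")
  anchors <- xy[AFFINE_ANCHORS + 1L, ]
  if (qr(cbind(anchors, 1))$rank < 3) {
    crm_stop("reference-face affine anchors are collinear", "crm_geometry_error")
  }
  structure(xy, provenance = provenance, class = c("reference_face", "matrix", "array"))
}

#' Affine-register a recording onto a reference face
#'
#' Per frame, fits the least-squares affine transform carrying the frame's
#' six anchor landmarks (0, 16, 39, 42, 27, 33) onto the reference anchors
#' and applies it to all 66 landmarks.
#'
#' @param recording A (frontalized) [subject_recording()].
#' @param reference A [reference_face()] / [as_reference_face()] target.
#' @param anchors 0-based anchor indices (default the standard six).
#' @return The registered [subject_recording()].
#' @export
affine_register <- function(recording, reference, anchors = AFFINE_ANCHORS) {
  ref_a <- reference[anchors + 1L, , drop = FALSE]
  coords <- recording$coords
  for (i in seq_len(nrow(coords))) {
    xy <- row_to_xy(coords[i, ])
    tf <- tryCatch(fit_affine(xy[anchors + 1L, , drop = FALSE], ref_a),
                   crmface_error = function(e) {
                     crm_stop(sprintf("frame %d of subject '%s': %s",
                                      recording$frames[i], recording$subject_id,
                                      conditionMessage(e)),
                              "crm_singular_fit_error")
                   })
    coords[i, ] <- xy_to_row(apply_affine(tf, xy))
  }
  recording$coords <- coords
  recording
}

#' Part-wise similarity registration
#'
#' For each face part with anchor landmarks, fits a similarity transform from
#' the frame's anchors to the reference anchors and applies it to the part's
#' member landmarks. Lips carry no stable anchors and are left untouched.
#'
#' @inheritParams affine_register
#' @param parts A part map as returned by [face_part_map()].
#' @return The registered [subject_recording()].
#' @export
partwise_similarity_register <- function(recording, reference,
                                         parts = face_part_map()) {
  validate_part_map(parts)
  coords <- recording$coords
  for (i in seq_len(nrow(coords))) {
    xy <- row_to_xy(coords[i, ])
    for (nm in names(parts)) {
      p <- parts[[nm]]
      if (length(p$anchors) == 0) next
      tf <- tryCatch(
        fit_similarity(xy[p$anchors + 1L, , drop = FALSE],
                       reference[p$anchors + 1L, , drop = FALSE]),
        crmface_error = function(e) {
          crm_stop(sprintf("part '%s', frame %d of subject '%s': %s",
                           nm, recording$frames[i], recording$subject_id,
                           conditionMessage(e)),
                   "crm_singular_fit_error")
        })
      xy[p$members + 1L, ] <- apply_similarity(tf, xy[p$members + 1L, , drop = FALSE])
    }
    coords[i, ] <- xy_to_row(xy)
  }
  recording$coords <- coords
  recording
}

resolve_neutral <- function(recording, neutral_frame) {
  if (identical(neutral_frame, "first")) return(1L)
  if (identical(neutral_frame, "auto")) {
    med <- apply(recording$coords, 2, stats::median)
    d <- rowMeans(abs(sweep(recording$coords, 2, med)))
    return(which.min(d))
  }
  crm_assert(is_count(neutral_frame), "neutral_frame must be 'first', 'auto' or a frame index")
  frame_row(recording, as.integer(neutral_frame))
}

#' Keypoint-movement (KPM) series of a recording
#'
#' Per frame, the 132-vector of coordinate displacements relative to the
#' subject's neutral frame, packed `[dx_0..dx_65, dy_0..dy_65]`. The KPM of
#' the neutral frame itself is identically zero.
#'
#' @param recording A fully preprocessed [subject_recording()].
#' @param neutral_frame 0-based frame index of the neutral frame, `"first"`
#'   (default), or `"auto"` (frame closest to the per-coordinate median face).
#' @return A `kpm_series`: list with `X` (T x 132 matrix), `frames`,
#'   `subject_id` and `neutral_frame_index`.
#' @export
compute_kpm <- function(recording, neutral_frame = "first") {
  ni <- resolve_neutral(recording, neutral_frame)
  X <- sweep(recording$coords, 2, recording$coords[ni, ])
  structure(list(subject_id = recording$subject_id, X = X,
                 frames = recording$frames,
                 neutral_frame_index = recording$frames[ni]),
            class = "kpm_series")
}

#' Registration configuration
#'
#' @param frontalization `"symmetrize"` (default) or `"none"`.
#' @param neutral_frame `"first"` (default), `"auto"`, or a 0-based frame
#'   index, applied to every subject.
#' @param affine,partwise Logical switches for the two registration stages
#'   (both on by default; turning both off with `frontalization = "none"`
#'   yields raw KPM, used for statistical calibration).
#' @param anchors 0-based affine anchor indices.
#' @param parts Part map for the similarity stage ([face_part_map()]).
#' @param reference Optional fixed [as_reference_face()]; default builds the
#'   cohort-mean reference.
#' @return A `registration_config` list.
#' @export
registration_config <- function(frontalization = "symmetrize",
                                neutral_frame = "first",
                                affine = TRUE, partwise = TRUE,
                                anchors = AFFINE_ANCHORS,
                                parts = face_part_map(),
                                reference = NULL) {
  crm_assert(frontalization %in% c("symmetrize", "none"),
             "unknown frontalization method", "crm_usage_error")
  structure(list(frontalization = frontalization, neutral_frame = neutral_frame,
                 affine = affine, partwise = partwise, anchors = anchors,
                 parts = parts, reference = reference),
            class = "registration_config")
}

#' Preprocess a cohort into KPM series
#'
#' Runs the full geometric pipeline per subject — frontalize, affine-register
#' to a shared reference face, part-wise similarity registration — and
#' converts the result to keypoint-movement vectors relative to each
#' subject's neutral frame.
#'
#' @param cohort A [cohort_dataset()].
#' @param config A [registration_config()].
#' @return List of `kpm_series` (one per subject) with attributes
#'   `reference` and `config`.
#' @export
preprocess_cohort <- function(cohort, config = registration_config()) {
  ref <- NULL
  if (config$affine || config$partwise) {
    ref <- config$reference %||% reference_face(cohort, config)
  }
  out <- lapply(cohort$recordings, function(rec) {
    r <- tryCatch({
      r <- frontalize(rec, config$frontalization)
      if (config$affine) r <- affine_register(r, ref, config$anchors)
      if (config$partwise) r <- partwise_similarity_register(r, ref, config$parts)
      r
    }, crmface_error = function(e) {
      crm_stop(sprintf("subject '%s': %s", rec$subject_id, conditionMessage(e)),
               class(e)[1])
    })
    compute_kpm(r, config$neutral_frame)
  })
  attr(out, "reference") <- ref
  attr(out, "config") <- config
  out
}
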