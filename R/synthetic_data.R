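# Synthetic cohorts of facial landmark trajectories with known ground-truth
# consistency structure: a canonical 66-point face template, per-subject
# shape variation, epochs of coherent AU-like displacement with per-subject
# participation, i.i.d. positional jitter, per-frame head-pose nuisance, and
# matching AU intensity labels.

#' Canonical symmetric 66-point face template
#'
#' A synthetic frontal face in a roughly 200 x 200 pixel box (y grows
#' downward), bilaterally symmetric about x = 100, with the standard layout:
#' jawline 0-16, brows 17-26, nose 27-35, eyes 36-47, lips 48-65.
#'
#' @return A 66 x 2 coordinate matrix.
#' @export
face_template <- function() {
  xy <- matrix(NA_real_, KEYPOINT_N, 2)
  # jawline: half-ellipse from left temple over the chin to the right temple
  th <- pi * (0:16) / 16
  xy[1:17, ] <- cbind(100 - 75 * cos(th), 60 + 110 * sin(th))
  # right brow (image-left) 17..21, inner point is 21; left brow mirrored
  bx <- seq(40, 85, length.out = 5)
  by <- 50 - 6 * sin(pi * (0:4) / 4)
  xy[18:22, ] <- cbind(bx, by)
  xy[23:27, ] <- cbind(200 - rev(bx), rev(by))
  # nose bridge 27..30 and nostril line 31..35
  xy[28:31, ] <- cbind(rep(100, 4), c(65, 80, 95, 108))
  xy[32:36, ] <- cbind(c(86, 93, 100, 107, 114), rep(118, 5))
  # right eye 36..41 (36 outer corner, 39 inner), left eye mirrored
  xy[37:42, ] <- cbind(c(55, 65, 75, 85, 75, 65), c(70, 64, 64, 70, 76, 76))
  xy[43:48, ] <- cbind(c(115, 125, 135, 145, 135, 125), c(70, 64, 64, 70, 76, 76))
  # outer lips 48..59 (corners 48, 54), inner lips 60..65
  xy[49:60, ] <- cbind(c(75, 84, 92, 100, 108, 116, 125, 116, 108, 100, 92, 84),
                       c(140, 133, 130, 129, 130, 133, 140, 148, 152, 153, 152, 148))
  xy[61:66, ] <- cbind(c(88, 100, 112, 112, 100, 88),
                       c(137, 136, 137, 143, 144, 143))
  xy
}

#' Unit displacement fields emulating the 12 coded action units
#'
#' For each coded AU, a 132-dimensional unit-norm displacement field
#' (`dx` then `dy` per keypoint, y-down image convention) encoding the
#' qualitative appearance change of that AU: e.g. inner-brow raise pulls the
#' inner brow points upward, the lip-corner puller moves the lip corners
#' obliquely up and outward, the jaw drop moves chin and lower lip down.
#' Each field is nonzero only on the keypoints of its face part.
#'
#' @return Named list (`"1"`, `"2"`, ..., `"26"`) of length-132 unit vectors.
#' @export
au_pattern_dictionary <- function() {
  field <- function(idx, dx, dy) {
    v <- numeric(KPM_DIM)
    v[idx + 1L] <- dx
    v[idx + 1L + 66L] <- dy
    v / sqrt(sum(v^2))
  }
  up <- -1  # y grows downward
  # Weights peak at the focal landmarks of each AU and decay over the
  # surrounding region the muscle group deforms (a lip-corner pull, for
  # instance, carries most of the lip outline with it, not just the two
  # corner points).
  corner_w <- c(1, 1, rep(0.5, 6), 0.25, 0.25)   # 48,54 strong; neighbors half
  corner_idx <- c(48, 54, 49, 53, 55, 59, 60, 62, 50, 52)
  list(
    "1"  = field(c(20, 21, 22, 23),              0, c(0.6, 1, 1, 0.6) * up),
    "2"  = field(c(17, 18, 25, 26),              0, c(1, 0.6, 0.6, 1) * up),
    "4"  = field(17:26,                          0, rep(-up, 10)),
    "5"  = field(c(37, 38, 43, 44),              0, rep(up, 4)),
    "6"  = field(c(40, 41, 46, 47),              0, rep(up, 4)),
    "9"  = field(c(31, 32, 33, 34, 35),          0, rep(up, 5)),
    "12" = field(corner_idx,
                 c(-1, 1, -1, 1, -1, 1, -1, 1, -1, 1) * corner_w / sqrt(2),
                 corner_w * up / sqrt(2)),
    "15" = field(corner_idx,                     0, corner_w * -up),
    "17" = field(c(7, 8, 9, 56, 57, 58),         0, rep(up, 6)),
    "20" = field(corner_idx,
                 c(-1, 1, -1, 1, -1, 1, -1, 1, -1, 1) * corner_w, 0),
    "25" = field(c(49:53, 60:62, 55:59, 63:65),  0,
                 c(rep(up, 8), rep(-up, 8)) * 0.7),
    "26" = field(c(5:11, 55:59, 63:65),          0, rep(-up, 15))
  )
}

#' Simulation configuration for synthetic cohorts
#'
#' Defaults describe a DISFA-like recording: 27 subjects filmed at 20 fps,
#' near-frontal with mild head motion, sub-pixel tracking jitter, and
#' emotion epochs in which a random subset of subjects displays a coherent
#' AU-like movement.
#'
#' @param n_subjects Number of subjects (default 27).
#' @param n_frames Frames per recording (default 600, i.e. 30 s at 20 fps —
#'   long enough for several epochs while keeping simulations fast).
#' @param fps Frames per second (default 20).
#' @param noise_sd Per-coordinate i.i.d. Gaussian tracking jitter, pixels
#'   (default 0.5: sub-pixel tracker noise).
#' @param shape_sd Per-subject affine shape jitter: entries of the linear
#'   part are perturbed uniformly by up to this fraction (default 0.05).
#' @param shape_translate Per-subject uniform translation range, pixels.
#' @param pose List with per-frame head-pose nuisance ranges: `rot_deg`
#'   (uniform in-plane rotation, degrees), `scale_dev` (uniform scale in
#'   `1 +- scale_dev`) and `trans_px` (uniform translation). Defaults are
#'   mild near-frontal motion (5 degrees, 5% scale, 10 px); set all to 0
#'   for a fixed head.
#' @param epochs List of epochs; each epoch is a list with fields `au`
#'   (coded AU id), `start`, `end` (0-based frames, inclusive), `p`
#'   (per-subject participation probability), `amp_mean`, `amp_sd`
#'   (displacement amplitude, pixels), `onset`, `offset` (linear ramp
#'   lengths, frames). Epochs of the same AU must not overlap.
#' @param intensity_bins Amplitude quantization: bin width for mapping a
#'   momentary displacement amplitude to intensity codes 0..5; default
#'   `2 * amp_mean / 6` per epoch (equal-width bins over `[0, 2 amp_mean]`).
#' @param seed Integer seed; one global seed drives per-subject substreams.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_subjects = 27L, n_frames = 600L, fps = 20,
                              noise_sd = 0.5, shape_sd = 0.05,
                              shape_translate = 5,
                              pose = list(rot_deg = 5, scale_dev = 0.05,
                                          trans_px = 10),
                              epochs = list(), intensity_bins = NULL,
                              seed = 1L) {
  crm_assert(is_count(n_subjects) && n_subjects >= 2, "n_subjects must be >= 2")
  crm_assert(is_count(n_frames) && n_frames >= 2, "n_frames must be >= 2")
  crm_assert(noise_sd >= 0, "noise_sd must be >= 0")
  for (e in epochs) {
    crm_assert(all(c("au", "start", "end", "p") %in% names(e)),
               "each epoch needs fields au, start, end, p")
    crm_assert(e$p >= 0 && e$p <= 1, "epoch participation p must be in [0, 1]")
    crm_assert(e$start >= 0 && e$end < n_frames && e$start <= e$end,
               "epoch frames must lie within [0, n_frames)")
    crm_assert((e$amp_mean %||% 1) >= 0, "epoch amplitude must be >= 0")
  }
  by_au <- split(epochs, vapply(epochs, function(e) as.character(e$au), character(1)))
  for (grp in by_au) {
    if (length(grp) > 1) {
      o <- order(vapply(grp, `[[`, numeric(1), "start"))
      s <- vapply(grp[o], `[[`, numeric(1), "start")
      e <- vapply(grp[o], `[[`, numeric(1), "end")
      crm_assert(all(s[-1] > e[-length(e)]),
                 "overlapping epochs on the same AU", "crm_structure_error")
    }
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_frames = as.integer(n_frames), fps = fps,
                 noise_sd = noise_sd, shape_sd = shape_sd,
                 shape_translate = shape_translate, pose = pose,
                 epochs = epochs, intensity_bins = intensity_bins,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

epoch_ramp <- function(e, n_frames) {
  r <- numeric(n_frames)
  idx <- (e$start):(e$end) + 1L
  onset <- e$onset %||% 0L
  offset <- e$offset %||% 0L
  len <- length(idx)
  ramp <- rep(1, len)
  if (onset > 0) ramp[seq_len(min(onset, len))] <- seq_len(min(onset, len)) / (onset + 1)
  if (offset > 0) {
    k <- min(offset, len)
    ramp[len - k + seq_len(k)] <- pmin(ramp[len - k + seq_len(k)], rev(seq_len(k) / (offset + 1)))
  }
  r[idx] <- ramp
  r
}

#' Simulate a synthetic cohort
#'
#' Generation per subject: canonical template -> per-subject shape affine ->
#' per frame, sum of epoch AU displacement fields (a subject participates in
#' an epoch with probability `p`; its amplitude is drawn once per
#' subject-epoch and scaled by a linear onset/apex/offset ramp) -> i.i.d.
#' Gaussian jitter -> per-frame similarity head-pose nuisance. Frame 0 is
#' the rest frame used as the KPM neutral reference and is emitted without
#' jitter or displacement (pose nuisance still applies), so displacement
#' noise downstream is i.i.d. across frames. AU intensity labels quantize
#' the momentary displacement amplitude to 0..5; the ground-truth
#' consistency equals the fraction of subjects with a codable (intensity
#' >= 1 at apex) participation wherever the epoch ramp is positive.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_cohort`: list with `cohort` (a [cohort_dataset()]
#'   with AU labels and per-epoch segments), `ground_truth` (data frame:
#'   `frame`, one fraction column per coded AU, and `overall`), and
#'   `participants` (subjects x epochs logical matrix).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  tmpl <- face_template()
  patterns <- au_pattern_dictionary()
  n <- config$n_subjects
  T_ <- config$n_frames
  epochs <- config$epochs
  n_ep <- length(epochs)
  ramps <- lapply(epochs, epoch_ramp, n_frames = T_)

  set.seed(config$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)

  recordings <- vector("list", n)
  labels <- vector("list", n)
  participates <- matrix(FALSE, n, max(1, n_ep))
  codable <- matrix(FALSE, n, max(1, n_ep))
  amps_all <- matrix(0, n, max(1, n_ep))
  for (i in seq_len(n)) {
    set.seed(subject_seeds[i])
    sid <- sprintf("S%03d", i)
    A <- diag(2) + matrix(stats::runif(4, -config$shape_sd, config$shape_sd), 2, 2)
    b <- stats::runif(2, -config$shape_translate, config$shape_translate)
    base <- sweep(tmpl %*% t(A), 2, b, `+`)

    amps <- numeric(n_ep)
    for (j in seq_len(n_ep)) {
      e <- epochs[[j]]
      participates[i, j] <- stats::runif(1) < e$p
      amp <- max(0, stats::rnorm(1, e$amp_mean %||% 3, e$amp_sd %||% 0))
      amps[j] <- if (participates[i, j]) amp else 0
      bin <- config$intensity_bins %||% (2 * (e$amp_mean %||% 3) / 6)
      codable[i, j] <- participates[i, j] && amps[j] >= bin
    }
    amps_all[i, seq_len(n_ep)] <- amps

    coords <- matrix(0, T_, KPM_DIM)
    intens <- matrix(0L, T_, 12L)
    for (tt in seq_len(T_)) {
      xy <- base
      for (j in seq_len(n_ep)) {
        a <- amps[j] * ramps[[j]][tt]
        if (a > 0) {
          f <- patterns[[as.character(epochs[[j]]$au)]]
          xy <- xy + a * cbind(f[1:66], f[67:132])
          bin <- config$intensity_bins %||% (2 * (epochs[[j]]$amp_mean %||% 3) / 6)
          intens[tt, au_index(epochs[[j]]$au)] <- min(5L, as.integer(floor(a / bin)))
        }
      }
      if (config$noise_sd > 0 && tt > 1) {
        xy <- xy + matrix(stats::rnorm(KPM_DIM, 0, config$noise_sd), KEYPOINT_N, 2)
      }
      pose <- config$pose
      if ((pose$rot_deg %||% 0) > 0 || (pose$scale_dev %||% 0) > 0 ||
          (pose$trans_px %||% 0) > 0) {
        th <- stats::runif(1, -1, 1) * (pose$rot_deg %||% 0) * pi / 180
        s <- 1 + stats::runif(1, -1, 1) * (pose$scale_dev %||% 0)
        tr <- stats::runif(2, -1, 1) * (pose$trans_px %||% 0)
        tf <- structure(list(s = s, theta = th, t = tr),
                        class = "similarity_transform")
        xy <- apply_similarity(tf, xy)
      }
      coords[tt, ] <- xy_to_row(xy)
    }
    recordings[[i]] <- subject_recording(coords, subject_id = sid, fps = config$fps)
    labels[[i]] <- au_label_sequence(intens, subject_id = sid)
  }

  segments <- if (n_ep > 0) {
    segment_table(data.frame(
      name = vapply(seq_len(n_ep), function(j)
        sprintf("AU%s_%d", epochs[[j]]$au, j), character(1)),
      start_frame = vapply(epochs, `[[`, numeric(1), "start"),
      end_frame = vapply(epochs, `[[`, numeric(1), "end"),
      emotion = vapply(epochs, function(e) e$emotion %||% "synthetic", character(1))))
  } else NULL

  # ground truth: fraction of subjects with a codable (intensity >= 1)
  # displacement at each frame; identical by construction to the emitted
  # labels' binarized consistency
  gt <- matrix(0, T_, 12L, dimnames = list(NULL, paste0("AU", AU_IDS)))
  for (j in seq_len(n_ep)) {
    bin <- config$intensity_bins %||% (2 * (epochs[[j]]$amp_mean %||% 3) / 6)
    frac_t <- vapply(seq_len(T_), function(tt)
      mean(amps_all[, j] * ramps[[j]][tt] >= bin), numeric(1))
    ai <- au_index(epochs[[j]]$au)
    gt[, ai] <- pmax(gt[, ai], frac_t)
  }
  ground_truth <- data.frame(frame = seq_len(T_) - 1L, gt,
                             overall = apply(gt, 1, max), check.names = FALSE)

  structure(list(cohort = cohort_dataset(recordings, au_labels = labels,
                                         segments = segments),
                 ground_truth = ground_truth,
                 participants = participates, codable = codable,
                 config = config),
            class = "synthetic_cohort")
}

#' Null cohort: jitter-only recordings with no consistent movement
#'
#' [simulate_cohort()] with no epochs and no head-pose nuisance; every frame
#' is the subject's rest face plus i.i.d. Gaussian jitter. Used to calibrate
#' the metrics' null sampling distributions.
#'
#' @param n Number of subjects, `T` frames, `noise_sd` jitter SD (pixels),
#'   `seed` RNG seed.
#' @param T,noise_sd,seed See above.
#' @return A `synthetic_cohort`.
#' @export
null_cohort <- function(n = 27L, T = 2000L, noise_sd = 0.5, seed = 1L) {
  simulate_cohort(simulation_config(
    n_subjects = n, n_frames = T, noise_sd = noise_sd,
    pose = list(rot_deg = 0, scale_dev = 0, trans_px = 0),
    epochs = list(), seed = seed))
}

#' Raw KPM series of a synthetic cohort (no registration)
#'
#' Convenience for calibration: keypoint-movement vectors computed directly
#' from the generated coordinates against frame 0, bypassing the geometric
#' pipeline. Only meaningful when the generator injected no head-pose
#' nuisance.
#'
#' @param sim A `synthetic_cohort`.
#' @return List of `kpm_series`.
#' @export
raw_kpm <- function(sim) {
  lapply(sim$cohort$recordings, compute_kpm, neutral_frame = "first")
}
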