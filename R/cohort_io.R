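# Reading and writing the stable text formats: landmark trajectories, AU
# intensity labels, emotion-segment tables and metric series.

#' Construct a subject recording
#'
#' @param coords Numeric matrix, one row per frame, 132 columns
#'   (`x_0..x_65, y_0..y_65`), pixel units (y grows downward).
#' @param frames Integer vector of 0-based frame indices, strictly increasing
#'   by 1. Defaults to `0:(nrow(coords)-1)`.
#' @param subject_id Subject identifier.
#' @param fps Recording rate in frames per second (default 20).
#' @return An object of class `subject_recording`.
#' @export
subject_recording <- function(coords, frames = NULL, subject_id = "subject", fps = 20) {
  coords <- as.matrix(coords)
  crm_assert(ncol(coords) == KPM_DIM,
             sprintf("expected %d coordinate columns, got %d", KPM_DIM, ncol(coords)),
             "crm_parse_error")
  crm_assert(all(is.finite(coords)), "landmark coordinates must be finite")
  frames <- if (is.null(frames)) seq_len(nrow(coords)) - 1L else as.integer(frames)
  crm_assert(length(frames) == nrow(coords), "frame index length mismatch")
  if (nrow(coords) > 1) {
    crm_assert(all(diff(frames) == 1L),
               "frame indices must be contiguous (strictly increasing by 1)",
               "crm_structure_error")
  }
  dimnames(coords) <- list(NULL, landmark_colnames()[-1])
  structure(list(subject_id = as.character(subject_id), coords = coords,
                 frames = frames, fps = fps),
            class = "subject_recording")
}

#' @export
print.subject_recording <- function(x, ...) {
  cat(sprintf("<subject_recording> %s: %d frames (%d..%d) @ %g fps, 66 keypoints\n",
              x$subject_id, length(x$frames), min(x$frames), max(x$frames), x$fps))
  invisible(x)
}

n_frames <- function(rec) nrow(rec$coords)

# Resolve a 0-based file frame index to a matrix row.
frame_row <- function(rec, frame_index) {
  i <- match(frame_index, rec$frames)
  crm_assert(!is.na(i), sprintf("frame %s not present in recording '%s'",
                                frame_index, rec$subject_id))
  i
}

read_table_auto <- function(path) {
  crm_assert(file.exists(path), sprintf("file not found: %s", path), "crm_io_error")
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    strip.white = TRUE)
}

#' Read a landmark trajectory file
#'
#' Default dialect: one flat CSV/TSV per subject with header
#' `frame,x_0,...,x_65,y_0,...,y_65`.
#'
#' @param path File path (`.csv` comma separated, `.tsv` tab separated).
#' @param subject_id Subject identifier; defaults to the file base name.
#' @param fps Frames per second recorded in the returned object.
#' @return A [subject_recording()].
#' @export
read_landmarks <- function(path, subject_id = NULL, fps = 20) {
  df <- read_table_auto(path)
  expected <- landmark_colnames()
  if (!identical(names(df), expected)) {
    crm_stop(sprintf(
      "malformed landmark file '%s': expected %d columns (frame, x_0..x_65, y_0..y_65), got %d",
      path, length(expected), ncol(df)), "crm_parse_error")
  }
  bad <- which(!stats::complete.cases(df) | rowSums(!sapply(df, is.finite)) > 0)
  if (length(bad)) {
    crm_stop(sprintf("malformed row %d in '%s': non-numeric or missing value",
                     bad[1], path), "crm_parse_error")
  }
  subject_id <- subject_id %||% sub("\\.(csv|tsv)$", "", basename(path), ignore.case = TRUE)
  subject_recording(as.matrix(df[, -1]), frames = df$frame,
                    subject_id = subject_id, fps = fps)
}

#' Write a landmark trajectory file
#'
#' Inverse of [read_landmarks()]; round trips are lossless (coordinates are
#' written with full double precision).
#'
#' @param recording A [subject_recording()].
#' @param path Output path; `.tsv` switches to tab separation.
#' @export
write_landmarks <- function(recording, path) {
  df <- data.frame(frame = recording$frames, recording$coords, check.names = FALSE)
  write_full_precision(df, path)
}

write_full_precision <- function(df, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) crm_stop(sprintf("cannot write '%s'", path), "crm_io_error")
  invisible(path)
}

#' Construct an AU label sequence
#'
#' @param intensities Integer matrix, one row per frame, 12 columns of AU
#'   intensity codes in 0..5 (column order `AU1,AU2,AU4,...,AU26`).
#' @param frames 0-based frame indices (default contiguous from 0).
#' @param subject_id Subject identifier.
#' @return An object of class `au_label_sequence`.
#' @export
au_label_sequence <- function(intensities, frames = NULL, subject_id = "subject") {
  intensities <- as.matrix(intensities)
  crm_assert(ncol(intensities) == 12L, "expected 12 AU intensity columns",
             "crm_parse_error")
  crm_assert(all(intensities %in% 0:5),
             "AU intensities must be integer codes in 0..5", "crm_validation_error")
  frames <- if (is.null(frames)) seq_len(nrow(intensities)) - 1L else as.integer(frames)
  crm_assert(length(frames) == nrow(intensities), "frame index length mismatch")
  storage.mode(intensities) <- "integer"
  colnames(intensities) <- paste0("AU", AU_IDS)
  structure(list(subject_id = as.character(subject_id),
                 intensities = intensities, frames = frames,
                 au_ids = AU_IDS),
            class = "au_label_sequence")
}

#' Read an AU intensity label file
#'
#' Expects header `frame,AU1,AU2,AU4,AU5,AU6,AU9,AU12,AU15,AU17,AU20,AU25,AU26`
#' with integer intensity codes 0-5.
#'
#' @inheritParams read_landmarks
#' @return An [au_label_sequence()].
#' @export
read_au_labels <- function(path, subject_id = NULL) {
  df <- read_table_auto(path)
  if (!identical(names(df), au_colnames())) {
    crm_stop(sprintf("malformed AU file '%s': expected header %s",
                     path, paste(au_colnames(), collapse = ",")), "crm_parse_error")
  }
  subject_id <- subject_id %||% sub("\\.(csv|tsv)$", "", basename(path), ignore.case = TRUE)
  au_label_sequence(as.matrix(df[, -1]), frames = df$frame, subject_id = subject_id)
}

#' @rdname read_au_labels
#' @param labels An [au_label_sequence()].
#' @export
write_au_labels <- function(labels, path) {
  df <- data.frame(frame = labels$frames, labels$intensities, check.names = FALSE)
  write_full_precision(df, path)
}

#' Read / write an emotion-segment table
#'
#' Segments file: CSV with header `name,start_frame,end_frame,emotion`;
#' `start_frame`/`end_frame` are inclusive 0-based frame numbers. Segments
#' must be sorted and non-overlapping.
#'
#' @param path File path.
#' @return A `segment_table` data frame.
#' @export
read_segments <- function(path) {
  df <- read_table_auto(path)
  crm_assert(identical(names(df), c("name", "start_frame", "end_frame", "emotion")),
             sprintf("malformed segments file '%s'", path), "crm_parse_error")
  segment_table(df)
}

#' @rdname read_segments
#' @param segments A `segment_table`.
#' @export
write_segments <- function(segments, path) {
  write_full_precision(as.data.frame(segments), path)
}

#' @rdname read_segments
#' @param df Data frame with columns `name`, `start_frame`, `end_frame`,
#'   `emotion`.
#' @export
segment_table <- function(df) {
  df <- as.data.frame(df)
  crm_assert(all(df$start_frame <= df$end_frame),
             "segment start_frame must be <= end_frame", "crm_structure_error")
  df <- df[order(df$start_frame), , drop = FALSE]
  if (nrow(df) > 1) {
    crm_assert(all(df$start_frame[-1] > df$end_frame[-nrow(df)]),
               "segments must not overlap", "crm_structure_error")
  }
  df$start_frame <- as.integer(df$start_frame)
  df$end_frame <- as.integer(df$end_frame)
  rownames(df) <- NULL
  class(df) <- c("segment_table", "data.frame")
  df
}

#' Write / read a per-frame metric series
#'
#' Two-column TSV `frame<TAB>value` with full double precision; round trips
#' are lossless.
#'
#' @param series A `metric_series` (see [metric_timeseries()]) or any data
#'   frame with columns `frame` and `value`.
#' @param path Output path.
#' @export
write_metric_series <- function(series, path) {
  crm_assert(all(is.finite(series$value)), "metric series must be finite")
  df <- data.frame(frame = series$frame, value = sprintf("%.17g", series$value))
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) crm_stop(sprintf("cannot write '%s'", path), "crm_io_error")
  invisible(path)
}

#' @rdname write_metric_series
#' @param metric Metric name stored in the returned object's attributes.
#' @export
read_metric_series <- function(path, metric = NA_character_) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  crm_assert(identical(names(df), c("frame", "value")),
             sprintf("malformed metric series '%s'", path), "crm_parse_error")
  metric_series(df$value, frames = df$frame, metric = metric)
}

metric_series <- function(values, frames, metric, options = list()) {
  structure(data.frame(frame = as.integer(frames), value = as.numeric(values)),
            metric = metric, options = options,
            class = c("metric_series", "data.frame"))
}

#' Assemble a cohort dataset
#'
#' Binds per-subject recordings (and optional AU label sequences and an
#' emotion-segment table) on a common frame axis. All recordings must share
#' the same frame count and frame indexing; at least two subjects are
#' required by the downstream cross-subject statistics.
#'
#' @param recordings List of [subject_recording()] objects.
#' @param au_labels Optional list of [au_label_sequence()] objects, matched to
#'   recordings by subject id.
#' @param segments Optional [segment_table()].
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(recordings, au_labels = NULL, segments = NULL) {
  crm_assert(length(recordings) >= 2,
             "a cohort needs at least 2 subjects", "crm_structure_error")
  Ts <- vapply(recordings, n_frames, integer(1))
  if (length(unique(Ts)) != 1) {
    crm_stop(sprintf("recordings have unequal frame counts: %s",
                     paste(unique(Ts), collapse = ", ")), "crm_structure_error")
  }
  f0 <- recordings[[1]]$frames
  for (r in recordings) {
    crm_assert(identical(r$frames, f0), "recordings disagree on frame indices",
               "crm_structure_error")
  }
  ids <- vapply(recordings, `[[`, character(1), "subject_id")
  crm_assert(!anyDuplicated(ids), "duplicate subject ids in cohort")
  names(recordings) <- ids
  if (!is.null(au_labels)) {
    lids <- vapply(au_labels, `[[`, character(1), "subject_id")
    names(au_labels) <- lids
    crm_assert(setequal(lids, ids), "AU labels do not match cohort subjects",
               "crm_structure_error")
    au_labels <- au_labels[ids]
    for (l in au_labels) {
      crm_assert(nrow(l$intensities) == Ts[1],
                 sprintf("AU frame count mismatch for subject '%s'", l$subject_id),
                 "crm_structure_error")
    }
  }
  structure(list(recordings = recordings, au_labels = au_labels,
                 segments = segments, n = length(recordings), T = Ts[[1]]),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d subjects x %d frames%s%s\n", x$n, x$T,
              if (is.null(x$au_labels)) "" else ", with AU labels",
              if (is.null(x$segments)) "" else sprintf(", %d segments", nrow(x$segments))))
  invisible(x)
}

#' Read / write a cohort directory
#'
#' Directory layout: `landmarks/<id>.csv` (one per subject), optional
#' `au_labels/<id>.csv`, optional `segments.csv`.
#'
#' @param dir Cohort directory.
#' @param fps Frames per second for the recordings.
#' @return A [cohort_dataset()].
#' @export
read_cohort <- function(dir, fps = 20) {
  crm_assert(dir.exists(dir), sprintf("cohort directory not found: %s", dir),
             "crm_io_error")
  lm_files <- sort(list.files(file.path(dir, "landmarks"),
                              pattern = "\\.(csv|tsv)$", full.names = TRUE))
  crm_assert(length(lm_files) > 0, sprintf("no landmark files under %s/landmarks", dir),
             "crm_io_error")
  recs <- lapply(lm_files, read_landmarks, fps = fps)
  au_dir <- file.path(dir, "au_labels")
  labels <- NULL
  if (dir.exists(au_dir)) {
    au_files <- sort(list.files(au_dir, pattern = "\\.(csv|tsv)$", full.names = TRUE))
    if (length(au_files)) labels <- lapply(au_files, read_au_labels)
  }
  seg_path <- file.path(dir, "segments.csv")
  segments <- if (file.exists(seg_path)) read_segments(seg_path) else NULL
  cohort_dataset(recs, au_labels = labels, segments = segments)
}

#' @rdname read_cohort
#' @param cohort A [cohort_dataset()].
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "landmarks"), recursive = TRUE, showWarnings = FALSE)
  for (r in cohort$recordings) {
    write_landmarks(r, file.path(dir, "landmarks", paste0(r$subject_id, ".csv")))
  }
  if (!is.null(cohort$au_labels)) {
    dir.create(file.path(dir, "au_labels"), showWarnings = FALSE)
    for (l in cohort$au_labels) {
      write_au_labels(l, file.path(dir, "au_labels", paste0(l$subject_id, ".csv")))
    }
  }
  if (!is.null(cohort$segments)) {
    write_segments(cohort$segments, file.path(dir, "segments.csv"))
  }
  invisible(dir)
}
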