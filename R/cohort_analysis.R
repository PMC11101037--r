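# Cohort-analysis layer: percentile consistency classes, per-segment class
# distribution tables, KL-divergence table comparison and linear-regression
# agreement between metrics.

CLASS_NAMES <- c("Inconsistent", "Low Consistent", "Mild Consistent",
                 "High Consistent")

#' Consistency-class boundaries from a metric series
#'
#' Splits a per-frame series into four classes at its empirical sample
#' percentiles (default 30th, 60th and 90th; nearest-rank / type-1
#' percentiles). The class intervals are half-open,
#' `[b0,b1), [b1,b2), [b2,b3), [b3,max]`, so a value equal to a boundary
#' falls in the upper class. A constant series yields degenerate (equal)
#' boundaries and everything classifies into the top class containing the
#' value.
#'
#' @param series A `metric_series`, `consistency_series` or numeric vector.
#' @param percentiles Three increasing percentages (default `c(30, 60, 90)`).
#' @return A `class_boundaries` object: list with `boundaries` (3 values),
#'   `percentiles`, `classes` and `metric`.
#' @export
class_boundaries <- function(series, percentiles = c(30, 60, 90)) {
  v <- series_values(series)
  crm_assert(length(v) >= 4, "need at least 4 frames to place class boundaries")
  crm_assert(length(percentiles) == 3 && !is.unsorted(percentiles) &&
               all(percentiles > 0 & percentiles < 100),
             "percentiles must be three increasing values in (0, 100)")
  sv <- sort(v)
  b <- sv[pmax(1L, ceiling(percentiles / 100 * length(sv)))]
  structure(list(boundaries = as.numeric(b), percentiles = percentiles,
                 classes = CLASS_NAMES, metric = series_metric(series)),
            class = "class_boundaries")
}

series_values <- function(series) {
  if (inherits(series, "consistency_series")) return(series$kappa_au)
  if (is.data.frame(series)) return(series$value)
  as.numeric(series)
}

series_metric <- function(series) {
  if (inherits(series, "consistency_series")) return("kappa_au")
  attr(series, "metric") %||% NA_character_
}

series_frames <- function(series) {
  if (is.data.frame(series)) return(series$frame)
  seq_along(series_values(series)) - 1L
}

#' Classify a series into consistency classes
#'
#' Half-open interval membership against [class_boundaries()]; boundary
#' values go to the upper class.
#'
#' @param series Series or numeric vector on the same scale as `boundaries`.
#' @param boundaries A `class_boundaries` object.
#' @return Factor of class labels, one per frame.
#' @export
classify <- function(series, boundaries) {
  v <- series_values(series)
  b <- boundaries$boundaries
  idx <- 1L + (v >= b[1]) + (v >= b[2]) + (v >= b[3])
  factor(CLASS_NAMES[idx], levels = CLASS_NAMES)
}

#' Per-segment class-distribution table
#'
#' For each emotion segment, the percentage of its frames falling in each of
#' the four consistency classes. With `extend_to_isg` (default), each
#' segment is stretched through its following inter-segment gap, i.e. to the
#' frame before the next segment's start (the last segment extends to the
#' end of the recording) — expressions decay slowly, so the gap carries the
#' tail of the preceding segment's response.
#'
#' @param labels Factor from [classify()], one label per frame.
#' @param frames 0-based frame indices aligned with `labels`.
#' @param segments A [segment_table()].
#' @param extend_to_isg Extend segment ends through the following gap.
#' @return A `class_distribution_table`: segments x 4 matrix of percentages
#'   (full precision), with a `counts` attribute.
#' @export
segment_distribution <- function(labels, frames, segments,
                                 extend_to_isg = TRUE) {
  crm_assert(length(labels) == length(frames), "labels/frames length mismatch")
  starts <- segments$start_frame
  ends <- segments$end_frame
  if (extend_to_isg) {
    ends <- c(starts[-1] - 1L, max(frames))
  }
  tab <- matrix(0, nrow(segments), 4,
                dimnames = list(segments$name, CLASS_NAMES))
  counts <- tab
  for (i in seq_len(nrow(segments))) {
    sel <- frames >= starts[i] & frames <= ends[i]
    if (!any(sel)) {
      crm_stop(sprintf("segment '%s' (%d..%d) lies outside the series",
                       segments$name[i], starts[i], ends[i]), "crm_structure_error")
    }
    cnt <- table(labels[sel])
    counts[i, ] <- as.numeric(cnt[CLASS_NAMES])
    tab[i, ] <- counts[i, ] / sum(counts[i, ]) * 100
  }
  structure(tab, counts = counts, class = c("class_distribution_table",
                                            "matrix", "array"))
}

#' @rdname segment_distribution
#' @param tab A `class_distribution_table`.
#' @return `format_distribution_table()`: integer matrix rounded half-up,
#'   mirroring how such tables are reported (rows may sum to 99-101).
#' @export
format_distribution_table <- function(tab) {
  round_half_up(unclass(tab))
}

#' Kullback-Leibler divergence between two distribution rows
#'
#' \eqn{\sum_j p_j \ln(p_j / q_j)} in nats. Rows are normalized to
#' probabilities internally (percentage rows are accepted); zero cells in
#' both rows are replaced by `epsilon` and the rows renormalized, so the
#' divergence is always finite.
#'
#' @param p,q Non-negative numeric vectors of equal length.
#' @param epsilon Zero-cell replacement (default 1e-12).
#' @return Scalar divergence in nats (>= 0 up to smoothing).
#' @export
kl_divergence <- function(p, q, epsilon = 1e-12) {
  crm_assert(length(p) == length(q), "distributions must have equal length")
  crm_assert(all(p >= 0) && all(q >= 0),
             "distributions must be non-negative", "crm_validation_error")
  crm_assert(sum(p) > 0 && sum(q) > 0, "distributions must have positive mass")
  p <- p / sum(p); q <- q / sum(q)
  p[p == 0] <- epsilon; q[q == 0] <- epsilon
  p <- p / sum(p); q <- q / sum(q)
  sum(p * log(p / q))
}

#' Row-wise averaged KL divergence between two class-distribution tables
#'
#' Pairs rows by name and averages [kl_divergence()] across them. Default
#' direction is metric -> AU (the metric's row as `p`, the AU table's row as
#' `q`); `direction = "au_to_metric"` flips every row-wise call.
#'
#' @param table_metric,table_au `class_distribution_table`s (or plain
#'   matrices) with identical row and column names.
#' @param direction `"metric_to_au"` (default) or `"au_to_metric"`.
#' @param epsilon Zero-cell smoothing, see [kl_divergence()].
#' @return Scalar mean divergence.
#' @export
avg_rowwise_kl <- function(table_metric, table_au,
                           direction = c("metric_to_au", "au_to_metric"),
                           epsilon = 1e-12) {
  direction <- match.arg(direction)
  crm_assert(setequal(rownames(table_metric), rownames(table_au)) &&
               ncol(table_metric) == ncol(table_au),
             "tables must share rows and columns", "crm_structure_error")
  rows <- rownames(table_metric)
  kl <- vapply(rows, function(r) {
    p <- table_metric[r, ]; q <- table_au[r, ]
    if (direction == "metric_to_au") kl_divergence(p, q, epsilon)
    else kl_divergence(q, p, epsilon)
  }, numeric(1))
  mean(kl)
}

#' Ordinary least-squares agreement between two per-frame series
#'
#' Simple linear regression of `y` on `x`; the coefficient of determination
#' equals the squared Pearson correlation. A constant `y` is defined to give
#' R-squared 0; a constant `x` is a degenerate fit and errors.
#'
#' @param x,y Equal-length series (metric and reference) or numeric vectors.
#' @return A `regression_fit`: list with `slope`, `intercept`, `r2`, `n`.
#' @export
fit_r2 <- function(x, y) {
  xv <- series_values(x); yv <- series_values(y)
  crm_assert(length(xv) == length(yv) && length(xv) >= 3,
             "series must have equal length >= 3")
  if (stats::var(xv) == 0) {
    crm_stop("regression on a constant series is degenerate", "crm_degenerate_fit_error")
  }
  slope <- stats::cov(xv, yv) / stats::var(xv)
  intercept <- mean(yv) - slope * mean(xv)
  r2 <- if (stats::var(yv) == 0) 0 else stats::cor(xv, yv)^2
  structure(list(slope = slope, intercept = intercept, r2 = r2, n = length(xv)),
            class = "regression_fit")
}

#' Compare keypoint metrics against the AU-consistency reference
#'
#' For each keypoint metric series: R-squared (and slope/intercept) of a
#' linear regression against the AU-consistency series, and the row-wise
#' averaged KL divergence between the two metrics' per-segment
#' class-distribution tables. Metrics are ranked by ascending KL and by
#' descending R-squared.
#'
#' @param metric_list Named list of `metric_series`.
#' @param au_series A `consistency_series` from [au_consistency_series()].
#' @param segments A [segment_table()].
#' @param percentiles Class percentiles (see [class_boundaries()]).
#' @param extend_to_isg See [segment_distribution()].
#' @param direction,epsilon See [avg_rowwise_kl()].
#' @return A `crm_report` list: per-metric statistics, rankings, and the
#'   distribution tables; serializable with [write_report()].
#' @export
compare_metrics <- function(metric_list, au_series, segments,
                            percentiles = c(30, 60, 90), extend_to_isg = TRUE,
                            direction = "metric_to_au", epsilon = 1e-12) {
  crm_assert(length(metric_list) >= 1 && !is.null(names(metric_list)),
             "metric_list must be a named list of metric series")
  au_b <- class_boundaries(au_series, percentiles)
  au_tab <- segment_distribution(classify(au_series, au_b),
                                 series_frames(au_series), segments,
                                 extend_to_isg)
  per_metric <- lapply(names(metric_list), function(nm) {
    ms <- metric_list[[nm]]
    fit <- fit_r2(ms, au_series)
    b <- class_boundaries(ms, percentiles)
    tab <- segment_distribution(classify(ms, b), series_frames(ms), segments,
                                extend_to_isg)
    list(metric = nm, r2 = fit$r2, slope = fit$slope, intercept = fit$intercept,
         avg_kl = avg_rowwise_kl(tab, au_tab, direction, epsilon),
         boundaries = b$boundaries, table = tab)
  })
  names(per_metric) <- names(metric_list)
  r2s <- vapply(per_metric, `[[`, numeric(1), "r2")
  kls <- vapply(per_metric, `[[`, numeric(1), "avg_kl")
  structure(list(metrics = per_metric,
                 au_table = au_tab, au_boundaries = au_b$boundaries,
                 ranking_by_r2 = names(sort(r2s, decreasing = TRUE)),
                 ranking_by_kl = names(sort(kls)),
                 options = list(percentiles = percentiles,
                                extend_to_isg = extend_to_isg,
                                direction = direction, epsilon = epsilon)),
            class = "crm_report")
}

#' @rdname compare_metrics
#' @param report A `crm_report`.
#' @param path JSON output path.
#' @export
write_report <- function(report, path) {
  out <- report
  out$metrics <- lapply(report$metrics, function(m) {
    m$table <- as.data.frame(unclass(m$table))
    m
  })
  out$au_table <- as.data.frame(unclass(report$au_table))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

#' Published DISFA class-distribution reference tables
#'
#' Per-segment class-distribution tables (percent of frames per consistency
#' class, integer-rounded) for the DISFA cohort, for the AU-consistency
#' reference metric and the five keypoint metrics, as reported in the
#' published analysis of that dataset. Shipped as a text fixture; used to
#' benchmark table-comparison conventions without access to the restricted
#' recordings.
#'
#' @return Named list of 9 x 4 matrices: `kappa_au`, `avg_t`, `max_t`,
#'   `avg_t2`, `max_t2`, `pca_t2`.
#' @export
disfa_reference_tables <- function() {
  path <- system.file("extdata", "disfa_class_distribution_reference.csv",
                      package = "crmface", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  metrics <- setdiff(names(df), c("segment", "class"))
  segs <- unique(df$segment)
  lapply(stats::setNames(metrics, metrics), function(m) {
    tab <- matrix(NA_real_, length(segs), 4, dimnames = list(segs, CLASS_NAMES))
    for (i in seq_len(nrow(df))) tab[df$segment[i], df$class[i]] <- df[[m]][i]
    tab
  })
}
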