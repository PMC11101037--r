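# Per-frame cross-subject consistency metrics on KPM vectors, under three
# statistical models: independent univariate Gaussian coordinates (t-scores),
# independent bivariate keypoints (Hotelling T-squared), and a PCA-reduced
# multivariate Gaussian (Hotelling T-squared in score space).

METRIC_NAMES <- c("avg_t", "max_t", "avg_t2", "max_t2", "pca_t2")

# Structural-degeneracy tolerance, in pixels. Registration pins some
# coordinates exactly (part anchors land on the reference, midline x equals
# the nose-bridge x after symmetrization), leaving pure floating-point noise
# (~1e-14 px) where the model sees a coordinate. Sample SDs and means below
# this tolerance are snapped to exact zero so the zero-variance conventions
# apply; real facial motion is >= 1e-3 px, six orders of magnitude away.
SNAP_TOL <- 1e-8

snap0 <- function(x, tol = SNAP_TOL) {
  x[abs(x) < tol] <- 0
  x
}

#' Per-coordinate one-sample t-scores of a cohort KPM slice
#'
#' For each of the 132 coordinates, the one-sample Student t statistic
#' \eqn{t_i = \bar X_i / (s_i / \sqrt n)} testing that the mean displacement
#' is zero across subjects. Zero-variance convention: a coordinate with zero
#' sample variance yields t = 0 when its mean is also zero and a signed cap
#' (`zero_cap`) otherwise.
#'
#' @param slice Numeric n x 132 matrix: one KPM vector per subject at a
#'   single frame (n >= 2).
#' @param zero_cap Magnitude assigned when the sample variance is exactly
#'   zero but the mean is not (default 1e6).
#' @return Numeric vector of 132 t-scores.
#' @export
t_scores <- function(slice, zero_cap = 1e6) {
  slice <- as.matrix(slice)
  n <- nrow(slice)
  if (n < 2) crm_stop("t-scores need at least 2 subjects", "crm_sample_error")
  m <- snap0(colMeans(slice))
  v <- snap0(colSums(sweep(slice, 2, m)^2) / (n - 1), SNAP_TOL^2)
  se <- sqrt(v / n)
  t <- ifelse(se > 0, m / se, ifelse(m == 0, 0, sign(m) * zero_cap))
  unname(t)
}

#' Scalar metrics over a t-score vector
#'
#' `avg_t` is the mean absolute t-score over the k = 132 coordinates;
#' `max_t` is the maximum absolute t-score. `literal_scaling` applies a 1/k
#' prefactor to the maximum as well (off by default: it would force the
#' maximum below the average, contradicting the metric's purpose; it does not
#' affect rank-based analyses).
#'
#' @param t Numeric vector of t-scores.
#' @param literal_scaling Apply the 1/k prefactor to the maximum.
#' @return A scalar.
#' @export
avg_t <- function(t) mean(abs(t))

#' @rdname avg_t
#' @export
max_t <- function(t, literal_scaling = FALSE) {
  m <- max(abs(t))
  if (literal_scaling) m / length(t) else m
}

# One-sample Hotelling T-squared of an n x p sample against mean zero:
# t2 = n * m' S^-1 m with S the sample covariance.
hotelling_t2 <- function(x, ridge = 1e-8, zero_cap = 1e6) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n <= p) {
    crm_stop(sprintf(
      "Hotelling T-squared needs the number of subjects (%d) to exceed the dimension (%d); use fewer components",
      n, p), "crm_singular_error")
  }
  m <- colMeans(x)
  S <- stats::cov(x)
  t2 <- tryCatch(drop(n * crossprod(m, solve(S, m))), error = function(e) NA_real_)
  if (!is.finite(t2)) {
    tr <- mean(diag(S))
    if (tr <= 0) return(if (all(m == 0)) 0 else zero_cap)
    t2 <- tryCatch(drop(n * crossprod(m, solve(S + diag(ridge * tr, p), m))),
                   error = function(e) zero_cap)
  }
  max(t2, 0)
}

#' Per-keypoint Hotelling T-squared scores of a cohort KPM slice
#'
#' Treats each keypoint's (dx, dy) displacement as a bivariate normal sample
#' across subjects and computes the one-sample Hotelling statistic
#' \eqn{t^2_i = n\,\bar r_i^\top \hat\Sigma_i^{-1} \bar r_i} against mean
#' (0, 0), for each of the 66 keypoints. A singular 2x2 sample covariance is
#' ridged with `ridge * mean(diag)` on the diagonal (with a warning); a fully
#' zero covariance yields 0 when the mean is zero and `zero_cap` otherwise.
#'
#' @param slice Numeric n x 132 matrix (n >= 3).
#' @param ridge Relative ridge added to singular covariances (default 1e-8).
#' @param zero_cap Value assigned for zero covariance with nonzero mean.
#' @return Numeric vector of 66 non-negative scores.
#' @export
hotelling_t2_per_keypoint <- function(slice, ridge = 1e-8, zero_cap = 1e6) {
  slice <- as.matrix(slice)
  n <- nrow(slice)
  if (n < 3) crm_stop("per-keypoint Hotelling T-squared needs at least 3 subjects",
                      "crm_sample_error")
  A <- slice[, 1:66, drop = FALSE]
  B <- slice[, 67:132, drop = FALSE]
  ma <- colMeans(A); mb <- colMeans(B)
  A0 <- sweep(A, 2, ma); B0 <- sweep(B, 2, mb)
  Sxx <- colSums(A0^2) / (n - 1)
  Syy <- colSums(B0^2) / (n - 1)
  Sxy <- colSums(A0 * B0) / (n - 1)
  compute_t2_cells(ma, mb, Sxx, Syy, Sxy, n, ridge, zero_cap)
}

# Shared vectorized 2x2 Hotelling kernel (works on vectors or matrices).
# Structurally zero axes (see SNAP_TOL) fall back to the univariate limit on
# the live axis; genuinely singular covariances with two live axes are
# ridge-stabilized with a warning.
compute_t2_cells <- function(ma, mb, Sxx, Syy, Sxy, n, ridge, zero_cap) {
  ma <- snap0(ma); mb <- snap0(mb)
  Sxx <- snap0(Sxx, SNAP_TOL^2); Syy <- snap0(Syy, SNAP_TOL^2)
  Sxy <- snap0(Sxy, SNAP_TOL^2)
  tr <- Sxx + Syy
  det <- Sxx * Syy - Sxy^2
  axis_dead <- Sxx == 0 | Syy == 0
  sing <- !(det > 1e-12 * (tr / 2)^2) & !axis_dead # tr==0 implies axis_dead
  n_sing <- sum(sing)
  if (n_sing > 0) {
    warning(sprintf("%d singular 2x2 covariance(s) stabilized with ridge %g",
                    n_sing, ridge))
    r <- ridge * tr / 2
    Sxx <- ifelse(sing, Sxx + r, Sxx)
    Syy <- ifelse(sing, Syy + r, Syy)
    det <- ifelse(sing, Sxx * Syy - Sxy^2, det)
  }
  t2 <- n * (ma^2 * Syy - 2 * ma * mb * Sxy + mb^2 * Sxx) / det
  # one dead axis: univariate t^2 on the live axis, or the cap if the dead
  # axis nonetheless has a nonzero mean; two dead axes: 0 or the cap
  uni <- n * ifelse(Sxx == 0 & Syy > 0, mb^2 / Syy,
                    ifelse(Syy == 0 & Sxx > 0, ma^2 / Sxx, 0))
  dead_mean_live <- (Sxx == 0 & ma != 0) | (Syy == 0 & mb != 0)
  t2[axis_dead] <- ifelse(dead_mean_live[axis_dead], zero_cap, uni[axis_dead])
  t2[!is.finite(t2)] <- zero_cap
  pmax(t2, 0)
}

#' Scalar metrics over per-keypoint Hotelling scores
#'
#' `avg_t2` is the mean of the 66 per-keypoint scores, `max_t2` their
#' maximum (optionally with the literal 1/k prefactor, as for [max_t()]).
#'
#' @param t2 Numeric vector of per-keypoint scores.
#' @inheritParams avg_t
#' @return A scalar.
#' @export
avg_t2 <- function(t2) mean(t2)

#' @rdname avg_t2
#' @export
max_t2 <- function(t2, literal_scaling = FALSE) {
  m <- max(t2)
  if (literal_scaling) m / length(t2) else m
}

#' Uncentered principal-component reduction of pooled KPM data
#'
#' Truncated SVD of the pooled 132 x m data matrix (columns = all subjects'
#' frames). Uncentered by default so that the origin — the neutral face —
#' is preserved in score space and the zero-mean null hypothesis keeps its
#' meaning; `center = TRUE` subtracts the pooled mean first (the tested null
#' then refers to the pooled mean rather than the neutral face).
#'
#' @param Y Numeric 132 x m matrix of pooled KPM columns.
#' @param k Number of components to keep, or `NULL` to choose from
#'   `variance_target`.
#' @param variance_target Smallest k whose cumulative explained variance
#'   reaches this fraction is used when `k` is `NULL`.
#' @param center Subtract the pooled mean before decomposition.
#' @return A `pca_model`: list with loading matrix `P` (132 x k), scores `Q`
#'   (k x m), `k`, per-component `explained` variance fractions, `center`
#'   and `mean`.
#' @export
pca_reduce <- function(Y, k = NULL, variance_target = NULL, center = FALSE) {
  Y <- as.matrix(Y)
  d <- nrow(Y); m <- ncol(Y)
  crm_assert(d == KPM_DIM, "pooled KPM matrix must have 132 rows")
  mu <- if (center) rowMeans(Y) else rep(0, d)
  Yc <- if (center) Y - mu else Y
  G <- tcrossprod(Yc) / m
  eg <- eigen(G, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  explained <- if (sum(ev) > 0) ev / sum(ev) else rep(0, d)
  if (is.null(k)) {
    crm_assert(!is.null(variance_target) && variance_target > 0 && variance_target <= 1,
               "either k or variance_target in (0, 1] must be given", "crm_usage_error")
    k <- which(cumsum(explained) >= variance_target)[1]
    if (is.na(k)) k <- d
  }
  if (!(is_count(k) && k >= 1 && k < d && k < m)) {
    crm_stop(sprintf("k must satisfy 1 <= k < min(132, m); got k=%s, m=%d", k, m),
             "crm_dimension_error")
  }
  P <- eg$vectors[, seq_len(k), drop = FALSE]
  structure(list(P = P, Q = crossprod(P, Yc), k = as.integer(k),
                 explained = explained[seq_len(k)], explained_all = explained,
                 center = center, mean = mu),
            class = "pca_model")
}

#' @rdname pca_reduce
#' @param model A `pca_model`.
#' @param X n x 132 matrix of KPM vectors to project.
#' @return `pca_scores()`: n x k matrix of component scores.
#' @export
pca_scores <- function(model, X) {
  sweep(as.matrix(X), 2, model$mean) %*% model$P
}

#' Hotelling T-squared of PCA score vectors at one frame
#'
#' One-sample Hotelling statistic of the n subjects' k-dimensional component
#' scores against a zero mean; requires n > k.
#'
#' @param scores n x k matrix of per-subject component scores at one frame.
#' @return The scalar statistic.
#' @export
pca_t2 <- function(scores) hotelling_t2(scores)

#' F-based critical value for the one-sample Hotelling test
#'
#' \eqn{\frac{p(n-1)}{n-p} F_{p, n-p}(1-\alpha)}.
#'
#' @param n Sample size, `p` dimension, `alpha` test level.
#' @param p,alpha See above.
#' @export
hotelling_critical <- function(n, p, alpha = 0.05) {
  p * (n - 1) / (n - p) * stats::qf(1 - alpha, p, n - p)
}

#' Per-frame consistency metric series for a cohort
#'
#' Applies one of the five metrics frame by frame to a cohort's KPM series:
#' `avg_t` / `max_t` (independent univariate model), `avg_t2` / `max_t2`
#' (independent bivariate model), or `pca_t2` (Hotelling T-squared on
#' PCA-reduced scores; the model is fit once on the pooled matrix of all
#' subjects and frames).
#'
#' @param kpm_list List of `kpm_series` (equal lengths), from
#'   [preprocess_cohort()].
#' @param metric One of `"avg_t"`, `"max_t"`, `"avg_t2"`, `"max_t2"`,
#'   `"pca_t2"`.
#' @param literal_scaling Apply the literal 1/k prefactor to max metrics.
#' @param k Number of PCA components for `pca_t2` (default 5).
#' @param variance_target Alternative to `k`: keep the smallest number of
#'   components explaining this variance fraction.
#' @param center Center the PCA (see [pca_reduce()]).
#' @param zero_cap,ridge Degenerate-sample conventions (see [t_scores()] and
#'   [hotelling_t2_per_keypoint()]).
#' @return A `metric_series` data frame (`frame`, `value`) with attributes
#'   `metric` and `options`.
#' @export
metric_timeseries <- function(kpm_list, metric = METRIC_NAMES,
                              literal_scaling = FALSE,
                              k = 5L, variance_target = NULL, center = FALSE,
                              zero_cap = 1e6, ridge = 1e-8) {
  if (length(metric) > 1) metric <- metric[1]
  if (!metric %in% METRIC_NAMES) {
    crm_stop(sprintf("unknown metric '%s'; choose one of %s", metric,
                     paste(METRIC_NAMES, collapse = ", ")), "crm_usage_error")
  }
  n <- length(kpm_list)
  crm_assert(n >= 2, "metrics need at least 2 subjects", "crm_sample_error")
  Ts <- vapply(kpm_list, function(s) nrow(s$X), integer(1))
  crm_assert(length(unique(Ts)) == 1, "KPM series have unequal lengths",
             "crm_structure_error")
  T_ <- Ts[1]
  frames <- kpm_list[[1]]$frames
  opts <- list(n = n, literal_scaling = literal_scaling, zero_cap = zero_cap,
               ridge = ridge)

  if (metric %in% c("avg_t", "max_t")) {
    S1 <- Reduce(`+`, lapply(kpm_list, `[[`, "X"))
    S2 <- Reduce(`+`, lapply(kpm_list, function(s) s$X^2))
    m <- snap0(S1 / n)
    v <- snap0(pmax(S2 - n * m^2, 0) / (n - 1), SNAP_TOL^2)
    se <- sqrt(v / n)
    t <- ifelse(se > 0, m / se, ifelse(m == 0, 0, sign(m) * zero_cap))
    val <- if (metric == "avg_t") rowMeans(abs(t)) else {
      mx <- apply(abs(t), 1, max)
      if (literal_scaling) mx / KPM_DIM else mx
    }
    return(metric_series(val, frames, metric, opts))
  }

  if (metric %in% c("avg_t2", "max_t2")) {
    crm_assert(n >= 3, "per-keypoint Hotelling metrics need at least 3 subjects",
               "crm_sample_error")
    xi <- 1:66; yi <- 67:132
    SA <- SB <- SAA <- SBB <- SAB <- matrix(0, T_, 66)
    for (s in kpm_list) {
      A <- s$X[, xi, drop = FALSE]; B <- s$X[, yi, drop = FALSE]
      SA <- SA + A; SB <- SB + B
      SAA <- SAA + A^2; SBB <- SBB + B^2; SAB <- SAB + A * B
    }
    ma <- SA / n; mb <- SB / n
    Sxx <- pmax(SAA - n * ma^2, 0) / (n - 1)
    Syy <- pmax(SBB - n * mb^2, 0) / (n - 1)
    Sxy <- (SAB - n * ma * mb) / (n - 1)
    t2 <- compute_t2_cells(ma, mb, Sxx, Syy, Sxy, n, ridge, zero_cap)
    val <- if (metric == "avg_t2") rowMeans(t2) else {
      mx <- apply(t2, 1, max)
      if (literal_scaling) mx / KEYPOINT_N else mx
    }
    return(metric_series(val, frames, metric, opts))
  }

  # pca_t2: fit the pooled model, then Hotelling per frame in score space
  Y <- t(do.call(rbind, lapply(kpm_list, `[[`, "X")))  # 132 x (n*T)
  model <- pca_reduce(Y, k = if (is.null(variance_target)) k else NULL,
                      variance_target = variance_target, center = center)
  if (n <= model$k) {
    crm_stop(sprintf(
      "pca_t2 needs the number of subjects (%d) to exceed k (%d); choose a smaller k",
      n, model$k), "crm_singular_error")
  }
  scores <- lapply(kpm_list, function(s) pca_scores(model, s$X))  # T x k each
  val <- vapply(seq_len(T_), function(ti) {
    sl <- do.call(rbind, lapply(scores, function(q) q[ti, ]))
    hotelling_t2(sl)
  }, numeric(1))
  opts$k <- model$k
  opts$explained <- sum(model$explained)
  metric_series(val, frames, metric, opts)
}
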