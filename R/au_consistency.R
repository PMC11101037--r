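# FACS-based reference metric: AU consistency — the percentage of subjects
# displaying the same action unit at a frame, maximized over the 12 coded AUs.

#' Binarize AU intensity labels into a presence matrix
#'
#' Intensity codes 0-5 are mapped to binary presence: present iff
#' intensity >= `threshold`. Threshold 1 (default) counts any coded activity
#' as present; 2 is a common stricter convention.
#'
#' @param au_labels List of [au_label_sequence()] objects (or a
#'   [cohort_dataset()] with AU labels).
#' @param threshold Integer in 1..5.
#' @return An `au_label_matrix`: binary array of dimension
#'   (subjects, 12 AUs, frames), with a `threshold` attribute.
#' @export
binarize_au <- function(au_labels, threshold = 1L) {
  if (inherits(au_labels, "cohort_dataset")) au_labels <- au_labels$au_labels
  crm_assert(!is.null(au_labels) && length(au_labels) > 0, "no AU labels given")
  crm_assert(is_count(threshold) && threshold >= 1 && threshold <= 5,
             "threshold must be an integer in 1..5")
  n <- length(au_labels)
  T_ <- nrow(au_labels[[1]]$intensities)
  ids <- vapply(au_labels, `[[`, character(1), "subject_id")
  mu <- array(0L, dim = c(n, 12L, T_),
              dimnames = list(ids, paste0("AU", AU_IDS),
                              au_labels[[1]]$frames))
  for (i in seq_len(n)) {
    crm_assert(nrow(au_labels[[i]]$intensities) == T_,
               "AU label sequences have unequal lengths", "crm_structure_error")
    mu[i, , ] <- t(au_labels[[i]]$intensities >= threshold)
  }
  structure(mu, threshold = as.integer(threshold), class = "au_label_matrix")
}

au_index <- function(k) {
  i <- match(k, AU_IDS)
  if (is.na(i)) crm_stop(sprintf("unknown AU id %s (coded AUs: %s)", k,
                                 paste(AU_IDS, collapse = ", ")), "crm_usage_error")
  i
}

#' AU consistency of one AU at one frame
#'
#' \eqn{\kappa_{AU}(k, \tau) = \frac{1}{n}\sum_i \mu(i,k,\tau) \times 100}:
#' the percentage of subjects with AU `k` present at frame `tau`.
#'
#' @param mu An `au_label_matrix` from [binarize_au()].
#' @param k AU id (one of 1, 2, 4, 5, 6, 9, 12, 15, 17, 20, 25, 26).
#' @param tau 0-based frame index.
#' @return Percentage in \[0, 100\] (full precision, no rounding).
#' @export
au_consistency_per_au <- function(mu, k, tau) {
  fi <- match(as.character(tau), dimnames(mu)[[3]])
  crm_assert(!is.na(fi), sprintf("frame %s not in AU label matrix", tau))
  mean(mu[, au_index(k), fi]) * 100
}

#' Overall AU consistency at one frame
#'
#' \eqn{\kappa_{AU}(\tau) = \max_k \kappa_{AU}(k, \tau)} over the 12 coded
#' AUs.
#'
#' @inheritParams au_consistency_per_au
#' @return Percentage in \[0, 100\].
#' @export
au_consistency <- function(mu, tau) {
  fi <- match(as.character(tau), dimnames(mu)[[3]])
  crm_assert(!is.na(fi), sprintf("frame %s not in AU label matrix", tau))
  max(colMeans(mu[, , fi, drop = TRUE])) * 100
}

#' Per-frame AU consistency series
#'
#' Computes, for every frame, the per-AU consistency values and the overall
#' consistency (their maximum), plus the arg-max AU id. All values lie on
#' the grid \{0, 100/n, 200/n, ..., 100\} exactly (no rounding is applied).
#'
#' @param mu An `au_label_matrix` from [binarize_au()].
#' @return A `consistency_series` data frame with columns `frame`,
#'   `kappa_au`, `argmax_au`, and attribute `per_au` (12 x T percentage
#'   matrix).
#' @export
au_consistency_series <- function(mu) {
  n <- dim(mu)[1]
  per_au <- apply(mu, c(2, 3), sum) / n * 100      # 12 x T
  kmax <- apply(per_au, 2, max)
  amax <- AU_IDS[apply(per_au, 2, which.max)]
  frames <- as.integer(dimnames(mu)[[3]])
  structure(data.frame(frame = frames, kappa_au = as.numeric(kmax),
                       argmax_au = amax),
            per_au = per_au, n = n,
            class = c("consistency_series", "data.frame"))
}

#' @rdname au_consistency_series
#' @param series A `consistency_series`.
#' @param path Output path for a TSV with columns
#'   `frame`, `kappa_au`, `argmax_au`.
#' @export
write_consistency_series <- function(series, path) {
  df <- data.frame(frame = series$frame,
                   kappa_au = sprintf("%.17g", series$kappa_au),
                   argmax_au = series$argmax_au)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
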