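#' Scrubbing rule
#'
#' Outlier-scan thresholds: timepoints whose global signal deviates from
#' its mean by more than `global_signal_sd_threshold` standard deviations,
#' or whose framewise displacement exceeds `fd_mm_threshold` mm, are
#' censored before correlation.
#'
#' @param global_signal_sd_threshold positive real (default 5).
#' @param fd_mm_threshold positive real, in mm (default 0.9).
#' @return object of class `scrubbing_rule`.
#' @export
scrubbing_rule <- function(global_signal_sd_threshold = 5,
                           fd_mm_threshold = 0.9) {
  if (global_signal_sd_threshold <= 0 || fd_mm_threshold <= 0)
    stopf("scrubbing thresholds must be positive")
  structure(list(global_signal_sd_threshold = global_signal_sd_threshold,
                 fd_mm_threshold = fd_mm_threshold),
            class = "scrubbing_rule")
}

#' Censor outlier timepoints from an ROI time series
#'
#' Removes (does not interpolate) every timepoint flagged by either rule;
#' a timepoint flagged by both rules is removed once.
#'
#' @param timeseries a [roi_timeseries()].
#' @param fd numeric framewise-displacement trace, same length as the
#'   series.
#' @param global_signal numeric global-signal trace, same length.
#' @param rule a [scrubbing_rule()].
#' @return a `roi_timeseries` containing only the surviving timepoints.
#' @export
scrub <- function(timeseries, fd, global_signal, rule = scrubbing_rule()) {
  stopifnot(inherits(timeseries, "roi_timeseries"),
            inherits(rule, "scrubbing_rule"))
  n_t <- nrow(timeseries$data)
  if (length(fd) != n_t || length(global_signal) != n_t)
    stopf("nuisance traces must have one value per timepoint (%d)", n_t)
  gs_dev <- abs(global_signal - mean(global_signal))
  bad <- gs_dev > rule$global_signal_sd_threshold * stats::sd(global_signal) |
    fd > rule$fd_mm_threshold
  if (sum(!bad) < 10)
    stopf("scrubbing leaves %d timepoints (< 10) for subject %s",
          sum(!bad), timeseries$subject_id)
  roi_timeseries(timeseries$subject_id,
                 timeseries$data[!bad, , drop = FALSE],
                 timeseries$roi_labels, timeseries$tr_seconds)
}

#' Pearson ROI-to-ROI connectivity matrix
#'
#' The correlation of each ROI pair's mean-centred BOLD series: the
#' centred cross-product normalized by the product of centred norms.
#' Symmetric with unit diagonal.
#'
#' @param timeseries a [roi_timeseries()].
#' @return object of class `connectivity_matrix` with elements
#'   `subject_id`, `r` (N x N), `z` (`NULL` until [fisher_z()]),
#'   `roi_labels`, `n_timepoints_used`.
#' @export
pearson_matrix <- function(timeseries) {
  stopifnot(inherits(timeseries, "roi_timeseries"))
  x <- timeseries$data
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stopf("zero-variance ROI series: '%s'",
          timeseries$roi_labels[which(sds == 0)[1]])
  r <- stats::cor(x)
  dimnames(r) <- list(timeseries$roi_labels, timeseries$roi_labels)
  structure(list(subject_id = timeseries$subject_id, r = r, z = NULL,
                 roi_labels = timeseries$roi_labels,
                 n_timepoints_used = nrow(x)),
            class = "connectivity_matrix")
}

#' Fisher z-transform a connectivity matrix
#'
#' `z = atanh(r)` off-diagonal; the diagonal is stored as 0 and excluded
#' from all downstream statistics. Off-diagonal entries at the boundary
#' |r| = 1 (possible for duplicated synthetic signals) are clipped to
#' `1 - 1e-7` with a warning naming the pair, so pipelines keep running
#' with an audit trail.
#'
#' @param conn a `connectivity_matrix` from [pearson_matrix()].
#' @return the same object with `z` populated.
#' @export
fisher_z <- function(conn) {
  stopifnot(inherits(conn, "connectivity_matrix"))
  r <- conn$r
  off <- row(r) != col(r)
  hit <- off & abs(r) >= 1
  if (any(hit)) {
    idx <- which(hit, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    warnf("|r| = 1 clipped for pair(s): %s",
          paste(sprintf("%s ~ %s", conn$roi_labels[idx[, 1]],
                        conn$roi_labels[idx[, 2]]), collapse = "; "))
    r[hit] <- sign(r[hit]) * (1 - 1e-7)
  }
  z <- atanh(r)
  diag(z) <- 0
  dimnames(z) <- dimnames(conn$r)
  conn$z <- z
  conn
}

#' Time series to Fisher-z connectivity in one step
#'
#' @param timeseries a [roi_timeseries()].
#' @return a `connectivity_matrix` with both `r` and `z`.
#' @export
connectivity <- function(timeseries) fisher_z(pearson_matrix(timeseries))

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> subject %s: %d ROIs, %d timepoints%s\n",
              x$subject_id, length(x$roi_labels), x$n_timepoints_used,
              if (is.null(x$z)) " (r only)" else " (r + Fisher z)"))
  invisible(x)
}
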