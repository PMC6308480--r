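## Evaluation against reference annotations.
##
## Protocol: per reference fiducial, pair the nearest detection of the same
## label within a matching window; signed error in ms (negative = early).
## Per-record mean and sample SD, then unweighted averaging of per-record
## statistics into the aggregate mu / sigma. Stability is judged against
## the CSE inter-expert tolerances: SD of error <= 6.5 ms for the QRS
## onset and <= 11.6 ms for the offset.

#' CSE tolerances for delineation-error standard deviation (ms)
#' @format Named numeric: `onset` (6.5), `offset` (11.6).
#' @export
cse_tolerances <- c(onset = 6.5, offset = 11.6)

#' Signed per-beat delineation errors
#'
#' @param detected,reference [annotation_set()]s.
#' @param fs sampling frequency in Hz (> 0).
#' @param match_window_ms matching half-window in ms (default 150: larger
#'   than any plausible delineation error, below half the shortest RR).
#' @param labels labels to evaluate.
#' @return Data frame with one row per reference fiducial of the requested
#'   labels: `label`, `ref_index`, `det_index` (NA if unmatched),
#'   `error_ms` (detected minus reference; negative = early).
#' @export
beat_errors <- function(detected, reference, fs, match_window_ms = 150,
                        labels = c("Qon", "Rpeak", "Soff")) {
  stopifnot(inherits(detected, "annotation_set"),
            inherits(reference, "annotation_set"))
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  win_samp <- match_window_ms / 1000 * fs
  rows <- lapply(labels, function(lab) {
    ref <- ann_indices(reference, lab)
    det <- ann_indices(detected, lab)
    if (length(ref) == 0) return(NULL)
    det_i <- vapply(ref, function(r) {
      if (length(det) == 0) return(NA_integer_)
      j <- which.min(abs(det - r))
      if (abs(det[[j]] - r) <= win_samp) as.integer(det[[j]]) else NA_integer_
    }, integer(1))
    data.frame(label = lab, ref_index = as.integer(ref), det_index = det_i,
               error_ms = (det_i - ref) * 1000 / fs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(label = character(), ref_index = integer(),
                      det_index = integer(), error_ms = numeric())
  }
  out
}

#' Intra-record error statistics
#'
#' @param errors numeric vector of signed errors in ms.
#' @return Named numeric `c(mean_ms, sd_ms)`; the SD uses the sample
#'   (n - 1) denominator and is `NA` for fewer than 2 errors.
#' @export
record_stats <- function(errors) {
  errors <- errors[!is.na(errors)]
  c(mean_ms = if (length(errors) > 0) mean(errors) else NA_real_,
    sd_ms = if (length(errors) >= 2) stats::sd(errors) else NA_real_)
}

#' Aggregate per-record statistics
#'
#' The aggregate mean mu and SD sigma are the unweighted means of the
#' per-record means and SDs (records with many beats do not dominate).
#'
#' @param per_record data frame or matrix with columns/fields `mean_ms`
#'   and `sd_ms`, one row per record.
#' @return Named numeric `c(mu_ms, sigma_ms)`.
#' @export
aggregate_stats <- function(per_record) {
  per_record <- as.data.frame(per_record)
  if (nrow(per_record) == 0) stop("no per-record statistics to aggregate")
  c(mu_ms = mean(per_record$mean_ms, na.rm = TRUE),
    sigma_ms = mean(per_record$sd_ms, na.rm = TRUE))
}

#' Per-record channel selection
#'
#' Reference annotators mark one annotation stream per record while the
#' delineator runs per channel; per record, the channel with the smaller
#' error-magnitude criterion `|mean| + sd` is kept.
#'
#' @param stats_ch1,stats_ch2 data frames with columns `record`, `mean_ms`,
#'   `sd_ms` (one row per record).
#' @return Data frame `record`, `channel` (1 or 2), `mean_ms`, `sd_ms`,
#'   `flagged` (TRUE when the record was present in one channel only).
#'   Ties resolve to channel 1.
#' @export
best_channel <- function(stats_ch1, stats_ch2) {
  recs <- union(stats_ch1$record, stats_ch2$record)
  rows <- lapply(recs, function(r) {
    s1 <- stats_ch1[stats_ch1$record == r, , drop = FALSE]
    s2 <- stats_ch2[stats_ch2$record == r, , drop = FALSE]
    if (nrow(s1) == 0 || nrow(s2) == 0) {
      s <- if (nrow(s1) > 0) s1 else s2
      return(data.frame(record = r, channel = if (nrow(s1) > 0) 1L else 2L,
                        mean_ms = s$mean_ms, sd_ms = s$sd_ms, flagged = TRUE))
    }
    c1 <- abs(s1$mean_ms) + s1$sd_ms
    c2 <- abs(s2$mean_ms) + s2$sd_ms
    pick <- if (c2 < c1) 2L else 1L
    s <- if (pick == 1L) s1 else s2
    data.frame(record = r, channel = pick, mean_ms = s$mean_ms,
               sd_ms = s$sd_ms, flagged = FALSE)
  })
  do.call(rbind, rows)
}

#' QR and RS section statistics
#'
#' Mean and SD of the QR section (onset to R-peak) and RS section (R-peak
#' to offset) lengths in ms, grouped by beat label (e.g. normal vs PVC).
#'
#' @param fiducials data frame as returned in
#'   `delineate_record()$fiducials`.
#' @param fs sampling frequency in Hz.
#' @param beat_labels optional character vector, one label per beat row;
#'   defaults to a single group `"all"`.
#' @param min_count groups with fewer complete beats are dropped
#'   (default 2; raise to e.g. 30 to emulate sparse-arrhythmia filtering).
#' @return Data frame `label`, `n`, `qr_mean_ms`, `qr_sd_ms`, `rs_mean_ms`,
#'   `rs_sd_ms`.
#' @export
section_stats <- function(fiducials, fs, beat_labels = NULL, min_count = 2) {
  if (is.null(beat_labels)) beat_labels <- rep("all", nrow(fiducials))
  stopifnot(length(beat_labels) == nrow(fiducials))
  qr <- (fiducials$r - fiducials$q_on) * 1000 / fs
  rs <- (fiducials$s_off - fiducials$r) * 1000 / fs
  rows <- lapply(unique(beat_labels), function(lab) {
    sel <- beat_labels == lab & !is.na(qr) & !is.na(rs)
    if (sum(sel) < min_count) return(NULL)
    data.frame(label = lab, n = sum(sel),
               qr_mean_ms = mean(qr[sel]), qr_sd_ms = stats::sd(qr[sel]),
               rs_mean_ms = mean(rs[sel]), rs_sd_ms = stats::sd(rs[sel]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(label = character(), n = integer(),
                      qr_mean_ms = numeric(), qr_sd_ms = numeric(),
                      rs_mean_ms = numeric(), rs_sd_ms = numeric())
  }
  out
}

#' Check aggregate stability against the CSE tolerances
#'
#' @param sigma_onset_ms,sigma_offset_ms aggregate error SDs in ms.
#' @return Named logical `c(onset, offset)`: `TRUE` when the SD is at or
#'   below the tolerance (boundary inclusive).
#' @export
check_tolerance <- function(sigma_onset_ms, sigma_offset_ms) {
  c(onset = sigma_onset_ms <= cse_tolerances[["onset"]],
    offset = sigma_offset_ms <= cse_tolerances[["offset"]])
}
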