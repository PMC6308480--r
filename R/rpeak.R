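## R-peak detection (Pan-Tompkins) and R-R segmentation.
##
## The detector runs the classic chain — band-pass 5-15 Hz, five-point
## derivative, squaring, 150 ms moving-window integration, dual adaptive
## thresholds with search-back — on a detection-only signal. Delineation
## itself always operates on the 1-25 Hz preprocessed signal; detections are
## therefore refined to the extremum of the absolute 1-25 Hz-filtered
## amplitude within +/-50 ms (inside the normal QRS half-width), which also
## makes the returned index polarity-robust (downward QRS complexes are
## found at the same sample as their upright twins).

#' Detect R-peaks
#'
#' @param record an [ecg_record()].
#' @param channel channel index or name (default 1).
#' @param refine_ms half-width of the polarity-robust refinement window in
#'   ms (default 50).
#' @return Integer vector of strictly increasing 1-based R-peak sample
#'   indices; empty for a zero-variance signal.
#' @examples
#' sim <- generate_record(beat_spec(), n_beats = 8, rr_s = 0.8, fs = 250)
#' detect_rpeaks(sim$record)
#' @export
detect_rpeaks <- function(record, channel = 1L, refine_ms = 50) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  x <- channel(record, channel)
  n <- length(x)
  if (n < 2 * fs) stop("record must be at least 2 s long for adaptive thresholds")
  if (stats::sd(x) == 0) return(integer(0))

  ## detection-stage signal chain
  bp <- bandpass_filter_vec(x, fs, low_hz = 5, high_hz = 15, order = 2)
  d <- c(0, 0, (-bp[1:(n - 4)] - 2 * bp[2:(n - 3)] +
                  2 * bp[4:(n - 1)] + bp[5:n]) / 8, 0, 0)
  sq <- d^2
  win <- max(1L, as.integer(round(0.150 * fs)))
  # centered moving-window integral: zero group delay by construction
  mwi <- stats::filter(sq, rep(1 / win, win), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  ## candidate peaks of the integrated signal
  pk <- which(diff(sign(diff(mwi))) < 0) + 1L
  if (length(pk) == 0) return(integer(0))

  refractory <- as.integer(round(0.200 * fs))
  learn <- seq_len(min(n, as.integer(2 * fs)))
  spki <- max(mwi[learn]) / 3
  npki <- mean(mwi[learn]) / 2
  thr1 <- function() npki + 0.25 * (spki - npki)

  sig_pk <- integer(0)
  rr_avg <- NA_real_
  last <- -Inf
  noise_between <- integer(0)
  for (p in pk) {
    if (mwi[p] > thr1() && (p - last) > refractory) {
      ## search-back: a long gap suggests a missed beat among "noise" peaks
      if (!is.na(rr_avg) && (p - last) > 1.66 * rr_avg &&
          length(noise_between) > 0) {
        cand <- noise_between[mwi[noise_between] > 0.5 * thr1() &
                                noise_between - last > refractory &
                                p - noise_between > refractory]
        if (length(cand) > 0) {
          sb <- cand[which.max(mwi[cand])]
          sig_pk <- c(sig_pk, sb)
          spki <- 0.25 * mwi[sb] + 0.75 * spki
          last <- sb
        }
      }
      sig_pk <- c(sig_pk, p)
      spki <- 0.125 * mwi[p] + 0.875 * spki
      if (length(sig_pk) >= 2) {
        rrs <- diff(utils::tail(sig_pk, 9))
        rr_avg <- mean(rrs)
      }
      last <- p
      noise_between <- integer(0)
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
      noise_between <- c(noise_between, p)
    }
  }
  if (length(sig_pk) == 0) return(integer(0))

  ## the integrated signal can plateau over a symmetric QRS, leaving the
  ## detected peak at the plateau edge: snap to the squared-derivative
  ## maximum (the steepest QRS limb) before amplitude refinement
  sig_pk <- vapply(sig_pk, function(p) {
    lo <- max(1L, p - win)
    hi <- min(n, p + win)
    lo + which.max(sq[lo:hi]) - 1L
  }, integer(1))

  ## refine on the delineation-stage signal (polarity-robust)
  del <- abs(bandpass_filter_vec(x, fs, low_hz = 1, high_hz = 25, order = 2))
  half <- as.integer(round(refine_ms / 1000 * fs))
  refined <- vapply(sig_pk, function(p) {
    lo <- max(1L, p - half)
    hi <- min(n, p + half)
    lo + which.max(del[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory period after refinement
  keep <- c(TRUE, diff(refined) >= refractory)
  while (!all(keep)) {
    refined <- refined[keep]
    keep <- c(TRUE, diff(refined) >= refractory)
  }
  as.integer(refined)
}

#' Split a record into R-R beat segments
#'
#' @param record an [ecg_record()].
#' @param rpeaks strictly increasing R-peak sample indices.
#' @param channel channel index or name.
#' @return List of `beat_segment` objects, one per consecutive R-peak pair;
#'   segment `i` ends on the sample where segment `i + 1` starts (the shared
#'   R-peak). Fewer than two peaks give an empty list.
#' @export
segment_rr <- function(record, rpeaks, channel = 1L) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(rpeaks) < 2) return(list())
  if (any(diff(rpeaks) <= 0)) stop("`rpeaks` must be strictly increasing")
  if (rpeaks[[1]] < 1 || rpeaks[[length(rpeaks)]] > n_samples(record)) {
    stop("R-peak index outside the record")
  }
  x <- channel(record, channel)
  lapply(seq_len(length(rpeaks) - 1L), function(i) {
    a <- rpeaks[[i]]; b <- rpeaks[[i + 1]]
    beat_segment(start_index = a, end_index = b, samples = x[a:b],
                 fs = record$fs)
  })
}

#' Construct a beat segment
#'
#' One R-R section: the samples between two consecutive R-peaks, inclusive.
#'
#' @param start_index,end_index 1-based record coordinates of the bounding
#'   R-peaks.
#' @param samples amplitudes over `[start_index, end_index]`.
#' @param fs sampling frequency (Hz).
#' @return A `beat_segment` list.
#' @export
beat_segment <- function(start_index, end_index, samples, fs) {
  if (end_index <= start_index) stop("end_index must exceed start_index")
  if (length(samples) != end_index - start_index + 1) {
    stop("samples length must equal end_index - start_index + 1")
  }
  structure(list(start_index = as.integer(start_index),
                 end_index = as.integer(end_index),
                 samples = as.numeric(samples), fs = fs),
            class = "beat_segment")
}
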