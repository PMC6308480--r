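## Fiducial-point detection on the cumulative vertex signal.
##
## Each interior vertex of a segment's cumulative signal is scored with
## three feature families and the QRS onset / offset is the argmax:
##
##   onset : wA(A_R) + wT(T_R) + wC(theta_L) + wS(theta_R)
##   offset: wA(A_L) + wT(T_L) + wS(theta_L) + wC(theta_R)
##
## A_L / A_R are cumulative-amplitude distances from the bounding R-peaks,
## T_L / T_R time distances from a reference 0.3 s away from the R-peak,
## theta_L / theta_R the chord angles to the neighbor vertices. wA
## normalizes by the maximum over the search window, wT by 0.3*fs, and the
## angle weights are (cos theta)^0.5 (tolerant of noisy baselines) and
## (sin theta)^2 (selective for the steep waveform side). The onset is
## searched within 0.3 s before the next R-peak, the offset within 0.3 s
## after the previous one, so every weight term lies in [0, 1].

#' Feature weights for fiducial scoring
#'
#' @param window_s reference/search offset from the R-peak in seconds
#'   (default 0.3; the normal QRS width is about 0.08-0.12 s, so 0.3 s
#'   bounds any plausible onset/offset while excluding most of the P wave).
#' @param cos_exponent exponent on `cos(theta)` for the baseline-direction
#'   weight (default 0.5; the square root keeps the weight high even when
#'   noise tilts the baseline chord by 30-40 degrees).
#' @param sin_exponent exponent on `sin(theta)` for the waveform-direction
#'   weight (default 2; the square suppresses non-fiducial vertices).
#' @param angle_y_frac fraction of the segment's total cumulative range
#'   used as the angle y-axis reference (default 0.1). With the x-axis
#'   reference at `window_s * fs`, a deflection of 10% of the total
#'   amplitude change spread over the whole window maps to 45 degrees, so
#'   genuine QRS limbs (large amplitude over few samples) map near 90
#'   degrees and baseline chords near 0 — including shallow Q/S
#'   deflections, whose steepness is what separates the true onset/offset
#'   from the adjacent Q/S trough vertex.
#' @return A `feature_weights` list.
#' @export
feature_weights <- function(window_s = 0.3, cos_exponent = 0.5,
                            sin_exponent = 2, angle_y_frac = 0.1) {
  stopifnot(window_s > 0, cos_exponent > 0, sin_exponent > 0,
            angle_y_frac > 0)
  structure(list(window_s = window_s, cos_exponent = cos_exponent,
                 sin_exponent = sin_exponent, angle_y_frac = angle_y_frac),
            class = "feature_weights")
}

#' Cumulative-amplitude features of a vertex
#'
#' @param cum a `cumulative_vertex_set` (see [cumulative_signal()]).
#' @param i vertex index (1-based row).
#' @return Named numeric `c(AL, AR)`: cumulative-amplitude distance from
#'   the first and last vertex; both non-negative, summing to the total
#'   cumulative range.
#' @export
amplitude_features <- function(cum, i) {
  check_cum_index(cum, i)
  c(AL = cum$vyDp[[i]] - cum$vyDp[[1]],
    AR = cum$vyDp[[nrow(cum)]] - cum$vyDp[[i]])
}

#' Time features of a vertex
#'
#' @inheritParams amplitude_features
#' @param fs sampling frequency in Hz.
#' @param window_s reference offset in seconds (default 0.3).
#' @return Named numeric `c(TL, TR)` in samples: distance from the
#'   reference points `window_s` after the previous R-peak and before the
#'   next one; may be negative outside the window.
#' @export
time_features <- function(cum, i, fs, window_s = 0.3) {
  check_cum_index(cum, i)
  n <- nrow(cum)
  c(TL = (cum$vx[[1]] + window_s * fs) - cum$vx[[i]],
    TR = cum$vx[[i]] - (cum$vx[[n]] - window_s * fs))
}

#' Chord angles of a vertex to its neighbors
#'
#' Angles between the horizontal and the chords to the left/right neighbor
#' vertices, computed after rescaling x by `x_scale` and y by `y_scale`
#' (the angle of a sampled chord is meaningless without an aspect ratio).
#'
#' @inheritParams amplitude_features
#' @param x_scale x-axis scale in samples (the pipeline uses
#'   `window_s * fs`).
#' @param y_scale y-axis scale in cumulative-amplitude units (the pipeline
#'   uses the segment's total cumulative range).
#' @return Named numeric `c(thetaL, thetaR)` in radians, each in
#'   `[0, pi/2]`.
#' @export
vertex_angles <- function(cum, i, x_scale, y_scale) {
  check_cum_index(cum, i)
  if (i == 1L || i == nrow(cum)) {
    stop("angles are undefined at boundary vertices (they are R-peaks)")
  }
  stopifnot(x_scale > 0, y_scale > 0)
  ang <- function(j) {
    dx <- abs(cum$vx[[j]] - cum$vx[[i]]) / x_scale
    dy <- abs(cum$vyDp[[j]] - cum$vyDp[[i]]) / y_scale
    atan2(dy, dx)
  }
  c(thetaL = ang(i - 1L), thetaR = ang(i + 1L))
}

check_cum_index <- function(cum, i) {
  stopifnot(inherits(cum, "cumulative_vertex_set"))
  if (i < 1L || i > nrow(cum)) stop("vertex index out of range")
}

# Score every candidate vertex for one side. Returns a data frame with one
# row per candidate (empty if the search set is empty).
score_vertices <- function(cum, fs, w = feature_weights(),
                           side = c("onset", "offset")) {
  side <- match.arg(side)
  n <- nrow(cum)
  win <- w$window_s * fs
  if (n < 3) return(score_frame())
  idx <- 2:(n - 1L)
  vx <- cum$vx[idx]
  in_set <- if (side == "onset") {
    vx >= cum$vx[[n]] - win & vx < cum$vx[[n]]
  } else {
    vx > cum$vx[[1]] & vx <= cum$vx[[1]] + win
  }
  idx <- idx[in_set]
  if (length(idx) == 0) return(score_frame())
  y_scale <- w$angle_y_frac * (cum$vyDp[[n]] - cum$vyDp[[1]])
  A <- vapply(idx, function(i) {
    a <- amplitude_features(cum, i)
    if (side == "onset") a[["AR"]] else a[["AL"]]
  }, numeric(1))
  Tm <- vapply(idx, function(i) {
    tf <- time_features(cum, i, fs, w$window_s)
    if (side == "onset") tf[["TR"]] else tf[["TL"]]
  }, numeric(1))
  th <- t(vapply(idx, function(i) {
    if (y_scale > 0) vertex_angles(cum, i, x_scale = win, y_scale = y_scale)
    else c(thetaL = 0, thetaR = 0)
  }, numeric(2)))
  wA <- if (max(A) > 0) A / max(A) else rep(0, length(A))
  wT <- Tm / win
  if (side == "onset") {
    wC <- cos(th[, "thetaL"])^w$cos_exponent
    wS <- sin(th[, "thetaR"])^w$sin_exponent
  } else {
    wS <- sin(th[, "thetaL"])^w$sin_exponent
    wC <- cos(th[, "thetaR"])^w$cos_exponent
  }
  data.frame(i = idx, vx = cum$vx[idx], wA = wA, wT = wT, wC = wC, wS = wS,
             score = wA + wT + wC + wS)
}

score_frame <- function() {
  data.frame(i = integer(), vx = integer(), wA = numeric(), wT = numeric(),
             wC = numeric(), wS = numeric(), score = numeric())
}

#' Detect the QRS onset on a cumulative vertex signal
#'
#' Scores the interior vertices lying within `window_s` before the
#' segment-ending R-peak and returns the argmax. Ties break toward the
#' vertex closest to the R-peak (the conservative, shorter-QRS choice).
#'
#' @param cum a `cumulative_vertex_set` for one R-R segment.
#' @param fs sampling frequency in Hz.
#' @param w a [feature_weights()].
#' @return Row index of the selected vertex in `cum`, or `NA_integer_` if
#'   the search set is empty (detection failure for the beat; reported,
#'   not fatal). The score table is attached as attribute `"scores"`.
#' @export
detect_onset <- function(cum, fs, w = feature_weights()) {
  pick_argmax(score_vertices(cum, fs, w, "onset"), prefer = "last")
}

#' Detect the QRS offset on a cumulative vertex signal
#'
#' Mirror of [detect_onset()]: searches within `window_s` after the
#' segment-starting R-peak, with the left/right feature roles swapped.
#'
#' @inheritParams detect_onset
#' @return Row index of the selected vertex in `cum`, or `NA_integer_`.
#' @export
detect_offset <- function(cum, fs, w = feature_weights()) {
  pick_argmax(score_vertices(cum, fs, w, "offset"), prefer = "first")
}

pick_argmax <- function(sc, prefer) {
  if (nrow(sc) == 0) {
    out <- NA_integer_
    attr(out, "scores") <- sc
    return(out)
  }
  best <- which(sc$score == max(sc$score))
  pick <- if (prefer == "last") best[[length(best)]] else best[[1]]
  out <- sc$i[[pick]]
  attr(out, "scores") <- sc
  out
}

#' Delineate the QRS onsets and offsets of a record
#'
#' Full pipeline: optional 1-25 Hz zero-phase band-pass, R-peak detection
#' (or externally supplied peaks), R-R segmentation, polygonal
#' approximation, cumulative signal, and per-segment onset/offset scoring.
#' For each beat, the offset comes from the segment starting at its R-peak
#' and the onset from the segment ending at it; the first beat therefore
#' has no onset and the last no offset (flagged via `complete`).
#'
#' @param record an [ecg_record()].
#' @param channel channel index or name.
#' @param config a [pq_config()].
#' @param rpeaks optional externally supplied R-peak sample indices
#'   (bypasses the Pan-Tompkins detector).
#' @param diagnostics logical; keep per-segment score tables.
#' @return List with:
#'   * `fiducials`: data frame (`beat`, `r`, `q_on`, `s_off`, `complete`)
#'     of 1-based record sample indices (`NA` where undefined),
#'   * `annotations`: an [annotation_set()] of all detected points,
#'   * `rpeaks`: the R-peak indices used,
#'   * `scores`: list of per-segment score tables when `diagnostics = TRUE`.
#' @examples
#' sim <- generate_record(beat_spec(), n_beats = 6, rr_s = 0.8, fs = 250)
#' del <- delineate_record(sim$record)
#' head(del$fiducials)
#' @export
delineate_record <- function(record, channel = 1L, config = pq_config(),
                             rpeaks = NULL, diagnostics = FALSE) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  work <- if (isTRUE(config$filter)) {
    bandpass_filter(record, config$bp_low, config$bp_high, config$bp_order)
  } else {
    record
  }
  if (is.null(rpeaks)) rpeaks <- detect_rpeaks(work, channel)
  if (length(rpeaks) == 0) {
    warning("no R-peaks detected; empty delineation")
    return(list(fiducials = data.frame(beat = integer(), r = integer(),
                                       q_on = integer(), s_off = integer(),
                                       complete = logical()),
                annotations = annotation_set(), rpeaks = integer(0),
                scores = NULL))
  }
  segs <- segment_rr(work, rpeaks, channel)
  support_k <- max(1L, as.integer(round(config$support_ms / 1000 * fs)))
  w <- feature_weights(config$window_s, config$cos_exponent,
                       config$sin_exponent, config$angle_y_frac)
  nb <- length(rpeaks)
  q_on <- rep(NA_integer_, nb)
  s_off <- rep(NA_integer_, nb)
  scores <- if (diagnostics) vector("list", length(segs)) else NULL
  for (si in seq_along(segs)) {
    seg <- segs[[si]]
    verts <- approximate(seg, support_k = support_k,
                         curv_threshold = config$curv_threshold,
                         tolerance = config$tolerance)
    cum <- cumulative_signal(verts)
    on_i <- detect_onset(cum, fs, w)
    off_i <- detect_offset(cum, fs, w)
    if (!is.na(off_i)) s_off[si] <- seg$start_index + cum$vx[[off_i]] - 1L
    if (!is.na(on_i)) q_on[si + 1L] <- seg$start_index + cum$vx[[on_i]] - 1L
    if (diagnostics) {
      scores[[si]] <- list(onset = attr(on_i, "scores"),
                           offset = attr(off_i, "scores"))
    }
  }
  fid <- data.frame(beat = seq_len(nb), r = as.integer(rpeaks),
                    q_on = q_on, s_off = s_off,
                    complete = !is.na(q_on) & !is.na(s_off))
  ann <- annotation_set(
    sample_index = c(rpeaks, q_on[!is.na(q_on)], s_off[!is.na(s_off)]),
    label = c(rep("Rpeak", nb), rep("Qon", sum(!is.na(q_on))),
              rep("Soff", sum(!is.na(s_off)))))
  list(fiducials = fid, annotations = ann, rpeaks = as.integer(rpeaks),
       scores = scores)
}
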