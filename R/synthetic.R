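## Synthetic ECG with exact fiducial ground truth.
##
## Beats are sums of Gaussian deflections (P, Q, R, S, T). A Gaussian-sum
## model is used instead of a dynamical-system simulator because it gives
## closed-form, exact ground-truth onsets/offsets: the true QRS onset is
## defined as 3 sigma before the center of the earliest included QRS
## component, and the true offset as 3 sigma after the latest one (99.7% of
## the deflection energy lies inside, matching the visual boundary between
## waveform and baseline regions). Wave centers are snapped to the sample
## grid so truth indices are exact integers and independent of noise.

#' Specify a synthetic beat morphology
#'
#' @param waves named list of Gaussian parameters, one entry per wave
#'   (`P`, `Q`, `R`, `S`, `T`), each `c(center, sigma, amp)`: center offset
#'   from the R peak in seconds, width sigma in seconds, signed amplitude
#'   in mV. Defaults give a normal upright beat with a 104 ms QRS at 250 Hz.
#' @param include_q,include_s logical; drop the Q or S deflection to emulate
#'   the corresponding morphology classes.
#' @param polarity `"upright"` or `"inverted"` (negates the whole beat;
#'   emulates a downward QRS complex).
#' @param widened factor >= 1 scaling QRS centers and widths (PVC-like
#'   widening).
#' @param notch_amp,notch_center,notch_sigma optional extra mid-QRS Gaussian
#'   (amplitude mV, center s, sigma s) emulating a notched wide QRS; scaled
#'   by `widened` like the other QRS components. The default center/width
#'   place the notch on the terminal limb between the S trough and the QRS
#'   offset, where ventricular beats typically slur; a steep limb would
#'   otherwise swallow a small bump. Does not move ground truth (keep its
#'   support inside the boundary components' 3 sigma span).
#' @return A `beat_spec` list.
#' @export
beat_spec <- function(waves = list(P = c(-0.220, 0.025, 0.15),
                                   Q = c(-0.028, 0.008, -0.12),
                                   R = c(0.000, 0.010, 1.00),
                                   S = c(0.028, 0.008, -0.20),
                                   T = c(0.300, 0.050, 0.35)),
                      include_q = TRUE, include_s = TRUE,
                      polarity = c("upright", "inverted"),
                      widened = 1,
                      notch_amp = 0, notch_center = 0.036, notch_sigma = 0.005) {
  polarity <- match.arg(polarity)
  stopifnot(is.list(waves), all(c("P", "Q", "R", "S", "T") %in% names(waves)))
  for (w in waves) {
    if (length(w) != 3 || w[[2]] <= 0) stop("each wave needs c(center, sigma>0, amp)")
  }
  if (widened < 1) stop("`widened` must be >= 1")
  qrs_amps <- abs(c(if (include_q) waves$Q[[3]], waves$R[[3]],
                    if (include_s) waves$S[[3]]))
  if (abs(waves$R[[3]]) < max(qrs_amps) || sum(qrs_amps == max(qrs_amps)) > 1) {
    stop("R amplitude magnitude must be strictly largest among QRS components")
  }
  structure(list(waves = waves, include_q = include_q, include_s = include_s,
                 polarity = polarity, widened = widened,
                 notch_amp = notch_amp, notch_center = notch_center,
                 notch_sigma = notch_sigma),
            class = "beat_spec")
}

#' Preset beat morphologies
#'
#' Shorthand for the morphology classes used in testing: `"normal"`,
#' `"no-q"` (Q absent), `"no-s"` (S absent), `"inverted"` (downward QRS),
#' `"pvc"` (widened, high-amplitude, P absent).
#'
#' @param class morphology class name.
#' @param ... overrides passed to [beat_spec()].
#' @return A `beat_spec`.
#' @export
beat_morphology <- function(class = c("normal", "no-q", "no-s", "inverted",
                                      "pvc"), ...) {
  class <- match.arg(class)
  switch(class,
    "normal"   = beat_spec(...),
    "no-q"     = beat_spec(include_q = FALSE, ...),
    "no-s"     = beat_spec(include_s = FALSE, ...),
    "inverted" = beat_spec(polarity = "inverted", ...),
    "pvc"      = {
      waves <- list(P = c(-0.220, 0.025, 0.00),   # PVCs lack a preceding P
                    Q = c(-0.028, 0.008, -0.12),
                    R = c(0.000, 0.010, 1.10),
                    S = c(0.028, 0.008, -0.30),
                    T = c(0.300, 0.050, 0.35))
      beat_spec(waves = waves, widened = 2, ...)
    })
}

# Per-beat component table in snapped sample units.
# Returns data.frame(center_samp, sigma_samp, amp, qrs) for included waves.
beat_components <- function(spec, fs) {
  w <- spec$widened
  rows <- list()
  for (nm in c("P", "Q", "R", "S", "T")) {
    if (nm == "Q" && !spec$include_q) next
    if (nm == "S" && !spec$include_s) next
    p <- spec$waves[[nm]]
    if (p[[3]] == 0) next
    qrs <- nm %in% c("Q", "R", "S")
    scale <- if (qrs) w else 1
    rows[[nm]] <- data.frame(
      wave = nm,
      center_samp = round(scale * p[[1]] * fs),
      sigma_samp = scale * p[[2]] * fs,
      amp = p[[3]], qrs = qrs, stringsAsFactors = FALSE)
  }
  if (spec$notch_amp != 0) {
    rows[["notch"]] <- data.frame(
      wave = "notch",
      center_samp = round(w * spec$notch_center * fs),
      sigma_samp = w * spec$notch_sigma * fs,
      amp = spec$notch_amp, qrs = FALSE, stringsAsFactors = FALSE)
  }
  comp <- do.call(rbind, rows)
  if (spec$polarity == "inverted") comp$amp <- -comp$amp
  comp
}

# Ground-truth fiducials in samples relative to the R center sample.
beat_truth <- function(spec, fs) {
  w <- spec$widened
  qrs <- list(R = spec$waves$R)
  if (spec$include_q) qrs$Q <- spec$waves$Q
  if (spec$include_s) qrs$S <- spec$waves$S
  centers <- vapply(qrs, function(p) round(w * p[[1]] * fs), numeric(1))
  halfw <- vapply(qrs, function(p) round(3 * w * p[[2]] * fs), numeric(1))
  first <- names(which.min(centers))
  last <- names(which.max(centers))
  list(q_on = unname(centers[first] - halfw[first]),
       r_peak = unname(round(w * spec$waves$R[[1]] * fs)),
       s_off = unname(centers[last] + halfw[last]))
}

#' Generate one synthetic beat
#'
#' @param spec a [beat_spec()].
#' @param fs sampling frequency in Hz (>= 100).
#' @return List with `samples` (numeric vector covering the beat support),
#'   `r_index` (1-based index of the R center within `samples`), and `truth`:
#'   1-based indices of `q_on`, `r_peak`, `s_off` within `samples`.
#' @examples
#' b <- generate_beat(beat_spec(), fs = 250)
#' b$truth$s_off - b$truth$q_on    # QRS duration in samples
#' @export
generate_beat <- function(spec, fs) {
  stopifnot(inherits(spec, "beat_spec"))
  if (fs < 100) stop("fs must be >= 100 Hz")
  comp <- beat_components(spec, fs)
  lo <- floor(min(comp$center_samp - 4 * comp$sigma_samp))
  hi <- ceiling(max(comp$center_samp + 4 * comp$sigma_samp))
  n_grid <- lo:hi
  samples <- numeric(length(n_grid))
  for (k in seq_len(nrow(comp))) {
    samples <- samples + comp$amp[[k]] *
      exp(-(n_grid - comp$center_samp[[k]])^2 / (2 * comp$sigma_samp[[k]]^2))
  }
  tr <- beat_truth(spec, fs)
  off <- 1L - lo  # map sample-offset coordinates to 1-based vector indices
  list(samples = samples, r_index = tr$r_peak + off,
       truth = list(q_on = tr$q_on + off, r_peak = tr$r_peak + off,
                    s_off = tr$s_off + off))
}

#' Specify additive noise
#'
#' The noise model follows the standard ECG noise taxonomy: baseline wander
#' (low-frequency respiratory drift, 0.15-0.3 Hz), powerline interference
#' (50/60 Hz mains) and broadband white noise.
#'
#' @param baseline_freq baseline wander frequency in Hz (default 0.25).
#' @param baseline_amp baseline wander amplitude in mV (default 0).
#' @param powerline_freq mains frequency, 50 or 60 Hz (default 60).
#' @param powerline_amp mains amplitude in mV (default 0).
#' @param white_sd white-noise standard deviation in mV (default 0).
#' @param seed integer RNG seed for phases and white noise.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(baseline_freq = 0.25, baseline_amp = 0,
                       powerline_freq = 60, powerline_amp = 0,
                       white_sd = 0, seed = 1L) {
  stopifnot(baseline_amp >= 0, powerline_amp >= 0, white_sd >= 0,
            baseline_freq > 0, powerline_freq > 0)
  structure(list(baseline_freq = baseline_freq, baseline_amp = baseline_amp,
                 powerline_freq = powerline_freq, powerline_amp = powerline_amp,
                 white_sd = white_sd, seed = as.integer(seed)),
            class = "noise_spec")
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Add synthetic noise to a sample vector
#'
#' @param samples numeric vector.
#' @param fs sampling frequency in Hz.
#' @param noise a [noise_spec()]. Sinusoid phases and white noise are drawn
#'   from the spec's seed, so identical specs give identical noise.
#' @return Noisy samples, same length.
#' @export
add_noise <- function(samples, fs, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$baseline_amp == 0 && noise$powerline_amp == 0 &&
      noise$white_sd == 0) {
    return(samples)
  }
  n <- length(samples)
  t <- (seq_len(n) - 1) / fs
  with_seed(noise$seed, {
    ph <- stats::runif(2, 0, 2 * pi)
    out <- samples
    if (noise$baseline_amp > 0) {
      out <- out + noise$baseline_amp * sin(2 * pi * noise$baseline_freq * t + ph[[1]])
    }
    if (noise$powerline_amp > 0) {
      out <- out + noise$powerline_amp * sin(2 * pi * noise$powerline_freq * t + ph[[2]])
    }
    if (noise$white_sd > 0) {
      out <- out + stats::rnorm(n, 0, noise$white_sd)
    }
    out
  })
}

#' Generate a synthetic ECG record with ground-truth annotations
#'
#' Beats are placed at cumulative R positions separated by `rr_s`; every
#' Gaussian component is evaluated over the whole record, so the clean
#' record is exactly the sum-of-Gaussians model. Noise never moves the
#' ground-truth annotations.
#'
#' @param specs list of [beat_spec()] (one per beat), or a single spec to
#'   replicate.
#' @param n_beats number of beats when `specs` is a single spec.
#' @param rr_s R-R intervals in seconds: scalar (replicated) or vector of
#'   length `n_beats - 1`.
#' @param fs sampling frequency in Hz.
#' @param noise a [noise_spec()] (default: clean).
#' @param pad_s flat margin before the first and after the last R (s).
#' @return List with `record` (single-channel [ecg_record()]), `truth`
#'   (an [annotation_set()] of Qon/Rpeak/Soff for every beat) and
#'   `r_positions` (1-based R sample indices).
#' @examples
#' sim <- generate_record(beat_spec(), n_beats = 5, rr_s = 0.8, fs = 250)
#' sim$truth
#' @export
generate_record <- function(specs, n_beats = NULL, rr_s = 0.8, fs = 250,
                            noise = noise_spec(), pad_s = 0.6) {
  if (inherits(specs, "beat_spec")) {
    if (is.null(n_beats)) stop("`n_beats` required when `specs` is a single spec")
    specs <- rep(list(specs), n_beats)
  }
  nb <- length(specs)
  if (nb < 1) stop("at least one beat required")
  if (length(rr_s) == 1) rr_s <- rep(rr_s, max(nb - 1, 0))
  if (length(rr_s) != nb - 1) stop("need one R-R interval per consecutive beat pair")
  comps <- lapply(specs, beat_components, fs = fs)
  sup_left <- vapply(comps, function(cc)
    max(-(cc$center_samp - 3 * cc$sigma_samp)) / fs, numeric(1))
  sup_right <- vapply(comps, function(cc)
    max(cc$center_samp + 3 * cc$sigma_samp) / fs, numeric(1))
  if (nb > 1 && any(rr_s <= sup_right[-nb] + sup_left[-1])) {
    stop("overlapping beats: R-R intervals shorter than adjacent beat supports")
  }
  r_pos <- as.integer(round(pad_s * fs)) + 1L +
    c(0L, as.integer(cumsum(round(rr_s * fs))))
  n <- r_pos[[nb]] + as.integer(round(pad_s * fs))
  x <- numeric(n)
  grid <- seq_len(n)
  for (b in seq_len(nb)) {
    cc <- comps[[b]]
    lo <- max(1L, r_pos[[b]] + as.integer(floor(min(cc$center_samp - 9 * cc$sigma_samp))))
    hi <- min(n, r_pos[[b]] + as.integer(ceiling(max(cc$center_samp + 9 * cc$sigma_samp))))
    idx <- lo:hi
    for (k in seq_len(nrow(cc))) {
      x[idx] <- x[idx] + cc$amp[[k]] *
        exp(-(idx - r_pos[[b]] - cc$center_samp[[k]])^2 / (2 * cc$sigma_samp[[k]]^2))
    }
  }
  x <- add_noise(x, fs, noise)
  truths <- lapply(specs, beat_truth, fs = fs)
  ann <- annotation_set(
    sample_index = unlist(lapply(seq_len(nb), function(b) {
      r_pos[[b]] + c(truths[[b]]$q_on, truths[[b]]$r_peak, truths[[b]]$s_off)
    })),
    label = rep(c("Qon", "Rpeak", "Soff"), nb))
  list(record = ecg_record(x, fs = fs, channel_names = "synth", units = "mV"),
       truth = ann, r_positions = r_pos)
}
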