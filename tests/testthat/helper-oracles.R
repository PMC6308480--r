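# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own vectorized code paths.

# Normalized coordinates of a sample vector (time to [0,1], amplitude to [0,1]).
oracle_norm <- function(y) {
  n <- length(y)
  x <- (seq_len(n) - 1) / (n - 1)
  r <- range(y)
  yy <- if (diff(r) > 0) (y - r[1]) / diff(r) else rep(0.5, n)
  list(x = x, y = yy)
}

# Per-sample k-cosine curvature by direct angle computation.
oracle_curvature <- function(y, k) {
  nc <- oracle_norm(y)
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (i <= k || i > n - k) next
    a <- c(nc$x[i - k] - nc$x[i], nc$y[i - k] - nc$y[i])
    b <- c(nc$x[i + k] - nc$x[i], nc$y[i + k] - nc$y[i])
    out[i] <- pi - atan2(abs(a[1] * b[2] - a[2] * b[1]), sum(a * b))
  }
  out
}

# Max normalized perpendicular deviation of each sample from its covering
# polyline chord.
oracle_deviation <- function(y, vx) {
  nc <- oracle_norm(y)
  devs <- numeric(length(y))
  for (s in seq_along(y)) {
    j <- findInterval(s, vx, rightmost.closed = TRUE)
    j <- min(max(j, 1), length(vx) - 1)
    a <- vx[j]; b <- vx[j + 1]
    dx <- nc$x[b] - nc$x[a]; dy <- nc$y[b] - nc$y[a]
    len <- sqrt(dx^2 + dy^2)
    devs[s] <- abs(dy * (nc$x[s] - nc$x[a]) - dx * (nc$y[s] - nc$y[a])) / len
  }
  devs
}

# Total squared vertical error of the polyline with knots vx over y,
# computed chord by chord with stats::approx.
oracle_sse <- function(y, vx) {
  pred <- stats::approx(vx, y[vx], xout = vx[1]:vx[length(vx)])$y
  sum((pred - y[vx[1]:vx[length(vx)]])^2)
}

# Exhaustive optimum over all interior knot placements (m knots strictly
# between positions a and b of y).
oracle_dp_optimum <- function(y, a, b, m) {
  if (m == 0) return(oracle_sse(y, c(a, b)))
  interior <- (a + 1):(b - 1)
  combs <- utils::combn(interior, m)
  best <- Inf
  for (j in seq_len(ncol(combs))) {
    sse <- oracle_sse(y, c(a, combs[, j], b))
    if (sse < best) best <- sse
  }
  best
}

# Independent per-vertex scoring of a cumulative vertex set (direct
# formula transcription, loops only).
oracle_scores <- function(cum, fs, side, window_s = 0.3, cos_exp = 0.5,
                          sin_exp = 2, y_frac = 0.1) {
  n <- nrow(cum)
  win <- window_s * fs
  total <- cum$vyDp[n] - cum$vyDp[1]
  cand <- c()
  for (i in 2:(n - 1)) {
    vx <- cum$vx[i]
    inset <- if (side == "onset") vx >= cum$vx[n] - win && vx < cum$vx[n]
             else vx > cum$vx[1] && vx <= cum$vx[1] + win
    if (inset) cand <- c(cand, i)
  }
  if (length(cand) == 0) return(NULL)
  A <- Tm <- thL <- thR <- numeric(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    A[j] <- if (side == "onset") cum$vyDp[n] - cum$vyDp[i]
            else cum$vyDp[i] - cum$vyDp[1]
    Tm[j] <- if (side == "onset") cum$vx[i] - (cum$vx[n] - win)
             else (cum$vx[1] + win) - cum$vx[i]
    ys <- y_frac * total
    thL[j] <- atan2(abs(cum$vyDp[i - 1] - cum$vyDp[i]) / ys,
                    abs(cum$vx[i - 1] - cum$vx[i]) / win)
    thR[j] <- atan2(abs(cum$vyDp[i + 1] - cum$vyDp[i]) / ys,
                    abs(cum$vx[i + 1] - cum$vx[i]) / win)
  }
  wA <- if (max(A) > 0) A / max(A) else rep(0, length(A))
  wT <- Tm / win
  score <- if (side == "onset") {
    wA + wT + cos(thL)^cos_exp + sin(thR)^sin_exp
  } else {
    wA + wT + sin(thL)^sin_exp + cos(thR)^cos_exp
  }
  data.frame(i = cand, vx = cum$vx[cand], score = score)
}

# Standard ambulatory-style noise used across tests.
test_noise <- function(seed, r_amp = 1) {
  noise_spec(baseline_freq = 0.25, baseline_amp = 0.2 * r_amp,
             powerline_freq = 60, powerline_amp = 0.1 * r_amp,
             white_sd = 0.02 * r_amp, seed = seed)
}

# Smooth random segment: low-pass filtered Gaussian walk, endpoints held.
random_segment <- function(n, seed) {
  set.seed(seed)
  y <- cumsum(rnorm(n))
  as.numeric(stats::filter(y, rep(1 / 3, 3), sides = 2, circular = TRUE))
}
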