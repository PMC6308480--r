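## Polygonal approximation of an R-R section.
##
## Pipeline per segment: (1) curvature-based initial vertices (k-cosine
## curvature on axis-normalized coordinates), (2) sequential split
## refinement between each initial-vertex pair until every sample lies
## within `tolerance` of its covering chord, (3) dynamic-programming
## repositioning of the added vertices to minimize the total squared
## vertical reconstruction error, with the initial vertices held fixed.
##
## Axis normalization: within each segment, time is rescaled to [0, 1] over
## the R-R interval and amplitude to [0, 1] over the segment's amplitude
## range before any angle or distance computation. This makes support_k,
## curv_threshold and tolerance dimensionless and transferable across
## sampling rates and gains, and makes vertex x-positions invariant under
## polarity flips and uniform amplitude scaling.

# Normalized (x, y) coordinates of a segment (or any sample vector).
norm_xy <- function(y) {
  n <- length(y)
  xs <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
  rng <- range(y)
  ys <- if (diff(rng) > 0) (y - rng[[1]]) / diff(rng) else rep(0.5, n)
  list(x = xs, y = ys)
}

seg_samples <- function(segment) {
  if (inherits(segment, "beat_segment")) segment$samples else as.numeric(segment)
}

#' k-cosine curvature of a beat segment
#'
#' The curvature at sample `i` is `pi` minus the interior angle formed at
#' `i` by the chords to samples `i - k` and `i + k`, computed on
#' axis-normalized coordinates. Collinear samples give 0; a perfect fold
#' gives `pi`. The first and last `k` samples have no full support and are
#' assigned 0.
#'
#' @param segment a [beat_segment()] or numeric sample vector.
#' @param support_k chord half-support in samples (>= 1).
#' @return Numeric vector of curvature values in `[0, pi]`, one per sample.
#' @export
curvature <- function(segment, support_k) {
  y <- seg_samples(segment)
  n <- length(y)
  if (support_k < 1) stop("support_k must be >= 1")
  if (n <= 2 * support_k) stop("segment too short for the curvature support")
  nc <- norm_xy(y)
  k <- as.integer(support_k)
  i <- (k + 1):(n - k)
  ax <- nc$x[i - k] - nc$x[i]; ay <- nc$y[i - k] - nc$y[i]
  bx <- nc$x[i + k] - nc$x[i]; by <- nc$y[i + k] - nc$y[i]
  # interior angle via atan2(|cross|, dot): well-conditioned near 0 and pi
  out <- numeric(n)
  out[i] <- pi - atan2(abs(ax * by - ay * bx), ax * bx + ay * by)
  out
}

#' Curvature-based initial vertices
#'
#' Selects the segment endpoints (the bounding R-peaks, themselves
#' high-curvature poles) plus every sample that is a strict local maximum
#' of the curvature sequence and exceeds `curv_threshold`.
#'
#' @inheritParams curvature
#' @param curv_threshold curvature threshold in radians.
#' @return A `vertex_set` (see [vertex_set()]).
#' @export
initial_vertices <- function(segment, support_k, curv_threshold) {
  y <- seg_samples(segment)
  n <- length(y)
  cv <- curvature(segment, support_k)
  interior <- 2:(n - 1)
  is_max <- cv[interior] > cv[interior - 1] & cv[interior] > cv[interior + 1] &
    cv[interior] > curv_threshold
  vx <- sort(unique(c(1L, interior[is_max], n)))
  vertex_set(vx, y[vx])
}

#' Construct a vertex set
#'
#' Ordered vertices `(vx, vy)` lying on the signal; `vx` are 1-based sample
#' indices within the segment.
#'
#' @param vx strictly increasing integer sample indices.
#' @param vy amplitudes at `vx`.
#' @return A `vertex_set`: data frame with columns `vx`, `vy`.
#' @export
vertex_set <- function(vx, vy) {
  if (length(vx) != length(vy)) stop("vx and vy must have equal length")
  if (length(vx) > 1 && any(diff(vx) <= 0)) stop("vx must be strictly increasing")
  structure(data.frame(vx = as.integer(vx), vy = as.numeric(vy)),
            class = c("vertex_set", "data.frame"))
}

# Perpendicular distance of points (px, py) from the line through
# (x1, y1)-(x2, y2); all in normalized coordinates.
chord_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  abs(dy * (px - x1) - dx * (py - y1)) / len
}

#' Sequential polygonal approximation between two vertices
#'
#' Greedy recursive splitting: while any sample between `vA` and `vB`
#' deviates (perpendicularly, in normalized coordinates) from its covering
#' chord by more than `tolerance`, a vertex is inserted at the sample of
#' maximum deviation. Terminates because every split strictly reduces the
#' maximum deviation of its interval and vertices never repeat.
#'
#' @param segment a [beat_segment()] or numeric vector (used for
#'   normalization context and amplitudes).
#' @param vA,vB bounding vertices: 1-based sample indices into the segment,
#'   `vA < vB`.
#' @param tolerance maximum allowed normalized deviation (> 0).
#' @return A `vertex_set` spanning `[vA, vB]`, first vertex `vA`, last `vB`.
#' @export
sequential_approximation <- function(segment, vA, vB, tolerance) {
  y <- seg_samples(segment)
  if (vB <= vA) stop("vB must exceed vA")
  if (tolerance <= 0) stop("tolerance must be positive")
  nc <- norm_xy(y)
  split <- function(a, b) {
    if (b - a < 2) return(integer(0))
    ii <- (a + 1):(b - 1)
    d <- chord_dist(nc$x[ii], nc$y[ii], nc$x[a], nc$y[a], nc$x[b], nc$y[b])
    mx <- which.max(d)
    if (d[[mx]] <= tolerance) return(integer(0))
    m <- ii[[mx]]
    c(split(a, m), m, split(m, b))
  }
  vx <- c(vA, split(vA, vB), vB)
  vertex_set(vx, y[vx])
}

# Squared-vertical-error cost matrix: E[p, q] = sum over samples x in p..q
# of (linear interpolation between (p, y[p]) and (q, y[q]) minus y[x])^2.
# Computed in O(n^2) via prefix sums.
chord_cost_matrix <- function(y) {
  n <- length(y)
  cs_y <- cumsum(y); cs_y2 <- cumsum(y^2)
  xs <- seq_len(n)
  cs_xy <- cumsum(xs * y)
  E <- matrix(0, n, n)
  for (p in seq_len(n - 1L)) {
    q <- (p + 1L):n
    L <- q - p
    # sums over x = p..q (inclusive)
    S_y <- cs_y[q] - if (p > 1) cs_y[p - 1] else 0
    S_y2 <- cs_y2[q] - if (p > 1) cs_y2[p - 1] else 0
    S_xy <- cs_xy[q] - if (p > 1) cs_xy[p - 1] else 0
    # t = (x - p) / L in [0, 1]; St_y = sum t*y; sums of t and t^2 are
    # closed-form over the integer grid
    St_y <- (S_xy - p * S_y) / L
    m <- L + 1                          # samples under the chord
    S_t <- (L + 1) / 2                  # sum_{j=0..L} j/L
    S_t2 <- (L + 1) * (2 * L + 1) / (6 * L)   # sum_{j=0..L} (j/L)^2
    yp <- y[[p]]; yq <- y[q]
    # sum over x of (y - (1-t) yp - t yq)^2 expanded
    E[p, q] <- S_y2 - 2 * yp * (S_y - St_y) - 2 * yq * St_y +
      yp^2 * (m - 2 * S_t + S_t2) + 2 * yp * yq * (S_t - S_t2) + yq^2 * S_t2
  }
  pmax(E, 0)
}

# Total squared vertical error of a polyline with knots `vx` over y.
polyline_sse <- function(y, vx) {
  tot <- 0
  for (i in seq_len(length(vx) - 1L)) {
    a <- vx[[i]]; b <- vx[[i + 1]]
    xs <- a:b
    pred <- y[[a]] + (xs - a) * (y[[b]] - y[[a]]) / (b - a)
    # interior samples only on the left end to avoid double-counting the
    # shared knot (knots contribute zero anyway since vertices lie on y)
    tot <- tot + sum((pred - y[xs])^2)
  }
  tot
}

#' Dynamic-programming vertex position optimization
#'
#' Repositions the interior vertices of `verts` (endpoints fixed) to the
#' integer sample positions that minimize the total squared vertical error
#' between the piecewise-linear reconstruction and the signal over the
#' spanned range, subject to strict ordering and a fixed interior count.
#' Equal-cost placements resolve deterministically to the leftmost
#' configuration.
#'
#' @param segment a [beat_segment()] or numeric vector.
#' @param verts a [vertex_set()] whose first/last vertices bound the range.
#' @return A `vertex_set` with the same vertex count; its reconstruction
#'   error never exceeds that of the input placement.
#' @export
dp_optimize <- function(segment, verts) {
  y <- seg_samples(segment)
  stopifnot(inherits(verts, "vertex_set"))
  nv <- nrow(verts)
  m <- nv - 2L
  if (m <= 0L) return(verts)
  a <- verts$vx[[1]]; b <- verts$vx[[nv]]
  ys <- y[a:b]
  n <- length(ys)
  if (n - 2L < m) return(verts)   # not enough interior samples to move
  E <- chord_cost_matrix(ys)
  # D[j, x]: best cost of covering 1..x with j interior knots, last at x
  D <- matrix(Inf, m, n)
  D[1, ] <- E[1, ]
  if (m > 1) {
    for (j in 2:m) {
      for (x in (j + 1):(n - (m - j) - 1L)) {
        prev <- j:(x - 1L)
        D[j, x] <- min(D[j - 1, prev] + E[prev, x])
      }
    }
  }
  final <- D[m, ] + E[, n]
  final[c(1L, n)] <- Inf
  # backtrack, preferring the leftmost position at each choice
  pick <- integer(m)
  pick[m] <- which.min(final)
  if (m > 1) {
    for (j in (m - 1L):1L) {
      nxt <- pick[j + 1L]
      cand <- (j + 1L):(nxt - 1L)
      costs <- D[j, cand] + E[cand, nxt]
      pick[j] <- cand[[which.min(costs)]]
    }
  }
  vx <- c(a, a + pick - 1L, b)
  vertex_set(vx, y[vx])
}

#' Full polygonal approximation of an R-R section
#'
#' Composition of [initial_vertices()], per-interval
#' [sequential_approximation()] and per-interval [dp_optimize()]; the merged
#' result is strictly ordered, starts and ends at the bounding R-peaks, and
#' every vertex lies on the signal.
#'
#' @param segment a [beat_segment()] or numeric vector.
#' @param support_k curvature chord half-support in samples; default
#'   `round(0.02 * fs)` (20 ms) when a [beat_segment()] is supplied.
#' @param curv_threshold curvature threshold in radians (default 0.15).
#' @param tolerance normalized deviation tolerance (default 0.02, i.e. 2%
#'   of the segment amplitude range).
#' @return A `vertex_set` over the segment.
#' @examples
#' sim <- generate_record(beat_spec(), n_beats = 3, rr_s = 0.8, fs = 250)
#' seg <- segment_rr(sim$record, sim$r_positions)[[1]]
#' approximate(seg)
#' @export
approximate <- function(segment, support_k = NULL, curv_threshold = 0.15,
                        tolerance = 0.02) {
  y <- seg_samples(segment)
  if (is.null(support_k)) {
    fs <- if (inherits(segment, "beat_segment")) segment$fs else
      stop("support_k required when segment is a bare vector")
    support_k <- max(1L, as.integer(round(0.02 * fs)))
  }
  iv <- initial_vertices(y, support_k, curv_threshold)
  vx_all <- integer(0)
  for (i in seq_len(nrow(iv) - 1L)) {
    sa <- sequential_approximation(y, iv$vx[[i]], iv$vx[[i + 1]], tolerance)
    opt <- dp_optimize(y, sa)
    vx_all <- c(vx_all, opt$vx[-nrow(opt)])
  }
  vx_all <- c(vx_all, iv$vx[[nrow(iv)]])
  vertex_set(vx_all, y[vx_all])
}

#' Piecewise-linear reconstruction from a vertex set
#'
#' @param verts a [vertex_set()] spanning `[1, length]`.
#' @param length output length; must match the vertex span.
#' @return Numeric vector: linear interpolation between consecutive
#'   vertices, exact at vertex positions.
#' @export
reconstruct <- function(verts, length) {
  stopifnot(inherits(verts, "vertex_set"))
  if (verts$vx[[1]] != 1L || verts$vx[[nrow(verts)]] != length) {
    stop("vertex span must cover [1, length]")
  }
  stats::approx(verts$vx, verts$vy, xout = seq_len(length))$y
}
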