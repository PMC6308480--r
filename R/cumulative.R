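## Cumulative auxiliary signal over the polygonal vertices.
##
## The vertex-to-vertex amplitude differences are rectified and summed,
## giving a monotone non-decreasing signal whose total equals the total
## variation of the vertex amplitudes. Downward QRS complexes and beats
## with or without Q/S deflections all map to cumulative signals of
## similar shape, which is what makes the downstream vertex scoring
## polarity- and morphology-robust. The cumulative signal is kept at
## vertex resolution: all downstream features are defined on vertices.

#' Vertex-to-vertex amplitude differences
#'
#' @param verts a [vertex_set()].
#' @return Data frame with columns `vx` (unchanged) and `vyD`: the signed
#'   difference `vy_i - vy_(i-1)`, with the first element 0. The sum of
#'   `vyD` telescopes to `vy_last - vy_first`.
#' @export
amplitude_difference <- function(verts) {
  stopifnot(inherits(verts, "vertex_set"))
  if (nrow(verts) == 0) stop("empty vertex set")
  data.frame(vx = verts$vx, vyD = c(0, diff(verts$vy)))
}

#' Accumulate rectified amplitude differences
#'
#' @param diffs data frame from [amplitude_difference()] (columns `vx`,
#'   `vyD`; first `vyD` must be 0).
#' @return A `cumulative_vertex_set`: data frame with columns `vx`, `vyD`
#'   and `vyDp` (the running sum of `|vyD|`), which is non-decreasing,
#'   starts at 0 and ends at the total variation of the vertex amplitudes.
#' @export
accumulate <- function(diffs) {
  stopifnot(is.data.frame(diffs), all(c("vx", "vyD") %in% names(diffs)))
  if (nrow(diffs) == 0) stop("empty difference set")
  if (diffs$vyD[[1]] != 0) stop("first amplitude difference must be 0")
  out <- data.frame(vx = diffs$vx, vyD = diffs$vyD,
                    vyDp = cumsum(abs(diffs$vyD)))
  class(out) <- c("cumulative_vertex_set", "data.frame")
  out
}

#' Cumulative signal of a vertex set
#'
#' Composition of [amplitude_difference()] and [accumulate()].
#'
#' @param verts a [vertex_set()].
#' @return A `cumulative_vertex_set`.
#' @examples
#' v <- vertex_set(c(1, 5, 9, 12), c(0, 5, 2, 2))
#' cumulative_signal(v)$vyDp   # 0 5 8 8
#' @export
cumulative_signal <- function(verts) {
  accumulate(amplitude_difference(verts))
}
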