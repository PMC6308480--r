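#' Pipeline configuration
#'
#' One flat container for every tunable of the pipeline. All parameters are
#' dimensionless or in physical units, so one configuration transfers
#' across sampling rates.
#'
#' @param bp_low,bp_high,bp_order preprocessing band edges (Hz) and
#'   Butterworth design order (applied zero-phase, forward-backward).
#' @param filter logical; disable to delineate an externally filtered record.
#' @param support_ms curvature chord half-support in ms (default 20, below
#'   the narrowest QRS feature).
#' @param curv_threshold curvature threshold in radians (default 0.15).
#' @param tolerance sequential-approximation deviation tolerance as a
#'   fraction of the segment amplitude range (default 0.02).
#' @param window_s fiducial search-window / time-reference offset in
#'   seconds (default 0.3).
#' @param cos_exponent,sin_exponent exponents of the baseline-direction
#'   `cos` and waveform-direction `sin` angle weights (defaults 0.5 and 2).
#' @param angle_y_frac angle y-axis reference as a fraction of the total
#'   cumulative range (default 0.1; see [feature_weights()]).
#' @param eval_window_ms evaluation matching window in ms (default 150).
#' @param seed integer seed for any randomized step.
#' @return A `pq_config` list.
#' @export
pq_config <- function(bp_low = 1, bp_high = 25, bp_order = 2, filter = TRUE,
                      support_ms = 20, curv_threshold = 0.15,
                      tolerance = 0.02, window_s = 0.3,
                      cos_exponent = 0.5, sin_exponent = 2,
                      angle_y_frac = 0.1,
                      eval_window_ms = 150, seed = 1L) {
  cfg <- list(bp_low = bp_low, bp_high = bp_high, bp_order = bp_order,
              filter = filter, support_ms = support_ms,
              curv_threshold = curv_threshold, tolerance = tolerance,
              window_s = window_s, cos_exponent = cos_exponent,
              sin_exponent = sin_exponent, angle_y_frac = angle_y_frac,
              eval_window_ms = eval_window_ms,
              seed = as.integer(seed))
  stopifnot(cfg$bp_low > 0, cfg$bp_high > cfg$bp_low, cfg$support_ms > 0,
            cfg$tolerance > 0, cfg$window_s > 0, cfg$cos_exponent > 0,
            cfg$sin_exponent > 0, cfg$eval_window_ms > 0)
  structure(cfg, class = "pq_config")
}

#' Read / write a pipeline configuration
#'
#' Flat `key = value` text format; round-trips unchanged. Unknown keys are
#' rejected.
#'
#' @param path file path.
#' @return `read_config()` returns a [pq_config()]; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) stop("config lines must be 'key = value'")
  keys <- trimws(vapply(kv, `[[`, character(1), 1))
  vals <- trimws(vapply(kv, `[[`, character(1), 2))
  defaults <- pq_config()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  args <- list()
  for (j in seq_along(keys)) {
    k <- keys[[j]]
    args[[k]] <- if (is.logical(defaults[[k]])) as.logical(vals[[j]])
                 else if (is.integer(defaults[[k]])) as.integer(vals[[j]])
                 else as.numeric(vals[[j]])
  }
  do.call(pq_config, args)
}

#' @rdname read_config
#' @param config a [pq_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pq_config"))
  writeLines(vapply(names(config), function(k) {
    sprintf("%s = %s", k, format(config[[k]], digits = 17))
  }, character(1)), path)
  invisible(path)
}
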