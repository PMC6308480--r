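#' Construct an ECG record
#'
#' An `ecg_record` holds one or more equal-length sampled channels together
#' with the sampling frequency. All in-memory sample indices in this package
#' are 1-based (R convention); on-disk formats (CSV, WFDB) store 0-based
#' indices and are converted at the I/O boundary.
#'
#' @param samples numeric matrix (rows = samples, columns = channels) or a
#'   numeric vector for a single channel.
#' @param fs sampling frequency in Hz; must be positive.
#' @param channel_names optional character vector of channel labels
#'   (e.g. `"MLII"`, `"V5"`); defaults to `ch1`, `ch2`, ...
#' @param units per-channel unit strings; recycled if length 1. Default `"mV"`.
#' @return An object of class `ecg_record` with fields `samples` (matrix),
#'   `fs`, `channel_names`, `units`.
#' @examples
#' rec <- ecg_record(sin(seq(0, 2 * pi, length.out = 250)), fs = 250)
#' n_samples(rec)
#' @export
ecg_record <- function(samples, fs, channel_names = NULL, units = "mV") {
  if (is.vector(samples) && is.numeric(samples)) {
    samples <- matrix(samples, ncol = 1L)
  }
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric vector or matrix")
  }
  if (nrow(samples) < 1L) stop("record must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  nc <- ncol(samples)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc) stop("one channel name per channel required")
  units <- rep_len(as.character(units), nc)
  colnames(samples) <- channel_names
  structure(
    list(samples = samples, fs = as.numeric(fs),
         channel_names = as.character(channel_names), units = units),
    class = "ecg_record"
  )
}

#' Number of samples in a record
#' @param record an `ecg_record`.
#' @return Integer number of samples per channel.
#' @export
n_samples <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  nrow(record$samples)
}

#' Number of channels in a record
#' @param record an `ecg_record`.
#' @return Integer channel count.
#' @export
n_channels <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  ncol(record$samples)
}

#' Extract one channel as a numeric vector
#' @param record an `ecg_record`.
#' @param channel channel index (1-based) or channel name.
#' @return Numeric vector of amplitudes.
#' @export
channel <- function(record, channel = 1L) {
  stopifnot(inherits(record, "ecg_record"))
  if (is.character(channel)) {
    channel <- match(channel, record$channel_names)
    if (is.na(channel)) stop("unknown channel name")
  }
  if (channel < 1L || channel > n_channels(record)) stop("channel out of range")
  record$samples[, channel]
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples x %d channel(s) @ %g Hz (%.2f s)\n",
              n_samples(x), n_channels(x), x$fs, n_samples(x) / x$fs))
  cat("  channels:", paste(sprintf("%s [%s]", x$channel_names, x$units),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Construct a fiducial annotation set
#'
#' Ordered (sample index, label) pairs. Recognized labels are `"Qon"`,
#' `"Rpeak"`, `"Soff"`; any other string is preserved verbatim ("other").
#' Indices are 1-based in memory.
#'
#' @param sample_index integer vector of 1-based sample indices (>= 1).
#' @param label character vector of labels, same length.
#' @return An `annotation_set`: a data frame with columns `sample_index`
#'   and `label`, ordered by `sample_index`.
#' @examples
#' annotation_set(c(101, 131, 166), c("Qon", "Rpeak", "Soff"))
#' @export
annotation_set <- function(sample_index = integer(), label = character()) {
  if (length(sample_index) != length(label)) {
    stop("`sample_index` and `label` must have the same length")
  }
  sample_index <- as.integer(round(sample_index))
  if (any(sample_index < 1L)) stop("sample indices must be >= 1")
  label <- as.character(label)
  ord <- order(sample_index)
  ann <- data.frame(sample_index = sample_index[ord], label = label[ord],
                    stringsAsFactors = FALSE)
  # within a label stream indices must be strictly increasing
  for (lab in unique(ann$label)) {
    idx <- ann$sample_index[ann$label == lab]
    if (any(diff(idx) <= 0)) {
      stop(sprintf("duplicate sample index within label stream '%s'", lab))
    }
  }
  class(ann) <- c("annotation_set", "data.frame")
  ann
}

#' Subset an annotation set by label
#' @param ann an `annotation_set`.
#' @param labels character vector of labels to keep.
#' @return Integer vector of sample indices carrying those labels, in order.
#' @export
ann_indices <- function(ann, labels) {
  stopifnot(inherits(ann, "annotation_set"))
  ann$sample_index[ann$label %in% labels]
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d entries\n", nrow(x)))
  if (nrow(x) > 0) {
    tab <- table(x$label)
    cat("  ", paste(sprintf("%s: %d", names(tab), as.integer(tab)),
                    collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
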