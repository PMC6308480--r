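## Record and annotation I/O.
##
## Two dialects are supported throughout:
##  * "csv"  — plain text, '#'-prefixed header comments carrying fs / units /
##             channel names, one row per sample, comma-separated channels.
##             Diffable and suitable as a test fixture format.
##  * "wfdb" — PhysioNet WFDB: text .hea header plus binary .dat in format
##             212 or 16 for signals, and the standard binary annotation
##             format for fiducials. Only the subset needed to consume
##             QT-DB / MIT-BIH style records is implemented.
##
## On-disk sample indices are 0-based (WFDB convention, and the CSV dialect
## follows it for interoperability); the in-memory API is 1-based.

#' Read an ECG record
#'
#' @param path path to the record. For `format = "wfdb"` this is the header
#'   file (`.hea`) or the record name without extension.
#' @param format `"csv"` or `"wfdb"`.
#' @return An [ecg_record()].
#' @details The CSV dialect expects comment lines `# fs: <Hz>` (required),
#'   and optionally `# channels: a,b` and `# units: mV,mV`. WFDB signal
#'   formats 212 and 16 are supported; amplitudes are converted to physical
#'   units using the header gain and baseline.
#' @export
read_record <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "csv") read_record_csv(path) else read_record_wfdb(path)
}

#' Write an ECG record
#'
#' @param record an [ecg_record()].
#' @param path output path (for `"wfdb"`, the `.hea` path or record name).
#' @param format `"csv"` or `"wfdb"` (format 16, gain 200 adu/mV).
#' @return Invisibly, `path`.
#' @export
write_record <- function(record, path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  stopifnot(inherits(record, "ecg_record"))
  if (format == "csv") write_record_csv(record, path)
  else write_record_wfdb(record, path)
  invisible(path)
}

read_record_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  get_field <- function(key) {
    m <- grep(sprintf("^#\\s*%s\\s*:", key), hdr, value = TRUE)
    if (length(m) == 0) return(NULL)
    trimws(sub(sprintf("^#\\s*%s\\s*:", key), "", m[[1]]))
  }
  fs <- get_field("fs")
  if (is.null(fs)) stop("csv record is missing an '# fs:' header comment")
  fs <- as.numeric(fs)
  if (!is.finite(fs) || fs <= 0) stop("invalid fs in csv header")
  if (length(body) == 0) stop("csv record contains no samples")
  rows <- strsplit(body, ",", fixed = TRUE)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1) stop("inconsistent channel counts across rows")
  mat <- matrix(as.numeric(unlist(rows)), ncol = ncols[[1]], byrow = TRUE)
  if (anyNA(mat)) stop("non-numeric sample value in csv record")
  chn <- get_field("channels")
  chn <- if (is.null(chn)) NULL else trimws(strsplit(chn, ",")[[1]])
  un <- get_field("units")
  un <- if (is.null(un)) "mV" else trimws(strsplit(un, ",")[[1]])
  ecg_record(mat, fs = fs, channel_names = chn, units = un)
}

write_record_csv <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fs: %.17g", record$fs),
    sprintf("# channels: %s", paste(record$channel_names, collapse = ",")),
    sprintf("# units: %s", paste(record$units, collapse = ","))
  ), con)
  apply_fmt <- function(row) paste(sprintf("%.17g", row), collapse = ",")
  writeLines(vapply(seq_len(nrow(record$samples)),
                    function(i) apply_fmt(record$samples[i, ]), character(1)),
             con)
}

## --- WFDB signals ---------------------------------------------------------

parse_hea <- function(hea_path) {
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rec_line <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  name <- sub("/.*$", "", rec_line[[1]])
  nsig <- as.integer(rec_line[[2]])
  fs <- if (length(rec_line) >= 3) as.numeric(sub("/.*$", "", rec_line[[3]])) else 250
  nsamp <- if (length(rec_line) >= 4) as.integer(rec_line[[4]]) else NA_integer_
  sig <- lapply(lines[1 + seq_len(nsig)], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    gain_spec <- if (length(f) >= 3) f[[3]] else "200"
    units <- "mV"
    if (grepl("/", gain_spec, fixed = TRUE)) {
      units <- sub("^[^/]*/", "", gain_spec)
      gain_spec <- sub("/.*$", "", gain_spec)
    }
    baseline <- NA_integer_
    if (grepl("\\(", gain_spec)) {
      baseline <- as.integer(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_spec))
      gain_spec <- sub("\\(.*$", "", gain_spec)
    }
    gain <- as.numeric(gain_spec)
    if (!is.finite(gain) || gain == 0) gain <- 200
    adczero <- if (length(f) >= 5) as.integer(f[[5]]) else 0L
    if (is.na(baseline)) baseline <- adczero
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else NA_character_
    list(file = f[[1]], format = as.integer(sub("x.*|:.*|\\+.*", "", f[[2]])),
         gain = gain, baseline = baseline, units = units, desc = desc)
  })
  list(name = name, nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

read_dat_212 <- function(path, n_values) {
  raw <- readBin(path, "raw", n = file.size(path))
  n_pairs <- ceiling(n_values / 2)
  if (length(raw) < 3 * n_pairs) stop("wfdb .dat file shorter than header declares")
  b <- as.integer(raw[seq_len(3 * n_pairs)])
  b0 <- b[seq(1, length(b), by = 3)]
  b1 <- b[seq(2, length(b), by = 3)]
  b2 <- b[seq(3, length(b), by = 3)]
  s1 <- b0 + bitwShiftL(bitwAnd(b1, 0x0FL), 8)
  s2 <- b2 + bitwShiftL(bitwShiftR(b1, 4), 8)
  tc <- function(x) ifelse(x >= 2048L, x - 4096L, x)  # 12-bit two's complement
  vals <- as.vector(rbind(tc(s1), tc(s2)))
  vals[seq_len(n_values)]
}

read_dat_16 <- function(path, n_values) {
  v <- readBin(path, "integer", n = n_values, size = 2, signed = TRUE,
               endian = "little")
  if (length(v) < n_values) stop("wfdb .dat file shorter than header declares")
  v
}

read_record_wfdb <- function(path) {
  hea_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea_path)) stop(sprintf("file not found: %s", hea_path))
  h <- parse_hea(hea_path)
  dir <- dirname(hea_path)
  fmts <- vapply(h$signals, `[[`, integer(1), "format")
  files <- vapply(h$signals, `[[`, character(1), "file")
  if (length(unique(files)) != 1) stop("multi-file wfdb records are not supported")
  fmt <- unique(fmts)
  if (length(fmt) != 1 || !fmt %in% c(212L, 16L)) {
    stop("only wfdb signal formats 212 and 16 are supported")
  }
  dat_path <- file.path(dir, files[[1]])
  if (!file.exists(dat_path)) stop(sprintf("file not found: %s", dat_path))
  if (is.na(h$nsamp)) {
    bytes <- file.size(dat_path)
    per_val <- if (fmt == 212L) 1.5 else 2
    h$nsamp <- as.integer(floor(bytes / (per_val * h$nsig)))
  }
  n_values <- h$nsamp * h$nsig
  adc <- if (fmt == 212L) read_dat_212(dat_path, n_values)
         else read_dat_16(dat_path, n_values)
  mat <- matrix(adc, ncol = h$nsig, byrow = TRUE)  # samples interleaved by frame
  for (j in seq_len(h$nsig)) {
    mat[, j] <- (mat[, j] - h$signals[[j]]$baseline) / h$signals[[j]]$gain
  }
  desc <- vapply(h$signals, function(s)
    if (is.na(s$desc)) NA_character_ else s$desc, character(1))
  if (anyNA(desc)) desc <- NULL
  ecg_record(mat, fs = h$fs, channel_names = desc,
             units = vapply(h$signals, `[[`, character(1), "units"))
}

write_record_wfdb <- function(record, path) {
  hea_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  rec_name <- sub("\\.hea$", "", basename(hea_path))
  dat_name <- paste0(rec_name, ".dat")
  gain <- 200
  n <- n_samples(record)
  nc <- n_channels(record)
  adc <- round(record$samples * gain)
  adc <- pmin(pmax(adc, -32768), 32767)
  hdr <- c(sprintf("%s %d %.17g %d", rec_name, nc, record$fs, n),
           vapply(seq_len(nc), function(j) {
             sprintf("%s 16 %g(0)/%s 16 0 0 0 0 %s", dat_name, gain,
                     record$units[[j]], record$channel_names[[j]])
           }, character(1)))
  writeLines(hdr, hea_path)
  vals <- as.integer(t(adc))  # interleave channels frame by frame
  writeBin(vals, file.path(dirname(hea_path), dat_name), size = 2,
           endian = "little")
}

## --- Annotations ----------------------------------------------------------

# WFDB annotation code table (subset of the standard mnemonics).
.wfdb_codes <- c(
  "1" = "N", "2" = "L", "3" = "R", "4" = "a", "5" = "V", "6" = "F", "7" = "J",
  "8" = "A", "9" = "S", "10" = "E", "11" = "j", "12" = "/", "13" = "Q",
  "14" = "~", "16" = "|", "18" = "s", "19" = "T", "20" = "*", "21" = "D",
  "22" = "\"", "23" = "=", "24" = "p", "25" = "B", "26" = "^", "27" = "t",
  "28" = "+", "29" = "u", "30" = "?", "31" = "!", "32" = "[", "33" = "]",
  "34" = "e", "35" = "n", "36" = "@", "37" = "x", "38" = "f",
  "39" = "(", "40" = ")"
)

label_to_code <- function(label) {
  if (label == "Rpeak") return(1L)
  if (label == "Qon") return(39L)
  if (label == "Soff") return(40L)
  hit <- names(.wfdb_codes)[match(label, .wfdb_codes)]
  if (!is.na(hit)) return(as.integer(hit))
  13L  # unclassifiable
}

code_to_label <- function(code) {
  if (code == 1L) return("Rpeak")
  if (code == 39L) return("Qon")
  if (code == 40L) return("Soff")
  mn <- .wfdb_codes[as.character(code)]
  if (!is.na(mn)) unname(mn) else sprintf("code%d", code)
}

#' Read fiducial annotations
#'
#' @param path annotation file path.
#' @param format `"csv"` (rows of `index,label`, 0-based on disk) or
#'   `"wfdb"` (standard binary annotation format; code 1 maps to `Rpeak`,
#'   `'('` to `Qon`, `')'` to `Soff`, all other codes to their mnemonic).
#' @return An [annotation_set()] with 1-based in-memory indices.
#' @export
read_annotations <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "csv") {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
    if (length(lines) == 0) return(annotation_set())
    parts <- strsplit(lines, ",", fixed = TRUE)
    if (any(lengths(parts) < 2)) stop("annotation rows must be 'index,label'")
    idx <- as.numeric(vapply(parts, `[[`, character(1), 1))
    if (anyNA(idx)) stop("non-numeric annotation index")
    if (any(idx < 0)) stop("negative annotation index")
    lab <- trimws(vapply(parts, `[[`, character(1), 2))
    annotation_set(idx + 1, lab)   # disk is 0-based
  } else {
    read_annotations_wfdb(path)
  }
}

#' Write fiducial annotations
#'
#' @param ann an [annotation_set()].
#' @param path output path.
#' @param format `"csv"` or `"wfdb"`. CSV stores 0-based indices.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(ann, path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  stopifnot(inherits(ann, "annotation_set"))
  if (format == "csv") {
    writeLines(sprintf("%d,%s", ann$sample_index - 1L, ann$label), path)
  } else {
    write_annotations_wfdb(ann, path)
  }
  invisible(path)
}

read_annotations_wfdb <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) %% 2 == 1) raw <- raw[-length(raw)]
  words <- readBin(raw, "integer", n = length(raw) / 2, size = 2,
                   signed = FALSE, endian = "little")
  t0 <- 0
  i <- 1
  idx <- integer(0); lab <- character(0)
  while (i <= length(words)) {
    w <- words[[i]]
    code <- bitwShiftR(w, 10)
    interval <- bitwAnd(w, 1023L)
    if (w == 0L) break                       # end of file
    if (code == 59L) {                       # SKIP: 4-byte interval follows
      if (i + 2 > length(words)) stop("truncated wfdb annotation file")
      hi <- words[[i + 1]]; lo <- words[[i + 2]]
      t0 <- t0 + hi * 65536 + lo
      i <- i + 3
      next
    }
    if (code >= 60L) { i <- i + 1; next }    # NUM/SUB/CHN/AUX: no time
    t0 <- t0 + interval
    idx <- c(idx, t0)
    lab <- c(lab, code_to_label(code))
    i <- i + 1
  }
  if (length(idx) == 0) return(annotation_set())
  annotation_set(idx + 1, lab)               # wfdb times are 0-based
}

write_annotations_wfdb <- function(ann, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  t_prev <- 0
  for (k in seq_len(nrow(ann))) {
    t <- ann$sample_index[[k]] - 1L          # to 0-based
    dt <- t - t_prev
    code <- label_to_code(ann$label[[k]])
    if (dt > 1023) {
      writeBin(as.integer(bitwShiftL(59L, 10)), con, size = 2, endian = "little")
      writeBin(as.integer(dt %/% 65536), con, size = 2, endian = "little")
      writeBin(as.integer(dt %% 65536), con, size = 2, endian = "little")
      dt <- 0
    }
    writeBin(as.integer(bitwShiftL(code, 10) + dt), con, size = 2,
             endian = "little")
    t_prev <- t
  }
  writeBin(0L, con, size = 2, endian = "little")
}
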