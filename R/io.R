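#' Construct a two-lead ECG record
#'
#' A record holds two simultaneously sampled ECG leads from one subject as
#' integer ADC values. It is a tibble with columns `sample`, `lead1`, `lead2`
#' and attributes `subject_id` and `fs` (sampling rate, Hz), so it chains with
#' dplyr verbs while keeping the metadata the pipeline needs.
#'
#' @param lead1,lead2 Integer sample vectors of equal length (ADC units).
#' @param subject_id Opaque subject label.
#' @param fs Sampling rate in Hz (default 128).
#' @return A tibble of class `ecg_record`.
#' @examples
#' rec <- ecg_record(c(-3L, 10L, 7L), c(0L, 4L, 9L), "S01")
#' attr(rec, "fs")
#' @export
ecg_record <- function(lead1, lead2, subject_id = "unknown", fs = 128) {
  if (length(lead1) != length(lead2)) {
    abort("lead1 and lead2 must have equal length")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("fs must be a single positive number")
  }
  out <- tibble(
    sample = seq_along(lead1),
    lead1 = as.integer(round(lead1)),
    lead2 = as.integer(round(lead2))
  )
  attr(out, "subject_id") <- as.character(subject_id)
  attr(out, "fs") <- fs
  class(out) <- c("ecg_record", class(out))
  out
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf(
    "<ecg_record> subject %s: %d samples at %g Hz (%.1f s)\n",
    attr(x, "subject_id"), nrow(x), attr(x, "fs"), nrow(x) / attr(x, "fs")
  ))
  NextMethod()
}

#' Read a two-lead record from CSV or WFDB files
#'
#' CSV input is two integer columns (lead 1, lead 2), comma separated, with an
#' optional header row. WFDB input is a PhysioNet-style header (`.hea`) plus
#' signal file; formats 212 (12-bit packed) and 16 (16-bit little endian) are
#' supported and the first two channels in file order become lead 1 and lead 2.
#' Samples are returned as raw ADC units; no gain or baseline is applied.
#'
#' @param path CSV file, or WFDB record name / header path (with or without
#'   the `.hea` extension).
#' @param format `"csv"` or `"wfdb"`.
#' @param subject_id Subject label; defaults to the file base name.
#' @param fs Sampling rate for CSV input (WFDB reads it from the header).
#' @return An [ecg_record()] tibble.
#' @export
read_record <- function(path, format = c("csv", "wfdb"), subject_id = NULL,
                        fs = 128) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!file.exists(path)) abort(sprintf("file not found: %s", path))
    subject_id <- subject_id %||% sub("\\.[^.]*$", "", basename(path))
    read_record_csv(path, subject_id, fs)
  } else {
    read_record_wfdb(path, subject_id)
  }
}

read_record_csv <- function(path, subject_id, fs) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) abort(sprintf("empty csv record: %s", path))
  toks <- strsplit(first, ",", fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(toks)))
  df <- read.csv(path, header = has_header, strip.white = TRUE)
  if (ncol(df) < 2L) abort("csv record needs at least two columns (one per lead)")
  if (nrow(df) == 0L) abort("csv record has no sample rows")
  for (j in 1:2) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      bad <- suppressWarnings(as.numeric(as.character(col)))
      if (anyNA(bad)) abort(sprintf("non-numeric value in csv column %d", j))
      df[[j]] <- bad
    }
    if (anyNA(df[[j]])) abort(sprintf("missing value in csv column %d", j))
  }
  ecg_record(df[[1]], df[[2]], subject_id, fs)
}

# Minimal WFDB reader: single-segment records, one signal file shared by all
# channels, formats 212 and 16. Enough for PhysioNet two-channel Holter data.
read_record_wfdb <- function(path, subject_id = NULL) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) abort(sprintf("header file not found: %s", hea))
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec) < 2L) abort("malformed wfdb header record line")
  nsig <- as.integer(rec[2])
  if (is.na(nsig) || nsig < 2L) {
    abort("record must have at least two signal channels")
  }
  fs <- if (length(rec) >= 3) as.numeric(sub("/.*", "", rec[3])) else 250
  nsamp <- if (length(rec) >= 4) as.numeric(rec[4]) else NA_real_
  sig <- strsplit(trimws(lines[2:(1 + nsig)]), "\\s+")
  dat <- vapply(sig, `[`, character(1), 1L)
  fmt <- vapply(sig, `[`, character(1), 2L)
  fmt <- as.integer(sub("[x:+].*$", "", fmt))
  if (length(unique(dat)) != 1L) {
    abort("multi-file wfdb records are not supported")
  }
  if (!all(fmt == fmt[1]) || !fmt[1] %in% c(16L, 212L)) {
    abort(sprintf("unsupported wfdb signal format: %s", paste(fmt, collapse = ",")))
  }
  datfile <- file.path(dirname(hea), dat[1])
  if (!file.exists(datfile)) abort(sprintf("signal file not found: %s", datfile))
  samp <- if (fmt[1] == 16L) {
    read_dat16(datfile)
  } else {
    read_dat212(datfile)
  }
  per_frame <- nsig
  nframes <- length(samp) %/% per_frame
  if (!is.na(nsamp) && nframes > nsamp) nframes <- nsamp
  m <- matrix(samp[seq_len(nframes * per_frame)], nrow = per_frame)
  subject_id <- subject_id %||% sub("\\.hea$", "", basename(hea))
  ecg_record(m[1, ], m[2, ], subject_id, fs)
}

read_dat16 <- function(path) {
  n <- file.size(path) %/% 2L
  readBin(path, integer(), n = n, size = 2L, signed = TRUE, endian = "little")
}

read_dat212 <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  nb <- (length(raw) %/% 3L) * 3L
  b <- as.integer(raw[seq_len(nb)])
  b1 <- b[seq(1, nb, 3)]
  b2 <- b[seq(2, nb, 3)]
  b3 <- b[seq(3, nb, 3)]
  s1 <- b1 + bitwShiftL(bitwAnd(b2, 0x0FL), 8)
  s2 <- b3 + bitwShiftL(bitwShiftR(b2, 4), 8)
  s1 <- ifelse(s1 >= 2048L, s1 - 4096L, s1)
  s2 <- ifelse(s2 >= 2048L, s2 - 4096L, s2)
  as.integer(rbind(s1, s2))
}

# Internal writers used to build round-trip fixtures in code.
write_record_wfdb <- function(record, dir, name, format = 212L) {
  fs <- attr(record, "fs")
  n <- nrow(record)
  hea <- file.path(dir, paste0(name, ".hea"))
  dat <- paste0(name, ".dat")
  writeLines(c(
    sprintf("%s 2 %g %d", name, fs, n),
    sprintf("%s %d 200 12 0 0 0 0 lead1", dat, format),
    sprintf("%s %d 200 12 0 0 0 0 lead2", dat, format),
    sprintf("# synthetic record %s", name)
  ), hea)
  samp <- as.integer(rbind(record$lead1, record$lead2))
  datfile <- file.path(dir, dat)
  if (format == 16L) {
    writeBin(samp, datfile, size = 2L, endian = "little")
  } else if (format == 212L) {
    if (any(samp < -2048L | samp > 2047L)) abort("format 212 needs 12-bit samples")
    u <- ifelse(samp < 0L, samp + 4096L, samp)
    s1 <- u[seq(1, length(u), 2)]
    s2 <- u[seq(2, length(u), 2)]
    b1 <- bitwAnd(s1, 0xFFL)
    b2 <- bitwOr(bitwShiftR(s1, 8), bitwShiftL(bitwShiftR(s2, 8), 4))
    b3 <- bitwAnd(s2, 0xFFL)
    writeBin(as.raw(rbind(b1, b2, b3)), datfile)
  } else {
    abort("unsupported write format")
  }
  invisible(hea)
}

#' Write a two-lead record as CSV
#'
#' @param record An [ecg_record()].
#' @param path Output file.
#' @param header Write a `lead1,lead2` header row?
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path, header = TRUE) {
  df <- data.frame(lead1 = record$lead1, lead2 = record$lead2)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!header) {
    lines <- readLines(path)
    writeLines(lines[-1], path)
  }
  invisible(path)
}

#' Shift sample values by a fixed offset
#'
#' ECG ADC values can be negative; adding a fixed offset (default +500) moves
#' them into the non-negative index range of the co-occurrence matrix. The
#' shift is exactly invertible by `shift_offset(rec, -offset)`. Values that
#' still fall outside `[0, N)` are clipped later, at matrix mapping.
#'
#' @param record An [ecg_record()].
#' @param offset Integer added to every sample of both leads.
#' @return The shifted record; `subject_id` and `fs` are unchanged.
#' @export
shift_offset <- function(record, offset = 500L) {
  record$lead1 <- as.integer(record$lead1 + offset)
  record$lead2 <- as.integer(record$lead2 + offset)
  record
}

#' Cut aligned fixed-length segments from a record
#'
#' Segments are the unit of enrollment and probing: `L` consecutive samples
#' from both leads. With `stride >= L` (the default `stride = L`) segments are
#' pairwise non-overlapping, and with `start = 1` their concatenation
#' reproduces the record prefix exactly.
#'
#' @param record An [ecg_record()].
#' @param L Segment length in samples (default 1280, i.e. 10 s at 128 Hz).
#' @param n_segments Number of segments to cut; default as many as fit.
#' @param start 1-based start index of the first segment.
#' @param stride Step between segment starts (default `L`).
#' @return A tibble of class `ecg_segments` with columns `subject_id`,
#'   `segment`, `origin` (start index) and list-columns `x1`, `x2`.
#' @export
extract_segments <- function(record, L = 1280L, n_segments = NULL, start = 1L,
                             stride = L) {
  n <- nrow(record)
  L <- as.integer(L)
  stride <- as.integer(stride)
  if (L < 1L || stride < 1L || start < 1L) abort("L, stride and start must be >= 1")
  max_fit <- if (n - start + 1L < L) 0L else (n - start + 1L - L) %/% stride + 1L
  n_segments <- n_segments %||% max_fit
  if (n_segments < 1L || n_segments > max_fit) {
    abort(sprintf(
      "record too short: %d samples cannot yield %s segments of length %d (start %d, stride %d)",
      n, as.character(n_segments), L, start, stride
    ))
  }
  origins <- start + (seq_len(n_segments) - 1L) * stride
  out <- tibble(
    subject_id = attr(record, "subject_id"),
    segment = seq_len(n_segments),
    origin = origins,
    x1 = map(origins, function(o) record$lead1[o:(o + L - 1L)]),
    x2 = map(origins, function(o) record$lead2[o:(o + L - 1L)])
  )
  attr(out, "L") <- L
  attr(out, "fs") <- attr(record, "fs")
  class(out) <- c("ecg_segments", class(out))
  out
}
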