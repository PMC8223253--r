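# Minimal EDF (16-bit European Data Format) reader/writer. Annotations travel
# in a tab-separated sidecar file (label, onset_s, duration_s, channel) rather
# than EDF+ TAL blocks. No EDF package exists in the supported library, so the
# fixed-width header and int16 payload are handled directly.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

num_field <- function(x, width = 8) {
  for (d in 7:1) {
    s <- formatC(x, format = "g", digits = d)
    if (nchar(s) <= width) return(list(str = pad_field(s, width),
                                       val = as.numeric(s)))
  }
  stop("cannot format ", x, " into ", width, " chars")
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16 bits over a symmetric per-channel physical
#' range, so the round-trip error is at most one quantization step of
#' `(physical_max - physical_min) / 2^16`. Annotations, if present, are
#' written to a sidecar `<path>.ann.tsv` (exact text round trip).
#'
#' @param recording An `eeg_recording` with at least one channel.
#' @param path Output file path.
#' @param physical_unit Unit string stored per signal (default `"uV"`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, physical_unit = "uV") {
  x <- recording$data
  if (is.null(dim(x)) || ncol(x) == 0L || nrow(x) == 0L)
    stop("cannot write an empty recording (0 channels or 0 samples)")
  fs <- recording$fs
  n <- nrow(x)
  ns <- ncol(x)
  if (abs(n / fs - round(n / fs)) < 1e-9 && n >= fs) {
    n_rec <- as.integer(round(n / fs)); spr <- as.integer(round(fs))
    rec_dur <- 1
  } else {
    n_rec <- 1L; spr <- n; rec_dur <- n / fs
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(pad_field("0", 8))
  wr(pad_field("X X X X", 80))
  wr(pad_field("Startdate 01-JAN-2000 X X X", 80))
  wr(pad_field("01.01.00", 8))
  wr(pad_field("00.00.00", 8))
  wr(pad_field(256 + 256 * ns, 8))
  wr(pad_field("", 44))
  wr(pad_field(n_rec, 8))
  wr(num_field(rec_dur)$str)
  wr(pad_field(ns, 4))
  pmin <- pmax <- dmin <- dmax <- numeric(ns)
  for (j in seq_len(ns)) {
    r <- max(abs(x[, j]), 1e-6)
    fld <- num_field(r * 1.0001)
    pmax[j] <- fld$val; pmin[j] <- -fld$val
    dmin[j] <- -32768; dmax[j] <- 32767
  }
  for (j in seq_len(ns)) wr(pad_field(recording$channel_names[j], 16))
  for (j in seq_len(ns)) wr(pad_field("", 80))
  for (j in seq_len(ns)) wr(pad_field(physical_unit, 8))
  for (j in seq_len(ns)) wr(num_field(pmin[j])$str)
  for (j in seq_len(ns)) wr(num_field(pmax[j])$str)
  for (j in seq_len(ns)) wr(pad_field(format(dmin[j]), 8))
  for (j in seq_len(ns)) wr(pad_field(format(dmax[j]), 8))
  for (j in seq_len(ns)) wr(pad_field("", 80))
  for (j in seq_len(ns)) wr(pad_field(spr, 8))
  for (j in seq_len(ns)) wr(pad_field("", 32))
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (j in seq_len(ns)) {
      d <- round((x[idx, j] - pmin[j]) / scale[j] + dmin[j])
      d <- pmin(pmax(d, dmin[j]), dmax[j])
      writeBin(as.integer(d), con, size = 2, endian = "little")
    }
  }
  if (nrow(recording$annotations))
    write_annotations_tsv(recording$annotations, paste0(path, ".ann.tsv"))
  invisible(path)
}

#' Read an EDF file
#'
#' Reads a 16-bit EDF file written by [write_edf()] (or any single-rate EDF).
#' A sidecar `<path>.ann.tsv` annotation file is loaded when present.
#'
#' @param path EDF file path.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) {
    out <- readChar(con, nc, useBytes = TRUE)
    if (nchar(out, type = "bytes") < nc) stop("malformed EDF header: truncated")
    out
  }
  version <- trimws(rd(8))
  if (version != "0") stop("malformed EDF header: version '", version, "'")
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(trimws(rd(8)))
  rd(44)
  n_rec <- as.integer(trimws(rd(8)))
  rec_dur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  if (is.na(ns) || ns < 1) stop("malformed EDF header: bad signal count")
  rdn <- function(width) vapply(seq_len(ns), function(j) trimws(rd(width)),
                                character(1))
  labels <- rdn(16)
  rdn(80)
  rdn(8)
  pmin <- as.numeric(rdn(8)); pmax <- as.numeric(rdn(8))
  dmin <- as.numeric(rdn(8)); dmax <- as.numeric(rdn(8))
  rdn(80)
  spr <- as.integer(rdn(8))
  rdn(32)
  if (anyDuplicated(labels))
    stop("duplicate channel labels in EDF: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (length(unique(spr)) != 1L)
    stop("unsupported EDF: signals with different sampling rates")
  if (is.na(header_bytes) || header_bytes != 256 + 256 * ns)
    stop("malformed EDF header: header byte count mismatch")
  spr1 <- spr[1]
  fs <- spr1 / rec_dur
  scale <- (pmax - pmin) / (dmax - dmin)
  data <- matrix(0, nrow = n_rec * spr1, ncol = ns)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr1 + 1):(r * spr1)
    for (j in seq_len(ns)) {
      d <- readBin(con, integer(), n = spr1, size = 2, endian = "little")
      if (length(d) < spr1) stop("malformed EDF: truncated data record")
      data[idx, j] <- (d - dmin[j]) * scale[j] + pmin[j]
    }
  }
  ann_path <- paste0(path, ".ann.tsv")
  ann <- if (file.exists(ann_path)) read_annotations_tsv(ann_path) else NULL
  eeg_recording(data, labels, fs, ann)
}

#' Annotation sidecar files
#'
#' Tab-separated annotation tables (`label`, `onset_s`, `duration_s`,
#' `channel`). Numeric columns are serialised with 17 significant digits so
#' doubles round-trip exactly.
#'
#' @param annotations Annotation data.frame.
#' @param path File path.
#' @return `read_annotations_tsv` returns the annotation data.frame.
#' @export
write_annotations_tsv <- function(annotations, path) {
  out <- data.frame(label = annotations$label,
                    onset_s = sprintf("%.17g", annotations$onset_s),
                    duration_s = sprintf("%.17g", annotations$duration_s),
                    channel = annotations$channel)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations_tsv
#' @export
read_annotations_tsv <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "numeric", "numeric",
                                   "character"))
  names(ann) <- c("label", "onset_s", "duration_s", "channel")
  ann
}
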