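## BioSemi BDF: the 24-bit variant of the European Data Format.
## Layout: 256-byte main header, 256 bytes per channel, then data records;
## within a record, channel blocks of ns samples, each sample 3 bytes
## little-endian two's complement. Physical calibration per channel via
## (physical_min/max, digital_min/max).

.BDF_DIG_MIN <- -8388608
.BDF_DIG_MAX <- 8388607
.BDF_PHYS_MIN <- -262144
.BDF_PHYS_MAX <- 262143

.pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

.num_field <- function(x, width) {
  s <- format(x, trim = TRUE, scientific = FALSE, digits = 15)
  if (nchar(s) > width)
    stop("numeric header field does not fit in ", width, " bytes: ", s)
  .pad_field(s, width)
}

## raw (3 bytes/sample, LE) -> signed integer vector
.decode24 <- function(raw3) {
  m <- matrix(as.integer(raw3), nrow = 3)
  v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
  ifelse(v >= 8388608, v - 16777216, v)
}

## signed integer vector -> raw (3 bytes/sample, LE)
.encode24 <- function(d) {
  v <- ifelse(d < 0, d + 16777216, d)
  out <- integer(3 * length(v))
  out[seq(1, length(out), 3)] <- v %% 256
  out[seq(2, length(out), 3)] <- (v %/% 256) %% 256
  out[seq(3, length(out), 3)] <- (v %/% 65536) %% 256
  as.raw(out)
}

#' Write a recording as a BioSemi BDF file
#'
#' Produces a bit-valid BDF: 8-byte magic (0xFF then `"BIOSEMI"`), a
#' 256-byte main header plus 256 bytes per channel, and 24-bit
#' little-endian two's-complement samples in fixed-duration data records.
#' Calibration is fixed at digital -8388608..8388607 over physical
#' -262144..262143 microvolts (about 0.03 uV per LSB). Records are 1 s
#' long when the sample count divides evenly by `fs`; otherwise a single
#' record spanning the whole signal is written.
#'
#' @param recording a [SWRecording-class]; all values must lie within the
#'   representable physical range.
#' @param path output file path.
#' @return the path, invisibly.
#' @seealso [readBDF()]
#' @export
writeBDF <- function(recording, path) {
  stopifnot(is(recording, "SWRecording"))
  x <- recording@samples
  nch <- nrow(x)
  ns_total <- ncol(x)
  fs <- recording@fs
  out_of_range <- which(x < .BDF_PHYS_MIN | x > .BDF_PHYS_MAX, arr.ind = TRUE)
  if (nrow(out_of_range))
    stop(sprintf(
      "value outside physical range [%d, %d] uV at channel %d, sample %d",
      .BDF_PHYS_MIN, .BDF_PHYS_MAX, out_of_range[1, 1], out_of_range[1, 2]))

  if (fs == round(fs) && ns_total %% fs == 0) {
    spr <- as.integer(fs)          # 1 s records
    n_rec <- ns_total %/% spr
    dur <- 1
  } else {
    spr <- ns_total                # single record
    n_rec <- 1L
    dur <- ns_total / fs
  }

  gain <- (.BDF_PHYS_MAX - .BDF_PHYS_MIN) / (.BDF_DIG_MAX - .BDF_DIG_MIN)
  dig <- round((x - .BDF_PHYS_MIN) / gain) + .BDF_DIG_MIN
  dig <- pmin(pmax(dig, .BDF_DIG_MIN), .BDF_DIG_MAX)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(0xFF), con)
  writeChar("BIOSEMI", con, nchars = 7, eos = NULL)
  writeChar(.pad_field("gastroMap", 80), con, eos = NULL)        # patient id
  writeChar(.pad_field("gastroMap recording", 80), con, eos = NULL)
  writeChar(.pad_field("01.01.00", 8), con, eos = NULL)          # start date
  writeChar(.pad_field("00.00.00", 8), con, eos = NULL)          # start time
  writeChar(.num_field(256 * (nch + 1), 8), con, eos = NULL)
  writeChar(.pad_field("24BIT", 44), con, eos = NULL)
  writeChar(.num_field(n_rec, 8), con, eos = NULL)
  writeChar(.num_field(dur, 8), con, eos = NULL)
  writeChar(.num_field(nch, 4), con, eos = NULL)

  per <- function(vals, width)
    writeChar(paste0(vapply(vals, .pad_field, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  per(recording@channelIds, 16)
  per(rep("", nch), 80)                                # transducer
  per(rep("uV", nch), 8)
  per(rep(format(.BDF_PHYS_MIN), nch), 8)
  per(rep(format(.BDF_PHYS_MAX), nch), 8)
  per(rep(format(.BDF_DIG_MIN), nch), 8)
  per(rep(format(.BDF_DIG_MAX), nch), 8)
  per(rep("", nch), 80)                                # prefiltering
  per(rep(format(spr), nch), 8)
  per(rep("", nch), 32)

  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    block <- t(dig[, cols, drop = FALSE])              # channel-major order
    writeBin(.encode24(as.vector(block)), con)
  }
  invisible(path)
}

#' Read a BioSemi BDF file
#'
#' Parses the BioSemi 24-bit dialect only: files whose identification bytes
#' are not `0xFF` + `"BIOSEMI"` (for instance 16-bit EDF) are rejected, not
#' guessed at. Samples are scaled to physical units (microvolts) using the
#' per-channel calibration fields and data records are concatenated in
#' order. All channels must share one sampling rate.
#'
#' @param path path to a `.bdf` file.
#' @return a [SWRecording-class].
#' @seealso [writeBDF()]
#' @export
readBDF <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  if (length(magic) < 8 || magic[1] != as.raw(0xFF) ||
      rawToChar(magic[2:8]) != "BIOSEMI")
    stop("not a BioSemi BDF file (bad magic): ", path)
  rd <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd(80); rd(80); rd(8); rd(8)                     # ids, date, time
  header_bytes <- as.numeric(rd(8))
  version <- rd(44)
  if (!grepl("24BIT", version))
    stop("unsupported BDF data-format version: '", version, "'")
  n_rec <- as.numeric(rd(8))
  dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  if (is.na(nch) || nch < 1) stop("invalid channel count in header")
  if (!is.na(header_bytes) && header_bytes != 256 * (nch + 1))
    stop("inconsistent header size field")

  rdv <- function(width) {
    raw <- readBin(con, "raw", width * nch)
    vapply(seq_len(nch), function(i)
      trimws(rawToChar(raw[((i - 1) * width + 1):(i * width)])),
      character(1))
  }
  labels <- rdv(16)
  rdv(80); rdv(8)                                  # transducer, dimension
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin_ <- as.numeric(rdv(8)); dmax_ <- as.numeric(rdv(8))
  rdv(80)                                          # prefiltering
  spr <- as.integer(rdv(8))
  rdv(32)                                          # reserved

  if (any(pmin_ == pmax_)) stop("degenerate calibration: physical_min == physical_max")
  if (any(dmin_ == dmax_)) stop("degenerate calibration: digital_min == digital_max")
  if (length(unique(spr)) != 1L)
    stop("mixed per-channel sampling rates are unsupported")
  spr <- spr[1L]
  if (dur <= 0) stop("invalid record duration")
  fs <- spr / dur

  rec_bytes <- 3 * spr * nch
  payload <- readBin(con, "raw", n = rec_bytes * max(n_rec, 0) + rec_bytes)
  n_complete <- length(payload) %/% rec_bytes
  if (n_rec >= 0 && n_complete < n_rec)
    stop(sprintf(
      "truncated BDF: header promises %d data records, last complete record is %d",
      as.integer(n_rec), n_complete))
  n_use <- if (n_rec >= 0) as.integer(n_rec) else n_complete
  if (n_use < 1) stop("BDF file contains no complete data record")

  x <- matrix(0, nrow = nch, ncol = n_use * spr)
  for (r in seq_len(n_use)) {
    off <- (r - 1) * rec_bytes
    d <- .decode24(payload[(off + 1):(off + rec_bytes)])
    block <- matrix(d, nrow = spr, ncol = nch)     # channel-major in record
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    x[, cols] <- t(block)
  }
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  x <- (x - dmin_) * gain + pmin_
  if (anyDuplicated(labels))
    labels <- make.unique(labels)
  swRecording(x, fs = fs, channelIds = labels)
}
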