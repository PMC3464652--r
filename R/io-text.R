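#' Read signals from a delimited text file
#'
#' Imports a rectangular numeric table as a recording. Orientation is
#' explicit: `channels = "rows"` (default) reads one channel per line,
#' `channels = "cols"` one channel per column. With `header = TRUE` the
#' first line (or column, for `channels = "cols"` the first row is still
#' the header) supplies channel labels.
#'
#' @param path input file.
#' @param fs sampling rate in Hz (the text format carries none).
#' @param delimiter field separator; default any whitespace.
#' @param channels `"rows"` or `"cols"`.
#' @param header logical; take channel labels from the first line.
#' @return a [SWRecording-class].
#' @seealso [writeTextSignals()]
#' @export
readTextSignals <- function(path, fs, delimiter = "", channels = "rows",
                            header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  channels <- match.arg(channels, c("rows", "cols"))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty signal file: ", path)
  splitf <- function(ln)
    if (nzchar(delimiter)) strsplit(ln, delimiter, fixed = TRUE)[[1L]]
    else strsplit(trimws(ln), "[[:space:]]+")[[1L]]
  cells <- lapply(lines, splitf)
  labels <- NULL
  if (header) {
    labels <- trimws(cells[[1L]])
    cells <- cells[-1L]
    if (!length(cells)) stop("signal file has a header but no data rows")
  }
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L)
    stop(sprintf("ragged rows: line %d has %d fields, expected %d",
                 which(widths != widths[1L])[1L] + as.integer(header),
                 widths[widths != widths[1L]][1L], widths[1L]))
  m <- matrix(NA_real_, nrow = length(cells), ncol = widths[1L])
  for (i in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(cells[[i]]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop(sprintf("non-numeric cell '%s' at row %d, column %d",
                   cells[[i]][j], i + as.integer(header), j))
    }
    m[i, ] <- v
  }
  if (channels == "cols") m <- t(m)
  ## a header line names the channels: columns for channels="cols",
  ## otherwise it is only usable when one label per channel row was given
  if (!is.null(labels) && length(labels) != nrow(m))
    stop(sprintf("header has %d labels for %d channels",
                 length(labels), nrow(m)))
  swRecording(m, fs = fs, channelIds = labels)
}

#' Write recording samples as delimited text
#'
#' One channel per row, tab-delimited, full double precision; a header
#' line of channel labels is written when `header = TRUE`. The output
#' re-parses exactly through [readTextSignals()].
#'
#' @param recording a [SWRecording-class].
#' @param path output file.
#' @param header write a channel-label header line (only meaningful with
#'   `channels = "cols"` on re-import; default `FALSE`).
#' @return the path, invisibly.
#' @export
writeTextSignals <- function(recording, path, header = FALSE) {
  x <- recording@samples
  con <- file(path, "w")
  on.exit(close(con))
  if (header)
    writeLines(paste(recording@channelIds, collapse = "\t"), con)
  apply_fmt <- function(row)
    paste(formatC(row, format = "g", digits = 17), collapse = "\t")
  writeLines(vapply(seq_len(nrow(x)), function(i) apply_fmt(x[i, ]),
                    character(1)), con)
  invisible(path)
}
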