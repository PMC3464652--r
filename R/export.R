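## Tab-delimited text export of analysis products, one documented header
## line per file. Statistical exports carry non-interpolated values only.

.fmt_num <- function(x) {
  vapply(x, function(v)
    if (is.na(v)) "NA" else sprintf("%.17g", v), character(1))
}

.write_table <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cols <- lapply(df, function(col)
      if (is.numeric(col)) .fmt_num(col) else as.character(col))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Export analysis products as tab-delimited text
#'
#' Writes one product per call with a single header line of column names.
#' Interpolated values are excluded from statistical exports; for the
#' activation table, `include_interpolated = TRUE` keeps them and adds a
#' `flag` column distinguishing measured from interpolated sites. The
#' marks dialect is one row per mark: `channel_id`, `row`, `col`,
#' `time_s`, `cycle_or_orphan`.
#'
#' @param session an [AnalysisSession-class].
#' @param what `"marks"`, `"activation"`, `"amplitude"`, `"velocity"` or
#'   `"intervals"`.
#' @param path output file.
#' @param include_interpolated keep interpolated activation sites
#'   (flagged) in the activation table.
#' @return the path, invisibly.
#' @export
exportText <- function(session, what, path, include_interpolated = FALSE) {
  what <- match.arg(what, c("marks", "activation", "amplitude",
                            "velocity", "intervals"))
  if (is.null(session@marks))
    stop("cannot export ", what, ": the detection stage has not run")
  marks <- session@marks
  layout <- session@layout
  m <- marks@marks
  pos <- .layout_pos(layout, m$channel)
  if (what == "marks") {
    cyc <- if (!is.null(session@assignment)) {
      ifelse(is.na(session@assignment@cycle), "orphan",
             as.character(session@assignment@cycle))
    } else rep("unclustered", nrow(m))
    return(.write_table(data.frame(
      channel_id = m$channel, row = pos$row, col = pos$col,
      time_s = m$time, cycle_or_orphan = cyc,
      stringsAsFactors = FALSE), path))
  }
  if (is.null(session@assignment))
    stop("cannot export ", what, ": the clustering stage has not run")
  assignment <- session@assignment
  if (assignment@nCycles < 1L)
    stop("cannot export ", what, ": clustering produced no cycles")
  params <- session@params
  grid_rows <- function(grid_mat, flag_mat, value_name) {
    idx <- which(!is.na(grid_mat), arr.ind = TRUE)
    df <- data.frame(row = idx[, 1] - 1L, col = idx[, 2] - 1L,
                     value = grid_mat[idx], flag = flag_mat[idx],
                     stringsAsFactors = FALSE)
    names(df)[3] <- value_name
    df
  }
  out <- list()
  if (what == "activation") {
    for (k in seq_len(assignment@nCycles)) {
      amap <- buildActivationMap(assignment, marks, layout, k)
      if (include_interpolated)
        amap <- sivInterpolate(amap, param(params, "siv.k1"),
                               param(params, "siv.k2"))
      df <- grid_rows(amap@times, amap@flags, "time_s")
      if (!include_interpolated) {
        df <- df[df$flag == "measured", , drop = FALSE]
        df$flag <- NULL
      }
      if (nrow(df)) df <- cbind(cycle = k, df)
      out[[k]] <- df
    }
  } else if (what == "amplitude") {
    rec <- session@recording
    for (k in seq_len(assignment@nCycles)) {
      am <- buildAmplitudeMap(assignment, marks, layout, rec, k, params)
      df <- grid_rows(am@amplitude, am@confidence, "amplitude_uv")
      names(df)[4] <- "confidence"
      if (nrow(df)) df <- cbind(cycle = k, df)
      out[[k]] <- df
    }
  } else if (what == "velocity") {
    for (k in seq_len(assignment@nCycles)) {
      amap <- buildActivationMap(assignment, marks, layout, k)
      vf <- tryCatch(
        computeVelocityField(amap,
          sigma_sites = param(params, "velocity.sigma_sites"),
          min_grad = param(params, "velocity.min_grad_s_mm"),
          use_interpolated = FALSE),
        error = function(e) NULL)
      if (is.null(vf)) next
      idx <- which(vf@flags == "defined", arr.ind = TRUE)
      if (!nrow(idx)) next
      out[[length(out) + 1L]] <- data.frame(
        cycle = k, row = idx[, 1] - 1L, col = idx[, 2] - 1L,
        vx_mm_s = vf@vx[idx], vy_mm_s = vf@vy[idx],
        speed_mm_s = vf@speed[idx], stringsAsFactors = FALSE)
    }
  } else if (what == "intervals") {
    if (assignment@nCycles < 2L)
      stop("cannot export intervals: need at least 2 cycles")
    ivs <- computeIntervals(assignment, marks, layout,
                            bounds_cpm = c(param(params, "intervals.brady_cpm"),
                                           param(params, "intervals.tachy_cpm")))
    for (im in ivs) {
      idx <- which(!is.na(im@intervals), arr.ind = TRUE)
      if (!nrow(idx)) next
      out[[length(out) + 1L]] <- data.frame(
        pair = im@pair[1L], row = idx[, 1] - 1L, col = idx[, 2] - 1L,
        interval_s = im@intervals[idx], freq_cpm = im@freqCpm[idx],
        class = im@siteClass[idx], stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  out <- out[vapply(out, nrow, integer(1)) > 0L]
  df <- if (length(out)) do.call(rbind, out) else
    stop("cannot export ", what, ": no defined values")
  .write_table(df, path)
}

#' Re-parse a marks text export
#'
#' Inverse of `exportText(session, "marks", ...)`; round-trips the mark
#' table exactly.
#'
#' @param path a marks export file.
#' @return data.frame with the export's columns.
#' @export
readMarksExport <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(channel_id = "character",
                                   cycle_or_orphan = "character"))
}
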