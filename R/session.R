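.SESSION_FORMAT <- "gastroMap-session"
.SESSION_VERSION <- 1L

#' Bundle the pieces of an analysis into a session
#'
#' @param recording the (filtered) [SWRecording-class].
#' @param layout an [ElectrodeLayout-class].
#' @param params a [ParameterSet-class].
#' @param marks optional [EventMarks-class].
#' @param assignment optional [CycleAssignment-class].
#' @return an [AnalysisSession-class].
#' @export
analysisSession <- function(recording, layout, params = defaultParameters(),
                            marks = NULL, assignment = NULL) {
  new("AnalysisSession", recording = recording, layout = layout,
      params = params, marks = marks, assignment = assignment,
      provenance = list(
        tool = "gastroMap",
        tool_version = as.character(utils::packageVersion("gastroMap")),
        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
}

#' Save / load an analysis session
#'
#' The session archive is a single versioned JSON file holding the
#' filtered samples at full double precision, the layout, parameters,
#' marks and cycle assignment: reloading reproduces every downstream
#' product identically. A version mismatch or corrupted payload raises an
#' error; a load never succeeds partially.
#'
#' @param session an [AnalysisSession-class].
#' @param path file path.
#' @return `loadSession` returns the [AnalysisSession-class].
#' @export
saveSession <- function(session, path) {
  r <- session@recording
  payload <- list(
    format = .SESSION_FORMAT, version = .SESSION_VERSION,
    provenance = session@provenance,
    recording = list(samples = unname(split(r@samples, row(r@samples))),
                     fs = r@fs, channel_ids = r@channelIds, t0 = r@t0,
                     channel_status = r@channelStatus),
    layout = list(grid_shape = session@layout@gridShape,
                  spacing_mm = session@layout@spacingMm,
                  orientation_deg = session@layout@orientationDeg,
                  placement = session@layout@placement),
    params = session@params@values,
    marks = if (!is.null(session@marks)) session@marks@marks,
    assignment = if (!is.null(session@assignment))
      list(cycle = session@assignment@cycle,
           n_cycles = session@assignment@nCycles))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                              na = "null", dataframe = "columns"), path)
  invisible(path)
}

#' @rdname saveSession
#' @export
loadSession <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("corrupted session file: ", conditionMessage(e)))
  if (!identical(obj$format, .SESSION_FORMAT))
    stop("not a gastroMap session file: ", path)
  if (!identical(as.integer(obj$version), .SESSION_VERSION))
    stop(sprintf("session version mismatch: file has %s, this build reads %d",
                 obj$version, .SESSION_VERSION))
  smp <- obj$recording$samples
  if (is.list(smp)) smp <- do.call(rbind, smp)
  rec <- swRecording(smp,
                     fs = obj$recording$fs,
                     channelIds = obj$recording$channel_ids,
                     t0 = obj$recording$t0,
                     channelStatus = obj$recording$channel_status)
  layout <- electrodeLayout(obj$layout$grid_shape,
                            as.data.frame(obj$layout$placement),
                            obj$layout$spacing_mm, obj$layout$orientation_deg)
  params <- parameterSet(.coerce_param_types(obj$params))
  marks <- if (!is.null(obj$marks) && length(obj$marks)) {
    md <- as.data.frame(obj$marks)
    md$channel <- as.character(md$channel)
    md$time <- as.numeric(md$time)
    md$source <- as.character(md$source)
    md$score <- as.numeric(md$score)
    new("EventMarks", marks = md)
  }
  assignment <- if (!is.null(obj$assignment) && length(obj$assignment))
    new("CycleAssignment",
        cycle = as.integer(obj$assignment$cycle),
        nCycles = as.integer(obj$assignment$n_cycles))
  s <- analysisSession(rec, layout, params, marks, assignment)
  s@provenance <- c(obj$provenance,
                    list(reloaded_from = basename(path)))
  s
}
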