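#' Run the analysis pipeline end to end
#'
#' Chains the three stages -- pre-processing, processing (detection +
#' clustering) and post-processing (maps, exports, animation) -- over a
#' recording, writing a session file, the requested text exports, rendered
#' maps and a machine-readable run log listing every effective parameter.
#' Identical inputs, parameters and seed produce byte-identical text
#' exports.
#'
#' @param recording a [SWRecording-class], or a path to a `.bdf` or
#'   delimited-text file (text needs `text_fs`).
#' @param layout an [ElectrodeLayout-class] or a layout file path.
#' @param params a [ParameterSet-class] or a parameter file path.
#' @param stages subset of `c("preprocess", "detect", "cluster", "maps",
#'   "animate")`, executed in that order.
#' @param out_dir output directory (created if absent).
#' @param text_fs sampling rate for text-format recordings.
#' @param session_in optional session file to resume from (skips the
#'   stages already present in it).
#' @param seed RNG seed recorded in the run log (the pipeline itself is
#'   deterministic; the seed matters when the recording comes from
#'   [generateRecording()] upstream).
#' @return the final [AnalysisSession-class], invisibly.
#' @export
runPipeline <- function(recording = NULL, layout = NULL,
                        params = defaultParameters(),
                        stages = c("preprocess", "detect", "cluster", "maps"),
                        out_dir = ".", text_fs = NULL, session_in = NULL,
                        seed = NULL) {
  stages <- match.arg(stages, c("preprocess", "detect", "cluster",
                                "maps", "animate"), several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(params)) params <- loadParameters(params)
  marks <- NULL; assignment <- NULL
  if (!is.null(session_in)) {
    ses <- loadSession(session_in)
    rec <- ses@recording; lay <- ses@layout
    marks <- ses@marks; assignment <- ses@assignment
  } else {
    if (is.null(recording) || is.null(layout))
      stop("stage 'input' failed: need a recording and a layout (or session_in)")
    rec <- if (is.character(recording)) {
      if (grepl("\\.bdf$", recording, ignore.case = TRUE)) readBDF(recording)
      else {
        if (is.null(text_fs))
          stop("stage 'input' failed: text recordings need text_fs")
        readTextSignals(recording, fs = text_fs)
      }
    } else recording
    lay <- if (is.character(layout)) loadLayout(layout) else layout
  }

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  if ("preprocess" %in% stages)
    rec <- run_stage("preprocess", preprocessDefault(rec, params))
  if ("detect" %in% stages)
    marks <- run_stage("detect", fevtDetect(rec, lay, params))
  if ("cluster" %in% stages) {
    if (is.null(marks))
      stop("stage 'cluster' requires marks: run the detect stage first")
    assignment <- run_stage("cluster", regroupsCluster(marks, lay, params))
  }
  session <- analysisSession(rec, lay, params, marks, assignment)
  if ("maps" %in% stages) {
    if (is.null(marks))
      stop("stage 'maps' requires marks: run the detect stage first")
    if (is.null(assignment))
      stop("stage 'maps' requires cycles: run the cluster stage first")
    run_stage("maps", {
      exportText(session, "marks", file.path(out_dir, "marks.tsv"))
      exportText(session, "activation", file.path(out_dir, "activation.tsv"))
      exportText(session, "velocity", file.path(out_dir, "velocity.tsv"))
      exportText(session, "amplitude", file.path(out_dir, "amplitude.tsv"))
      if (assignment@nCycles >= 2L)
        exportText(session, "intervals", file.path(out_dir, "intervals.tsv"))
      map_dir <- file.path(out_dir, "maps")
      dir.create(map_dir, showWarnings = FALSE)
      style <- mapStyle(isochrone_interval_s =
                          param(params, "map.isochrone_interval_s"))
      for (k in seq_len(min(assignment@nCycles, 12L))) {
        amap <- buildActivationMap(assignment, marks, lay, k)
        if (isTRUE(param(params, "map.use_interpolated")))
          amap <- sivInterpolate(amap, param(params, "siv.k1"),
                                 param(params, "siv.k2"))
        renderMap(amap, file.path(map_dir, sprintf("activation_%02d.png", k)),
                  style)
        vf <- tryCatch(computeVelocityField(amap,
                sigma_sites = param(params, "velocity.sigma_sites"),
                min_grad = param(params, "velocity.min_grad_s_mm")),
              error = function(e) NULL)
        if (!is.null(vf) && any(vf@flags == "defined"))
          renderMap(vf, file.path(map_dir, sprintf("velocity_%02d.png", k)),
                    style)
      }
    })
  }
  if ("animate" %in% stages) {
    if (is.null(marks))
      stop("stage 'animate' requires marks: run the detect stage first")
    run_stage("animate", {
      tr <- range(marks@marks$time)
      renderAnimation(marks, lay, file.path(out_dir, "animation"),
                      assignment = assignment,
                      fps = param(params, "animation.fps"),
                      tail_s = param(params, "animation.tail_s"),
                      t_start = tr[1], t_end = min(tr[2], tr[1] + 60))
    })
  }
  saveSession(session, file.path(out_dir, "session.json"))
  log <- list(tool = "gastroMap",
              tool_version = as.character(utils::packageVersion("gastroMap")),
              stages = stages, seed = seed,
              parameters = params@values,
              n_channels = nrow(rec@samples), fs = rec@fs,
              n_marks = if (!is.null(marks)) nrow(marks@marks) else 0L,
              n_cycles = if (!is.null(assignment)) assignment@nCycles else 0L)
  writeLines(jsonlite::toJSON(log, auto_unbox = TRUE, digits = I(17),
                              pretty = TRUE, null = "null"),
             file.path(out_dir, "run_log.json"))
  invisible(session)
}

#' Write a synthetic scenario to disk as recording + truth table
#'
#' Convenience wrapper used by the command-line `simulate` subcommand:
#' generates the scenario, writes the recording as BDF and the
#' ground-truth marks as a tab-delimited table, and saves the matching
#' layout file.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param out_bdf recording output path.
#' @param out_truth truth-table output path (TSV).
#' @param out_layout layout output path (JSON).
#' @return the generated list from [generateRecording()], invisibly.
#' @export
simulateToFiles <- function(scenario, out_bdf, out_truth = NULL,
                            out_layout = NULL) {
  gen <- generateRecording(scenario)
  writeBDF(gen$recording, out_bdf)
  if (!is.null(out_truth))
    .write_table(gen$truth$marks, out_truth)
  if (!is.null(out_layout))
    saveLayout(gen$layout, out_layout)
  invisible(gen)
}
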