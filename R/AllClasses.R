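#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Multi-electrode extracellular recording
#'
#' A `SWRecording` holds a dense channels-by-samples matrix of extracellular
#' potentials in microvolts together with the sampling rate, ordered channel
#' labels, a start offset and a per-channel status flag. Channels flagged
#' `"excluded"` are passed through filters untouched, skipped by event
#' detection and treated as missing sites by mapping.
#'
#' @slot samples numeric matrix, `n_channels x n_samples`, in microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelIds character vector of unique channel labels (row order).
#' @slot t0 recording start offset in seconds (sample 1 is at `t0`).
#' @slot channelStatus character vector, `"ok"` or `"excluded"` per channel.
#'
#' @seealso [swRecording()], [readBDF()], [readTextSignals()]
#' @export
setClass("SWRecording",
  representation(
    samples = "matrix",
    fs = "numeric",
    channelIds = "character",
    t0 = "numeric",
    channelStatus = "character"
  )
)

setValidity("SWRecording", function(object) {
  msg <- character()
  s <- object@samples
  if (!is.numeric(s)) msg <- c(msg, "samples must be a numeric matrix")
  if (nrow(s) < 1L || ncol(s) < 1L)
    msg <- c(msg, "recording must have at least one channel and one sample")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single finite positive number")
  if (length(object@channelIds) != nrow(s))
    msg <- c(msg, "channelIds length must equal number of channels")
  if (anyDuplicated(object@channelIds))
    msg <- c(msg, "channelIds must be unique")
  if (length(object@channelStatus) != nrow(s) ||
      !all(object@channelStatus %in% c("ok", "excluded")))
    msg <- c(msg, "channelStatus must be 'ok' or 'excluded' for every channel")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msg <- c(msg, "t0 must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Electrode grid layout
#'
#' Maps channel labels to sites of a rectangular recording array. Grid
#' indices are 0-based and row-major; row 0 is displayed at the top.
#' `orientationDeg` rotates rendered maps only and never enters any
#' computation.
#'
#' @slot gridShape integer vector `(n_rows, n_cols)`.
#' @slot placement data.frame with columns `channel`, `row`, `col`
#'   (0-based indices into the grid).
#' @slot spacingMm inter-electrode distance in millimetres.
#' @slot orientationDeg display rotation in degrees.
#'
#' @seealso [gridLayout()], [loadLayout()]
#' @export
setClass("ElectrodeLayout",
  representation(
    gridShape = "integer",
    placement = "data.frame",
    spacingMm = "numeric",
    orientationDeg = "numeric"
  )
)

setValidity("ElectrodeLayout", function(object) {
  msg <- character()
  gs <- object@gridShape
  p <- object@placement
  if (length(gs) != 2L || any(gs < 1L))
    msg <- c(msg, "gridShape must be two positive integers")
  need <- c("channel", "row", "col")
  if (!all(need %in% names(p)))
    msg <- c(msg, "placement needs columns channel, row, col")
  else {
    if (anyDuplicated(p$channel))
      msg <- c(msg, "duplicate channel in placement")
    if (anyDuplicated(p[, c("row", "col")]))
      msg <- c(msg, "duplicate grid site: at most one channel per site")
    if (nrow(p) && (any(p$row < 0L) || any(p$col < 0L) ||
        any(p$row >= gs[1L]) || any(p$col >= gs[2L])))
      msg <- c(msg, "placement outside gridShape")
  }
  if (length(object@spacingMm) != 1L || !is.finite(object@spacingMm) ||
      object@spacingMm <= 0)
    msg <- c(msg, "spacingMm must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Activation-time marks
#'
#' Per-channel sorted slow-wave activation times, each flagged as
#' automatically detected or manually placed, with the detector score
#' (peak detection-signal-to-threshold ratio) where available.
#'
#' @slot marks data.frame with columns `channel` (label), `time` (seconds),
#'   `source` (`"auto"` or `"manual"`) and `score` (unitless, `>= 0`;
#'   `NA` for manual marks).
#'
#' @seealso [fevtDetect()], [editMarks()]
#' @export
setClass("EventMarks", representation(marks = "data.frame"))

setValidity("EventMarks", function(object) {
  m <- object@marks
  need <- c("channel", "time", "source", "score")
  if (!all(need %in% names(m)))
    return("marks needs columns channel, time, source, score")
  if (nrow(m)) {
    if (!all(m$source %in% c("auto", "manual")))
      return("source must be 'auto' or 'manual'")
    if (any(!is.finite(m$time)))
      return("mark times must be finite")
    bad <- vapply(split(m$time, m$channel),
                  function(t) is.unsorted(t, strictly = TRUE), logical(1))
    if (any(bad))
      return("mark times must be strictly increasing within each channel")
  }
  TRUE
})

#' Assignment of marks to wavefront cycles
#'
#' Maps every mark of an [EventMarks-class] table to a 1-based cycle index
#' or to the orphan pool (`NA`). Cycle numbering is ordered by mean member
#' activation time and each cycle holds at most one mark per channel.
#'
#' @slot cycle integer vector parallel to the mark table rows; `NA` marks
#'   an orphan.
#' @slot nCycles number of cycles.
#'
#' @seealso [regroupsCluster()], [editCluster()]
#' @export
setClass("CycleAssignment",
  representation(cycle = "integer", nCycles = "integer"))

setValidity("CycleAssignment", function(object) {
  cy <- object@cycle
  n <- object@nCycles
  if (length(n) != 1L || is.na(n) || n < 0L)
    return("nCycles must be a single non-negative integer")
  if (length(cy) && any(!is.na(cy) & (cy < 1L | cy > n)))
    return("cycle indices must be in 1..nCycles or NA (orphan)")
  TRUE
})

#' Per-cycle activation-time grid
#'
#' Activation times of one wavefront placed on the electrode grid, with a
#' per-site flag distinguishing measured marks, SIV-interpolated values and
#' missing sites.
#'
#' @slot times numeric matrix (seconds), `NA` where missing.
#' @slot flags character matrix, `"measured"`, `"interpolated"` or `"missing"`.
#' @slot cycle the 1-based cycle index this map belongs to.
#' @slot spacingMm electrode spacing carried over from the layout.
#'
#' @seealso [buildActivationMap()], [sivInterpolate()]
#' @export
setClass("ActivationMap",
  representation(times = "matrix", flags = "matrix",
                 cycle = "integer", spacingMm = "numeric"))

setValidity("ActivationMap", function(object) {
  if (!identical(dim(object@times), dim(object@flags)))
    return("times and flags must have identical dimensions")
  if (!all(object@flags %in% c("measured", "interpolated", "missing")))
    return("flags must be measured/interpolated/missing")
  if (any(is.na(object@times[object@flags != "missing"])))
    return("non-missing sites must carry a time")
  TRUE
})

#' Per-cycle conduction-velocity field
#'
#' @slot vx,vy velocity components in mm/s (`NA` where undefined).
#' @slot speed speed in mm/s, `sqrt(vx^2 + vy^2)`.
#' @slot flags character matrix, `"defined"` or `"undefined"`.
#' @slot cycle cycle index.
#'
#' @seealso [computeVelocityField()]
#' @export
setClass("VelocityField",
  representation(vx = "matrix", vy = "matrix", speed = "matrix",
                 flags = "matrix", cycle = "integer"))

setValidity("VelocityField", function(object) {
  d <- dim(object@vx)
  if (!identical(d, dim(object@vy)) || !identical(d, dim(object@speed)) ||
      !identical(d, dim(object@flags)))
    return("vx, vy, speed, flags must share dimensions")
  def <- object@flags == "defined"
  if (any(def)) {
    sp <- sqrt(object@vx[def]^2 + object@vy[def]^2)
    if (any(abs(sp - object@speed[def]) > 1e-9 * pmax(1, sp)))
      return("speed must equal sqrt(vx^2+vy^2) at defined sites")
  }
  TRUE
})

#' Per-cycle peak-to-trough amplitude grid
#'
#' @slot amplitude numeric matrix in microvolts, `NA` where no mark.
#' @slot confidence character matrix, `"high"`, `"low"` or `"missing"`.
#' @slot cycle cycle index.
#'
#' @seealso [estimateAmplitude()], [buildAmplitudeMap()]
#' @export
setClass("AmplitudeMap",
  representation(amplitude = "matrix", confidence = "matrix",
                 cycle = "integer"))

setValidity("AmplitudeMap", function(object) {
  if (!identical(dim(object@amplitude), dim(object@confidence)))
    return("amplitude and confidence must share dimensions")
  a <- object@amplitude
  if (any(!is.na(a) & a < 0)) return("amplitudes must be non-negative")
  TRUE
})

#' Inter-cycle time-interval (frequency) grid
#'
#' Activation-time intervals between one consecutive cycle pair, per
#' electrode site, with the equivalent frequency in cycles/min and a
#' bradygastric/normal/tachygastric classification against configurable
#' bounds. Defined only where both cycles carry measured (non-interpolated)
#' marks.
#'
#' @slot intervals numeric matrix in seconds (`NA` undefined).
#' @slot freqCpm numeric matrix, `60 / intervals`.
#' @slot siteClass character matrix, `"brady"`, `"normal"`, `"tachy"` or
#'   `"undefined"`.
#' @slot pair integer vector `(k, k+1)`.
#' @slot meanS,sdS summary mean and SD of the defined intervals (seconds).
#'
#' @seealso [computeIntervals()]
#' @export
setClass("IntervalMap",
  representation(intervals = "matrix", freqCpm = "matrix",
                 siteClass = "matrix", pair = "integer",
                 meanS = "numeric", sdS = "numeric"))

setValidity("IntervalMap", function(object) {
  if (!identical(dim(object@intervals), dim(object@freqCpm)) ||
      !identical(dim(object@intervals), dim(object@siteClass)))
    return("intervals, freqCpm, siteClass must share dimensions")
  iv <- object@intervals
  if (any(!is.na(iv) & iv <= 0)) return("intervals must be positive")
  if (length(object@pair) != 2L) return("pair must be (k, k+1)")
  TRUE
})

#' Filter specification
#'
#' One of four filter kinds applied by [applyFilter()]:
#' `moving_median` (params: `window_s`), `savitzky_golay` (`window_s`,
#' `poly_order`), `butterworth` (`band` in low/high/band, `cutoff_hz`,
#' `order`) and `wavelet` (`wavelet_name`, `decomposition_level`,
#' `kept_bands`).
#'
#' @slot kind filter kind.
#' @slot params named list of kind-specific parameters.
#'
#' @seealso [filterSpec()], [applyFilter()]
#' @export
setClass("FilterSpec", representation(kind = "character", params = "list"))

setValidity("FilterSpec", function(object) {
  kinds <- c("moving_median", "savitzky_golay", "butterworth", "wavelet")
  if (length(object@kind) != 1L || !(object@kind %in% kinds))
    return(paste("kind must be one of:", paste(kinds, collapse = ", ")))
  TRUE
})

#' Parameter set for the full analysis pipeline
#'
#' A complete, validated set of tunables for every stage, each with a
#' documented default (see [defaultParameters()]). Unknown keys are
#' rejected; serialisation through [saveParameters()]/[loadParameters()]
#' round-trips losslessly.
#'
#' @slot values named list of parameter values.
#'
#' @seealso [parameterSet()], [defaultParameters()]
#' @export
setClass("ParameterSet", representation(values = "list"))

setClassUnion("CycleAssignmentOrNULL", c("CycleAssignment", "NULL"))
setClassUnion("EventMarksOrNULL", c("EventMarks", "NULL"))

#' Analysis session
#'
#' Bundles a (filtered) recording, its electrode layout, the parameter set
#' and any marks/cycle assignment produced so far, plus provenance. Saving
#' and re-loading a session reproduces identical downstream outputs.
#'
#' @slot recording the filtered [SWRecording-class].
#' @slot layout the [ElectrodeLayout-class].
#' @slot params the [ParameterSet-class].
#' @slot marks [EventMarks-class] or `NULL` if detection has not run.
#' @slot assignment [CycleAssignment-class] or `NULL` if clustering has not run.
#' @slot provenance named list (tool version, creation timestamp).
#'
#' @seealso [analysisSession()], [saveSession()], [loadSession()]
#' @export
setClass("AnalysisSession",
  representation(recording = "SWRecording", layout = "ElectrodeLayout",
                 params = "ParameterSet", marks = "EventMarksOrNULL",
                 assignment = "CycleAssignmentOrNULL", provenance = "list"))

setValidity("AnalysisSession", function(object) {
  if (!is.null(object@marks)) {
    unknown <- setdiff(unique(object@marks@marks$channel),
                       object@recording@channelIds)
    if (length(unknown))
      return(paste("marks reference unknown channels:",
                   paste(unknown, collapse = ", ")))
  }
  if (!is.null(object@assignment)) {
    if (is.null(object@marks))
      return("assignment present without marks")
    if (length(object@assignment@cycle) != nrow(object@marks@marks))
      return("assignment length must equal number of marks")
  }
  TRUE
})

#' Synthetic slow-wave scenario
#'
#' Full description of a simulated multi-electrode serosal recording:
#' grid geometry, sampling, propagation pattern, waveform shape, noise
#' model, dead channels and the RNG seed. [generateRecording()] turns a
#' scenario into a recording plus exact ground truth.
#'
#' Patterns: `planar` (`direction_deg`, `speed_mm_s`), `radial`
#' (`origin_row`, `origin_col`, `speed_mm_s`), `retrograde`
#' (`speed_mm_s`; planar at 180 degrees), `block` (`planar` params plus
#' `mask_rows`, `mask_cols`, `delay_s`), `tachy_patch` (`planar` params
#' plus `patch_rows`, `patch_cols`, `patch_period_s`).
#'
#' @slot grid list: `rows`, `cols`, `spacing_mm`.
#' @slot fs sampling rate in Hz.
#' @slot duration recording length in seconds.
#' @slot pattern list with `type` and pattern parameters.
#' @slot periodS slow-wave period in seconds (baseline cycle spacing).
#' @slot waveform list: `amplitude_uv` (peak-to-trough), `width_s`,
#'   `shape` (`"biphasic"` or `"triphasic"`).
#' @slot noise list: `white_sd_uv`, `line_hz`, `line_amp_uv`, `wander_hz`,
#'   `wander_amp_uv`, `wander_walk_uv`.
#' @slot deadChannels integer vector of 1-based channel indices that carry
#'   noise only.
#' @slot seed RNG seed; all randomness in the generator flows from it.
#'
#' @seealso [slowWaveScenario()], [generateRecording()]
#' @export
setClass("SyntheticScenario",
  representation(grid = "list", fs = "numeric", duration = "numeric",
                 pattern = "list", periodS = "numeric", waveform = "list",
                 noise = "list", deadChannels = "integer", seed = "integer"))

setValidity("SyntheticScenario", function(object) {
  msg <- character()
  g <- object@grid
  if (!all(c("rows", "cols", "spacing_mm") %in% names(g)) ||
      g$rows < 1 || g$cols < 1 || g$spacing_mm <= 0)
    msg <- c(msg, "grid needs rows >= 1, cols >= 1, spacing_mm > 0")
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (object@duration <= 0) msg <- c(msg, "duration must be positive")
  pt <- object@pattern
  if (is.null(pt$type) || !(pt$type %in%
      c("planar", "radial", "retrograde", "block", "tachy_patch")))
    msg <- c(msg, "unknown pattern type")
  sp <- pt$speed_mm_s
  if (!is.null(sp) && sp <= 0) msg <- c(msg, "speed must be positive")
  wf <- object@waveform
  if (object@periodS <= wf$width_s)
    msg <- c(msg, "period_s must exceed the waveform width")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "a seed is mandatory")
  if (length(msg)) msg else TRUE
})
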