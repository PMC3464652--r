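#' Construct a recording
#'
#' @param samples numeric matrix, channels x samples, microvolts.
#' @param fs sampling rate (Hz).
#' @param channelIds channel labels; defaults to `"ch1".."chN"`.
#' @param t0 start offset in seconds.
#' @param channelStatus per-channel `"ok"`/`"excluded"`; defaults to all ok.
#' @return a [SWRecording-class].
#' @examples
#' rec <- swRecording(matrix(rnorm(200), 2, 100), fs = 10)
#' nChannels(rec)
#' @export
swRecording <- function(samples, fs, channelIds = NULL, t0 = 0,
                        channelStatus = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(channelIds)) channelIds <- paste0("ch", seq_len(nrow(samples)))
  if (is.null(channelStatus)) channelStatus <- rep("ok", nrow(samples))
  new("SWRecording", samples = samples, fs = as.numeric(fs),
      channelIds = as.character(channelIds), t0 = as.numeric(t0),
      channelStatus = channelStatus)
}

#' @rdname swRecording
#' @param x a `SWRecording`.
#' @export
samples <- function(x) x@samples

#' @rdname swRecording
#' @export
samplingRate <- function(x) x@fs

#' @rdname swRecording
#' @export
channelIds <- function(x) x@channelIds

#' @rdname swRecording
#' @export
channelStatus <- function(x) {
  stats::setNames(x@channelStatus, x@channelIds)
}

#' @rdname swRecording
#' @export
nChannels <- function(x) nrow(x@samples)

#' @rdname swRecording
#' @export
nSamples <- function(x) ncol(x@samples)

#' @rdname swRecording
#' @export
startTime <- function(x) x@t0

#' Time axis of a recording
#'
#' @param x a [SWRecording-class].
#' @return numeric vector of sample times in seconds (`t0` at sample 1).
#' @export
timeAxis <- function(x) x@t0 + (seq_len(ncol(x@samples)) - 1) / x@fs

#' Mark or clear channel exclusion
#'
#' Excluded channels are passed through filtering untouched, skipped by
#' [fevtDetect()] and treated as missing sites by the mapping stage. The
#' flag is reversible and the stored samples are never altered.
#'
#' @param recording a [SWRecording-class].
#' @param channelId channel label to modify.
#' @param status `"ok"` or `"excluded"`.
#' @return the updated recording.
#' @export
setChannelStatus <- function(recording, channelId, status) {
  status <- match.arg(status, c("ok", "excluded"))
  i <- match(channelId, recording@channelIds)
  if (is.na(i))
    stop("unknown channel: ", channelId)
  recording@channelStatus[i] <- status
  recording
}

#' @rdname gridLayout
#' @param x an `ElectrodeLayout`.
#' @export
spacingMm <- function(x) x@spacingMm

#' @rdname gridLayout
#' @export
gridShape <- function(x) x@gridShape

#' @rdname gridLayout
#' @export
placement <- function(x) x@placement

#' Construct an event-mark table
#'
#' @param channel channel labels (one per mark).
#' @param time activation times in seconds.
#' @param source `"auto"` or `"manual"` per mark.
#' @param score detection score per mark (`NA` for manual).
#' @return an [EventMarks-class], sorted by channel then time.
#' @export
eventMarks <- function(channel = character(), time = numeric(),
                       source = rep("auto", length(time)),
                       score = rep(NA_real_, length(time))) {
  m <- data.frame(channel = as.character(channel), time = as.numeric(time),
                  source = as.character(source), score = as.numeric(score),
                  stringsAsFactors = FALSE)
  m <- m[order(m$channel, m$time), , drop = FALSE]
  rownames(m) <- NULL
  new("EventMarks", marks = m)
}

#' @rdname eventMarks
#' @param x an `EventMarks` object.
#' @export
marksTable <- function(x) x@marks

#' @rdname eventMarks
#' @export
nMarks <- function(x) nrow(x@marks)

#' @rdname regroupsCluster
#' @param x a `CycleAssignment`.
#' @export
cycleOf <- function(x) x@cycle

#' @rdname regroupsCluster
#' @export
nCycles <- function(x) x@nCycles

#' @rdname regroupsCluster
#' @export
orphanCount <- function(x) sum(is.na(x@cycle))

#' @rdname regroupsCluster
#' @param k cycle index.
#' @export
cycleMembers <- function(x, k) which(!is.na(x@cycle) & x@cycle == k)

#' @rdname buildActivationMap
#' @param x an `ActivationMap`.
#' @export
activationTimes <- function(x) x@times

#' @rdname buildActivationMap
#' @export
siteFlags <- function(x) x@flags

#' @rdname computeVelocityField
#' @param x a `VelocityField`.
#' @export
speedGrid <- function(x) x@speed

#' @rdname computeVelocityField
#' @export
velocityComponents <- function(x) list(vx = x@vx, vy = x@vy)

#' @rdname computeIntervals
#' @param x an `IntervalMap`.
#' @export
intervalGrid <- function(x) x@intervals

#' @rdname computeIntervals
#' @export
siteClasses <- function(x) x@siteClass

#' @rdname computeIntervals
#' @export
intervalSummary <- function(x) c(mean_s = x@meanS, sd_s = x@sdS)

setMethod("show", "SWRecording", function(object) {
  cat(sprintf(
    "SWRecording: %d channels x %d samples @ %g Hz (%.1f s, t0 = %g s)\n",
    nrow(object@samples), ncol(object@samples), object@fs,
    ncol(object@samples) / object@fs, object@t0))
  nx <- sum(object@channelStatus == "excluded")
  if (nx) cat(sprintf("  %d channel(s) excluded\n", nx))
})

setMethod("show", "ElectrodeLayout", function(object) {
  cat(sprintf("ElectrodeLayout: %d x %d grid, %g mm spacing, %d channels placed\n",
              object@gridShape[1L], object@gridShape[2L], object@spacingMm,
              nrow(object@placement)))
})

setMethod("show", "EventMarks", function(object) {
  m <- object@marks
  cat(sprintf("EventMarks: %d marks on %d channels (%d auto, %d manual)\n",
              nrow(m), length(unique(m$channel)),
              sum(m$source == "auto"), sum(m$source == "manual")))
})

setMethod("show", "CycleAssignment", function(object) {
  cat(sprintf("CycleAssignment: %d cycles, %d assigned marks, %d orphans\n",
              object@nCycles, sum(!is.na(object@cycle)),
              sum(is.na(object@cycle))))
})

setMethod("show", "ActivationMap", function(object) {
  f <- object@flags
  cat(sprintf(
    "ActivationMap (cycle %d): %d x %d grid; %d measured, %d interpolated, %d missing\n",
    object@cycle, nrow(f), ncol(f), sum(f == "measured"),
    sum(f == "interpolated"), sum(f == "missing")))
})

setMethod("show", "VelocityField", function(object) {
  def <- object@flags == "defined"
  cat(sprintf("VelocityField (cycle %d): %d defined sites", object@cycle,
              sum(def)))
  if (any(def))
    cat(sprintf("; median speed %.2f mm/s", stats::median(object@speed[def])))
  cat("\n")
})

setMethod("show", "IntervalMap", function(object) {
  cat(sprintf(
    "IntervalMap (cycles %d-%d): mean %.2f +/- %.2f s (%d defined sites)\n",
    object@pair[1L], object@pair[2L], object@meanS, object@sdS,
    sum(!is.na(object@intervals))))
})

setMethod("show", "AnalysisSession", function(object) {
  cat("AnalysisSession\n")
  show(object@recording)
  show(object@layout)
  if (!is.null(object@marks)) show(object@marks) else cat("  no marks yet\n")
  if (!is.null(object@assignment)) show(object@assignment)
})
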