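## FEVT: falling-edge, variable-threshold detection of slow-wave
## activation times. The detection signal is a smoothed power of the
## rectified negative slope, the threshold a scaled moving median of it.

## centred moving average, replicate-padded edges
.movavg <- function(x, k) {
  if (k <= 1L) return(x)
  h <- (k - 1L) %/% 2L
  padded <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  cs <- cumsum(padded)
  (cs[(k):(k + length(x) - 1L)] -
     c(0, cs[seq_len(length(x) - 1L)])) / k
}

## rectified negative slope (uV/s); centred difference over +-k samples
.neg_slope <- function(x, fs, k = 1L) {
  n <- length(x)
  d <- numeric(n)
  if (n > 2L * k) {
    i <- (k + 1L):(n - k)
    d[i] <- (x[i + k] - x[i - k]) / (2 * k) * fs
    d[seq_len(k)] <- d[k + 1L]
    d[(n - k + 1L):n] <- d[n - k]
  }
  pmax(0, -d)
}

#' Falling-edge detection transform
#'
#' Maps a pre-processed signal to a non-negative detection signal that is
#' large over high-energy, high-frequency downward deflections and exactly
#' zero on rising edges: the centred first difference (scaled to uV/s) is
#' rectified to its negative part, raised to `power_p` and smoothed with a
#' centred moving average of length `smooth_s`.
#'
#' @param x numeric signal (one channel, microvolts).
#' @param fs sampling rate (Hz).
#' @param edge_len_s slope stencil half-width in seconds; `0` uses the
#'   single-sample centred difference.
#' @param power_p exponent on the rectified negative slope.
#' @param smooth_s moving-average window (s); `0` disables smoothing.
#' @return numeric detection signal, same length as `x`, `>= 0`.
#' @seealso [variableThreshold()], [fevtDetect()]
#' @export
fallingEdgeTransform <- function(x, fs, edge_len_s = 0, power_p = 2,
                                 smooth_s = 0.25) {
  if (any(!is.finite(x))) stop("signal contains non-finite samples")
  k <- max(1L, round(edge_len_s * fs))
  D <- .neg_slope(x, fs, k)^power_p
  if (smooth_s > 0) D <- .movavg(D, .odd_window(smooth_s, fs))
  D
}

#' Time-varying detection threshold
#'
#' The threshold tracks the local background of the detection signal:
#' `theta(t) = max(floor_eps, eta * moving_median(D, window_s))`. The
#' moving median makes it robust to the sparse high-energy events
#' themselves (duty cycle below half the window leaves the median at the
#' noise floor), while `eta` sets how far above background an event must
#' rise. A strictly positive floor keeps silent channels from firing.
#'
#' @param D detection signal from [fallingEdgeTransform()].
#' @param fs sampling rate (Hz).
#' @param window_s moving-median window (s); should be much longer than an
#'   event.
#' @param eta threshold multiplier.
#' @param floor_eps threshold floor; default is scale-aware
#'   (`1e-12 * max(D)`, never below the smallest positive double).
#' @return threshold series, same length as `D`, everywhere `> 0`.
#' @export
variableThreshold <- function(D, fs, window_s = 15, eta = 5,
                              floor_eps = NULL) {
  if (eta <= 0) stop("eta must be positive")
  k <- .odd_window(window_s, fs)
  if (k < 3L) stop("threshold window must span at least 3 samples")
  if (is.null(floor_eps))
    floor_eps <- max(.Machine$double.xmin, 1e-12 * max(D))
  pmax(floor_eps, eta * .moving_median(D, k))
}

## supra-threshold runs as (start, end) index pairs
.runs_above <- function(above) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

## merge runs whose gap is shorter than `gap` samples
.merge_runs <- function(runs, gap) {
  if (nrow(runs) <= 1L) return(runs)
  out <- runs[1L, , drop = FALSE]
  for (i in 2L:nrow(runs)) {
    if (runs[i, "start"] - out[nrow(out), "end"] < gap)
      out[nrow(out), "end"] <- runs[i, "end"]
    else
      out <- rbind(out, runs[i, , drop = FALSE])
  }
  out
}

## local maxima indices (plateau-aware: first sample of a plateau)
.local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer())
  which(diff(sign(diff(v))) < 0) + 1L
}

## pick the mark sample within one supra-threshold run:
## single-deflection runs take the steepest descent; runs containing
## several descent maxima separated by > sep_samps take the FIRST whose
## detection signal reaches frac of the run's peak (first-major-deflection
## convention for fractionated events)
.mark_in_run <- function(ns, D, i0, i1, sep_samps, frac) {
  seg <- ns[i0:i1]
  peaks <- .local_maxima(seg)
  if (!length(peaks)) peaks <- which.max(seg)
  ## greedy thin: keep the larger of any two peaks closer than sep_samps
  peaks <- peaks[order(seg[peaks], decreasing = TRUE)]
  kept <- integer()
  for (p in peaks)
    if (!length(kept) || all(abs(kept - p) > sep_samps)) kept <- c(kept, p)
  kept <- sort(kept)
  if (length(kept) >= 2L) {
    dmax <- max(D[i0:i1])
    ok <- kept[D[i0 + kept - 1L] >= frac * dmax]
    if (length(ok)) return(i0 + ok[1L] - 1L)
  }
  i0 + which.max(seg) - 1L
}

#' Detect slow-wave activation times (FEVT)
#'
#' Runs the falling-edge variable-threshold detector on every active
#' channel of a filtered recording. Supra-threshold runs of the detection
#' signal are found, runs closer than the refractory period are merged,
#' and each surviving run yields one mark at the steepest negative slope
#' of the signal within the run (for fractionated multi-deflection runs,
#' at the first deflection reaching `fevt.deflection_frac` of the run's
#' peak). The detection score of a mark is the peak detection-to-threshold
#' ratio of its run. Channels flagged `"excluded"` yield no marks.
#'
#' Mark times are invariant to positive rescaling of a channel (the
#' threshold scales with the detection signal) and equivariant to time
#' shifts away from the recording edges.
#'
#' @param recording a filtered [SWRecording-class].
#' @param layout optional [ElectrodeLayout-class] (not used by detection
#'   itself; accepted so pipeline stages share one signature).
#' @param params a [ParameterSet-class]; the `fevt.*` keys apply.
#' @return an [EventMarks-class]; empty when nothing crosses threshold.
#' @export
fevtDetect <- function(recording, layout = NULL,
                       params = defaultParameters()) {
  stopifnot(is(recording, "SWRecording"))
  fs <- recording@fs
  refr <- param(params, "fevt.refractory_s")
  sep_samps <- max(1L, round(param(params, "fevt.deflection_sep_s") * fs))
  frac <- param(params, "fevt.deflection_frac")
  ch <- character(); tt <- numeric(); sc <- numeric()
  for (i in seq_len(nrow(recording@samples))) {
    if (recording@channelStatus[i] == "excluded") next
    x <- recording@samples[i, ]
    D <- fallingEdgeTransform(x, fs,
                              edge_len_s = param(params, "fevt.edge_len_s"),
                              power_p = param(params, "fevt.power_p"),
                              smooth_s = param(params, "fevt.smooth_s"))
    theta <- variableThreshold(D, fs,
                               window_s = param(params, "fevt.threshold_window_s"),
                               eta = param(params, "fevt.eta"))
    runs <- .runs_above(D > theta)
    if (!nrow(runs)) next
    runs <- .merge_runs(runs, gap = round(refr * fs))
    k <- max(1L, round(param(params, "fevt.edge_len_s") * fs))
    ns <- .neg_slope(x, fs, k)
    for (r in seq_len(nrow(runs))) {
      i0 <- runs[r, "start"]; i1 <- runs[r, "end"]
      m <- .mark_in_run(ns, D, i0, i1, sep_samps, frac)
      ch <- c(ch, recording@channelIds[i])
      tt <- c(tt, recording@t0 + (m - 1L) / fs)
      sc <- c(sc, max(D[i0:i1] / theta[i0:i1]))
    }
  }
  eventMarks(ch, tt, source = rep("auto", length(tt)), score = sc)
}

#' Add or delete activation marks manually
#'
#' `add` inserts a manual mark; when a recording is supplied and snapping
#' is on, the mark lands on the steepest-descent sample within the snap
#' window around the requested time. `delete` removes the mark nearest the
#' requested time within the snap window. Mark invariants (per-channel
#' ordering, refractory spacing) are re-validated.
#'
#' @param marks an [EventMarks-class].
#' @param action `"add"` or `"delete"`.
#' @param channel channel label.
#' @param time requested time (s).
#' @param recording optional [SWRecording-class], enables snapping for `add`.
#' @param params a [ParameterSet-class] (`fevt.snap_window_s`,
#'   `fevt.refractory_s`).
#' @return the updated [EventMarks-class].
#' @export
editMarks <- function(marks, action, channel, time, recording = NULL,
                      params = defaultParameters()) {
  action <- match.arg(action, c("add", "delete"))
  m <- marks@marks
  snap <- param(params, "fevt.snap_window_s")
  if (action == "delete") {
    on_ch <- which(m$channel == channel)
    if (!length(on_ch)) stop("no marks on channel ", channel)
    d <- abs(m$time[on_ch] - time)
    if (min(d) > snap)
      stop(sprintf("no mark within %.2f s of t = %.3f s on channel %s",
                   snap, time, channel))
    m <- m[-on_ch[which.min(d)], , drop = FALSE]
    rownames(m) <- NULL
    return(new("EventMarks", marks = m))
  }
  t_new <- time
  if (!is.null(recording)) {
    i <- match(channel, recording@channelIds)
    if (is.na(i)) stop("unknown channel: ", channel)
    fs <- recording@fs
    c0 <- max(1L, round((time - snap - recording@t0) * fs) + 1L)
    c1 <- min(ncol(recording@samples),
              round((time + snap - recording@t0) * fs) + 1L)
    ns <- .neg_slope(recording@samples[i, ], fs)
    t_new <- recording@t0 + (c0 + which.max(ns[c0:c1]) - 2L) / fs
  }
  refr <- param(params, "fevt.refractory_s")
  near <- which(m$channel == channel & abs(m$time - t_new) < refr)
  if (length(near))
    stop(sprintf(
      "refractory conflict: existing mark at t = %.3f s on channel %s",
      m$time[near[1L]], channel))
  m <- rbind(m, data.frame(channel = channel, time = t_new,
                           source = "manual", score = NA_real_,
                           stringsAsFactors = FALSE))
  m <- m[order(m$channel, m$time), , drop = FALSE]
  rownames(m) <- NULL
  new("EventMarks", marks = m)
}
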