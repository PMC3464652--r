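## Synthetic gastric slow-wave generator: rectangular electrode array,
## closed-form wavefront arrival times, biphasic/triphasic deflections,
## seeded noise -- with exact ground truth for validating every stage.

#' White-noise level for a target signal-to-noise ratio
#'
#' SNR here is defined as peak-to-trough amplitude over twice the noise
#' RMS, in dB: `snr_db = 20*log10(A_pp / (2*sd))`.
#'
#' @param amplitude_uv peak-to-trough event amplitude (uV).
#' @param snr_db target SNR in dB.
#' @return white-noise standard deviation in uV.
#' @export
snrToWhiteSd <- function(amplitude_uv, snr_db)
  amplitude_uv / (2 * 10^(snr_db / 20))

#' Describe a synthetic slow-wave scenario
#'
#' Defaults emulate a typical gastric serosal mapping preparation: an
#' 8 x 8 array at 4 mm spacing sampled at 32 Hz for 10 minutes, planar
#' antegrade propagation at 6 mm/s, one wave every 20 s (3 cycles/min),
#' biphasic 400 uV deflections of 2 s width, white noise at 5 dB SNR
#' (on the peak-to-trough over 2 x RMS definition) plus slow sinusoidal
#' baseline wander with a small random-walk component. Line interference
#' defaults to off because typical mapping sampling rates sit below the
#' mains frequency.
#'
#' @param rows,cols,spacing_mm grid geometry.
#' @param fs sampling rate (Hz).
#' @param duration recording length (s).
#' @param pattern list with `type` (`"planar"`, `"radial"`, `"retrograde"`,
#'   `"block"`, `"tachy_patch"`) and its parameters; see
#'   [SyntheticScenario-class].
#' @param period_s slow-wave period (s).
#' @param amplitude_uv peak-to-trough deflection amplitude (uV).
#' @param width_s deflection width (s).
#' @param shape `"biphasic"` or `"triphasic"`.
#' @param white_sd_uv white-noise SD (uV).
#' @param line_hz,line_amp_uv mains interference frequency and amplitude.
#' @param wander_hz,wander_amp_uv sinusoidal baseline-wander frequency and
#'   amplitude.
#' @param wander_walk_uv per-sample SD of the random-walk wander component.
#' @param dead_channels 1-based indices of channels carrying noise only.
#' @param seed RNG seed (mandatory; all generator randomness flows from it).
#' @return a [SyntheticScenario-class].
#' @examples
#' sc <- slowWaveScenario(duration = 120, seed = 1)
#' gen <- generateRecording(sc)
#' gen$recording
#' @export
slowWaveScenario <- function(rows = 8, cols = 8, spacing_mm = 4,
                             fs = 32, duration = 600,
                             pattern = list(type = "planar",
                                            direction_deg = 0,
                                            speed_mm_s = 6),
                             period_s = 20,
                             amplitude_uv = 400, width_s = 2,
                             shape = "biphasic",
                             white_sd_uv = snrToWhiteSd(amplitude_uv, 5),
                             line_hz = 50, line_amp_uv = 0,
                             wander_hz = 0.005, wander_amp_uv = 200,
                             wander_walk_uv = 0.5,
                             dead_channels = integer(), seed) {
  if (missing(seed)) stop("a seed is mandatory")
  new("SyntheticScenario",
      grid = list(rows = rows, cols = cols, spacing_mm = spacing_mm),
      fs = fs, duration = duration, pattern = pattern, periodS = period_s,
      waveform = list(amplitude_uv = amplitude_uv, width_s = width_s,
                      shape = shape),
      noise = list(white_sd_uv = white_sd_uv, line_hz = line_hz,
                   line_amp_uv = line_amp_uv, wander_hz = wander_hz,
                   wander_amp_uv = wander_amp_uv,
                   wander_walk_uv = wander_walk_uv),
      deadChannels = as.integer(dead_channels), seed = as.integer(seed))
}

#' Sampled slow-wave deflection template
#'
#' Extracellular slow-wave deflections approximate derivatives of a
#' Gaussian: `"biphasic"` is the (negated) first derivative -- a positive
#' lobe followed by a sharp negative deflection -- and `"triphasic"` the
#' second derivative (Ricker-like). The template is scaled so its
#' peak-to-trough span equals `amplitude_uv`, integrates to ~0, and is
#' returned together with its steepest-descent sample, which defines the
#' activation time.
#'
#' @param shape `"biphasic"` or `"triphasic"`.
#' @param amplitude_uv peak-to-trough amplitude (uV).
#' @param width_s template width (s); support spans about `+-width_s/2`.
#' @param fs sampling rate (Hz); `width_s * fs` must be at least 8.
#' @return list with `samples` and `activation_index` (1-based index of
#'   the steepest-descent sample).
#' @export
waveformTemplate <- function(shape, amplitude_uv, width_s, fs) {
  if (width_s * fs < 8) stop("template too short: width_s * fs must be >= 8")
  shape <- match.arg(shape, c("biphasic", "triphasic"))
  sigma <- width_s / 6
  t <- seq(-width_s / 2, width_s / 2, by = 1 / fs)
  f <- switch(shape,
    biphasic = -t * exp(-t^2 / (2 * sigma^2)),
    triphasic = (1 - t^2 / sigma^2) * exp(-t^2 / (2 * sigma^2)))
  f <- f * amplitude_uv / (max(f) - min(f))
  d <- numeric(length(f))
  i <- 2:(length(f) - 1)
  d[i] <- (f[i + 1] - f[i - 1]) / 2
  d[1] <- d[2]; d[length(d)] <- d[length(d) - 1]
  list(samples = f, activation_index = which.min(d))
}

## 0-based site coordinates in mm; x along columns, y along rows
.site_xy <- function(rows, cols, spacing_mm) {
  data.frame(row = rep(0:(rows - 1), each = cols),
             col = rep(0:(cols - 1), times = rows),
             x = rep(0:(cols - 1), times = rows) * spacing_mm,
             y = rep(0:(rows - 1), each = cols) * spacing_mm)
}

## per-site wavefront delay (s) relative to the earliest site of a cycle
.pattern_delays <- function(scenario) {
  g <- scenario@grid
  pt <- scenario@pattern
  xy <- .site_xy(g$rows, g$cols, g$spacing_mm)
  sp <- pt$speed_mm_s
  if (is.null(sp) || sp <= 0) stop("pattern needs speed_mm_s > 0")
  type <- pt$type
  if (type == "retrograde") {
    type <- "planar"
    pt$direction_deg <- (if (is.null(pt$direction_deg)) 0 else pt$direction_deg) + 180
  }
  if (type %in% c("planar", "block", "tachy_patch")) {
    th <- (if (is.null(pt$direction_deg)) 0 else pt$direction_deg) * pi / 180
    proj <- xy$x * cos(th) + xy$y * sin(th)
    delay <- (proj - min(proj)) / sp
  } else if (type == "radial") {
    if (is.null(pt$origin_row) || is.null(pt$origin_col))
      stop("radial pattern needs origin_row, origin_col")
    dx <- xy$x - pt$origin_col * g$spacing_mm
    dy <- xy$y - pt$origin_row * g$spacing_mm
    delay <- sqrt(dx^2 + dy^2) / sp
  } else stop("unknown pattern type: ", pt$type)
  if (identical(pt$type, "block")) {
    masked <- xy$row %in% pt$mask_rows & xy$col %in% pt$mask_cols
    delay[masked] <- delay[masked] + pt$delay_s
  }
  list(xy = xy, delay = delay)
}

#' Closed-form ground-truth arrival times for a scenario
#'
#' Computes the exact activation schedule every other module is validated
#' against: planar wavefronts arrive at `t_cycle + (r . u)/speed`, radial
#' ones at `t_cycle + |r - r0|/speed`, conduction-block scenarios delay
#' the masked rectangle, and a tachygastric patch runs on its own shorter
#' local period. Times are snapped to the sample grid (where the generator
#' places the steepest descent), so noise-free detection recovers them
#' exactly.
#'
#' @param scenario a [SyntheticScenario-class].
#' @return list: `marks` (data.frame `channel`, `cycle`, `time`, `row`,
#'   `col`), `velocity` (data.frame per site `vx`, `vy` in mm/s),
#'   `amplitude_uv`, `period_s` per channel, `layout` the matching
#'   [ElectrodeLayout-class], and `snr_db`.
#' @export
waveArrivalTimes <- function(scenario) {
  g <- scenario@grid
  pd <- .pattern_delays(scenario)
  xy <- pd$xy
  n_sites <- nrow(xy)
  chan <- paste0("ch", seq_len(n_sites))
  wf <- scenario@waveform
  fs <- scenario@fs
  margin <- wf$width_s / 2 + 2 / fs
  t_first <- wf$width_s                       # headroom before the first wave
  period <- rep(scenario@periodS, n_sites)
  pt <- scenario@pattern
  if (identical(pt$type, "tachy_patch")) {
    patch <- xy$row %in% pt$patch_rows & xy$col %in% pt$patch_cols
    if (pt$patch_period_s <= wf$width_s)
      stop("patch period must exceed the waveform width")
    period[patch] <- pt$patch_period_s
  }
  rows <- list()
  for (s in seq_len(n_sites)) {
    if (s %in% scenario@deadChannels) next
    t0 <- t_first + pd$delay[s]
    times <- seq(t0, scenario@duration - margin, by = period[s])
    times <- times[times >= margin]
    if (!length(times)) next
    times <- round(times * fs) / fs           # snap to the sample grid
    rows[[length(rows) + 1L]] <- data.frame(
      channel = chan[s], cycle = seq_along(times), time = times,
      row = xy$row[s], col = xy$col[s], stringsAsFactors = FALSE)
  }
  marks <- do.call(rbind, rows)
  sp <- pt$speed_mm_s
  vel <- if (pt$type %in% c("planar", "retrograde", "block", "tachy_patch")) {
    th <- ((if (is.null(pt$direction_deg)) 0 else pt$direction_deg) +
             if (pt$type == "retrograde") 180 else 0) * pi / 180
    data.frame(row = xy$row, col = xy$col,
               vx = rep(sp * cos(th), n_sites),
               vy = rep(sp * sin(th), n_sites))
  } else {
    dx <- xy$x - pt$origin_col * g$spacing_mm
    dy <- xy$y - pt$origin_row * g$spacing_mm
    rr <- pmax(sqrt(dx^2 + dy^2), .Machine$double.eps)
    data.frame(row = xy$row, col = xy$col,
               vx = sp * dx / rr, vy = sp * dy / rr)
  }
  layout <- gridLayout(g$rows, g$cols, g$spacing_mm, channel_ids = chan)
  list(marks = marks, velocity = vel,
       amplitude_uv = wf$amplitude_uv, period_s = period,
       layout = layout,
       snr_db = 20 * log10(wf$amplitude_uv /
                             (2 * max(scenario@noise$white_sd_uv,
                                      .Machine$double.xmin))))
}

#' Generate a synthetic recording with ground truth
#'
#' Each channel is the sum of deflection templates placed so their
#' steepest-descent sample lands exactly on the ground-truth activation
#' time, plus seeded white noise, optional mains sinusoid and slow
#' baseline wander (sinusoid + random walk). Dead channels carry noise
#' only. The output is fully deterministic for a given scenario seed.
#'
#' @param scenario a [SyntheticScenario-class].
#' @return list: `recording` ([SWRecording-class]), `truth` (see
#'   [waveArrivalTimes()]), `layout`.
#' @export
generateRecording <- function(scenario) {
  truth <- waveArrivalTimes(scenario)
  fs <- scenario@fs
  n <- round(scenario@duration * fs)
  g <- scenario@grid
  n_ch <- g$rows * g$cols
  wf <- scenario@waveform
  tmpl <- waveformTemplate(wf$shape, wf$amplitude_uv, wf$width_s, fs)
  if (min(truth$period_s) <= wf$width_s)
    stop("period too short: templates would overlap within a channel")
  x <- matrix(0, nrow = n_ch, ncol = n)
  chan <- paste0("ch", seq_len(n_ch))
  by_ch <- split(truth$marks$time, truth$marks$channel)
  L <- length(tmpl$samples)
  for (i in seq_len(n_ch)) {
    tt <- by_ch[[chan[i]]]
    if (is.null(tt)) next
    for (t1 in tt) {
      c0 <- round(t1 * fs) + 1L - (tmpl$activation_index - 1L)
      idx <- c0:(c0 + L - 1L)
      ok <- idx >= 1L & idx <= n
      x[i, idx[ok]] <- x[i, idx[ok]] + tmpl$samples[ok]
    }
  }
  nz <- scenario@noise
  tax <- (seq_len(n) - 1) / fs
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(scenario@seed)
  for (i in seq_len(n_ch)) {
    if (nz$white_sd_uv > 0)
      x[i, ] <- x[i, ] + stats::rnorm(n, sd = nz$white_sd_uv)
    if (nz$line_amp_uv > 0)
      x[i, ] <- x[i, ] + nz$line_amp_uv *
        sin(2 * pi * nz$line_hz * tax + stats::runif(1, 0, 2 * pi))
    if (nz$wander_amp_uv > 0)
      x[i, ] <- x[i, ] + nz$wander_amp_uv *
        sin(2 * pi * nz$wander_hz * tax + stats::runif(1, 0, 2 * pi))
    if (nz$wander_walk_uv > 0)
      x[i, ] <- x[i, ] + cumsum(stats::rnorm(n, sd = nz$wander_walk_uv))
  }
  if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv())
  rec <- swRecording(x, fs = fs, channelIds = chan)
  truth$dead_channels <- chan[scenario@deadChannels]
  list(recording = rec, truth = truth, layout = truth$layout)
}
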