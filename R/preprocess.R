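#' Create a filter specification
#'
#' @param kind `"moving_median"`, `"savitzky_golay"`, `"butterworth"` or
#'   `"wavelet"`.
#' @param ... kind-specific parameters: `window_s` (moving_median,
#'   savitzky_golay), `poly_order` (savitzky_golay), `band`/`cutoff_hz`/
#'   `order` (butterworth), `wavelet_name`/`decomposition_level`/
#'   `kept_bands` (wavelet).
#' @return a [FilterSpec-class].
#' @examples
#' filterSpec("savitzky_golay", window_s = 1, poly_order = 2)
#' @export
filterSpec <- function(kind, ...) {
  p <- list(...)
  kind <- match.arg(kind, c("moving_median", "savitzky_golay",
                            "butterworth", "wavelet"))
  defaults <- switch(kind,
    moving_median = list(window_s = 1),
    savitzky_golay = list(window_s = 1, poly_order = 2),
    butterworth = list(band = "low", cutoff_hz = 2, order = 3),
    wavelet = list(wavelet_name = "db4", decomposition_level = 6,
                   kept_bands = "approx"))
  unknown <- setdiff(names(p), names(defaults))
  if (length(unknown))
    stop("unknown ", kind, " parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(p)] <- p
  if (!is.null(defaults$window_s) && defaults$window_s <= 0)
    stop("window_s must be positive")
  if (kind == "butterworth") {
    if (!defaults$band %in% c("low", "high", "band"))
      stop("band must be low, high or band")
    if (any(defaults$cutoff_hz <= 0))
      stop("cutoff_hz must be positive")
  }
  new("FilterSpec", kind = kind, params = defaults)
}

## seconds -> odd sample count (round up)
.odd_window <- function(window_s, fs) {
  w <- max(1L, ceiling(window_s * fs))
  if (w %% 2L == 0L) w <- w + 1L
  w
}

## moving median with replicate-padded edges
.moving_median <- function(x, k) {
  if (k >= 2L * length(x)) stop("median window longer than signal")
  if (k == 1L) return(x)
  h <- (k - 1L) %/% 2L
  padded <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  sm <- stats::runmed(padded, k, endrule = "keep")
  sm[(h + 1L):(h + length(x))]
}

## Savitzky-Golay smoother with replicate-padded edges
.sgolay_smooth <- function(x, k, order) {
  if (k > length(x)) stop("Savitzky-Golay window longer than signal")
  if (order >= k) stop("poly_order must be below the window length in samples")
  h <- (k - 1L) %/% 2L
  padded <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  sm <- signal::sgolayfilt(padded, p = order, n = k)
  sm[(h + 1L):(h + length(x))]
}

## zero-phase Butterworth with odd-reflection padding
.butter_zerophase <- function(x, fs, band, cutoff_hz, order) {
  nyq <- fs / 2
  if (any(cutoff_hz <= 0) || any(cutoff_hz >= nyq))
    stop("Butterworth cutoff must lie strictly inside (0, fs/2)")
  type <- switch(band, low = "low", high = "high", band = "pass")
  W <- cutoff_hz / nyq
  if (band == "band" && length(W) != 2L)
    stop("band filter needs two cutoff frequencies")
  bf <- signal::butter(order, W, type = type)
  n <- length(x)
  p <- min(n - 1L, max(3L * order * 10L, 100L))
  if (p < 1L) return(signal::filtfilt(bf, x))
  left <- 2 * x[1L] - x[(p + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - p)]
  y <- signal::filtfilt(bf, c(left, x, right))
  y[(p + 1L):(p + n)]
}

## ---- periodized orthogonal DWT (Daubechies) ------------------------------
.db_filters <- list(
  db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
  db4 = c(0.23037781330885523, 0.71484657055254153, 0.63088076792959036,
          -0.02798376941698385, -0.18703481171888114, 0.03084138183598697,
          0.03288301166698295, -0.01059740178499728))

.dwt_step <- function(x, h) {
  n <- length(x)
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)          # QMF highpass
  half <- n %/% 2L
  idx <- outer(2 * (seq_len(half) - 1L), seq_len(L) - 1L, `+`) %% n + 1L
  xm <- matrix(x[idx], nrow = half)
  list(a = as.vector(xm %*% h), d = as.vector(xm %*% g))
}

.idwt_step <- function(a, d, h, n) {
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  x <- numeric(n)
  for (k in seq_along(a)) {
    pos <- (2 * (k - 1L) + seq_len(L) - 1L) %% n + 1L
    x[pos] <- x[pos] + h * a[k] + g * d[k]
  }
  x
}

## decompose to `level`, zero the bands not kept, reconstruct
.wavelet_filter <- function(x, wavelet_name, level, kept_bands) {
  h <- .db_filters[[wavelet_name]]
  if (is.null(h)) stop("unknown wavelet: ", wavelet_name,
                       " (available: ", paste(names(.db_filters), collapse = ", "), ")")
  n0 <- length(x)
  block <- 2^level
  n <- ceiling(n0 / block) * block
  xp <- c(x, rep(x[n0], n - n0))              # replicate-pad to 2^level multiple
  kept <- trimws(strsplit(kept_bands, ",")[[1L]])
  a <- xp
  details <- vector("list", level)
  lens <- integer(level)
  for (j in seq_len(level)) {
    lens[j] <- length(a)
    st <- .dwt_step(a, h)
    details[[j]] <- st$d
    a <- st$a
  }
  if (!("approx" %in% kept)) a <- numeric(length(a))
  for (j in seq_len(level)) {
    if (!(paste0("d", j) %in% kept))
      details[[j]] <- numeric(length(details[[j]]))
  }
  for (j in rev(seq_len(level)))
    a <- .idwt_step(a, details[[j]], h, lens[j])
  a[seq_len(n0)]
}

.filter_channel <- function(x, spec, fs) {
  p <- spec@params
  switch(spec@kind,
    moving_median = .moving_median(x, .odd_window(p$window_s, fs)),
    savitzky_golay = .sgolay_smooth(x, .odd_window(p$window_s, fs),
                                    p$poly_order),
    butterworth = .butter_zerophase(x, fs, p$band, p$cutoff_hz, p$order),
    wavelet = .wavelet_filter(x, p$wavelet_name, p$decomposition_level,
                              p$kept_bands))
}

#' Apply a filter to every active channel of a recording
#'
#' Removes baseline wander and/or high-frequency noise ahead of event
#' detection. Moving-median and Savitzky-Golay act as smoothers (the
#' output is the smoothed signal), the Butterworth filter is applied
#' zero-phase (forward-backward, odd-reflection padding) and the wavelet
#' filter reconstructs only the kept bands of a periodised Daubechies
#' decomposition. Channels flagged `"excluded"` pass through untouched.
#' The shape, sampling rate and channel order never change and the result
#' is deterministic.
#'
#' @param recording a [SWRecording-class].
#' @param spec a [FilterSpec-class].
#' @return the filtered [SWRecording-class].
#' @seealso [removeBaseline()], [filterSpec()]
#' @export
applyFilter <- function(recording, spec) {
  stopifnot(is(recording, "SWRecording"), is(spec, "FilterSpec"))
  x <- recording@samples
  if (any(!is.finite(x[recording@channelStatus == "ok", , drop = FALSE])))
    stop("recording contains non-finite samples")
  for (i in seq_len(nrow(x))) {
    if (recording@channelStatus[i] == "excluded") next
    x[i, ] <- .filter_channel(x[i, ], spec, recording@fs)
  }
  recording@samples <- x
  recording
}

#' Remove baseline wander
#'
#' `moving_median_subtract` subtracts a long-window moving median from each
#' channel (output mean over any drift-free segment is near zero);
#' `highpass` applies a zero-phase Butterworth high-pass at the given
#' cutoff. A baseline window of at least five dominant slow-wave periods is
#' recommended; pass `dominant_period_s` to get a warning when the window
#' is shorter.
#'
#' @param recording a [SWRecording-class].
#' @param method `"moving_median_subtract"` or `"highpass"`.
#' @param window_s_or_cutoff median window in seconds, or high-pass cutoff
#'   in Hz.
#' @param dominant_period_s optional dominant slow-wave period used only to
#'   check the recommended window length.
#' @return the baseline-corrected [SWRecording-class].
#' @export
removeBaseline <- function(recording, method = "moving_median_subtract",
                           window_s_or_cutoff = 20,
                           dominant_period_s = NULL) {
  method <- match.arg(method, c("moving_median_subtract", "highpass"))
  if (method == "moving_median_subtract") {
    if (!is.null(dominant_period_s) &&
        window_s_or_cutoff < 5 * dominant_period_s)
      warning("baseline window below 5x the dominant slow-wave period")
    k <- .odd_window(window_s_or_cutoff, recording@fs)
    x <- recording@samples
    for (i in seq_len(nrow(x))) {
      if (recording@channelStatus[i] == "excluded") next
      x[i, ] <- x[i, ] - .moving_median(x[i, ], k)
    }
    recording@samples <- x
    recording
  } else {
    applyFilter(recording, filterSpec("butterworth", band = "high",
                                      cutoff_hz = window_s_or_cutoff,
                                      order = 2))
  }
}

#' Recommended pre-processing chain for gastric serosal recordings
#'
#' Moving-median baseline subtraction (default 20 s window) followed by
#' Savitzky-Golay smoothing (default 1 s window, order 2): the combination
#' found most appropriate for typical gastric mapping work.
#'
#' @param recording a [SWRecording-class].
#' @param params a [ParameterSet-class]; uses `baseline.window_s`,
#'   `filter.window_s`, `filter.poly_order`.
#' @return the pre-processed [SWRecording-class].
#' @export
preprocessDefault <- function(recording, params = defaultParameters()) {
  r <- removeBaseline(recording, "moving_median_subtract",
                      param(params, "baseline.window_s"))
  applyFilter(r, filterSpec("savitzky_golay",
                            window_s = param(params, "filter.window_s"),
                            poly_order = param(params, "filter.poly_order")))
}
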