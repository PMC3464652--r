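## Per-cycle spatial products: activation-time grids, SIV interpolation,
## smoothed finite-difference velocity fields, zero-crossing amplitude
## estimation and inter-cycle interval (frequency) maps.

#' Place one cycle's marks on the electrode grid
#'
#' @param assignment a [CycleAssignment-class].
#' @param marks the matching [EventMarks-class].
#' @param layout an [ElectrodeLayout-class].
#' @param cycle_k 1-based cycle index.
#' @return an [ActivationMap-class]: member marks as `measured` sites,
#'   everything else `missing`.
#' @export
buildActivationMap <- function(assignment, marks, layout, cycle_k) {
  if (cycle_k < 1L || cycle_k > assignment@nCycles)
    stop("cycle index out of range: ", cycle_k, " (have ",
         assignment@nCycles, " cycles)")
  gs <- layout@gridShape
  tm <- matrix(NA_real_, gs[1L], gs[2L])
  fl <- matrix("missing", gs[1L], gs[2L])
  mem <- which(!is.na(assignment@cycle) & assignment@cycle == cycle_k)
  m <- marks@marks[mem, , drop = FALSE]
  pos <- .layout_pos(layout, m$channel)
  for (i in seq_len(nrow(m))) {
    r <- pos$row[i] + 1L; c <- pos$col[i] + 1L
    tm[r, c] <- m$time[i]
    fl[r, c] <- "measured"
  }
  new("ActivationMap", times = tm, flags = fl, cycle = as.integer(cycle_k),
      spacingMm = layout@spacingMm)
}

## values and positions of a site's 8-neighbours matching `which` flags
.nb_values <- function(times, flags, r, c, which_flags) {
  nr <- nrow(times); nc <- ncol(times)
  rr <- pmax(1L, r - 1L):pmin(nr, r + 1L)
  cc <- pmax(1L, c - 1L):pmin(nc, c + 1L)
  v <- c(); f <- c()
  for (i in rr) for (j in cc) {
    if (i == r && j == c) next
    v <- c(v, times[i, j]); f <- c(f, flags[i, j])
  }
  v[f %in% which_flags]
}

#' Two-stage spatial interpolation of blank sites (SIV)
#'
#' Stage 1 fills every missing site surrounded by at least `K1` measured
#' 8-neighbours with the median of those neighbours; stage 2 repeats the
#' rule with threshold `K2`, this time counting measured and stage-1
#' interpolated sites, to fill in the missing borders. Exactly two stages
#' run -- there is no further recursion -- and measured values are never
#' altered.
#'
#' @param map an [ActivationMap-class].
#' @param K1,K2 neighbour-count thresholds (1..8).
#' @return the interpolated [ActivationMap-class].
#' @export
sivInterpolate <- function(map, K1 = 5, K2 = 3) {
  stopifnot(K1 >= 1, K1 <= 8, K2 >= 1, K2 <= 8)
  tm <- map@times; fl <- map@flags
  stage <- function(tm, fl, K, sources) {
    tm2 <- tm; fl2 <- fl
    for (r in seq_len(nrow(tm))) for (c in seq_len(ncol(tm))) {
      if (fl[r, c] != "missing") next
      v <- .nb_values(tm, fl, r, c, sources)
      if (length(v) >= K) {
        tm2[r, c] <- stats::median(v)
        fl2[r, c] <- "interpolated"
      }
    }
    list(tm = tm2, fl = fl2)
  }
  s1 <- stage(tm, fl, K1, "measured")
  s2 <- stage(s1$tm, s1$fl, K2, c("measured", "interpolated"))
  new("ActivationMap", times = s2$tm, flags = s2$fl, cycle = map@cycle,
      spacingMm = map@spacingMm)
}

## centred/one-sided finite differences along one dimension; NA-aware
.grad_1d <- function(v) {
  n <- length(v)
  g <- rep(NA_real_, n)
  if (n < 2L) return(g)
  for (i in seq_len(n)) {
    lo <- if (i > 1L) v[i - 1L] else NA
    hi <- if (i < n) v[i + 1L] else NA
    g[i] <- if (!is.na(lo) && !is.na(hi)) (hi - lo) / 2
            else if (!is.na(hi) && !is.na(v[i])) hi - v[i]
            else if (!is.na(lo) && !is.na(v[i])) v[i] - lo
            else NA_real_
  }
  g
}

## Gaussian smoothing of a grid, ignoring NAs (missing-aware normalisation)
.gauss_smooth_grid <- function(g, sigma) {
  if (sigma <= 0) return(g)
  rad <- ceiling(3 * sigma)
  k <- outer(-rad:rad, -rad:rad,
             function(dr, dc) exp(-(dr^2 + dc^2) / (2 * sigma^2)))
  nr <- nrow(g); nc <- ncol(g)
  out <- g
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(g[r, c])) next
    rr <- max(1L, r - rad):min(nr, r + rad)
    cc <- max(1L, c - rad):min(nc, c + rad)
    sub <- g[rr, cc, drop = FALSE]
    w <- k[rr - r + rad + 1L, cc - c + rad + 1L, drop = FALSE]
    w[is.na(sub)] <- 0
    sub[is.na(sub)] <- 0
    out[r, c] <- sum(w * sub) / sum(w)
  }
  out
}

#' Conduction-velocity field by smoothed finite differences
#'
#' The activation-time gradient is taken by central differences (one-sided
#' at borders and next to missing sites), both components are smoothed
#' with a missing-aware truncated Gaussian kernel, and velocity follows as
#' `v = g / |g|^2` scaled to mm/s by the electrode spacing. Because
#' smoothing a constant gradient with a normalised kernel is the identity,
#' an exact planar wave yields the closed-form speed `spacing/delay` at
#' every defined site. Sites whose gradient magnitude falls below
#' `min_grad` (simultaneous activation; would imply unphysically high
#' speed) are flagged undefined.
#'
#' @param map an [ActivationMap-class] (optionally SIV-interpolated).
#' @param spacing_mm electrode spacing; defaults to the map's.
#' @param sigma_sites Gaussian smoothing sigma in electrode units
#'   (kernel truncated at 3 sigma).
#' @param min_grad minimum gradient magnitude in s/mm.
#' @param use_interpolated include SIV-interpolated sites; set `FALSE` to
#'   restrict to measured sites.
#' @return a [VelocityField-class].
#' @export
computeVelocityField <- function(map, spacing_mm = map@spacingMm,
                                 sigma_sites = 1, min_grad = 1e-3,
                                 use_interpolated = TRUE) {
  if (spacing_mm <= 0) stop("spacing_mm must be positive")
  keep <- if (use_interpolated) c("measured", "interpolated") else "measured"
  tm <- map@times
  tm[!(map@flags %in% keep)] <- NA
  if (all(is.na(tm))) stop("activation map has no usable sites")
  nr <- nrow(tm); nc <- ncol(tm)
  gx <- t(apply(tm, 1L, .grad_1d))          # d/dcol, s per site
  gy <- apply(tm, 2L, .grad_1d)             # d/drow
  if (nc == 1L) gx <- matrix(NA_real_, nr, nc)
  if (nr == 1L) gy <- matrix(NA_real_, nr, nc)
  gx <- .gauss_smooth_grid(gx, sigma_sites)
  gy <- .gauss_smooth_grid(gy, sigma_sites)
  gx_mm <- gx / spacing_mm; gy_mm <- gy / spacing_mm
  g2 <- gx_mm^2 + gy_mm^2
  ok <- !is.na(g2) & sqrt(g2) >= min_grad
  vx <- matrix(NA_real_, nr, nc); vy <- vx; sp <- vx
  vx[ok] <- gx_mm[ok] / g2[ok]
  vy[ok] <- gy_mm[ok] / g2[ok]
  sp[ok] <- sqrt(vx[ok]^2 + vy[ok]^2)
  fl <- matrix("undefined", nr, nc)
  fl[ok] <- "defined"
  new("VelocityField", vx = vx, vy = vy, speed = sp, flags = fl,
      cycle = map@cycle)
}

#' Peak-to-trough amplitude at one activation mark
#'
#' Takes a `window_s` (default 1.5 s) stretch of signal centred on the
#' mark, smooths its first derivative with a short Savitzky-Golay filter,
#' locates the zero crossings of the smoothed derivative, classifies each
#' by the sign change (falling crossing = local maximum, rising = local
#' minimum) and returns the span from the highest maximum to the lowest
#' minimum. This resists competing noise and fractionated deflections
#' better than a raw max-minus-min. When no maximum or no minimum is
#' found, or the window is truncated by a recording edge, the raw
#' max-minus-min is returned with `confidence = "low"`. Adding a constant
#' offset to the signal leaves the estimate unchanged.
#'
#' @param x one channel's signal (uV).
#' @param fs sampling rate (Hz).
#' @param t_mark mark time (s, relative to sample 1 at `t = 0`).
#' @param window_s analysis window length (s).
#' @param smooth_s Savitzky-Golay derivative-smoothing window (s).
#' @return list: `amplitude_uv`, `confidence` (`"high"`/`"low"`).
#' @export
estimateAmplitude <- function(x, fs, t_mark, window_s = 1.5,
                              smooth_s = 0.25) {
  n <- length(x)
  i_mark <- round(t_mark * fs) + 1L
  if (i_mark < 1L || i_mark > n)
    stop(sprintf("mark at t = %.3f s lies outside the recording", t_mark))
  half <- round(window_s / 2 * fs)
  i0 <- i_mark - half; i1 <- i_mark + half
  truncated <- i0 < 1L || i1 > n
  i0 <- max(1L, i0); i1 <- min(n, i1)
  seg <- x[i0:i1]
  conf <- if (truncated) "low" else "high"
  raw <- max(seg) - min(seg)
  if (length(seg) < 5L)
    return(list(amplitude_uv = raw, confidence = "low"))
  d <- numeric(length(seg))
  ii <- 2:(length(seg) - 1)
  d[ii] <- (seg[ii + 1] - seg[ii - 1]) / 2
  d[1] <- d[2]; d[length(d)] <- d[length(d) - 1]
  k <- .odd_window(smooth_s, fs)
  ds <- if (k < length(seg)) .sgolay_smooth(d, k, 2) else d
  s <- sign(ds)
  cross <- which(s[-length(s)] * s[-1] < 0)
  maxima <- c(); minima <- c()
  for (ci in cross) {
    if (ds[ci] > 0) maxima <- c(maxima, seg[ci + 1])   # falling crossing
    else minima <- c(minima, seg[ci + 1])              # rising crossing
  }
  if (!length(maxima) || !length(minima))
    return(list(amplitude_uv = raw, confidence = "low"))
  list(amplitude_uv = max(maxima) - min(minima), confidence = conf)
}

#' Amplitude map for one cycle
#'
#' Runs [estimateAmplitude()] at every member mark of the cycle and places
#' the results on the grid. Sites without a mark are missing.
#'
#' @param assignment a [CycleAssignment-class].
#' @param marks the matching [EventMarks-class].
#' @param layout an [ElectrodeLayout-class].
#' @param recording the filtered [SWRecording-class].
#' @param cycle_k cycle index.
#' @param params a [ParameterSet-class] (`amplitude.window_s`,
#'   `amplitude.smooth_s`).
#' @return an [AmplitudeMap-class].
#' @export
buildAmplitudeMap <- function(assignment, marks, layout, recording, cycle_k,
                              params = defaultParameters()) {
  if (cycle_k < 1L || cycle_k > assignment@nCycles)
    stop("cycle index out of range: ", cycle_k)
  gs <- layout@gridShape
  am <- matrix(NA_real_, gs[1L], gs[2L])
  cf <- matrix("missing", gs[1L], gs[2L])
  mem <- which(!is.na(assignment@cycle) & assignment@cycle == cycle_k)
  m <- marks@marks[mem, , drop = FALSE]
  pos <- .layout_pos(layout, m$channel)
  for (i in seq_len(nrow(m))) {
    ch <- match(m$channel[i], recording@channelIds)
    est <- estimateAmplitude(recording@samples[ch, ], recording@fs,
                             m$time[i] - recording@t0,
                             window_s = param(params, "amplitude.window_s"),
                             smooth_s = param(params, "amplitude.smooth_s"))
    am[pos$row[i] + 1L, pos$col[i] + 1L] <- est$amplitude_uv
    cf[pos$row[i] + 1L, pos$col[i] + 1L] <- est$confidence
  }
  new("AmplitudeMap", amplitude = am, confidence = cf,
      cycle = as.integer(cycle_k))
}

#' Inter-cycle interval (frequency) maps
#'
#' For every consecutive cycle pair the per-site interval between the two
#' measured activation times, the equivalent frequency in cycles/min and
#' a bradygastric/normal/tachygastric classification against
#' `bounds_cpm = (low, high)`. A site is defined only where both cycles
#' hold a measured (never interpolated) mark on that channel.
#'
#' @param assignment a [CycleAssignment-class] with at least two cycles.
#' @param marks the matching [EventMarks-class].
#' @param layout an [ElectrodeLayout-class].
#' @param bounds_cpm numeric `(low, high)` in cycles/min.
#' @return list of [IntervalMap-class], one per consecutive pair.
#' @export
computeIntervals <- function(assignment, marks, layout,
                             bounds_cpm = c(2, 4)) {
  if (assignment@nCycles < 2L)
    stop("need at least 2 cycles to compute intervals")
  gs <- layout@gridShape
  m <- marks@marks
  pos <- .layout_pos(layout, m$channel)
  grid_of <- function(k) {
    tm <- matrix(NA_real_, gs[1L], gs[2L])
    mem <- which(!is.na(assignment@cycle) & assignment@cycle == k)
    for (i in mem) tm[pos$row[i] + 1L, pos$col[i] + 1L] <- m$time[i]
    tm
  }
  out <- vector("list", assignment@nCycles - 1L)
  for (k in seq_len(assignment@nCycles - 1L)) {
    t1 <- grid_of(k); t2 <- grid_of(k + 1L)
    iv <- t2 - t1
    iv[!is.na(iv) & iv <= 0] <- NA
    fq <- 60 / iv
    cl <- matrix("undefined", gs[1L], gs[2L])
    def <- !is.na(iv)
    cl[def & fq < bounds_cpm[1L]] <- "brady"
    cl[def & fq > bounds_cpm[2L]] <- "tachy"
    cl[def & fq >= bounds_cpm[1L] & fq <= bounds_cpm[2L]] <- "normal"
    vals <- iv[def]
    out[[k]] <- new("IntervalMap", intervals = iv, freqCpm = fq,
                    siteClass = cl, pair = c(k, k + 1L),
                    meanS = if (length(vals)) mean(vals) else NA_real_,
                    sdS = if (length(vals) > 1L) stats::sd(vals) else NA_real_)
  }
  out
}
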