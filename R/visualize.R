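## Deterministic raster rendering of maps and propagation animations.
## Images are composed as numeric RGB arrays and written with png::writePNG,
## so identical inputs produce byte-identical files.

#' Map rendering style
#'
#' @param isochrone_interval_s time width of one isochronal band (s).
#' @param mode `"isochrone"` (banded) or `"patch"` (one colour per site).
#' @param show_grid overlay electrode circles: black = measured site,
#'   white = missing/interpolated.
#' @param cell_px rendered pixel size of one electrode cell.
#' @return list of style settings for [renderMap()].
#' @export
mapStyle <- function(isochrone_interval_s = 2, mode = "isochrone",
                     show_grid = TRUE, cell_px = 32) {
  if (isochrone_interval_s <= 0) stop("isochrone_interval_s must be positive")
  list(isochrone_interval_s = isochrone_interval_s,
       mode = match.arg(mode, c("isochrone", "patch")),
       show_grid = show_grid, cell_px = as.integer(cell_px))
}

## red-to-blue spectrum: early sites red, late sites blue
.redblue <- function(n) {
  ramp <- grDevices::colorRamp(c("#d73027", "#fdae61", "#ffffbf",
                                 "#74add1", "#313695"))
  m <- ramp(seq(0, 1, length.out = max(n, 2L)))[seq_len(max(n, 1L)), ,
                                                drop = FALSE] / 255
  m
}

#' Isochronal band indices of an activation map
#'
#' Bands are half-open intervals `[t_min + k*interval, t_min + (k+1)*interval)`.
#'
#' @param map an [ActivationMap-class].
#' @param interval_s band width (s).
#' @return list: `band` (integer matrix, `NA` at missing sites) and
#'   `n_bands` (number of occupied bands).
#' @export
isochroneBands <- function(map, interval_s) {
  tm <- map@times
  tm[map@flags == "missing"] <- NA
  if (all(is.na(tm))) stop("activation map has no usable sites")
  band <- floor((tm - min(tm, na.rm = TRUE)) / interval_s)
  list(band = band, n_bands = length(unique(band[!is.na(band)])))
}

## value grid [0,1] -> RGB array; NA -> grey
.grid_to_rgb <- function(u, palette_n = 64L) {
  pal <- .redblue(palette_n)
  nr <- nrow(u); nc <- ncol(u)
  img <- array(0.85, dim = c(nr, nc, 3))     # light grey background
  idx <- which(!is.na(u))
  if (length(idx)) {
    pi_ <- pmin(palette_n, pmax(1L, 1L + floor(u[idx] * (palette_n - 1L) + 0.5)))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- pal[pi_, ch]
      img[, , ch] <- plane
    }
  }
  img
}

## nearest-neighbour upscale of an RGB array by `f`
.upscale <- function(img, f) {
  img[rep(seq_len(nrow(img)), each = f),
      rep(seq_len(ncol(img)), each = f), , drop = FALSE]
}

## draw a filled circle of colour `col` at cell (r, c) centre
.draw_circle <- function(img, r, c, cell, radius, col) {
  cy <- (r - 0.5) * cell; cx <- (c - 0.5) * cell
  ys <- max(1, floor(cy - radius)):min(dim(img)[1], ceiling(cy + radius))
  xs <- max(1, floor(cx - radius)):min(dim(img)[2], ceiling(cx + radius))
  for (y in ys) for (x in xs)
    if ((y - cy)^2 + (x - cx)^2 <= radius^2)
      img[y, x, ] <- col
  img
}

## draw a line segment (naive supercover) in pixel coordinates
.draw_line <- function(img, y0, x0, y1, x1, col) {
  n <- max(2L, ceiling(max(abs(y1 - y0), abs(x1 - x0))) + 1L)
  ys <- round(seq(y0, y1, length.out = n))
  xs <- round(seq(x0, x1, length.out = n))
  ok <- ys >= 1 & ys <= dim(img)[1] & xs >= 1 & xs <= dim(img)[2]
  for (i in which(ok)) img[ys[i], xs[i], ] <- col
  img
}

#' Render an analysis product to a PNG image
#'
#' Activation maps render as isochronal bands (red-to-blue spectrum, early
#' to late) or as patch plots; velocity fields as a speed pseudo-colour
#' with direction arrows at the electrode sites; amplitude maps as
#' pseudo-colour patches; interval maps as patch plots. With
#' `show_grid`, electrode sites are overlaid as black circles where an
#' event was measured and white circles where the site is missing or
#' interpolated. Rendering is a pure function of its inputs: repeated
#' calls produce byte-identical files and never mutate the products.
#'
#' @param product an [ActivationMap-class], [VelocityField-class],
#'   [AmplitudeMap-class] or [IntervalMap-class].
#' @param path output PNG path.
#' @param style a [mapStyle()] list.
#' @return the path, invisibly.
#' @export
renderMap <- function(product, path, style = mapStyle()) {
  cell <- style$cell_px
  if (is(product, "ActivationMap")) {
    tm <- product@times; tm[product@flags == "missing"] <- NA
    if (all(is.na(tm))) stop("no defined sites to render")
    u <- if (style$mode == "isochrone") {
      b <- isochroneBands(product, style$isochrone_interval_s)$band
      if (max(b, na.rm = TRUE) > 0) b / max(b, na.rm = TRUE) else b * 0
    } else {
      rng <- range(tm, na.rm = TRUE)
      if (diff(rng) > 0) (tm - rng[1]) / diff(rng) else tm * 0
    }
    img <- .upscale(.grid_to_rgb(u), cell)
    overlay_flags <- product@flags
  } else if (is(product, "VelocityField")) {
    def <- product@flags == "defined"
    if (!any(def)) stop("no defined sites to render")
    sp <- product@speed
    rng <- range(sp[def])
    u <- (sp - rng[1]) / max(diff(rng), .Machine$double.eps)
    u[!def] <- NA
    img <- .upscale(.grid_to_rgb(u), cell)
    for (r in seq_len(nrow(sp))) for (c in seq_len(ncol(sp))) {
      if (!def[r, c]) next
      vn <- sqrt(product@vx[r, c]^2 + product@vy[r, c]^2)
      dx <- product@vx[r, c] / vn * 0.4 * cell
      dy <- product@vy[r, c] / vn * 0.4 * cell
      cy <- (r - 0.5) * cell; cx <- (c - 0.5) * cell
      img <- .draw_line(img, cy - dy, cx - dx, cy + dy, cx + dx, c(0, 0, 0))
      img <- .draw_circle(img, r, c, cell, 2, c(0, 0, 0))
    }
    overlay_flags <- NULL
  } else if (is(product, "AmplitudeMap")) {
    a <- product@amplitude
    if (all(is.na(a))) stop("no defined sites to render")
    rng <- range(a, na.rm = TRUE)
    u <- (a - rng[1]) / max(diff(rng), .Machine$double.eps)
    img <- .upscale(.grid_to_rgb(u), cell)
    overlay_flags <- ifelse(is.na(a), "missing", "measured")
    dim(overlay_flags) <- dim(a)
  } else if (is(product, "IntervalMap")) {
    iv <- product@intervals
    if (all(is.na(iv))) stop("no defined sites to render")
    rng <- range(iv, na.rm = TRUE)
    u <- (iv - rng[1]) / max(diff(rng), .Machine$double.eps)
    img <- .upscale(.grid_to_rgb(u), cell)    # patch plot
    overlay_flags <- ifelse(is.na(iv), "missing", "measured")
    dim(overlay_flags) <- dim(iv)
  } else stop("cannot render objects of class ", class(product))

  if (isTRUE(style$show_grid) && !is.null(overlay_flags)) {
    for (r in seq_len(nrow(overlay_flags)))
      for (c in seq_len(ncol(overlay_flags))) {
        col <- if (overlay_flags[r, c] == "measured") c(0, 0, 0) else c(1, 1, 1)
        img <- .draw_circle(img, r, c, cell, max(2, cell %/% 8), col)
      }
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Refractory-tail fade law
#'
#' Intensity of a site `dt` seconds after its activation: 1 at activation,
#' fading linearly to 0 over `tail_s` (0 before activation and from
#' `tail_s` onwards).
#'
#' @param dt time since activation (s); may be a vector.
#' @param tail_s fade-out duration (s).
#' @return intensities in `[0, 1]`.
#' @export
fadeIntensity <- function(dt, tail_s) {
  ifelse(dt < 0, 0, pmax(0, 1 - dt / tail_s))
}

#' Render a propagation animation as numbered PNG frames
#'
#' Each electrode site lights up at its activation time and fades linearly
#' over `tail_s` (the "refractory tail"). With a cycle assignment, each
#' wavefront gets its own colour; without one, a single colour is used.
#' Frame `f` shows time `t_start + (f-1)/fps`; the frame count is
#' `ceiling((t_end - t_start) * fps)`.
#'
#' @param marks an [EventMarks-class].
#' @param layout an [ElectrodeLayout-class].
#' @param out_dir output directory; frames are written as
#'   `frame_%05d.png`.
#' @param assignment optional [CycleAssignment-class] for per-cycle colours.
#' @param fps frames per second.
#' @param tail_s fade duration (s).
#' @param t_start,t_end animation window (s).
#' @param cell_px pixels per electrode cell.
#' @return character vector of frame paths, invisibly.
#' @export
renderAnimation <- function(marks, layout, out_dir, assignment = NULL,
                            fps = 10, tail_s = 2, t_start, t_end,
                            cell_px = 32) {
  if (fps <= 0) stop("fps must be positive")
  if (t_start >= t_end) stop("t_start must precede t_end")
  m <- marks@marks
  win <- m$time >= t_start - tail_s & m$time <= t_end
  if (!any(m$time >= t_start & m$time <= t_end))
    stop("no marks inside the animation window")
  pos <- .layout_pos(layout, m$channel)
  gs <- layout@gridShape
  n_frames <- ceiling((t_end - t_start) * fps)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cyc <- if (!is.null(assignment)) assignment@cycle else rep(1L, nrow(m))
  n_col <- max(1L, max(cyc, na.rm = TRUE))
  hues <- (seq_len(n_col) - 1L) / n_col
  base_cols <- t(vapply(hues, function(h) grDevices::col2rgb(
    grDevices::hsv(h, 0.9, 0.9)) / 255, numeric(3)))
  paths <- character(n_frames)
  for (f in seq_len(n_frames)) {
    tf <- t_start + (f - 1L) / fps
    img <- array(0, dim = c(gs[1L], gs[2L], 3))
    ## per site: most recent activation at or before tf
    for (i in which(win & m$time <= tf)) {
      inten <- fadeIntensity(tf - m$time[i], tail_s)
      if (inten <= 0) next
      r <- pos$row[i] + 1L; c <- pos$col[i] + 1L
      k <- if (is.na(cyc[i])) NA_integer_ else cyc[i]
      col <- if (is.na(k)) c(0.5, 0.5, 0.5) else base_cols[k, ]
      cur <- img[r, c, ]
      cand <- col * inten
      if (sum(cand) > sum(cur)) img[r, c, ] <- cand
    }
    p <- file.path(out_dir, sprintf("frame_%05d.png", f))
    png::writePNG(.upscale(img, cell_px), p)
    paths[f] <- p
  }
  invisible(paths)
}

#' Mean lit-site position of one animation frame time
#'
#' Intensity-weighted centroid of the lit sites at time `t`; used to
#' verify that a planar-wave animation advances along the propagation
#' axis.
#'
#' @param marks an [EventMarks-class].
#' @param layout an [ElectrodeLayout-class].
#' @param t frame time (s).
#' @param tail_s fade duration (s).
#' @return numeric `(row, col)` centroid in 0-based grid units, or `NA`s
#'   when nothing is lit.
#' @export
litCentroid <- function(marks, layout, t, tail_s) {
  m <- marks@marks
  pos <- .layout_pos(layout, m$channel)
  w <- fadeIntensity(t - m$time, tail_s)
  if (sum(w) <= 0) return(c(row = NA_real_, col = NA_real_))
  c(row = sum(w * pos$row) / sum(w), col = sum(w * pos$col) / sum(w))
}
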