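#' Build a rectangular electrode-grid layout
#'
#' Template form of a layout: an `n_rows x n_cols` grid filled row-major
#' with sequential channel labels. Grid indices are 0-based; row 0 is the
#' top row of rendered maps.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param spacing_mm inter-electrode distance in millimetres.
#' @param channel_ids labels to place row-major; defaults to `"ch1".."chN"`.
#' @param orientation_deg display rotation (degrees); rendering only.
#' @return an [ElectrodeLayout-class].
#' @examples
#' lay <- gridLayout(8, 8, 4)
#' placement(lay)[1, ]   # ch1 at (0, 0)
#' @export
gridLayout <- function(n_rows, n_cols, spacing_mm, channel_ids = NULL,
                       orientation_deg = 0) {
  n <- n_rows * n_cols
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(n))
  if (length(channel_ids) != n)
    stop("need ", n, " channel ids to fill the grid")
  p <- data.frame(channel = as.character(channel_ids),
                  row = rep(0:(n_rows - 1), each = n_cols),
                  col = rep(0:(n_cols - 1), times = n_rows),
                  stringsAsFactors = FALSE)
  new("ElectrodeLayout", gridShape = as.integer(c(n_rows, n_cols)),
      placement = p, spacingMm = as.numeric(spacing_mm),
      orientationDeg = as.numeric(orientation_deg))
}

#' @rdname gridLayout
#' @param gridShape integer `(n_rows, n_cols)`.
#' @param placement data.frame `channel`, `row`, `col` (0-based).
#' @export
electrodeLayout <- function(gridShape, placement, spacing_mm,
                            orientation_deg = 0) {
  placement$channel <- as.character(placement$channel)
  placement$row <- as.integer(placement$row)
  placement$col <- as.integer(placement$col)
  new("ElectrodeLayout", gridShape = as.integer(gridShape),
      placement = placement[, c("channel", "row", "col")],
      spacingMm = as.numeric(spacing_mm),
      orientationDeg = as.numeric(orientation_deg))
}

#' Read / write an electrode-layout file
#'
#' Layouts serialise to a small schema-versioned JSON file listing the grid
#' shape, spacing and every channel placement; the round trip preserves
#' the placement map exactly.
#'
#' @param layout an [ElectrodeLayout-class].
#' @param path file path.
#' @return `loadLayout` returns an [ElectrodeLayout-class].
#' @export
saveLayout <- function(layout, path) {
  payload <- list(format = "gastroMap-layout", version = 1L,
                  grid_shape = layout@gridShape,
                  spacing_mm = layout@spacingMm,
                  orientation_deg = layout@orientationDeg,
                  placement = layout@placement)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                              pretty = TRUE, dataframe = "columns"), path)
  invisible(path)
}

#' @rdname saveLayout
#' @export
loadLayout <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "gastroMap-layout"))
    stop("not a gastroMap layout file: ", path)
  electrodeLayout(obj$grid_shape, as.data.frame(obj$placement),
                  obj$spacing_mm, obj$orientation_deg)
}

## channel label -> 0-based (row, col); NA rows for unplaced channels
.layout_pos <- function(layout, channel) {
  i <- match(channel, layout@placement$channel)
  data.frame(row = layout@placement$row[i], col = layout@placement$col[i])
}

## 8-connected neighbours of a 0-based site, clipped to the grid
.neighbours8 <- function(row, col, gridShape) {
  d <- expand.grid(dr = -1:1, dc = -1:1)
  d <- d[!(d$dr == 0 & d$dc == 0), ]
  r <- row + d$dr; c <- col + d$dc
  ok <- r >= 0 & r < gridShape[1L] & c >= 0 & c < gridShape[2L]
  data.frame(row = r[ok], col = c[ok])
}
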