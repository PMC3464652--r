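## Registry of every tunable in the pipeline: default value + one-line doc.
## The flat dotted keys serialise directly to the JSON parameter file.
.param_registry <- list(
  filter.kind = list(default = "savitzky_golay",
    doc = "smoothing filter kind: moving_median | savitzky_golay | butterworth | wavelet"),
  filter.window_s = list(default = 1,
    doc = "smoother window length in seconds (moving_median, savitzky_golay)"),
  filter.poly_order = list(default = 2,
    doc = "Savitzky-Golay polynomial order"),
  filter.band = list(default = "low",
    doc = "Butterworth band: low | high | band"),
  filter.cutoff_hz = list(default = 2,
    doc = "Butterworth cutoff (Hz); two values for band"),
  filter.order = list(default = 3,
    doc = "Butterworth order"),
  filter.wavelet_name = list(default = "db4",
    doc = "wavelet family for the wavelet filter (db2|db4)"),
  filter.decomposition_level = list(default = 6,
    doc = "wavelet decomposition level"),
  filter.kept_bands = list(default = "approx",
    doc = "wavelet bands kept on reconstruction: 'approx' or comma list like 'approx,d6,d5'"),
  baseline.method = list(default = "moving_median_subtract",
    doc = "baseline removal: moving_median_subtract | highpass"),
  baseline.window_s = list(default = 20,
    doc = "moving-median baseline window (s); or high-pass cutoff (Hz) for highpass"),
  fevt.edge_len_s = list(default = 0,
    doc = "half-width of the slope stencil (s); 0 = single-sample centred difference"),
  fevt.power_p = list(default = 2,
    doc = "exponent applied to the rectified negative slope"),
  fevt.smooth_s = list(default = 0.25,
    doc = "moving-average smoothing of the detection signal (s)"),
  fevt.eta = list(default = 25,
    doc = "threshold multiplier on the moving median of the detection signal; calibrate on the slope scale and raise to power_p (default 5^2)"),
  fevt.threshold_window_s = list(default = 15,
    doc = "moving-median window for the variable threshold (s)"),
  fevt.refractory_s = list(default = 2,
    doc = "minimum spacing between marks on one channel (s)"),
  fevt.snap_window_s = list(default = 0.5,
    doc = "snap window for manual mark placement/deletion (s)"),
  fevt.deflection_sep_s = list(default = 0.5,
    doc = "minimum separation of descent maxima treated as distinct deflections (s)"),
  fevt.deflection_frac = list(default = 0.5,
    doc = "fraction of the run's peak detection signal a deflection must reach"),
  regroups.tau_s = list(default = 3,
    doc = "acceptance tolerance |t - t_pred| for region growing (s)"),
  regroups.seed_window_s = list(default = 10,
    doc = "neighbour time window used when scoring seed candidates (s)"),
  regroups.n_batch = list(default = 5,
    doc = "surface refit cadence: refit after this many acceptances"),
  regroups.min_cycle_size = list(default = 1,
    doc = "cycles smaller than this are dissolved into orphans"),
  regroups.resid_factor = list(default = 2,
    doc = "ejection threshold = max(resid_factor * fit RMS, tau_s)"),
  siv.k1 = list(default = 5,
    doc = "stage-1 neighbour threshold for SIV interpolation (1..8)"),
  siv.k2 = list(default = 3,
    doc = "stage-2 neighbour threshold for SIV interpolation (1..8)"),
  velocity.sigma_sites = list(default = 1,
    doc = "Gaussian smoothing sigma for gradient components (electrode units)"),
  velocity.min_grad_s_mm = list(default = 1e-3,
    doc = "gradient magnitude below this (s/mm) -> site undefined"),
  amplitude.window_s = list(default = 1.5,
    doc = "analysis window centred on the mark for amplitude estimation (s)"),
  amplitude.smooth_s = list(default = 0.25,
    doc = "Savitzky-Golay smoothing of the derivative before zero-crossing search (s)"),
  intervals.brady_cpm = list(default = 2,
    doc = "frequency below this (cycles/min) is classed bradygastric"),
  intervals.tachy_cpm = list(default = 4,
    doc = "frequency above this (cycles/min) is classed tachygastric"),
  map.isochrone_interval_s = list(default = 2,
    doc = "time width of one isochronal band (s)"),
  map.use_interpolated = list(default = TRUE,
    doc = "whether SIV-interpolated sites feed isochronal/velocity display"),
  animation.fps = list(default = 10,
    doc = "animation frame rate (frames/s)"),
  animation.tail_s = list(default = 2,
    doc = "refractory-tail fade-out duration after a site activates (s)")
)

#' Default pipeline parameters
#'
#' Returns the complete set of tunables with their documented defaults,
#' suitable for typical gastric applications. See
#' [describeParameters()] for the one-line documentation of each key.
#'
#' @return a [ParameterSet-class] holding every key at its default.
#' @examples
#' p <- defaultParameters()
#' param(p, "fevt.eta")
#' @export
defaultParameters <- function() {
  new("ParameterSet", values = lapply(.param_registry, `[[`, "default"))
}

#' @rdname defaultParameters
#' @return `describeParameters`: data.frame of key, default, description.
#' @export
describeParameters <- function() {
  data.frame(
    key = names(.param_registry),
    default = vapply(.param_registry,
                     function(x) paste(format(x$default), collapse = ","),
                     character(1)),
    description = vapply(.param_registry, `[[`, character(1), "doc"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Build or update a parameter set
#'
#' Starts from the defaults and applies the named overrides. Unknown keys
#' are rejected with an error naming them.
#'
#' @param ... named overrides, e.g. `parameterSet(fevt.eta = 4)`.
#' @param .base a [ParameterSet-class] to start from instead of the defaults.
#' @return a [ParameterSet-class].
#' @export
parameterSet <- function(..., .base = defaultParameters()) {
  ov <- list(...)
  if (length(ov) == 1L && is.null(names(ov)) && is.list(ov[[1L]]))
    ov <- ov[[1L]]
  unknown <- setdiff(names(ov), names(.param_registry))
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  vals <- .base@values
  vals[names(ov)] <- ov
  new("ParameterSet", values = vals)
}

#' @rdname parameterSet
#' @param params a `ParameterSet`.
#' @param key parameter key (see [describeParameters()]).
#' @export
param <- function(params, key) {
  if (!key %in% names(.param_registry))
    stop("unknown parameter key: ", key)
  params@values[[key]]
}

#' Read / write a parameter file
#'
#' Parameters serialise to a flat JSON object with a schema-version field;
#' the round trip is lossless. Unknown keys in a file are rejected.
#'
#' @param params a [ParameterSet-class].
#' @param path file path.
#' @return `loadParameters` returns a [ParameterSet-class].
#' @export
saveParameters <- function(params, path) {
  payload <- c(list(format = "gastroMap-parameters", version = 1L),
               params@values)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname saveParameters
#' @export
loadParameters <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "gastroMap-parameters"))
    stop("not a gastroMap parameter file: ", path)
  obj$format <- NULL
  obj$version <- NULL
  parameterSet(.coerce_param_types(obj))
}

## JSON parses whole numbers as integer; registry numerics are doubles
.coerce_param_types <- function(values) {
  lapply(values, function(v) if (is.integer(v)) as.numeric(v) else v)
}

setMethod("show", "ParameterSet", function(object) {
  cat(sprintf("ParameterSet: %d keys (see describeParameters())\n",
              length(object@values)))
})
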