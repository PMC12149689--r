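# Run configuration: one validated nested document holding every tunable
# of the pipeline, echoed verbatim into reports for auditability.

default_config <- function() {
  list(
    seed = 1L,
    peaks = list(          # keyframe extraction from the phase curve
      smooth_window = 3L,
      min_prominence = 0.3,
      min_separation = 5L
    ),
    detect = list(         # oriented detection head / post-processing
      conf_thresh = 0.25,
      nms_iou = 0.5,
      n_angle_bins = 36L,  # CSL bins used by the detector head (5 deg)
      csl_radius = 2L,     # Gaussian window radius, in head bins
      score_floor = 0.05   # decode floor before NMS
    ),
    depth = list(lo = 0.5, hi = 0.75, h2_mode = "union"),
    caa = list(lo = 75, hi = 95),
    scoring = list(aggregate = "max"),
    model = list(
      image_size = 128L,
      segment_length = 60L,
      backbone_channels = c(8L, 16L, 32L),
      rnn_hidden = 24L,
      rnn_layers = 2L,
      lr = 1e-3,
      detector_epochs = 25L,
      phase_epochs = 250L,
      gain_epochs = 150L,
      batch_size = 8L
    )
  )
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    if (!key %in% names(base)) {
      abort_validation(sprintf("unknown config key: %s%s", path, key))
    }
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]],
                                  paste0(path, key, "."))
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Build a validated run configuration
#'
#' Starts from the package defaults and merges a nested list of overrides.
#' Unknown keys are rejected. The resolved configuration is embedded in
#' every report the pipeline writes.
#'
#' @param ... named overrides, e.g. `depth = list(lo = 2/3, hi = 4/5)`, or a
#'   single nested list.
#' @param file optional path to a JSON (or YAML, when the yaml package is
#'   installed) configuration document applied before `...`.
#' @return a `qc_config` nested list.
#' @examples
#' cfg <- qc_config(caa = list(lo = 70, hi = 110))
#' cfg$caa
#' @export
qc_config <- function(..., file = NULL) {
  cfg <- default_config()
  if (!is.null(file)) {
    cfg <- merge_config(cfg, read_config_file(file))
  }
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && is.list(dots[[1L]])) {
    dots <- dots[[1L]]
  }
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      abort_validation("config overrides must be named")
    }
    cfg <- merge_config(cfg, dots)
  }
  structure(cfg, class = "qc_config")
}

read_config_file <- function(file) {
  if (!file.exists(file)) abort_validation(sprintf("config file not found: %s", file))
  ext <- tolower(tools::file_ext(file))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort_validation("YAML config requires the 'yaml' package; use JSON")
    }
    yaml::read_yaml(file)
  } else {
    jsonlite::read_json(file, simplifyVector = TRUE)
  }
}

#' @export
print.qc_config <- function(x, ...) {
  cat(jsonlite::toJSON(unclass(x), auto_unbox = TRUE, pretty = TRUE), "\n")
  invisible(x)
}

# Flat echo of the config used in report JSON.
config_echo <- function(config) {
  unclass(config)
}
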