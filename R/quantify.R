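# Depth (D = h2/h1) and cardiac-axis-angle (C) quantification from
# detections on the ES target frame, with open-interval thresholding.

#' Threshold presets for depth and cardiac-axis angle
#'
#' `"operational"` is the statistically calibrated default: depth normal in
#' (0.5, 0.75), axis angle normal in (75, 95) degrees. `"protocol"` mirrors
#' the clinical protocol wording: the heart silhouette covers 2/3 to 4/5 of
#' the image, and the cardiac axis deviates at most 20 degrees from the
#' vertical (long-side angle in (70, 110)).
#'
#' @param name `"operational"` or `"protocol"`.
#' @return list with `depth = c(lo, hi)` and `caa = c(lo, hi)`.
#' @export
threshold_preset <- function(name = c("operational", "protocol")) {
  name <- match.arg(name)
  switch(name,
    operational = list(depth = c(0.5, 0.75), caa = c(75, 95)),
    protocol = list(depth = c(2 / 3, 4 / 5), caa = c(70, 110))
  )
}

#' Imaging-depth quantification
#'
#' Measures the heart-silhouette-to-image height ratio `D = h2 / h1` from
#' detections on the ES target frame. `h2` is the vertical extent of the
#' union of all detection corner polygons (`h2_mode = "union"`, default) or
#' the largest single-box vertical extent (`"max_single"`); `h1` is the
#' image height. Thresholds are an open interval: boundary values fail.
#'
#' @param dets a [detections()] table (at least one detection required for a
#'   computable result).
#' @param image_height image height `h1`, pixels.
#' @param lo,hi open-interval normal range for `D` (defaults 0.5, 0.75).
#' @param h2_mode `"union"` or `"max_single"`.
#' @return a `depth_result`: list with `d`, `h2`, `h1`, `passed`,
#'   `computable`. With no detections, `computable = FALSE`, `d = NA` and
#'   `passed = FALSE` (consumed by scoring as a criterion failure that is
#'   reported distinctly from an out-of-range measurement).
#' @export
depth_ratio <- function(dets, image_height, lo = 0.5, hi = 0.75,
                        h2_mode = c("union", "max_single")) {
  h2_mode <- match.arg(h2_mode)
  dets <- as_detections(dets)
  if (!is.numeric(image_height) || image_height <= 0) {
    abort_validation("`image_height` must be positive")
  }
  if (nrow(dets) == 0L) {
    return(structure(list(d = NA_real_, h2 = NA_real_, h1 = image_height,
                          passed = FALSE, computable = FALSE,
                          lo = lo, hi = hi),
                     class = "depth_result"))
  }
  ys <- lapply(seq_len(nrow(dets)), function(i) box_corners(det_box(dets, i))[, 2])
  h2 <- if (h2_mode == "union") {
    max(unlist(ys)) - min(unlist(ys))
  } else {
    max(vapply(ys, function(y) max(y) - min(y), numeric(1)))
  }
  d <- h2 / image_height
  structure(list(d = d, h2 = h2, h1 = image_height,
                 passed = d > lo && d < hi, computable = TRUE,
                 lo = lo, hi = hi),
            class = "depth_result")
}

#' @export
print.depth_result <- function(x, ...) {
  if (!x$computable) {
    cat("<depth_result> not computable (no detections)\n")
  } else {
    cat(sprintf("<depth_result> D = %.4f (h2 = %.1f / h1 = %.1f) in (%g, %g): %s\n",
                x$d, x$h2, x$h1, x$lo, x$hi,
                if (x$passed) "normal" else "abnormal"))
  }
  invisible(x)
}

#' Cardiac-axis-angle quantification
#'
#' The cardiac-axis angle `C` is the angle between the major axis of the
#' left-ventricle detection box and the image x-axis; with the long-side
#' box convention it is directly the LV box `theta`. The highest-confidence
#' LV detection is used. Thresholds are an open interval.
#'
#' @param dets a [detections()] table.
#' @param lo,hi open-interval normal range, degrees (defaults 75, 95).
#' @return a `caa_result`: list with `c`, `passed`, `computable`. With no
#'   LV detection, `computable = FALSE`, `c = NA`, `passed = FALSE`.
#' @export
caa_angle <- function(dets, lo = 75, hi = 95) {
  dets <- as_detections(dets)
  lv <- dets[dets$label == "LV", , drop = FALSE]
  if (nrow(lv) == 0L) {
    return(structure(list(c = NA_real_, passed = FALSE, computable = FALSE,
                          lo = lo, hi = hi), class = "caa_result"))
  }
  best <- which.max(lv$conf)
  c_deg <- lv$theta[best]
  structure(list(c = c_deg, passed = c_deg > lo && c_deg < hi,
                 computable = TRUE, lo = lo, hi = hi),
            class = "caa_result")
}

#' @export
print.caa_result <- function(x, ...) {
  if (!x$computable) {
    cat("<caa_result> not computable (no LV detection)\n")
  } else {
    cat(sprintf("<caa_result> C = %.1f deg in (%g, %g): %s\n",
                x$c, x$lo, x$hi, if (x$passed) "normal" else "abnormal"))
  }
  invisible(x)
}
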