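# Oriented bounding boxes: geometry, circular smooth labels (CSL),
# rotated IoU / NMS, and the anatomical-structure presence check.

#' Anatomical structure labels of the A4C view
#'
#' Left/right ventricle, left/right atrium, interventricular septum, mitral
#' and tricuspid valve. The first five are the "essential" structures of the
#' QC protocol; the valves are optional due to individual variability.
#' @export
STRUCTURE_LABELS <- c("LV", "RV", "LA", "RA", "IVS", "MV", "TV")

#' @rdname STRUCTURE_LABELS
#' @export
ESSENTIAL_STRUCTURES <- c("LV", "RV", "LA", "RA", "IVS")

#' Oriented bounding box
#'
#' Rotated rectangle in image coordinates (x right, y down, origin at the
#' top-left pixel corner). `w` is the long side, `h` the short side, and
#' `theta` the angle of the long side against the +x axis in degrees,
#' normalized to `[0, 180)`.
#'
#' @param cx,cy center, pixels.
#' @param w,h long / short side lengths, pixels; `w >= h > 0`.
#' @param theta long-side angle, degrees in `[0, 180)`.
#' @return an `oriented_box` object.
#' @export
oriented_box <- function(cx, cy, w, h, theta) {
  for (nm in c("cx", "cy", "w", "h", "theta")) {
    stopifnot_scalar_number(get(nm), nm)
  }
  if (h <= 0 || w < h) abort_validation("need w >= h > 0")
  theta <- theta %% 180
  structure(list(cx = cx, cy = cy, w = w, h = h, theta = theta),
            class = "oriented_box")
}

#' @export
print.oriented_box <- function(x, ...) {
  cat(sprintf("<oriented_box> c=(%.1f, %.1f) %gx%g @ %.1f deg\n",
              x$cx, x$cy, x$w, x$h, x$theta))
  invisible(x)
}

#' Corner polygon of an oriented box
#'
#' @param box an `oriented_box` (or a list with cx, cy, w, h, theta).
#' @return a 4x2 matrix of (x, y) corners in consistent winding order.
#' @export
box_corners <- function(box) {
  t <- box$theta * pi / 180
  u <- c(cos(t), sin(t))          # long-side direction
  v <- c(-sin(t), cos(t))         # short-side direction
  hw <- box$w / 2; hh <- box$h / 2
  ctr <- c(box$cx, box$cy)
  rbind(ctr + hw * u + hh * v,
        ctr - hw * u + hh * v,
        ctr - hw * u - hh * v,
        ctr + hw * u - hh * v)
}

polygon_area <- function(p) {
  n <- nrow(p)
  if (is.null(n) || n < 3L) return(0)
  i2 <- c(2:n, 1L)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

# Sutherland-Hodgman clipping of convex polygon `subj` by convex `clip`.
clip_polygon <- function(subj, clip) {
  # ensure counter-clockwise orientation of the clip polygon (in the
  # mathematical sense of the signed area; consistent for the inside test)
  n <- nrow(clip)
  i2 <- c(2:n, 1L)
  signed <- sum(clip[, 1] * clip[i2, 2] - clip[i2, 1] * clip[, 2]) / 2
  if (signed < 0) clip <- clip[n:1, , drop = FALSE]
  out <- subj
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (is.null(nrow(out)) || nrow(out) == 0L) return(matrix(0, 0, 2))
    a <- clip[e, ]; b <- clip[if (e == nc) 1L else e + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    # inside: left of directed edge a->b
    d <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    d <- -d  # y-down flips handedness; sign handled via CCW normalization
    inside <- d <= 1e-12
    m <- nrow(out)
    nxt <- c(2:m, 1L)
    res <- matrix(0, 0, 2)
    for (i in seq_len(m)) {
      j <- nxt[i]
      if (inside[i]) res <- rbind(res, out[i, ])
      if (inside[i] != inside[j]) {
        t <- d[i] / (d[i] - d[j])
        res <- rbind(res, out[i, ] + t * (out[j, ] - out[i, ]))
      }
    }
    out <- res
  }
  out
}

#' Rotated intersection-over-union
#'
#' Exact IoU of two oriented boxes via convex polygon clipping of their
#' corner rectangles.
#'
#' @param a,b `oriented_box` objects.
#' @return IoU in `[0, 1]`.
#' @export
rotated_iou <- function(a, b) {
  pa <- box_corners(a); pb <- box_corners(b)
  inter <- polygon_area(clip_polygon(pa, pb))
  aa <- a$w * a$h; ab <- b$w * b$h
  un <- aa + ab - inter
  if (un <= 0) return(0)
  max(0, min(1, inter / un))
}

# --- circular smooth labels -------------------------------------------------

#' Encode a box angle as a circular smooth label (CSL) vector
#'
#' The angle is binned over `[0, 180)` degrees into `n_bins` circular bins.
#' The target vector is 1 at the angle's bin, falls off as a Gaussian
#' `exp(-d^2 / (2 r^2))` of circular bin distance `d` up to
#' `window_radius`, and is 0 elsewhere. The circular window wraps across
#' the 0/180 boundary, which removes the boundary discontinuity of plain
#' angle regression.
#'
#' @param theta angle, degrees in `[0, 180)`.
#' @param window_radius Gaussian window radius in bins (default 6).
#' @param n_bins number of angle bins (default 180, i.e. 1 degree each).
#' @return numeric label vector of length `n_bins`.
#' @examples
#' which.max(csl_encode(90))  # bin 91 (1-based) == angle bin 90
#' @export
csl_encode <- function(theta, window_radius = 6L, n_bins = 180L) {
  if (window_radius < 0) abort_validation("`window_radius` must be >= 0")
  if (!is_count(n_bins) || n_bins < 1L) abort_validation("bad `n_bins`")
  width <- 180 / n_bins
  center <- round(theta / width) %% n_bins      # 0-based bin
  bins <- 0:(n_bins - 1L)
  d <- pmin(abs(bins - center), n_bins - abs(bins - center))
  out <- numeric(n_bins)
  if (window_radius == 0) {
    out[d == 0] <- 1
  } else {
    w <- d <= window_radius
    out[w] <- exp(-d[w]^2 / (2 * window_radius^2))
    out[d == 0] <- 1
  }
  out
}

#' Decode a CSL score vector to an angle
#'
#' Argmax bin mapped back to degrees; ties resolve to the smallest bin
#' index.
#'
#' @param scores numeric vector of per-bin scores (length = `n_bins`).
#' @return angle in degrees in `[0, 180)`.
#' @export
csl_decode <- function(scores) {
  if (length(scores) == 0L) abort_validation("empty score vector")
  bin <- which.max(scores) - 1L  # which.max takes the first maximum
  width <- 180 / length(scores)
  (bin * width) %% 180
}

# --- detections -------------------------------------------------------------

#' Detection table
#'
#' Detections are plain data frames with columns `label`, `cx`, `cy`, `w`,
#' `h`, `theta` and (optionally, for predictions) `conf`. Ground-truth
#' tables omit `conf`; a missing `conf` column is treated as confidence 1.
#'
#' @param label character vector of structure labels.
#' @param cx,cy,w,h,theta numeric box parameters (see [oriented_box()]).
#' @param conf confidences in `[0, 1]`.
#' @return a `detections` data frame.
#' @export
detections <- function(label = character(), cx = numeric(), cy = numeric(),
                       w = numeric(), h = numeric(), theta = numeric(),
                       conf = rep(1, length(label))) {
  if (length(conf) && (any(conf < 0) || any(conf > 1))) {
    abort_validation("confidence must be in [0, 1]")
  }
  df <- data.frame(label = as.character(label), cx = cx, cy = cy, w = w,
                   h = h, theta = theta %% 180, conf = conf,
                   stringsAsFactors = FALSE)
  class(df) <- c("detections", "data.frame")
  df
}

as_detections <- function(df) {
  if (is.null(df) || nrow(as.data.frame(df)) == 0L) return(detections())
  df <- as.data.frame(df)
  if (!"conf" %in% names(df)) df$conf <- 1
  detections(df$label, df$cx, df$cy, df$w, df$h, df$theta, df$conf)
}

det_box <- function(det, i) {
  oriented_box(det$cx[i], det$cy[i], det$w[i], det$h[i], det$theta[i])
}

#' Rotated non-maximum suppression
#'
#' Greedy class-wise suppression: detections are visited in order of
#' descending confidence (stable with respect to the input order on ties);
#' a detection is dropped when a kept detection of the same class overlaps
#' it with rotated IoU at or above `iou_thresh`.
#'
#' @param dets a [detections()] table.
#' @param iou_thresh suppression threshold in `(0, 1]` (default 0.5).
#' @return the surviving [detections()], in original relative order.
#' @export
rotated_nms <- function(dets, iou_thresh = 0.5) {
  dets <- as_detections(dets)
  if (iou_thresh <= 0 || iou_thresh > 1) {
    abort_validation("`iou_thresh` must be in (0, 1]")
  }
  n <- nrow(dets)
  if (n <= 1L) return(dets)
  ord <- order(-dets$conf)  # stable: ties keep input order
  keep <- logical(n)
  for (i in ord) {
    ok <- TRUE
    for (j in which(keep)) {
      if (dets$label[j] == dets$label[i] &&
          rotated_iou(det_box(dets, i), det_box(dets, j)) >= iou_thresh) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  dets[keep, , drop = FALSE]
}

#' Keep the highest-confidence detection per label
#'
#' After NMS, duplicate same-label detections may survive at distant
#' locations; downstream quantification (depth, axis angle, structure
#' check) uses only the most confident one per structure.
#'
#' @param dets a [detections()] table.
#' @return [detections()] with at most one row per label (ties: first).
#' @export
top_per_label <- function(dets) {
  dets <- as_detections(dets)
  if (nrow(dets) <= 1L) return(dets)
  keep <- unlist(lapply(unique(dets$label), function(lab) {
    i <- which(dets$label == lab)
    i[which.max(dets$conf[i])]
  }))
  dets[sort(keep), , drop = FALSE]
}

#' Anatomical-structure presence check
#'
#' The five essential structures (LV, RV, LA, RA, IVS) must be visible in
#' both the ED and the ES target frame; the mitral and tricuspid valves
#' never affect the result. A structure counts as visible in a frame when
#' some detection of its label has confidence at or above `conf_thresh`.
#'
#' @param dets_ed,dets_es [detections()] on the ED / ES target frame
#'   (already NMS-filtered).
#' @param conf_thresh visibility confidence threshold (default 0.25).
#' @return a `structure_check`: list with `passed` (logical) and `missing`
#'   (data frame of `label`, `frame` in {"ED","ES"}).
#' @export
check_structures <- function(dets_ed, dets_es, conf_thresh = 0.25) {
  dets_ed <- as_detections(dets_ed)
  dets_es <- as_detections(dets_es)
  visible <- function(dets, lab) {
    any(dets$label == lab & dets$conf >= conf_thresh)
  }
  missing <- data.frame(label = character(), frame = character(),
                        stringsAsFactors = FALSE)
  for (lab in ESSENTIAL_STRUCTURES) {
    if (!visible(dets_ed, lab)) {
      missing <- rbind(missing, data.frame(label = lab, frame = "ED"))
    }
    if (!visible(dets_es, lab)) {
      missing <- rbind(missing, data.frame(label = lab, frame = "ES"))
    }
  }
  structure(list(passed = nrow(missing) == 0L, missing = missing),
            class = "structure_check")
}

#' @export
print.structure_check <- function(x, ...) {
  if (x$passed) {
    cat("<structure_check> passed: all essential structures visible\n")
  } else {
    cat("<structure_check> FAILED, missing:",
        paste(x$missing$label, x$missing$frame, sep = "@", collapse = ", "),
        "\n")
  }
  invisible(x)
}
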