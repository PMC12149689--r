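# Cardiac phase analysis: left-ventricular volume curve (LVVC) construction,
# keyframe extraction, cycle completeness, QC target selection.

#' Keyframe label list
#'
#' A validated list of end-diastole (ED) / end-systole (ES) keyframe labels.
#' Frame indices are 0-based. Labels must be strictly increasing in frame and
#' alternate in phase (no two consecutive labels share a phase).
#'
#' @param frame integer vector of 0-based frame indices.
#' @param phase character vector, each `"ED"` or `"ES"`.
#' @return a `keyframes` data frame with columns `frame` and `phase`.
#' @examples
#' keyframes(c(0, 10, 20), c("ED", "ES", "ED"))
#' @export
keyframes <- function(frame = integer(), phase = character()) {
  if (length(frame) != length(phase)) {
    abort_validation("`frame` and `phase` must have equal length")
  }
  kf <- data.frame(frame = as.integer(frame), phase = as.character(phase),
                   stringsAsFactors = FALSE)
  class(kf) <- c("keyframes", "data.frame")
  validate_keyframes(kf)
}

#' Validate a keyframe label list
#'
#' @param kf a data frame with columns `frame` (0-based) and `phase`
#'   (`"ED"`/`"ES"`).
#' @return the validated `keyframes` object, invisibly classed.
#' @export
validate_keyframes <- function(kf) {
  if (!all(c("frame", "phase") %in% names(kf))) {
    abort_validation("keyframes need `frame` and `phase` columns")
  }
  n <- nrow(kf)
  if (n == 0L) {
    class(kf) <- unique(c("keyframes", class(kf)))
    return(kf)
  }
  if (any(is.na(kf$frame)) || any(kf$frame < 0L)) {
    abort_validation("keyframe frame indices must be non-negative (0-based)")
  }
  if (!all(kf$phase %in% c("ED", "ES"))) {
    abort_validation("keyframe phases must be 'ED' or 'ES'")
  }
  if (n > 1L) {
    d <- diff(kf$frame)
    if (any(d == 0L)) abort_validation("duplicate keyframe frame indices")
    if (any(d < 0L)) abort_validation("keyframes must be sorted by frame index")
    if (any(kf$phase[-1L] == kf$phase[-n])) {
      abort_validation("keyframe phases must alternate (ED/ES)")
    }
  }
  class(kf) <- unique(c("keyframes", class(kf)))
  kf
}

#' Construct the ground-truth left-ventricular volume curve
#'
#' Builds the per-frame volume proxy in `[-1, 1]` from ED/ES keyframe labels.
#' Within a diastole segment (ES at `f_es` to ED at `f_ed`) the value at
#' frame `x` is `sin(3*pi/2 - pi*(f_es - x)/(f_ed - f_es))`; within a systole
#' segment (ED to ES) it is `sin(3*pi/2 + pi*(x - f_es)/(f_es - f_ed))`.
#' ED frames evaluate to exactly +1 and ES frames to exactly -1.
#'
#' Frames outside the labeled span carry no defined value: by default they
#' are `NA` with a `FALSE` supervision mask. With `extend = TRUE` the curve
#' is continued periodically beyond the span (mirroring the adjacent
#' segment's period) and the mask is all-`TRUE`; the phantom generator uses
#' this to provide full-span supervision.
#'
#' @param labels a [keyframes()] list with at least two entries.
#' @param n_frames total number of frames; must exceed the last label index.
#' @param extend logical; periodically extend outside the labeled span.
#' @return a `phase_curve`: list with numeric `values` (length `n_frames`)
#'   and logical `mask` marking supervised frames.
#' @examples
#' pc <- lvvc_ground_truth(keyframes(c(0, 10, 20), c("ED", "ES", "ED")), 21)
#' pc$values[c(1, 6, 11, 21)]  # +1, 0, -1, +1
#' @export
lvvc_ground_truth <- function(labels, n_frames, extend = FALSE) {
  labels <- validate_keyframes(labels)
  if (nrow(labels) < 2L) {
    abort_validation("at least two keyframe labels are required")
  }
  if (!is_count(n_frames) || n_frames <= max(labels$frame)) {
    abort_validation("`n_frames` must exceed the largest keyframe index")
  }
  n_frames <- as.integer(n_frames)
  f <- labels$frame
  p <- labels$phase

  if (extend) {
    # Periodic extension: prepend/append virtual keyframes mirroring the
    # first/last segment until the whole [0, n_frames-1] range is spanned.
    while (f[1L] > 0L) {
      gap <- f[2L] - f[1L]
      f <- c(f[1L] - gap, f)
      p <- c(setdiff(c("ED", "ES"), p[1L]), p)
    }
    while (f[length(f)] < n_frames - 1L) {
      m <- length(f)
      gap <- f[m] - f[m - 1L]
      f <- c(f, f[m] + gap)
      p <- c(p, setdiff(c("ED", "ES"), p[m]))
    }
  }

  values <- rep(NA_real_, n_frames)
  x_all <- seq_len(n_frames) - 1L  # 0-based positions
  for (i in seq_len(length(f) - 1L)) {
    f1 <- f[i]; f2 <- f[i + 1L]
    in_seg <- x_all >= f1 & x_all <= f2
    x <- x_all[in_seg]
    if (p[i] == "ES") {       # diastole: ES -> ED
      f_es <- f1; f_ed <- f2
      y <- sin(3 * pi / 2 - pi * (f_es - x) / (f_ed - f_es))
    } else {                  # systole: ED -> ES
      f_ed <- f1; f_es <- f2
      y <- sin(3 * pi / 2 + pi * (x - f_es) / (f_es - f_ed))
    }
    values[in_seg] <- y
  }
  # Endpoints are exact by construction of the sine arguments; pin them to
  # kill last-bit float error so downstream equality checks are stable.
  on_label <- f[f >= 0L & f <= n_frames - 1L]
  ph_label <- p[f >= 0L & f <= n_frames - 1L]
  values[on_label + 1L] <- ifelse(ph_label == "ED", 1, -1)

  mask <- !is.na(values)
  structure(list(values = values, mask = mask), class = "phase_curve")
}

#' @export
length.phase_curve <- function(x) length(x$values)

#' @export
print.phase_curve <- function(x, ...) {
  cat(sprintf("<phase_curve> %d frames, %d supervised, range [%.3f, %.3f]\n",
              length(x$values), sum(x$mask),
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Plot a phase curve
#' @param x a `phase_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.phase_curve <- function(x, ...) {
  graphics::plot(seq_along(x$values) - 1L, x$values, type = "l",
                 xlab = "frame", ylab = "LVVC value", ylim = c(-1, 1), ...)
}

as_phase_curve <- function(x) {
  if (inherits(x, "phase_curve")) return(x)
  if (is.numeric(x)) {
    return(structure(list(values = as.numeric(x), mask = !is.na(x)),
                     class = "phase_curve"))
  }
  abort_validation("cannot interpret input as a phase curve")
}

moving_average <- function(v, window) {
  if (window <= 1L) return(v)
  n <- length(v)
  half <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- mean(v[lo:hi])
  }
  out
}

# Local extrema (peaks of `v`) with topographic prominence.
# Returns data.frame(idx, height, prominence); idx is 1-based into v.
# Plateaus report their left-most index; endpoints count as candidates
# when strictly above their single inner neighbour (callers gate them).
find_peaks <- function(v) {
  n <- length(v)
  if (n == 0L) {
    return(data.frame(idx = integer(), height = numeric(),
                      prominence = numeric()))
  }
  if (n == 1L) return(data.frame(idx = 1L, height = v, prominence = 0))
  cand <- integer()
  for (i in seq_len(n)) {
    left_ok <- (i == 1L) || v[i] > v[i - 1L]
    right_ok <- (i == n) || v[i] >= v[i + 1L]
    if (left_ok && right_ok) {
      # skip flat continuation: plateau interior has v[i] == v[i-1]
      cand <- c(cand, i)
    }
  }
  prom <- vapply(cand, function(i) {
    h <- v[i]
    # topographic prominence: the key saddle is the lowest point on the
    # path to the nearest strictly higher terrain; a side without higher
    # terrain imposes no constraint, and a global maximum's prominence is
    # its height over the curve minimum
    lmin <- Inf; j <- i - 1L; l_found <- FALSE
    while (j >= 1L) {
      if (v[j] > h) { l_found <- TRUE; break }
      lmin <- min(lmin, v[j]); j <- j - 1L
    }
    rmin <- Inf; j <- i + 1L; r_found <- FALSE
    while (j <= n) {
      if (v[j] > h) { r_found <- TRUE; break }
      rmin <- min(rmin, v[j]); j <- j + 1L
    }
    base <- c(if (l_found) lmin, if (r_found) rmin)
    if (length(base) == 0L) h - min(v) else h - max(base)
  }, numeric(1))
  data.frame(idx = cand, height = v[cand], prominence = prom)
}

# Enforce a minimum index separation among candidates of one phase:
# greedy accept by descending prominence (ties: left-most first).
enforce_separation <- function(peaks, min_separation) {
  if (nrow(peaks) <= 1L) return(peaks)
  ord <- order(-peaks$prominence, peaks$idx)
  kept <- integer()
  for (k in ord) {
    if (all(abs(peaks$idx[k] - kept) >= min_separation)) {
      kept <- c(kept, peaks$idx[k])
    }
  }
  peaks[peaks$idx %in% kept, , drop = FALSE]
}

#' Extract ED/ES keyframes from a phase curve
#'
#' Inverts a (predicted or ground-truth) volume curve into keyframe labels:
#' local maxima become ED and local minima become ES, after optional
#' moving-average smoothing. Output alternates in phase; when two adjacent
#' keyframes share a phase the one with lower prominence is dropped.
#' A constant curve yields an empty label list. `NA` stretches (unsupervised
#' frames) are skipped; each contiguous valid run is processed on its own.
#'
#' @param curve a `phase_curve` or numeric vector.
#' @param min_separation minimum frame distance between two keyframes of the
#'   same phase (default 5).
#' @param min_prominence minimum topographic prominence of an extremum on the
#'   smoothed curve (default 0.3; curve amplitude is 2).
#' @param smooth_window moving-average window in frames (default 3; use 1 to
#'   disable smoothing).
#' @return a [keyframes()] list.
#' @export
extract_keyframes <- function(curve, min_separation = 5L,
                              min_prominence = 0.3, smooth_window = 3L) {
  curve <- as_phase_curve(curve)
  if (length(curve) == 0L) abort_validation("curve must be non-empty")
  if (min_separation < 1L) abort_validation("`min_separation` must be >= 1")
  v_all <- curve$values
  runs <- rle(!is.na(v_all))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ed <- data.frame(idx = integer(), height = numeric(),
                   prominence = numeric())
  es <- ed
  # Candidates at the raw start/end of the curve are usually truncation
  # artifacts (a rising or falling tail of a cut-off cycle), so they are
  # admitted only when they reach the amplitude established by the other
  # extrema of the same phase, within `edge_tol` of the curve range.
  # Edges of the supervised span that abut unsupervised (NA) frames carry
  # exact keyframes by construction and are always admitted.
  edge_tol <- 0.2
  gate_edges <- function(cand, run_len, at_array_start, at_array_end, rng) {
    if (nrow(cand) == 0L) return(cand)
    is_edge <- (cand$idx == 1L & at_array_start) |
      (cand$idx == run_len & at_array_end)
    if (!any(is_edge)) return(cand)
    interior_max <- if (any(!is_edge)) max(cand$height[!is_edge]) else -Inf
    keep <- !is_edge | is.infinite(interior_max) |
      cand$height >= interior_max - edge_tol * rng
    cand[keep, , drop = FALSE]
  }
  for (r in seq_along(runs$values)) {
    if (!runs$values[r]) next
    sl <- starts[r]:ends[r]
    v <- moving_average(v_all[sl], smooth_window)
    rng <- max(v) - min(v)
    if (rng < 1e-12) next  # constant stretch: no keyframes
    at_start <- starts[r] == 1L
    at_end <- ends[r] == length(v_all)
    pk <- gate_edges(find_peaks(v), length(v), at_start, at_end, rng)
    tr <- gate_edges(find_peaks(-v), length(v), at_start, at_end, rng)
    pk <- pk[pk$prominence >= min_prominence, , drop = FALSE]
    tr <- tr[tr$prominence >= min_prominence, , drop = FALSE]
    pk <- enforce_separation(pk, min_separation)
    tr <- enforce_separation(tr, min_separation)
    pk$idx <- pk$idx + sl[1L] - 1L
    tr$idx <- tr$idx + sl[1L] - 1L
    ed <- rbind(ed, pk)
    es <- rbind(es, tr)
  }
  if (nrow(ed) + nrow(es) == 0L) return(keyframes())
  all <- rbind(
    if (nrow(ed)) cbind(ed, phase = "ED"),
    if (nrow(es)) cbind(es, phase = "ES")
  )
  all <- all[order(all$idx), , drop = FALSE]
  # alternation: drop the lesser-prominence member of same-phase adjacent
  # pairs (ties: drop the later one) until the sequence alternates
  repeat {
    if (nrow(all) < 2L) break
    same <- which(all$phase[-1L] == all$phase[-nrow(all)])
    if (length(same) == 0L) break
    i <- same[1L]
    drop <- if (all$prominence[i + 1L] <= all$prominence[i]) i + 1L else i
    all <- all[-drop, , drop = FALSE]
  }
  keyframes(frame = all$idx - 1L, phase = all$phase)
}

#' Find complete cardiac cycles
#'
#' A complete cycle is a consecutive alternating keyframe triple:
#' ED-ES-ED or ES-ED-ES. All stride-1 triples are returned, so consecutive
#' cycles share keyframes.
#'
#' @param labels a [keyframes()] list.
#' @return list of `cardiac_cycle` objects (possibly empty), each with
#'   `start`, `mid`, `end` (frame, phase) and `pattern`
#'   (`"ED_ES_ED"` or `"ES_ED_ES"`).
#' @examples
#' find_complete_cycles(keyframes(c(3, 12, 24), c("ED", "ES", "ED")))
#' @export
find_complete_cycles <- function(labels) {
  labels <- validate_keyframes(labels)
  n <- nrow(labels)
  if (n < 3L) return(list())
  lapply(seq_len(n - 2L), function(i) {
    cardiac_cycle(
      start = list(frame = labels$frame[i], phase = labels$phase[i]),
      mid = list(frame = labels$frame[i + 1L], phase = labels$phase[i + 1L]),
      end = list(frame = labels$frame[i + 2L], phase = labels$phase[i + 2L])
    )
  })
}

#' Cardiac cycle triple
#'
#' @param start,mid,end lists with `frame` and `phase` fields.
#' @return a `cardiac_cycle` object.
#' @export
cardiac_cycle <- function(start, mid, end) {
  if (!(start$frame < mid$frame && mid$frame < end$frame)) {
    abort_validation("cycle keyframes must be strictly increasing")
  }
  if (start$phase != end$phase || start$phase == mid$phase) {
    abort_validation("cycle must be ED-ES-ED or ES-ED-ES")
  }
  pattern <- if (start$phase == "ED") "ED_ES_ED" else "ES_ED_ES"
  structure(list(start = start, mid = mid, end = end, pattern = pattern),
            class = "cardiac_cycle")
}

#' @export
print.cardiac_cycle <- function(x, ...) {
  cat(sprintf("<cardiac_cycle> %s: %d - %d - %d\n", x$pattern,
              x$start$frame, x$mid$frame, x$end$frame))
  invisible(x)
}

#' Select the QC target frames of a cycle
#'
#' The ES target is the cycle's ES keyframe (the mid keyframe of an
#' ED-ES-ED cycle; the start keyframe of an ES-ED-ES cycle). The ED target
#' is the remaining keyframe nearest the cycle start (the start keyframe
#' for ED-ES-ED, the mid keyframe for ES-ED-ES).
#'
#' @param cycle a `cardiac_cycle`.
#' @return a list with `ed_frame`, `es_frame`, `cycle`.
#' @export
select_qc_targets <- function(cycle) {
  stopifnot(inherits(cycle, "cardiac_cycle"))
  if (cycle$pattern == "ED_ES_ED") {
    list(ed_frame = cycle$start$frame, es_frame = cycle$mid$frame,
         cycle = cycle)
  } else {
    list(ed_frame = cycle$mid$frame, es_frame = cycle$start$frame,
         cycle = cycle)
  }
}

#' Write a phase curve to CSV
#'
#' Columns `frame` (0-based), `value`, `mask`.
#' @param curve a `phase_curve`.
#' @param path output file path.
#' @export
write_phase_curve <- function(curve, path) {
  curve <- as_phase_curve(curve)
  utils::write.csv(
    data.frame(frame = seq_along(curve$values) - 1L,
               value = curve$values, mask = curve$mask),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a phase curve from CSV
#' @param path CSV written by [write_phase_curve()].
#' @return a `phase_curve`.
#' @export
read_phase_curve <- function(path) {
  df <- utils::read.csv(path)
  structure(list(values = df$value, mask = as.logical(df$mask)),
            class = "phase_curve")
}
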