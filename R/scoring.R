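# The five-point QC scoring protocol: per-cycle score cards and the
# per-video report. A complete cardiac cycle gates everything; gain, depth
# and cardiac-axis angle are worth one point each, structure visibility two.

#' Score one cardiac cycle against the QC protocol
#'
#' Scoring starts at 0. An incomplete cardiac cycle ends QC immediately
#' with a total of 0. Otherwise: +1 if the gain on the ES target frame is
#' medium (neither high nor low), +1 if the depth ratio is in its normal
#' range, +1 if the cardiac-axis angle is in its normal range, and +2 if
#' all essential structures are visible in both the ED and ES target
#' frames. A perfect cycle scores 5. Every failed criterion contributes a
#' human-readable reason string.
#'
#' @param complete logical; does the video contain this complete cycle?
#' @param gain_class `"low"`, `"medium"` or `"high"` (or `NA` for
#'   not-computable, scored 0 with a reason).
#' @param structure a `structure_check` from [check_structures()].
#' @param depth a `depth_result` from [depth_ratio()].
#' @param caa a `caa_result` from [caa_angle()].
#' @param cycle optional `cardiac_cycle` carried into the card.
#' @return a `scorecard`: list with `complete_cycle`, `gain_score`,
#'   `depth_score`, `caa_score`, `structure_score`, `total`, `reasons`,
#'   `cycle`.
#' @examples
#' sc <- score_cycle(
#'   complete = TRUE, gain_class = "medium",
#'   structure = check_structures(
#'     detections(ESSENTIAL_STRUCTURES, 64, 64, 30, 15, 90, 0.9),
#'     detections(ESSENTIAL_STRUCTURES, 64, 64, 30, 15, 90, 0.9)),
#'   depth = depth_ratio(detections("LV", 64, 64, 300, 150, 90), 600),
#'   caa = caa_angle(detections("LV", 64, 64, 30, 15, 85)))
#' sc$total
#' @export
score_cycle <- function(complete, gain_class, structure, depth, caa,
                        cycle = NULL) {
  stopifnot(is.logical(complete), length(complete) == 1L)
  if (!complete) {
    return(new_scorecard(FALSE, 0L, 0L, 0L, 0L,
                         reasons = "incomplete cardiac cycle", cycle = cycle))
  }
  reasons <- character()

  gain_score <- 0L
  if (is.na(gain_class)) {
    reasons <- c(reasons, "gain: not computable")
  } else if (identical(gain_class, "medium")) {
    gain_score <- 1L
  } else {
    reasons <- c(reasons, sprintf("gain: %s gain", gain_class))
  }

  depth_score <- 0L
  if (!isTRUE(depth$computable)) {
    reasons <- c(reasons, "depth: not computable (no detections)")
  } else if (depth$passed) {
    depth_score <- 1L
  } else {
    reasons <- c(reasons,
                 sprintf("depth: D = %.3f outside (%g, %g)",
                         depth$d, depth$lo, depth$hi))
  }

  caa_score <- 0L
  if (!isTRUE(caa$computable)) {
    reasons <- c(reasons, "caa: not computable (no LV detection)")
  } else if (caa$passed) {
    caa_score <- 1L
  } else {
    reasons <- c(reasons,
                 sprintf("caa: C = %.1f deg outside (%g, %g)",
                         caa$c, caa$lo, caa$hi))
  }

  structure_score <- 0L
  if (isTRUE(structure$passed)) {
    structure_score <- 2L
  } else {
    miss <- paste(structure$missing$label, structure$missing$frame,
                  sep = "@", collapse = ", ")
    reasons <- c(reasons, sprintf("structure: missing %s", miss))
  }

  new_scorecard(TRUE, gain_score, depth_score, caa_score, structure_score,
                reasons = reasons, cycle = cycle)
}

new_scorecard <- function(complete, gain, depth, caa, structure, reasons,
                          cycle = NULL) {
  structure(list(
    complete_cycle = complete,
    gain_score = as.integer(gain),
    depth_score = as.integer(depth),
    caa_score = as.integer(caa),
    structure_score = as.integer(structure),
    total = as.integer(gain + depth + caa + structure),
    reasons = reasons,
    cycle = cycle
  ), class = "scorecard")
}

#' @export
print.scorecard <- function(x, ...) {
  cat(sprintf("<scorecard> total %d/5 (gain %d, depth %d, caa %d, structure %d)\n",
              x$total, x$gain_score, x$depth_score, x$caa_score,
              x$structure_score))
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = "; "), "\n")
  invisible(x)
}

#' Aggregate per-cycle score cards into a video report
#'
#' The video total is by default the maximum over its cycles (an operator
#' looks for at least one standard cycle); `"min"` and `"first"`
#' aggregation are available. A video is standard iff its total is 5.
#'
#' @param cards list of `scorecard`s (possibly empty).
#' @param aggregate `"max"`, `"min"` or `"first"`.
#' @return a `video_report`: list with `per_cycle`, `video_total`,
#'   `standard`.
#' @export
score_video <- function(cards, aggregate = c("max", "min", "first")) {
  aggregate <- match.arg(aggregate)
  totals <- vapply(cards, function(c) c$total, integer(1))
  video_total <- if (length(totals) == 0L) 0L else switch(aggregate,
    max = max(totals), min = min(totals), first = totals[1L])
  structure(list(per_cycle = cards, video_total = as.integer(video_total),
                 standard = video_total == 5L, aggregate = aggregate),
            class = "video_report")
}

#' @export
print.video_report <- function(x, ...) {
  cat(sprintf("<video_report> total %d/5 (%s), %d cycle(s), aggregate = %s\n",
              x$video_total, if (x$standard) "standard" else "non-standard",
              length(x$per_cycle), x$aggregate))
  for (c in x$per_cycle) print(c)
  invisible(x)
}
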