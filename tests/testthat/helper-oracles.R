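# Independent oracles used by the test suite. These deliberately avoid the
# package's own computational paths.

# Monte-Carlo point-in-polygon IoU for two oriented boxes.
mc_rotated_iou <- function(a, b, n = 1e5) {
  pa <- box_corners(a); pb <- box_corners(b)
  xs <- range(c(pa[, 1], pb[, 1])); ys <- range(c(pa[, 2], pb[, 2]))
  px <- stats::runif(n, xs[1], xs[2]); py <- stats::runif(n, ys[1], ys[2])
  inpoly <- function(p, x, y) {
    np <- nrow(p); i2 <- c(2:np, 1L)
    if (sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]) / 2 < 0) p <- p[np:1, ]
    ok <- rep(TRUE, length(x))
    for (i in seq_len(np)) {
      j <- if (i == np) 1L else i + 1L
      d <- (p[j, 1] - p[i, 1]) * (y - p[i, 2]) -
        (p[j, 2] - p[i, 2]) * (x - p[i, 1])
      ok <- ok & (-d <= 1e-9)
    }
    ok
  }
  ia <- inpoly(pa, px, py); ib <- inpoly(pb, px, py)
  area <- diff(xs) * diff(ys)
  inter <- mean(ia & ib) * area
  un <- a$w * a$h + b$w * b$h - inter
  inter / un
}

# Brute-force complete-cycle finder: scan every index triple and keep those
# that are consecutive in the label list and match the ED-ES-ED / ES-ED-ES
# pattern.
brute_force_cycles <- function(kf) {
  n <- nrow(kf)
  out <- list()
  if (n < 3L) return(out)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (!(i < j && j < k)) next
    if (j != i + 1L || k != j + 1L) next  # must be consecutive labels
    if (kf$phase[i] != kf$phase[k]) next
    if (kf$phase[i] == kf$phase[j]) next
    out[[length(out) + 1L]] <- c(kf$frame[i], kf$frame[j], kf$frame[k])
  }
  out
}

# Naive all-point AP: explicit threshold sweep over every distinct
# confidence, with independent (nested-loop) greedy matching at each
# operating point, integrated via the running-maximum precision envelope.
naive_ap <- function(preds, gts, iou_thresh = 0.5) {
  n_gt <- nrow(gts)
  if (is.null(preds) || nrow(preds) == 0L) return(0)
  ord <- order(-preds$conf)
  preds <- preds[ord, , drop = FALSE]
  pr <- data.frame(recall = numeric(), precision = numeric())
  for (kcut in seq_len(nrow(preds))) {
    kept <- preds[seq_len(kcut), , drop = FALSE]
    used <- logical(n_gt)
    tp <- 0L
    for (i in seq_len(nrow(kept))) {
      best <- 0; bj <- 0L
      for (j in seq_len(n_gt)) {
        if (used[j] || gts$image[j] != kept$image[i]) next
        iou <- rotated_iou(
          oriented_box(kept$cx[i], kept$cy[i], kept$w[i], kept$h[i], kept$theta[i]),
          oriented_box(gts$cx[j], gts$cy[j], gts$w[j], gts$h[j], gts$theta[j]))
        if (iou > best) { best <- iou; bj <- j }
      }
      if (best >= iou_thresh && bj > 0L) { used[bj] <- TRUE; tp <- tp + 1L }
    }
    pr <- rbind(pr, data.frame(recall = tp / n_gt, precision = tp / kcut))
  }
  mrec <- c(0, pr$recall, 1)
  mpre <- c(0, pr$precision, 0)
  for (i in rev(seq_len(length(mpre) - 1L))) mpre[i] <- max(mpre[i], mpre[i + 1L])
  idx <- which(mrec[-1L] != mrec[-length(mrec)])
  sum((mrec[idx + 1L] - mrec[idx]) * mpre[idx + 1L])
}

# Scalar evaluation of the volume-curve construction, written directly from
# the closed form (independent of the vectorized implementation).
scalar_lvvc <- function(x, f1, p1, f2) {
  if (p1 == "ES") {
    f_es <- f1; f_ed <- f2
    sin(3 * pi / 2 - pi * (f_es - x) / (f_ed - f_es))
  } else {
    f_ed <- f1; f_es <- f2
    sin(3 * pi / 2 + pi * (x - f_es) / (f_es - f_ed))
  }
}

# Random alternating keyframe list with gaps in [gap_min, gap_max].
random_keyframes <- function(n_labels, gap_min = 4L, gap_max = 12L,
                             start_max = 5L) {
  gaps <- sample(gap_min:gap_max, n_labels - 1L, replace = TRUE)
  fr <- cumsum(c(sample(0:start_max, 1L), gaps))
  first <- sample(c("ED", "ES"), 1L)
  ph <- rep(if (first == "ED") c("ED", "ES") else c("ES", "ED"),
            length.out = n_labels)
  keyframes(fr, ph)
}

# Shoelace area (independent of the package's polygon_area).
polygon_area_test <- function(p) {
  n <- nrow(p)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + p[i, 1] * p[j, 2] - p[j, 1] * p[i, 2]
  }
  abs(s) / 2
}
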