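# Evaluation metrics: keyframe frame error, rotated-box mAP/mP/mR,
# Cohen's kappa, classification accuracy / precision / recall,
# one-vs-rest ROC AUC and confusion matrices.

#' Keyframe frame error
#'
#' Matches each ground-truth keyframe to the nearest predicted keyframe of
#' the same phase (greedy by increasing distance, one-to-one; ties go to
#' the earlier prediction) and reports per-phase absolute frame errors.
#' Unmatched ground-truth keyframes are counted as misses and excluded
#' from the error vectors.
#'
#' @param pred,gt [keyframes()] lists.
#' @return list with `ed`, `es` (numeric error vectors), `misses_ed`,
#'   `misses_es`.
#' @export
frame_error <- function(pred, gt) {
  pred <- validate_keyframes(pred)
  gt <- validate_keyframes(gt)
  one_phase <- function(phase) {
    p <- pred$frame[pred$phase == phase]
    g <- gt$frame[gt$phase == phase]
    if (length(g) == 0L) return(list(err = numeric(), miss = 0L))
    if (length(p) == 0L) return(list(err = numeric(), miss = length(g)))
    pairs <- expand.grid(pi = seq_along(p), gi = seq_along(g))
    pairs$d <- abs(p[pairs$pi] - g[pairs$gi])
    pairs <- pairs[order(pairs$d, p[pairs$pi], pairs$gi), , drop = FALSE]
    used_p <- logical(length(p)); used_g <- logical(length(g))
    err <- rep(NA_real_, length(g))
    for (r in seq_len(nrow(pairs))) {
      pi <- pairs$pi[r]; gi <- pairs$gi[r]
      if (used_p[pi] || used_g[gi]) next
      used_p[pi] <- TRUE; used_g[gi] <- TRUE
      err[gi] <- pairs$d[r]
    }
    list(err = err[!is.na(err)], miss = sum(is.na(err)))
  }
  ed <- one_phase("ED"); es <- one_phase("ES")
  list(ed = ed$err, es = es$err, misses_ed = ed$miss, misses_es = es$miss)
}

#' Frame-error statistics over a set of videos
#'
#' @param errors list of [frame_error()] results (one per video).
#' @return list with `fe_ed_mean`, `fe_ed_std`, `fe_es_mean`, `fe_es_std`,
#'   `n_videos`, `misses`.
#' @export
frame_error_stats <- function(errors) {
  ed <- unlist(lapply(errors, `[[`, "ed"))
  es <- unlist(lapply(errors, `[[`, "es"))
  miss <- sum(vapply(errors, function(e) e$misses_ed + e$misses_es,
                     numeric(1)))
  safe_sd <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  list(fe_ed_mean = if (length(ed)) mean(ed) else NA_real_,
       fe_ed_std = safe_sd(ed),
       fe_es_mean = if (length(es)) mean(es) else NA_real_,
       fe_es_std = safe_sd(es),
       n_videos = length(errors), misses = miss)
}

# all-point interpolated average precision from a precision/recall series
ap_from_pr <- function(tp, fp, n_gt) {
  if (n_gt == 0L || length(tp) == 0L) return(0)
  ctp <- cumsum(tp); cfp <- cumsum(fp)
  recall <- ctp / n_gt
  precision <- ctp / (ctp + cfp)
  # precision envelope (max to the right), integrate over recall steps
  mrec <- c(0, recall, 1)
  mpre <- c(0, precision, 0)
  for (i in rev(seq_len(length(mpre) - 1L))) {
    mpre[i] <- max(mpre[i], mpre[i + 1L])
  }
  idx <- which(mrec[-1L] != mrec[-length(mrec)])
  sum((mrec[idx + 1L] - mrec[idx]) * mpre[idx + 1L])
}

#' Rotated-box detection evaluation (mAP / mP / mR)
#'
#' Per-class all-point-interpolated average precision at a rotated-IoU
#' match threshold, with greedy confidence-ordered one-to-one matching
#' (each prediction may claim at most one ground-truth box, the one with
#' the highest IoU among unmatched candidates). Mean precision and recall
#' are computed over detections with confidence at or above `conf_thresh`.
#' Classes are taken from the ground truth; `map` is the unweighted mean
#' of the per-class APs.
#'
#' @param preds,gts data frames with columns `image`, `label`, `cx`, `cy`,
#'   `w`, `h`, `theta` and (preds only) `conf`.
#' @param iou_thresh rotated-IoU match threshold (default 0.5).
#' @param conf_thresh operating point for mP / mR (default 0.25).
#' @return list with `map`, `mp`, `mr`, `per_class_ap`.
#' @export
detection_map <- function(preds, gts, iou_thresh = 0.5, conf_thresh = 0.25) {
  preds <- as.data.frame(preds)
  gts <- as.data.frame(gts)
  classes <- sort(unique(gts$label))
  per_class_ap <- stats::setNames(numeric(length(classes)), classes)
  mp_k <- mr_k <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    p <- preds[preds$label == cl, , drop = FALSE]
    g <- gts[gts$label == cl, , drop = FALSE]
    n_gt <- nrow(g)
    if (nrow(p) == 0L) {
      per_class_ap[cl] <- 0; mp_k[cl] <- NA; mr_k[cl] <- 0
      next
    }
    p <- p[order(-p$conf), , drop = FALSE]
    matched_gt <- logical(n_gt)
    tp <- fp <- integer(nrow(p))
    tp_at_conf <- 0L
    for (i in seq_len(nrow(p))) {
      cand <- which(!matched_gt & g$image == p$image[i])
      best <- 0; best_j <- 0L
      bi <- oriented_box(p$cx[i], p$cy[i], max(p$w[i], p$h[i]),
                         min(p$w[i], p$h[i]),
                         if (p$w[i] >= p$h[i]) p$theta[i] else p$theta[i] + 90)
      for (j in cand) {
        bj <- oriented_box(g$cx[j], g$cy[j], max(g$w[j], g$h[j]),
                           min(g$w[j], g$h[j]),
                           if (g$w[j] >= g$h[j]) g$theta[j] else g$theta[j] + 90)
        iou <- rotated_iou(bi, bj)
        if (iou > best) { best <- iou; best_j <- j }
      }
      if (best >= iou_thresh && best_j > 0L) {
        tp[i] <- 1L
        matched_gt[best_j] <- TRUE
        if (p$conf[i] >= conf_thresh) tp_at_conf <- tp_at_conf + 1L
      } else {
        fp[i] <- 1L
      }
    }
    per_class_ap[cl] <- ap_from_pr(tp, fp, n_gt)
    n_pred_conf <- sum(p$conf >= conf_thresh)
    mp_k[cl] <- if (n_pred_conf > 0L) tp_at_conf / n_pred_conf else NA
    mr_k[cl] <- if (n_gt > 0L) tp_at_conf / n_gt else NA
  }
  list(map = mean(per_class_ap),
       mp = mean(mp_k, na.rm = TRUE),
       mr = mean(mr_k, na.rm = TRUE),
       per_class_ap = as.list(per_class_ap))
}

#' Cohen's kappa
#'
#' Unweighted chance-corrected agreement between two categorical raters:
#' `kappa = (p_o - p_e) / (1 - p_e)` with marginal-product expected
#' agreement. When both raters are constant (`p_e = 1`) kappa is defined
#' as 0 with a warning.
#'
#' @param a,b equal-length vectors of categorical scores.
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b)) abort_validation("score lists differ in length")
  if (length(a) == 0L) abort_validation("empty score lists")
  lev <- sort(unique(c(a, b)))
  ta <- table(factor(a, levels = lev))
  tb <- table(factor(b, levels = lev))
  n <- length(a)
  p_o <- mean(a == b)
  p_e <- sum(as.numeric(ta) * as.numeric(tb)) / n^2
  if (abs(1 - p_e) < 1e-12) {
    warning("degenerate kappa (both raters constant); returning 0")
    return(0)
  }
  (p_o - p_e) / (1 - p_e)
}

# one-vs-rest AUC by the rank statistic (Mann-Whitney, ties averaged)
rank_auc <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification report
#'
#' Accuracy, macro precision/recall, one-vs-rest ROC AUC per class with
#' macro average, and the confusion matrix. Classes absent from `labels`
#' get an undefined AUC and are excluded from the macro average with a
#' warning.
#'
#' @param pred_probs numeric matrix, one row per sample, columns = class
#'   probabilities (rows sum to 1); column names are the class labels.
#' @param labels character/factor vector of true labels.
#' @return list with `accuracy`, `macro_precision`, `macro_recall`, `auc`
#'   (per class), `macro_auc`, `confusion` (rows = truth).
#' @export
classification_report <- function(pred_probs, labels) {
  pred_probs <- as.matrix(pred_probs)
  if (is.null(colnames(pred_probs))) {
    abort_validation("`pred_probs` needs class column names")
  }
  if (any(abs(rowSums(pred_probs) - 1) > 1e-6)) {
    abort_validation("probability rows must sum to 1")
  }
  classes <- colnames(pred_probs)
  labels <- as.character(labels)
  pred <- classes[max.col(pred_probs, ties.method = "first")]
  acc <- mean(pred == labels)
  conf <- table(truth = factor(labels, levels = classes),
                pred = factor(pred, levels = classes))
  prec <- rec <- auc <- stats::setNames(rep(NA_real_, length(classes)),
                                        classes)
  for (cl in classes) {
    tp <- sum(pred == cl & labels == cl)
    prec[cl] <- if (sum(pred == cl) > 0L) tp / sum(pred == cl) else NA
    rec[cl] <- if (sum(labels == cl) > 0L) tp / sum(labels == cl) else NA
    auc[cl] <- rank_auc(pred_probs[, cl], labels == cl)
  }
  if (any(is.na(auc))) {
    warning("AUC undefined for class(es) absent from labels: ",
            paste(classes[is.na(auc)], collapse = ", "))
  }
  list(accuracy = acc,
       macro_precision = mean(prec, na.rm = TRUE),
       macro_recall = mean(rec, na.rm = TRUE),
       auc = as.list(auc),
       macro_auc = mean(auc, na.rm = TRUE),
       confusion = conf)
}
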