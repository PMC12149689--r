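# Trainable components with fixed contracts: shared convolutional backbone,
# oriented detection head with circular-smooth-label angle classification,
# bidirectional LSTM phase regressor, gain classification head, the staged
# training procedure (detector first; backbone frozen afterwards) and the
# end-to-end QC pipeline. Desk scale: everything trains on phantoms on one
# CPU. The backbone is a small configurable convolutional pyramid, not a
# YOLOv5 replica; the contracts (inputs, outputs, losses) are what is
# reproduced here.

GAIN_LEVELS <- c("low", "medium", "high")

backbone_stride <- 8L

# Three stride-2 stages plus a dilated stride-1 tail: a 16x16 grid at
# 128x128 input with a ~95-pixel receptive field. The wide field gives the
# context needed to tell the four chambers apart (the heart silhouette
# spans ~0.6 of the image); the 8-pixel stride keeps the in-cell offset
# regression fine enough for the thin valve bars.
new_backbone <- function(channels = c(8L, 16L, 32L)) {
  c1 <- channels[1]; c2 <- channels[2]; c3 <- channels[3]
  first <- nn_conv(1L, c1, k = 3L, stride = 2L)
  first$skip_input_grad <- TRUE
  list(
    first, nn_relu(),
    nn_conv(c1, c2, k = 3L, stride = 2L), nn_relu(),
    nn_conv(c2, c3, k = 3L, stride = 2L), nn_relu(),
    nn_conv(c3, c3, k = 3L, stride = 1L), nn_relu(),
    nn_conv(c3, c3, k = 3L, stride = 1L, dilation = 2L), nn_relu(),
    nn_conv(c3, c3, k = 3L, stride = 1L, dilation = 2L), nn_relu()
  )
}

backbone_channels_out <- function(bundle) {
  utils::tail(bundle$config$model$backbone_channels, 1L)
}

backbone_features <- function(bundle, frame) {
  x <- array(frame, c(dim(frame), 1L))
  net_forward(bundle$backbone, x)
}

pool_features <- function(fmap) {
  apply(fmap, 3L, mean)
}

# Statistics pooling for the gain head: per-channel mean and spatial
# standard deviation of the deep feature map. The detector-trained
# backbone is pushed towards gain-invariant responses, so second moments
# retain considerably more of the intensity regime than the mean alone.
pool_gain_features <- function(fmap) {
  m <- apply(fmap, 3L, mean)
  s <- apply(fmap, 3L, stats::sd)
  c(m, s)
}

#' Model bundle
#'
#' Container for the trained components: `backbone` (frame to feature
#' map), `detector` (feature map to oriented detections), `phase_head`
#' (pooled feature sequence to phase curve), `gain_head` (pooled features
#' to gain class probabilities), plus the resolved configuration and
#' training loss traces.
#'
#' @name model_bundle
NULL

new_bundle <- function(config) {
  structure(list(backbone = NULL, detector = NULL, phase_head = NULL,
                 gain_head = NULL, config = config,
                 loss_traces = list()),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  have <- c(backbone = !is.null(x$backbone), detector = !is.null(x$detector),
            phase = !is.null(x$phase_head), gain = !is.null(x$gain_head))
  cat("<model_bundle>", paste(names(have)[have], collapse = " + "), "\n")
  invisible(x)
}

#' Backbone parameter state
#'
#' Plain-list snapshot of all backbone parameters; used to verify that the
#' backbone stays frozen during phase / gain training.
#' @param bundle a `model_bundle`.
#' @return nested list of parameter arrays.
#' @export
backbone_state <- function(bundle) net_state(bundle$backbone)

# --- detector ---------------------------------------------------------------

# Channel layout of the dense head output, per cell:
# [K class logits | K * (tx, ty, tw, th) | K * n_bins angle logits].
# Box and angle predictors are per class: an A4C frame carries at most one
# instance of each structure, so class-specific regressors cannot collide
# when two structure centers share a grid cell.
detector_channels <- function(n_classes, n_bins) {
  n_classes * (5L + n_bins)
}

det_box_channels <- function(K, k) K + (k - 1L) * 4L + 1:4

det_ang_channels <- function(K, k, n_bins) {
  5L * K + (k - 1L) * n_bins + seq_len(n_bins)
}

# Build dense targets for one image: class map [G,G,K], box/angle targets
# at positive cells.
detector_targets <- function(boxes, S, n_bins, csl_radius) {
  G <- S %/% backbone_stride
  K <- length(STRUCTURE_LABELS)
  cls <- array(0, c(G, G, K))
  # classes absent from the frame (e.g. dropped structures) are explicit
  # negative supervision: their cells are up-weighted so the geometric
  # prior cannot hallucinate them cheaply
  absent <- !(STRUCTURE_LABELS %in% boxes$label)
  pos <- list()
  for (i in seq_len(nrow(boxes))) {
    cellx <- min(G, max(1L, 1L + boxes$cx[i] %/% backbone_stride))
    celly <- min(G, max(1L, 1L + boxes$cy[i] %/% backbone_stride))
    k <- match(boxes$label[i], STRUCTURE_LABELS)
    cls[celly, cellx, k] <- 1
    ang <- csl_encode(boxes$theta[i], csl_radius, n_bins)
    pos[[length(pos) + 1L]] <- list(
      row = celly, col = cellx, class = k,
      tx = boxes$cx[i] / backbone_stride - (cellx - 1L),
      ty = boxes$cy[i] / backbone_stride - (celly - 1L),
      tw = log(boxes$w[i] / S), th = log(boxes$h[i] / S),
      # IoU-aware offset weights: a fixed pixel error matters in
      # proportion to the box extent along that axis, so thin boxes
      # (valve bars) get a tighter localization target
      wx = min(3, max(0.5, backbone_stride / boxes$w[i])),
      wy = min(3, max(0.5, backbone_stride / boxes$h[i])),
      ang = ang / sum(ang))
  }
  list(cls = cls, pos = pos, G = G, absent = absent)
}

# Loss + gradient at the head output for one image.
# Head output layout along channel dim: [K class logits | tx ty tw th |
# n_bins angle logits].
detector_loss_grad <- function(out, tg, n_bins, pos_weight = 50,
                               absent_weight = 5) {
  K <- length(STRUCTURE_LABELS)
  G <- tg$G
  dout <- array(0, dim(out))
  # classification: weighted BCE with logits over all cells/classes
  z <- out[, , seq_len(K), drop = FALSE]
  t <- tg$cls
  p <- sigmoid(z)
  wts <- ifelse(t > 0, pos_weight, 1)
  if (any(tg$absent)) {
    for (k in which(tg$absent)) wts[, , k] <- absent_weight
  }
  n_cls <- length(z)
  eps <- 1e-12
  l_cls <- sum(wts * -(t * log(p + eps) + (1 - t) * log(1 - p + eps))) / n_cls
  dout[, , seq_len(K)] <- wts * (p - t) / n_cls

  l_box <- 0; l_ang <- 0
  npos <- length(tg$pos)
  if (npos > 0L) {
    box_w <- 5; ang_w <- 0.5
    for (ps in tg$pos) {
      r <- ps$row; c <- ps$col; k <- ps$class
      bc <- det_box_channels(K, k)
      zb <- out[r, c, bc]
      sxy <- sigmoid(zb[1:2])
      wv <- c(ps$wx, ps$wy, 1, 1)
      resid <- (c(sxy - c(ps$tx, ps$ty), zb[3:4] - c(ps$tw, ps$th))) * wv
      l_box <- l_box + sum(resid^2)
      dres <- 2 * resid * wv
      dout[r, c, bc] <- dout[r, c, bc] + box_w *
        c(dres[1:2] * sxy * (1 - sxy), dres[3:4]) / npos
      ac <- det_ang_channels(K, k, n_bins)
      za <- out[r, c, ac]
      pa <- exp(za - max(za)); pa <- pa / sum(pa)
      l_ang <- l_ang - sum(ps$ang * log(pa + 1e-12))
      dout[r, c, ac] <- dout[r, c, ac] + ang_w * (pa - ps$ang) / npos
    }
    l_box <- box_w * l_box / npos
    l_ang <- ang_w * l_ang / npos
  }
  list(loss = l_cls + l_box + l_ang, grad = dout,
       parts = c(cls = l_cls, box = l_box, ang = l_ang))
}

# Sub-bin angle decoding: circular softmax-weighted mean over a +-2 bin
# window around the argmax. The public csl_decode keeps the plain argmax
# contract; the detector uses this refinement so the angle resolution is
# not limited to the head's bin width.
csl_refine <- function(za, window = 2L) {
  n_bins <- length(za)
  width <- 180 / n_bins
  p <- exp(za - max(za)); p <- p / sum(p)
  bin <- which.max(p) - 1L
  offs <- -window:window
  idx <- ((bin + offs) %% n_bins) + 1L
  w <- p[idx]
  ((bin + sum(offs * w) / sum(w)) * width) %% 180
}

# 3x3 per-class local maxima above a floor.
local_max_cells <- function(score, floor) {
  G1 <- nrow(score); G2 <- ncol(score)
  out <- list()
  for (r in seq_len(G1)) {
    for (c in seq_len(G2)) {
      s <- score[r, c]
      if (s < floor) next
      nb <- score[max(1, r - 1):min(G1, r + 1), max(1, c - 1):min(G2, c + 1)]
      if (s >= max(nb)) out[[length(out) + 1L]] <- c(r, c)
    }
  }
  out
}

# Decode the dense head output into detections (pre-NMS).
decode_detections <- function(out, S, n_bins, score_floor = 0.05) {
  K <- length(STRUCTURE_LABELS)
  recs <- list()
  for (k in seq_len(K)) {
    sc <- sigmoid(out[, , k])
    for (cell in local_max_cells(sc, score_floor)) {
      r <- cell[1]; c <- cell[2]
      zb <- out[r, c, det_box_channels(K, k)]
      cx <- (c - 1L + sigmoid(zb[1])) * backbone_stride
      cy <- (r - 1L + sigmoid(zb[2])) * backbone_stride
      w <- exp(zb[3]) * S
      h <- exp(zb[4]) * S
      theta <- csl_refine(out[r, c, det_ang_channels(K, k, n_bins)])
      if (h > w) { tmp <- w; w <- h; h <- tmp; theta <- (theta + 90) %% 180 }
      recs[[length(recs) + 1L]] <- data.frame(
        label = STRUCTURE_LABELS[k], cx = cx, cy = cy, w = w, h = h,
        theta = theta, conf = sc[r, c], stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0L) return(detections())
  as_detections(do.call(rbind, recs))
}

#' Train the oriented structure detector (stage 1)
#'
#' Trains the shared backbone and the oriented detection head jointly. The
#' loss combines class (weighted binary cross-entropy over the prediction
#' grid), box regression (in-cell offset and log-size squared error) and
#' circular-smooth-label angle classification (soft cross-entropy) terms.
#'
#' @param dataset list of items, each `list(image = matrix, boxes =`
#'   [detections()] `)` (ground-truth boxes, `conf` ignored).
#' @param config a [qc_config()]; relevant keys under `model` and `detect`.
#' @return a `model_bundle` with trained `backbone` and `detector`, and a
#'   per-epoch `loss_traces$detector`.
#' @export
train_detector <- function(dataset, config = qc_config()) {
  if (length(dataset) == 0L) abort_validation("empty detector dataset")
  mc <- config$model
  n_bins <- config$detect$n_angle_bins
  with_seed(derive_seed(config$seed, 101L), {
    bundle <- new_bundle(config)
    bundle$backbone <- new_backbone(mc$backbone_channels)
    c3 <- utils::tail(mc$backbone_channels, 1L)
    bundle$detector <- nn_conv(c3, detector_channels(length(STRUCTURE_LABELS),
                                                     n_bins),
                               k = 1L, pad = 0L, bias_init = 0)
    # start class logits low so the background BCE is calm at init
    K <- length(STRUCTURE_LABELS)
    bundle$detector$b[seq_len(K)] <- -3
    # size bias near a typical structure scale (~0.2 of the image)
    for (k in seq_len(K)) bundle$detector$b[det_box_channels(K, k)[3:4]] <- log(0.2)
    layers <- c(bundle$backbone, list(bundle$detector))
    targets <- lapply(dataset, function(it) {
      detector_targets(as_detections(it$boxes), nrow(it$image), n_bins,
                       config$detect$csl_radius)
    })
    trace <- numeric(0)
    step <- 0L
    zero_grads(layers)
    for (ep in seq_len(mc$detector_epochs)) {
      ord <- sample.int(length(dataset))
      ep_loss <- 0
      nb <- 0L
      # step decay: drop the rate for the final third of training
      lr_ep <- mc$lr * if (ep > 0.7 * mc$detector_epochs) 0.3 else 1
      for (ii in seq_along(ord)) {
        it <- dataset[[ord[ii]]]
        x <- array(it$image, c(dim(it$image), 1L))
        out <- net_forward(layers, x)
        lg <- detector_loss_grad(out, targets[[ord[ii]]], n_bins)
        ep_loss <- ep_loss + lg$loss
        net_backward(layers, lg$grad)
        nb <- nb + 1L
        if (nb %% mc$batch_size == 0L || ii == length(ord)) {
          step <- step + 1L
          adam_step(layers, lr_ep, step)
          zero_grads(layers)
        }
      }
      trace <- c(trace, ep_loss / length(ord))
    }
    bundle$loss_traces$detector <- trace
    bundle
  })
}

#' Run the trained detector on one frame
#'
#' @param bundle a `model_bundle` with backbone and detector.
#' @param frame grayscale matrix in `[0, 1]`.
#' @param conf_thresh confidence threshold applied after NMS (default from
#'   the bundle config).
#' @return a [detections()] table.
#' @export
detect_structures <- function(bundle, frame,
                              conf_thresh = bundle$config$detect$conf_thresh) {
  fmap <- backbone_features(bundle, frame)
  detect_structures_fmap(bundle, fmap, nrow(frame), conf_thresh)
}

detect_structures_fmap <- function(bundle, fmap, S, conf_thresh) {
  out <- layer_forward(bundle$detector, fmap)
  dets <- decode_detections(out, S, bundle$config$detect$n_angle_bins,
                            bundle$config$detect$score_floor)
  dets <- rotated_nms(dets, bundle$config$detect$nms_iou)
  dets[dets$conf >= conf_thresh, , drop = FALSE]
}

# --- phase head -------------------------------------------------------------

# Per-sequence standardization of pooled features (per channel over time):
# removes inter-video appearance offsets, keeping the temporal oscillation
# the phase head regresses on.
standardize_seq <- function(Fmat) {
  mu <- colMeans(Fmat)
  sd <- apply(Fmat, 2L, stats::sd)
  sweep(sweep(Fmat, 2L, mu, "-"), 2L, pmax(sd, 1e-6), "/")
}

video_pooled_features <- function(bundle, frames) {
  t(vapply(frames, function(fr) pool_features(backbone_features(bundle, fr)),
           numeric(backbone_channels_out(bundle))))
}

# Sample a training window of length L that contains the labeled triple.
phase_window <- function(n, L, first_label, last_label) {
  if (n <= L) return(c(0L, n - 1L))
  lo <- max(0L, last_label - L + 1L)
  hi <- min(first_label, n - L)
  if (hi < lo) lo <- hi <- max(0L, min(first_label, n - L))
  s <- if (hi > lo) sample(lo:hi, 1L) else lo
  c(s, s + L - 1L)
}

#' Train the phase regression head (stage 2)
#'
#' Freezes the backbone of a detector-trained bundle and trains the
#' 2-layer bidirectional LSTM head with masked mean-squared error against
#' ground-truth volume curves on fixed-length windows guaranteed to
#' contain the labeled ED/ES triple. Videos shorter than the segment
#' length are padded by repeating edge frames, with padded frames masked
#' out of the loss.
#'
#' @param dataset list of items `list(frames = list of matrices,
#'   keyframes = ` [keyframes()] `)`.
#' @param bundle a `model_bundle` with a trained backbone.
#' @param config a [qc_config()].
#' @return the bundle with a trained `phase_head` (backbone untouched).
#' @export
train_phase <- function(dataset, bundle, config = bundle$config) {
  if (length(dataset) == 0L) abort_validation("empty phase dataset")
  if (is.null(bundle$backbone)) abort_validation("bundle lacks a backbone")
  mc <- config$model
  L <- mc$segment_length
  feats <- lapply(dataset, function(it) {
    standardize_seq(video_pooled_features(bundle, it$frames))
  })
  curves <- lapply(dataset, function(it) {
    lvvc_ground_truth(it$keyframes, length(it$frames))
  })
  with_seed(derive_seed(config$seed, 202L), {
    head <- new_bilstm_head(backbone_channels_out(bundle), mc$rnn_hidden,
                            mc$rnn_layers)
    hl <- bilstm_all_layers(head)
    trace <- numeric(0)
    step <- 0L
    for (ep in seq_len(mc$phase_epochs)) {
      ord <- sample.int(length(dataset))
      ep_loss <- 0
      lr_ep <- mc$lr * if (ep > 0.7 * mc$phase_epochs) 0.3 else 1
      for (vi in ord) {
        Fm <- feats[[vi]]
        cu <- curves[[vi]]
        n <- nrow(Fm)
        kf <- dataset[[vi]]$keyframes
        win <- phase_window(n, L, min(kf$frame), max(kf$frame))
        idx <- (win[1]:win[2]) + 1L
        X <- Fm[idx, , drop = FALSE]
        tgt <- cu$values[idx]
        msk <- cu$mask[idx]
        if (nrow(X) < L) {  # pad short videos with repeated edge frames
          padn <- L - nrow(X)
          X <- rbind(X, X[rep(nrow(X), padn), , drop = FALSE])
          tgt <- c(tgt, rep(0, padn))
          msk <- c(msk, rep(FALSE, padn))
        }
        stopifnot(all(kf$frame >= win[1] & kf$frame <= win[2]) || n <= L)
        if (!any(msk)) next
        tgt[!msk] <- 0  # NA outside the supervised span; masked out below
        zero_grads(hl)
        y <- bilstm_forward(head, X)
        resid <- (y - tgt) * msk
        loss <- sum(resid^2) / sum(msk)
        ep_loss <- ep_loss + loss
        bilstm_backward(head, 2 * resid / sum(msk))
        step <- step + 1L
        adam_step(hl, lr_ep, step)
      }
      trace <- c(trace, ep_loss / length(ord))
    }
    bundle$phase_head <- head
    bundle$loss_traces$phase <- trace
    bundle
  })
}

#' Predict the phase curve of a video
#'
#' Runs the frozen backbone + phase head over every frame; output values
#' are clipped to `[-1, 1]`.
#'
#' @param bundle a `model_bundle` with phase head.
#' @param frames list of grayscale matrices.
#' @return a `phase_curve` (all frames supervised).
#' @export
predict_phase_curve <- function(bundle, frames) {
  Fm <- standardize_seq(video_pooled_features(bundle, frames))
  y <- bilstm_forward(bundle$phase_head, Fm)
  structure(list(values = pmin(pmax(y, -1), 1),
                 mask = rep(TRUE, length(y))), class = "phase_curve")
}

# --- gain head --------------------------------------------------------------

#' Train the gain classification head (stage 2)
#'
#' Freezes the backbone and trains a softmax classifier on globally pooled
#' deep features of single frames.
#'
#' @param dataset list of items `list(image = matrix, gain = "low" |
#'   "medium" | "high")`. All three classes must be present.
#' @param bundle a `model_bundle` with a trained backbone.
#' @param config a [qc_config()].
#' @return the bundle with a trained `gain_head` (backbone untouched).
#' @export
train_gain <- function(dataset, bundle, config = bundle$config) {
  if (length(dataset) == 0L) abort_validation("empty gain dataset")
  if (is.null(bundle$backbone)) abort_validation("bundle lacks a backbone")
  labels <- vapply(dataset, function(it) it$gain, character(1))
  if (!all(GAIN_LEVELS %in% labels)) {
    abort_validation("every gain class (low/medium/high) must appear in training data")
  }
  mc <- config$model
  X <- t(vapply(dataset, function(it) {
    pool_gain_features(backbone_features(bundle, it$image))
  }, numeric(2L * backbone_channels_out(bundle))))
  yk <- match(labels, GAIN_LEVELS)
  with_seed(derive_seed(config$seed, 303L), {
    head <- nn_linear(ncol(X), 3L)
    trace <- numeric(0)
    for (ep in seq_len(mc$gain_epochs)) {
      zero_grads(list(head))
      Z <- sweep(X %*% head$W, 2L, head$b, "+")
      Z <- Z - apply(Z, 1L, max)
      P <- exp(Z) / rowSums(exp(Z))
      n <- nrow(X)
      loss <- -mean(log(P[cbind(seq_len(n), yk)] + 1e-12))
      D <- P
      D[cbind(seq_len(n), yk)] <- D[cbind(seq_len(n), yk)] - 1
      # small L2 penalty: the head is linear and must not overfit the
      # speckle realizations of the (few) training videos
      head$dW <- crossprod(X, D) / n + 1e-4 * head$W
      head$db <- colSums(D) / n
      adam_step(list(head), mc$lr * 10, ep)
      trace <- c(trace, loss)
    }
    bundle$gain_head <- head
    bundle$loss_traces$gain <- trace
    bundle
  })
}

#' Predict gain class probabilities for one frame
#'
#' @param bundle a `model_bundle` with gain head.
#' @param frame grayscale matrix.
#' @return named probability vector over low/medium/high (sums to 1).
#' @export
predict_gain <- function(bundle, frame) {
  f <- pool_gain_features(backbone_features(bundle, frame))
  z <- as.numeric(crossprod(bundle$gain_head$W, f)) + bundle$gain_head$b
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  names(p) <- GAIN_LEVELS
  p
}

# --- end-to-end pipeline ----------------------------------------------------

#' Run quality control on a video
#'
#' Pipeline order: phase curve, keyframes, complete-cycle gate, QC targets,
#' detections on the ED/ES frames, structure check, depth and cardiac-axis
#' quantification on the ES frame, gain on the ES frame, per-cycle score
#' cards, video report. The code path is identical in learned mode
#' (`bundle` supplied) and oracle mode (`annotations` supplied: the
#' ground-truth curve/keyframes, per-frame boxes and gain class bypass all
#' learned components).
#'
#' @param video an [echo_video()] (frames may be `NULL` in oracle mode).
#' @param bundle a complete `model_bundle` (learned mode).
#' @param annotations oracle annotations: a `phantom_ground_truth` or a
#'   list with `keyframes`, optionally `curve`, `boxes_per_frame` (1-based
#'   list by frame), `gain_class`, and `image_height` when no frames are
#'   available.
#' @param config a [qc_config()].
#' @return a `video_report` with attributes `targets` (per-cycle QC target
#'   frames) and `fps` (processing throughput).
#' @export
run_qc <- function(video, bundle = NULL, annotations = NULL,
                   config = if (!is.null(bundle)) bundle$config else qc_config()) {
  t0 <- proc.time()[3]
  oracle <- !is.null(annotations)
  if (!oracle && is.null(bundle)) {
    abort_validation("need either a model bundle or oracle annotations")
  }
  frames <- video$frames
  n <- if (!is.null(frames)) length(frames) else length(annotations$boxes_per_frame)
  if (n == 0L) abort_validation("video has no frames")
  image_height <- if (!is.null(frames)) {
    nrow(frames[[1L]])
  } else {
    annotations$spec$image_size %||% annotations$image_height %||%
      abort_validation("oracle mode without frames needs image_height")
  }

  # 1. phase curve
  curve <- if (oracle) {
    if (!is.null(annotations$curve)) {
      annotations$curve
    } else if (nrow(annotations$keyframes) >= 2L) {
      lvvc_ground_truth(annotations$keyframes, n, extend = TRUE)
    } else {
      structure(list(values = rep(0, n), mask = rep(TRUE, n)),
                class = "phase_curve")
    }
  } else {
    predict_phase_curve(bundle, frames)
  }

  # 2. keyframes and cycle gate
  kf <- extract_keyframes(curve,
                          min_separation = config$peaks$min_separation,
                          min_prominence = config$peaks$min_prominence,
                          smooth_window = config$peaks$smooth_window)
  cycles <- find_complete_cycles(kf)
  if (length(cycles) == 0L) {
    card <- score_cycle(FALSE, NA_character_, NULL, NULL, NULL)
    rep <- score_video(list(card), aggregate = config$scoring$aggregate)
    attr(rep, "keyframes") <- kf
    attr(rep, "fps") <- n / max(proc.time()[3] - t0, 1e-6)
    return(rep)
  }

  # cached detections per needed frame
  det_cache <- new.env(parent = emptyenv())
  get_dets <- function(frame_idx) {
    key <- as.character(frame_idx)
    if (!is.null(det_cache[[key]])) return(det_cache[[key]])
    d <- if (oracle) {
      raw <- annotations$boxes_per_frame[[frame_idx + 1L]]
      raw <- as_detections(raw)
      raw <- rotated_nms(raw, config$detect$nms_iou)
      raw[raw$conf >= config$detect$conf_thresh, , drop = FALSE]
    } else {
      detect_structures_fmap(bundle, backbone_features(bundle, frames[[frame_idx + 1L]]),
                             image_height, config$detect$conf_thresh)
    }
    det_cache[[key]] <- d
    d
  }

  cards <- lapply(cycles, function(cy) {
    tgt <- select_qc_targets(cy)
    dets_ed <- top_per_label(get_dets(tgt$ed_frame))
    dets_es <- top_per_label(get_dets(tgt$es_frame))
    gain_class <- if (oracle) {
      annotations$gain_class
    } else {
      GAIN_LEVELS[which.max(predict_gain(bundle, frames[[tgt$es_frame + 1L]]))]
    }
    score_cycle(
      complete = TRUE,
      gain_class = gain_class,
      structure = check_structures(dets_ed, dets_es,
                                   config$detect$conf_thresh),
      depth = depth_ratio(dets_es, image_height,
                          lo = config$depth$lo, hi = config$depth$hi,
                          h2_mode = config$depth$h2_mode),
      caa = caa_angle(dets_es, lo = config$caa$lo, hi = config$caa$hi),
      cycle = cy)
  })
  rep <- score_video(cards, aggregate = config$scoring$aggregate)
  attr(rep, "keyframes") <- kf
  attr(rep, "fps") <- n / max(proc.time()[3] - t0, 1e-6)
  rep
}
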