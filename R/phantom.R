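# Synthetic A4C phantom: fan-shaped sector images containing the seven
# heart structures as oriented ellipses/bars, periodic left-ventricular
# contraction following the ground-truth volume curve, three gain regimes,
# variable imaging depth and cardiac-axis rotation, structure dropout, and
# multiplicative speckle. Appearance realism is not a goal; the phantom
# reproduces the statistical/geometric structure the QC pipeline consumes.

# Canonical heart layout: unit coordinates, y down, ventricles on top
# (apex towards the sector apex), atria below, heart axis vertical
# (axis angle 90 deg). `a` = semi-long, `b` = semi-short axis; `axis` is
# the long-side angle in the canonical frame; `pulse` scales the ellipse
# with the volume curve.
canonical_heart <- function() {
  list(
    LV  = list(shape = "ellipse", cx = -0.20, cy = -0.22, a = 0.28, b = 0.150,
               axis = 90, pulse = 0.35),
    RV  = list(shape = "ellipse", cx = +0.20, cy = -0.24, a = 0.24, b = 0.130,
               axis = 90, pulse = 0.25),
    LA  = list(shape = "ellipse", cx = -0.18, cy = +0.24, a = 0.18, b = 0.130,
               axis = 90, pulse = 0),
    RA  = list(shape = "ellipse", cx = +0.19, cy = +0.24, a = 0.18, b = 0.120,
               axis = 90, pulse = 0),
    IVS = list(shape = "rect", cx = 0.00, cy = -0.22, a = 0.24, b = 0.040,
               axis = 90, pulse = 0),
    MV  = list(shape = "rect", cx = -0.19, cy = +0.03, a = 0.11, b = 0.025,
               axis = 0, pulse = 0),
    TV  = list(shape = "rect", cx = +0.20, cy = +0.03, a = 0.10, b = 0.025,
               axis = 0, pulse = 0)
  )
}

# render intensities (before gain transform and speckle)
PHANTOM_LEVELS <- list(background = 0.03, tissue = 0.50, chamber = 0.13,
                       septum = 0.85, valve = 0.62)

#' Phantom specification
#'
#' Parameters of one synthetic A4C video. Defaults describe a standard
#' acquisition: 60 frames covering a 46-frame cardiac cycle (the average
#' cycle length of clinical A4C cines at conventional frame rates), medium
#' gain, depth ratio 0.62 and axis angle 85 degrees (the clinical normal
#' means), no structure dropout.
#'
#' @param n_frames number of frames (default 60).
#' @param cycle_length cardiac cycle length in frames (>= 8; default 46).
#' @param phase_offset frame index of the first ED keyframe (default 5;
#'   clamped so a complete ED-ES-ED triple fits when one can fit).
#' @param image_size square image side, pixels (default 128).
#' @param depth target heart-silhouette-to-image height ratio in
#'   (0.1, 0.95) measured on the ES frame (default 0.62).
#' @param axis_deg target cardiac-axis angle, degrees in `[0, 180)`
#'   (default 85; 90 is a vertical axis).
#' @param gain `"low"`, `"medium"` or `"high"` (default medium).
#' @param dropout structure labels to omit from rendering and ground truth.
#' @param speckle_sigma multiplicative speckle strength (default 0.08).
#' @param seed integer seed; identical specs render bit-identical videos.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(n_frames = 60L, cycle_length = 46L,
                         phase_offset = 5L, image_size = 128L,
                         depth = 0.62, axis_deg = 85, gain = "medium",
                         dropout = character(), speckle_sigma = 0.08,
                         seed = 1L) {
  if (!is_count(n_frames) || n_frames < 1L) abort_validation("bad `n_frames`")
  if (!is_count(cycle_length) || cycle_length < 8L) {
    abort_validation("`cycle_length` must be >= 8 frames")
  }
  if (depth <= 0.1 || depth >= 0.95) {
    abort_validation("`depth` must lie in (0.1, 0.95)")
  }
  if (axis_deg < 0 || axis_deg >= 180) {
    abort_validation("`axis_deg` must lie in [0, 180)")
  }
  if (!gain %in% c("low", "medium", "high")) {
    abort_validation("`gain` must be low/medium/high")
  }
  if (!all(dropout %in% STRUCTURE_LABELS)) {
    abort_validation("unknown dropout label")
  }
  structure(list(n_frames = as.integer(n_frames),
                 cycle_length = as.integer(cycle_length),
                 phase_offset = as.integer(phase_offset),
                 image_size = as.integer(image_size),
                 depth = depth, axis_deg = axis_deg, gain = gain,
                 dropout = dropout, speckle_sigma = speckle_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Keyframe schedule over an extended horizon (for curve construction past
# the video end); returns list(all = keyframes on horizon, visible =
# keyframes inside the video).
phantom_keyframes <- function(spec) {
  c_len <- spec$cycle_length
  half <- round(c_len / 2)
  offset <- spec$phase_offset
  # clamp so a complete triple fits whenever the video is long enough
  if (spec$n_frames > c_len) {
    offset <- max(0L, min(offset, spec$n_frames - 1L - c_len))
  }
  horizon <- spec$n_frames + 2L * c_len
  ed <- seq(offset, horizon, by = c_len)
  es <- ed + half
  f <- sort(c(ed, es))
  p <- ifelse(f %in% ed, "ED", "ES")
  keep <- f <= horizon
  all <- keyframes(f[keep], p[keep])
  vis <- all[all$frame <= spec$n_frames - 1L, , drop = FALSE]
  class(vis) <- class(all)
  list(all = all, visible = vis, offset = offset)
}

rot2 <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
}

# Oriented boxes of all rendered structures at volume-curve value `yv`,
# in canonical units scaled by `k`, rotated by `phi` about the origin and
# translated by `ctr`.
phantom_boxes_at <- function(heart, yv, k, phi, ctr) {
  R <- rot2(phi)
  labs <- names(heart)
  out <- lapply(labs, function(lab) {
    s <- heart[[lab]]
    scale <- if (s$pulse > 0) sqrt(1 + s$pulse * yv) else 1
    cen <- as.numeric(R %*% c(s$cx, s$cy)) * k + ctr
    data.frame(label = lab, cx = cen[1], cy = cen[2],
               w = 2 * s$a * scale * k, h = 2 * s$b * scale * k,
               theta = (s$axis + phi) %% 180, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  df$conf <- 1
  detections(df$label, df$cx, df$cy, df$w, df$h, df$theta, df$conf)
}

union_extent_y <- function(dets) {
  ys <- unlist(lapply(seq_len(nrow(dets)), function(i) {
    box_corners(det_box(dets, i))[, 2]
  }))
  c(min(ys), max(ys))
}

# Linear pixel indices (column-major, image is S x S) covered by one
# structure at curve value `yv`, restricted to the sector. Only the
# structure's bounding subgrid is evaluated.
structure_indices <- function(s, yv, k, phi, ctr, S, sector) {
  R <- rot2(phi)
  scale <- if (s$pulse > 0) sqrt(1 + s$pulse * yv) else 1
  cen <- as.numeric(R %*% c(s$cx, s$cy)) * k + ctr
  ang <- (s$axis + phi) * pi / 180
  a <- s$a * scale * k; b <- s$b * scale * k
  r <- sqrt(a^2 + b^2)  # bounding radius
  cols <- max(1L, floor(cen[1] - r)):min(S, ceiling(cen[1] + r))
  rows <- max(1L, floor(cen[2] - r)):min(S, ceiling(cen[2] + r))
  if (length(cols) == 0L || length(rows) == 0L) return(integer(0))
  px <- rep(cols - 0.5, each = length(rows))
  py <- rep(rows - 0.5, times = length(cols))
  dx <- px - cen[1]; dy <- py - cen[2]
  u <- dx * cos(ang) + dy * sin(ang)    # along long axis
  v <- -dx * sin(ang) + dy * cos(ang)
  inside <- if (s$shape == "ellipse") {
    (u / a)^2 + (v / b)^2 <= 1
  } else {
    abs(u) <= a & abs(v) <= b
  }
  idx <- rep(rows, times = length(cols)) +
    (rep(cols, each = length(rows)) - 1L) * S
  idx <- idx[inside]
  idx[sector[idx]]
}

apply_gain <- function(img, gain) {
  if (gain == "low") {
    img * 0.4
  } else if (gain == "high") {
    pmin(img * 1.8 + matrix(stats::rnorm(length(img), 0, 0.05),
                            nrow(img), ncol(img)), 1)
  } else {
    img
  }
}

apply_speckle <- function(img, sigma) {
  if (sigma <= 0) return(img)
  u <- stats::runif(length(img))
  r <- sqrt(-2 * log(pmax(u, 1e-12))) / sqrt(pi / 2)  # Rayleigh, mean 1
  pmin(pmax(img * (1 + sigma * (r - 1)), 0), 1)
}

#' Generate one phantom video with ground truth
#'
#' Renders the fan-shaped sector, the seven structures (minus dropout),
#' periodic LV/RV contraction whose normalized LV area follows the
#' ground-truth volume curve, the gain regime and multiplicative speckle.
#' The heart ensemble is rotated to `axis_deg` and scaled so that the
#' depth ratio measured from the ground-truth boxes on the ES frame equals
#' `spec$depth` (within rasterization tolerance). Output is bit-identical
#' for identical specs.
#'
#' @param spec a [phantom_spec()].
#' @param render if `FALSE`, skip image synthesis (frames are `NULL`);
#'   ground truth is still exact. Used for annotation-only workloads.
#' @return list with `video` (an [echo_video()], frames `NULL` when
#'   `render = FALSE`) and `gt` (a `phantom_ground_truth`: `keyframes`,
#'   `curve`, `boxes_per_frame`, `gain_class`, `depth_ratio`, `caa_deg`,
#'   `expected_scorecard`, `spec`).
#' @export
generate_video <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, generate_video_impl(spec, render))
}

generate_video_impl <- function(spec, render) {
  S <- spec$image_size
  heart <- canonical_heart()
  heart <- heart[setdiff(names(heart), spec$dropout)]
  if (length(heart) == 0L) abort_validation("all structures dropped")
  kf <- phantom_keyframes(spec)

  # volume curve over the extended horizon, cropped to the video
  horizon_n <- max(kf$all$frame) + 1L
  full_curve <- lvvc_ground_truth(kf$all, horizon_n, extend = TRUE)
  values <- full_curve$values[seq_len(spec$n_frames)]
  curve <- structure(list(values = values, mask = rep(TRUE, spec$n_frames)),
                     class = "phase_curve")

  # ES-frame value (exact -1) fixes the global scale so D == spec$depth
  phi <- spec$axis_deg - 90
  ext0 <- {
    d0 <- phantom_boxes_at(heart, -1, 1, phi, c(0, 0))
    union_extent_y(d0)
  }
  k <- spec$depth * S / (ext0[2] - ext0[1])
  # center the ES-frame silhouette vertically and horizontally
  ctr_y <- S / 2 - k * (ext0[1] + ext0[2]) / 2
  ctr <- c(S / 2, ctr_y)

  boxes_per_frame <- lapply(values, function(yv) {
    phantom_boxes_at(heart, yv, k, phi, ctr)
  })

  frames <- NULL
  if (render) {
    PX <- matrix(rep(seq_len(S) - 0.5, each = S), S, S)   # x of pixel centers
    PY <- matrix(rep(seq_len(S) - 0.5, times = S), S, S)  # y of pixel centers
    # fan-shaped sector: apex near top center
    apex <- c(S / 2, 0.04 * S)
    dx <- PX - apex[1]; dy <- PY - apex[2]
    rad <- sqrt(dx^2 + dy^2)
    ang <- atan2(dx, dy)  # 0 along +y (down), symmetric
    sector <- rad <= 0.93 * S & abs(ang) <= 38 * pi / 180 & dy >= 0
    lvl <- PHANTOM_LEVELS
    level_of <- function(lab) {
      if (lab %in% c("LV", "RV", "LA", "RA")) lvl$chamber
      else if (lab == "IVS") lvl$septum else lvl$valve
    }
    # static base: sector tissue + non-pulsing chambers; septum/valves are
    # repainted per frame so the walls stay on top of the ventricles
    base <- matrix(lvl$background, S, S)
    base[sector] <- lvl$tissue
    static_idx <- list()
    for (lab in names(heart)) {
      s <- heart[[lab]]
      if (s$pulse > 0) next
      static_idx[[lab]] <- structure_indices(s, 0, k, phi, ctr, S, sector)
      if (lab %in% c("LA", "RA")) base[static_idx[[lab]]] <- level_of(lab)
    }
    dynamic <- names(heart)[vapply(heart, function(s) s$pulse > 0, logical(1))]
    overlay <- intersect(c("IVS", "MV", "TV"), names(heart))
    frames <- lapply(values, function(yv) {
      img <- base
      for (lab in dynamic) {
        img[structure_indices(heart[[lab]], yv, k, phi, ctr, S, sector)] <-
          level_of(lab)
      }
      for (lab in overlay) img[static_idx[[lab]]] <- level_of(lab)
      img <- apply_gain(img, spec$gain)
      apply_speckle(img, spec$speckle_sigma)
    })
  }

  # ground-truth quantities on the QC target frames
  cycles <- find_complete_cycles(kf$visible)
  if (length(cycles) > 0L) {
    tgt <- select_qc_targets(cycles[[1L]])
    dets_es <- boxes_per_frame[[tgt$es_frame + 1L]]
    dets_ed <- boxes_per_frame[[tgt$ed_frame + 1L]]
    dr <- depth_ratio(dets_es, S)
    ca <- caa_angle(dets_es)
    card <- score_cycle(TRUE, spec$gain,
                        check_structures(dets_ed, dets_es),
                        dr, ca, cycle = cycles[[1L]])
    gt_depth <- dr$d
    gt_caa <- if (ca$computable) ca$c else NA_real_
  } else {
    card <- score_cycle(FALSE, spec$gain, NULL,
                        structure(list(computable = FALSE), class = "depth_result"),
                        structure(list(computable = FALSE), class = "caa_result"))
    gt_depth <- NA_real_
    gt_caa <- NA_real_
  }

  video <- structure(list(frames = frames, fps = 30,
                          video_id = sprintf("phantom_seed%d", spec$seed),
                          n_frames = spec$n_frames),
                     class = "echo_video")
  gt <- structure(list(
    keyframes = kf$visible,
    curve = curve,
    boxes_per_frame = boxes_per_frame,
    gain_class = spec$gain,
    depth_ratio = gt_depth,
    caa_deg = gt_caa,
    expected_scorecard = card,
    spec = spec
  ), class = "phantom_ground_truth")
  list(video = video, gt = gt)
}

#' @export
length.phantom_ground_truth <- function(x) length(x$boxes_per_frame)

#' @export
print.phantom_ground_truth <- function(x, ...) {
  cat(sprintf("<phantom_ground_truth> %d frames, gain %s, D %.3f, C %.1f, expected total %d\n",
              length(x$boxes_per_frame), x$gain_class,
              x$depth_ratio, x$caa_deg, x$expected_scorecard$total))
  invisible(x)
}

# sample helpers for stratified spec construction (seeded by the caller)
sample_depth <- function(pass) {
  if (pass) stats::runif(1, 0.55, 0.72)
  else if (stats::runif(1) < 0.5) stats::runif(1, 0.30, 0.46)
  else stats::runif(1, 0.78, 0.90)
}

sample_axis <- function(pass) {
  if (pass) stats::runif(1, 78, 92)
  else if (stats::runif(1) < 0.5) stats::runif(1, 52, 70)
  else stats::runif(1, 100, 125)
}

# Build one spec targeting a protocol total score.
spec_for_score <- function(target, variant, seed, image_size = 128L) {
  cyc <- sample(36:52, 1L)
  off <- sample(2:8, 1L)
  base <- list(n_frames = 60L, cycle_length = cyc, phase_offset = off,
               image_size = image_size, depth = sample_depth(TRUE),
               axis_deg = sample_axis(TRUE), gain = "medium",
               dropout = character(), seed = seed)
  if (target == 0L) {
    base$n_frames <- as.integer(floor(0.8 * cyc))
  } else if (target == 4L) {
    fail <- c("gain", "depth", "caa")[(variant %% 3L) + 1L]
    if (fail == "gain") base$gain <- sample(c("low", "high"), 1L)
    if (fail == "depth") base$depth <- sample_depth(FALSE)
    if (fail == "caa") base$axis_deg <- sample_axis(FALSE)
  } else if (target == 3L) {
    base$depth <- sample_depth(FALSE)
    base$axis_deg <- sample_axis(FALSE)
  } else if (target == 2L) {
    base$gain <- sample(c("low", "high"), 1L)
    base$depth <- sample_depth(FALSE)
    base$axis_deg <- sample_axis(FALSE)
  } else if (target == 1L) {
    base$dropout <- sample(ESSENTIAL_STRUCTURES, 1L)
    base$depth <- sample_depth(FALSE)
    base$axis_deg <- sample_axis(FALSE)
  } else if (target != 5L) {
    abort_validation("target score must be in 0..5 (3-point totals need mixed criteria)")
  }
  do.call(phantom_spec, base)
}

#' Generate a stratified phantom dataset
#'
#' Deterministic stratified sampling of phantom specs. By default the
#' videos cycle through a balance that covers all criterion states: the
#' target totals 5, 4 (rotating the failed criterion among gain, depth and
#' axis angle), 3, 2, 1 (including essential-structure dropout) and 0
#' (incomplete cycle), with randomized (seeded) cycle lengths, offsets and
#' in-band/out-of-band parameter values.
#'
#' @param n number of videos.
#' @param balance optional named list of spec fields to cycle round-robin
#'   across the dataset, e.g. `list(gain = c("low", "medium", "high"))` or
#'   `list(target_score = c(0, 4, 5))`. Recognized keys: `target_score`,
#'   `gain`, `depth`, `axis_deg`, `dropout` (a list of character vectors),
#'   `n_frames`, `cycle_length`, `image_size`.
#' @param seed integer master seed; drives every random choice.
#' @param render render frames (default TRUE).
#' @return list of `n` elements, each `list(video, gt)` as returned by
#'   [generate_video()].
#' @export
generate_dataset <- function(n, balance = NULL, seed = 1L, render = TRUE) {
  if (!is_count(n) || n < 1L) abort_validation("`n` must be a positive count")
  default_targets <- c(5L, 4L, 4L, 4L, 3L, 2L, 1L, 0L, 5L, 5L)
  specs <- with_seed(derive_seed(seed, 0L), {
    lapply(seq_len(n), function(i) {
      cyc_pick <- function(v) v[[((i - 1L) %% length(v)) + 1L]]
      tgt <- if (!is.null(balance$target_score)) {
        as.integer(cyc_pick(balance$target_score))
      } else {
        default_targets[((i - 1L) %% length(default_targets)) + 1L]
      }
      image_size <- if (!is.null(balance$image_size)) {
        as.integer(cyc_pick(balance$image_size))
      } else 128L
      sp <- spec_for_score(tgt, variant = i, seed = derive_seed(seed, i),
                           image_size = image_size)
      # direct field overrides from `balance`
      fields <- intersect(names(balance),
                          c("gain", "depth", "axis_deg", "n_frames",
                            "cycle_length"))
      for (f in fields) sp[[f]] <- cyc_pick(balance[[f]])
      if (!is.null(balance$dropout)) sp$dropout <- cyc_pick(balance$dropout)
      validate_spec <- do.call(phantom_spec, unclass(sp))
      validate_spec
    })
  })
  lapply(specs, generate_video, render = render)
}

#' Write a phantom dataset to disk
#'
#' Emits, per video, a PGM frame stack plus the keyframe and ground-truth
#' detection annotation JSON, and a top-level `manifest.csv` indexing the
#' dataset (video id, directory, frame count, gain class, depth, axis
#' angle, expected total).
#'
#' @param dataset result of [generate_dataset()] (with `render = TRUE`).
#' @param dir output directory.
#' @return path of the manifest, invisibly.
#' @export
write_phantom_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(dataset), function(i) {
    item <- dataset[[i]]
    vid <- sprintf("phantom_%03d", i - 1L)
    vdir <- file.path(dir, vid)
    dir.create(vdir, showWarnings = FALSE)
    if (!is.null(item$video$frames)) {
      write_video(item$video, file.path(vdir, "frames"))
    }
    gt <- item$gt
    n_frames <- length(gt$boxes_per_frame)
    write_keyframe_annotation(gt$keyframes, n_frames,
                              file.path(vdir, "keyframes.json"), video_id = vid)
    write_detection_annotation(gt$boxes_per_frame,
                               seq_len(n_frames) - 1L,
                               file.path(vdir, "boxes.json"), gt = TRUE)
    write_phase_curve(gt$curve, file.path(vdir, "curve.csv"))
    jsonlite::write_json(list(gain_class = gt$gain_class),
                         file.path(vdir, "gain.json"), auto_unbox = TRUE)
    data.frame(video_id = vid, dir = vid, n_frames = n_frames,
               gain = gt$gain_class,
               depth = round(gt$depth_ratio, 6),
               caa = round(gt$caa_deg, 3),
               expected_total = gt$expected_scorecard$total,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
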