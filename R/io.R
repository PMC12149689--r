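# File formats: PGM frame stacks (P2/P5), video reading, annotation /
# detection / report JSON.

#' Write a grayscale frame as PGM
#'
#' Values in `[0, 1]` are quantized to 8 bits. `binary = TRUE` writes P5
#' (raw), otherwise P2 (ASCII).
#'
#' @param frame numeric matrix (rows = image rows) in `[0, 1]`.
#' @param path output path.
#' @param binary write raw P5 (default) instead of ASCII P2.
#' @export
write_pgm <- function(frame, path, binary = TRUE) {
  stopifnot(is.matrix(frame))
  v <- pmin(255L, pmax(0L, as.integer(round(frame * 255))))
  h <- nrow(frame); w <- ncol(frame)
  bytes <- as.raw(as.vector(t(matrix(v, h, w))))  # row-major scan order
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(bytes, con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", sprintf("%d %d", w, h), "255"), con)
    writeLines(paste(matrix(v, h, w)[cbind(rep(1:h, each = w), rep(1:w, h))],
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read a PGM (P2 or P5) image
#'
#' @param path file path.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) break
      if (ch == "#") {           # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) break else next
      }
      tok <- paste0(tok, ch)
    }
    tok
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) abort_validation("not a PGM (P2/P5) file")
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (magic == "P5") {
    bytes <- readBin(con, "raw", n = w * h)
    v <- as.integer(bytes)
  } else {
    v <- integer(0)
    while (length(v) < w * h) {
      tok <- read_token()
      if (!nzchar(tok)) break
      v <- c(v, as.integer(tok))
    }
  }
  if (length(v) != w * h) abort_validation("truncated PGM data")
  matrix(v, nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' In-memory video object
#'
#' @param frames list of equally sized grayscale matrices in `[0, 1]`.
#' @param fps frames per second (metadata; default 30).
#' @param video_id identifier string.
#' @return an `echo_video` object.
#' @export
echo_video <- function(frames, fps = 30, video_id = "video") {
  stopifnot(is.list(frames), length(frames) > 0L)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort_validation("all frames must share one image size")
  }
  structure(list(frames = frames, fps = fps, video_id = video_id),
            class = "echo_video")
}

#' @export
length.echo_video <- function(x) length(x$frames)

#' @export
print.echo_video <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<echo_video> '%s': %d frames of %dx%d @ %g fps\n",
              x$video_id, length(x$frames), d[1], d[2], x$fps))
  invisible(x)
}

# natural numeric sort of frame filenames; lexicographic fallback
order_frame_files <- function(files) {
  nums <- suppressWarnings(as.numeric(gsub("\\D", "", basename(files))))
  if (any(is.na(nums))) {
    warning("non-numeric frame filenames; falling back to lexicographic order")
    return(files[order(basename(files))])
  }
  files[order(nums)]
}

#' Read a video from a directory of frames
#'
#' Frames are PGM files (PNG too, when the `png` package is installed),
#' converted to grayscale float in `[0, 1]` and ordered by the natural
#' numeric sort of their filenames (lexicographic fallback with a warning
#' when filenames carry no number).
#'
#' @param path directory containing the frame files.
#' @param fps frame rate metadata (default 30).
#' @return an [echo_video()].
#' @export
read_video <- function(path, fps = 30) {
  if (!dir.exists(path)) abort_validation(sprintf("not a directory: %s", path))
  files <- list.files(path, pattern = "\\.(pgm|png)$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L) abort_validation(sprintf("no frames in %s", path))
  files <- order_frame_files(files)
  frames <- lapply(files, function(f) {
    if (grepl("\\.png$", f, ignore.case = TRUE)) {
      if (!requireNamespace("png", quietly = TRUE)) {
        abort_validation("PNG frames require the 'png' package; use PGM")
      }
      img <- png::readPNG(f)
      if (length(dim(img)) == 3L) img <- img[, , 1L]  # grayscale channel
      img
    } else {
      read_pgm(f)
    }
  })
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort_validation("mixed frame sizes in video directory")
  }
  echo_video(frames, fps = fps, video_id = basename(normalizePath(path)))
}

#' Write a video as a PGM frame stack
#'
#' @param video an [echo_video()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_video <- function(video, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(video$frames)) {
    write_pgm(video$frames[[i]], file.path(dir, sprintf("frame_%04d.pgm", i - 1L)))
  }
  invisible(dir)
}

# --- annotation JSON --------------------------------------------------------

#' Write keyframe annotations to JSON
#'
#' Schema: `{"video_id": str, "n_frames": int,
#' "keyframes": [{"frame": int, "phase": "ED"|"ES"}]}` with 0-based frames.
#'
#' @param labels a [keyframes()] list.
#' @param n_frames frame count of the video.
#' @param path output path.
#' @param video_id identifier.
#' @export
write_keyframe_annotation <- function(labels, n_frames, path,
                                      video_id = "video") {
  labels <- validate_keyframes(labels)
  obj <- list(video_id = video_id, n_frames = as.integer(n_frames),
              keyframes = lapply(seq_len(nrow(labels)), function(i) {
                list(frame = labels$frame[i], phase = labels$phase[i])
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read keyframe annotations from JSON
#'
#' @param path JSON path (see [write_keyframe_annotation()]).
#' @return list with `video_id`, `n_frames`, `keyframes` (a [keyframes()]).
#' @export
read_keyframe_annotation <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  kfs <- obj$keyframes %||% list()
  list(video_id = obj$video_id, n_frames = as.integer(obj$n_frames),
       keyframes = keyframes(
         frame = vapply(kfs, function(k) as.integer(k$frame), integer(1)),
         phase = vapply(kfs, function(k) as.character(k$phase), character(1))))
}

#' Write per-frame detections to JSON
#'
#' Schema: a list of `{"frame": int, "detections": [{"label", "cx", "cy",
#' "w", "h", "theta", "conf"}]}`; ground truth omits `conf`.
#'
#' @param boxes_per_frame named or ordered list of [detections()] tables,
#'   one per annotated frame.
#' @param frames 0-based frame indices, same length.
#' @param path output path.
#' @param gt drop the `conf` column (ground-truth convention).
#' @export
write_detection_annotation <- function(boxes_per_frame, frames, path,
                                       gt = FALSE) {
  stopifnot(length(boxes_per_frame) == length(frames))
  obj <- lapply(seq_along(frames), function(i) {
    d <- as_detections(boxes_per_frame[[i]])
    dets <- lapply(seq_len(nrow(d)), function(j) {
      rec <- list(label = d$label[j], cx = d$cx[j], cy = d$cy[j],
                  w = d$w[j], h = d$h[j], theta = d$theta[j])
      if (!gt) rec$conf <- d$conf[j]
      rec
    })
    list(frame = as.integer(frames[i]), detections = dets)
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read per-frame detections from JSON
#'
#' @param path JSON path (see [write_detection_annotation()]).
#' @return named list (names = frame indices as characters) of
#'   [detections()] tables.
#' @export
read_detection_annotation <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list()
  for (rec in obj) {
    ds <- rec$detections %||% list()
    d <- detections(
      label = vapply(ds, function(x) as.character(x$label), character(1)),
      cx = vapply(ds, function(x) as.numeric(x$cx), numeric(1)),
      cy = vapply(ds, function(x) as.numeric(x$cy), numeric(1)),
      w = vapply(ds, function(x) as.numeric(x$w), numeric(1)),
      h = vapply(ds, function(x) as.numeric(x$h), numeric(1)),
      theta = vapply(ds, function(x) as.numeric(x$theta), numeric(1)),
      conf = vapply(ds, function(x) as.numeric(x$conf %||% 1), numeric(1)))
    out[[as.character(rec$frame)]] <- d
  }
  out
}

# --- report JSON ------------------------------------------------------------

report_to_list <- function(report, video_id, config) {
  list(
    video_id = video_id,
    video_total = report$video_total,
    standard = report$standard,
    cycles = lapply(report$per_cycle, function(card) {
      tgt <- if (!is.null(card$cycle)) select_qc_targets(card$cycle) else NULL
      list(
        pattern = if (!is.null(card$cycle)) card$cycle$pattern else NA,
        ed_frame = if (!is.null(tgt)) tgt$ed_frame else NA,
        es_frame = if (!is.null(tgt)) tgt$es_frame else NA,
        scores = list(gain = card$gain_score, depth = card$depth_score,
                      caa = card$caa_score, structure = card$structure_score),
        total = card$total,
        reasons = as.list(card$reasons)
      )
    }),
    config_echo = config_echo(config)
  )
}

#' Write a video QC report to JSON
#'
#' Field names are a stable output contract: `video_id`, `video_total`,
#' `standard`, `cycles` (with `pattern`, `ed_frame`, `es_frame`, `scores`,
#' `total`, `reasons`) and `config_echo`.
#'
#' @param report a `video_report` from [score_video()] or [run_qc()].
#' @param path output path.
#' @param video_id identifier.
#' @param config the `qc_config` used (echoed into the report).
#' @export
write_report <- function(report, path, video_id = "video",
                         config = qc_config()) {
  jsonlite::write_json(report_to_list(report, video_id, config), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a QC report JSON
#' @param path report path.
#' @return the report as a nested list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
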