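# phantom module: synthetic A4C generator and its ground truth.

test_that("spec validation", {
  expect_s3_class(phantom_spec(), "phantom_spec")
  expect_error(phantom_spec(cycle_length = 4), "cycle_length")
  expect_error(phantom_spec(depth = 0.05), "depth")
  expect_error(phantom_spec(axis_deg = 200), "axis_deg")
  expect_error(phantom_spec(gain = "huge"), "gain")
  expect_error(phantom_spec(dropout = "XX"), "dropout")
})

test_that("default phantom is a standard video by construction", {
  res <- generate_video(phantom_spec(), render = FALSE)
  gt <- res$gt
  expect_identical(gt$expected_scorecard$total, 5L)
  expect_equal(gt$depth_ratio, 0.62, tolerance = 0.01)
  expect_equal(gt$caa_deg, 85, tolerance = 1)
  expect_identical(gt$gain_class, "medium")
  expect_identical(nrow(gt$keyframes), 3L)
  expect_true(all(gt$curve$mask))
  expect_length(gt$boxes_per_frame, 60L)
})

test_that("criterion-state specs induce the expected scores", {
  expect_identical(
    generate_video(phantom_spec(n_frames = 30, cycle_length = 40),
                   render = FALSE)$gt$expected_scorecard$total, 0L)
  ax <- generate_video(phantom_spec(axis_deg = 60), render = FALSE)$gt
  expect_identical(ax$expected_scorecard$total, 4L)
  expect_match(paste(ax$expected_scorecard$reasons, collapse = " "), "caa")
  gn <- generate_video(phantom_spec(gain = "high"), render = FALSE)$gt
  expect_identical(gn$expected_scorecard$total, 4L)
  dp <- generate_video(phantom_spec(depth = 0.4), render = FALSE)$gt
  expect_identical(dp$expected_scorecard$total, 4L)
  dr <- generate_video(phantom_spec(dropout = "RA"), render = FALSE)$gt
  expect_identical(dr$expected_scorecard$total, 3L)
  expect_false(any(dr$keyframes$phase == "")) # still annotated
  expect_false("RA" %in% dr$boxes_per_frame[[1]]$label)
  # dropping valves only is still standard
  dv <- generate_video(phantom_spec(dropout = c("MV", "TV")), render = FALSE)$gt
  expect_identical(dv$expected_scorecard$total, 5L)
})

test_that("expected scorecard is self-consistent with the scoring module", {
  set.seed(31)
  ds <- generate_dataset(12, seed = 66, render = FALSE)
  for (it in ds) {
    gt <- it$gt
    cycles <- find_complete_cycles(gt$keyframes)
    if (length(cycles) == 0L) {
      expect_identical(gt$expected_scorecard$total, 0L)
      next
    }
    tgt <- select_qc_targets(cycles[[1]])
    S <- gt$spec$image_size
    redo <- score_cycle(
      TRUE, gt$gain_class,
      check_structures(gt$boxes_per_frame[[tgt$ed_frame + 1]],
                       gt$boxes_per_frame[[tgt$es_frame + 1]]),
      depth_ratio(gt$boxes_per_frame[[tgt$es_frame + 1]], S),
      caa_angle(gt$boxes_per_frame[[tgt$es_frame + 1]]),
      cycle = cycles[[1]])
    expect_identical(redo$total, gt$expected_scorecard$total)
    expect_identical(redo$reasons, gt$expected_scorecard$reasons)
  }
})

test_that("GT depth and LV angle match the spec parameters", {
  for (sd in 1:4) {
    sp <- phantom_spec(depth = runif(1, 0.3, 0.9),
                       axis_deg = runif(1, 50, 130), seed = sd)
    gt <- generate_video(sp, render = FALSE)$gt
    cy <- find_complete_cycles(gt$keyframes)
    tgt <- select_qc_targets(cy[[1]])
    es_boxes <- gt$boxes_per_frame[[tgt$es_frame + 1]]
    expect_equal(depth_ratio(es_boxes, sp$image_size)$d, sp$depth,
                 tolerance = 0.02)
    lv <- es_boxes[es_boxes$label == "LV", ]
    expect_equal(lv$theta, sp$axis_deg, tolerance = 1)
  }
})

test_that("rendered LV area follows the volume curve (r > 0.99)", {
  sp <- phantom_spec(speckle_sigma = 0)
  res <- generate_video(sp)
  areas <- vapply(seq_along(res$video$frames), function(i) {
    lv <- res$gt$boxes_per_frame[[i]]
    lv <- lv[lv$label == "LV", ]
    img <- res$video$frames[[i]]
    S <- nrow(img)
    px <- matrix(rep(seq_len(S) - 0.5, each = S), S, S)
    py <- matrix(rep(seq_len(S) - 0.5, times = S), S, S)
    ang <- lv$theta * pi / 180
    dx <- px - lv$cx; dy <- py - lv$cy
    u <- dx * cos(ang) + dy * sin(ang)
    v <- -dx * sin(ang) + dy * cos(ang)
    inside <- (u / (lv$w / 2))^2 + (v / (lv$h / 2))^2 <= 1
    sum(abs(img - 0.13) < 0.01 & inside)  # chamber-intensity pixels
  }, numeric(1))
  expect_gt(cor(areas, res$gt$curve$values), 0.99)
})

test_that("generation is bit-identical for identical specs", {
  a <- generate_video(phantom_spec(seed = 7))
  b <- generate_video(phantom_spec(seed = 7))
  expect_identical(a$video$frames, b$video$frames)
  expect_identical(a$gt$boxes_per_frame, b$gt$boxes_per_frame)
  c <- generate_video(phantom_spec(seed = 8))
  expect_false(identical(a$video$frames, c$video$frames))
})

test_that("dataset balance and determinism", {
  d1 <- generate_dataset(30, balance = list(gain = c("low", "medium", "high")),
                         seed = 5, render = FALSE)
  gains <- table(vapply(d1, function(x) x$gt$gain_class, character(1)))
  expect_identical(as.integer(gains[c("low", "medium", "high")]),
                   c(10L, 10L, 10L))
  d2 <- generate_dataset(30, balance = list(gain = c("low", "medium", "high")),
                         seed = 5, render = FALSE)
  expect_identical(lapply(d1, function(x) x$gt$spec),
                   lapply(d2, function(x) x$gt$spec))
  # score balance honours the requested counts
  d3 <- generate_dataset(9, balance = list(target_score = c(0, 4, 5)),
                         seed = 6, render = FALSE)
  tot <- vapply(d3, function(x) x$gt$expected_scorecard$total, integer(1))
  expect_identical(as.integer(table(factor(tot, levels = c(0, 4, 5)))),
                   c(3L, 3L, 3L))
})

test_that("phantom dataset round-trips through disk", {
  ds <- generate_dataset(2, seed = 12,
                         balance = list(n_frames = list(16L),
                                        cycle_length = list(10L)))
  dir <- tempfile("phantomds")
  write_phantom_dataset(ds, dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_identical(nrow(man), 2L)
  vdir <- file.path(dir, man$dir[1])
  vid <- read_video(file.path(vdir, "frames"))
  expect_identical(length(vid), 16L)
  kf <- read_keyframe_annotation(file.path(vdir, "keyframes.json"))
  expect_identical(kf$keyframes$frame, ds[[1]]$gt$keyframes$frame)
  boxes <- read_detection_annotation(file.path(vdir, "boxes.json"))
  b0 <- boxes[["0"]]
  expect_equal(b0$cx, ds[[1]]$gt$boxes_per_frame[[1]]$cx, tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})
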