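# obb module: box geometry, CSL coding, rotated IoU / NMS, structure check.

test_that("oriented box validation and corner geometry", {
  b <- oriented_box(10, 20, 8, 4, 30)
  expect_equal(polygon_area_test(box_corners(b)), 32, tolerance = 1e-6)
  expect_error(oriented_box(0, 0, 2, 4, 0), "w >= h")
  expect_error(oriented_box(0, 0, 4, 0, 0), "w >= h")
  expect_equal(oriented_box(0, 0, 4, 2, 190)$theta, 10)
})

test_that("csl_encode produces the Gaussian circular window", {
  v <- csl_encode(90, window_radius = 0)
  expect_identical(which(v == 1), 91L)
  expect_identical(sum(v > 0), 1L)
  v6 <- csl_encode(179, window_radius = 6)
  expect_equal(v6[180], 1)
  expect_equal(v6[2], exp(-4 / 72), tolerance = 1e-10)  # wraps: distance 2
  expect_equal(max(v6), 1)
  # circular symmetry about the center bin
  for (d in 1:6) {
    expect_equal(v6[(179 + d) %% 180 + 1], v6[(179 - d) %% 180 + 1])
  }
  expect_error(csl_encode(10, window_radius = -1), "window_radius")
})

test_that("csl decode: argmax, ties, and encode round trip", {
  expect_equal(csl_decode(rep(1, 180)), 0)  # uniform -> smallest index
  two <- numeric(180); two[c(46, 120)] <- c(0.9, 0.5)
  expect_equal(csl_decode(two), 45)
  for (t in seq(0, 179, by = 7)) {
    for (r in c(0, 2, 6, 30)) {
      expect_equal(csl_decode(csl_encode(t, r)), t)
    }
  }
  # non-default bin count: 36 bins, 5 degree resolution
  expect_equal(csl_decode(csl_encode(88, 2, n_bins = 36)), 90)
})

test_that("rotated IoU: exact values and symmetry", {
  a <- oriented_box(0, 0, 4, 2, 0)
  expect_equal(rotated_iou(a, a), 1)
  b <- oriented_box(0, 0, 4, 2, 90)
  expect_equal(rotated_iou(a, b), 1 / 3, tolerance = 1e-9)  # overlap 2x2=4, union 12
  far <- oriented_box(10 * (4 + 2), 10 * (4 + 2), 4, 2, 45)
  expect_equal(rotated_iou(a, far), 0)
  # equals axis-aligned IoU when both angles are in {0, 90}
  c1 <- oriented_box(1, 0, 4, 2, 0)
  inter <- 3 * 2
  expect_equal(rotated_iou(a, c1), inter / (8 + 8 - inter), tolerance = 1e-9)
})

test_that("rotated IoU agrees with the Monte-Carlo oracle on random pairs", {
  set.seed(303)
  worst <- 0
  for (i in 1:60) {
    a <- oriented_box(runif(1, 30, 70), runif(1, 30, 70),
                      runif(1, 12, 40), runif(1, 6, 12), runif(1, 0, 180))
    b <- oriented_box(runif(1, 30, 70), runif(1, 30, 70),
                      runif(1, 12, 40), runif(1, 6, 12), runif(1, 0, 180))
    d1 <- rotated_iou(a, b)
    expect_equal(d1, rotated_iou(b, a), tolerance = 1e-12)  # symmetric
    worst <- max(worst, abs(d1 - mc_rotated_iou(a, b, n = 4e4)))
  }
  expect_lt(worst, 0.015)
})

test_that("rotated NMS suppresses class-wise by confidence", {
  d1 <- detections("LV", 0, 0, 4, 2, 0, 0.9)
  expect_identical(nrow(rotated_nms(d1, 0.5)), 1L)
  two <- detections(c("LV", "LV"), c(0, 0), c(0, 0), c(4, 4), c(2, 2),
                    c(0, 0), c(0.8, 0.9))
  kept <- rotated_nms(two, 0.5)
  expect_identical(nrow(kept), 1L)
  expect_equal(kept$conf, 0.9)
  disjoint <- detections(c("LV", "LV"), c(0, 100), c(0, 100), c(4, 4),
                         c(2, 2), c(0, 0), c(0.9, 0.8))
  expect_identical(nrow(rotated_nms(disjoint, 0.5)), 2L)
  # different classes never suppress each other
  cross <- detections(c("LV", "RV"), c(0, 0), c(0, 0), c(4, 4), c(2, 2),
                      c(0, 0), c(0.9, 0.8))
  expect_identical(nrow(rotated_nms(cross, 0.5)), 2L)
  expect_error(rotated_nms(d1, 0), "iou_thresh")
})

test_that("top_per_label keeps one detection per structure", {
  d <- detections(c("LV", "LV", "RV"), c(0, 50, 0), c(0, 50, 0),
                  c(4, 4, 4), c(2, 2, 2), c(0, 0, 0), c(0.6, 0.9, 0.5))
  out <- top_per_label(d)
  expect_identical(nrow(out), 2L)
  expect_equal(out$conf[out$label == "LV"], 0.9)
})

test_that("structure check follows the essential-set rule", {
  full <- detections(STRUCTURE_LABELS, seq_along(STRUCTURE_LABELS) * 10, 50,
                     8, 4, 90, rep(0.9, 7))
  expect_true(check_structures(full, full, 0.25)$passed)
  # RA absent from the ES frame only
  no_ra <- full[full$label != "RA", ]
  chk <- check_structures(full, no_ra, 0.25)
  expect_false(chk$passed)
  expect_identical(chk$missing$label, "RA")
  expect_identical(chk$missing$frame, "ES")
  # valves never matter
  ess <- full[full$label %in% ESSENTIAL_STRUCTURES, ]
  expect_true(check_structures(ess, ess, 0.25)$passed)
  # sub-threshold confidence does not count as visible
  faint <- full; faint$conf[faint$label == "LV"] <- 0.1
  expect_false(check_structures(faint, full, 0.25)$passed)
})

test_that("structure check is monotone in added detections", {
  set.seed(404)
  for (rep in 1:25) {
    labs <- sample(STRUCTURE_LABELS, sample(3:7, 1))
    base <- detections(labs, runif(length(labs), 0, 100),
                       runif(length(labs), 0, 100), 8, 4, 0,
                       runif(length(labs), 0.3, 1))
    extra <- detections(sample(STRUCTURE_LABELS, 2), c(10, 20), c(10, 20),
                        8, 4, 0, c(0.9, 0.9))
    before <- check_structures(base, base)$passed
    after <- check_structures(rbind(base, extra), rbind(base, extra))$passed
    expect_true(!before || after)
  }
})
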