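# lvvc_phase module: volume-curve construction, keyframe extraction,
# cycle completeness, QC target selection.

test_that("keyframe validation enforces alternation and ordering", {
  expect_s3_class(keyframes(c(0, 10, 20), c("ED", "ES", "ED")), "keyframes")
  expect_error(keyframes(c(0, 10), c("ED", "ED")), "alternate")
  expect_error(keyframes(c(10, 0), c("ED", "ES")), "sorted")
  expect_error(keyframes(c(5, 5), c("ED", "ES")), "duplicate")
  expect_error(keyframes(-1, "ED"), "non-negative")
  expect_error(keyframes(3, "X"), "'ED' or 'ES'")
})

test_that("volume curve hits the exact endpoint and midpoint values", {
  kf <- keyframes(c(0, 10, 20), c("ED", "ES", "ED"))
  pc <- lvvc_ground_truth(kf, 21)
  expect_identical(pc$values[c(1, 11, 21)], c(1, -1, 1))   # sin(pi/2), sin(3pi/2)
  expect_equal(pc$values[6], 0, tolerance = 1e-12)         # mid-systole
  expect_equal(pc$values[16], 0, tolerance = 1e-12)        # mid-diastole
  expect_true(all(pc$values >= -1 & pc$values <= 1))
  expect_true(all(pc$mask))
})

test_that("volume curve matches the scalar closed form everywhere", {
  kf <- keyframes(c(3, 11, 24, 33), c("ES", "ED", "ES", "ED"))
  pc <- lvvc_ground_truth(kf, 40)
  for (x in 3:33) {
    seg <- max(which(kf$frame <= x & kf$frame < max(kf$frame)))
    want <- scalar_lvvc(x, kf$frame[seg], kf$phase[seg], kf$frame[seg + 1])
    expect_equal(pc$values[x + 1], want, tolerance = 1e-9)
  }
  # quarter-phase diastole value, frozen from direct evaluation:
  # labels (ED 0, ES 10, ED 20), x = 12.5 -> sin(3pi/2 + pi/4) = -sqrt(2)/2
  expect_equal(scalar_lvvc(12.5, 10, "ES", 20), -sqrt(2) / 2,
               tolerance = 1e-12)
})

test_that("curve is continuous at interior keyframes and masked outside", {
  kf <- keyframes(c(4, 12, 21, 30), c("ED", "ES", "ED", "ES"))
  pc <- lvvc_ground_truth(kf, 36)
  # continuity: one-sided limits from the scalar form agree below 1e-9
  for (i in 2:3) {
    f <- kf$frame[i]
    left <- scalar_lvvc(f - 1e-7, kf$frame[i - 1], kf$phase[i - 1], f)
    right <- scalar_lvvc(f + 1e-7, f, kf$phase[i], kf$frame[i + 1])
    expect_lt(abs(left - right), 1e-9)
  }
  expect_true(all(is.na(pc$values[1:4])))     # before first label
  expect_true(all(is.na(pc$values[32:36])))   # after last label
  expect_identical(pc$mask, !is.na(pc$values))
})

test_that("periodic extension fills the whole span deterministically", {
  kf <- keyframes(c(5, 15, 25), c("ED", "ES", "ED"))
  pc <- lvvc_ground_truth(kf, 40, extend = TRUE)
  expect_true(all(pc$mask))
  expect_identical(pc$values[6], 1)    # real ED
  expect_identical(pc$values[36], -1)  # extended ES at frame 35
  expect_equal(pc$values[1], scalar_lvvc(0, -5, "ES", 5), tolerance = 1e-9)
})

test_that("input validation errors are raised", {
  expect_error(lvvc_ground_truth(keyframes(5, "ED"), 10), "two keyframe")
  expect_error(lvvc_ground_truth(keyframes(c(0, 8), c("ED", "ES")), 8),
               "exceed")
})

test_that("extraction inverts construction (round trip, smoothing off)", {
  set.seed(101)
  for (rep in 1:40) {
    L <- random_keyframes(sample(3:6, 1))
    n <- max(L$frame) + sample(1:6, 1)
    ex <- extract_keyframes(lvvc_ground_truth(L, n), smooth_window = 1)
    expect_identical(ex$frame, L$frame)
    expect_identical(ex$phase, L$phase)
  }
})

test_that("extraction handles analytic sinusoids and edge truncation", {
  # analytic extrema of sin(3pi/2 + 2pi t / 20), t = 0..59: peaks at
  # t = 10, 30, 50 and troughs at t = 0, 20, 40 (frozen via the numeric
  # argmax oracle below). Both curve endpoints lie within the amplitude
  # gate: the t = 0 trough is exact, and t = 59 (value -0.95) is one frame
  # shy of the analytic trough at t = 60, so it is reported too.
  v <- sin(3 * pi / 2 + 2 * pi * (0:59) / 20)
  stopifnot(which.max(v[1:20]) - 1 == 10, which.min(v[1:20]) - 1 == 0)
  ex <- extract_keyframes(v, smooth_window = 1)
  expect_identical(ex$frame[ex$phase == "ED"], c(10L, 30L, 50L))
  expect_identical(ex$frame[ex$phase == "ES"], c(0L, 20L, 40L, 59L))

  # a truncated mid-segment tail must not fabricate a keyframe
  kf <- keyframes(c(2, 20, 38), c("ED", "ES", "ED"))
  full <- lvvc_ground_truth(kf, 39, extend = TRUE)
  crop <- structure(list(values = full$values[1:28], mask = rep(TRUE, 28)),
                    class = "phase_curve")
  ex2 <- extract_keyframes(crop)
  expect_identical(ex2$frame, c(2L, 20L))
})

test_that("constant curves and separation/prominence rules", {
  expect_identical(nrow(extract_keyframes(rep(0.3, 30))), 0L)
  # two nearby maxima: min_separation keeps the higher one
  v <- c(0, 0.5, 1, 0.9, 0.98, 0.4, -1, 0.1)
  ex <- extract_keyframes(v, min_separation = 5, smooth_window = 1,
                          min_prominence = 0.05)
  expect_identical(ex$frame[ex$phase == "ED"], 2L)
  # low-prominence wiggles are ignored
  v2 <- sin(3 * pi / 2 + 2 * pi * (0:39) / 20) + 0.05 * sin(2 * pi * (0:39) / 3)
  ex2 <- extract_keyframes(v2, smooth_window = 1)
  expect_lte(sum(ex2$phase == "ED"), 2L)
})

test_that("cycle finder matches brute-force enumeration on random labels", {
  set.seed(202)
  for (rep in 1:100) {
    L <- random_keyframes(sample(2:8, 1))
    got <- find_complete_cycles(L)
    want <- brute_force_cycles(L)
    expect_identical(length(got), length(want))
    if (length(got)) {
      got_triples <- lapply(got, function(cy) {
        c(cy$start$frame, cy$mid$frame, cy$end$frame)
      })
      expect_identical(got_triples, want)
    }
    expect_identical(length(got), max(0L, nrow(L) - 2L))
  }
})

test_that("cycle patterns and QC target selection follow the protocol", {
  cys <- find_complete_cycles(keyframes(c(2, 10, 20, 30),
                                        c("ES", "ED", "ES", "ED")))
  expect_length(cys, 2L)
  expect_identical(cys[[1]]$pattern, "ES_ED_ES")
  expect_identical(cys[[2]]$pattern, "ED_ES_ED")
  t1 <- select_qc_targets(cys[[1]])
  expect_identical(c(t1$ed_frame, t1$es_frame), c(10L, 2L))
  cy <- find_complete_cycles(keyframes(c(3, 12, 24), c("ED", "ES", "ED")))[[1]]
  t2 <- select_qc_targets(cy)
  expect_identical(c(t2$ed_frame, t2$es_frame), c(3L, 12L))
  # targets are members of the cycle keyframes
  expect_true(all(c(t2$ed_frame, t2$es_frame) %in% c(3, 12, 24)))
  expect_length(find_complete_cycles(keyframes(c(3, 12), c("ED", "ES"))), 0L)
})

test_that("phase-curve CSV round trip", {
  kf <- keyframes(c(2, 9, 17), c("ED", "ES", "ED"))
  pc <- lvvc_ground_truth(kf, 20)
  path <- tempfile(fileext = ".csv")
  write_phase_curve(pc, path)
  back <- read_phase_curve(path)
  expect_equal(back$values, pc$values)
  expect_identical(back$mask, pc$mask)
})
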