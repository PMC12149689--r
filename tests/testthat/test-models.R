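# models module: fast structural checks. (The scaled-down learning-quality
# bands live in test-acceptance.R.)

tiny_cfg <- function(...) {
  mod <- list(image_size = 64L, detector_epochs = 2L, phase_epochs = 4L,
              gain_epochs = 30L, batch_size = 2L, rnn_hidden = 8L)
  dots <- list(...)
  for (n in names(dots)) mod[[n]] <- dots[[n]]
  qc_config(seed = 5L, model = mod)
}

tiny_det_items <- function(n, seed, image_size = 64L) {
  ds <- generate_dataset(n, seed = seed,
                         balance = list(cycle_length = list(8L),
                                        n_frames = list(12L),
                                        image_size = list(image_size)))
  lapply(ds, function(it) {
    fi <- select_qc_targets(find_complete_cycles(it$gt$keyframes)[[1]])$ed_frame
    list(image = it$video$frames[[fi + 1]],
         boxes = it$gt$boxes_per_frame[[fi + 1]])
  })
}

test_that("conv and Bi-LSTM gradients match numerical differentiation", {
  set.seed(1)
  layers <- list(echoqc:::nn_conv(2, 3, k = 3, stride = 2),
                 echoqc:::nn_relu(),
                 echoqc:::nn_conv(3, 2, k = 3, stride = 1))
  x <- array(rnorm(7 * 7 * 2), c(7, 7, 2))
  R <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  lossf <- function() sum(echoqc:::net_forward(layers, x) * R)
  echoqc:::zero_grads(layers)
  invisible(echoqc:::net_forward(layers, x))
  dx <- echoqc:::net_backward(layers, R)
  eps <- 1e-5
  l1 <- layers[[1]]
  num <- l1$W * 0
  for (i in seq_along(l1$W)) {
    l1$W[i] <- l1$W[i] + eps; lp <- lossf()
    l1$W[i] <- l1$W[i] - 2 * eps; lm <- lossf()
    l1$W[i] <- l1$W[i] + eps
    num[i] <- (lp - lm) / (2 * eps)
  }
  expect_lt(max(abs(num - l1$dW)), 1e-6)
  numx <- array(0, dim(x))
  for (i in seq_along(x)) {
    x[i] <- x[i] + eps; lp <- lossf()
    x[i] <- x[i] - 2 * eps; lm <- lossf()
    x[i] <- x[i] + eps
    numx[i] <- (lp - lm) / (2 * eps)
  }
  expect_lt(max(abs(numx - dx)), 1e-6)

  set.seed(2)
  head <- echoqc:::new_bilstm_head(3, 4, n_layers = 2)
  X <- matrix(rnorm(6 * 3), 6, 3)
  tgt <- rnorm(6)
  lossh <- function() sum((echoqc:::bilstm_forward(head, X) - tgt)^2)
  echoqc:::zero_grads(echoqc:::bilstm_all_layers(head))
  y <- echoqc:::bilstm_forward(head, X)
  dX <- echoqc:::bilstm_backward(head, 2 * (y - tgt))
  l <- head$layers[[1]]
  num <- l$Wx * 0
  for (i in seq_along(l$Wx)) {
    l$Wx[i] <- l$Wx[i] + eps; lp <- lossh()
    l$Wx[i] <- l$Wx[i] - 2 * eps; lm <- lossh()
    l$Wx[i] <- l$Wx[i] + eps
    num[i] <- (lp - lm) / (2 * eps)
  }
  expect_lt(max(abs(num - l$dWx)), 1e-6)
  numX <- X * 0
  for (i in seq_along(X)) {
    X[i] <- X[i] + eps; lp <- lossh()
    X[i] <- X[i] - 2 * eps; lm <- lossh()
    X[i] <- X[i] + eps
    numX[i] <- (lp - lm) / (2 * eps)
  }
  expect_lt(max(abs(numX - dX)), 1e-6)
})

test_that("detector can overfit a single frame to mAP 1 (capacity check)", {
  item <- tiny_det_items(1, seed = 9)[[1]]
  cfg <- tiny_cfg(detector_epochs = 150L, batch_size = 1L, lr = 2e-3)
  bundle <- train_detector(list(item), cfg)
  d <- detect_structures(bundle, item$image)
  preds <- as.data.frame(d); preds$image <- 1
  gts <- as.data.frame(item$boxes); gts$image <- 1
  expect_equal(detection_map(preds, gts)$map, 1)
})

test_that("fixed seed gives identical loss traces (determinism mode)", {
  items <- tiny_det_items(2, seed = 10)
  cfg <- tiny_cfg()
  b1 <- train_detector(items, cfg)
  b2 <- train_detector(items, cfg)
  expect_identical(b1$loss_traces$detector, b2$loss_traces$detector)
  expect_identical(echoqc:::net_state(b1$backbone),
                   echoqc:::net_state(b2$backbone))
})

test_that("empty datasets and missing classes raise errors", {
  expect_error(train_detector(list(), tiny_cfg()), "empty")
  bundle <- train_detector(tiny_det_items(1, 9), tiny_cfg())
  expect_error(train_phase(list(), bundle), "empty")
  one_class <- list(list(image = matrix(0.5, 64, 64), gain = "medium"))
  expect_error(train_gain(one_class, bundle), "every gain class")
})

test_that("backbone freezing is real during phase and gain training", {
  bundle <- train_detector(tiny_det_items(2, 11), tiny_cfg())
  before <- backbone_state(bundle)
  ds <- generate_dataset(2, seed = 12,
                         balance = list(image_size = list(64L)),
                         render = TRUE)
  bundle <- train_phase(lapply(ds, function(it)
    list(frames = it$video$frames, keyframes = it$gt$keyframes)), bundle)
  expect_identical(backbone_state(bundle), before)
  gain_items <- unlist(lapply(generate_dataset(3, seed = 13,
      balance = list(gain = c("low", "medium", "high"),
                     cycle_length = list(8L), n_frames = list(12L),
                     image_size = list(64L))), function(it) {
    lapply(c(1L, 7L), function(fi)
      list(image = it$video$frames[[fi]], gain = it$gt$gain_class))
  }), recursive = FALSE)
  bundle <- train_gain(gain_items, bundle)
  expect_identical(backbone_state(bundle), before)
  expect_equal(sum(predict_gain(bundle, gain_items[[1]]$image)), 1,
               tolerance = 1e-6)
})

test_that("constant input yields a near-constant curve and no keyframes", {
  bundle <- train_detector(tiny_det_items(1, 9), tiny_cfg())
  ds <- generate_dataset(1, seed = 12, balance = list(image_size = list(64L)))
  bundle <- train_phase(list(list(frames = ds[[1]]$video$frames,
                                  keyframes = ds[[1]]$gt$keyframes)), bundle)
  frames <- replicate(20, matrix(0.4, 64, 64), simplify = FALSE)
  pc <- predict_phase_curve(bundle, frames)
  expect_lt(max(pc$values) - min(pc$values), 0.05)
  expect_identical(nrow(extract_keyframes(pc)), 0L)
})

test_that("permuted gain labels train to chance accuracy (null check)", {
  bundle <- train_detector(tiny_det_items(2, 14), tiny_cfg())
  ds <- generate_dataset(9, seed = 15,
                         balance = list(gain = c("low", "medium", "high"),
                                        cycle_length = list(8L),
                                        n_frames = list(12L),
                                        image_size = list(64L)))
  items <- unlist(lapply(ds, function(it) {
    lapply(c(1L, 6L, 11L), function(fi)
      list(image = it$video$frames[[fi]], gain = it$gt$gain_class))
  }), recursive = FALSE)
  set.seed(44)
  perm <- items
  labs <- vapply(items, `[[`, character(1), "gain")
  shuffled <- sample(labs)
  for (i in seq_along(perm)) perm[[i]]$gain <- shuffled[i]
  bundle <- train_gain(perm, bundle, tiny_cfg(gain_epochs = 60L))
  held <- generate_dataset(6, seed = 16,
                           balance = list(gain = c("low", "medium", "high"),
                                          cycle_length = list(8L),
                                          n_frames = list(12L),
                                          image_size = list(64L)))
  acc <- mean(vapply(held, function(it) {
    p <- predict_gain(bundle, it$video$frames[[6]])
    names(p)[which.max(p)] == it$gt$gain_class
  }, logical(1)))
  expect_lt(acc, 0.75)  # chance is 1/3; true labels reach >= 0.95
})

test_that("run_qc oracle mode scores phantoms by construction", {
  std <- generate_video(phantom_spec(n_frames = 24, cycle_length = 14,
                                     seed = 21), render = FALSE)
  rep <- run_qc(std$video, annotations = std$gt)
  expect_identical(rep$video_total, 5L)
  expect_true(rep$standard)
  part <- generate_video(phantom_spec(n_frames = 8, cycle_length = 20,
                                      seed = 22), render = FALSE)
  rep0 <- run_qc(part$video, annotations = part$gt)
  expect_identical(rep0$video_total, 0L)
  expect_match(rep0$per_cycle[[1]]$reasons, "incomplete")
  expect_error(run_qc(std$video), "bundle or oracle")
})

test_that("learned-mode and oracle-mode reports share one schema", {
  bundle <- train_detector(tiny_det_items(2, 17), tiny_cfg())
  ds <- generate_dataset(2, seed = 18, balance = list(image_size = list(64L)))
  bundle <- train_phase(lapply(ds, function(it)
    list(frames = it$video$frames, keyframes = it$gt$keyframes)), bundle)
  gain_items <- unlist(lapply(generate_dataset(3, seed = 19,
      balance = list(gain = c("low", "medium", "high"),
                     cycle_length = list(8L), n_frames = list(12L),
                     image_size = list(64L))), function(it) {
    lapply(c(1L, 7L), function(fi)
      list(image = it$video$frames[[fi]], gain = it$gt$gain_class))
  }), recursive = FALSE)
  bundle <- train_gain(gain_items, bundle)
  it <- ds[[1]]
  rl <- run_qc(it$video, bundle = bundle)
  ro <- run_qc(it$video, annotations = it$gt)
  cfg <- bundle$config
  ll <- echoqc:::report_to_list(rl, "v", cfg)
  lo <- echoqc:::report_to_list(ro, "v", cfg)
  expect_identical(names(ll), names(lo))
  expect_identical(names(ll$cycles[[1]]), names(lo$cycles[[1]]))
  expect_gte(attr(rl, "fps"), 0)
})

test_that("bundle state survives a checkpoint round trip", {
  bundle <- train_detector(tiny_det_items(1, 9), tiny_cfg())
  path <- tempfile(fileext = ".rds")
  saveRDS(bundle_state(bundle), path)
  back <- bundle_restore(readRDS(path))
  img <- tiny_det_items(1, 9)[[1]]$image
  expect_identical(detect_structures(back, img), detect_structures(bundle, img))
})
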