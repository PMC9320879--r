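test_that("the network emits well-formed softmax vectors", {
  m <- build_model(small_model_config(), seed = 1)
  set.seed(2)
  x <- matrix(rnorm(84375 * 3), ncol = 3)
  p <- predict_probs(m, x)
  expect_equal(dim(p), c(3, 3))
  expect_equal(unname(rowSums(p)), rep(1, 3), tolerance = 1e-6)
  expect_true(all(p >= 0))
  # binary variant
  m2 <- build_model(small_model_config(n_classes = 2), seed = 1)
  p2 <- predict_probs(m2, x)
  expect_equal(dim(p2), c(3, 2))
  expect_equal(colnames(p2), c("left", "right"))
  expect_equal(unname(rowSums(p2)), rep(1, 3), tolerance = 1e-6)
  # wrong input shape is rejected
  expect_error(predict_probs(m, matrix(0, 100, 2)), "shape mismatch")
  # a conv stack too deep for 75 px input is rejected at config time
  expect_error(model_config(conv_filters = rep(8, 6)), "too deep")
})

test_that("weighted cross-entropy honors the 1:0.66:0.66 contract", {
  expect_equal(weighted_ce_loss(c(away = 1, left = 0, right = 0), "away"), 0)
  u <- rep(1 / 3, 3)
  expect_equal(weighted_ce_loss(u, "away") / weighted_ce_loss(u, "left"),
               1 / 0.66, tolerance = 1e-12)
  # the ratio holds for arbitrary probability vectors with equal mass on
  # the true class
  set.seed(6)
  for (i in 1:20) {
    p <- runif(1, 0.05, 0.95)
    rest <- runif(1)
    u_away <- c(p, (1 - p) * rest, (1 - p) * (1 - rest))
    u_left <- c((1 - p) * rest, p, (1 - p) * (1 - rest))
    expect_equal(weighted_ce_loss(u_away, "away") /
                   weighted_ce_loss(u_left, "left"),
                 1 / 0.66, tolerance = 1e-12)
  }
  # epsilon clamp keeps zero-probability losses finite
  expect_true(is.finite(weighted_ce_loss(c(0, 1, 0), "away")))
  # matrix form
  um <- rbind(c(0.8, 0.1, 0.1), c(0.2, 0.5, 0.3))
  expect_equal(weighted_ce_loss(um, c("away", "left")),
               c(-1 * log(0.8), -0.66 * log(0.5)))
})

test_that("plateau and early-stopping schedule follows the patience rules", {
  # a vanishing learning rate freezes the validation loss, so epoch 1 is
  # the only improvement; the lr halves after 3 stagnant epochs and
  # training stops after 5
  dp <- simulate_training_datapoints(40, renderer = fast_renderer(),
                                     seed = 31, chunk_frames = 49)
  tr <- subset_datapoints(dp, 1:30)
  va <- subset_datapoints(dp, 31:40)
  m <- build_model(small_model_config(), seed = 2)
  cfg <- train_config(initial_lr = 1e-30, max_epochs = 50, seed = 9,
                      blackout = FALSE, brightness = FALSE)
  fit <- train_gaze_model(m, tr, va, cfg)
  h <- fit$history
  expect_equal(nrow(h), 6)                  # 1 improvement + 5 stagnant
  expect_equal(h$lr, c(rep(1e-30, 4), rep(0.5e-30, 2)))
  expect_equal(length(unique(round(h$val_loss, 12))), 1)
})

test_that("training is reproducible under a fixed seed", {
  dp <- simulate_training_datapoints(60, renderer = fast_renderer(),
                                     seed = 13, chunk_frames = 40)
  tr <- subset_datapoints(dp, 1:45)
  va <- subset_datapoints(dp, 46:60)
  cfg <- train_config(initial_lr = 5e-4, max_epochs = 2, seed = 77)
  f1 <- train_gaze_model(build_model(small_model_config(), 5), tr, va, cfg)
  f2 <- train_gaze_model(build_model(small_model_config(), 5), tr, va, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  expect_error(train_gaze_model(build_model(small_model_config(), 5),
                                subset_datapoints(tr, integer(0)), va, cfg),
               "empty")
})

test_that("inference applies the missing-face rules frame by frame", {
  # rules are independent of the weights: an untrained model with
  # hand-set stats exercises the plumbing deterministically
  m <- build_model(small_model_config(), seed = 8)
  m$norm_stats <- structure(list(mean = rep(0.4, 3), sd = rep(0.2, 3)),
                            class = "norm_stats")
  r <- fast_renderer()
  frames <- lapply(1:20, function(i) render_frame("left", r, rng_seed = i))
  # frame 10 (0-based 9) undetectable: as a target frame it forces away
  frames[[10]] <- render_frame("away", r, rng_seed = 10, missing = TRUE)
  tl <- annotate_video(m, frames)
  expect_s3_class(tl, "gaze_timeline")
  expect_equal(nrow(tl), 20)
  expect_equal(tl$label[9 + 1], "away")
  expect_equal(unname(unlist(tl[9 + 1, c("p_away", "p_left", "p_right")])),
               c(1, 0, 0))
  # neighbors of the missing frame still get predictions (black image
  # substitution), and every non-edge frame is labeled
  centers <- 4:(20 - 6)
  others <- setdiff(centers, 9)
  probs <- as.matrix(tl[others + 1, c("p_away", "p_left", "p_right")])
  expect_false(anyNA(probs))
  expect_equal(unname(rowSums(probs)), rep(1, length(others)),
               tolerance = 1e-6)
  # edge frames are away and flagged
  expect_true(all(tl$edge[c(1:4, 16:20)]))
  expect_true(all(tl$label[c(1:4, 16:20)] == "away"))
  expect_false(any(tl$edge[centers + 1]))
  expect_error(annotate_video(m, frames[1:9]), "at least 10")
})

test_that("checkpoints round-trip weights, config and norm stats", {
  m <- build_model(small_model_config(), seed = 21)
  m$norm_stats <- structure(list(mean = c(0.3, 0.4, 0.5),
                                 sd = c(0.2, 0.2, 0.25)),
                            class = "norm_stats")
  dir <- withr::local_tempdir()
  save_gaze_model(m, dir)
  back <- load_gaze_model(dir)
  expect_equal(back$config, m$config)
  expect_equal(back$params, m$params)
  expect_equal(back$norm_stats, m$norm_stats)
  expect_equal(back$classes, m$classes)
  # restored models predict identically
  set.seed(3)
  x <- matrix(rnorm(84375 * 2), ncol = 2)
  expect_identical(predict_probs(back, x), predict_probs(m, x))
})
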