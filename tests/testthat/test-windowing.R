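# build a packed crop collection with constant-valued crops; value encodes
# the frame index so window membership can be verified exactly
indexed_crops <- function(n) {
  pix <- matrix(rep(seq_len(n) / (n + 1), each = 75 * 75 * 3), ncol = n)
  structure(list(pix = pix, missing = logical(n),
                 source_frame = seq_len(n) - 1L),
            class = "face_crops")
}

test_that("window enumeration matches brute force for N in 0..50", {
  # independent enumerator: count starts s with all of s..s+9 in range
  brute_count <- function(N) {
    count <- 0
    s <- 0
    while (TRUE) {
      if (s + 9 <= N - 1) count <- count + 1 else break
      s <- s + 1
    }
    count
  }
  for (N in 0:50) {
    dps <- make_datapoints(indexed_crops(N), rep("away", N))
    expect_equal(dps$n, brute_count(N))
    expect_equal(dps$n, max(0, N - 9))
  }
})

test_that("data points take alternating frames and the middle frame's label", {
  N <- 14
  labels <- c("away", "left", "right", "away", "left", "right", "away",
              "left", "right", "away", "left", "right", "away", "left")
  dps <- make_datapoints(indexed_crops(N), labels)
  expect_equal(dps$n, 5)
  # first window: frames {0,2,4,6,8}, label from frame 4
  stack <- datapoint_stack(dps, 1)
  expect_equal(dim(stack), c(5, 75, 75, 3))
  frame_vals <- apply(stack, 1, function(a) unique(as.vector(a)))
  expect_equal(frame_vals, (c(0, 2, 4, 6, 8) + 1) / (N + 1))
  expect_equal(dps$label[1], labels[4 + 1])
  # every data point's label aligns with window_start + 4
  expect_equal(dps$label, labels[dps$window_start + 4 + 1])
  expect_error(make_datapoints(indexed_crops(5), rep("away", 4)),
               "lengths differ")
})

test_that("label alignment holds on randomly generated sessions", {
  set.seed(12)
  for (rep in 1:10) {
    N <- sample(10:40, 1)
    labels <- random_labels(N)
    dps <- make_datapoints(indexed_crops(N), labels)
    expect_equal(dps$label, labels[dps$window_start + 4 + 1])
  }
})

test_that("face detection uses the synthetic box and fails soft", {
  f <- render_frame("left", fast_renderer(), 1)
  expect_equal(detect_face(f), as.numeric(attr(f, "face_box")))
  fm <- render_frame("away", fast_renderer(), 1, missing = TRUE)
  expect_null(detect_face(fm))
  blank <- array(0, c(20, 20, 3))
  expect_null(detect_face(blank))
  # erroring detectors degrade to no-detection
  expect_null(detect_face(blank, detector = function(fr) stop("boom")))
  # multiple candidates: the largest box wins, after the filter hook
  boxes <- rbind(c(1, 1, 10, 10), c(1, 1, 19, 19))
  expect_equal(detect_face(blank, detector = function(fr) boxes),
               c(1, 1, 19, 19))
  expect_equal(detect_face(blank, detector = function(fr) boxes,
                           filter = function(b) b[1, , drop = FALSE]),
               c(1, 1, 10, 10))
})

test_that("crop extraction clips, resizes, and preserves exact-size crops", {
  fr <- render_frame("left", renderer_config(), 1)   # 96 px frame, 80 box
  crop <- crop_and_resize(fr, detect_face(fr))
  expect_equal(dim(crop$pixels), c(75, 75, 3))
  expect_false(crop$missing)
  # 75x75 box -> identity
  sub <- fr[1:75, 1:75, ]
  crop_id <- crop_and_resize(fr, c(1, 1, 75, 75))
  expect_equal(crop_id$pixels, array(sub, c(75, 75, 3)))
  # boxes hanging over the edge are clipped, not fatal
  crop_edge <- crop_and_resize(fr, c(-10, 50, 120, 200))
  expect_equal(dim(crop_edge$pixels), c(75, 75, 3))
  expect_error(crop_and_resize(fr, c(50, 50, 20, 20)), "degenerate")
})

test_that("normalization statistics match their definition", {
  mk <- function(val) face_crop(array(val, c(75, 75, 3)))
  # constant input: sd collapses to the epsilon guard
  st <- compute_norm_stats(list(mk(0.5), mk(0.5)))
  expect_equal(st$mean, rep(0.5, 3))
  expect_equal(st$sd, rep(1e-6, 3))
  # two crops of values 0 and 2 -> mean 1, sd 1
  st2 <- compute_norm_stats(list(mk(0), mk(2)))
  expect_equal(st2$mean, rep(1, 3))
  expect_equal(st2$sd, rep(1, 3))
  # missing crops are excluded; all-missing input errors
  st3 <- compute_norm_stats(list(mk(0), mk(2), face_crop(missing = TRUE)))
  expect_equal(st3$mean, rep(1, 3))
  expect_error(compute_norm_stats(list(face_crop(missing = TRUE))),
               "all crops missing")
  # random set against an independent accumulation
  set.seed(5)
  crops <- lapply(1:6, function(i) face_crop(array(runif(75 * 75 * 3),
                                                   c(75, 75, 3))))
  st4 <- compute_norm_stats(crops)
  for (ch in 1:3) {
    v <- unlist(lapply(crops, function(cr) as.vector(cr$pixels[, , ch])))
    expect_equal(st4$mean[ch], mean(v), tolerance = 1e-6)
    expect_equal(st4$sd[ch], sqrt(mean((v - mean(v))^2)), tolerance = 1e-6)
  }
})

test_that("normalization is invertible and preserves the missing sentinel", {
  set.seed(6)
  crop <- face_crop(array(runif(75 * 75 * 3), c(75, 75, 3)))
  stats <- structure(list(mean = c(0.4, 0.5, 0.6), sd = c(0.2, 0.25, 0.3)),
                     class = "norm_stats")
  norm <- normalize_crop(crop, stats)
  back <- denormalize_crop(norm, stats)
  expect_equal(back$pixels, crop$pixels, tolerance = 1e-6)
  # a crop equal to the channel means normalizes to all zeros
  cm <- face_crop(array(rep(c(0.4, 0.5, 0.6), each = 75 * 75),
                        c(75, 75, 3)))
  expect_equal(max(abs(normalize_crop(cm, stats)$pixels)), 0)
  # missing crops stay the all-zero black image
  m <- normalize_crop(face_crop(missing = TRUE), stats)
  expect_true(all(m$pixels == 0))
  # a normalized dataset has channel mean ~0 and sd ~1
  crops <- as_many <- lapply(1:8, function(i)
    face_crop(array(runif(75 * 75 * 3), c(75, 75, 3))))
  st <- compute_norm_stats(crops)
  packed <- normalize_crop(gazecoder:::as_face_crops(crops), st)
  npx <- 75 * 75
  for (ch in 1:3) {
    v <- packed$pix[((ch - 1) * npx + 1):(ch * npx), ]
    expect_lt(abs(mean(v)), 1e-3)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-3)
  }
})

test_that("blackout augmentation zeroes exactly one crop uniformly", {
  N <- 24
  labels <- random_labels(N)
  dps <- make_datapoints(indexed_crops(N), labels)
  aug <- blackout_augment(dps, rng_seed = 8)
  expect_identical(aug$label, dps$label)
  am <- dp_matrix(aug)
  crop_block <- function(x, k) x[((k - 1) * 16875 + 1):(k * 16875), ]
  for (j in seq_len(aug$n)) {
    zeroed <- vapply(1:5, function(k) all(crop_block(am$x, k)[, j] == 0),
                     logical(1))
    expect_equal(sum(zeroed), 1)
    expect_equal(which(zeroed), which(am$missing[, j]))
  }
  # augmentation must not corrupt the original shared crop store
  expect_false(any(dp_matrix(dps)$missing))
  # position choice is uniform over the five slots: 10,000 seeds, one
  # data point each
  one <- make_datapoints(indexed_crops(10), rep("away", 10))
  pos <- vapply(1:10000, function(s) {
    which(dp_matrix(blackout_augment(one, rng_seed = s))$missing[, 1])
  }, integer(1))
  freq <- tabulate(pos, 5) / 10000
  expect_true(all(abs(freq - 0.2) < 0.02))
})

test_that("brightness augmentation scales all five crops identically", {
  N <- 15
  dps <- make_datapoints(indexed_crops(N), rep("left", N))
  x0 <- dp_matrix(dps)$x
  # factor range (1, 1) is the identity
  same <- brightness_augment(dps, rng_seed = 2, range = c(1, 1))
  expect_equal(dp_matrix(same)$x, x0)
  aug <- brightness_augment(dps, rng_seed = 2, range = c(0.5, 0.9))
  # inter-crop ratios preserved: every column scaled by one factor
  ratio <- dp_matrix(aug)$x / x0
  for (j in seq_len(aug$n)) {
    expect_lt(diff(range(ratio[, j])), 1e-12)
  }
  # output stays in the valid pixel range even for amplifying factors
  hot <- brightness_augment(dps, rng_seed = 3, range = c(2.5, 3))
  expect_lte(max(dp_matrix(hot)$x), 1)
  expect_gte(min(dp_matrix(hot)$x), 0)
})
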