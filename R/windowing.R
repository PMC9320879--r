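# Geometry of a data point: a rolling window of WINDOW_LEN frames from
# which the ALTERNATE offsets are stacked; the label comes from the middle
# (third) of the five selected frames, i.e., window offset CENTER_OFFSET.
WINDOW_LEN <- 10L
ALTERNATE_OFFSETS <- c(0L, 2L, 4L, 6L, 8L)
CENTER_OFFSET <- 4L
CROP_SIZE <- 75L
CROP_LEN <- CROP_SIZE * CROP_SIZE * 3L

#' Construct a face crop
#'
#' @param pixels `75 x 75 x 3` array in `[0, 1]` (ignored when `missing`).
#' @param missing `TRUE` for the all-zero "black image" sentinel used for
#'   undetectable faces.
#' @param source_frame 0-based index of the originating frame.
#' @return list of class `face_crop`.
#' @export
face_crop <- function(pixels = NULL, missing = FALSE, source_frame = NA) {
  if (missing || is.null(pixels)) {
    pixels <- array(0, dim = c(CROP_SIZE, CROP_SIZE, 3))
    missing <- TRUE
  }
  stopifnot(all(dim(pixels) == c(CROP_SIZE, CROP_SIZE, 3)))
  structure(list(pixels = pixels, missing = missing,
                 source_frame = source_frame),
            class = "face_crop")
}

#' Detect a face in a frame
#'
#' In synthetic mode frames carry their generator ground-truth bounding box
#' as the `face_box` attribute, which is returned directly - no external
#' face-extraction model is consulted. For real images a pluggable
#' `detector` function can be supplied; it receives the frame and must
#' return a box `c(r1, c1, r2, c2)` (1-based inclusive) or `NULL`. When
#' several candidate boxes are returned (a matrix, one box per row), the
#' largest is taken; a user-supplied `filter` hook may veto boxes first
#' (e.g., to drop a parent's face). Detector failures yield `NULL`, never
#' an error.
#'
#' @param frame image array.
#' @param detector optional function(frame) -> box / matrix of boxes / NULL.
#' @param filter optional function(boxes) -> boxes, applied before the
#'   largest-box rule.
#' @return numeric box `c(r1, c1, r2, c2)` or `NULL`.
#' @export
detect_face <- function(frame, detector = NULL, filter = NULL) {
  box <- attr(frame, "face_box")
  if (is.null(box) && !is.null(detector)) {
    box <- tryCatch(detector(frame), error = function(e) NULL)
  }
  if (is.null(box)) return(NULL)
  if (is.matrix(box)) {
    if (!is.null(filter)) box <- filter(box)
    if (is.null(box) || nrow(box) == 0) return(NULL)
    area <- (box[, 3] - box[, 1] + 1) * (box[, 4] - box[, 2] + 1)
    box <- box[which.max(area), ]
  }
  as.numeric(box)
}

#' Crop a face box out of a frame and resize to 75 x 75
#'
#' The box is clipped to the frame bounds; the cropped region is resized
#' to the fixed `75 x 75 x 3` network input resolution (bilinear, via
#' EBImage) unless it already has that size.
#'
#' @param frame image array `H x W x 3`.
#' @param box `c(r1, c1, r2, c2)`, 1-based inclusive.
#' @return a non-missing [face_crop()].
#' @export
crop_and_resize <- function(frame, box) {
  d <- dim(frame)
  r1 <- max(1L, floor(box[1])); c1 <- max(1L, floor(box[2]))
  r2 <- min(d[1], ceiling(box[3])); c2 <- min(d[2], ceiling(box[4]))
  if (r2 < r1 || c2 < c1) stop("degenerate face box after clipping")
  sub <- frame[r1:r2, c1:c2, , drop = FALSE]
  if (nrow(sub) != CROP_SIZE || ncol(sub) != CROP_SIZE) {
    img <- EBImage::resize(EBImage::Image(sub, colormode = "Color"),
                           w = CROP_SIZE, h = CROP_SIZE)
    sub <- array(EBImage::imageData(img), dim = c(CROP_SIZE, CROP_SIZE, 3))
    sub <- pmin(pmax(sub, 0), 1)
  } else {
    sub <- array(sub, dim = c(CROP_SIZE, CROP_SIZE, 3))
  }
  face_crop(sub, missing = FALSE)
}

#' Extract crops from a sequence of frames
#'
#' Runs [detect_face()] / [crop_and_resize()] over every frame and packs
#' the result into a `face_crops` collection (one feature column per
#' frame); frames without a detectable face become missing crops.
#'
#' @param frames list of image arrays.
#' @param detector,filter passed to [detect_face()].
#' @return list of class `face_crops`: `pix` (`16875 x n` matrix, channel
#'   blocks in column-major pixel order), `missing` (logical), and
#'   `source_frame`.
#' @export
frames_to_crops <- function(frames, detector = NULL, filter = NULL) {
  n <- length(frames)
  pix <- matrix(0, nrow = CROP_LEN, ncol = n)
  missing <- logical(n)
  for (i in seq_len(n)) {
    box <- detect_face(frames[[i]], detector, filter)
    if (is.null(box)) {
      missing[i] <- TRUE
    } else {
      pix[, i] <- as.vector(crop_and_resize(frames[[i]], box)$pixels)
    }
  }
  structure(list(pix = pix, missing = missing,
                 source_frame = seq_len(n) - 1L),
            class = "face_crops")
}

as_face_crops <- function(crops) {
  if (inherits(crops, "face_crops")) return(crops)
  stopifnot(is.list(crops), all(vapply(crops, inherits, logical(1),
                                       "face_crop")))
  pix <- vapply(crops, function(cr) as.vector(cr$pixels),
                numeric(CROP_LEN))
  structure(list(pix = matrix(pix, nrow = CROP_LEN),
                 missing = vapply(crops, `[[`, logical(1), "missing"),
                 source_frame = vapply(crops, function(cr)
                   as.integer(cr$source_frame), integer(1))),
            class = "face_crops")
}

#' Channelwise normalization statistics
#'
#' Per-channel mean and standard deviation over all non-missing crops of a
#' (training) dataset; crops are later normalized as `(x - mean) / sd`.
#' A constant channel is guarded with an epsilon so the division is always
#' defined.
#'
#' @param crops a `face_crops` collection or list of `face_crop`.
#' @param eps lower bound added to the standard deviation.
#' @return list of class `norm_stats` with `mean` and `sd` (length 3).
#' @export
compute_norm_stats <- function(crops, eps = 1e-6) {
  crops <- as_face_crops(crops)
  keep <- !crops$missing
  if (!any(keep)) stop("cannot compute normalization stats: all crops missing")
  px <- crops$pix[, keep, drop = FALSE]
  npx <- CROP_SIZE * CROP_SIZE
  ch_mean <- ch_sd <- numeric(3)
  for (ch in 1:3) {
    rows <- ((ch - 1) * npx + 1):(ch * npx)
    v <- px[rows, ]
    ch_mean[ch] <- mean(v)
    ch_sd[ch] <- sqrt(mean((v - ch_mean[ch])^2))
  }
  structure(list(mean = ch_mean, sd = pmax(ch_sd, eps)),
            class = "norm_stats")
}

#' Normalize a face crop (or crop collection)
#'
#' Subtracts the per-channel mean and divides by the per-channel standard
#' deviation. Missing crops are the all-zero black-image sentinel *after*
#' normalization: they pass through unchanged so the network always sees
#' the same missing-frame signal.
#'
#' @param crop a `face_crop` or `face_crops`.
#' @param stats a `norm_stats`.
#' @return same type as `crop`.
#' @export
normalize_crop <- function(crop, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  if (inherits(crop, "face_crop")) {
    if (crop$missing) return(crop)
    for (ch in 1:3) {
      crop$pixels[, , ch] <- (crop$pixels[, , ch] - stats$mean[ch]) /
        stats$sd[ch]
    }
    return(crop)
  }
  crops <- as_face_crops(crop)
  crops$pix <- normalize_pix(crops$pix, stats)
  if (any(crops$missing)) crops$pix[, crops$missing] <- 0
  crops
}

# matrix-form normalization used on packed pixel columns
normalize_pix <- function(pix, stats) {
  npx <- CROP_SIZE * CROP_SIZE
  for (ch in 1:3) {
    rows <- ((ch - 1) * npx + 1):(ch * npx)
    pix[rows, ] <- (pix[rows, ] - stats$mean[ch]) / stats$sd[ch]
  }
  pix
}

#' Undo crop normalization
#'
#' @inheritParams normalize_crop
#' @return same type as `crop`.
#' @export
denormalize_crop <- function(crop, stats) {
  stopifnot(inherits(crop, "face_crop"), inherits(stats, "norm_stats"))
  if (crop$missing) return(crop)
  for (ch in 1:3) {
    crop$pixels[, , ch] <- crop$pixels[, , ch] * stats$sd[ch] +
      stats$mean[ch]
  }
  crop
}

#' Build five-crop data points from a frame sequence
#'
#' Applies the rolling ten-frame window: for every window start
#' `s = 0 .. N - 10` (0-based), the crops at frames `s + {0,2,4,6,8}` are
#' stacked into one data point labeled by the annotation of the middle
#' selected frame, `s + 4`. Fewer than ten frames yield no data points.
#'
#' Consecutive windows overlap by nine frames, so the collection stores
#' each frame's crop once and keeps per-window column references; the
#' five-crop pixel stack of any subset is assembled on demand (see
#' [dp_matrix()]).
#'
#' @param crops a `face_crops` collection (or list of `face_crop`), one
#'   per frame, in frame order.
#' @param labels per-frame gaze labels, same length.
#' @param starts optional subset of 0-based window starts.
#' @return list of class `gaze_datapoints`: `pix` (`16875 x F` shared crop
#'   store), `cmiss` (per-crop missing flags), `win_cols` (`5 x n` crop
#'   column indices per data point), `label`, `window_start`, `n`.
#' @export
make_datapoints <- function(crops, labels, starts = NULL) {
  crops <- as_face_crops(crops)
  n <- ncol(crops$pix)
  if (length(labels) != n) {
    stop("crops and labels lengths differ (", n, " vs ", length(labels), ")")
  }
  all_starts <- if (n >= WINDOW_LEN) 0:(n - WINDOW_LEN) else integer(0)
  if (is.null(starts)) starts <- all_starts
  stopifnot(all(starts %in% all_starts))
  pix <- crops$pix
  if (any(crops$missing)) pix[, crops$missing] <- 0
  structure(list(pix = pix, cmiss = crops$missing,
                 win_cols = outer(ALTERNATE_OFFSETS + 1L, as.integer(starts),
                                  `+`),
                 label = as.character(labels)[starts + CENTER_OFFSET + 1L],
                 window_start = as.integer(starts),
                 n = length(starts)),
            class = "gaze_datapoints")
}

#' Assemble the pixel matrix of a set of data points
#'
#' Gathers the five crop columns of each requested data point from the
#' shared crop store into the packed network-input form.
#'
#' @param dps a `gaze_datapoints`.
#' @param idx data-point indices (default: all).
#' @return list with `x` (`84375 x k` matrix: five 16875-long crop blocks
#'   per column) and `missing` (`5 x k` logical).
#' @export
dp_matrix <- function(dps, idx = seq_len(dps$n)) {
  cols <- dps$win_cols[, idx, drop = FALSE]
  x <- dps$pix[, as.vector(cols), drop = FALSE]
  dim(x) <- c(CROP_LEN * 5L, length(idx))
  miss <- matrix(dps$cmiss[as.vector(cols)], nrow = 5L)
  list(x = x, missing = miss)
}

# give every data point its own private copies of its five crops, so
# per-data-point pixel edits (augmentation) cannot leak into windows that
# share frames
materialize_datapoints <- function(dps) {
  m <- dp_matrix(dps)
  pix <- m$x
  dim(pix) <- c(CROP_LEN, 5L * dps$n)
  structure(list(pix = pix, cmiss = as.vector(m$missing),
                 win_cols = matrix(seq_len(5L * dps$n), nrow = 5L),
                 label = dps$label, window_start = dps$window_start,
                 n = dps$n),
            class = "gaze_datapoints")
}

#' Extract one data point's crop stack
#'
#' @param dps a `gaze_datapoints`.
#' @param i data-point index.
#' @return array `5 x 75 x 75 x 3` (crop, row, column, channel).
#' @export
datapoint_stack <- function(dps, i) {
  stopifnot(i >= 1, i <= dps$n)
  v <- array(dp_matrix(dps, i)$x, dim = c(CROP_SIZE, CROP_SIZE, 3, 5))
  aperm(v, c(4, 1, 2, 3))
}

#' Black-out augmentation
#'
#' Replaces exactly one of the five crops of each data point, chosen
#' uniformly at random, with the all-zero black image - the same sentinel
#' the inference path uses for undetected faces - so the trained network
#' is robust to missing frames. Labels are unchanged.
#'
#' @param dps a `gaze_datapoints`.
#' @param rng_seed integer seed.
#' @return augmented `gaze_datapoints`.
#' @export
blackout_augment <- function(dps, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  out <- materialize_datapoints(dps)
  pos <- sample.int(5L, out$n, replace = TRUE)
  cols <- out$win_cols[cbind(pos, seq_len(out$n))]
  out$pix[, cols] <- 0
  out$cmiss[cols] <- TRUE
  out
}

#' Brightness augmentation
#'
#' Draws one multiplicative brightness factor per data point and applies
#' it to all five crops identically (inter-crop ratios are preserved),
#' clipping to the valid `[0, 1]` pixel range. Intended for raw
#' (pre-normalization) pixels.
#'
#' @param dps a `gaze_datapoints` holding raw pixels.
#' @param rng_seed integer seed.
#' @param range factor range (uniform draw).
#' @return augmented `gaze_datapoints`.
#' @export
brightness_augment <- function(dps, rng_seed = NULL, range = c(0.7, 1.3)) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  out <- materialize_datapoints(dps)
  f <- runif(out$n, range[1], range[2])
  fac <- rep(f, each = 5L)
  out$pix <- pmin(pmax(sweep(out$pix, 2, fac, "*"), 0), 1)
  out
}
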