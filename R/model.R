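#' Model configuration for the multi-frame gaze classifier
#'
#' The network consumes a stack of five 75 x 75 RGB face crops (15 input
#' channels) and emits a softmax probability vector over the gaze classes.
#' Every convolutional layer uses a 3 x 3 kernel with stride 1 and no
#' padding, and each block is followed by 2 x 2 max-pooling; the
#' convolutional stack feeds one ReLU dense layer and the softmax output.
#' Filter counts and the dense width are configurable; the default
#' (32, 64, 128, 128 filters, 256 dense units) is sized for real video
#' corpora, while desk-scale synthetic experiments run well with far
#' smaller stacks (e.g., `conv_filters = c(8, 16)`).
#'
#' @param n_classes 3 (away/left/right) or 2 (left/right).
#' @param conv_filters integer vector of per-block filter counts.
#' @param dense_units hidden dense-layer width.
#' @param input_size crop side length (75).
#' @param n_stack number of stacked crops (5).
#' @param channels color channels per crop (3; grayscale inputs are
#'   replicated to 3 channels upstream).
#' @return list of class `model_config`.
#' @export
model_config <- function(n_classes = 3, conv_filters = c(32, 64, 128, 128),
                         dense_units = 256, input_size = 75, n_stack = 5,
                         channels = 3) {
  stopifnot(n_classes %in% c(2, 3), length(conv_filters) >= 1,
            all(conv_filters >= 1), dense_units >= 1)
  h <- input_size
  for (f in conv_filters) {
    h <- h - 2                      # valid 3x3 convolution
    if (h < 2) stop("conv stack too deep for the input size")
    h <- h %/% 2                    # 2x2 max-pool
    if (h < 1) stop("conv stack too deep for the input size")
  }
  structure(list(n_classes = as.integer(n_classes),
                 conv_filters = as.integer(conv_filters),
                 dense_units = as.integer(dense_units),
                 input_size = as.integer(input_size),
                 n_stack = as.integer(n_stack),
                 channels = as.integer(channels),
                 in_channels = as.integer(n_stack * channels),
                 n_blocks = length(conv_filters),
                 final_size = as.integer(h)),
            class = "model_config")
}

#' Build an untrained gaze classifier
#'
#' Initializes all weights (He-scaled Gaussian) for the architecture in
#' `cfg`. The returned model carries its configuration, parameters, class
#' names (`away`, `left`, `right`, or `left`, `right` for the binary
#' variant) and - once trained - the normalization statistics that must
#' travel with the weights.
#'
#' @param cfg a `model_config`.
#' @param seed integer seed for weight initialization.
#' @return list of class `gaze_model`.
#' @export
build_model <- function(cfg = model_config(), seed = 1) {
  stopifnot(inherits(cfg, "model_config"))
  set.seed(seed)
  he <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / nc)), nr, nc)
  conv_W <- list(); conv_b <- list()
  cin <- cfg$in_channels
  for (b in seq_len(cfg$n_blocks)) {
    f <- cfg$conv_filters[b]
    conv_W[[b]] <- he(f, cin * 9)
    conv_b[[b]] <- numeric(f)
    cin <- f
  }
  flat <- cfg$conv_filters[cfg$n_blocks] * cfg$final_size^2
  params <- list(conv_W = conv_W, conv_b = conv_b,
                 dense_W = he(cfg$dense_units, flat),
                 dense_b = numeric(cfg$dense_units),
                 out_W = he(cfg$n_classes, cfg$dense_units),
                 out_b = numeric(cfg$n_classes))
  classes <- if (cfg$n_classes == 3) gaze_levels() else c("left", "right")
  structure(list(config = cfg, params = params, classes = classes,
                 norm_stats = NULL),
            class = "gaze_model")
}

#' @export
print.gaze_model <- function(x, ...) {
  cat(sprintf("gaze_model: %d-class, conv filters (%s), dense %d, %s\n",
              x$config$n_classes,
              paste(x$config$conv_filters, collapse = ", "),
              x$config$dense_units,
              if (is.null(x$norm_stats)) "untrained" else "with norm stats"))
  invisible(x)
}

cpp_cfg <- function(cfg) {
  list(input_size = cfg$input_size, in_channels = cfg$in_channels,
       n_blocks = cfg$n_blocks)
}

#' Predict class probabilities for data points
#'
#' Runs the forward pass on already-normalized feature columns. Each
#' column yields a probability vector over the model's classes (softmax:
#' nonnegative, summing to one).
#'
#' @param model a `gaze_model`.
#' @param x numeric matrix of already-normalized feature columns
#'   (`84375 x n` for the default configuration); see
#'   [classify_datapoints()] for the raw-pixel entry point.
#' @param batch_size forward-pass batch size (memory control only;
#'   every data point is processed independently regardless).
#' @return numeric matrix `n x n_classes`, columns named by class.
#' @export
predict_probs <- function(model, x, batch_size = 64) {
  stopifnot(inherits(model, "gaze_model"), is.matrix(x))
  expect_len <- model$config$in_channels * model$config$input_size^2
  if (nrow(x) != expect_len) {
    stop("input shape mismatch: ", nrow(x), " features per data point, ",
         "expected ", expect_len)
  }
  n <- ncol(x)
  out <- matrix(NA_real_, n, model$config$n_classes,
                dimnames = list(NULL, model$classes))
  for (s in seq(1, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1)
    out[s:e, ] <- t(cnn_forward_cpp(model$params,
                                    x[, s:e, drop = FALSE],
                                    cpp_cfg(model$config)))
  }
  out
}

#' Hard labels from probability rows
#'
#' Argmax with the fixed tie-breaking order away < left < right (column
#' order of the probability matrix).
#'
#' @param probs matrix from [predict_probs()].
#' @return character vector of labels.
#' @export
probs_to_labels <- function(probs) {
  colnames(probs)[max.col(probs, ties.method = "first")]
}

#' Class-weighted categorical cross-entropy
#'
#' `loss = -w(label) * log U[label]`, with the probability clamped at
#' `eps` so the loss stays finite. The default weights 1 : 0.66 : 0.66
#' (away : left : right) make an away misclassification cost 1/0.66 times
#' a side misclassification at the same predicted probability,
#' compensating the away class's smaller sample share and noisier human
#' labels.
#'
#' @param U probability vector (named, or ordered away/left/right) or a
#'   matrix of probability rows.
#' @param label true label (vector, recycled against matrix rows).
#' @param weights named class weights.
#' @param eps probability clamp.
#' @return numeric loss (vector for matrix input).
#' @export
weighted_ce_loss <- function(U, label,
                             weights = c(away = 1, left = 0.66,
                                         right = 0.66),
                             eps = 1e-12) {
  if (is.matrix(U)) {
    if (is.null(colnames(U))) colnames(U) <- names(weights)
    p <- U[cbind(seq_len(nrow(U)), match(label, colnames(U)))]
  } else {
    if (is.null(names(U))) names(U) <- names(weights)
    p <- U[[label]]
  }
  -unname(weights[label]) * log(pmax(p, eps))
}

#' Classify data points with a trained model
#'
#' Normalizes the raw-pixel data points with the model's stored channel
#' statistics (missing crops keep the all-zero sentinel) and runs the
#' forward pass batch by batch.
#'
#' @param model a trained `gaze_model` carrying `norm_stats`.
#' @param dps a `gaze_datapoints` on the raw pixel scale.
#' @param batch_size forward-pass batch size.
#' @return list with `probs` (matrix, one row per data point) and `label`
#'   (argmax labels, ties broken in class order).
#' @export
classify_datapoints <- function(model, dps, batch_size = 64) {
  stopifnot(inherits(model, "gaze_model"),
            inherits(dps, "gaze_datapoints"))
  if (is.null(model$norm_stats)) stop("model carries no normalization stats")
  n <- dps$n
  probs <- matrix(NA_real_, n, model$config$n_classes,
                  dimnames = list(NULL, model$classes))
  for (s in seq(1, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1)
    bm <- dp_matrix(dps, s:e)
    xb <- normalize_dp_matrix(bm$x, bm$missing, model$norm_stats)
    probs[s:e, ] <- t(cnn_forward_cpp(model$params, xb,
                                      cpp_cfg(model$config)))
  }
  list(probs = probs, label = probs_to_labels(probs))
}

#' Save / load a gaze model checkpoint
#'
#' Writes the weights to `weights.rds` and a human-readable
#' `model.yaml` carrying the architecture configuration, the class order,
#' and the channel normalization statistics. The statistics always travel
#' with the weights: inference must normalize new video with the training
#' set's statistics, so a checkpoint without them would be unusable.
#'
#' @param model a `gaze_model`.
#' @param dir checkpoint directory (created if needed).
#' @rdname model_io
#' @return `save_gaze_model` returns `dir` invisibly; `load_gaze_model`
#'   returns the restored `gaze_model`.
#' @export
save_gaze_model <- function(model, dir) {
  stopifnot(inherits(model, "gaze_model"))
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to write checkpoints")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model$params, file.path(dir, "weights.rds"))
  meta <- list(
    config = unclass(model$config),
    classes = model$classes,
    norm_stats = if (is.null(model$norm_stats)) NULL else
      list(mean = model$norm_stats$mean, sd = model$norm_stats$sd))
  yaml::write_yaml(meta, file.path(dir, "model.yaml"))
  invisible(dir)
}

#' @rdname model_io
#' @export
load_gaze_model <- function(dir) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read checkpoints")
  }
  meta <- yaml::read_yaml(file.path(dir, "model.yaml"))
  cfg <- do.call(model_config,
                 meta$config[c("n_classes", "conv_filters", "dense_units",
                               "input_size", "n_stack", "channels")])
  model <- structure(list(config = cfg,
                          params = readRDS(file.path(dir, "weights.rds")),
                          classes = unlist(meta$classes),
                          norm_stats = NULL),
                     class = "gaze_model")
  if (!is.null(meta$norm_stats)) {
    model$norm_stats <- structure(list(mean = unlist(meta$norm_stats$mean),
                                       sd = unlist(meta$norm_stats$sd)),
                                  class = "norm_stats")
  }
  model
}
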