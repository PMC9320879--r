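#' Training configuration
#'
#' Defaults mirror the original training schedule: mini-batches of 16 data
#' points, Adam with initial learning rate 1e-5, learning rate halved when
#' validation loss stops improving for 3 consecutive epochs, training
#' stopped after 5 stagnant epochs, and away : left : right
#' misclassification costs weighted 1 : 0.66 : 0.66. "Improvement" is a
#' validation-loss decrease greater than `min_delta`. Desk-scale synthetic
#' experiments typically raise `initial_lr` (the synthetic task is far
#' easier than real video) - see the package vignette.
#'
#' @param batch_size mini-batch size.
#' @param initial_lr initial Adam learning rate.
#' @param lr_plateau_patience stagnant epochs before the lr is reduced.
#' @param early_stop_patience stagnant epochs before training stops.
#' @param lr_factor multiplicative lr reduction.
#' @param min_delta minimum validation-loss decrease that counts as
#'   improvement.
#' @param max_epochs epoch cap.
#' @param class_weights named misclassification weights.
#' @param blackout,brightness augmentation switches.
#' @param brightness_range brightness-factor range.
#' @param seed RNG seed for shuffling and augmentation.
#' @return list of class `train_config`.
#' @export
train_config <- function(batch_size = 16, initial_lr = 1e-5,
                         lr_plateau_patience = 3, early_stop_patience = 5,
                         lr_factor = 0.5, min_delta = 1e-4, max_epochs = 50,
                         class_weights = c(away = 1, left = 0.66,
                                           right = 0.66),
                         blackout = TRUE, brightness = TRUE,
                         brightness_range = c(0.7, 1.3), seed = 1) {
  stopifnot(batch_size >= 1, initial_lr > 0, lr_plateau_patience >= 1,
            early_stop_patience >= 1, lr_factor > 0, lr_factor < 1,
            all(class_weights > 0))
  structure(as.list(environment()), class = "train_config")
}

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  out <- Map(upd, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = state$t))
}

label_index0 <- function(labels, classes) {
  idx <- match(labels, classes)
  if (anyNA(idx)) stop("labels outside model classes: ",
                       paste(unique(labels[is.na(idx)]), collapse = ", "))
  as.integer(idx - 1L)
}

# mean weighted CE over a dataset (forward only, batched, normalizing
# each batch as it is assembled)
dataset_loss <- function(model, dps, y0, weights, stats, batch_size = 64) {
  n <- dps$n
  total <- 0
  for (s in seq(1, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1)
    bm <- dp_matrix(dps, s:e)
    xb <- normalize_dp_matrix(bm$x, bm$missing, stats)
    p <- cnn_forward_cpp(model$params, xb, cpp_cfg(model$config))
    idx <- cbind(y0[s:e] + 1L, seq_len(e - s + 1))
    total <- total + sum(-weights[y0[s:e] + 1L] * log(pmax(p[idx], 1e-12)))
  }
  total / n
}

#' Train the gaze classifier
#'
#' Mini-batch Adam training with per-epoch shuffling, per-data-point
#' brightness and black-out augmentation, plateau-based learning-rate
#' reduction and early stopping, all driven by the validation loss. Data
#' points arrive as raw-pixel [make_datapoints()] output; normalization
#' statistics are computed from the training crops (unless the model
#' already carries some) and applied after augmentation, matching the
#' inference path. The weights from the best validation epoch are
#' restored at the end.
#'
#' @param model an untrained (or warm) `gaze_model`.
#' @param train,val `gaze_datapoints` with raw pixels; must be disjoint.
#' @param cfg a `train_config`.
#' @param verbose print per-epoch progress.
#' @return the trained `gaze_model`, with `$history` (data.frame of epoch,
#'   lr, train and validation loss) and `$norm_stats` attached.
#' @export
train_gaze_model <- function(model, train, val, cfg = train_config(),
                             verbose = FALSE) {
  stopifnot(inherits(model, "gaze_model"), inherits(cfg, "train_config"),
            inherits(train, "gaze_datapoints"),
            inherits(val, "gaze_datapoints"))
  if (train$n == 0 || val$n == 0) stop("empty training or validation set")
  set.seed(cfg$seed)
  if (is.null(model$norm_stats)) {
    model$norm_stats <- norm_stats_from_datapoints(train)
  }
  stats <- model$norm_stats
  w <- cfg$class_weights[model$classes]
  y_tr <- label_index0(train$label, model$classes)
  y_va <- label_index0(val$label, model$classes)

  state <- adam_init(model$params)
  lr <- cfg$initial_lr
  best_loss <- Inf
  best_params <- model$params
  stagnant <- 0
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_loss = numeric(), val_loss = numeric())

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(train$n)
    ep_loss <- 0
    nb <- 0
    for (s in seq(1, train$n, by = cfg$batch_size)) {
      e <- min(train$n, s + cfg$batch_size - 1)
      idx <- ord[s:e]
      bm <- dp_matrix(train, idx)
      xb <- bm$x
      mb <- bm$missing
      nbatch <- length(idx)
      if (cfg$brightness) {
        f <- runif(nbatch, cfg$brightness_range[1], cfg$brightness_range[2])
        xb <- pmin(pmax(sweep(xb, 2, f, "*"), 0), 1)
      }
      xb <- normalize_dp_matrix(xb, mb, stats)
      if (cfg$blackout) {
        pos <- sample.int(5L, nbatch, replace = TRUE)
        for (j in seq_len(nbatch)) {
          rows <- ((pos[j] - 1) * CROP_LEN + 1):(pos[j] * CROP_LEN)
          xb[rows, j] <- 0
        }
      }
      res <- cnn_loss_grad_cpp(model$params, xb, y_tr[idx], w,
                               cpp_cfg(model$config))
      stepped <- adam_step(model$params, res$grads, state, lr)
      model$params <- stepped$params
      state <- stepped$state
      ep_loss <- ep_loss + res$loss
      nb <- nb + 1
    }
    val_loss <- dataset_loss(model, val, y_va, w, stats)
    history <- rbind(history,
                     data.frame(epoch = epoch, lr = lr,
                                train_loss = ep_loss / nb,
                                val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  train %.4f  val %.4f",
                      epoch, lr, ep_loss / nb, val_loss))
    }
    if (val_loss < best_loss - cfg$min_delta) {
      best_loss <- val_loss
      best_params <- model$params
      stagnant <- 0
    } else {
      stagnant <- stagnant + 1
      if (stagnant >= cfg$early_stop_patience) break
      if (stagnant %% cfg$lr_plateau_patience == 0) lr <- lr * cfg$lr_factor
    }
  }
  model$params <- best_params
  model$history <- history
  model
}

# channel stats over the (deduplicated) crops referenced by a data-point
# collection, skipping missing crops
norm_stats_from_datapoints <- function(dps) {
  used <- sort(unique(as.vector(dps$win_cols)))
  keep <- used[!dps$cmiss[used]]
  if (!length(keep)) stop("all crops missing; cannot compute stats")
  npx <- CROP_SIZE * CROP_SIZE
  m <- s <- numeric(3)
  for (ch in 1:3) {
    v <- dps$pix[((ch - 1) * npx + 1):(ch * npx), keep]
    m[ch] <- mean(v)
    s[ch] <- sqrt(mean((v - m[ch])^2))
  }
  structure(list(mean = m, sd = pmax(s, 1e-6)), class = "norm_stats")
}

# normalize packed 5-crop feature columns; missing crop slots stay zero
normalize_dp_matrix <- function(x, missing, stats) {
  npx <- CROP_SIZE * CROP_SIZE
  for (k in 1:5) {
    for (ch in 1:3) {
      rows <- ((k - 1) * CROP_LEN + (ch - 1) * npx + 1):
        ((k - 1) * CROP_LEN + ch * npx)
      x[rows, ] <- (x[rows, ] - stats$mean[ch]) / stats$sd[ch]
    }
    mk <- missing[k, ]
    if (any(mk)) {
      rows <- ((k - 1) * CROP_LEN + 1):(k * CROP_LEN)
      x[rows, mk] <- 0
    }
  }
  x
}
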