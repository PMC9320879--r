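#' Annotate a frame sequence with gaze labels
#'
#' Runs the full inference path over a video's frames: face detection,
#' crop + resize, normalization (with the statistics that traveled with
#' the trained model), five-crop window assembly and the classifier
#' forward pass, one independent prediction per complete centered window.
#'
#' Missing-face rules: if the *target* (center) frame of a window has no
#' detectable face the frame is labeled away outright, with probability
#' vector (1, 0, 0) - an undetected face almost always means the infant
#' is not looking at the screen. If one of the other four frames is
#' missing, it is replaced by the all-zero black image and the prediction
#' proceeds. Frames too close to the sequence edges to center a window
#' (the first 4 and last 5) are labeled away and flagged `edge = TRUE` so
#' every frame carries a label for downstream analysis.
#'
#' The returned timeline is raw classifier output;
#' [enforce_constraints()] applies the physical-plausibility correction.
#'
#' @param model a trained `gaze_model` carrying `norm_stats`.
#' @param frames list of frame arrays (>= 10 frames).
#' @param detector,filter passed to [detect_face()].
#' @param stats normalization statistics (default: the model's own).
#' @param fps frames per second recorded in the timeline.
#' @return a [gaze_timeline()] with one row per input frame.
#' @export
annotate_video <- function(model, frames, detector = NULL, filter = NULL,
                           stats = model$norm_stats, fps = 30) {
  stopifnot(inherits(model, "gaze_model"))
  if (is.null(stats)) stop("model carries no normalization stats; train it ",
                           "or supply stats explicitly")
  n <- length(frames)
  if (n < WINDOW_LEN) stop("need at least ", WINDOW_LEN, " frames, got ", n)
  crops <- frames_to_crops(frames, detector, filter)
  annotate_crops(model, crops, stats = stats, fps = fps)
}

# shared inference core over packed crops
annotate_crops <- function(model, crops, stats, fps = 30) {
  n <- ncol(crops$pix)
  crops$pix <- normalize_pix(crops$pix, stats)
  if (any(crops$missing)) crops$pix[, crops$missing] <- 0
  k <- length(model$classes)
  probs <- matrix(NA_real_, n, k, dimnames = list(NULL, model$classes))
  labels <- rep("away", n)
  edge <- rep(TRUE, n)
  centers <- (CENTER_OFFSET):(n - WINDOW_LEN + CENTER_OFFSET)  # 0-based
  edge[centers + 1L] <- FALSE
  forced <- crops$missing[centers + 1L]
  if (model$config$n_classes == 3 && any(forced)) {
    probs[centers[forced] + 1L, ] <-
      matrix(rep(c(1, 0, 0), sum(forced)), ncol = 3, byrow = TRUE)
  }
  todo <- centers[!forced]
  batch <- 64L
  if (length(todo)) for (s in seq(1, length(todo), by = batch)) {
    e <- min(length(todo), s + batch - 1L)
    cen <- todo[s:e]
    x <- matrix(0, CROP_LEN * 5L, length(cen))
    for (j in seq_along(cen)) {
      idx <- cen[j] - CENTER_OFFSET + ALTERNATE_OFFSETS + 1L
      x[, j] <- as.vector(crops$pix[, idx])
    }
    p <- t(cnn_forward_cpp(model$params, x, cpp_cfg(model$config)))
    colnames(p) <- model$classes
    probs[cen + 1L, ] <- p
    labels[cen + 1L] <- probs_to_labels(p)
  }
  gaze_timeline(labels, probs = probs, fps = fps, edge = edge)
}

#' Annotate a synthetic session with a trained model
#'
#' Renders the session's frames trial by trial (deterministically, from
#' the session seed) and runs the inference path on each trial block,
#' keeping memory constant in session length. Each trial block is
#' annotated independently; trial boundaries are genuine sequence edges
#' in these sessions (trials are separated by attention-getter frames),
#' and the critical analysis window never touches the per-trial edge
#' frames.
#'
#' @param model a trained `gaze_model`.
#' @param session a `synthetic_session`.
#' @param postprocess apply [enforce_constraints()] to the result.
#' @return a [gaze_timeline()] covering the whole session.
#' @export
annotate_session <- function(model, session, postprocess = TRUE) {
  stopifnot(inherits(session, "synthetic_session"))
  len <- session$params$study$trial_len_frames
  fps <- session$params$dyn$fps
  pieces <- lapply(seq_len(nrow(session$trials)), function(t) {
    fr <- ((t - 1L) * len):(t * len - 1L)
    frames <- render_session_frames(session, frames = fr)
    annotate_video(model, frames, fps = fps)
  })
  labels <- unlist(lapply(pieces, function(p) p$label))
  probs <- do.call(rbind, lapply(pieces, timeline_probs))
  edge <- unlist(lapply(pieces, function(p) p$edge))
  gaze_timeline(labels, probs = probs, fps = fps, edge = edge)
}
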