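#' Frame-level confusion matrix between predicted and reference labels
#'
#' Counts are accumulated only over frames the human coder tagged as valid;
#' rows are reference classes, columns predicted classes.
#'
#' @param pred character vector of predicted labels.
#' @param ref character vector of reference (human) labels.
#' @param valid logical or 0/1 vector; frames with `valid = 0` are skipped.
#'   Defaults to all valid.
#' @param levels class levels defining matrix order; defaults to the full
#'   three-way label set.
#' @return integer matrix `length(levels) x length(levels)`, rows = reference.
#' @export
confusion_matrix <- function(pred, ref, valid = NULL, levels = gaze_levels()) {
  pred <- as.character(pred)
  ref <- as.character(ref)
  if (length(pred) != length(ref)) {
    stop("pred and ref must have equal length (",
         length(pred), " vs ", length(ref), ")")
  }
  if (is.null(valid)) valid <- rep(TRUE, length(ref))
  stopifnot(length(valid) == length(ref))
  keep <- as.logical(valid)
  tab <- table(factor(ref[keep], levels = levels),
               factor(pred[keep], levels = levels))
  m <- matrix(as.integer(tab), nrow = length(levels),
              dimnames = list(ref = levels, pred = levels))
  m
}

#' Row-normalize a confusion matrix
#'
#' @param m count matrix from [confusion_matrix()].
#' @return matrix of row proportions; all-zero rows stay zero.
#' @export
normalize_confusion <- function(m) {
  rs <- rowSums(m)
  rs[rs == 0] <- 1
  sweep(m, 1, rs, "/")
}

#' Support-weighted F1 score
#'
#' Per-class F1 is the harmonic mean of precision and recall,
#' `2PR/(P+R)`; the reported score is the mean of per-class F1 weighted by
#' reference support (frame counts). Classes with zero reference support
#' are excluded from the weighting: a class that is predicted but never
#' occurs in the reference has F1 = 0 but zero weight, so it cannot
#' contribute. Only frames with `valid = 1` are scored.
#'
#' @inheritParams confusion_matrix
#' @return numeric scalar in `[0, 1]`.
#' @export
weighted_f1 <- function(pred, ref, valid = NULL, levels = gaze_levels()) {
  pred <- as.character(pred)
  ref <- as.character(ref)
  if (length(pred) != length(ref)) {
    stop("pred and ref must have equal length (",
         length(pred), " vs ", length(ref), ")")
  }
  if (is.null(valid)) valid <- rep(TRUE, length(ref))
  keep <- as.logical(valid)
  pred <- pred[keep]
  ref <- ref[keep]
  if (length(ref) == 0) stop("no valid frames to score")
  # counts taken from the raw vectors so that predictions outside the level
  # set (e.g., away in two-class mode) still count against recall
  f1 <- support <- numeric(length(levels))
  for (i in seq_along(levels)) {
    cl <- levels[i]
    tp <- sum(pred == cl & ref == cl)
    predicted <- sum(pred == cl)
    support[i] <- sum(ref == cl)
    p <- if (predicted > 0) tp / predicted else 0
    r <- if (support[i] > 0) tp / support[i] else 0
    f1[i] <- if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  use <- support > 0
  sum(f1[use] * support[use]) / sum(support[use])
}

#' Evaluate predicted timelines against reference annotations across videos
#'
#' Computes the per-video support-weighted F1 and reports the average and
#' (min-max) range across videos, the way automated-coder agreement is
#' conventionally summarized, together with the pooled confusion matrix.
#' In two-class mode scoring is restricted to frames whose reference label
#' is left or right (the binary left-vs-right task); predictions of away on
#' such frames count against recall of the true side.
#'
#' @param pairs list of videos; each element is a list with components
#'   `pred` (a `gaze_timeline` or character labels) and `ref` (an
#'   annotation data.frame with `label` and `valid`, or character labels).
#' @param two_class logical; score the binary left/right task.
#' @return object of class `eval_report`: list with `per_video_f1`, `avg`,
#'   `min`, `max`, `confusion` (pooled counts), `confusion_norm`,
#'   `n_valid_frames`.
#' @export
evaluate_videos <- function(pairs, two_class = FALSE) {
  if (length(pairs) == 0) stop("no videos to evaluate")
  levels <- if (two_class) c("left", "right") else gaze_levels()
  per_f1 <- numeric(length(pairs))
  n_valid <- integer(length(pairs))
  pooled <- matrix(0L, length(levels), length(levels),
                   dimnames = list(ref = levels, pred = levels))
  for (i in seq_along(pairs)) {
    pv <- pairs[[i]]
    pred <- if (inherits(pv$pred, "gaze_timeline")) pv$pred$label else
      as.character(pv$pred)
    if (is.data.frame(pv$ref)) {
      ref <- as.character(pv$ref$label)
      valid <- as.logical(pv$ref$valid)
    } else {
      ref <- as.character(pv$ref)
      valid <- rep(TRUE, length(ref))
    }
    if (length(pred) != length(ref)) {
      stop("video ", i, ": prediction and reference lengths differ (",
           length(pred), " vs ", length(ref), ")")
    }
    if (two_class) valid <- valid & ref %in% c("left", "right")
    # pooled confusion drops predictions outside the level set (two-class
    # mode with an away prediction); per-class recall still sees them via
    # weighted_f1's confusion on the same levels.
    per_f1[i] <- weighted_f1(pred, ref, valid, levels = levels)
    pooled <- pooled + confusion_matrix(pred, ref, valid, levels = levels)
    n_valid[i] <- sum(valid)
  }
  structure(list(
    per_video_f1 = per_f1,
    avg = mean(per_f1),
    min = min(per_f1),
    max = max(per_f1),
    confusion = pooled,
    confusion_norm = normalize_confusion(pooled),
    n_valid_frames = n_valid
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Weighted F1 across %d video(s): %.3f (%.3f-%.3f)\n",
              length(x$per_video_f1), x$avg, x$min, x$max))
  cat("Pooled confusion matrix (rows = reference):\n")
  print(x$confusion)
  invisible(x)
}
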