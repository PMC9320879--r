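#' Enforce physical-plausibility constraints on a gaze timeline
#'
#' Video recorded at 30 fps cannot show an infant's gaze jumping from one
#' screen side to the other between consecutive frames: initiating a gaze
#' shift takes on the order of 200 ms, several frames. Manual-coding
#' software encodes this as an illegal transition, but a classifier that
#' scores each five-frame window independently can emit such flips. This
#' function makes the predicted label sequence legal again.
#'
#' A single left-to-right scan is applied: for each frame `t >= 2` (1-based),
#' if the already-corrected label at `t - 1` is a side label and the raw
#' label at `t` is the opposite side, the label at `t` is replaced by
#' `"away"`; otherwise the raw label is kept. This preserves both fixations
#' and the timing of the shift, only frames participating in an illegal
#' adjacent pair are altered (and only to away), and the operation is
#' idempotent. Probabilities, when present, are left untouched.
#'
#' @param timeline a `gaze_timeline` (see [gaze_timeline()]) or a character
#'   vector of labels.
#' @return object of the same kind with a legal label sequence.
#' @seealso [smooth_min_run()] for optional minimum-fixation smoothing,
#'   which is *not* applied here.
#' @export
#' @examples
#' enforce_constraints(c("left", "left", "right", "right"))
enforce_constraints <- function(timeline) {
  if (is.character(timeline) || is.factor(timeline)) {
    return(enforce_label_scan(as.character(timeline)))
  }
  stopifnot(inherits(timeline, "gaze_timeline"))
  timeline$label <- enforce_label_scan(as.character(timeline$label))
  timeline
}

enforce_label_scan <- function(labels) {
  n <- length(labels)
  if (n < 2L) return(labels)
  out <- labels
  for (t in 2:n) {
    if (is_side(out[t - 1L]) && out[t] == opposite_side(out[t - 1L])) {
      out[t] <- "away"
    }
  }
  out
}

#' Check a label sequence for illegal side flips
#'
#' @param labels character vector of gaze labels.
#' @return `TRUE` if no adjacent frame pair is left,right or right,left.
#' @export
is_legal_sequence <- function(labels) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 2L) return(TRUE)
  a <- labels[-n]
  b <- labels[-1L]
  !any((a == "left" & b == "right") | (a == "right" & b == "left"))
}

#' Optional minimum-run smoothing
#'
#' Relabels maximal left/right runs shorter than `min_run` frames as away.
#' The mandatory post-processing step is only the illegal-flip correction
#' of [enforce_constraints()]; this smoother is provided for users whose
#' downstream pipelines additionally require a minimum fixation duration,
#' and is off by default everywhere in the package.
#'
#' @param labels character vector of gaze labels.
#' @param min_run minimum acceptable side-run length in frames.
#' @return character vector of labels.
#' @export
smooth_min_run <- function(labels, min_run) {
  stopifnot(min_run >= 1)
  labels <- as.character(labels)
  runs <- label_runs(labels)
  for (i in seq_len(nrow(runs))) {
    if (is_side(runs$label[i]) && runs$length[i] < min_run) {
      idx <- runs$start[i] + seq_len(runs$length[i])
      labels[idx] <- "away"
    }
  }
  labels
}
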