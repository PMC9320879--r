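#' Construct a gaze timeline
#'
#' A gaze timeline holds, for every frame of a session, the hard gaze label
#' and (for classifier output) the class probability vector. Frame indices
#' are 0-based; at 30 fps frame `k` has timestamp `k * (100/3)` ms.
#'
#' @param label character vector of per-frame labels.
#' @param probs optional numeric matrix, one row per frame, columns
#'   `away`, `left`, `right` (or `left`, `right` for the two-class model).
#' @param frame optional 0-based frame indices (default `0:(n-1)`).
#' @param fps frames per second (default 30).
#' @param edge optional logical vector flagging frames labeled by the edge
#'   policy rather than by a complete centered window.
#' @return data.frame of class `gaze_timeline` with columns `frame`,
#'   `label`, one `p_<class>` column per class, and `edge`.
#' @export
gaze_timeline <- function(label, probs = NULL, frame = NULL, fps = 30,
                          edge = NULL) {
  n <- length(label)
  if (is.null(frame)) frame <- seq_len(n) - 1L
  stopifnot(length(frame) == n)
  if (is.null(probs)) {
    probs <- matrix(NA_real_, nrow = n, ncol = 3,
                    dimnames = list(NULL, gaze_levels()))
  }
  probs <- as.matrix(probs)
  stopifnot(nrow(probs) == n, !is.null(colnames(probs)))
  if (is.null(edge)) edge <- rep(FALSE, n)
  out <- data.frame(frame = as.integer(frame),
                    label = as.character(label),
                    stringsAsFactors = FALSE)
  for (cl in colnames(probs)) out[[paste0("p_", cl)]] <- probs[, cl]
  out$edge <- edge
  attr(out, "fps") <- fps
  class(out) <- c("gaze_timeline", "data.frame")
  out
}

timeline_probs <- function(timeline) {
  pcols <- grep("^p_", names(timeline), value = TRUE)
  m <- as.matrix(timeline[, pcols, drop = FALSE])
  colnames(m) <- sub("^p_", "", pcols)
  m
}

#' Read / write a timeline CSV (`frame,label,p_away,p_left,p_right`)
#'
#' @param path file path.
#' @rdname timeline_io
#' @return `read_timeline` returns a `gaze_timeline`.
#' @export
read_timeline <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("frame", "label") %in% names(d)))
  pcols <- grep("^p_", names(d), value = TRUE)
  probs <- if (length(pcols)) {
    m <- as.matrix(d[, pcols, drop = FALSE])
    colnames(m) <- sub("^p_", "", pcols)
    m
  } else NULL
  gaze_timeline(d$label, probs = probs, frame = d$frame,
                edge = if ("edge" %in% names(d)) as.logical(d$edge) else NULL)
}

#' @param timeline a `gaze_timeline`.
#' @rdname timeline_io
#' @export
write_timeline <- function(timeline, path) {
  write.csv(as.data.frame(timeline), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a frame annotation CSV (`frame,label,valid`)
#'
#' The human (or ground-truth) annotation format: 0-based frame index,
#' label in away/left/right, and a 0/1 validity flag (frames a coder marked
#' uncodable carry `valid = 0`).
#'
#' @param path file path.
#' @rdname annotation_io
#' @return `read_annotation` returns a data.frame with columns `frame`
#'   (integer), `label` (character), `valid` (integer 0/1).
#' @export
read_annotation <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("frame", "label", "valid") %in% names(d)))
  as_gaze_label(d$label)  # validates
  d$frame <- as.integer(d$frame)
  d$valid <- as.integer(d$valid)
  d
}

#' @param annotation data.frame with columns `frame`, `label`, `valid`.
#' @rdname annotation_io
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(all(c("frame", "label", "valid") %in% names(annotation)))
  write.csv(annotation[, c("frame", "label", "valid")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a trial metadata CSV
#'
#' Columns: `trial`, `participant`, `noun_condition` (high/low),
#' `frame_condition` (typical/atypical), `target_side` (left/right),
#' `onset_frame` (0-based frame of target-noun onset), `end_frame`
#' (0-based, inclusive last frame of the trial).
#'
#' @param path file path.
#' @rdname trial_io
#' @export
read_trials <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "participant", "noun_condition", "frame_condition",
            "target_side", "onset_frame", "end_frame")
  stopifnot(all(need %in% names(d)))
  stopifnot(all(d$target_side %in% c("left", "right")))
  d
}

#' @param trials trial metadata data.frame.
#' @rdname trial_io
#' @export
write_trials <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
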