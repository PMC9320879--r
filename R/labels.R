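#' Gaze label levels
#'
#' The three-way per-frame gaze code used throughout the package:
#' `"away"` (neither on-screen image, or face undetectable), `"left"` and
#' `"right"` (the screen side the child is looking at, from the child's
#' perspective). The fixed order `away < left < right` is also the
#' tie-breaking order used when predicted class probabilities are equal.
#'
#' @return Character vector `c("away", "left", "right")`.
#' @export
gaze_levels <- function() c("away", "left", "right")

#' Coerce a vector of labels to a gaze factor
#'
#' @param x character vector (or factor) of labels.
#' @param two_class if `TRUE`, levels are restricted to left/right.
#' @return factor with the canonical gaze levels.
#' @export
as_gaze_label <- function(x, two_class = FALSE) {
  lev <- if (two_class) c("left", "right") else gaze_levels()
  x <- as.character(x)
  bad <- !(x %in% lev)
  if (any(bad)) {
    stop("invalid gaze label(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  factor(x, levels = lev)
}

is_side <- function(x) x %in% c("left", "right")

opposite_side <- function(x) {
  out <- x
  out[x == "left"] <- "right"
  out[x == "right"] <- "left"
  out
}

#' Run-length summary of a label sequence
#'
#' Thin wrapper around [rle()] returning a data.frame of maximal runs with
#' 0-based start frames, used by the dwell-time invariant checks and the
#' away-run exclusion rule.
#'
#' @param labels character vector of gaze labels.
#' @return data.frame with columns `label`, `start` (0-based), `length`.
#' @export
label_runs <- function(labels) {
  r <- rle(as.character(labels))
  ends <- cumsum(r$lengths)
  data.frame(
    label = r$values,
    start = ends - r$lengths,
    length = r$lengths,
    stringsAsFactors = FALSE
  )
}
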