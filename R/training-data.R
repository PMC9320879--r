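#' Simulate a labeled training set of five-crop data points
#'
#' Samples ground-truth gaze sequences from the semi-Markov dynamics,
#' renders their frames, extracts and windows the face crops, and packs
#' the result as raw-pixel data points ready for [train_gaze_model()].
#' Target side alternates between chunks so left and right are balanced;
#' away frames arise at the dynamics' natural rate, which leaves the away
#' class underrepresented - the situation the 1 : 0.66 : 0.66 class
#' weighting is designed for.
#'
#' @param n number of data points to generate.
#' @param dyn a `dynamics_config`.
#' @param renderer a `renderer_config`.
#' @param seed integer seed.
#' @param chunk_frames frames per independently sampled sequence chunk.
#' @return a `gaze_datapoints` with `n` data points (raw pixel scale).
#' @export
simulate_training_datapoints <- function(n, dyn = dynamics_config(),
                                         renderer = renderer_config(),
                                         seed = 1, chunk_frames = 200) {
  stopifnot(n >= 1, chunk_frames >= WINDOW_LEN)
  set.seed(seed)
  per_chunk <- chunk_frames - WINDOW_LEN + 1L
  n_chunks <- ceiling(n / per_chunk)
  pix <- matrix(0, nrow = CROP_LEN, ncol = n_chunks * chunk_frames)
  cmiss <- logical(n_chunks * chunk_frames)
  win_cols <- matrix(0L, nrow = 5L, ncol = n_chunks * per_chunk)
  label <- character(n_chunks * per_chunk)
  side <- "left"
  for (ch in seq_len(n_chunks)) {
    labs <- gaze_segment(dyn, chunk_frames, side)
    side <- opposite_side(side)
    missing <- labs == "away" & runif(chunk_frames) < dyn$p_missing_face
    frames <- lapply(seq_along(labs), function(i) {
      render_engine(labs[i], renderer, missing = missing[i])
    })
    crops <- frames_to_crops(frames)
    f0 <- (ch - 1L) * chunk_frames       # crop-store offset of this chunk
    w0 <- (ch - 1L) * per_chunk          # window offset
    pix[, f0 + seq_len(chunk_frames)] <- crops$pix
    cmiss[f0 + seq_len(chunk_frames)] <- crops$missing
    starts <- 0:(chunk_frames - WINDOW_LEN)
    win_cols[, w0 + seq_along(starts)] <-
      outer(ALTERNATE_OFFSETS + 1L + f0, starts, `+`)
    label[w0 + seq_along(starts)] <-
      labs[starts + CENTER_OFFSET + 1L]
  }
  dps <- structure(list(pix = pix, cmiss = cmiss, win_cols = win_cols,
                        label = label,
                        window_start = rep(NA_integer_,
                                           n_chunks * per_chunk),
                        n = n_chunks * per_chunk),
                   class = "gaze_datapoints")
  if (dps$n > n) dps <- subset_datapoints(dps, seq_len(n))
  dps
}

#' Subset a data-point collection
#'
#' Keeps the shared crop store and selects a subset of data points; use it
#' to split a simulated set into training and validation halves.
#'
#' @param dps a `gaze_datapoints`.
#' @param idx data-point indices to keep.
#' @return a `gaze_datapoints` with the selected data points.
#' @export
subset_datapoints <- function(dps, idx) {
  structure(list(pix = dps$pix, cmiss = dps$cmiss,
                 win_cols = dps$win_cols[, idx, drop = FALSE],
                 label = dps$label[idx],
                 window_start = dps$window_start[idx],
                 n = length(idx)),
            class = "gaze_datapoints")
}
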