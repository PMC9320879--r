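#' Renderer configuration for synthetic face frames
#'
#' A parametric cartoon face on a plain background: elliptical head, two
#' sclera disks, and pupil disks whose horizontal offset encodes the gaze
#' class. The goal is not photorealism but a controllable stimulus whose
#' usable face occupies roughly the same ~75-80 px region as a real
#' webcam-recorded infant face, with the same nuisance factors the
#' classifier must tolerate: variable brightness, pixel noise, face
#' position jitter, and occasional frames with no detectable face.
#'
#' Side labels are from the child's perspective. The camera faces the
#' child, so a child looking to *their* left appears in the image with
#' pupils shifted toward increasing column index (image right), and
#' vice versa; away is rendered with centered, lowered pupils. What
#' matters for the classifier is that the mapping is consistent, not its
#' direction.
#'
#' @param frame_size frame side length in pixels (square frames).
#' @param face_size face bounding-box side length in pixels.
#' @param eye_offset_x,eye_offset_y eye-center offsets from face center
#'   (columns, rows).
#' @param eye_radius,pupil_radius disk radii in pixels.
#' @param pupil_offset_px horizontal pupil displacement for left/right.
#' @param pupil_drop_px vertical pupil displacement for away.
#' @param jitter_px maximum absolute face-position jitter per axis.
#' @param brightness_range length-2 range of the multiplicative brightness
#'   factor drawn per frame.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (pixels live in `[0, 1]`).
#' @return list of class `renderer_config`.
#' @export
renderer_config <- function(frame_size = 96, face_size = 80,
                            eye_offset_x = 14, eye_offset_y = -8,
                            eye_radius = 7, pupil_radius = 3,
                            pupil_offset_px = 4, pupil_drop_px = 3,
                            jitter_px = 4, brightness_range = c(0.7, 1.3),
                            noise_sd = 0.03) {
  stopifnot(frame_size >= face_size, face_size > 4 * eye_radius,
            pupil_radius < eye_radius, length(brightness_range) == 2,
            brightness_range[1] <= brightness_range[2], noise_sd >= 0)
  structure(list(frame_size = frame_size, face_size = face_size,
                 eye_offset_x = eye_offset_x, eye_offset_y = eye_offset_y,
                 eye_radius = eye_radius, pupil_radius = pupil_radius,
                 pupil_offset_px = pupil_offset_px,
                 pupil_drop_px = pupil_drop_px, jitter_px = jitter_px,
                 brightness_range = brightness_range, noise_sd = noise_sd),
            class = "renderer_config")
}

# Renders one frame consuming the current RNG stream. All random draws
# (jitter, brightness, noise) happen before any label-dependent geometry,
# so frames rendered for different labels under the same seed share their
# randomness exactly.
render_engine <- function(label, renderer, missing = FALSE) {
  r <- renderer
  n <- r$frame_size
  jit <- if (r$jitter_px > 0) {
    round(runif(2, -r$jitter_px, r$jitter_px))
  } else c(0, 0)
  bright <- runif(1, r$brightness_range[1], r$brightness_range[2])
  noise <- if (r$noise_sd > 0) rnorm(n * n * 3, sd = r$noise_sd) else 0
  img <- array(0.22, dim = c(n, n, 3))  # background
  box <- NULL
  if (!missing) {
    cy <- (n + 1) / 2 + jit[1]  # row of face center
    cx <- (n + 1) / 2 + jit[2]  # column of face center
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    half <- r$face_size / 2
    disk <- function(y, x, rad) (rows - y)^2 + (cols - x)^2 <= rad^2
    face <- ((rows - cy) / half)^2 + ((cols - cx) / (0.85 * half))^2 <= 1
    skin <- c(0.85, 0.70, 0.60)
    dx <- switch(label, left = r$pupil_offset_px,
                 right = -r$pupil_offset_px, away = 0)
    dy <- if (label == "away") r$pupil_drop_px else 0
    eyes <- disk(cy + r$eye_offset_y, cx - r$eye_offset_x, r$eye_radius) |
      disk(cy + r$eye_offset_y, cx + r$eye_offset_x, r$eye_radius)
    pupils <- disk(cy + r$eye_offset_y + dy, cx - r$eye_offset_x + dx,
                   r$pupil_radius) |
      disk(cy + r$eye_offset_y + dy, cx + r$eye_offset_x + dx,
           r$pupil_radius)
    pupils <- pupils & eyes
    mouth <- ((rows - (cy + 0.45 * half)) / 2)^2 +
      ((cols - cx) / (0.3 * half))^2 <= 1
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[face] <- skin[ch]
      plane[eyes] <- 0.95
      plane[pupils] <- 0.08
      plane[mouth & face] <- 0.45
      img[, , ch] <- plane
    }
    r1 <- max(1L, round(cy - half))
    c1 <- max(1L, round(cx - half))
    box <- c(r1 = r1, c1 = c1,
             r2 = min(n, r1 + r$face_size - 1L),
             c2 = min(n, c1 + r$face_size - 1L))
  }
  img <- pmin(pmax(img * bright + noise, 0), 1)
  dim(img) <- c(n, n, 3)
  attr(img, "face_box") <- box
  attr(img, "label") <- label
  img
}

#' Render a single synthetic face frame
#'
#' @param label gaze label (`"away"`, `"left"`, `"right"`).
#' @param renderer a `renderer_config`.
#' @param rng_seed integer seed; identical seeds share jitter, brightness
#'   and noise across labels.
#' @param missing if `TRUE`, no face is drawn (undetectable-face frame).
#' @return `frame_size x frame_size x 3` array in `[0, 1]` with attribute
#'   `face_box` (`c(r1, c1, r2, c2)`, 1-based inclusive; `NULL` when
#'   missing).
#' @export
render_frame <- function(label, renderer = renderer_config(), rng_seed = 1,
                         missing = FALSE) {
  label <- match.arg(label, gaze_levels())
  set.seed(rng_seed)
  render_engine(label, renderer, missing = missing)
}

#' Render the frames of a synthetic session
#'
#' Renders ground-truth frames for a whole session or one slice of it.
#' Each frame's seed derives deterministically from the session seed and
#' the frame index, so any slice can be rendered independently and
#' reproducibly.
#'
#' @param session a `synthetic_session`.
#' @param frames 0-based frame indices to render (default: all).
#' @return list of frame arrays (see [render_frame()]) in the order of
#'   `frames`.
#' @export
render_session_frames <- function(session, frames = NULL) {
  stopifnot(inherits(session, "synthetic_session"))
  if (is.null(frames)) frames <- session$truth$frame
  renderer <- session$params$renderer
  lapply(frames, function(k) {
    set.seed(derive_seed(session$seed, 1000L + k))
    render_engine(session$truth$label[k + 1L], renderer,
                  missing = session$missing[k + 1L])
  })
}
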