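#' Gaze-dynamics configuration for the session simulator
#'
#' Ground-truth gaze is modeled as a semi-Markov process over the states
#' left / right / away with explicitly sampled dwell times. Side fixations
#' dwell at least `min_dwell_frames` frames - at 30 fps the default of 6
#' frames is 200 ms, the approximate minimum time an infant needs to
#' initiate an eye movement - with a shifted-geometric tail giving mean
#' `mean_dwell_side`. Opposite-side fixations are always separated by at
#' least one away frame, mirroring the transition constraints manual-coding
#' software enforces on human annotations.
#'
#' @param fps frames per second.
#' @param min_dwell_frames minimum side-fixation dwell, frames.
#' @param mean_dwell_side mean side-fixation dwell, frames.
#' @param mean_dwell_away mean away-bout dwell, frames (minimum 1).
#' @param p_away probability an away bout is inserted before a fixation
#'   (also the probability a segment opens with an away bout).
#' @param p_missing_face per-frame probability that an away frame's face is
#'   undetectable. Missing faces occur only during away bouts: an infant
#'   whose face the detector loses has, with overwhelming likelihood,
#'   turned from the screen, and the ground-truth label for such frames is
#'   away by definition.
#' @param side_bias probability a fixation lands on the trial's target side.
#' @return list of class `dynamics_config`.
#' @export
dynamics_config <- function(fps = 30, min_dwell_frames = 6,
                            mean_dwell_side = 9, mean_dwell_away = 8,
                            p_away = 0.25, p_missing_face = 0.05,
                            side_bias = 0.5) {
  stopifnot(fps > 0, min_dwell_frames >= 1,
            mean_dwell_side >= min_dwell_frames, mean_dwell_away >= 1)
  probs <- c(p_away = p_away, p_missing_face = p_missing_face,
             side_bias = side_bias)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  }
  if (min_dwell_frames * (1000 / fps) < 200) {
    warning("min_dwell_frames corresponds to < 200 ms at this fps; ",
            "side fixations shorter than the infant saccade latency")
  }
  structure(list(fps = fps, min_dwell_frames = min_dwell_frames,
                 mean_dwell_side = mean_dwell_side,
                 mean_dwell_away = mean_dwell_away,
                 p_away = p_away, p_missing_face = p_missing_face,
                 side_bias = side_bias),
            class = "dynamics_config")
}

# Shifted-geometric dwell: minimum + geometric tail with the given mean.
sample_dwell <- function(min_dwell, mean_dwell) {
  extra <- mean_dwell - min_dwell
  if (extra <= 0) return(min_dwell)
  min_dwell + rgeom(1L, 1 / (extra + 1))
}

# Core semi-Markov sampler; consumes the current RNG stream (no seeding).
# Guarantees: side runs >= min_dwell, opposite sides separated by >= 1 away
# frame, tail too short for a legal fixation is filled with away.
gaze_segment <- function(dyn, n, target_side, bias = dyn$side_bias) {
  other <- opposite_side(target_side)
  labels <- character(n)
  pos <- 0L
  prev <- NULL
  while (pos < n) {
    ins_away <- runif(1) < dyn$p_away
    s <- if (runif(1) < bias) target_side else other
    if (ins_away) {
      d <- min(sample_dwell(1L, dyn$mean_dwell_away), n - pos)
      labels[(pos + 1L):(pos + d)] <- "away"
      pos <- pos + d
      if (pos >= n) break
    } else if (!is.null(prev) && s != prev) {
      labels[pos + 1L] <- "away"
      pos <- pos + 1L
      if (pos >= n) break
    }
    if (n - pos < dyn$min_dwell_frames) {
      labels[(pos + 1L):n] <- "away"
      break
    }
    d <- min(sample_dwell(dyn$min_dwell_frames, dyn$mean_dwell_side), n - pos)
    labels[(pos + 1L):(pos + d)] <- s
    pos <- pos + d
    prev <- s
  }
  labels
}

#' Sample a ground-truth gaze label sequence
#'
#' Draws a semi-Markov state sequence over left / right / away (see
#' [dynamics_config()] for the process). The sequence never switches
#' directly between opposite sides, every side run is at least
#' `min_dwell_frames` long, and side fixations land on `target_side` with
#' probability `side_bias`. The same seed always reproduces the same
#' sequence.
#'
#' @param dyn a `dynamics_config`.
#' @param n_frames sequence length (>= 1).
#' @param target_side `"left"` or `"right"`.
#' @param rng_seed integer seed.
#' @return character vector of length `n_frames`.
#' @export
sample_gaze_sequence <- function(dyn, n_frames, target_side, rng_seed) {
  if (!is.numeric(n_frames) || n_frames < 1) {
    stop("n_frames must be a positive integer")
  }
  stopifnot(target_side %in% c("left", "right"))
  set.seed(rng_seed)
  gaze_segment(dyn, as.integer(n_frames), target_side)
}

#' Study design configuration
#'
#' Defines the 2x2 looking-while-listening design: target-noun frequency
#' (high / low) crossed with sentence frame (typical / atypical), with a
#' planted true looking accuracy for each cell. Each participant
#' contributes `n_trials` trials covering all four cells equally, target
#' side balanced within cell.
#'
#' @param n_participants number of participants.
#' @param n_trials trials per participant, divisible by 4 (default 32,
#'   i.e., 8 per cell).
#' @param planted_acc named numeric of length 4 - cells
#'   `high_typical`, `high_atypical`, `low_typical`, `low_atypical` - the
#'   true probability that a fixation inside the critical window lands on
#'   the target.
#' @param trial_len_frames frames per trial.
#' @param onset_frame 0-based target-noun onset within each trial.
#' @param seed global study seed; all participant and frame seeds derive
#'   from it.
#' @return list of class `study_config`.
#' @export
study_config <- function(n_participants = 30, n_trials = 32,
                         planted_acc = c(high_typical = 0.70,
                                         high_atypical = 0.70,
                                         low_typical = 0.60,
                                         low_atypical = 0.60),
                         trial_len_frames = 86, onset_frame = 15,
                         seed = 1) {
  if (n_trials %% 4 != 0) {
    stop("n_trials must be divisible by 4 to cover the 2x2 cells equally")
  }
  need <- c("high_typical", "high_atypical", "low_typical", "low_atypical")
  if (!all(need %in% names(planted_acc))) {
    stop("planted_acc must name all four cells: ",
         paste(need, collapse = ", "))
  }
  if (any(planted_acc < 0 | planted_acc > 1)) {
    stop("planted accuracies must lie in [0, 1]")
  }
  structure(list(n_participants = n_participants, n_trials = n_trials,
                 planted_acc = planted_acc[need],
                 trial_len_frames = trial_len_frames,
                 onset_frame = onset_frame, seed = seed),
            class = "study_config")
}

# Deterministic sub-seed derivation, kept under 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 10007 + index) %% 2147483647)
}

#' Generate one fully annotated synthetic session
#'
#' Builds the participant's trial list (all four cells, target side
#' balanced, order randomized), then samples each trial's ground-truth
#' label sequence. Before the critical window fixations are unbiased
#' (`dyn$side_bias`); from the first window frame onward fixations land on
#' the target with the trial cell's planted accuracy. Trial sequences end
#' with a forced away frame (the inter-trial attention getter), so
#' concatenated trials always form a legal session timeline.
#'
#' @param study a `study_config`.
#' @param dyn a `dynamics_config`.
#' @param renderer a `renderer_config` (stored with the session; frames are
#'   rendered on demand).
#' @param participant_index 1-based participant number.
#' @param render if `TRUE`, frames are rendered immediately into
#'   `$frames` (memory-heavy; intended for short sessions).
#' @return list of class `synthetic_session`: `truth` (annotation
#'   data.frame `frame,label,valid`), `missing` (per-frame logical),
#'   `trials` (trial metadata), `params`, `participant`, `seed`, and
#'   optionally `frames`.
#' @export
generate_session <- function(study, dyn, renderer = renderer_config(),
                             participant_index = 1, render = FALSE) {
  stopifnot(inherits(study, "study_config"), inherits(dyn, "dynamics_config"))
  win0 <- critical_window(0, fps = dyn$fps)[1]
  len_pre <- study$onset_frame + win0
  len <- study$trial_len_frames
  if (len_pre < 2 || len - len_pre < 11) {
    stop("inconsistent trial layout: trial too short for onset + window")
  }
  if (study$onset_frame + max(critical_window(0, fps = dyn$fps)) > len - 1) {
    stop("inconsistent trial layout: critical window exceeds trial length")
  }
  seed_p <- derive_seed(study$seed, participant_index)
  set.seed(seed_p)
  cells <- rep(names(study$planted_acc), each = study$n_trials / 4)
  sides <- unlist(lapply(seq_len(4), function(i) {
    k <- study$n_trials / 4
    s <- rep(c("left", "right"), length.out = k)
    s[sample.int(k)]
  }))
  ord <- sample.int(study$n_trials)
  cells <- cells[ord]
  sides <- sides[ord]
  labels <- character(study$n_trials * len)
  pid <- sprintf("p%03d", participant_index)
  trials <- data.frame(
    trial = seq_len(study$n_trials),
    participant = pid,
    noun_condition = sub("_.*", "", cells),
    frame_condition = sub(".*_", "", cells),
    target_side = sides,
    onset_frame = (seq_len(study$n_trials) - 1L) * len + study$onset_frame,
    end_frame = seq_len(study$n_trials) * len - 1L,
    stringsAsFactors = FALSE)
  for (t in seq_len(study$n_trials)) {
    planted <- study$planted_acc[[cells[t]]]
    pre <- c(gaze_segment(dyn, len_pre - 1L, sides[t]), "away")
    win <- gaze_segment(dyn, len - len_pre - 1L, sides[t], bias = planted)
    labels[((t - 1L) * len + 1L):(t * len)] <- c(pre, win, "away")
  }
  missing <- labels == "away" & runif(length(labels)) < dyn$p_missing_face
  truth <- data.frame(frame = seq_along(labels) - 1L, label = labels,
                      valid = 1L)
  sess <- structure(list(truth = truth, missing = missing, trials = trials,
                         params = list(study = study, dyn = dyn,
                                       renderer = renderer),
                         participant = pid, seed = seed_p, frames = NULL),
                    class = "synthetic_session")
  if (render) sess$frames <- render_session_frames(sess)
  sess
}

#' Generate a full synthetic study
#'
#' One session per participant; every per-participant seed derives from the
#' single study seed, so the same `study_config` always reproduces the same
#' study.
#'
#' @inheritParams generate_session
#' @return list of `synthetic_session` objects, named by participant id.
#' @export
generate_study <- function(study, dyn, renderer = renderer_config(),
                           render = FALSE) {
  sessions <- lapply(seq_len(study$n_participants), function(i) {
    generate_session(study, dyn, renderer, participant_index = i,
                     render = render)
  })
  names(sessions) <- vapply(sessions, `[[`, character(1), "participant")
  sessions
}

#' Ground-truth per-trial accuracy of a synthetic session
#'
#' Convenience for calibration checks: runs [assess_trials()] on the
#' session's own ground-truth labels.
#'
#' @param sessions list of `synthetic_session` (or a single one).
#' @param ... passed to [assess_trials()].
#' @return trial-results data.frame.
#' @export
ground_truth_results <- function(sessions, ...) {
  if (inherits(sessions, "synthetic_session")) sessions <- list(sessions)
  timelines <- lapply(sessions, function(s) s$truth$label)
  names(timelines) <- vapply(sessions, `[[`, character(1), "participant")
  trials <- do.call(rbind, lapply(sessions, `[[`, "trials"))
  fps <- sessions[[1]]$params$dyn$fps
  assess_trials(timelines, trials, fps = fps, ...)
}
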