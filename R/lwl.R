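#' Critical analysis window after target-noun onset
#'
#' The looking-while-listening accuracy measure is computed over frames
#' whose onset-relative timestamp falls in 367-2000 ms (inclusive), the
#' span in which a gaze shift can plausibly be a response to the target
#' noun. Frame `k` is timestamped `(k - onset) * (1000 / fps)` ms, so at
#' 30 fps the window covers onset offsets 12 through 60 - exactly 49
#' frames.
#'
#' @param onset 0-based frame index of the target-noun onset.
#' @param fps frames per second (default 30).
#' @param window_ms length-2 numeric, window bounds in ms (inclusive).
#' @return integer vector of 0-based frame indices.
#' @export
#' @examples
#' length(critical_window(0))  # 49
critical_window <- function(onset, fps = 30, window_ms = c(367, 2000)) {
  stopifnot(fps > 0, length(window_ms) == 2, window_ms[1] <= window_ms[2])
  ms_per_frame <- 1000 / fps
  kmax <- ceiling(window_ms[2] / ms_per_frame) + 1L
  k <- 0:kmax
  t_ms <- k * ms_per_frame
  eps <- 1e-9
  k <- k[t_ms >= window_ms[1] - eps & t_ms <= window_ms[2] + eps]
  as.integer(onset + k)
}

#' Assess a single trial: exclusion rules and looking accuracy
#'
#' A trial is excluded if the participant was looking away at the first
#' frame of the critical window (`away_at_start`), or looked away for more
#' than `max_away_run` consecutive frames anywhere inside the window
#' (`long_away_run`; a run touching the window edge counts only its
#' in-window length). For usable trials, accuracy is the number of window
#' frames on the target side divided by frames on target or distracter;
#' away frames do not enter the ratio.
#'
#' Frames annotated invalid (`valid = 0`) are treated as away for the
#' exclusion rules and excluded from the accuracy ratio when
#' `invalid_as_away = TRUE` (the default); with `FALSE` they are dropped
#' from the window entirely before any rule is applied.
#'
#' @param labels per-frame label vector (0-based frame `k` at `labels[k+1]`),
#'   or a `gaze_timeline`.
#' @param trial one-row data.frame (or list) with `target_side` and
#'   `onset_frame`.
#' @param fps frames per second.
#' @param valid optional 0/1 validity vector aligned with `labels`.
#' @param max_away_run exclusion threshold: more than this many consecutive
#'   away frames in the window excludes the trial (default 15).
#' @param invalid_as_away see Details.
#' @return list of class `trial_result`: `usable`, `exclusion_reason`
#'   (`"none"`, `"away_at_start"` or `"long_away_run"`), `accuracy`
#'   (`NA` when unusable), `n_target`, `n_distracter`, `n_away`.
#' @export
assess_trial <- function(labels, trial, fps = 30, valid = NULL,
                         max_away_run = 15, invalid_as_away = TRUE) {
  if (inherits(labels, "gaze_timeline")) labels <- labels$label
  labels <- as.character(labels)
  target <- trial$target_side
  stopifnot(target %in% c("left", "right"))
  win <- critical_window(trial$onset_frame, fps = fps)
  if (max(win) + 1L > length(labels)) {
    stop("critical window [", min(win), ", ", max(win),
         "] exceeds timeline of length ", length(labels))
  }
  wl <- labels[win + 1L]
  if (!is.null(valid)) {
    wv <- as.logical(valid[win + 1L])
    if (invalid_as_away) wl[!wv] <- "away" else wl <- wl[wv]
  }
  res <- list(usable = FALSE, exclusion_reason = "none", accuracy = NA_real_,
              n_target = sum(wl == target),
              n_distracter = sum(is_side(wl) & wl != target),
              n_away = sum(wl == "away"))
  if (length(wl) == 0 || wl[1] == "away") {
    res$exclusion_reason <- "away_at_start"
  } else if (max_run_length(wl == "away") > max_away_run) {
    res$exclusion_reason <- "long_away_run"
  } else {
    res$usable <- TRUE
    res$accuracy <- res$n_target / (res$n_target + res$n_distracter)
  }
  class(res) <- "trial_result"
  res
}

max_run_length <- function(flag) {
  if (!any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}

#' Assess all trials of a study against their timelines
#'
#' @param timelines named list of per-participant label vectors (or
#'   `gaze_timeline`s); names are participant ids.
#' @param trials trial metadata data.frame (see [read_trials()]).
#' @param valid optional named list of validity vectors parallel to
#'   `timelines`.
#' @inheritParams assess_trial
#' @return data.frame with one row per trial: trial metadata plus
#'   `usable`, `exclusion_reason`, `accuracy`, frame counts.
#' @export
assess_trials <- function(timelines, trials, fps = 30, valid = NULL,
                          max_away_run = 15, invalid_as_away = TRUE) {
  rows <- lapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    pid <- as.character(tr$participant)
    labs <- timelines[[pid]]
    if (is.null(labs)) stop("no timeline for participant ", pid)
    v <- if (is.null(valid)) NULL else valid[[pid]]
    res <- assess_trial(labs, tr, fps = fps, valid = v,
                        max_away_run = max_away_run,
                        invalid_as_away = invalid_as_away)
    cbind(tr, data.frame(usable = res$usable,
                         exclusion_reason = res$exclusion_reason,
                         accuracy = res$accuracy,
                         n_target = res$n_target,
                         n_distracter = res$n_distracter,
                         n_away = res$n_away))
  })
  do.call(rbind, rows)
}

#' Participant inclusion filter
#'
#' A participant is retained only with usable data for at least
#' `min_per_cell` trials in every one of the four condition cells
#' (noun high/low x frame typical/atypical).
#'
#' @param results trial results data.frame from [assess_trials()].
#' @param min_per_cell minimum usable trials per cell (default 2).
#' @return character vector of included participant ids.
#' @export
filter_participants <- function(results, min_per_cell = 2) {
  cells <- expand.grid(noun_condition = c("high", "low"),
                       frame_condition = c("typical", "atypical"),
                       stringsAsFactors = FALSE)
  keep <- character(0)
  for (pid in unique(as.character(results$participant))) {
    sub <- results[results$participant == pid & results$usable, ]
    ok <- all(vapply(seq_len(nrow(cells)), function(i) {
      sum(sub$noun_condition == cells$noun_condition[i] &
            sub$frame_condition == cells$frame_condition[i]) >= min_per_cell
    }, logical(1)))
    if (ok) keep <- c(keep, pid)
  }
  keep
}

#' Per-cell condition summary
#'
#' Trial accuracies are first averaged within participant x cell, then
#' across participants; the SEM is over participants (0 for a single
#' participant).
#'
#' @param results usable-trial results restricted to included participants.
#' @return list with `participant_cell` (participant x cell mean table) and
#'   `cells` (per-cell `mean`, `sem`, `n_participants`).
#' @export
condition_summary <- function(results) {
  res <- results[results$usable, ]
  if (nrow(res) == 0) stop("no usable trials")
  pc <- aggregate(accuracy ~ participant + noun_condition + frame_condition,
                  data = res, FUN = mean)
  cells <- aggregate(accuracy ~ noun_condition + frame_condition, data = pc,
                     FUN = function(x) c(mean = mean(x),
                                         sem = if (length(x) > 1)
                                           sd(x) / sqrt(length(x)) else 0,
                                         n = length(x)))
  cells <- cbind(cells[, c("noun_condition", "frame_condition")],
                 as.data.frame(cells$accuracy))
  names(cells) <- c("noun_condition", "frame_condition",
                    "mean", "sem", "n_participants")
  list(participant_cell = pc, cells = cells)
}

#' One-sample tests of looking accuracy against chance
#'
#' Two-sided one-sample t test of the participant-level cell means against
#' 0.5 (chance: two images on screen), one test per condition cell. Cells
#' whose participant means have zero variance are flagged `degenerate` and
#' return `NA` statistics instead of failing.
#'
#' @param participant_cell participant x cell mean table from
#'   [condition_summary()].
#' @param chance the chance accuracy level (0.5: two images on screen).
#' @return data.frame per cell: `mean`, `t`, `df`, `p`, `degenerate`.
#' @export
vs_chance_tests <- function(participant_cell, chance = 0.5) {
  pc <- participant_cell
  cells <- unique(pc[, c("noun_condition", "frame_condition")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    x <- pc$accuracy[pc$noun_condition == cells$noun_condition[i] &
                       pc$frame_condition == cells$frame_condition[i]]
    if (length(x) < 2) stop("need >= 2 participants per cell")
    degenerate <- sd(x) == 0
    if (degenerate && mean(x) == chance) {
      tt <- list(statistic = 0, parameter = length(x) - 1, p.value = 1)
    } else if (degenerate) {
      tt <- list(statistic = NA_real_, parameter = length(x) - 1,
                 p.value = NA_real_)
    } else {
      t0 <- t.test(x, mu = chance)
      tt <- list(statistic = unname(t0$statistic),
                 parameter = unname(t0$parameter), p.value = t0$p.value)
    }
    data.frame(noun_condition = cells$noun_condition[i],
               frame_condition = cells$frame_condition[i],
               mean = mean(x), t = tt$statistic, df = tt$parameter,
               p = tt$p.value, degenerate = degenerate)
  })
  do.call(rbind, out)
}

#' Two-by-two fully-within-subjects ANOVA with partial eta squared
#'
#' Classical repeated-measures sums-of-squares decomposition for a 2x2
#' design in which every participant contributes all four cells (one mean
#' per cell). Each effect (noun main effect, frame main effect,
#' interaction) is tested against its own participant-by-effect error term:
#' `F = MS_effect / MS_effect:participant` with `(1, n - 1)` degrees of
#' freedom, and partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param participant_cell data.frame with columns `participant`,
#'   `noun_condition` (high/low), `frame_condition` (typical/atypical) and
#'   `accuracy` - exactly one row per participant x cell.
#' @return object of class `lwl_anova`: per-effect `F`, `p`, `pes`
#'   (partial eta squared), `df`, plus SS components and cell means/SEM.
#' @export
rm_anova_2x2 <- function(participant_cell) {
  pc <- participant_cell
  pc$participant <- as.character(pc$participant)
  pids <- unique(pc$participant)
  n <- length(pids)
  if (n < 2) stop("need >= 2 participants")
  # y[i, a, b]: participant x noun x frame cell means
  y <- array(NA_real_, c(n, 2, 2),
             dimnames = list(pids, c("high", "low"), c("typical", "atypical")))
  for (r in seq_len(nrow(pc))) {
    y[pc$participant[r], pc$noun_condition[r], pc$frame_condition[r]] <-
      pc$accuracy[r]
  }
  if (anyNA(y)) {
    miss <- pids[apply(y, 1, anyNA)]
    stop("incomplete 2x2 cell table for participant(s): ",
         paste(miss, collapse = ", "))
  }
  m <- mean(y)
  m_a <- apply(y, 2, mean)            # noun level means
  m_b <- apply(y, 3, mean)            # frame level means
  m_ab <- apply(y, c(2, 3), mean)     # cell means
  m_s <- apply(y, 1, mean)            # participant means
  m_as <- apply(y, c(1, 2), mean)     # participant x noun
  m_bs <- apply(y, c(1, 3), mean)     # participant x frame
  ss <- function(x) sum(x^2)
  SS_A <- 2 * n * ss(m_a - m)
  SS_B <- 2 * n * ss(m_b - m)
  SS_AB <- n * ss(sweep(sweep(m_ab, 1, m_a), 2, m_b) + m)
  SS_AS <- 2 * ss(sweep(sweep(m_as, 2, m_a), 1, m_s) + m)
  SS_BS <- 2 * ss(sweep(sweep(m_bs, 2, m_b), 1, m_s) + m)
  resid <- y
  for (i in seq_len(n)) for (a in 1:2) for (b in 1:2) {
    resid[i, a, b] <- y[i, a, b] - m_ab[a, b] - m_as[i, a] - m_bs[i, b] +
      m_a[a] + m_b[b] + m_s[i] - m
  }
  SS_ABS <- ss(resid)
  eff <- function(ss_eff, ss_err) {
    ms_err <- ss_err / (n - 1)
    F <- if (ms_err > 0) ss_eff / ms_err else if (ss_eff == 0) 0 else Inf
    list(F = F, df1 = 1, df2 = n - 1,
         p = if (is.finite(F)) pf(F, 1, n - 1, lower.tail = FALSE) else 0,
         pes = if (ss_eff + ss_err > 0) ss_eff / (ss_eff + ss_err) else 0,
         ss_effect = ss_eff, ss_error = ss_err)
  }
  cells <- data.frame(
    noun_condition = rep(c("high", "low"), 2),
    frame_condition = rep(c("typical", "atypical"), each = 2),
    mean = c(m_ab[, "typical"], m_ab[, "atypical"]),
    sem = c(apply(y[, , "typical", drop = FALSE], 2, sd) / sqrt(n),
            apply(y[, , "atypical", drop = FALSE], 2, sd) / sqrt(n)))
  structure(list(noun = eff(SS_A, SS_AS), frame = eff(SS_B, SS_BS),
                 interaction = eff(SS_AB, SS_ABS),
                 n_participants = n, cells = cells),
            class = "lwl_anova")
}

#' @export
print.lwl_anova <- function(x, ...) {
  cat(sprintf("2x2 repeated-measures ANOVA (n = %d)\n", x$n_participants))
  for (nm in c("noun", "frame", "interaction")) {
    e <- x[[nm]]
    cat(sprintf("  %-12s F(%d, %d) = %.3f, p = %.4f, pes = %.3f\n",
                nm, e$df1, e$df2, e$F, e$p, e$pes))
  }
  invisible(x)
}

#' Run the full looking-while-listening analysis
#'
#' Convenience wrapper: per-trial assessment, participant filtering,
#' condition summary, vs-chance tests, and the 2x2 repeated-measures
#' ANOVA.
#'
#' @inheritParams assess_trials
#' @param min_per_cell participant inclusion threshold (default 2 usable
#'   trials per cell).
#' @return list with `trial_results`, `included`, `summary`, `vs_chance`,
#'   `anova`, and `grand_mean` (mean of participant-level cell means).
#' @export
lwl_analysis <- function(timelines, trials, fps = 30, valid = NULL,
                         max_away_run = 15, invalid_as_away = TRUE,
                         min_per_cell = 2) {
  res <- assess_trials(timelines, trials, fps = fps, valid = valid,
                       max_away_run = max_away_run,
                       invalid_as_away = invalid_as_away)
  included <- filter_participants(res, min_per_cell = min_per_cell)
  if (length(included) < 2) stop("fewer than 2 participants pass inclusion")
  use <- res[res$participant %in% included & res$usable, ]
  summ <- condition_summary(use)
  list(trial_results = res,
       included = included,
       summary = summ,
       vs_chance = vs_chance_tests(summ$participant_cell),
       anova = rm_anova_2x2(summ$participant_cell),
       grand_mean = mean(summ$participant_cell$accuracy))
}
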