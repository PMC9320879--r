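test_that("critical window covers 367-2000 ms inclusively and translates", {
  w <- critical_window(0)
  expect_length(w, 49)
  expect_equal(w, 12:60)
  expect_equal(critical_window(100), 12:60 + 100)
  # independent enumeration of offsets whose timestamp is in range
  k <- 0:100
  expect_equal(critical_window(0),
               k[k * (1000 / 30) >= 367 - 1e-9 &
                   k * (1000 / 30) <= 2000 + 1e-9])
})

make_window_labels <- function(per_frame, onset = 0) {
  # build a timeline long enough for the window at `onset`
  labs <- rep("away", onset + 61 + 5)
  labs[critical_window(onset) + 1] <- per_frame
  labs
}

test_that("trial exclusion rules follow the window-start and away-run criteria", {
  trial <- list(target_side = "left", onset_frame = 0)
  # away at the window's first frame -> excluded
  wl <- rep("left", 49)
  wl[1] <- "away"
  res <- assess_trial(make_window_labels(wl), trial)
  expect_false(res$usable)
  expect_equal(res$exclusion_reason, "away_at_start")
  # a run of exactly 15 away frames is tolerated; 16 is not
  wl15 <- c("left", rep("away", 15), rep("left", 33))
  res15 <- assess_trial(make_window_labels(wl15), trial)
  expect_true(res15$usable)
  wl16 <- c("left", rep("away", 16), rep("left", 32))
  res16 <- assess_trial(make_window_labels(wl16), trial)
  expect_false(res16$usable)
  expect_equal(res16$exclusion_reason, "long_away_run")
  # window exceeding the timeline is an error
  expect_error(assess_trial(rep("left", 30), trial), "exceeds timeline")
})

test_that("accuracy is target / (target + distracter), away excluded", {
  trial <- list(target_side = "right", onset_frame = 5)
  wl <- c(rep("right", 30), rep("left", 10), rep("away", 9))
  res <- assess_trial(make_window_labels(wl, onset = 5), trial)
  expect_true(res$usable)
  expect_equal(res$accuracy, 30 / (30 + 10))
  expect_equal(res$n_target, 30)
  expect_equal(res$n_distracter, 10)
  expect_equal(res$n_away, 9)
  # all-on-target window
  res1 <- assess_trial(make_window_labels(rep("right", 49), onset = 5), trial)
  expect_equal(res1$accuracy, 1)
})

test_that("adding away frames never rescues an excluded trial", {
  set.seed(9)
  trial <- list(target_side = "left", onset_frame = 0)
  for (i in 1:50) {
    wl <- sample(c("left", "right", "away"), 49, replace = TRUE,
                 prob = c(.4, .3, .3))
    base <- assess_trial(make_window_labels(wl), trial)
    wl2 <- wl
    idx <- sample(49, 8)
    wl2[idx] <- "away"
    more <- assess_trial(make_window_labels(wl2), trial)
    if (!base$usable) expect_false(more$usable)
  }
})

test_that("invalid frames act as away for exclusion and leave the ratio", {
  trial <- list(target_side = "left", onset_frame = 0)
  labs <- make_window_labels(rep("left", 49))
  valid <- rep(1, length(labs))
  valid[critical_window(0)[1] + 1] <- 0   # first window frame invalid
  res <- assess_trial(labs, trial, valid = valid)
  expect_false(res$usable)
  expect_equal(res$exclusion_reason, "away_at_start")
  # dropped instead when invalid_as_away = FALSE
  res2 <- assess_trial(labs, trial, valid = valid, invalid_as_away = FALSE)
  expect_true(res2$usable)
  expect_equal(res2$n_target, 48)
})

test_that("participants need two usable trials in every cell", {
  mk <- function(pid, noun, frame, usable, n) {
    data.frame(participant = pid, noun_condition = noun,
               frame_condition = frame, usable = usable,
               accuracy = 0.6, stringsAsFactors = FALSE)[rep(1, n), ]
  }
  cells <- expand.grid(noun = c("high", "low"),
                       frame = c("typical", "atypical"),
                       stringsAsFactors = FALSE)
  # exactly 2 usable everywhere -> included
  ok <- do.call(rbind, lapply(seq_len(4), function(i)
    mk("a", cells$noun[i], cells$frame[i], TRUE, 2)))
  expect_equal(filter_participants(ok), "a")
  # 1 usable in one cell, many elsewhere -> excluded
  short <- rbind(mk("b", "high", "typical", TRUE, 1),
                 mk("b", "high", "atypical", TRUE, 8),
                 mk("b", "low", "typical", TRUE, 8),
                 mk("b", "low", "atypical", TRUE, 8))
  expect_length(filter_participants(short), 0)
  # no trials at all -> excluded
  expect_length(filter_participants(ok[0, ]), 0)
  # unusable trials do not count
  unus <- ok
  unus$usable[1] <- FALSE
  expect_length(filter_participants(unus), 0)
})

test_that("condition summary equals a brute-force group-by", {
  set.seed(31)
  res <- expand.grid(participant = paste0("p", 1:6),
                     noun_condition = c("high", "low"),
                     frame_condition = c("typical", "atypical"),
                     rep = 1:3, stringsAsFactors = FALSE)
  res$usable <- TRUE
  res$accuracy <- runif(nrow(res))
  s <- condition_summary(res)
  for (i in seq_len(nrow(s$cells))) {
    cell <- s$cells[i, ]
    pm <- sapply(paste0("p", 1:6), function(p) {
      mean(res$accuracy[res$participant == p &
                          res$noun_condition == cell$noun_condition &
                          res$frame_condition == cell$frame_condition])
    })
    expect_equal(cell$mean, mean(pm))
    expect_equal(cell$sem, sd(pm) / sqrt(6))
  }
  # two participants with cell means 0.6 and 0.8 -> 0.7
  two <- data.frame(participant = c("x", "y"), noun_condition = "high",
                    frame_condition = "typical", usable = TRUE,
                    accuracy = c(0.6, 0.8))
  expect_equal(condition_summary(two)$cells$mean, 0.7)
})

test_that("vs-chance tests equal the closed-form one-sample t", {
  set.seed(17)
  pc <- expand.grid(participant = paste0("p", 1:8),
                    noun_condition = c("high", "low"),
                    frame_condition = c("typical", "atypical"),
                    stringsAsFactors = FALSE)
  pc$accuracy <- runif(nrow(pc), 0.4, 0.9)
  out <- vs_chance_tests(pc)
  for (i in seq_len(nrow(out))) {
    x <- pc$accuracy[pc$noun_condition == out$noun_condition[i] &
                       pc$frame_condition == out$frame_condition[i]]
    tstat <- (mean(x) - 0.5) / (sd(x) / sqrt(length(x)))
    expect_equal(out$t[i], tstat, tolerance = 1e-12)
    expect_equal(out$p[i], 2 * pt(-abs(tstat), length(x) - 1),
                 tolerance = 1e-12)
  }
  # all means exactly at chance -> t = 0, p = 1
  pc0 <- pc
  pc0$accuracy <- 0.5
  out0 <- vs_chance_tests(pc0)
  expect_true(all(out0$t == 0))
  expect_true(all(out0$p == 1))
  # constant but off-chance means are flagged, not an error
  pc6 <- pc
  pc6$accuracy <- 0.6
  out6 <- vs_chance_tests(pc6)
  expect_true(all(out6$degenerate))
  expect_true(all(is.na(out6$t)))
})

ref_anova_aov <- function(pc) {
  pc$participant <- factor(pc$participant)
  pc$noun <- factor(pc$noun_condition)
  pc$frame <- factor(pc$frame_condition)
  fit <- stats::aov(accuracy ~ noun * frame +
                      Error(participant / (noun * frame)), data = pc)
  s <- summary(fit)
  getF <- function(stratum, term) {
    tab <- s[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  c(noun = getF("Error: participant:noun", "noun"),
    frame = getF("Error: participant:frame", "frame"),
    interaction = getF("Error: participant:noun:frame", "noun:frame"))
}

test_that("repeated-measures ANOVA matches the aov error-strata oracle", {
  set.seed(23)
  for (rep in 1:5) {
    n <- sample(c(4, 9, 15), 1)
    pc <- expand.grid(participant = paste0("p", seq_len(n)),
                      noun_condition = c("high", "low"),
                      frame_condition = c("typical", "atypical"),
                      stringsAsFactors = FALSE)
    pc$accuracy <- runif(nrow(pc), 0.3, 0.9)
    mine <- rm_anova_2x2(pc)
    oracle <- ref_anova_aov(pc)
    expect_equal(mine$noun$F, unname(oracle["noun"]), tolerance = 1e-9)
    expect_equal(mine$frame$F, unname(oracle["frame"]), tolerance = 1e-9)
    expect_equal(mine$interaction$F, unname(oracle["interaction"]),
                 tolerance = 1e-9)
    expect_equal(mine$noun$df2, n - 1)
    # F is invariant to adding a constant to every cell
    pc2 <- pc
    pc2$accuracy <- pc2$accuracy + 0.17
    mine2 <- rm_anova_2x2(pc2)
    expect_equal(mine2$noun$F, mine$noun$F, tolerance = 1e-9)
  }
})

test_that("ANOVA agrees with a hand-worked SS decomposition", {
  # 4 participants; noun effect equals a paired t-test on the per-participant
  # noun contrast, computed here independently of the SS code path
  pc <- expand.grid(participant = c("a", "b", "c", "d"),
                    noun_condition = c("high", "low"),
                    frame_condition = c("typical", "atypical"),
                    stringsAsFactors = FALSE)
  set.seed(4)
  pc$accuracy <- round(runif(16, 0.4, 0.9), 2)
  out <- rm_anova_2x2(pc)
  contrast <- sapply(c("a", "b", "c", "d"), function(p) {
    hi <- mean(pc$accuracy[pc$participant == p & pc$noun_condition == "high"])
    lo <- mean(pc$accuracy[pc$participant == p & pc$noun_condition == "low"])
    hi - lo
  })
  tt <- t.test(contrast)
  expect_equal(out$noun$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(out$noun$p, tt$p.value, tolerance = 1e-9)
  # partial eta squared from the paired-t identity: t^2 / (t^2 + df)
  expect_equal(out$noun$pes,
               unname(tt$statistic)^2 / (unname(tt$statistic)^2 + 3),
               tolerance = 1e-9)
  # zero between-cell variation -> all F = 0
  pc0 <- pc
  pc0$accuracy <- rep(sapply(c("a", "b", "c", "d"), function(p) {
    mean(pc$accuracy[pc$participant == p])
  }), 4)
  out0 <- rm_anova_2x2(pc0)
  expect_equal(out0$noun$F, 0)
  expect_equal(out0$frame$F, 0)
  expect_equal(out0$interaction$F, 0)
  # incomplete table names the offender
  expect_error(rm_anova_2x2(pc[-1, ]), "incomplete.*a")
})
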