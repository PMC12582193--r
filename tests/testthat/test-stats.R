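test_that("screening excludes floor/ceiling participants at the documented criterion", {
  log <- generate_dataset(1, n_participants = 2,
                          pop = point_population(conditions = c("Upright", "Inverted", "TempScr", "SpatScr"), jitter = 1),
                          seed = 3)
  # clean dataset: nobody excluded
  scr <- screen_participants(log)
  expect_false(any(scr$report$excluded))
  expect_equal(nrow(scr$clean), nrow(log))

  # an observer whose every reCFS sits at the floor is excluded
  floored <- log
  floored$clamped[floored$participant == 2 & floored$kind == "reCFS"] <- TRUE
  scr2 <- screen_participants(floored)
  expect_true(scr2$report$excluded[scr2$report$participant == 2])
  expect_false(2 %in% scr2$clean$participant)

  # boundary: exactly 10% clamped is retained (strict > criterion)
  exact <- tibble::tibble(
    participant = rep(1:2, each = 40),
    clamped = c(rep(FALSE, 40), rep(c(TRUE, FALSE), c(4, 36)))
  )
  rep3 <- screen_participants(exact)$report
  expect_equal(rep3$frac_clamped[rep3$participant == 2], 0.1)
  expect_false(rep3$excluded[rep3$participant == 2])
  # one more clamped response tips it over
  over <- exact
  over$clamped[41:45] <- TRUE
  expect_true(screen_participants(over)$report$excluded[2])

  expect_error(screen_participants(log[0, ]), "empty")
})

test_that("aggregation recovers planted thresholds and is order-invariant", {
  obs <- det_observer(bcfs = -10, depth = 14)
  res <- run_session(obs, design = experiment_design(1), seed = 2)
  log <- session_log(res)
  agg <- aggregate_thresholds(log)
  step <- engine_config()$step_db_per_frame
  expect_true(all(abs(agg$mean_bcfs_db - (-10)) <= step))
  expect_true(all(abs(agg$mean_recfs_db - (-24)) <= step))
  expect_true(all(abs(agg$depth_db - 14) <= 2 * step))
  expect_equal(agg$depth_db, agg$mean_bcfs_db - agg$mean_recfs_db)
  expect_true(all(agg$n_bcfs == 48)) # 6 per trial x 8 trials
  # permutation invariance
  shuffled <- log[sample(nrow(log)), ]
  expect_equal(aggregate_thresholds(shuffled), agg)
  # missing kind is named
  broken <- log[!(log$condition == "Upright" & log$kind == "bCFS"), ]
  expect_error(aggregate_thresholds(broken), "Upright")
})

test_that("group means at the planted grand levels imply the printed depth", {
  # two planted grand levels 13.4 dB apart must aggregate to that depth
  pop <- point_population(bcfs = -10.4, depth = 13.4,
                          conditions = c("Upright", "Inverted", "TempScr", "SpatScr"),
                          jitter = 0)
  log <- generate_dataset(1, n_participants = 2, pop = pop, seed = 5)
  agg <- aggregate_thresholds(log)
  expect_equal(mean(agg$mean_bcfs_db), -10.4, tolerance = 0.01)
  expect_equal(mean(agg$mean_recfs_db), -23.8, tolerance = 0.01)
  expect_equal(mean(agg$depth_db), 13.4, tolerance = 0.02)
})

test_that("within-participant SEM removes subject offsets", {
  # data differing only by per-participant shifts: corrected SEM is zero
  base <- c(10, 12, 14)
  df <- expand.grid(participant = 1:5, condition = c("a", "b", "c"))
  df$depth_db <- base[as.integer(df$condition)] + df$participant * 2
  sem <- within_subject_sem(df, "depth_db")
  expect_true(all(abs(sem$sem_ws) < 1e-10))

  # hand-computed 3-participant x 2-condition toy table
  toy <- data.frame(
    participant = rep(1:3, 2),
    condition = rep(c("x", "y"), each = 3),
    depth_db = c(1, 4, 7, 3, 5, 6)
  )
  grand <- mean(toy$depth_db)
  pm <- tapply(toy$depth_db, toy$participant, mean)
  centred <- toy$depth_db - pm[toy$participant] + grand
  manual <- tapply(centred, toy$condition, sd) / sqrt(3) * sqrt(2 / 1)
  sem2 <- within_subject_sem(toy, "depth_db")
  expect_equal(sem2$sem_ws, as.vector(manual[sem2$condition]))

  expect_error(within_subject_sem(toy[toy$condition == "x", ], "depth_db"),
               "single condition")
})

test_that("corrected SEM is below the raw SEM when subject variance dominates", {
  smaller <- vapply(1:50, function(s) {
    df <- expand.grid(participant = 1:10, condition = c("a", "b", "c", "d"))
    subj <- rnorm(10, sd = 5)
    set.seed(s)
    df$y <- subj[df$participant] + rnorm(nrow(df), sd = 0.5)
    sem <- within_subject_sem(df, "y")
    raw <- tapply(df$y, df$condition, function(x) sd(x) / sqrt(length(x)))
    mean(sem$sem_ws) < mean(raw)
  }, TRUE)
  expect_gt(mean(smaller), 0.9)
})

test_that("rm_anova matches aov on multi-factor within designs", {
  set.seed(42)
  d <- expand.grid(participant = factor(1:8), kind = c("bCFS", "reCFS"),
                   mask = c("low", "med", "high"), orient = c("up", "inv"))
  d$value <- rnorm(nrow(d)) + as.numeric(d$mask) + rep(rnorm(8), 12)
  mine <- rm_anova(d, dv = "value", within = c("kind", "mask", "orient"))
  fit <- summary(aov(value ~ kind * mask * orient +
                       Error(participant / (kind * mask * orient)), data = d))
  for (i in seq_len(nrow(mine))) {
    stratum <- fit[[paste0("Error: participant:", gsub(":", ":", mine$effect[i]))]]
    tab <- stratum[[1]]
    expect_equal(mine$F[i], tab$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$p[i], tab$`Pr(>F)`[1], tolerance = 1e-10)
    expect_equal(mine$df_num[i], tab$Df[1])
    expect_equal(mine$df_den[i], tab$Df[2])
    expect_equal(mine$ss[i], tab$`Sum Sq`[1], tolerance = 1e-10)
    expect_equal(mine$ss_error[i], tab$`Sum Sq`[2], tolerance = 1e-10)
  }
})

test_that("two-level factors reduce to the squared paired t", {
  set.seed(1)
  wide <- data.frame(a = rnorm(9, 10), b = rnorm(9, 11))
  long <- data.frame(
    participant = rep(1:9, 2),
    condition = rep(c("a", "b"), each = 9),
    value = c(wide$a, wide$b)
  )
  res <- rm_anova(long, dv = "value", within = "condition")
  tt <- t.test(wide$a, wide$b, paired = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  expect_equal(res$df_num, 1)
  expect_equal(res$df_den, 8)
})

test_that("rm_anova limiting cases and design validation", {
  # no condition differences: SS_effect = 0, F = 0
  d <- expand.grid(participant = 1:6, condition = c("a", "b", "c"))
  d$value <- rep(c(1, 2, 3, 4, 5, 6), 3)
  res <- rm_anova(d, dv = "value", within = "condition")
  expect_equal(res$ss, 0)
  expect_equal(res$F, 0)
  # deterministic separation: eta_p^2 = 1
  d2 <- d
  d2$value <- as.numeric(factor(d2$condition))
  res2 <- rm_anova(d2, dv = "value", within = "condition")
  expect_equal(res2$partial_eta_sq, 1)
  # unbalanced designs are rejected
  expect_error(rm_anova(d[-1, ], dv = "value", within = "condition"),
               "balanced")
})

test_that("post hoc pairwise tests match first-principles computation", {
  set.seed(3)
  df <- expand.grid(participant = 1:12, condition = c("w", "x", "y", "z"))
  df$depth_db <- rnorm(nrow(df), mean = as.numeric(df$condition))
  res <- posthoc_pairwise(df, dv = "depth_db", within = "condition")
  expect_equal(nrow(res), 6) # C(4,2)
  expect_true(all(res$n_comparisons == 6))
  wide <- tapply(df$depth_db, list(df$participant, df$condition), mean)
  pr <- c("w", "x")
  diffs <- wide[, "w"] - wide[, "x"]
  t_manual <- mean(diffs) / (sd(diffs) / sqrt(12))
  p_manual <- 2 * pt(abs(t_manual), 11, lower.tail = FALSE)
  d_manual <- mean(diffs) / ((sd(wide[, "w"]) + sd(wide[, "x"])) / 2)
  row <- res[res$pair == "w - x", ]
  expect_equal(row$t, t_manual, tolerance = 1e-12)
  expect_equal(row$p_bonferroni, min(1, p_manual * 6), tolerance = 1e-12)
  expect_equal(row$cohens_d, d_manual, tolerance = 1e-12)
  # identical vectors: t = 0, p_bonf = 1, d = 0
  df0 <- df
  df0$depth_db <- rep(rnorm(12), 4)
  res0 <- posthoc_pairwise(df0, dv = "depth_db", within = "condition")
  expect_true(all(res0$t == 0))
  expect_true(all(res0$p_bonferroni == 1))
  expect_true(all(res0$cohens_d == 0))
  # d_z variant
  resz <- posthoc_pairwise(df, dv = "depth_db", within = "condition", d_type = "z")
  expect_equal(resz$cohens_d[resz$pair == "w - x"],
               mean(diffs) / sd(diffs), tolerance = 1e-12)
  expect_error(posthoc_pairwise(df[df$condition == "w", ], dv = "depth_db",
                                within = "condition"), "two conditions")
})

test_that("recovered depth is invariant to shifting both planted levels", {
  # mask-contrast analogue: adding a constant to bCFS and reCFS together
  # moves thresholds in tandem but conserves depth
  mk <- function(shift) {
    pop <- point_population(bcfs = -10.4 + shift, depth = 13.0,
                            conditions = c("Upright", "Inverted", "TempScr", "SpatScr"),
                            jitter = 0.5)
    log <- generate_dataset(1, n_participants = 3, pop = pop, seed = 77)
    mean(aggregate_thresholds(log)$depth_db)
  }
  d0 <- mk(0)
  d2 <- mk(-2)
  expect_equal(d0, d2, tolerance = 0.01)
  expect_equal(d0, 13.0 + 0.07, tolerance = 0.1) # + half-step quantisation x2
})

test_that("report output is deterministic and consistent with aggregation", {
  log <- generate_dataset(1, n_participants = 3, seed = 8)
  res <- analyze_tcfs(log)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  report_tcfs(log, res, dir1, figures = FALSE)
  report_tcfs(log, res, dir2, figures = FALSE)
  for (f in c("summaries.csv", "anova_depth.csv", "depth_panel.csv", "trace_panel.csv")) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
  }
  depth_panel <- read.csv(file.path(dir1, "depth_panel.csv"))
  agg_means <- tapply(res$summaries$depth_db, res$summaries$condition, mean)
  expect_equal(depth_panel$mean_depth_db,
               as.vector(agg_means[depth_panel$condition]), tolerance = 1e-12)
  trace <- read.csv(file.path(dir1, "trace_panel.csv"))
  first <- trace[trace$response_index == 0, ]
  expect_true(all(first$mean_db == 0)) # trials start at 0 dB
})
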