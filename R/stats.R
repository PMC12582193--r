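# Analysis pipeline: participant screening, threshold aggregation,
# suppression depth, within-participant error bars, fully within-subject
# repeated-measures ANOVA with partial eta squared, and Bonferroni-corrected
# pairwise post hocs with Cohen's d.

#' Screen participants for floor/ceiling effects
#'
#' Excludes participants whose fraction of clamp-bound responses (responses
#' recorded while the contrast ramp was pinned at the floor or ceiling)
#' exceeds `max_clamped_frac`. The comparison is strict (`>`), so a
#' participant sitting exactly at the criterion is retained.
#'
#' @param log tidy trial log (the [session_log()] schema, with a `clamped`
#'   column).
#' @param max_clamped_frac exclusion criterion (default 0.10).
#' @return a list with `clean` (the retained rows) and `report` (a tibble
#'   with `participant`, `n_responses`, `frac_clamped`, `excluded`).
#' @export
screen_participants <- function(log, max_clamped_frac = 0.1) {
  if (is.null(log) || nrow(log) == 0) stop("empty trial log")
  rep_tbl <- log |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      n_responses = dplyr::n(),
      frac_clamped = mean(.data$clamped),
      .groups = "drop"
    ) |>
    dplyr::mutate(excluded = .data$frac_clamped > max_clamped_frac)
  keep <- rep_tbl$participant[!rep_tbl$excluded]
  list(
    clean = dplyr::filter(log, .data$participant %in% keep),
    report = rep_tbl
  )
}

#' Aggregate thresholds per participant and condition
#'
#' Averages the bCFS and reCFS responses within each participant-by-
#' condition cell and computes suppression depth as their difference in
#' decibels.
#'
#' @param log screened tidy trial log.
#' @return a tibble of condition summaries: `participant`, `condition`,
#'   `mean_bcfs_db`, `mean_recfs_db`, `depth_db`, `n_bcfs`, `n_recfs`.
#' @export
aggregate_thresholds <- function(log) {
  if (is.null(log) || nrow(log) == 0) stop("empty trial log")
  out <- log |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::summarise(
      mean_bcfs_db = mean(.data$contrast_db[.data$kind == "bCFS"]),
      mean_recfs_db = mean(.data$contrast_db[.data$kind == "reCFS"]),
      n_bcfs = sum(.data$kind == "bCFS"),
      n_recfs = sum(.data$kind == "reCFS"),
      .groups = "drop"
    )
  bad <- out$n_bcfs == 0 | out$n_recfs == 0
  if (any(bad)) {
    cell <- out[which(bad)[1], ]
    stop(sprintf("missing %s responses for participant %s, condition %s",
                 if (cell$n_bcfs == 0) "bCFS" else "reCFS",
                 cell$participant, cell$condition))
  }
  dplyr::mutate(out, depth_db = .data$mean_bcfs_db - .data$mean_recfs_db) |>
    dplyr::select("participant", "condition", "mean_bcfs_db",
                  "mean_recfs_db", "depth_db", "n_bcfs", "n_recfs")
}

#' Reshape condition summaries to one row per threshold kind
#'
#' Convenience pivot for the two-way (threshold kind x condition) ANOVA.
#'
#' @param summaries output of [aggregate_thresholds()].
#' @return a tibble with `participant`, `condition`, `kind`
#'   (`"bCFS"`/`"reCFS"`) and `value` (mean threshold in dB).
#' @export
thresholds_long <- function(summaries) {
  dplyr::bind_rows(
    dplyr::transmute(summaries, participant = .data$participant,
                     condition = .data$condition, kind = "bCFS",
                     value = .data$mean_bcfs_db),
    dplyr::transmute(summaries, participant = .data$participant,
                     condition = .data$condition, kind = "reCFS",
                     value = .data$mean_recfs_db)
  )
}

#' Within-participant corrected SEM per condition
#'
#' Subject-centres the repeated measures (subtract each participant's mean
#' across conditions, add back the grand mean) and applies the
#' `sqrt(J / (J - 1))` small-sample correction for `J` conditions, so error
#' bars reflect within-subject variability only.
#'
#' @param summaries output of [aggregate_thresholds()] (complete
#'   participant x condition grid).
#' @param measure column to summarise (default `"depth_db"`).
#' @return a tibble with `condition`, `mean`, `sem_ws`, `n`.
#' @export
within_subject_sem <- function(summaries, measure = "depth_db") {
  J <- length(unique(summaries$condition))
  if (J < 2) stop("within-participant correction undefined for a single condition")
  tab <- table(summaries$participant, summaries$condition)
  if (any(tab != 1)) stop("summaries must contain exactly one row per participant x condition")
  grand <- mean(summaries[[measure]])
  centred <- summaries |>
    dplyr::group_by(.data$participant) |>
    dplyr::mutate(.y = .data[[measure]] - mean(.data[[measure]]) + grand) |>
    dplyr::ungroup()
  centred |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      mean = mean(.data[[measure]]),
      sem_ws = stats::sd(.data$.y) / sqrt(dplyr::n()) * sqrt(J / (J - 1)),
      n = dplyr::n(),
      .groups = "drop"
    )
}

# ---- repeated-measures ANOVA ------------------------------------------------

# All effects of a balanced, fully crossed, fully within-subject design are
# computed by the classical sums-of-squares decomposition: for any term T
# (a subset of the experimental factors, or such a subset plus the subject
# factor), the effect estimate at each marginal cell is the marginal mean
# minus all lower-order effect estimates, and
# SS_T = (N / #cells_T) * sum(effect^2). The error term for an
# experimental effect T is its interaction with subjects, giving the
# uncorrected (sphericity-assumed) univariate F tests.
subset_key <- function(s) paste(sort(s), collapse = "*")

# Per-observation effect estimates: eff(T) at an observation is the mean of
# the dv over that observation's marginal cell of T, minus the grand mean
# and all lower-order effects. Summing eff(T)^2 over observations gives
# SS_T directly, since each marginal cell is replicated N / #cells times.
rm_anova_effects <- function(df, dv, factors) {
  memo <- new.env(parent = emptyenv())
  grand <- mean(df[[dv]])
  eff <- function(term) {
    key <- subset_key(term)
    if (!is.null(memo[[key]])) return(memo[[key]])
    idx <- interaction(df[term], drop = TRUE)
    vals <- stats::ave(df[[dv]], idx) - grand
    if (length(term) > 1) {
      for (size in seq_len(length(term) - 1)) {
        for (s in utils::combn(term, size, simplify = FALSE)) {
          vals <- vals - eff(s)
        }
      }
    }
    memo[[key]] <- vals
    vals
  }
  list(eff = eff, grand = grand)
}

#' Repeated-measures ANOVA (fully within-subject, balanced)
#'
#' Classical univariate sums-of-squares decomposition for designs in which
#' every factor is within-subject, with one observation per participant per
#' cell. Each effect is tested against its interaction with participants;
#' degrees of freedom are the uncorrected (sphericity-assumed) products of
#' `(levels - 1)`. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data long-format data frame.
#' @param dv name of the dependent-variable column.
#' @param within character vector of within-subject factor column names.
#' @param subject name of the participant identifier column.
#' @return a tibble of class `anova_result` with one row per effect:
#'   `effect`, `df_num`, `df_den`, `ss`, `ss_error`, `F`, `p`,
#'   `partial_eta_sq`.
#' @export
rm_anova <- function(data, dv = "value", within, subject = "participant") {
  df <- as.data.frame(data)
  for (f in c(within, subject)) df[[f]] <- factor(df[[f]])
  cells <- interaction(df[c(subject, within)], drop = FALSE)
  counts <- table(cells)
  if (any(counts != 1)) {
    stop("design must be balanced with exactly one observation per participant per cell")
  }
  if (anyNA(df[[dv]])) stop("missing values in the dependent variable")
  N <- nrow(df)
  helper <- rm_anova_effects(df, dv, c(within, subject))
  n_levels <- vapply(df[c(within, subject)], nlevels, integer(1))
  ss_of <- function(term) sum(helper$eff(term)^2)
  df_of <- function(term) prod(n_levels[term] - 1L)
  rows <- list()
  for (size in seq_along(within)) {
    for (term in utils::combn(within, size, simplify = FALSE)) {
      err_term <- c(term, subject)
      ss_e <- ss_of(term)
      ss_err <- ss_of(err_term)
      df_n <- df_of(term)
      df_d <- df_of(err_term)
      Fv <- if (ss_err == 0) {
        if (ss_e == 0) 0 else Inf
      } else {
        (ss_e / df_n) / (ss_err / df_d)
      }
      pv <- if (is.infinite(Fv)) 0 else stats::pf(Fv, df_n, df_d, lower.tail = FALSE)
      rows[[length(rows) + 1]] <- tibble::tibble(
        effect = paste(term, collapse = ":"),
        df_num = df_n, df_den = df_d,
        ss = ss_e, ss_error = ss_err,
        F = Fv, p = pv,
        partial_eta_sq = if (ss_e + ss_err == 0) 0 else ss_e / (ss_e + ss_err)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("anova_result", class(out))
  attr(out, "design") <- stats::setNames(as.integer(n_levels), c(within, subject))
  out
}

#' Pairwise post hoc comparisons with Bonferroni correction
#'
#' Paired t-tests between all level pairs of a single within-subject
#' factor. Raw p-values are multiplied by the number of comparisons and
#' capped at 1. Cohen's d defaults to the average-SD variant
#' `d_av = mean(diff) / ((sd_1 + sd_2) / 2)`; `d_type = "z"` gives
#' `d_z = mean(diff) / sd(diff)`. The sign follows the level-pair order
#' (first minus second).
#'
#' @param data long-format data frame.
#' @param dv dependent-variable column name.
#' @param within the (single) within-subject factor column name.
#' @param subject participant identifier column name.
#' @param d_type `"av"` or `"z"`.
#' @return a tibble with `pair`, `level_1`, `level_2`, `mean_diff`, `t`,
#'   `df`, `p_raw`, `p_bonferroni`, `cohens_d`, `d_type`, `n_comparisons`.
#' @export
posthoc_pairwise <- function(data, dv = "value", within, subject = "participant",
                             d_type = c("av", "z")) {
  d_type <- match.arg(d_type)
  df <- as.data.frame(data)
  levs <- unique(as.character(df[[within]]))
  if (length(levs) < 2) stop("need at least two conditions for post hoc comparisons")
  wide <- tapply(df[[dv]], list(df[[subject]], df[[within]]), mean)
  if (nrow(wide) < 2) stop("need at least two participants for paired comparisons")
  if (anyNA(wide)) stop("incomplete participant x condition grid")
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    x <- wide[, pr[1]]; y <- wide[, pr[2]]
    diffs <- x - y
    n <- length(diffs)
    se <- stats::sd(diffs) / sqrt(n)
    tval <- if (se == 0) 0 else mean(diffs) / se
    p_raw <- if (se == 0 && mean(diffs) == 0) 1 else
      2 * stats::pt(abs(tval), n - 1, lower.tail = FALSE)
    d <- if (d_type == "av") {
      denom <- (stats::sd(x) + stats::sd(y)) / 2
      if (denom == 0) 0 else mean(diffs) / denom
    } else {
      if (stats::sd(diffs) == 0) 0 else mean(diffs) / stats::sd(diffs)
    }
    tibble::tibble(
      pair = paste(pr[1], "-", pr[2]), level_1 = pr[1], level_2 = pr[2],
      mean_diff = mean(diffs), t = tval, df = n - 1,
      p_raw = p_raw, p_bonferroni = min(1, p_raw * m),
      cohens_d = d, d_type = d_type, n_comparisons = m
    )
  })
  dplyr::bind_rows(rows)
}

#' Full analysis of a trial log
#'
#' Runs the complete pipeline on a tidy trial log: screening, aggregation,
#' the two-way (threshold kind x condition) ANOVA, the one-way ANOVA on
#' suppression depth, depth post hocs, and within-participant error bars.
#'
#' @param log tidy trial log.
#' @param max_clamped_frac screening criterion.
#' @return a list with `screening`, `summaries`, `anova_thresholds`,
#'   `anova_depth`, `posthoc_depth`, `sem_depth`, `condition_means`,
#'   `grand_means`.
#' @export
analyze_tcfs <- function(log, max_clamped_frac = 0.1) {
  scr <- screen_participants(log, max_clamped_frac)
  summaries <- aggregate_thresholds(scr$clean)
  long <- thresholds_long(summaries)
  list(
    screening = scr$report,
    summaries = summaries,
    anova_thresholds = rm_anova(long, dv = "value",
                                within = c("kind", "condition")),
    anova_depth = rm_anova(summaries, dv = "depth_db", within = "condition"),
    posthoc_depth = posthoc_pairwise(summaries, dv = "depth_db",
                                     within = "condition"),
    sem_depth = within_subject_sem(summaries, "depth_db"),
    condition_means = summaries |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(
        mean_bcfs_db = mean(.data$mean_bcfs_db),
        mean_recfs_db = mean(.data$mean_recfs_db),
        mean_depth_db = mean(.data$depth_db),
        sd_depth_db = stats::sd(.data$depth_db),
        .groups = "drop"
      ),
    grand_means = tibble::tibble(
      bcfs_db = mean(summaries$mean_bcfs_db),
      recfs_db = mean(summaries$mean_recfs_db),
      depth_db = mean(summaries$depth_db)
    )
  )
}
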