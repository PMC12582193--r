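# Synthetic observers. An observer is defined directly in measurement
# space: a planted breakthrough (bCFS) level, a planted suppression depth
# (so the re-suppression level is bcfs - depth), per-reversal Gaussian
# threshold jitter, an optional lapse probability and an optional reaction
# delay in frames. A population adds participant-level random intercepts
# (shared across conditions within a participant) and per-condition effects
# on both the bCFS level and the depth.

#' Synthetic observer parameters
#'
#' @param bcfs_mean_db planted breakthrough threshold in dB.
#' @param depth_db planted suppression depth in dB (>= 0); the planted
#'   re-suppression level is `bcfs_mean_db - depth_db`.
#' @param jitter_sd_db SD of the fresh Gaussian threshold draw made at
#'   every reversal.
#' @param lapse_prob per-reversal probability of a mistimed response at a
#'   uniformly random point of the ramp.
#' @param delay_frames reaction delay in frames; the ramp keeps moving
#'   during the delay, biasing measured depth upward by
#'   `2 * delay_frames * step` per cycle.
#' @return a list of class `tcfs_observer`.
#' @export
observer_params <- function(bcfs_mean_db = -10.4, depth_db = 13.4,
                            jitter_sd_db = 1, lapse_prob = 0,
                            delay_frames = 0) {
  if (depth_db < 0) stop("`depth_db` must be non-negative")
  if (lapse_prob < 0 || lapse_prob >= 0.5) stop("`lapse_prob` must be in [0, 0.5)")
  if (jitter_sd_db < 0) stop("`jitter_sd_db` must be non-negative")
  if (delay_frames < 0) stop("`delay_frames` must be non-negative")
  structure(
    list(bcfs_mean_db = bcfs_mean_db, depth_db = depth_db,
         jitter_sd_db = jitter_sd_db, lapse_prob = lapse_prob,
         delay_frames = as.integer(delay_frames)),
    class = "tcfs_observer"
  )
}

#' Observer response predicate
#'
#' The frame-level response rule used by the reference engine: on a
#' downward ramp the observer responds once contrast has reached or passed
#' its current threshold draw and `delay_frames` further frames have
#' elapsed; upward ramps are symmetric.
#'
#' @param obs an [observer_params()] object.
#' @param contrast_db current target contrast in dB.
#' @param direction `"down"` or `"up"`.
#' @param threshold_db the active threshold draw for this reversal.
#' @param frames_since_crossing frames elapsed since the threshold was
#'   first reached (`NA` if not yet crossed).
#' @return logical: respond at this frame?
#' @export
observer_respond <- function(obs, contrast_db, direction = c("down", "up"),
                             threshold_db, frames_since_crossing = 0) {
  direction <- match.arg(direction)
  crossed <- if (direction == "down") contrast_db <= threshold_db + 1e-12
             else contrast_db >= threshold_db - 1e-12
  isTRUE(crossed) && !is.na(frames_since_crossing) &&
    frames_since_crossing >= obs$delay_frames
}

#' Population parameters
#'
#' Defines the hierarchical structure of a simulated participant sample:
#' per-condition planted `(bcfs_db, depth_db)` pairs, between-participant
#' SDs of the bCFS and depth intercepts, and the shared jitter / lapse /
#' delay settings.
#'
#' With `empirical = TRUE` (the default) the sampled participant
#' intercepts are standardised so that their sample mean is exactly 0 and
#' their sample SD exactly equals the population SD; condition means of
#' the planted levels then coincide with the population values, which
#' separates the measurement machinery's recovery error from finite-sample
#' intercept noise in parameter-recovery runs.
#'
#' @param conditions named list: each element a list with `bcfs_db` and
#'   `depth_db` for one condition.
#' @param sd_bcfs_db between-participant SD of the bCFS intercept.
#' @param sd_depth_db between-participant SD of the depth intercept.
#' @param jitter_sd_db,lapse_prob,delay_frames passed to every observer.
#' @param empirical use exact-moment (mean/SD-matching) intercept sampling.
#' @return a list of class `tcfs_population`.
#' @export
population_params <- function(conditions, sd_bcfs_db = 3, sd_depth_db = 1.5,
                              jitter_sd_db = 1, lapse_prob = 0,
                              delay_frames = 0, empirical = TRUE) {
  if (!length(conditions) || is.null(names(conditions))) {
    stop("`conditions` must be a named list")
  }
  ok <- vapply(conditions, function(x) {
    all(c("bcfs_db", "depth_db") %in% names(x)) && x$depth_db >= 0
  }, logical(1))
  if (!all(ok)) stop("every condition needs `bcfs_db` and a non-negative `depth_db`")
  if (sd_bcfs_db < 0 || sd_depth_db < 0) stop("population SDs must be non-negative")
  structure(
    list(conditions = conditions, sd_bcfs_db = sd_bcfs_db,
         sd_depth_db = sd_depth_db, jitter_sd_db = jitter_sd_db,
         lapse_prob = lapse_prob, delay_frames = as.integer(delay_frames),
         empirical = empirical),
    class = "tcfs_population"
  )
}

#' Load a shipped population preset
#'
#' Presets `exp1.json`, `exp2.json`, `exp3.json` under
#' `extdata/populations/` plant the group-level condition means of the
#' three experiment layouts and ship as editable JSON.
#'
#' @param experiment 1, 2 or 3, or a path to a preset JSON file.
#' @return a [population_params()] object.
#' @export
load_population_preset <- function(experiment) {
  path <- if (is.character(experiment) && file.exists(experiment)) {
    experiment
  } else {
    system.file("extdata", "populations",
                sprintf("exp%s.json", experiment), package = "tcfsim",
                mustWork = TRUE)
  }
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  population_params(
    conditions = js$conditions,
    sd_bcfs_db = js$sd_bcfs_db, sd_depth_db = js$sd_depth_db,
    jitter_sd_db = js$jitter_sd_db %||% 1,
    lapse_prob = js$lapse_prob %||% 0,
    delay_frames = js$delay_frames %||% 0,
    empirical = js$empirical %||% TRUE
  )
}

# standardise draws to exact mean 0 / SD `s`
exact_moments <- function(x, s) {
  if (length(x) == 1 || s == 0) return(rep(0, length(x)))
  x <- x - mean(x)
  sx <- stats::sd(x)
  if (sx < 1e-12) return(rep(0, length(x)))
  x / sx * s
}

#' Sample participant-level intercepts
#'
#' @param pop a [population_params()] object.
#' @param n number of participants.
#' @param seed integer seed.
#' @return a tibble with `participant`, `intercept_bcfs_db`,
#'   `intercept_depth_db`.
#' @export
sample_population <- function(pop, n, seed = 1) {
  stopifnot(inherits(pop, "tcfs_population"), n >= 1)
  with_seed(seed, {
    ib <- rnorm(n, 0, pop$sd_bcfs_db)
    id <- rnorm(n, 0, pop$sd_depth_db)
    if (pop$empirical) {
      ib <- exact_moments(ib, pop$sd_bcfs_db)
      id <- exact_moments(id, pop$sd_depth_db)
    }
    tibble::tibble(participant = seq_len(n),
                   intercept_bcfs_db = ib, intercept_depth_db = id)
  })
}

#' Sample one observer from a population
#'
#' Participant intercepts are drawn from a seed derived from
#' `(seed, participant_id)` only, so the same participant shares its
#' intercepts across conditions, and the same `(seed, participant,
#' condition)` triple always yields the identical observer. (Single-draw
#' sampling cannot apply the population's exact-moment centring, which is
#' a whole-sample operation; see [generate_dataset()].)
#'
#' @param pop a [population_params()] object.
#' @param participant_id integer id.
#' @param condition condition name (must exist in `pop$conditions`).
#' @param seed population seed.
#' @return an [observer_params()] object.
#' @export
sample_observer <- function(pop, participant_id, condition, seed = 1) {
  eff <- pop$conditions[[condition]]
  if (is.null(eff)) stop("unknown condition: ", condition)
  ints <- with_seed(derive_seed(seed, participant_id), {
    c(rnorm(1, 0, pop$sd_bcfs_db), rnorm(1, 0, pop$sd_depth_db))
  })
  observer_params(
    bcfs_mean_db = eff$bcfs_db + ints[1],
    depth_db = max(0, eff$depth_db + ints[2]),
    jitter_sd_db = pop$jitter_sd_db,
    lapse_prob = pop$lapse_prob,
    delay_frames = pop$delay_frames
  )
}

#' Simulate a full multi-participant threshold dataset
#'
#' Samples a participant population, builds each participant's
#' per-condition observers (participant intercepts shared across
#' conditions, plus the population's condition effects), runs every
#' participant through [run_session()] under the experiment's
#' trial-by-block design, and returns the combined tidy trial log.
#'
#' @param experiment 1, 2 or 3 (selects design and default population).
#' @param n_participants number of simulated participants (defaults to the
#'   experiment's sample size).
#' @param pop a [population_params()]; defaults to the experiment preset.
#' @param cfg an [engine_config()].
#' @param seed master seed; everything downstream derives from it.
#' @return a tidy tibble in the [session_log()] schema, one row per
#'   threshold response
#'   (`participants x blocks x trials_per_block x responses_per_trial`
#'   rows).
#' @export
generate_dataset <- function(experiment = 1, n_participants = NULL,
                             pop = NULL, cfg = engine_config(), seed = 1) {
  design <- experiment_design(experiment)
  if (is.null(pop)) pop <- load_population_preset(experiment)
  missing_conds <- setdiff(design$conditions, names(pop$conditions))
  if (length(missing_conds)) {
    stop("population lacks conditions: ", paste(missing_conds, collapse = ", "))
  }
  n <- n_participants %||% design$n_participants_default
  ints <- sample_population(pop, n, seed = derive_seed(seed, 1))
  logs <- vector("list", n)
  for (p in seq_len(n)) {
    observers <- lapply(design$conditions, function(cond) {
      eff <- pop$conditions[[cond]]
      observer_params(
        bcfs_mean_db = eff$bcfs_db + ints$intercept_bcfs_db[p],
        depth_db = max(0, eff$depth_db + ints$intercept_depth_db[p]),
        jitter_sd_db = pop$jitter_sd_db,
        lapse_prob = pop$lapse_prob,
        delay_frames = pop$delay_frames
      )
    })
    names(observers) <- design$conditions
    res <- run_session(observers, design = design, cfg = cfg,
                       seed = derive_seed(seed, 2, p))
    logs[[p]] <- session_log(res, participant = p,
                             experiment = design$experiment)
  }
  out <- dplyr::bind_rows(logs)
  attr(out, "planted") <- list(population = pop, intercepts = ints,
                               design = design, seed = seed)
  out
}
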