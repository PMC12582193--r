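# The tCFS trial state machine. A trial starts with the target at maximum
# contrast (0 dB) ramping DOWN; the observer's first response marks a
# re-suppression (reCFS) threshold and flips the ramp direction, the next
# response marks a breakthrough (bCFS) threshold, and so on, alternating
# until `responses_per_trial` responses have been collected. Contrast moves
# in fixed decibel steps per frame (perceptually linearised ramping) and is
# clamped to [floor, ceiling]; frames at a clamp bound are flagged so the
# screening stage can detect floor/ceiling observers.

#' Convert contrast between linear and decibel units
#'
#' Contrast is expressed on a normalised 0-1 linear scale with
#' `to_db(c) = 20 * log10(c)`, so full contrast (1.0) is 0 dB and the
#' minimum coded target contrast 0.02 is -33.98 dB.
#'
#' @param c linear contrast in `(0, 1]`.
#' @param db contrast in decibels.
#' @return `to_db` returns decibels; `from_db` returns linear contrast.
#' @export
to_db <- function(c) {
  if (any(c <= 0)) stop("linear contrast must be positive")
  20 * log10(c)
}

#' @rdname to_db
#' @export
from_db <- function(db) 10^(db / 20)

#' Engine configuration
#'
#' Defaults follow the standard tCFS setup: 60 Hz display, contrast steps
#' of 0.07 dB per frame (4.2 dB/s), target contrast clamped between
#' -33.98 dB (linear 0.02) and 0 dB (linear 1.0), 12 responses per trial
#' (6 reCFS + 6 bCFS), and the target placed 5 degrees left or right of
#' fixation, alternating between trials.
#'
#' @param frame_rate_hz display frame rate.
#' @param step_db_per_frame contrast step magnitude in dB per frame.
#' @param contrast_floor_db lower contrast clamp in dB.
#' @param contrast_ceiling_db upper contrast clamp in dB.
#' @param responses_per_trial responses collected per trial (even, so
#'   reCFS/bCFS counts pair up).
#' @param target_offset_deg eccentricity of the target centre.
#' @param max_trial_frames watchdog budget: a trial exceeding this many
#'   frames aborts with an error.
#' @return a list of class `engine_config`.
#' @export
engine_config <- function(frame_rate_hz = 60, step_db_per_frame = 0.07,
                          contrast_floor_db = 20 * log10(0.02),
                          contrast_ceiling_db = 0,
                          responses_per_trial = 12,
                          target_offset_deg = 5,
                          max_trial_frames = 200000) {
  if (contrast_floor_db >= contrast_ceiling_db) stop("floor must be below ceiling")
  if (step_db_per_frame <= 0) stop("`step_db_per_frame` must be positive")
  if (responses_per_trial %% 2 != 0) stop("`responses_per_trial` must be even")
  structure(
    list(
      frame_rate_hz = frame_rate_hz,
      step_db_per_frame = step_db_per_frame,
      contrast_floor_db = contrast_floor_db,
      contrast_ceiling_db = contrast_ceiling_db,
      responses_per_trial = as.integer(responses_per_trial),
      target_offset_deg = target_offset_deg,
      max_trial_frames = max_trial_frames
    ),
    class = "engine_config"
  )
}

#' Experiment designs
#'
#' The three shipped trial-by-block layouts:
#' * Experiment 1 — 4 trials x 8 blocks: Upright, Inverted, TempScr,
#'   SpatScr biological motion.
#' * Experiment 2 — 6 trials x 8 blocks: low/medium/high mask RMS contrast
#'   (0.07 / 0.10 / 0.13) crossed with upright/inverted biomotion.
#' * Experiment 3 — 5 trials x 8 blocks: FastBM, NormalBM, Static,
#'   CoherOF, TempOF.
#'
#' @param experiment 1, 2 or 3.
#' @return a list with `conditions`, `blocks`, `n_participants_default`,
#'   and for experiment 2 the per-condition mask RMS levels.
#' @export
experiment_design <- function(experiment) {
  switch(as.character(experiment),
    "1" = list(
      experiment = 1L,
      conditions = c("Upright", "Inverted", "TempScr", "SpatScr"),
      blocks = 8L,
      n_participants_default = 15L
    ),
    "2" = list(
      experiment = 2L,
      conditions = c("LowUp", "LowInv", "MedUp", "MedInv", "HighUp", "HighInv"),
      blocks = 8L,
      n_participants_default = 20L,
      mask_rms = c(LowUp = 0.07, LowInv = 0.07, MedUp = 0.10,
                   MedInv = 0.10, HighUp = 0.13, HighInv = 0.13)
    ),
    "3" = list(
      experiment = 3L,
      conditions = c("FastBM", "NormalBM", "Static", "CoherOF", "TempOF"),
      blocks = 8L,
      n_participants_default = 25L
    ),
    stop("`experiment` must be 1, 2 or 3")
  )
}

# Pre-draw the stochastic response behaviour for every reversal of a trial:
# a jittered threshold per reversal and a lapse indicator. Drawing these up
# front lets the fast event-driven engine and the frame-stepping reference
# engine consume identical randomness.
reversal_draws <- function(observer, n, seed = NULL) {
  with_seed(seed, {
    kinds <- rep(c("reCFS", "bCFS"), length.out = n)
    planted <- ifelse(kinds == "bCFS", observer$bcfs_mean_db,
                      observer$bcfs_mean_db - observer$depth_db)
    tibble::tibble(
      kind = kinds,
      threshold_db = rnorm(n, planted, observer$jitter_sd_db),
      lapse = runif(n) < observer$lapse_prob,
      lapse_u = runif(n)
    )
  })
}

#' Run one tCFS trial
#'
#' Simulates a complete trial against a synthetic observer (see
#' [observer_params()]): contrast starts at the ceiling and ramps down in
#' `step_db_per_frame` steps; at each response the current contrast is
#' recorded and the ramp direction flips; the trial ends after
#' `responses_per_trial` responses. The observer responds at the first
#' frame at or past its (jittered) threshold, `delay_frames` later; during
#' the delay the ramp keeps moving, so a reaction delay inflates measured
#' suppression depth by `2 * delay_frames * step_db_per_frame`. Contrast is
#' clamped to the floor/ceiling; responses issued while pinned at a bound
#' are flagged `clamped`.
#'
#' @param observer an [observer_params()] object.
#' @param condition condition tag recorded in the output.
#' @param cfg an [engine_config()].
#' @param seed integer seed for the observer's threshold jitter and lapses.
#' @param side `"left"` or `"right"` target placement.
#' @return a list of class `trial_result` with elements `records` (a tibble
#'   with one row per response: `response_index`, `kind`, `contrast_db`,
#'   `frame`, `clamped`, `lapse`), `trace` (per-frame contrast in dB,
#'   starting at the ceiling), `condition`, `side`.
#' @export
run_trial <- function(observer, condition = "Upright", cfg = engine_config(),
                      seed = NULL, side = "left", trace = TRUE) {
  stopifnot(inherits(observer, "tcfs_observer"), inherits(cfg, "engine_config"))
  draws <- reversal_draws(observer, cfg$responses_per_trial, seed)
  run_trial_given_draws(draws, observer, condition, cfg, side, trace)
}

run_trial_given_draws <- function(draws, observer, condition, cfg, side,
                                  trace = TRUE) {
  step <- cfg$step_db_per_frame
  floor_db <- cfg$contrast_floor_db
  ceil_db <- cfg$contrast_ceiling_db
  delay <- observer$delay_frames

  n <- nrow(draws)
  c_cur <- ceil_db
  frame_cur <- 0L
  rec <- vector("list", n)
  segs <- vector("list", n)

  for (k in seq_len(n)) {
    down <- draws$kind[k] == "reCFS"
    thr <- draws$threshold_db[k]
    to_bound <- if (down) ceiling((c_cur - floor_db) / step - 1e-9)
                else ceiling((ceil_db - c_cur) / step - 1e-9)
    to_bound <- max(0L, as.integer(to_bound))
    if (draws$lapse[k]) {
      n_cross <- as.integer(ceiling(draws$lapse_u[k] * max(1L, to_bound)))
      clamped <- FALSE
    } else {
      n_cross <- if (down) ceiling((c_cur - thr) / step - 1e-9)
                 else ceiling((thr - c_cur) / step - 1e-9)
      n_cross <- max(0L, as.integer(n_cross))
      clamped <- n_cross > to_bound
      if (clamped) n_cross <- to_bound
    }
    n_total <- n_cross + delay
    raw <- if (down) c_cur - n_total * step else c_cur + n_total * step
    rec_db <- min(max(raw, floor_db), ceil_db)
    clamped <- clamped || raw < floor_db - 1e-12 || raw > ceil_db + 1e-12
    frame_cur <- frame_cur + n_total
    if (frame_cur > cfg$max_trial_frames) {
      stop(sprintf("trial exceeded the %d-frame watchdog budget", cfg$max_trial_frames))
    }
    rec[[k]] <- tibble::tibble(
      response_index = k, kind = draws$kind[k], contrast_db = rec_db,
      frame = frame_cur, clamped = clamped, lapse = draws$lapse[k]
    )
    if (trace) {
      sgn <- if (down) -1 else 1
      seg <- c_cur + sgn * step * seq_len(n_total)
      segs[[k]] <- pmin(pmax(seg, floor_db), ceil_db)
    }
    c_cur <- rec_db
  }

  structure(
    list(
      records = dplyr::bind_rows(rec),
      trace = if (trace) c(ceil_db, unlist(segs)) else NULL,
      condition = condition,
      side = side,
      cfg = cfg
    ),
    class = "trial_result"
  )
}

# Frame-by-frame reference engine. Literally steps the contrast one frame
# at a time and asks the observer predicate at every frame. Slow; used as
# the independent cross-check of the event-driven engine.
run_trial_framewise <- function(observer, condition = "Upright",
                                cfg = engine_config(), seed = NULL,
                                side = "left") {
  draws <- reversal_draws(observer, cfg$responses_per_trial, seed)
  step <- cfg$step_db_per_frame
  floor_db <- cfg$contrast_floor_db
  ceil_db <- cfg$contrast_ceiling_db
  c_cur <- ceil_db
  frame_cur <- 0L
  rec <- vector("list", nrow(draws))
  for (k in seq_len(nrow(draws))) {
    down <- draws$kind[k] == "reCFS"
    thr <- draws$threshold_db[k]
    frames_since_crossing <- NA_integer_
    clamped_pending <- FALSE
    repeat {
      at_bound <- if (down) c_cur <= floor_db + 1e-12 else c_cur >= ceil_db - 1e-12
      crossed <- if (down) c_cur <= thr + 1e-12 else c_cur >= thr - 1e-12
      if (crossed || at_bound) {
        if (is.na(frames_since_crossing)) {
          frames_since_crossing <- 0L
          clamped_pending <- at_bound && !crossed
        }
        if (frames_since_crossing >= observer$delay_frames) {
          rec[[k]] <- tibble::tibble(
            response_index = k, kind = draws$kind[k], contrast_db = c_cur,
            frame = frame_cur,
            clamped = clamped_pending ||
              c_cur <= floor_db + 1e-12 || (k > 1 && c_cur >= ceil_db - 1e-12),
            lapse = FALSE
          )
          break
        }
      }
      c_cur <- if (down) max(c_cur - step, floor_db) else min(c_cur + step, ceil_db)
      frame_cur <- frame_cur + 1L
      if (!is.na(frames_since_crossing)) {
        frames_since_crossing <- frames_since_crossing + 1L
      }
      if (frame_cur > cfg$max_trial_frames) {
        stop(sprintf("trial exceeded the %d-frame watchdog budget", cfg$max_trial_frames))
      }
    }
    c_cur <- rec[[k]]$contrast_db
  }
  structure(
    list(records = dplyr::bind_rows(rec), trace = NULL,
         condition = condition, side = side, cfg = cfg),
    class = "trial_result"
  )
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result> %s (%s side): %d responses\n",
              x$condition, x$side, nrow(x$records)))
  print(x$records)
  invisible(x)
}

#' Run a session of tCFS trials
#'
#' Presents each condition once per block in a freshly randomised order
#' (drawn from the session seed), alternating the target side between
#' consecutive trials.
#'
#' @param observers either a single [observer_params()] used for every
#'   condition, or a named list mapping each condition to its observer.
#' @param design an [experiment_design()] (or any list with `conditions`
#'   and `blocks`).
#' @param cfg an [engine_config()].
#' @param seed session seed; trial-level jitter seeds are derived from it.
#' @return a list of `trial_result`s, with block/trial metadata attached to
#'   each element; collect into a tidy log with [session_log()].
#' @export
run_session <- function(observers, design = experiment_design(1),
                        cfg = engine_config(), seed = 1) {
  conditions <- design$conditions
  if (length(conditions) < 1) stop("design has an empty condition list")
  get_obs <- function(cond) {
    if (inherits(observers, "tcfs_observer")) return(observers)
    obs <- observers[[cond]]
    if (is.null(obs)) stop("no observer supplied for condition ", cond)
    obs
  }
  results <- list()
  trial_counter <- 0L
  for (b in seq_len(design$blocks)) {
    order_b <- with_seed(derive_seed(seed, b), sample(conditions))
    for (j in seq_along(order_b)) {
      trial_counter <- trial_counter + 1L
      cond <- order_b[j]
      side <- if (trial_counter %% 2 == 1) "left" else "right"
      tr <- run_trial(get_obs(cond), condition = cond, cfg = cfg,
                      seed = derive_seed(seed, b, j, 7919), side = side,
                      trace = FALSE)
      tr$block <- b
      tr$trial <- trial_counter
      results[[trial_counter]] <- tr
    }
  }
  results
}

#' Collect session results into a tidy trial log
#'
#' @param results a list of `trial_result`s from [run_session()].
#' @param participant participant identifier recorded in every row.
#' @param experiment experiment identifier.
#' @return a tibble with one row per threshold response: `participant`,
#'   `experiment`, `block`, `trial`, `condition`, `response_index`, `kind`,
#'   `contrast_db`, `frame`, `side`, `clamped`, `lapse`.
#' @export
session_log <- function(results, participant = 1L, experiment = 1L) {
  rows <- lapply(results, function(tr) {
    dplyr::mutate(tr$records,
      participant = participant, experiment = experiment,
      block = tr$block %||% NA_integer_, trial = tr$trial %||% NA_integer_,
      condition = tr$condition, side = tr$side
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::select(out, "participant", "experiment", "block", "trial",
                "condition", "response_index", "kind", "contrast_db",
                "frame", "side", "clamped", "lapse")
}
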