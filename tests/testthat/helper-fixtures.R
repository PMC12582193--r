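# Shared fixtures: everything is generated in code at test time.

# A small, fast walker used where the full 300-frame default is not needed.
small_walker <- function(seed = 1) {
  synth_gait(gait_params(loop_frames = 60, frame_rate_hz = 60), seed = seed)
}

# Deterministic observer: no jitter, no lapses, no delay.
det_observer <- function(bcfs = -10, depth = 14) {
  observer_params(bcfs_mean_db = bcfs, depth_db = depth,
                  jitter_sd_db = 0, lapse_prob = 0, delay_frames = 0)
}

# A zero-variance single-condition population for engine-level checks.
point_population <- function(bcfs = -10.4, depth = 13.4, conditions = "Upright",
                             jitter = 0, delay = 0) {
  cond <- stats::setNames(
    lapply(conditions, function(x) list(bcfs_db = bcfs, depth_db = depth)),
    conditions
  )
  population_params(cond, sd_bcfs_db = 0, sd_depth_db = 0,
                    jitter_sd_db = jitter, lapse_prob = 0,
                    delay_frames = delay)
}
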