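# Stimulus manipulations. All of these preserve each dot's frame-to-frame
# motion (or modulate it in a closed form) while altering the global
# configuration — the contrast that the tCFS experiments exploit.

#' Invert an animation vertically
#'
#' Reflects every dot about the animation's vertical centre
#' (`y' = 2 * y_c - y`, with `y_c` the midpoint of the full y-range over
#' all frames). Horizontal coordinates and timing are untouched, so every
#' local motion vector magnitude is preserved.
#'
#' @param anim a [dot_animation()].
#' @return the inverted [dot_animation()], labelled `"Inverted"`.
#' @export
invert_animation <- function(anim) {
  y <- anim$positions[, , 2]
  yc <- (max(y) + min(y)) / 2
  out <- anim
  out$positions[, , 2] <- 2 * yc - y
  out$label <- if (anim$label == "Inverted") "Upright" else "Inverted"
  out
}

#' Spatially scramble an animation
#'
#' Redraws each dot's starting (frame-0) position uniformly within the
#' animation subspace bounds and then replays that dot's original
#' frame-to-frame displacement series verbatim from the new origin. Local
#' motion is conserved exactly; the global form is destroyed and the dots
#' typically disperse over more of the display than the tightly clustered
#' walker. Excursions outside the subspace are not clipped (clipping would
#' alter local motion); the fraction of out-of-bounds dot-frames is
#' recorded in the `oob_fraction` attribute.
#'
#' @param anim a [dot_animation()].
#' @param seed integer seed for the redrawn starting positions.
#' @return a [dot_animation()] labelled `"SpatScr"`.
#' @export
spatial_scramble <- function(anim, seed = 1) {
  p <- anim$positions
  d <- dim(p)
  half <- anim$subspace_px / 2
  starts <- with_seed(seed, matrix(runif(d[2] * d[3], -half, half), nrow = d[2]))
  out_pos <- p
  for (k in seq_len(d[3])) {
    # displacement series relative to frame 0, re-anchored at the new start
    rel <- sweep(p[, , k, drop = FALSE], 2:3, p[1, , k, drop = FALSE], "-")
    out_pos[, , k] <- rel[, , 1] + matrix(starts[, k], d[1], d[2], byrow = TRUE)
  }
  out <- anim
  out$positions <- out_pos
  out$label <- "SpatScr"
  attr(out, "oob_fraction") <- mean(abs(out_pos) > half)
  out
}

#' Temporally scramble an animation
#'
#' Starts each dot at a random temporal position of its own looped
#' trajectory: dot `i`'s trajectory is cyclically shifted by
#' `k_i ~ Uniform{0, ..., loop_frames - 1}` frames. Each dot's orbit (the
#' multiset of positions it visits over one loop) is untouched; only the
#' phase relationships between dots are destroyed.
#'
#' @param anim a looped [dot_animation()].
#' @param seed integer seed for the per-dot shifts.
#' @param shifts optional integer vector of per-dot shifts (overrides the
#'   random draw; all zeros gives the identity).
#' @return a [dot_animation()] labelled `"TempScr"`.
#' @export
temporal_scramble <- function(anim, seed = 1, shifts = NULL) {
  d <- dim(anim$positions)
  L <- anim$loop_frames
  if (is.null(shifts)) {
    shifts <- with_seed(seed, sample(0:(L - 1), d[2], replace = TRUE))
  }
  stopifnot(length(shifts) == d[2])
  out <- anim
  for (i in seq_len(d[2])) {
    idx <- ((seq_len(L) - 1 + shifts[i]) %% L) + 1
    out$positions[, i, ] <- anim$positions[idx, i, ]
  }
  out$label <- "TempScr"
  attr(out, "shifts") <- as.integer(shifts)
  out
}

#' Optic-flow parameters
#'
#' Parameters of the sinusoidal radial modulation
#' `r_i(t) = r0_i * (1 + 0.2 * amp * sin(2*pi*t / modperiod + phi_i))`
#' applied about the display centre. The peak fractional radial excursion
#' is `0.2 * amp` and must stay below 1 so that dots never cross the
#' centre. `modperiod` defaults to one walker step cycle (frame rate /
#' 1.05), matching the modulation frequency to the walker's step rate.
#'
#' @param amp modulation amplitude (dimensionless; default 1).
#' @param modperiod modulation period in frames.
#' @param duration_frames output animation length.
#' @param phase_mode `"coherent"` (all dots share phase 0) or `"random"`
#'   (per-dot uniform random phase).
#' @param literal_randoffsets if `TRUE`, the scrambled variant randomises
#'   each dot's modulation *period* (drawn uniformly in
#'   `[0.5, 1.5] * modperiod`) instead of its phase.
#' @param seed integer seed for the random phases/periods.
#' @return a list of class `opticflow_params`.
#' @export
opticflow_params <- function(amp = 1, modperiod = 60 / 1.05,
                             duration_frames = 300,
                             phase_mode = c("coherent", "random"),
                             literal_randoffsets = FALSE, seed = 1) {
  phase_mode <- match.arg(phase_mode)
  if (amp < 0) stop("`amp` must be non-negative")
  if (modperiod <= 0) stop("`modperiod` must be positive")
  if (0.2 * amp >= 1) stop("0.2 * amp must be < 1 (dots would cross the centre)")
  structure(
    list(amp = amp, modperiod = modperiod,
         duration_frames = as.integer(duration_frames),
         phase_mode = phase_mode,
         literal_randoffsets = literal_randoffsets, seed = seed),
    class = "opticflow_params"
  )
}

optic_flow_core <- function(static, p, phases, periods = NULL) {
  fr <- static$positions[1, , , drop = TRUE]
  if (is.null(dim(fr))) fr <- matrix(fr, ncol = n_dims(static))
  k <- ncol(fr)
  r0 <- sqrt(rowSums(fr^2))
  unit <- fr / ifelse(r0 > 0, r0, 1)
  t <- seq_len(p$duration_frames) - 1
  nd <- nrow(fr)
  pos <- array(0, dim = c(p$duration_frames, nd, k))
  per <- if (is.null(periods)) rep(p$modperiod, nd) else periods
  for (i in seq_len(nd)) {
    r_t <- r0[i] * (1 + 0.2 * p$amp * sin(2 * pi * t / per[i] + phases[i]))
    for (ax in seq_len(k)) pos[, i, ax] <- r_t * unit[i, ax]
  }
  out <- dot_animation(pos,
    frame_rate_hz = static$frame_rate_hz,
    loop_frames = p$duration_frames,
    dot_diameter_px = static$dot_diameter_px,
    subspace_px = static$subspace_px
  )
  attr(out, "r0") <- r0
  attr(out, "phases") <- phases
  attr(out, "periods") <- per
  out
}

#' Generate coherent radial optic flow from a static frame
#'
#' Each dot moves radially about the display centre with sinusoidal
#' magnitude, all dots in phase:
#' `r_i(t) = r0_i * (1 + 0.2 * amp * sin(2*pi*t / modperiod))`.
#' Local speed is proportional to the dot's eccentricity `r0_i`, as in
#' expanding/contracting optic flow. At `t = 0` the positions equal the
#' static frame.
#'
#' @param static a single-frame (or frozen) [dot_animation()] providing the
#'   starting coordinates.
#' @param p an [opticflow_params()] with `phase_mode = "coherent"`.
#' @return a [dot_animation()] labelled `"CoherOF"`.
#' @export
coherent_optic_flow <- function(static, p = opticflow_params()) {
  if (p$phase_mode != "coherent") stop("`p$phase_mode` must be \"coherent\"")
  nd <- n_dots(static)
  out <- optic_flow_core(static, p, phases = rep(0, nd))
  out$label <- "CoherOF"
  out
}

#' Generate temporally scrambled radial optic flow
#'
#' Identical per-dot radial modulation as [coherent_optic_flow()] but with
#' an independent uniform random phase per dot, which decorrelates the
#' dots' radial velocities while leaving each dot's modulation amplitude
#' unchanged. With `literal_randoffsets = TRUE` in `p`, the per-dot
#' modulation *period* is randomised instead.
#'
#' @inheritParams coherent_optic_flow
#' @param p an [opticflow_params()] with `phase_mode = "random"`.
#' @return a [dot_animation()] labelled `"TempOF"`.
#' @export
scrambled_optic_flow <- function(static, p = opticflow_params(phase_mode = "random")) {
  if (p$phase_mode != "random") stop("`p$phase_mode` must be \"random\"")
  nd <- n_dots(static)
  if (p$literal_randoffsets) {
    periods <- with_seed(p$seed, runif(nd, 0.5, 1.5) * p$modperiod)
    out <- optic_flow_core(static, p, phases = rep(0, nd), periods = periods)
  } else {
    phases <- with_seed(p$seed, runif(nd, 0, 2 * pi))
    out <- optic_flow_core(static, p, phases = phases)
  }
  out$label <- "TempOF"
  out
}

#' Per-dot radial velocity time series
#'
#' Finite-difference rate of change of each dot's distance from the display
#' centre, in px/s; used to verify the eccentricity scaling and phase
#' structure of the optic-flow stimuli.
#'
#' @param anim a [dot_animation()].
#' @return a `(frames - 1) x dots` matrix.
#' @export
radial_velocity <- function(anim) {
  p <- anim$positions
  r <- sqrt(apply(p^2, c(1, 2), sum))
  diff(r) * anim$frame_rate_hz
}
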