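# Point-light walker stimuli.
#
# A `dot_animation` is the universal stimulus currency of the package: an
# array of dot positions over frames, either 3D world coordinates (k = 3,
# x rightward, y upward, z toward the viewer) or 2D screen coordinates
# (k = 2) after projection. Units are pixels; the procedural walker lives in
# a 150-pixel subspace (coordinates within +/- 75 px of the origin) and is
# scaled by 0.75 into the 112.5-px target motion boundary at projection time.

#' Construct a dot animation
#'
#' @param positions numeric array of dimension `frames x dots x k` with
#'   `k = 3` (world coordinates) or `k = 2` (screen coordinates), in pixels.
#' @param frame_rate_hz playback frame rate in Hz.
#' @param loop_frames loop length in frames; frame indexing is modulo this
#'   value so the animation loops seamlessly.
#' @param dot_diameter_px rendered dot diameter in pixels.
#' @param label condition tag carried through transforms.
#' @param subspace_px side length of the square (or cubic) region the
#'   animation is defined in, centred on the origin.
#'
#' @return An object of class `dot_animation`.
#' @export
dot_animation <- function(positions, frame_rate_hz = 60, loop_frames = dim(positions)[1],
                          dot_diameter_px = 4, label = "Upright", subspace_px = 150) {
  if (!is.array(positions) || length(dim(positions)) != 3) {
    stop("`positions` must be a frames x dots x k array")
  }
  k <- dim(positions)[3]
  if (!k %in% c(2, 3)) stop("last dimension of `positions` must be 2 or 3")
  if (!all(is.finite(positions))) stop("positions must be finite")
  stopifnot(frame_rate_hz > 0, loop_frames >= 1)
  structure(
    list(
      positions = positions,
      frame_rate_hz = frame_rate_hz,
      loop_frames = as.integer(loop_frames),
      dot_diameter_px = dot_diameter_px,
      label = label,
      subspace_px = subspace_px
    ),
    class = "dot_animation"
  )
}

#' @export
print.dot_animation <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf(
    "<dot_animation> %s: %d frames x %d dots (%dD), %.4g Hz, loop %d frames\n",
    x$label, d[1], d[2], d[3], x$frame_rate_hz, x$loop_frames
  ))
  invisible(x)
}

#' Number of frames / dots / spatial dimensions of an animation
#' @param anim a [dot_animation()].
#' @return integer scalar.
#' @export
n_frames <- function(anim) dim(anim$positions)[1]

#' @rdname n_frames
#' @export
n_dots <- function(anim) dim(anim$positions)[2]

#' @rdname n_frames
#' @export
n_dims <- function(anim) dim(anim$positions)[3]

#' Positions at a frame, with modular (seamless-loop) indexing
#'
#' Frame indices are 0-based and wrapped modulo `loop_frames`, so
#' `frame_positions(a, loop_frames)` equals `frame_positions(a, 0)`.
#'
#' @param anim a [dot_animation()].
#' @param frame 0-based frame index (any integer; wrapped into the loop).
#' @return a `dots x k` matrix.
#' @export
frame_positions <- function(anim, frame) {
  i <- (as.integer(frame) %% anim$loop_frames) + 1L
  anim$positions[i, , , drop = TRUE]
}

#' Gait parameters for the procedural walker
#'
#' The walker steps at `step_frequency_hz` footfalls per second (default
#' 1.05, roughly 1 Hz). Because the loop must close seamlessly, the
#' generator snaps the number of step cycles in one loop to the nearest
#' integer; at the defaults (300 frames at 60 Hz, i.e. a 5 s loop) the
#' effective rate becomes 1.0 steps/s while the nominal 1.05 is retained in
#' the animation metadata.
#'
#' @param step_frequency_hz nominal stepping rate, footfalls per second.
#' @param marker_count number of body markers (dots).
#' @param loop_frames loop length in frames.
#' @param frame_rate_hz frame rate in Hz.
#' @param subspace_px side of the square subspace the walker occupies.
#' @param scale projection scale factor applied when mapping into the
#'   target motion boundary.
#' @param limb_amplitude global multiplier on limb swing amplitudes
#'   (1 = default gait).
#' @return a list of class `gait_params`.
#' @export
gait_params <- function(step_frequency_hz = 1.05, marker_count = 31,
                        loop_frames = 300, frame_rate_hz = 60,
                        subspace_px = 150, scale = 0.75,
                        limb_amplitude = 1) {
  if (step_frequency_hz <= 0) stop("`step_frequency_hz` must be positive")
  if (marker_count <= 0) stop("`marker_count` must be positive")
  stopifnot(loop_frames >= 2, frame_rate_hz > 0, limb_amplitude >= 0)
  structure(
    list(
      step_frequency_hz = step_frequency_hz,
      marker_count = as.integer(marker_count),
      loop_frames = as.integer(loop_frames),
      frame_rate_hz = frame_rate_hz,
      subspace_px = subspace_px,
      scale = scale,
      limb_amplitude = limb_amplitude
    ),
    class = "gait_params"
  )
}

# Base marker layout: 31 markers over head/torso/arms/legs, with deliberate
# clusters at the head, neck, shoulders and hips so that several dots sit in
# close proximity or overlap, as in toolbox-rendered walkers. Columns:
# base position (bx, by, bz), first-harmonic amplitude vector (a1x, a1y,
# a1z) and phase ph1, second-harmonic amplitude vector (a2x, a2y, a2z) and
# phase ph2. Phases are in units of the step cycle (0..1).
walker_skeleton_template <- function() {
  m <- function(name, bx, by, bz, a1z = 0, a1y = 0, a1x = 0, ph1 = 0,
                a2y = 0, a2z = 0, a2x = 0, ph2 = 0) {
    data.frame(marker = name, bx = bx, by = by, bz = bz,
               a1x = a1x, a1y = a1y, a1z = a1z, ph1 = ph1,
               a2x = a2x, a2y = a2y, a2z = a2z, ph2 = ph2)
  }
  # Legs are antiphase (ph1 offset 0.5); arms counter-swing their
  # ipsilateral leg. The trunk bobs vertically twice per step cycle.
  rows <- list(
    # head cluster (3)
    m("head_top",   0, 64, 0, a1x = 1.0, ph1 = 0.25, a2y = 2.0),
    m("head_l",    -2, 61, 0, a1x = 1.0, ph1 = 0.25, a2y = 2.0),
    m("head_r",     2, 61, 0, a1x = 1.0, ph1 = 0.25, a2y = 2.0),
    # neck cluster (2)
    m("neck_1",     0, 53, 0, a1x = 1.2, ph1 = 0.25, a2y = 2.2),
    m("neck_2",     0, 51, 1, a1x = 1.2, ph1 = 0.25, a2y = 2.2),
    # shoulder clusters (2 + 2)
    m("shoulder_l",  -14, 48, 0, a1z = 4, ph1 = 0.5, a2y = 2.0),
    m("shoulder_l2", -13, 47, 1, a1z = 4, ph1 = 0.5, a2y = 2.0),
    m("shoulder_r",   14, 48, 0, a1z = 4, ph1 = 0.0, a2y = 2.0),
    m("shoulder_r2",  13, 47, 1, a1z = 4, ph1 = 0.0, a2y = 2.0),
    # sternum + spine (4)
    m("sternum",    0, 42, 2, a1x = 1.5, ph1 = 0.25, a2y = 2.4),
    m("spine_1",    0, 34, 1, a1x = 1.6, ph1 = 0.25, a2y = 2.6),
    m("spine_2",    0, 26, 0, a1x = 1.8, ph1 = 0.25, a2y = 2.8),
    m("spine_3",    0, 18, 0, a1x = 2.0, ph1 = 0.25, a2y = 3.0),
    # hip cluster (4)
    m("hip_l",     -8, 10, 0, a1x = 2.2, a1y = 1.0, ph1 = 0.25, a2y = 3.0),
    m("hip_l2",    -7,  9, 1, a1x = 2.2, a1y = 1.0, ph1 = 0.25, a2y = 3.0),
    m("hip_r",      8, 10, 0, a1x = 2.2, a1y = 1.0, ph1 = 0.75, a2y = 3.0),
    m("hip_r2",     7,  9, 1, a1x = 2.2, a1y = 1.0, ph1 = 0.75, a2y = 3.0),
    # arms: elbow, wrist, hand (left swings with right leg)
    m("elbow_l",  -19, 34, 0, a1z =  9, ph1 = 0.5,  a2y = 1.6),
    m("elbow_r",   19, 34, 0, a1z =  9, ph1 = 0.0,  a2y = 1.6),
    m("wrist_l",  -23, 21, 2, a1z = 15, ph1 = 0.52, a2y = 1.4),
    m("wrist_r",   23, 21, 2, a1z = 15, ph1 = 0.02, a2y = 1.4),
    m("hand_l",   -24, 15, 3, a1z = 17, ph1 = 0.54, a2y = 1.2),
    m("hand_r",    24, 15, 3, a1z = 17, ph1 = 0.04, a2y = 1.2),
    # legs: knee, ankle, heel, toe (right leg leads at phase 0)
    m("knee_l",    -9, -26, 0, a1z = 16, a1y = 4, ph1 = 0.5,  a2y = 2.0),
    m("knee_r",     9, -26, 0, a1z = 16, a1y = 4, ph1 = 0.0,  a2y = 2.0),
    m("ankle_l",  -10, -58, 0, a1z = 26, a1y = 8, ph1 = 0.56, a2y = 3.0, a2z = 4),
    m("ankle_r",   10, -58, 0, a1z = 26, a1y = 8, ph1 = 0.06, a2y = 3.0, a2z = 4),
    m("heel_l",   -10, -64, -2, a1z = 26, a1y = 7, ph1 = 0.58, a2y = 2.6, a2z = 4),
    m("heel_r",    10, -64, -2, a1z = 26, a1y = 7, ph1 = 0.08, a2y = 2.6, a2z = 4),
    m("toe_l",    -11, -66, 5, a1z = 30, a1y = 6, ph1 = 0.60, a2y = 2.4, a2z = 5),
    m("toe_r",     11, -66, 5, a1z = 30, a1y = 6, ph1 = 0.10, a2y = 2.4, a2z = 5)
  )
  do.call(rbind, rows)
}

#' Synthesise a point-light walker animation
#'
#' Generates a 31-dot, 300-frame looped walker (at the defaults) from a
#' procedural two-level kinematic model: a pelvis/trunk carrier with
#' vertical bob at twice the step rate, plus sinusoidal limb pendula at the
#' step rate, legs in antiphase and arms counter-swinging. Each marker
#' trajectory is a sum of first- and second-harmonic sinusoids of the step
#' cycle, so every marker is exactly periodic over the loop and the
#' animation loops seamlessly. The `seed` individualises the walker
#' slightly (sub-pixel jitter of base positions within clusters and a few
#' percent of amplitude variation).
#'
#' The per-marker harmonic table used to generate the trajectories is
#' attached as the `skeleton` attribute, which makes analytic velocity
#' checks possible.
#'
#' @param params a [gait_params()] object.
#' @param seed integer seed for marker individualisation.
#' @return a 3D [dot_animation()] labelled `"Upright"`, with attributes
#'   `skeleton` (the harmonic table) and `step_frequency_effective_hz`.
#' @export
synth_gait <- function(params = gait_params(), seed = 1) {
  stopifnot(inherits(params, "gait_params"))
  loop_s <- params$loop_frames / params$frame_rate_hz
  # snap to an integer number of step cycles per loop for seamlessness
  cycles <- max(1L, round(params$step_frequency_hz * loop_s))
  f_eff <- cycles / loop_s

  skel <- walker_skeleton_template()
  # resize the marker set if a non-default count is requested
  nm <- params$marker_count
  if (nm <= nrow(skel)) {
    skel <- skel[seq_len(nm), , drop = FALSE]
  } else {
    extra <- skel[rep(seq_len(nrow(skel)), length.out = nm - nrow(skel)), , drop = FALSE]
    skel <- rbind(skel, extra)
  }

  skel <- with_seed(seed, {
    jit <- matrix(runif(nrow(skel) * 3, -1.5, 1.5), ncol = 3)
    ampf <- runif(nrow(skel), 0.95, 1.05)
    skel$bx <- skel$bx + jit[, 1]
    skel$by <- skel$by + jit[, 2]
    skel$bz <- skel$bz + jit[, 3]
    for (cl in c("a1x", "a1y", "a1z", "a2x", "a2y", "a2z")) {
      skel[[cl]] <- skel[[cl]] * ampf * params$limb_amplitude
    }
    skel
  })

  t <- (seq_len(params$loop_frames) - 1) / params$frame_rate_hz
  theta <- 2 * pi * f_eff * t   # step-cycle phase per frame

  pos <- array(NA_real_, dim = c(params$loop_frames, nrow(skel), 3))
  for (i in seq_len(nrow(skel))) {
    s <- skel[i, ]
    p1 <- sin(theta + 2 * pi * s$ph1)
    p2 <- sin(2 * theta + 2 * pi * s$ph2)
    pos[, i, 1] <- s$bx + s$a1x * p1 + s$a2x * p2
    pos[, i, 2] <- s$by + s$a1y * p1 + s$a2y * p2
    pos[, i, 3] <- s$bz + s$a1z * p1 + s$a2z * p2
  }

  half <- params$subspace_px / 2
  if (max(abs(pos)) > half) {
    pos <- pos * (half / max(abs(pos)))
  }

  anim <- dot_animation(pos,
    frame_rate_hz = params$frame_rate_hz,
    loop_frames = params$loop_frames,
    label = "Upright",
    subspace_px = params$subspace_px
  )
  attr(anim, "skeleton") <- skel
  attr(anim, "step_frequency_nominal_hz") <- params$step_frequency_hz
  attr(anim, "step_frequency_effective_hz") <- f_eff
  attr(anim, "scale") <- params$scale
  anim
}

#' Save / load dot trajectories as a plain-text table
#'
#' One frame per row; columns `x1 y1 z1 x2 y2 z2 ...` (or `x1 y1 x2 y2 ...`
#' for 2D animations), whitespace-separated, with a header comment line
#' recording the frame rate, marker count and dimensionality.
#'
#' @param anim a [dot_animation()].
#' @param path file path.
#' @return `load_trajectories` returns a [dot_animation()];
#'   `save_trajectories` returns `path` invisibly.
#' @export
save_trajectories <- function(anim, path) {
  d <- dim(anim$positions)
  mat <- matrix(aperm(anim$positions, c(3, 2, 1)), nrow = d[1], byrow = TRUE)
  header <- sprintf("# frame_rate_hz=%.10g markers=%d dims=%d loop_frames=%d label=%s",
                    anim$frame_rate_hz, d[2], d[3], anim$loop_frames, anim$label)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(format(mat, digits = 17, scientific = TRUE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_trajectories
#' @export
load_trajectories <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty trajectory file: ", path)
  meta <- list(frame_rate_hz = 60, dims = 3, loop_frames = NA, label = "Loaded")
  body_start <- 1L
  if (grepl("^#", lines[1])) {
    body_start <- 2L
    kv <- regmatches(lines[1], gregexpr("[A-Za-z_]+=[^ ]+", lines[1]))[[1]]
    for (pair in kv) {
      parts <- strsplit(pair, "=", fixed = TRUE)[[1]]
      meta[[parts[1]]] <- parts[2]
    }
  }
  body <- lines[seq(body_start, length(lines))]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("trajectory file has no data rows: ", path)
  rows <- strsplit(trimws(body), "[,[:space:]]+")
  ncols <- length(rows[[1]])
  vals <- vector("list", length(rows))
  for (r in seq_along(rows)) {
    if (length(rows[[r]]) != ncols) {
      stop(sprintf("row %d has %d fields, expected %d", r, length(rows[[r]]), ncols))
    }
    v <- suppressWarnings(as.numeric(rows[[r]]))
    if (anyNA(v)) {
      stop(sprintf("non-numeric value in row %d", r))
    }
    vals[[r]] <- v
  }
  mat <- do.call(rbind, vals)
  k <- as.integer(meta$dims %||% 3)
  if (ncols %% k != 0) stop(sprintf("column count %d is not a multiple of dims=%d", ncols, k))
  dots <- ncols %/% k
  pos <- aperm(array(t(mat), dim = c(k, dots, nrow(mat))), c(3, 2, 1))
  lf <- suppressWarnings(as.integer(meta$loop_frames))
  dot_animation(pos,
    frame_rate_hz = as.numeric(meta$frame_rate_hz),
    loop_frames = if (is.na(lf)) nrow(mat) else lf,
    label = as.character(meta$label),
    subspace_px = 150
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Project a 3D animation to screen coordinates
#'
#' `"frontal"` drops the depth axis (orthographic projection of a walker
#' facing the viewer); `"profile"` first rotates the animation 90 degrees
#' about the vertical axis, so world depth maps onto the horizontal screen
#' axis, then drops depth. The result is scaled by `scale` (default 0.75,
#' mapping the 150-px subspace into the 112.5-px target motion boundary).
#'
#' @param anim a 3D [dot_animation()].
#' @param view `"frontal"` or `"profile"`.
#' @param scale scale factor into the target boundary.
#' @return a 2D [dot_animation()] with attribute `boundary_px`.
#' @export
project <- function(anim, view = c("frontal", "profile"), scale = NULL) {
  view <- match.arg(view)
  if (n_dims(anim) != 2 && n_dims(anim) != 3) stop("invalid animation")
  if (n_dims(anim) == 2) stop("animation is already projected to 2D")
  scale <- scale %||% (attr(anim, "scale") %||% 0.75)
  pos <- anim$positions
  if (view == "profile") pos <- rotate_y(pos, 90)
  out <- pos[, , 1:2, drop = FALSE] * scale
  res <- dot_animation(out,
    frame_rate_hz = anim$frame_rate_hz,
    loop_frames = anim$loop_frames,
    dot_diameter_px = anim$dot_diameter_px,
    label = anim$label,
    subspace_px = anim$subspace_px * scale
  )
  attr(res, "boundary_px") <- anim$subspace_px * scale
  attr(res, "view") <- view
  res
}

#' Rotate a 3D animation about the vertical (y) axis
#'
#' @param anim a 3D [dot_animation()] (or a raw positions array).
#' @param degrees rotation angle; 90 turns a frontal walker side-on.
#' @return object of the same type as the input.
#' @export
rotate_vertical <- function(anim, degrees = 90) {
  if (inherits(anim, "dot_animation")) {
    if (n_dims(anim) != 3) stop("rotation requires a 3D animation")
    out <- anim
    out$positions <- rotate_y(anim$positions, degrees)
    return(out)
  }
  rotate_y(anim, degrees)
}

rotate_y <- function(pos, degrees) {
  a <- degrees * pi / 180
  x <- pos[, , 1]; z <- pos[, , 3]
  out <- pos
  out[, , 1] <- cos(a) * x + sin(a) * z
  out[, , 3] <- -sin(a) * x + cos(a) * z
  out
}

#' Extract a static frame as a frozen animation
#'
#' Repeats a single frame (default the maximum-stride frame, index 40) for
#' `n_frames` frames, producing a stimulus with zero motion energy.
#' Frame indices are 0-based; set `index_base = 1` to interpret
#' `frame_index` as 1-based.
#'
#' @param anim a [dot_animation()].
#' @param frame_index frame to freeze (default 40).
#' @param n_frames duration of the static animation in frames.
#' @param index_base 0 or 1.
#' @return a [dot_animation()] labelled `"Static"`.
#' @export
extract_static <- function(anim, frame_index = 40, n_frames = anim$loop_frames,
                           index_base = 0) {
  stopifnot(index_base %in% c(0, 1))
  idx0 <- frame_index - index_base
  if (idx0 < 0 || idx0 >= anim$loop_frames) {
    stop(sprintf("frame_index %d out of range [%d, %d]",
                 frame_index, index_base, anim$loop_frames - 1 + index_base))
  }
  fr <- anim$positions[idx0 + 1, , , drop = FALSE]
  pos <- fr[rep(1, n_frames), , , drop = FALSE]
  out <- dot_animation(pos,
    frame_rate_hz = anim$frame_rate_hz,
    loop_frames = n_frames,
    dot_diameter_px = anim$dot_diameter_px,
    label = "Static",
    subspace_px = anim$subspace_px
  )
  attr(out, "source_frame") <- idx0
  out
}

#' Scale the playback speed of an animation by frame resampling
#'
#' Output frame `t` (0-based) shows input frame `round(factor * t)` modulo
#' the loop length; the playback frame rate is unchanged, so `factor = 2`
#' skips every other frame and shows the identical sequence at twice the
#' normal rate.
#'
#' @param anim a looped [dot_animation()].
#' @param factor speed multiplier (> 0).
#' @return a [dot_animation()] (labelled `"FastBM"` when `factor > 1`).
#' @export
scale_speed <- function(anim, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0) {
    stop("`factor` must be a positive number")
  }
  t_out <- seq_len(anim$loop_frames) - 1
  src <- (round(factor * t_out) %% anim$loop_frames) + 1
  out <- anim
  out$positions <- anim$positions[src, , , drop = FALSE]
  out$label <- if (factor > 1) "FastBM" else if (factor == 1) anim$label else "SlowBM"
  out
}

#' Per-frame dot displacements and speeds
#'
#' Finite-difference kinematics used throughout the test oracles:
#' `frame_displacements` returns the `(frames-1) x dots` (or `frames x dots`
#' with `wrap = TRUE`, including the last-to-first step) matrix of Euclidean
#' displacements per frame; `dot_speeds` divides by the frame period to give
#' speeds in px/s.
#'
#' @param anim a [dot_animation()].
#' @param wrap include the wrap-around (last to first frame) step.
#' @return a numeric matrix, frames x dots.
#' @export
frame_displacements <- function(anim, wrap = FALSE) {
  p <- anim$positions
  nf <- dim(p)[1]
  idx_from <- if (wrap) seq_len(nf) else seq_len(nf - 1)
  idx_to <- if (wrap) c(seq(2, nf), 1L) else seq(2, nf)
  d2 <- 0
  for (k in seq_len(dim(p)[3])) {
    d2 <- d2 + (p[idx_to, , k, drop = FALSE] - p[idx_from, , k, drop = FALSE])^2
  }
  sqrt(d2[, , 1, drop = TRUE])
}

#' @rdname frame_displacements
#' @export
dot_speeds <- function(anim, wrap = FALSE) {
  frame_displacements(anim, wrap = wrap) * anim$frame_rate_hz
}

#' Export per-frame dot coordinates as a tidy CSV
#'
#' @param anim a [dot_animation()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_anim_csv <- function(anim, path) {
  d <- dim(anim$positions)
  axes <- c("x", "y", "z")[seq_len(d[3])]
  df <- expand.grid(frame = seq_len(d[1]) - 1, dot = seq_len(d[2]))
  for (k in seq_len(d[3])) {
    df[[axes[k]]] <- as.vector(anim$positions[, , k])
  }
  utils::write.csv(df[order(df$frame, df$dot), ], path, row.names = FALSE)
  invisible(path)
}
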