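# Mondrian mask synthesis. Masks are grayscale patchworks of overlapping
# circles on a mid-gray canvas, rescaled to a target RMS contrast (the
# standard deviation of pixel intensities on a 0-1 scale) and refreshed at
# a fixed update rate below the playback rate.

#' Generate one Mondrian mask pattern
#'
#' Paints `n_circles` circles with random centres, radii and gray levels on
#' a mid-gray canvas, then affinely rescales intensities about the mean so
#' the pixel standard deviation hits `rms_target` (tolerance +/- 0.005
#' after clipping to `[0, 1]`) with the mean restored to 0.5.
#'
#' @param seed integer seed; patterns are deterministic per seed.
#' @param rms_target target RMS contrast, in `(0, 0.5]`.
#' @param size_px image side in pixels (default 400, i.e. 7 x 7 deg).
#' @param n_circles number of circles painted.
#' @param radius_range circle radius range in pixels; defaults to
#'   2-20% of the image side (8-80 px at the default size).
#' @return a `size_px x size_px` numeric matrix in `[0, 1]` with attribute
#'   `rms_contrast` (the measured pixel SD).
#' @export
make_mondrian <- function(seed = 1, rms_target = 0.1, size_px = 400,
                          n_circles = 300,
                          radius_range = c(0.02, 0.2) * size_px) {
  if (rms_target <= 0 || rms_target > 0.5) stop("`rms_target` must be in (0, 0.5]")
  img <- with_seed(seed, {
    cx <- runif(n_circles, 1, size_px)
    cy <- runif(n_circles, 1, size_px)
    rad <- runif(n_circles, radius_range[1], radius_range[2])
    lev <- runif(n_circles, 0, 1)
    canvas <- matrix(0.5, size_px, size_px)
    xs <- seq_len(size_px)
    for (j in seq_len(n_circles)) {
      x0 <- max(1L, floor(cx[j] - rad[j])); x1 <- min(size_px, ceiling(cx[j] + rad[j]))
      y0 <- max(1L, floor(cy[j] - rad[j])); y1 <- min(size_px, ceiling(cy[j] + rad[j]))
      if (x0 > x1 || y0 > y1) next
      dx <- (xs[x0:x1] - cx[j])^2
      dy <- (xs[y0:y1] - cy[j])^2
      inside <- outer(dy, dx, "+") <= rad[j]^2
      block <- canvas[y0:y1, x0:x1]
      block[inside] <- lev[j]
      canvas[y0:y1, x0:x1] <- block
    }
    canvas
  })
  s0 <- stats::sd(img)
  if (s0 < 1e-12) {
    stop("degenerate pattern: pixel SD is zero before rescaling; paint more circles")
  }
  scale <- rms_target / s0
  out <- 0.5 + (img - mean(img)) * scale
  out[out < 0] <- 0
  out[out > 1] <- 1
  achieved <- stats::sd(out)
  if (abs(achieved - rms_target) > 0.005) {
    stop(sprintf(
      "could not reach RMS contrast %.3f (achieved %.3f after clipping); try a lower target",
      rms_target, achieved
    ))
  }
  attr(out, "rms_contrast") <- achieved
  attr(out, "rescale_factor") <- scale
  out
}

#' Generate a Mondrian mask sequence
#'
#' A fresh pattern every `playback_hz / update_hz` playback frames (5 at
#' the 60 Hz / 12 Hz defaults), each pattern independently seeded from the
#' sequence seed.
#'
#' @param duration_frames number of playback frames covered.
#' @param seed integer seed for the pattern stream.
#' @param rms_target target RMS contrast of every pattern.
#' @param update_hz pattern refresh rate (default 12 Hz).
#' @param playback_hz display frame rate (default 60 Hz).
#' @param size_px pattern side in pixels.
#' @param n_circles circles per pattern.
#' @return an object of class `mask_sequence`: a list with `patterns` (list
#'   of matrices), `frame_pattern` (1-based pattern index per playback
#'   frame), `rms_contrast`, `update_hz`, `playback_hz`.
#' @export
mask_sequence <- function(duration_frames, seed = 1, rms_target = 0.1,
                          update_hz = 12, playback_hz = 60, size_px = 400,
                          n_circles = 300) {
  if (duration_frames <= 0) stop("`duration_frames` must be positive")
  if (update_hz > playback_hz) stop("`update_hz` cannot exceed `playback_hz`")
  frames_per_pattern <- playback_hz / update_hz
  if (abs(frames_per_pattern - round(frames_per_pattern)) > 1e-9) {
    stop("`playback_hz` must be an integer multiple of `update_hz`")
  }
  frames_per_pattern <- as.integer(round(frames_per_pattern))
  n_patterns <- as.integer(ceiling(duration_frames / frames_per_pattern))
  patterns <- lapply(seq_len(n_patterns), function(i) {
    make_mondrian(seed = derive_seed(seed, i), rms_target = rms_target,
                  size_px = size_px, n_circles = n_circles)
  })
  frame_pattern <- rep(seq_len(n_patterns), each = frames_per_pattern)[seq_len(duration_frames)]
  structure(
    list(
      patterns = patterns,
      frame_pattern = frame_pattern,
      rms_contrast = rms_target,
      update_hz = update_hz,
      playback_hz = playback_hz,
      size_px = size_px
    ),
    class = "mask_sequence"
  )
}

#' @export
print.mask_sequence <- function(x, ...) {
  cat(sprintf(
    "<mask_sequence> %d patterns (%d x %d px), RMS %.3f, %g Hz update at %g Hz playback\n",
    length(x$patterns), x$size_px, x$size_px, x$rms_contrast, x$update_hz, x$playback_hz
  ))
  invisible(x)
}

#' Export a mask pattern as PNG
#'
#' @param pattern a matrix from [make_mondrian()] (or an element of a
#'   [mask_sequence()]'s `patterns`).
#' @param path output path.
#' @return `path`, invisibly. Requires the `png` package.
#' @export
write_mask_png <- function(pattern, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the `png` package is required for PNG export")
  }
  png::writePNG(pattern, path)
  invisible(path)
}
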