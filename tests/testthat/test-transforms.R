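test_that("inversion is an isometric involution about the vertical centre", {
  a <- small_walker()
  inv <- invert_animation(a)
  expect_equal(invert_animation(inv)$positions, a$positions, tolerance = 1e-12)
  expect_equal(inv$positions[, , 1], a$positions[, , 1])
  # reflection preserves every displacement magnitude and the full per-dot
  # speed histograms over the loop
  expect_equal(frame_displacements(inv, wrap = TRUE),
               frame_displacements(a, wrap = TRUE), tolerance = 1e-12)
  sp_a <- apply(dot_speeds(a, wrap = TRUE), 2, sort)
  sp_i <- apply(dot_speeds(inv, wrap = TRUE), 2, sort)
  expect_equal(sp_i, sp_a, tolerance = 1e-12)
})

test_that("spatial scramble preserves displacement series exactly", {
  a <- small_walker()
  s <- spatial_scramble(a, seed = 11)
  for (k in seq_len(n_dims(a))) {
    expect_equal(diff(s$positions[, , k]), diff(a$positions[, , k]),
                 tolerance = 1e-12)
  }
  expect_identical(spatial_scramble(a, seed = 11)$positions, s$positions)
  expect_false(identical(spatial_scramble(a, seed = 12)$positions, s$positions))
  expect_equal(n_dots(s), n_dots(a))
  expect_equal(n_frames(s), n_frames(a))
})

test_that("spatial scramble disperses the clustered walker dots", {
  # Monte-Carlo: mean convex-hull area over frames should not shrink when
  # tightly clustered walker dots are re-seeded uniformly over the subspace
  a <- project(synth_gait(), "frontal")
  hull_area <- function(pts) {
    h <- chull(pts)
    x <- pts[h, 1]; y <- pts[h, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  frames <- seq(1, 300, by = 30)
  orig <- mean(vapply(frames, function(f) hull_area(a$positions[f, , ]), 0))
  scr <- vapply(1:100, function(s) {
    sc <- spatial_scramble(a, seed = s)
    mean(vapply(frames, function(f) hull_area(sc$positions[f, , ]), 0))
  }, 0)
  expect_gt(mean(scr), orig)
})

test_that("temporal scramble cyclically shifts orbits without changing them", {
  a <- small_walker()
  expect_equal(temporal_scramble(a, shifts = rep(0, n_dots(a)))$positions,
               a$positions)
  s <- temporal_scramble(a, seed = 5)
  expect_identical(temporal_scramble(a, seed = 5)$positions, s$positions)
  # each dot's orbit (sorted positions over the loop) is unchanged
  for (i in c(1, 15, 31)) {
    expect_equal(apply(s$positions[, i, ], 2, sort),
                 apply(a$positions[, i, ], 2, sort), tolerance = 1e-12)
    expect_equal(colMeans(s$positions[, i, ]), colMeans(a$positions[, i, ]),
                 tolerance = 1e-12)
  }
})

test_that("coherent optic flow follows the closed-form radial modulation", {
  st <- extract_static(project(synth_gait(), "profile"))
  p <- opticflow_params(amp = 1, modperiod = 60, duration_frames = 240)
  of <- coherent_optic_flow(st, p)
  # t = 0 reproduces the static frame
  expect_equal(of$positions[1, , ], st$positions[1, , ], tolerance = 1e-12)
  # peak radial excursion of each dot = 0.2 * amp * r0 (closed form)
  r0 <- attr(of, "r0")
  r <- sqrt(apply(of$positions^2, c(1, 2), sum))
  excursion <- apply(abs(sweep(r, 2, r0)), 2, max)
  expect_equal(excursion, 0.2 * 1 * r0, tolerance = 1e-3)
  # all dots share phase: radial velocities perfectly correlated
  rv <- radial_velocity(of)
  keep <- r0 > 1
  cc <- cor(rv[, keep])
  expect_true(all(abs(cc - 1) < 1e-9))
})

test_that("optic-flow local speed scales with eccentricity", {
  st <- extract_static(project(synth_gait(), "profile"))
  of <- coherent_optic_flow(st, opticflow_params(modperiod = 60))
  r0 <- attr(of, "r0")
  mean_speed <- colMeans(abs(radial_velocity(of)))
  fit <- lm(mean_speed ~ 0 + r0)
  # noiseless output: the fit is near-perfect by design
  expect_gt(suppressWarnings(summary(fit)$r.squared), 0.99)
})

test_that("scrambled optic flow randomises phase but not amplitude", {
  st <- extract_static(project(synth_gait(), "profile"))
  r0 <- sqrt(rowSums(st$positions[1, , ]^2))
  keep <- r0 > 1
  # all phases forced equal reduces to the coherent condition
  pc <- opticflow_params(modperiod = 60, duration_frames = 120)
  coh <- coherent_optic_flow(st, pc)
  ps <- opticflow_params(modperiod = 60, duration_frames = 120,
                         phase_mode = "random", seed = 9)
  scr <- scrambled_optic_flow(st, ps)
  expect_identical(scrambled_optic_flow(st, ps)$positions, scr$positions)

  # per-dot radial excursion amplitude matches the coherent condition
  amp_of <- function(anim) {
    r <- sqrt(apply(anim$positions^2, c(1, 2), sum))
    apply(r, 2, function(x) (max(x) - min(x)) / 2)
  }
  expect_equal(amp_of(scr)[keep], amp_of(coh)[keep], tolerance = 0.02)

  # mean pairwise radial-velocity correlation ~ 0 across seeds
  mean_cor <- vapply(1:30, function(s) {
    an <- scrambled_optic_flow(st, opticflow_params(
      modperiod = 60, duration_frames = 120, phase_mode = "random", seed = s))
    cc <- cor(radial_velocity(an)[, keep])
    mean(cc[upper.tri(cc)])
  }, 0)
  expect_lt(abs(mean(mean_cor)), 0.1)
})

test_that("optic-flow parameter validation enforces the no-centre-crossing bound", {
  expect_error(opticflow_params(amp = 5), "cross")
  expect_error(opticflow_params(modperiod = 0), "positive")
  st <- extract_static(small_walker(), n_frames = 10)
  expect_error(coherent_optic_flow(st, opticflow_params(phase_mode = "random")),
               "coherent")
  expect_error(scrambled_optic_flow(st, opticflow_params()), "random")
})
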