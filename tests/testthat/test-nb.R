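# Number & Brightness: registration, moments, brightness maps and QC.

make_drift_stack <- function(drift, T = 8, side = 48, seed = 3) {
  ctr <- (side + 1) / 2
  bump <- 1 + 20 * exp(-((row(diag(side)) - ctr)^2 +
                           (col(diag(side)) - ctr)^2) / (2 * 9))
  gen_nb_stack(nb_sim_params(mean_occupancy = 5, epsilon = 2, n_frames = T,
                             height = side, width = side,
                             drift_px_per_frame = drift,
                             occupancy_map = bump, seed = seed))
}

test_that("register_stack recovers known drift and is idempotent", {
  # no drift: identity shifts, frames untouched
  g0 <- gen_nb_stack(nb_sim_params(5, 1, n_frames = 5, height = 32,
                                   width = 32, seed = 1))
  r0 <- register_stack(g0$stack)
  expect_true(all(r0$shifts == 0))
  expect_identical(r0$stack$frames, g0$stack$frames)

  # 1 px/frame drift along columns -> correction (0, -t)
  gd <- make_drift_stack(1)
  rd <- register_stack(gd$stack)
  expect_equal(rd$shifts[, "col"], -(0:7))
  expect_true(all(rd$shifts[, "row"] == 0))

  # brute-force search oracle agrees frame by frame
  ref <- gd$stack$frames[, , 1]
  for (t in c(3, 6)) {
    bf <- brute_force_shift(ref, gd$stack$frames[, , t], max_shift = 8)
    expect_equal(unname(rd$shifts[t, ]), bf)
  }

  # second pass on the registered stack finds nothing to correct
  rd2 <- register_stack(rd$stack)
  expect_true(all(rd2$shifts == 0))

  # all-zero stack: flagged, identity shifts
  z <- image_stack(array(0, dim = c(8, 8, 3)))
  rz <- register_stack(z)
  expect_true("no_signal" %in% rz$flags)
  expect_true(all(rz$shifts == 0))
})

test_that("pixel_moments uses the population convention and handles NA", {
  # constant stack
  cst <- image_stack(array(5, dim = c(4, 4, 10)))
  m <- pixel_moments(cst)
  expect_true(all(m$mean_map == 5) && all(m$var_map == 0))
  # two frames 0 and 2: mean 1, population variance 1
  two <- image_stack(array(c(rep(0, 4), rep(2, 4)), dim = c(2, 2, 2)))
  m2 <- pixel_moments(two)
  expect_true(all(m2$mean_map == 1) && all(m2$var_map == 1))
  # Poisson stack: mean and variance both near lambda at nearly all pixels
  g <- gen_nb_stack(nb_sim_params(1, 0, background_rate = 4,
                                  n_frames = 10000, height = 10, width = 10,
                                  seed = 2))
  mp <- pixel_moments(g$stack)
  expect_gte(mean(abs(mp$mean_map - 4) / 4 < 0.03 &
                    abs(mp$var_map - 4) / 4 < 0.1), 0.99)
  # pixels with < 2 valid frames are invalidated
  fr <- array(1, dim = c(2, 2, 3))
  fr[1, 1, 2:3] <- NA
  mn <- pixel_moments(image_stack(fr))
  expect_true(is.na(mn$mean_map[1, 1]) && is.na(mn$var_map[1, 1]))
  expect_equal(mn$mean_map[2, 2], 1)
})

test_that("apparent and molecular brightness follow B = var/mean, eps = B - 1", {
  mean_map <- matrix(c(2, 4, 0.05, 2), 2, 2)
  var_map <- matrix(c(2, 8, 0.05, 0), 2, 2)
  b <- apparent_brightness(mean_map, var_map)
  expect_equal(b[1, 1], 1) # pure Poisson
  expect_equal(b[2, 1], 2)
  expect_true(is.na(b[1, 2])) # below mean floor
  expect_equal(b[2, 2], 0) # zero variance
  # invariant: B * mean = var on analyzable pixels
  ok <- is.finite(b)
  expect_equal(b[ok] * mean_map[ok], var_map[ok])
  expect_error(apparent_brightness(matrix(0.01, 2, 2), matrix(1, 2, 2)),
               "no analyzable")
  expect_error(apparent_brightness(matrix(1, 2, 2), matrix(1, 3, 3)),
               "congruent")

  s <- molecular_brightness(matrix(1, 5, 5))
  expect_equal(s$center, 0)
  expect_error(molecular_brightness(matrix(1.2, 5, 5), reference_epsilon = 0),
               "non-zero")
  s2 <- molecular_brightness(matrix(1.4, 5, 5), reference_epsilon = 0.2)
  expect_equal(s2$ratio, 2)
})

test_that("simulated dimer doubles the estimated brightness", {
  mono <- gen_nb_stack(nb_sim_params(2, 0.2, n_frames = 2000, height = 32,
                                     width = 32, seed = 5))
  dimer <- gen_nb_stack(nb_sim_params(2, 0.4, n_frames = 2000, height = 32,
                                      width = 32, seed = 6))
  e_mono <- molecular_brightness(pixel_moments(mono$stack))
  e_dim <- molecular_brightness(pixel_moments(dimer$stack),
                                reference_epsilon = e_mono$pooled)
  expect_equal(e_mono$pooled, 0.2, tolerance = 0.05)
  expect_equal(e_dim$ratio, 2, tolerance = 0.1)
  # robust central estimate of B within 10% of 1.2
  b <- apparent_brightness(pixel_moments(mono$stack)$mean_map,
                           pixel_moments(mono$stack)$var_map)
  expect_equal(median(b, na.rm = TRUE), 1.2, tolerance = 0.1)
})

test_that("qc_stack applies the 10% mean-decay and convergence rules", {
  st <- gen_nb_stack(nb_sim_params(2, 0.2, n_frames = 200, height = 32,
                                   width = 32, seed = 1))
  q <- qc_stack(st$stack)
  expect_true(q$accepted)
  expect_lte(q$convergence_slope, -0.5)

  bl <- gen_nb_stack(nb_sim_params(2, 0.2, n_frames = 200, height = 32,
                                   width = 32, bleach_fraction = 0.2,
                                   seed = 2))
  qb <- qc_stack(bl$stack)
  expect_false(qb$accepted)
  expect_true("mean_decay" %in% qb$reasons)
  expect_gt(qb$mean_decay_fraction, 0.10)

  qs <- qc_stack(make_step_stack())
  expect_false(qs$accepted)
  expect_true("no_convergence" %in% qs$reasons)

  short <- gen_nb_stack(nb_sim_params(2, 0.2, n_frames = 10, height = 8,
                                      width = 8, seed = 3))
  qsh <- qc_stack(short$stack)
  expect_false(qsh$accepted)
  expect_identical(qsh$reasons, "short_stack")
})

test_that("nb_analyze runs the full pipeline on a clean stack", {
  g <- gen_nb_stack(nb_sim_params(2, 0.4, n_frames = 300, height = 48,
                                  width = 48, seed = 9))
  res <- nb_analyze(g$stack, region = 32)
  expect_true(res$qc$accepted)
  expect_equal(dim(res$maps$b_map), c(32, 32))
  expect_equal(res$epsilon$pooled, 0.4, tolerance = 0.15)
})
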