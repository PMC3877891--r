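# Synthetic-data generators: construction guarantees, reproducibility, and
# the analytic limits the simulators were designed around.

test_that("gen_nb_stack obeys its analytic limits", {
  # pure background: variance/mean -> 1 (shot noise only)
  g <- gen_nb_stack(nb_sim_params(mean_occupancy = 1, epsilon = 0,
                                  background_rate = 2, n_frames = 2000,
                                  height = 16, width = 16, seed = 1))
  mom <- pixel_moments(g$stack)
  expect_equal(mean(mom$var_map / mom$mean_map), 1, tolerance = 0.02)
  expect_equal(g$truth$apparent_brightness, 1)

  # B = 1 + eps from the law of total variance
  g2 <- gen_nb_stack(nb_sim_params(mean_occupancy = 2, epsilon = 0.2,
                                   n_frames = 5000, height = 24, width = 24,
                                   seed = 2))
  expect_equal(g2$truth$apparent_brightness, 1.2)
  mom2 <- pixel_moments(g2$stack)
  pooled_b <- sum(mom2$var_map) / sum(mom2$mean_map)
  expect_equal(pooled_b, 1.2, tolerance = 0.05)

  # bleach schedule: last frame mean ~ 0.8x first
  g3 <- gen_nb_stack(nb_sim_params(mean_occupancy = 10, epsilon = 1,
                                   n_frames = 100, height = 32, width = 32,
                                   bleach_fraction = 0.2, seed = 3))
  fm <- apply(g3$stack$frames, 3, mean)
  expect_equal(fm[100] / fm[1], 0.8, tolerance = 0.05)
})

test_that("nb_sim_params validates its invariants", {
  expect_error(nb_sim_params(-1, 0.2), "mean_occupancy")
  expect_error(nb_sim_params(1, 0.2, n_frames = 1), ">= 2")
  expect_error(nb_sim_params(1, 0.2, n_frames = 2.5), "integer")
  expect_error(nb_sim_params(1, 0.2, bleach_fraction = 1), "< 1")
  expect_error(nb_sim_params(1, 0.2, height = 0), "zero-area")
})

test_that("generators are bit-reproducible for a fixed seed", {
  a <- gen_nb_stack(nb_sim_params(2, 0.3, n_frames = 20, height = 8,
                                  width = 8, seed = 42))
  b <- gen_nb_stack(nb_sim_params(2, 0.3, n_frames = 20, height = 8,
                                  width = 8, seed = 42))
  expect_identical(a$stack$frames, b$stack$frames)
  s1 <- gen_spot_image(spot_sim_params(5, seed = 7))
  s2 <- gen_spot_image(spot_sim_params(5, seed = 7))
  expect_identical(s1$image, s2$image)
  d1 <- gen_dose_response("hill", list(ec50 = 10, n = 2), c(1, 3, 10, 30),
                          noise_sd = 0.05, seed = 5)
  d2 <- gen_dose_response("hill", list(ec50 = 10, n = 2), c(1, 3, 10, 30),
                          noise_sd = 0.05, seed = 5)
  expect_identical(d1$response, d2$response)
  p1 <- gen_panel(seed = 3); p2 <- gen_panel(seed = 3)
  expect_identical(p1$ic50, p2$ic50)
  # and the global RNG stream is left untouched
  set.seed(1); x <- runif(1)
  set.seed(1); invisible(gen_panel(seed = 99)); y <- runif(1)
  expect_identical(x, y)
})

test_that("gen_spot_image plants what it promises", {
  sp <- gen_spot_image(spot_sim_params(n_spots = 12, seed = 1))
  expect_equal(nrow(sp$centers), 12)
  d <- as.matrix(dist(sp$centers))
  diag(d) <- Inf
  expect_true(min(d) >= sp$params$min_separation)

  # no spots, no blobs -> pure background field (deterministic)
  bg <- gen_spot_image(spot_sim_params(n_spots = 0, noise_sd = 0, seed = 1))
  expect_true(max(bg$image) - min(bg$image) <=
                bg$params$gradient_amplitude + 1e-9)

  # blobs are present in the image but not in the spot list
  bl <- gen_spot_image(spot_sim_params(n_spots = 3, n_large_blobs = 1,
                                       seed = 2))
  expect_equal(nrow(bl$centers), 3)
  expect_equal(nrow(bl$blob_centers), 1)
  expect_gt(max(bl$image), bl$params$background + bl$params$blob_amplitude / 2)

  # impossible separation errors out
  expect_error(gen_spot_image(spot_sim_params(n_spots = 200,
                                              min_separation = 30,
                                              seed = 1)),
               "cannot place")
})

test_that("gen_cell_image returns a consistent ring fixture", {
  cell <- gen_cell_image(rim_radius = 15, rim_width = 4)
  expect_true(all(dim(cell$image) == cell$size))
  expect_gte(mean(cell$image[cell$rim_mask] > cell$background), 0.99)
  expect_false(cell$degenerate_contrast)
  expect_equal(nrow(cell$seeds), 2)
  expect_true(cell$rim_mask[cbind(cell$seeds$row, cell$seeds$col)][1] == FALSE)

  flat <- gen_cell_image(rim_radius = 15, rim_width = 4, rim_intensity = 10,
                         background = 10)
  expect_true(flat$degenerate_contrast)
  expect_true(any(flat$rim_mask))

  expect_error(gen_cell_image(rim_radius = 100, rim_width = 4, size = 50),
               "fit")
  expect_error(gen_cell_image(rim_radius = 10, rim_width = 0.5), "rim_width")
})

test_that("gen_dose_response reproduces its model means", {
  conc <- c(1, 3, 10, 30, 100)
  tab <- gen_dose_response("hill", list(ec50 = 10, n = 2), conc,
                           n_reps = 2, noise_sd = 0)
  expect_equal(tab$response,
               rep(hill_curve(conc, 10, 2), each = 2))
  # c = EC50 sits at the curve midpoint
  mid <- gen_dose_response("hill", list(ec50 = 10, n = 2), 10, n_reps = 1,
                           noise_sd = 0)
  expect_equal(mid$response, 0.5)
  # oligomer model means equal the closed-form kill probability
  p <- oligomer_params(kd = 5.1, theta_mean = 0.2, theta_sigma = 0.6)
  tab2 <- gen_dose_response("oligomer", p, conc, n_reps = 1, noise_sd = 0)
  expect_equal(tab2$response, permeabilization_probability(conc, p))
  # noise is truncated into [0, 1] for fractions
  tab3 <- gen_dose_response("hill", list(ec50 = 10, n = 2), conc,
                            n_reps = 50, noise_sd = 0.5, seed = 1)
  expect_true(all(tab3$response >= 0 & tab3$response <= 1))
  expect_error(gen_dose_response("hill", list(ec50 = 10, n = 2), c(-1, 2, 3, 4)),
               "> 0")
  expect_error(gen_dose_response("banana", list(), conc))
})

test_that("gen_uptake_trace matches the closed form and its limits", {
  up <- uptake_params(k_on = 0.002, k_int = 0.005, S = 50, c = 1)
  tg <- seq(0, 120, by = 2)
  tr <- gen_uptake_trace(up, tg, noise_sd = 0)
  expect_equal(tr$intensity, solve_uptake(up, tg)$intensity)
  # S = 0 -> flat background
  up0 <- uptake_params(k_on = 0.002, k_int = 0.005, S = 0, c = 1,
                       background = 3)
  expect_equal(unique(gen_uptake_trace(up0, tg)$intensity), 3)
  expect_error(gen_uptake_trace(up, c(-1, 0, 1)), "negative")
})

test_that("gen_panel hits its correlation target on average", {
  expect_error(gen_panel(n_lines = 2), "n_lines")
  expect_error(gen_panel(rho = 1), "rho")
  tab <- gen_panel(seed = 1)
  expect_equal(nrow(tab), 21)
  expect_true(all(table(tab$cell_line) == 3))
  expect_true(all(tab$ic50 > 0) && all(tab$marker_level >= 0))
  # Monte-Carlo over seeds: mean sample r within 0.05 of the target -0.9
  rs <- vapply(1:400, function(s) {
    p <- gen_panel(seed = s)
    ag <- aggregate(cbind(ic50, marker_level) ~ cell_line, p, mean)
    cor(log(ag$ic50), ag$marker_level)
  }, numeric(1))
  expect_lt(abs(mean(rs) - (-0.9)), 0.05)
  # rho = 0 gives near-zero mean correlation
  rs0 <- vapply(1:400, function(s) {
    p <- gen_panel(rho = 0, seed = s)
    ag <- aggregate(cbind(ic50, marker_level) ~ cell_line, p, mean)
    cor(log(ag$ic50), ag$marker_level)
  }, numeric(1))
  expect_lt(abs(mean(rs0)), 0.05)
})
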