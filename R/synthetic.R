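# Synthetic-data generators. Every analysis input the package consumes can be
# simulated here with known ground truth, so the whole pipeline is testable
# without microscope or cytometer data.

#' Parameters for simulating an N&B image stack
#'
#' The simulator uses the fast-diffusion limit: the emitter occupancy of every
#' pixel is re-drawn independently in every frame from a Poisson distribution
#' with the stated mean. Detected counts are Poisson around
#' `occupancy * epsilon + background_rate`. Under this model the apparent
#' brightness has the closed form `B = 1 + epsilon` when the background is
#' zero (law of total variance), which provides the analytic oracle the N&B
#' estimators are validated against. With background,
#' `B = 1 + n * epsilon^2 / (n * epsilon + background_rate)`.
#'
#' @param mean_occupancy expected emitters per pixel per frame (>= 0).
#' @param epsilon molecular brightness: expected counts emitted per emitter
#'   per pixel dwell (>= 0).
#' @param background_rate Poisson background counts per pixel per frame.
#' @param n_frames number of frames (integer >= 2).
#' @param height,width frame size in pixels.
#' @param bleach_fraction fractional monotone decay of the expected count over
#'   the stack, applied as a multiplicative linear schedule from 1 down to
#'   `1 - bleach_fraction` (0 <= value < 1).
#' @param drift_px_per_frame lateral drift rate along columns; applied as
#'   cumulative integer pixel shifts of the occupancy pattern.
#' @param occupancy_map optional `height x width` non-negative multiplier
#'   giving the occupancy spatial pattern (default uniform). A non-uniform
#'   map is what makes drift observable and registerable.
#' @param seed RNG seed recorded in the output metadata.
#' @return An object of class `nb_sim_params`.
#' @export
nb_sim_params <- function(mean_occupancy, epsilon, background_rate = 0,
                          n_frames = 100, height = 64, width = 64,
                          bleach_fraction = 0, drift_px_per_frame = 0,
                          occupancy_map = NULL, seed = NULL) {
  assert_scalar_num(mean_occupancy, "mean_occupancy", 0)
  assert_scalar_num(epsilon, "epsilon", 0)
  assert_scalar_num(background_rate, "background_rate", 0)
  if (!is.numeric(n_frames) || length(n_frames) != 1 ||
      n_frames != round(n_frames))
    stop("'n_frames' must be an integer")
  if (n_frames < 2) stop("'n_frames' must be >= 2")
  if (height < 1 || width < 1) stop("zero-area image")
  assert_scalar_num(bleach_fraction, "bleach_fraction", 0)
  if (bleach_fraction >= 1) stop("'bleach_fraction' must be < 1")
  if (!is.null(occupancy_map)) {
    if (!is.matrix(occupancy_map) || nrow(occupancy_map) != height ||
        ncol(occupancy_map) != width || any(occupancy_map < 0))
      stop("'occupancy_map' must be a non-negative height x width matrix")
  }
  structure(list(mean_occupancy = mean_occupancy, epsilon = epsilon,
                 background_rate = background_rate,
                 n_frames = as.integer(n_frames),
                 height = as.integer(height), width = as.integer(width),
                 bleach_fraction = bleach_fraction,
                 drift_px_per_frame = drift_px_per_frame,
                 occupancy_map = occupancy_map, seed = seed),
            class = "nb_sim_params")
}

#' Simulate an N&B image stack with known ground truth
#'
#' @param params an [nb_sim_params()] object.
#' @return A list with elements `stack` (an [image_stack()]), `truth` (list
#'   with `epsilon`, `apparent_brightness` = expected B for the clean
#'   stationary configuration, `mean_count`, and `shifts`, the per-frame
#'   cumulative drift in pixels), and `params`.
#' @export
gen_nb_stack <- function(params) {
  stopifnot(inherits(params, "nb_sim_params"))
  p <- params
  H <- p$height; W <- p$width; T <- p$n_frames
  n_px <- H * W
  schedule <- 1 - p$bleach_fraction * (seq_len(T) - 1) / (T - 1)
  shifts <- as.integer(round(p$drift_px_per_frame * (seq_len(T) - 1)))
  map <- p$occupancy_map

  frames <- with_seed(p$seed, {
    if (is.null(map) && all(shifts == 0)) {
      # homogeneous fast path: one lambda per pixel-frame
      occ <- rpois(n_px * T, p$mean_occupancy)
      lam <- (occ * p$epsilon + p$background_rate) *
        rep(schedule, each = n_px)
      array(rpois(n_px * T, lam), dim = c(H, W, T))
    } else {
      if (is.null(map)) map <- matrix(1, H, W)
      out <- array(0, dim = c(H, W, T))
      for (t in seq_len(T)) {
        mt <- shift_matrix(map, 0, shifts[t], fill = 0)
        occ <- rpois(n_px, p$mean_occupancy * mt)
        out[, , t] <- rpois(n_px, schedule[t] *
                              (occ * p$epsilon + p$background_rate))
      }
      out
    }
  })

  mean_count <- p$mean_occupancy * p$epsilon + p$background_rate
  b_true <- if (mean_count > 0)
    1 + p$mean_occupancy * p$epsilon^2 / mean_count else NA_real_
  list(stack = image_stack(frames,
                           metadata = list(generator = "gen_nb_stack",
                                           seed = p$seed)),
       truth = list(epsilon = p$epsilon, apparent_brightness = b_true,
                    mean_count = mean_count, shifts = cbind(0L, shifts)),
       params = p)
}

# Shift matrix content by (dr, dc); exposed margin takes `fill`.
shift_matrix <- function(m, dr, dc, fill = NA_real_) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- seq_len(nr); sc <- seq_len(nc)
  r_dst <- sr + dr; c_dst <- sc + dc
  ok_r <- r_dst >= 1 & r_dst <= nr
  ok_c <- c_dst >= 1 & c_dst <= nc
  out[r_dst[ok_r], c_dst[ok_c]] <- m[sr[ok_r], sc[ok_c]]
  out
}

#' Parameters for the synthetic spot image
#'
#' @param n_spots number of Gaussian spots to plant.
#' @param spot_sigma spot width (px).
#' @param amplitude_range range from which spot amplitudes are drawn.
#' @param background base background level.
#' @param gradient_amplitude amplitude of a smooth diagonal background ramp.
#' @param n_large_blobs number of objects much larger than the top-hat scale
#'   (to exercise the size-selection step of the spot counter).
#' @param blob_radius radius (px) of the large blobs, modelled as smooth
#'   plateau discs with a soft logistic edge (an extended bright region, not
#'   a point emitter); the default diameter of 40 px is five times the
#'   default top-hat radius.
#' @param blob_amplitude amplitude of the large blobs.
#' @param min_separation minimum pairwise centre distance (px); defaults to
#'   `4 * spot_sigma`, the regime in which the default counter resolves all
#'   spots.
#' @param height,width image size.
#' @param noise_sd additive Gaussian noise level.
#' @param seed RNG seed.
#' @return An object of class `spot_sim_params`.
#' @export
spot_sim_params <- function(n_spots, spot_sigma = 2,
                            amplitude_range = c(50, 100), background = 10,
                            gradient_amplitude = 5, n_large_blobs = 0,
                            blob_radius = 20, blob_amplitude = 60,
                            min_separation = 4 * spot_sigma,
                            height = 128, width = 128, noise_sd = 0,
                            seed = NULL) {
  stopifnot(n_spots == round(n_spots), n_spots >= 0,
            n_large_blobs == round(n_large_blobs), n_large_blobs >= 0)
  assert_scalar_num(spot_sigma, "spot_sigma", 0, strict_lower = TRUE)
  assert_scalar_num(min_separation, "min_separation", 0)
  structure(list(n_spots = as.integer(n_spots), spot_sigma = spot_sigma,
                 amplitude_range = amplitude_range, background = background,
                 gradient_amplitude = gradient_amplitude,
                 n_large_blobs = as.integer(n_large_blobs),
                 blob_radius = blob_radius, blob_amplitude = blob_amplitude,
                 min_separation = min_separation,
                 height = as.integer(height), width = as.integer(width),
                 noise_sd = noise_sd, seed = seed),
            class = "spot_sim_params")
}

#' Simulate a punctate image with known spot centres
#'
#' Smooth background ramp + Gaussian spots + optional large blobs. The large
#' blobs are deliberately bigger than the counting pipeline's top-hat scale,
#' so a correct counter must not report them.
#'
#' @param params a [spot_sim_params()] object.
#' @return List with `image`, `centers` (n_spots x 2 matrix, (row, col)),
#'   `blob_centers`, and `params`.
#' @export
gen_spot_image <- function(params) {
  stopifnot(inherits(params, "spot_sim_params"))
  p <- params
  H <- p$height; W <- p$width
  margin <- ceiling(3 * p$spot_sigma) + 1
  if (2 * margin >= min(H, W))
    stop("spots do not fit inside the frame")
  rc <- outer(seq_len(H), rep(1, W)); cc <- outer(rep(1, H), seq_len(W))
  img <- p$background + p$gradient_amplitude * (rc + cc) / (H + W)
  with_seed(p$seed, {
    # blobs first (few and large), then spots keep clear of them
    blob_margin <- min(ceiling(p$blob_radius), floor(min(H, W) / 4))
    blob_centers <- place_points(p$n_large_blobs, H, W, blob_margin,
                                 2.5 * p$blob_radius)
    centers <- place_points(p$n_spots, H, W, margin, p$min_separation,
                            avoid = blob_centers,
                            avoid_sep = p$blob_radius + 4 * p$spot_sigma)
    if (p$n_spots > 0) {
      amps <- runif(p$n_spots, p$amplitude_range[1], p$amplitude_range[2])
      for (i in seq_len(p$n_spots))
        img <- img + amps[i] *
          exp(-((rc - centers[i, 1])^2 + (cc - centers[i, 2])^2) /
                (2 * p$spot_sigma^2))
    }
    if (p$n_large_blobs > 0) {
      edge <- 0.15 * p$blob_radius
      for (i in seq_len(p$n_large_blobs)) {
        d <- sqrt((rc - blob_centers[i, 1])^2 + (cc - blob_centers[i, 2])^2)
        img <- img + p$blob_amplitude * stats::plogis(-(d - p$blob_radius) / edge)
      }
    }
    if (p$noise_sd > 0)
      img <- img + matrix(rnorm(H * W, sd = p$noise_sd), H, W)
    list(image = img, centers = centers, blob_centers = blob_centers,
         params = p)
  })
}

place_points <- function(n, H, W, margin, min_sep, avoid = NULL,
                         avoid_sep = 0, max_tries = 2000) {
  pts <- matrix(numeric(0), 0, 2)
  if (n == 0) return(pts)
  tries <- 0
  while (nrow(pts) < n) {
    tries <- tries + 1
    if (tries > max_tries * n)
      stop("cannot place points at the requested separation")
    cand <- c(runif(1, margin + 1, H - margin), runif(1, margin + 1, W - margin))
    ok <- TRUE
    if (nrow(pts) > 0 &&
        min(sqrt(rowSums((pts - matrix(cand, nrow(pts), 2,
                                       byrow = TRUE))^2))) < min_sep)
      ok <- FALSE
    if (ok && !is.null(avoid) && nrow(avoid) > 0 &&
        min(sqrt(rowSums((avoid - matrix(cand, nrow(avoid), 2,
                                         byrow = TRUE))^2))) < avoid_sep)
      ok <- FALSE
    if (ok) pts <- rbind(pts, cand)
  }
  dimnames(pts) <- list(NULL, c("row", "col"))
  pts
}

#' Simulate a cell image with a rim-shaped membrane
#'
#' A ring of elevated intensity on a diffuse background, the fixture for the
#' seeded-watershed membrane segmentation. Returns the ground-truth rim mask
#' and one seed point inside and one outside the cell.
#'
#' @param rim_radius ring radius (px).
#' @param rim_width full width of the rim (px, >= 1).
#' @param rim_intensity absolute peak intensity of the rim. If it does not
#'   exceed `background` the image is flat and the result carries
#'   `degenerate_contrast = TRUE`.
#' @param background background level.
#' @param size frame side length; default fits the ring with margin.
#' @param noise_sd additive Gaussian noise level.
#' @param seed RNG seed.
#' @return List with `image`, `rim_mask` (logical matrix), `seeds`
#'   (data.frame row, col, label: 1 = cell interior, 2 = background),
#'   `degenerate_contrast`, and the call parameters.
#' @export
gen_cell_image <- function(rim_radius, rim_width = 4, rim_intensity = 100,
                           background = 10, size = NULL, noise_sd = 0,
                           seed = NULL) {
  if (rim_width < 1) stop("'rim_width' must be >= 1 px")
  assert_scalar_num(rim_radius, "rim_radius", 0, strict_lower = TRUE)
  size <- size %||% (2 * ceiling(rim_radius + 3 * rim_width) + 11)
  if (2 * (rim_radius + rim_width / 2) >= size)
    stop("rim does not fit inside the frame")
  ctr <- (size + 1) / 2
  rc <- outer(seq_len(size), rep(1, size))
  cc <- outer(rep(1, size), seq_len(size))
  d <- sqrt((rc - ctr)^2 + (cc - ctr)^2)
  amp <- rim_intensity - background
  degenerate <- amp <= 0
  prof_sigma <- rim_width / 2.355 # FWHM = rim_width
  img <- background + max(amp, 0) * exp(-(d - rim_radius)^2 /
                                          (2 * prof_sigma^2))
  if (noise_sd > 0)
    img <- img + with_seed(seed,
                           matrix(rnorm(size^2, sd = noise_sd), size, size))
  rim_mask <- abs(d - rim_radius) <= rim_width / 2
  seeds <- data.frame(row = c(round(ctr), 2),
                      col = c(round(ctr), 2),
                      label = c(1L, 2L))
  list(image = img, rim_mask = rim_mask, seeds = seeds,
       degenerate_contrast = degenerate,
       rim_radius = rim_radius, rim_width = rim_width,
       rim_intensity = rim_intensity, background = background, size = size)
}

#' Simulate a dose-response table
#'
#' Responses are the model mean (Hill curve or the oligomer-threshold kill
#' probability) plus additive Gaussian replicate noise, truncated to `[0, 1]`
#' for fraction-type responses and to non-negative values for intensities.
#'
#' @param model `"hill"` or `"oligomer"`.
#' @param model_params for `"hill"`: list with `ec50`, `n`, and optionally
#'   `top` (1) and `bottom` (0); for `"oligomer"`: an [oligomer_params()]
#'   object.
#' @param concentrations positive concentration vector (uM).
#' @param n_reps replicates per concentration (default 3, the usual plate
#'   layout).
#' @param noise_sd replicate noise standard deviation.
#' @param kind response kind: `"killing"`, `"viability"` (fractions) or
#'   `"binding"` (intensity-like, truncated at 0 only).
#' @param seed RNG seed.
#' @return A `data.frame` of class `dose_response_table` with columns
#'   `concentration`, `response`, `replicate`, `kind`.
#' @export
gen_dose_response <- function(model = c("hill", "oligomer"), model_params,
                              concentrations, n_reps = 3, noise_sd = 0,
                              kind = NULL, seed = NULL) {
  model <- match.arg(model)
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  assert_scalar_num(noise_sd, "noise_sd", 0)
  mu <- switch(model,
    hill = {
      mp <- model_params
      hill_curve(concentrations, mp$ec50, mp$n,
                 top = mp$top %||% 1, bottom = mp$bottom %||% 0)
    },
    oligomer = permeabilization_probability(concentrations, model_params))
  kind <- kind %||% if (model == "oligomer") "killing" else "killing"
  fraction <- kind %in% c("killing", "viability")
  resp <- with_seed(seed, {
    r <- rep(mu, each = n_reps) +
      rnorm(length(mu) * n_reps, sd = noise_sd)
    if (fraction) pmin(1, pmax(0, r)) else pmax(0, r)
  })
  out <- data.frame(concentration = rep(concentrations, each = n_reps),
                    response = resp,
                    replicate = rep(seq_len(n_reps), length(concentrations)),
                    kind = kind)
  class(out) <- c("dose_response_table", "data.frame")
  attr(out, "model") <- model
  attr(out, "seed") <- seed
  out
}

#' Simulate an uptake trace
#'
#' Closed-form two-compartment solution (see [solve_uptake()]) plus Gaussian
#' noise, truncated at zero.
#'
#' @param params an [uptake_params()] object.
#' @param t_grid increasing time grid starting at 0 (s).
#' @param noise_sd noise standard deviation (a.u.).
#' @param seed RNG seed.
#' @return An `uptake_trace` data.frame (`time`, `intensity`).
#' @export
gen_uptake_trace <- function(params, t_grid, noise_sd = 0, seed = NULL) {
  trace <- solve_uptake(params, t_grid)
  if (noise_sd > 0)
    trace$intensity <- with_seed(seed, pmax(0, trace$intensity +
        rnorm(nrow(trace), sd = noise_sd)))
  attr(trace, "seed") <- seed
  trace
}

#' Simulate a cell-line panel table
#'
#' Line-level `(log IC50, marker level)` pairs are drawn from a bivariate
#' normal with the requested correlation; small replicate noise is added on
#' top, emulating a panel of cell lines measured in independent replicates.
#'
#' @param n_lines number of cell lines (>= 3; default 7).
#' @param n_reps replicates per line (default 3).
#' @param rho target correlation between log IC50 and marker level
#'   (`|rho| < 1`).
#' @param log_ic50_mean,log_ic50_sd latent log-IC50 distribution
#'   (defaults `log(8)`, 0.8 — IC50s of a few to a few tens of uM).
#' @param marker_mean,marker_sd latent marker-level distribution (a.u.).
#' @param rep_sdlog_ic50,rep_sd_marker replicate noise scales.
#' @param condition condition label attached to all rows.
#' @param seed RNG seed.
#' @return A `data.frame` of class `panel_table` with columns `cell_line`,
#'   `replicate`, `condition`, `ic50`, `marker_level`. The latent line-level
#'   values are attached as attribute `latent`.
#' @export
gen_panel <- function(n_lines = 7, n_reps = 3, rho = -0.9,
                      log_ic50_mean = log(8), log_ic50_sd = 0.8,
                      marker_mean = 100, marker_sd = 25,
                      rep_sdlog_ic50 = 0.05, rep_sd_marker = 3,
                      condition = "normoxia", seed = NULL) {
  if (n_lines < 3) stop("'n_lines' must be >= 3")
  if (abs(rho) >= 1) stop("'rho' must satisfy |rho| < 1")
  with_seed(seed, {
    z1 <- rnorm(n_lines)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_lines)
    log_ic50 <- log_ic50_mean + log_ic50_sd * z1
    marker <- marker_mean + marker_sd * z2
    lines <- sprintf("line%02d", seq_len(n_lines))
    out <- data.frame(
      cell_line = rep(lines, each = n_reps),
      replicate = rep(seq_len(n_reps), n_lines),
      condition = condition,
      ic50 = exp(rep(log_ic50, each = n_reps) +
                   rnorm(n_lines * n_reps, sd = rep_sdlog_ic50)),
      marker_level = pmax(0, rep(marker, each = n_reps) +
                            rnorm(n_lines * n_reps, sd = rep_sd_marker)))
    class(out) <- c("panel_table", "data.frame")
    attr(out, "latent") <- data.frame(cell_line = lines,
                                      log_ic50 = log_ic50, marker = marker)
    attr(out, "seed") <- seed
    out
  })
}
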