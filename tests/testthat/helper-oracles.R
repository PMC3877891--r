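# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: brute-force shift search for registration, an RK4
# integrator for the uptake ODE, and direct formula arithmetic elsewhere.

# Brute-force integer-shift search: maximize overlap correlation between a
# reference frame and a candidate frame shifted by (dr, dc).
brute_force_shift <- function(ref, frame, max_shift = 6) {
  best <- c(0, 0); best_cor <- -Inf
  for (dr in -max_shift:max_shift) {
    for (dc in -max_shift:max_shift) {
      shifted <- raftperm:::shift_matrix(frame, dr, dc, fill = NA_real_)
      ok <- !is.na(shifted)
      if (sum(ok) < 16) next
      a <- ref[ok]; b <- shifted[ok]
      if (sd(a) == 0 || sd(b) == 0) next
      cc <- cor(a, b)
      if (cc > best_cor) { best_cor <- cc; best <- c(dr, dc) }
    }
  }
  best
}

# Fixed-step RK4 integration of the two-compartment uptake ODE:
# B' = a*(S) - (a + k_int)*B ... written in its mechanistic form
# B' = k_on*c*S - (k_on*c + k_int)*B, I' = k_int*B.
rk4_uptake <- function(params, t_grid, dt = 0.01) {
  a <- params$k_on * params$c
  deriv <- function(state) {
    c(a * params$S - (a + params$k_int) * state[1],
      params$k_int * state[1])
  }
  out <- numeric(length(t_grid))
  state <- c(0, 0)
  t_now <- 0
  ti <- 1
  if (t_grid[1] == 0) { out[1] <- 0; ti <- 2 }
  t_end <- max(t_grid)
  while (t_now < t_end - 1e-12 && ti <= length(t_grid)) {
    h <- min(dt, t_grid[ti] - t_now)
    k1 <- deriv(state)
    k2 <- deriv(state + h / 2 * k1)
    k3 <- deriv(state + h / 2 * k2)
    k4 <- deriv(state + h * k3)
    state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t_now <- t_now + h
    if (abs(t_now - t_grid[ti]) < 1e-9) {
      out[ti] <- sum(state)
      ti <- ti + 1
    }
  }
  params$alpha * out + params$background
}

# A stack with an abrupt mid-acquisition illumination step (bright enough
# that the nonstationarity is not buried under shot noise).
make_step_stack <- function(T = 200, side = 32, factor = 1.5, seed = 11) {
  a <- gen_nb_stack(nb_sim_params(20, 0.2, n_frames = T, height = side,
                                  width = side, seed = seed))$stack$frames
  b <- gen_nb_stack(nb_sim_params(20, 0.2, n_frames = T, height = side,
                                  width = side, seed = seed + 1))$stack$frames
  half <- T / 2
  image_stack(array(c(a[, , 1:half], round(b[, , 1:half] * factor)),
                    dim = c(side, side, T)))
}

# Match detected coordinates against planted centers within a tolerance;
# returns TRUE when the matching is one-to-one and complete.
spots_match <- function(found, truth, tol = 3) {
  if (nrow(found) != nrow(truth)) return(FALSE)
  if (nrow(truth) == 0) return(TRUE)
  d <- sqrt(outer(found[, 1], truth[, 1], "-")^2 +
              outer(found[, 2], truth[, 2], "-")^2)
  all(apply(d, 2, min) <= tol) && all(apply(d, 1, min) <= tol)
}
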