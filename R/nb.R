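# Number & Brightness analysis: registration, per-pixel moments, apparent and
# molecular brightness, and stack quality control.

#' Register an image stack by integer lateral shifts
#'
#' Each frame is aligned to the first frame by the integer translation that
#' maximizes the (mean-subtracted, cyclic) cross-correlation, computed by FFT.
#' Shifts are restricted to whole pixels so the Poisson photon-count
#' statistics of individual pixels are preserved; pixels exposed at frame
#' edges by the shift are set to `NA` and excluded from all downstream
#' moments.
#'
#' @param stack an [image_stack()].
#' @param max_shift largest |shift| considered per axis (px); defaults to a
#'   quarter of the frame size.
#' @param min_peak_z required z-score of the correlation peak against the
#'   bulk of the correlation surface (default 5). A featureless frame has no
#'   significant peak; chasing its noise maximum would invent shifts, so
#'   such frames keep the identity shift and are flagged.
#' @return List with `stack` (registered; invalid pixels `NA`), `shifts`
#'   (T x 2 matrix of applied (row, col) corrections; the first row is 0), and
#'   `flags` (character vector, e.g. `"no_signal"` for frames without
#'   registration signal, which keep the identity shift).
#' @export
register_stack <- function(stack, max_shift = NULL, min_peak_z = 5) {
  stopifnot(inherits(stack, "image_stack"))
  fr <- stack$frames
  d <- dim(fr)
  H <- d[1]; W <- d[2]; T <- d[3]
  max_shift <- max_shift %||% floor(min(H, W) / 4)
  ref <- fr[, , 1]
  ref[is.na(ref)] <- mean(ref, na.rm = TRUE)
  ref_c <- ref - mean(ref)
  flags <- character(0)
  shifts <- matrix(0L, T, 2, dimnames = list(NULL, c("row", "col")))
  if (sd(ref_c) == 0) {
    flags <- c(flags, "no_signal")
    return(list(stack = stack, shifts = shifts, flags = flags))
  }
  F_ref <- fft(ref_c)
  for (t in 2:T) {
    g <- fr[, , t]
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    g_c <- g - mean(g)
    if (sd(g_c) == 0) {
      flags <- c(flags, sprintf("no_signal_frame_%d", t))
      next
    }
    cc <- Re(fft(F_ref * Conj(fft(g_c)), inverse = TRUE))
    # peak significance: a real pattern stands far above the noise floor
    z <- (max(cc) - median(cc)) / max(mad(cc), .Machine$double.eps)
    if (z < min_peak_z) {
      flags <- c(flags, sprintf("no_signal_frame_%d", t))
      next
    }
    # wrap lags to signed shifts and restrict the search window
    lag_r <- c(0:(H - 1)); lag_r[lag_r > H / 2] <- lag_r[lag_r > H / 2] - H
    lag_c <- c(0:(W - 1)); lag_c[lag_c > W / 2] <- lag_c[lag_c > W / 2] - W
    ok <- outer(abs(lag_r) <= max_shift, abs(lag_c) <= max_shift)
    cc[!ok] <- -Inf
    best <- arrayInd(which.max(cc), dim(cc))
    shifts[t, ] <- c(lag_r[best[1]], lag_c[best[2]])
  }
  for (t in seq_len(T)) {
    if (any(shifts[t, ] != 0))
      fr[, , t] <- shift_matrix(fr[, , t], shifts[t, 1], shifts[t, 2],
                                fill = NA_real_)
  }
  stack$frames <- fr
  stack$metadata$registered <- TRUE
  list(stack = stack, shifts = shifts, flags = flags)
}

#' Per-pixel temporal mean and variance of a stack
#'
#' Population variance (denominator T) over the valid (non-`NA`) frames of
#' every pixel, the convention used for brightness maps; with typical stack
#' lengths (T = 100) the difference from the sample variance is 1%.
#'
#' @param stack an [image_stack()] (registered if drift is present).
#' @return List with `mean_map` and `var_map`; pixels with fewer than 2 valid
#'   frames are `NA` in both.
#' @export
pixel_moments <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  fr <- stack$frames
  d <- dim(fr)
  x <- matrix(fr, d[1] * d[2], d[3])
  if (anyNA(x)) {
    valid <- !is.na(x)
    n <- rowSums(valid)
    x0 <- x; x0[!valid] <- 0
    m <- rowSums(x0) / n
    v <- rowSums(x0^2) / n - m^2
    bad <- n < 2
    m[bad] <- NA_real_; v[bad] <- NA_real_
  } else {
    m <- rowMeans(x)
    v <- rowMeans(x^2) - m^2
  }
  v <- pmax(v, 0) # guard tiny negative rounding residue
  list(mean_map = matrix(m, d[1], d[2]), var_map = matrix(v, d[1], d[2]))
}

#' Apparent brightness map
#'
#' `B = sigma^2 / <k>` per pixel. Pixels whose mean count is at or below
#' `mean_floor` are excluded (`NA`): near-empty pixels make the ratio blow
#' up without carrying brightness information.
#'
#' @param mean_map,var_map congruent matrices from [pixel_moments()].
#' @param mean_floor minimum mean count for a pixel to be analyzable
#'   (default 0.1).
#' @return The apparent-brightness matrix.
#' @export
apparent_brightness <- function(mean_map, var_map, mean_floor = 0.1) {
  if (!all(dim(mean_map) == dim(var_map)))
    stop("mean and variance maps must be congruent")
  b <- var_map / mean_map
  b[is.na(mean_map) | mean_map <= mean_floor] <- NA_real_
  if (all(is.na(b))) stop("no analyzable pixels (all means below floor)")
  b
}

#' Molecular brightness summary
#'
#' Converts apparent brightness to molecular brightness `epsilon = B - 1`
#' (photon-counting convention: a pure shot-noise pixel has B = 1, so epsilon
#' is the photons per diffusing unit per dwell) and summarizes it over the
#' analysis region with a robust centre (median) and spread (MAD), plus the
#' pooled estimate `sum(var - mean)/sum(mean)`, which is the minimum-variance
#' choice for a spatially homogeneous region. If a monomer reference epsilon
#' is supplied, the oligomerization ratio `epsilon / epsilon_ref` is also
#' returned (2 for a pure dimer).
#'
#' @param b_map apparent-brightness matrix, or a list with `mean_map` and
#'   `var_map` (needed for the pooled estimate; if only `b_map` is given the
#'   pooled estimate equals the mean of `B - 1`).
#' @param reference_epsilon optional monomer reference (> 0).
#' @param negative_tolerance warn if the central epsilon is below minus this
#'   value (over-subtracted background or miscalibration).
#' @return Object of class `epsilon_summary`: `center`, `spread`, `pooled`,
#'   `mean`, `n`, `ratio` (or `NA`), `epsilon_map`.
#' @export
molecular_brightness <- function(b_map, reference_epsilon = NULL,
                                 negative_tolerance = 0.05) {
  maps <- NULL
  if (is.list(b_map) && !is.null(b_map$mean_map)) {
    maps <- b_map
    b_map <- apparent_brightness(maps$mean_map, maps$var_map)
  }
  eps <- b_map - 1
  ok <- is.finite(eps)
  if (!any(ok)) stop("no analyzable pixels")
  center <- median(eps[ok])
  pooled <- if (!is.null(maps)) {
    keep <- is.finite(b_map)
    sum(maps$var_map[keep] - maps$mean_map[keep]) / sum(maps$mean_map[keep])
  } else mean(eps[ok])
  if (center < -negative_tolerance)
    warning("negative molecular brightness: background over-subtraction?")
  ratio <- NA_real_
  if (!is.null(reference_epsilon)) {
    if (reference_epsilon == 0) stop("reference epsilon must be non-zero")
    ratio <- pooled / reference_epsilon
  }
  structure(list(center = center, spread = mad(eps[ok]), pooled = pooled,
                 mean = mean(eps[ok]), n = sum(ok), ratio = ratio,
                 epsilon_map = eps),
            class = "epsilon_summary")
}

#' @export
print.epsilon_summary <- function(x, ...) {
  cat(sprintf("molecular brightness: median %.4f (MAD %.4f), pooled %.4f, n = %d px\n",
              x$center, x$spread, x$pooled, x$n))
  if (!is.na(x$ratio))
    cat(sprintf("  oligomerization ratio vs reference: %.3f\n", x$ratio))
  invisible(x)
}

#' Stack quality control
#'
#' Applies the two acquisition QC rules for N&B stacks: (a) the image mean
#' must not decrease by more than 10% over the stack (stage shift /
#' photobleaching), measured as the relative drop between the mean of the
#' first and last deciles of frame means; (b) the per-pixel cumulative-mean
#' estimator must converge: the spatially averaged squared deviation of the
#' prefix mean from the full-stack mean must decay with a log-log slope of at
#' most `slope_threshold` in the prefix length (a stationary signal gives
#' about -1; trends and step changes plateau near 0).
#'
#' @param stack an [image_stack()] with at least 20 frames (shorter stacks
#'   are rejected as not evaluable with reason `"short_stack"`).
#' @param mean_decay_threshold maximum tolerated relative mean decrease
#'   (default 0.10).
#' @param slope_threshold maximum tolerated convergence slope (default -0.5).
#' @param n_prefix number of prefix lengths examined (default 8, log-spaced
#'   up to T/2).
#' @return Object of class `stack_qc`: `accepted`, `mean_decay_fraction`,
#'   `convergence_slope`, `reasons`.
#' @export
qc_stack <- function(stack, mean_decay_threshold = 0.10,
                     slope_threshold = -0.5, n_prefix = 8) {
  stopifnot(inherits(stack, "image_stack"))
  fr <- stack$frames
  T <- dim(fr)[3]
  if (T < 20) {
    return(structure(list(accepted = FALSE, mean_decay_fraction = NA_real_,
                          convergence_slope = NA_real_,
                          reasons = "short_stack"), class = "stack_qc"))
  }
  reasons <- character(0)
  x <- matrix(fr, dim(fr)[1] * dim(fr)[2], T)
  frame_means <- colMeans(x, na.rm = TRUE)
  dec <- max(2L, floor(T / 10))
  first <- mean(frame_means[seq_len(dec)])
  last <- mean(frame_means[(T - dec + 1):T])
  decay <- (first - last) / first
  if (is.finite(decay) && decay > mean_decay_threshold)
    reasons <- c(reasons, "mean_decay")

  # convergence of the cumulative-mean estimator
  prefixes <- unique(round(exp(seq(log(max(10, T / 50)), log(T / 2),
                                   length.out = n_prefix))))
  prefixes <- prefixes[prefixes >= 2]
  full_mean <- rowMeans(x, na.rm = TRUE)
  vv <- numeric(length(prefixes))
  x0 <- x; x0[is.na(x0)] <- 0
  nv <- matrix(as.numeric(!is.na(x)), nrow(x), ncol(x))
  csum <- 0; ccnt <- 0; prev <- 0L; k <- 1
  for (i in seq_along(prefixes)) {
    idx <- (prev + 1):prefixes[i]
    csum <- csum + rowSums(x0[, idx, drop = FALSE])
    ccnt <- ccnt + rowSums(nv[, idx, drop = FALSE])
    prev <- prefixes[i]
    m_n <- csum / pmax(ccnt, 1)
    vv[i] <- mean((m_n - full_mean)^2, na.rm = TRUE)
  }
  slope <- NA_real_
  if (all(vv < .Machine$double.eps * 100)) {
    # perfectly constant stack: converged by definition
    slope <- -Inf
  } else if (any(vv <= 0)) {
    reasons <- c(reasons, "no_convergence")
  } else {
    slope <- unname(coef(lm(log(vv) ~ log(prefixes)))[2])
    if (!is.finite(slope) || slope > slope_threshold)
      reasons <- c(reasons, "no_convergence")
  }
  structure(list(accepted = length(reasons) == 0,
                 mean_decay_fraction = decay,
                 convergence_slope = slope, reasons = reasons),
            class = "stack_qc")
}

#' @export
print.stack_qc <- function(x, ...) {
  cat(sprintf("stack QC: %s\n", if (x$accepted) "ACCEPTED" else "REJECTED"))
  cat(sprintf("  mean decay fraction: %.4f\n  convergence slope: %.3f\n",
              x$mean_decay_fraction, x$convergence_slope))
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

#' Full N&B analysis of a stack
#'
#' Convenience pipeline: registration, QC, central-region cropping, moments,
#' apparent brightness and the molecular-brightness summary.
#'
#' @param stack an [image_stack()].
#' @param region side of the central analysis square (default 128 px).
#' @param reference_epsilon optional monomer reference for the
#'   oligomerization ratio.
#' @param register run registration first (default TRUE).
#' @param mean_floor passed to [apparent_brightness()].
#' @return List with `qc`, `shifts`, `maps` (mean/var/B), `epsilon`
#'   (the [molecular_brightness()] summary).
#' @export
nb_analyze <- function(stack, region = 128, reference_epsilon = NULL,
                       register = TRUE, mean_floor = 0.1) {
  shifts <- NULL
  if (register) {
    reg <- register_stack(stack)
    stack <- reg$stack
    shifts <- reg$shifts
  }
  qc <- qc_stack(stack)
  cropped <- central_region(stack, region)
  mom <- pixel_moments(cropped)
  b <- apparent_brightness(mom$mean_map, mom$var_map, mean_floor = mean_floor)
  eps <- molecular_brightness(list(mean_map = mom$mean_map,
                                   var_map = mom$var_map),
                              reference_epsilon = reference_epsilon)
  list(qc = qc, shifts = shifts,
       maps = list(mean_map = mom$mean_map, var_map = mom$var_map, b_map = b),
       epsilon = eps)
}
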