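# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. A NULL seed uses (and advances) the global stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  if (x > upper)
    stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}

# Offsets (dr, dc) of a disk structuring element of the given radius.
disk_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  keep <- g$dr^2 + g$dc^2 <= radius^2 + 1e-9
  list(dr = as.integer(g$dr[keep]), dc = as.integer(g$dc[keep]))
}

gauss_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 1-D convolution of every column with kernel k, replicate padding.
conv_cols <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  nr <- nrow(m)
  mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
              m[rep(nr, r), , drop = FALSE])
  out <- matrix(0, nr, ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * mp[j:(j + nr - 1L), , drop = FALSE]
  out
}

# Separable Gaussian smoothing with replicate boundary handling.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gauss_kernel_1d(sigma)
  t(conv_cols(t(conv_cols(img, k)), k))
}

# Gradient magnitude by central differences (replicate edges).
gradient_magnitude <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gr <- (img[c(2:nr, nr), , drop = FALSE] -
           img[c(1, 1:(nr - 1)), , drop = FALSE]) / 2
  gc <- (img[, c(2:nc, nc), drop = FALSE] -
           img[, c(1, 1:(nc - 1)), drop = FALSE]) / 2
  sqrt(gr^2 + gc^2)
}

# Grey-scale opening with a disk structuring element.
grey_opening <- function(img, radius) {
  se <- disk_offsets(radius)
  er <- cpp_grey_morph(img, se$dr, se$dc, dilate = FALSE)
  cpp_grey_morph(er, se$dr, se$dc, dilate = TRUE)
}
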