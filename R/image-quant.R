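# 2-D image quantification: seeded-watershed membrane masking, background-
# corrected membrane intensity, bright-spot counting, colocalization and
# propidium-iodide positivity.

#' Seeded watershed membrane segmentation
#'
#' Runs Meyer's flooding watershed from manually placed seed points on a
#' relief (by default the gradient magnitude of the Gaussian-smoothed image:
#' basins are the flat interiors, ridges are the membrane edges). The
#' membrane mask is the set of pixels within `ridge_width` (Euclidean) of a
#' boundary separating a cell label from a non-cell label.
#'
#' @param image numeric matrix.
#' @param seeds data.frame/matrix with columns `row`, `col`, `label`
#'   (1-based coordinates; at least two distinct labels, conventionally
#'   label 1 = cell interior and higher labels = background).
#' @param ridge_width half-thickness of the membrane mask in px (default 3).
#' @param smooth_sigma Gaussian sigma used before the gradient (default 1).
#' @param cell_labels labels considered cell interiors (default 1).
#' @return Object of class `membrane_mask`: `label_map` (integer matrix
#'   partitioning the image), `mask` (logical membrane pixels), `boundary`
#'   (logical cell/non-cell interface pixels), `ridge_width`.
#' @export
seeded_watershed <- function(image, seeds, ridge_width = 3,
                             smooth_sigma = 1, cell_labels = 1L) {
  stopifnot(is.matrix(image))
  seeds <- as.data.frame(seeds)
  if (!all(c("row", "col", "label") %in% names(seeds)))
    stop("'seeds' needs columns row, col, label")
  if (nrow(seeds) < 2 || length(unique(seeds$label)) < 2)
    stop("need at least two seeds with distinct labels")
  if (any(seeds$row < 1 | seeds$row > nrow(image) |
          seeds$col < 1 | seeds$col > ncol(image)))
    stop("seeds outside image")
  relief <- gradient_magnitude(gaussian_blur(image, smooth_sigma))
  markers <- matrix(0L, nrow(image), ncol(image))
  markers[cbind(seeds$row, seeds$col)] <- as.integer(seeds$label)
  labels <- cpp_ws_flood(relief, markers, conn = 8L)
  is_cell <- matrix(labels %in% cell_labels, nrow(labels), ncol(labels))
  boundary <- interface_pixels(labels, is_cell)
  if (!any(boundary)) stop("no cell/background boundary found")
  se <- disk_offsets(ridge_width)
  mask <- cpp_grey_morph(boundary + 0, se$dr, se$dc, dilate = TRUE) > 0
  structure(list(label_map = labels, mask = mask, boundary = boundary,
                 ridge_width = ridge_width),
            class = "membrane_mask")
}

# Pixels with a 4-neighbour on the other side of the cell/non-cell divide.
interface_pixels <- function(labels, is_cell) {
  nr <- nrow(labels); nc <- ncol(labels)
  out <- matrix(FALSE, nr, nc)
  diff_v <- is_cell[-nr, ] != is_cell[-1, ]
  out[-nr, ] <- out[-nr, ] | diff_v
  out[-1, ] <- out[-1, ] | diff_v
  diff_h <- is_cell[, -nc] != is_cell[, -1]
  out[, -nc] <- out[, -nc] | diff_h
  out[, -1] <- out[, -1] | diff_h
  out
}

#' @export
print.membrane_mask <- function(x, ...) {
  cat(sprintf("membrane mask: %d px (ridge width %g), %d labels\n",
              sum(x$mask), x$ridge_width, length(unique(as.vector(x$label_map)))))
  invisible(x)
}

#' Background-corrected mean membrane intensity
#'
#' Mean intensity over the membrane mask minus the mean over a cell-free
#' background region. A negative corrected value is returned (not clipped)
#' and flagged.
#'
#' @param image numeric matrix.
#' @param mask a [seeded_watershed()] result or a logical matrix.
#' @param background_roi logical matrix marking a cell-free area; must be
#'   disjoint from the mask.
#' @return List of class `membrane_intensity`: `intensity` (corrected),
#'   `membrane_mean`, `background_mean`, `negative` flag.
#' @export
membrane_mean_intensity <- function(image, mask, background_roi) {
  if (inherits(mask, "membrane_mask")) mask <- mask$mask
  stopifnot(is.matrix(image), is.logical(mask), is.logical(background_roi))
  if (!any(mask)) stop("empty membrane mask")
  if (!any(background_roi)) stop("empty background ROI")
  if (any(mask & background_roi))
    stop("background ROI overlaps the membrane mask")
  mm <- mean(image[mask]); bm <- mean(image[background_roi])
  val <- mm - bm
  structure(list(intensity = val, membrane_mean = mm, background_mean = bm,
                 negative = val < 0),
            class = "membrane_intensity")
}

#' @export
print.membrane_intensity <- function(x, ...) {
  cat(sprintf("membrane intensity: %.3f (membrane %.3f - background %.3f)%s\n",
              x$intensity, x$membrane_mean, x$background_mean,
              if (x$negative) " [negative]" else ""))
  invisible(x)
}

#' Spot-counting parameters
#'
#' @param gauss_sigma Gaussian smoothing sigma (px).
#' @param tophat_radius disk radius of the white top-hat (px); must exceed
#'   `gauss_sigma` so that spot-scale structure survives the opening.
#' @param h_maxima depth of the extended-maxima transform on the
#'   max-normalized scale (0-1).
#' @return Object of class `spot_params`.
#' @export
spot_params <- function(gauss_sigma = 1.5, tophat_radius = 8,
                        h_maxima = 0.1) {
  assert_scalar_num(gauss_sigma, "gauss_sigma", 0, strict_lower = TRUE)
  assert_scalar_num(tophat_radius, "tophat_radius", 0, strict_lower = TRUE)
  assert_scalar_num(h_maxima, "h_maxima", 0, strict_lower = TRUE)
  if (tophat_radius <= gauss_sigma)
    stop("'tophat_radius' must exceed 'gauss_sigma'")
  structure(list(gauss_sigma = gauss_sigma, tophat_radius = tophat_radius,
                 h_maxima = h_maxima), class = "spot_params")
}

#' Count localized bright spots
#'
#' Fixed operator sequence: Gaussian smoothing, normalization to the image
#' maximum, white top-hat with a disk (removing objects larger than the spot
#' scale), extended-maxima transform, hole filling, and shrinking each
#' maxima component to a single point (its centroid; centroid ties round
#' toward the smaller index). The normalization step makes the count
#' invariant to multiplying the image by a positive constant.
#'
#' @param image numeric matrix (a constant image yields zero spots).
#' @param params a [spot_params()] object.
#' @return List with `count` and `coords` (count x 2 matrix of (row, col),
#'   1-based).
#' @export
count_bright_spots <- function(image, params = spot_params()) {
  stopifnot(is.matrix(image), inherits(params, "spot_params"))
  empty <- list(count = 0L, coords = matrix(numeric(0), 0, 2,
                                            dimnames = list(NULL, c("row", "col"))))
  if (diff(range(image)) == 0) return(empty)
  sm <- gaussian_blur(image, params$gauss_sigma)
  mx <- max(sm)
  if (mx <= 0) return(empty)
  sm <- sm / mx
  th <- sm - grey_opening(sm, params$tophat_radius)
  if (diff(range(th)) == 0) return(empty)
  hm <- cpp_reconstruct_dilate(th - params$h_maxima, th)
  emax <- cpp_regional_maxima(hm, conn = 8L)
  emax <- cpp_fill_holes(emax)
  labels <- cpp_label_components(emax, conn = 8L)
  k <- max(labels)
  if (k == 0) return(empty)
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  coords <- cbind(row = round_half_down(tapply(idx[, 1], lab, mean)),
                  col = round_half_down(tapply(idx[, 2], lab, mean)))
  rownames(coords) <- NULL
  list(count = k, coords = coords)
}

round_half_down <- function(x) ceiling(x - 0.5)

#' Pixel-wise colocalization (Pearson)
#'
#' @param channel1,channel2 congruent numeric matrices.
#' @param mask optional logical matrix restricting the pixel set (default:
#'   all pixels). At least 10 pixels are required and neither channel may be
#'   constant within the mask.
#' @return Pearson correlation coefficient of the masked pixel pairs.
#' @export
coloc_pearson <- function(channel1, channel2, mask = NULL) {
  stopifnot(is.matrix(channel1), is.matrix(channel2))
  if (!all(dim(channel1) == dim(channel2)))
    stop("channels must be congruent")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(channel1), ncol(channel1))
  if (!all(dim(mask) == dim(channel1))) stop("mask must be congruent")
  x <- channel1[mask]; y <- channel2[mask]
  if (length(x) < 10) stop("need at least 10 mask pixels")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant channel")
  cor(x, y)
}

#' Fraction of propidium-iodide-positive cells
#'
#' @param per_cell_intensities numeric vector of per-cell PI intensities.
#' @param threshold_mode `"otsu"` (default; Otsu's threshold computed on log
#'   intensities, suited to the bimodal live/dead mixture) or `"fixed"`.
#' @param threshold intensity cutoff for `"fixed"` mode.
#' @return Fraction in `[0, 1]`, with the threshold used attached as
#'   attribute `threshold`.
#' @export
pi_positive_fraction <- function(per_cell_intensities,
                                 threshold_mode = c("otsu", "fixed"),
                                 threshold = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  x <- per_cell_intensities
  if (length(x) < 1) stop("no cells")
  if (any(!is.finite(x) | x < 0)) stop("intensities must be finite and >= 0")
  if (threshold_mode == "fixed") {
    if (is.null(threshold)) stop("fixed mode needs a threshold")
    thr <- threshold
  } else {
    lx <- log(x + max(x) * 1e-6 + .Machine$double.eps)
    thr <- exp(otsu_threshold(lx))
  }
  structure(mean(x > thr), threshold = thr)
}

# Otsu's threshold on a numeric vector (256-bin histogram); returns a value
# on the input scale.
otsu_threshold <- function(x, n_bins = 256) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  breaks <- seq(r[1], r[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}
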