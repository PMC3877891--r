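#' Confocal image stack
#'
#' Container for a time series of photon-count-like frames, the substrate of
#' Number & Brightness analysis. Frames are stored as an `H x W x T` array
#' (rows, columns, frames); values must be non-negative and at least two
#' frames are required.
#'
#' @param frames numeric array of dimension `H x W x T` with non-negative
#'   values (counts). `NA` marks pixels invalidated by registration.
#' @param pixel_size pixel size in nm (default 82, the acquisition setting the
#'   analysis defaults were designed around).
#' @param dwell_time pixel dwell time in microseconds (default 10).
#' @param metadata free-form list carried along with the stack.
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size = 82, dwell_time = 10,
                        metadata = list()) {
  if (!is.array(frames) || length(dim(frames)) != 3)
    stop("'frames' must be a 3-d array (rows x cols x frames)")
  d <- dim(frames)
  if (d[1] < 1 || d[2] < 1) stop("zero-area image")
  if (d[3] < 2) stop("an image stack needs at least 2 frames")
  if (any(frames < 0, na.rm = TRUE)) stop("counts must be non-negative")
  assert_scalar_num(pixel_size, "pixel_size", 0, strict_lower = TRUE)
  assert_scalar_num(dwell_time, "dwell_time", 0, strict_lower = TRUE)
  structure(list(frames = frames, pixel_size = pixel_size,
                 dwell_time = dwell_time, metadata = metadata),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_stack: %d frames of %d x %d px (%g nm/px, %g us dwell)\n",
              d[3], d[1], d[2], x$pixel_size, x$dwell_time))
  cat(sprintf("  mean count %.3f, range [%g, %g]\n",
              mean(x$frames, na.rm = TRUE), min(x$frames, na.rm = TRUE),
              max(x$frames, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$frames)

n_frames <- function(stack) dim(stack$frames)[3]

#' Crop a stack or map to its central square region
#'
#' N&B analysis conventionally restricts to the central part of the field to
#' avoid scanner-turnaround artifacts at frame borders. If the requested size
#' is at least as large as the image, the input is returned unchanged.
#'
#' @param x an `image_stack` or a 2-d matrix.
#' @param size side length (px) of the central square, default 128.
#' @return Object of the same type, cropped.
#' @export
central_region <- function(x, size = 128) {
  if (inherits(x, "image_stack")) {
    d <- dim(x$frames)
    ri <- crop_idx(d[1], size); ci <- crop_idx(d[2], size)
    x$frames <- x$frames[ri, ci, , drop = FALSE]
    return(x)
  }
  ri <- crop_idx(nrow(x), size); ci <- crop_idx(ncol(x), size)
  x[ri, ci, drop = FALSE]
}

crop_idx <- function(n, size) {
  if (size >= n) return(seq_len(n))
  lo <- floor((n - size) / 2) + 1
  lo:(lo + size - 1)
}
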