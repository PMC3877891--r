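# Plain-text I/O: ASCII PGM images, CSV tables, JSON sidecars, and a simple
# text layout for image stacks. (The binary TIFF formats typically produced
# by acquisition software have no reader in this package's dependency set;
# all formats here are deliberately text-based.)

#' Write a 2-D image as ASCII PGM (P2)
#'
#' @param img numeric matrix; values are rounded and clipped to
#'   `[0, maxval]`.
#' @param path output file.
#' @param maxval maximum grey value recorded in the header (default 65535).
#' @export
write_pgm <- function(img, path, maxval = 65535) {
  stopifnot(is.matrix(img))
  v <- pmin(pmax(round(img), 0), maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(img), nrow(img)),
               sprintf("%d", maxval)), con)
  write(t(v), file = con, ncolumns = ncol(img))
  invisible(path)
}

#' Read an ASCII PGM (P2) image
#'
#' @param path file written by [write_pgm()] or any P2 PGM.
#' @return Numeric matrix.
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop("not an ASCII PGM (P2) file")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM payload")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write an image stack as plain text
#'
#' Stores the frames as a whitespace-separated matrix (one frame per row,
#' pixels in column-major order) next to a JSON sidecar
#' (`<path>.meta.json`) holding the dimensions and acquisition metadata.
#' Intended for small demonstration stacks; large stacks should be
#' regenerated from their simulation parameters instead.
#'
#' @param stack an [image_stack()].
#' @param path output file.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  m <- t(matrix(stack$frames, d[1] * d[2], d[3]))
  write(t(m), file = path, ncolumns = ncol(m))
  jsonlite::write_json(list(height = d[1], width = d[2], n_frames = d[3],
                            pixel_size = stack$pixel_size,
                            dwell_time = stack$dwell_time,
                            metadata = stack$metadata),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path stack file (the `.meta.json` sidecar must sit next to it).
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"))
  m <- matrix(scan(path, quiet = TRUE), nrow = meta$n_frames, byrow = TRUE)
  frames <- array(t(m), dim = c(meta$height, meta$width, meta$n_frames))
  image_stack(frames, pixel_size = meta$pixel_size,
              dwell_time = meta$dwell_time,
              metadata = as.list(meta$metadata))
}

#' Write ground truth or results as a JSON sidecar
#'
#' @param x list to serialize.
#' @param path base path; the sidecar is `<path>.truth.json` when
#'   `suffix = "truth"`.
#' @param suffix sidecar tag (default `"truth"`).
#' @export
write_truth_json <- function(x, path, suffix = "truth") {
  out <- paste0(path, ".", suffix, ".json")
  jsonlite::write_json(x, out, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out)
}
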