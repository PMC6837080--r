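#' Read and write PNG images
#'
#' A minimal PNG codec (8-bit, greyscale or RGB, non-interlaced) used for
#' scene images and label masks.  `read_png()` returns intensities in
#' `[0, 1]` as an `(H, W, 3)` array (RGB) or an `(H, W)` matrix (grey);
#' `write_png()` accepts the same shapes with values in `[0, 1]`.
#' Label masks store the integer class index directly as the pixel value:
#' `write_mask_png()` / `read_mask_png()` round-trip integer matrices.
#'
#' @param path file path.
#' @param img numeric array `(H, W, 3)` or matrix `(H, W)`, values in `[0, 1]`.
#' @param mask integer matrix of class indices (background = 0).
#' @return `read_png()`: numeric array or matrix in `[0, 1]`;
#'   `read_mask_png()`: integer matrix.  Writers return `path` invisibly.
#' @export
read_png <- function(path) {
  p <- cpp_read_png(path.expand(path))
  if (p$channels == 1L) {
    out <- matrix(p$data / 255, p$height, p$width)
  } else {
    out <- array(p$data / 255, dim = c(p$height, p$width, 3L))
  }
  out
}

#' @rdname read_png
#' @export
write_png <- function(img, path) {
  d <- dim(img)
  sg_check(length(d) %in% c(2L, 3L), "write_png: expected (H, W) or (H, W, 3)")
  ch <- if (length(d) == 2L) 1L else d[3]
  v <- as.integer(round(pmin(pmax(img, 0), 1) * 255))
  cpp_write_png(path.expand(path), v, d[1], d[2], ch)
  invisible(path)
}

#' @rdname read_png
#' @export
write_mask_png <- function(mask, path) {
  sg_check(is.matrix(mask), "write_mask_png: expected a matrix")
  sg_check(all(mask >= 0 & mask <= 255), "write_mask_png: class index out of 0..255")
  cpp_write_png(path.expand(path), as.integer(mask), nrow(mask), ncol(mask), 1L)
  invisible(path)
}

#' @rdname read_png
#' @export
read_mask_png <- function(path) {
  p <- cpp_read_png(path.expand(path))
  sg_check(p$channels == 1L, "read_mask_png: '%s' is not single-channel", path)
  matrix(as.integer(p$data), p$height, p$width)
}
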