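# Image and mask IO. Images are H x W x 3 numeric arrays in [0, 1]; masks
# are integer H x W matrices with values in {0, 1} (stored on disk as 8-bit
# PNG with 0 = background, 255 = grain).

#' Read an RGB image
#'
#' @param path PNG file path.
#' @return H x W x 3 numeric array in [0, 1].
#' @export
readImageRGB <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB image as PNG
#'
#' @param image H x W x 3 numeric array in [0, 1].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeImageRGB <- function(image, path) {
  png::writePNG(clamp(image), path)
  invisible(path)
}

#' Read a binary mask PNG
#'
#' @param path PNG path (8-bit, 0 = background, 255 = foreground).
#' @return integer H x W matrix with values in \{0, 1\}.
#' @export
readMask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(m > 0.5), nrow(m), ncol(m))
}

#' Write a binary mask PNG
#'
#' @param mask integer/logical H x W matrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Resize an image or mask
#'
#' Bilinear for images, nearest-neighbour for masks (so mask values stay
#' binary).
#'
#' @param x H x W x C array or H x W matrix.
#' @param size target size: one value (square) or \code{c(H, W)}.
#' @param mask logical; nearest-neighbour resampling if \code{TRUE}.
#' @return resized array/matrix.
#' @export
resizeImage <- function(x, size, mask = FALSE) {
  if (length(size) == 1) size <- c(size, size)
  if (all(dim(x)[1:2] == size)) return(x)
  if (mask) {
    ri <- round(seq(1, nrow(x), length.out = size[1]))
    ci <- round(seq(1, ncol(x), length.out = size[2]))
    if (is.matrix(x)) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
  } else {
    # EBImage uses x = columns; transpose in/out to keep row-major semantics
    y <- EBImage::resize(aperm(x, c(2, 1, 3)), w = size[1], h = size[2])
    clamp(aperm(as.array(y), c(2, 1, 3)))
  }
}
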