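# LabelMe polygon annotations -> binary region masks.
# Coordinate convention: pixels are (row, col), 0-based; polygon vertices
# are (x, y) in image coordinates as stored by LabelMe. A pixel belongs to
# a polygon when its centre (x = col + 0.5, y = row + 0.5) is inside under
# the even-odd rule.

#' Rasterize one polygon to a binary mask
#'
#' Scanline even-odd fill over pixel centres.
#'
#' @param points numeric matrix of vertices, columns (x, y).
#' @param image_size integer (H, W).
#' @return integer H x W matrix with values in \{0, 1\}.
#' @export
rasterizePolygon <- function(points, image_size) {
  H <- image_size[1]; W <- image_size[2]
  mask <- matrix(0L, H, W)
  if (nrow(points) < 3) stop("polygon needs at least 3 vertices")
  x <- points[, 1]; y <- points[, 2]
  nx <- c(x[-1], x[1]); ny <- c(y[-1], y[1])
  for (r in seq_len(H) - 1L) {
    yc <- r + 0.5
    cross <- (pmin(y, ny) <= yc) & (yc < pmax(y, ny))
    if (!any(cross)) next
    xi <- x[cross] + (yc - y[cross]) * (nx[cross] - x[cross]) /
      (ny[cross] - y[cross])
    xi <- sort(xi)
    for (k in seq(1, length(xi) - 1, by = 2)) {
      c0 <- ceiling(xi[k] - 0.5)
      c1 <- ceiling(xi[k + 1] - 0.5) - 1
      c0 <- max(c0, 0L); c1 <- min(c1, W - 1L)
      if (c0 <= c1) mask[r + 1L, (c0:c1) + 1L] <- 1L
    }
  }
  mask
}

#' Parse a LabelMe annotation document into a grain-region mask
#'
#' All polygons labelled \code{"grain"} are rasterized and unioned (a pixel
#' covered by several grain polygons counts once). Polygons labelled
#' \code{"dish"} are accepted but do not contribute to the grain mask;
#' any other label produces a warning and is skipped. A polygon with fewer
#' than 3 vertices is an error.
#'
#' @param doc path to a LabelMe JSON file, or the already-parsed list.
#' @param image_size integer (H, W); defaults to the document's
#'   \code{imageHeight}/\code{imageWidth}.
#' @return integer H x W matrix, 1 = grain region.
#' @export
parseLabelMe <- function(doc, image_size = NULL) {
  if (is.character(doc)) doc <- jsonlite::fromJSON(doc, simplifyVector = FALSE)
  if (is.null(image_size)) {
    if (is.null(doc$imageHeight) || is.null(doc$imageWidth))
      stop("image_size not given and not present in the document")
    image_size <- c(doc$imageHeight, doc$imageWidth)
  }
  image_size <- as.integer(image_size)
  mask <- matrix(0L, image_size[1], image_size[2])
  for (shape in doc$shapes) {
    pts <- shape$points
    if (is.list(pts)) pts <- do.call(rbind, lapply(pts, unlist))
    pts <- matrix(as.numeric(pts), ncol = 2)
    if (nrow(pts) < 3)
      stop("polygon with label '", shape$label, "' has fewer than 3 vertices")
    if (identical(shape$label, "grain")) {
      mask <- pmax(mask, rasterizePolygon(pts, image_size))
    } else if (identical(shape$label, "dish")) {
      # dish boundary: parsed and validated, not part of the grain mask
    } else {
      warning("skipping shape with unknown label '", shape$label, "'")
    }
  }
  mask
}
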