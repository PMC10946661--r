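#' @include manifest.R imageio.R
NULL

# Colour descriptors over masked grain pixels. For each of the 12 channels
# of four colour spaces (RGB, HSV, Lab, YCrCb) the descriptor registry holds
# the channel mean, the channel SD and a 196-bin normalized histogram of
# channel intensity (198 values per channel, 2,376 total), plus four
# whole-region descriptors (grayscale mean, grayscale SD, dark-pixel
# fraction at gray < 0.1, foreground-area fraction of the frame): 2,380
# descriptors. All channels are normalized to [0, 1] before statistics so
# thresholds are scale-meaningful across colour spaces.

descriptorHistBins <- 196L

#' Descriptor registry names
#'
#' @return character vector of the 2,380 descriptor names, in registry
#'   order (\code{space.channel.statistic} / \code{space.channel.hist_k}).
#' @export
descriptorNames <- function() {
  spaces <- list(RGB = c("R", "G", "B"), HSV = c("H", "S", "V"),
                 Lab = c("L", "a", "b"), YCrCb = c("Y", "Cr", "Cb"))
  out <- character(0)
  for (sp in names(spaces)) for (ch in spaces[[sp]]) {
    pre <- paste(sp, ch, sep = ".")
    out <- c(out, paste0(pre, ".mean"), paste0(pre, ".sd"),
             sprintf("%s.hist_%03d", pre, seq_len(descriptorHistBins)))
  }
  c(out, "gray.mean", "gray.sd", "gray.dark_fraction",
    "region.area_fraction")
}

# n x 3 RGB in [0,1] -> n x 12 matrix of all channels, each on [0, 1]
channelStack <- function(rgb) {
  r <- rgb[, 1]; g <- rgb[, 2]; b <- rgb[, 3]
  hsv <- t(grDevices::rgb2hsv(t(rgb), maxColorValue = 1))
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  # L in [0,100]; a, b roughly [-110, 110]: affine map to [0, 1]
  lab <- cbind(lab[, 1] / 100,
               clamp((lab[, 2] + 128) / 256),
               clamp((lab[, 3] + 128) / 256))
  y  <- 0.299 * r + 0.587 * g + 0.114 * b
  cr <- clamp((r - y) * 0.713 + 0.5)
  cb <- clamp((b - y) * 0.564 + 0.5)
  m <- cbind(r, g, b, hsv, lab, y, cr, cb)
  colnames(m) <- NULL
  m
}

#' Extract the 2,380 colour descriptors of one image
#'
#' Descriptors are computed over foreground (mask = 1) pixels only, so the
#' result is invariant to background pixel values. Histogram blocks are
#' normalized to sum to 1 per channel.
#'
#' @param image H x W x 3 numeric RGB array in [0, 1].
#' @param mask H x W binary matrix with at least one foreground pixel.
#' @return named numeric vector of length 2,380.
#' @examples
#' img <- array(0.5, c(8, 8, 3)); msk <- matrix(1L, 8, 8)
#' length(extractDescriptors(img, msk))
#' @export
extractDescriptors <- function(image, mask) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("image must be an H x W x 3 RGB array")
  if (!all(dim(mask) == dim(image)[1:2]))
    stop("mask dimensions must match the image")
  fg <- which(mask > 0)
  if (length(fg) == 0) stop("empty mask: no foreground pixels")
  rgb <- cbind(as.vector(image[, , 1])[fg],
               as.vector(image[, , 2])[fg],
               as.vector(image[, , 3])[fg])
  chans <- channelStack(rgb)
  nb <- descriptorHistBins
  vals <- numeric(0)
  for (j in seq_len(ncol(chans))) {
    v <- chans[, j]
    bins <- tabulate(pmin(floor(v * nb), nb - 1) + 1L, nbins = nb)
    vals <- c(vals, mean(v), stats::sd(v) %|0|% 0,
              bins / length(v))
  }
  gray <- 0.299 * rgb[, 1] + 0.587 * rgb[, 2] + 0.114 * rgb[, 3]
  vals <- c(vals, mean(gray), stats::sd(gray) %|0|% 0,
            mean(gray < 0.1), length(fg) / prod(dim(mask)))
  names(vals) <- descriptorNames()
  vals
}

# sd of a length-1 vector is NA; descriptors must stay finite
`%|0|%` <- function(x, y) if (is.na(x)) y else x

#' GrainFeatures: a SummarizedExperiment of colour descriptors
#'
#' Rows are the 2,380 descriptors, columns are images; \code{colData}
#' carries the manifest record of each image.
#'
#' @export
setClass("GrainFeatures", contains = "SummarizedExperiment")

#' Extract descriptors for every image of a manifest
#'
#' Masks are taken from the manifest's \code{mask_path} column, or
#' predicted with \code{segmenter} when given.
#'
#' @param manifest a \code{\linkS4class{GrainManifest}}.
#' @param segmenter optional fitted \code{\linkS4class{GrainSegmenter}}
#'   used when a record has no mask path.
#' @return a \code{\linkS4class{GrainFeatures}}.
#' @export
extractFeatures <- function(manifest, segmenter = NULL) {
  rec <- manifestRecords(manifest)
  if (nrow(rec) == 0) stop("empty manifest")
  mat <- vapply(seq_len(nrow(rec)), function(i) {
    img <- readImageRGB(rec$image_path[i])
    msk <- if (!is.na(rec$mask_path[i])) readMask(rec$mask_path[i])
           else if (!is.null(segmenter)) predictMask(segmenter, img)
           else stop("record ", i, " has no mask and no segmenter given")
    extractDescriptors(img, msk)
  }, numeric(length(descriptorNames())))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(descriptors = mat),
    colData = S4Vectors::DataFrame(rec, row.names = rec$image_path))
  new("GrainFeatures", se)
}

#' Feature matrix in analysis orientation
#'
#' @param x a \code{\linkS4class{GrainFeatures}}.
#' @return numeric matrix, rows = images, columns = descriptors.
#' @export
featureMatrix <- function(x) {
  stopifnot(is(x, "GrainFeatures"))
  t(SummarizedExperiment::assay(x, "descriptors"))
}
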