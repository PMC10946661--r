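#' @include AllGenerics.R nn-unet.R nn-core.R
NULL

# Grain-region segmentation: a compact encoder-decoder network separating
# the grain-filled dish region from background. The mask it produces feeds
# colour-descriptor extraction and the dish-region crop used by the CNN
# classifier.

#' Segmenter configuration
#'
#' @param encoder_family one of \code{"resnet18"}, \code{"resnet34"},
#'   \code{"efficientnetb0"}: width/depth presets of the compact encoder.
#' @param input_size training resolution; must be divisible by 32
#'   (five down/upsampling stages).
#' @param epochs,batch_size,learning_rate optimizer settings (Adam, fixed
#'   learning rate; batch accumulated over \code{batch_size} images).
#' @param loss_name \code{"bce_dice"}: binary cross-entropy + soft Dice.
#' @param seed integer seed governing initialization and shuffling.
#' @return a list of class \code{SegmenterConfig}.
#' @export
segmenterConfig <- function(encoder_family = "resnet18", input_size = 128L,
                            epochs = 5L, batch_size = 1L,
                            learning_rate = 0.02, loss_name = "bce_dice",
                            seed = 1L) {
  if (input_size %% 32 != 0)
    stop("input_size must be divisible by 32 (got ", input_size, ")")
  preset <- unetPreset(encoder_family)
  structure(list(encoder_family = encoder_family,
                 input_size = as.integer(input_size),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, loss_name = loss_name,
                 base = preset$base, depth = preset$depth,
                 seed = as.integer(seed)),
            class = "SegmenterConfig")
}

#' GrainSegmenter: fitted grain-region segmentation network
#'
#' @slot params named list of layer parameters.
#' @slot config the \code{\link{segmenterConfig}} used.
#' @slot history per-epoch training/validation losses and validation IoU.
#' @export
setClass("GrainSegmenter", representation(params = "list", config = "list",
                                          history = "data.frame"))

setMethod("show", "GrainSegmenter", function(object) {
  cat("GrainSegmenter (", object@config$encoder_family, "-style encoder, ",
      paramCount(object@params), " parameters)\n", sep = "")
  if (nrow(object@history))
    cat(sprintf("  trained %d epochs, final val IoU %.3f\n",
                nrow(object@history),
                object@history$val_iou[nrow(object@history)]))
})

#' Build an untrained segmenter
#'
#' The network has an encoder downsampling path, a decoder upsampling path,
#' skip connections at matching resolutions and a 1-channel sigmoid output
#' of the input spatial size. Two builds with the same seed are identical.
#'
#' @param config a \code{\link{segmenterConfig}}.
#' @return a \code{\linkS4class{GrainSegmenter}}.
#' @examples
#' seg <- buildSegmenter(segmenterConfig(input_size = 64))
#' @export
buildSegmenter <- function(config = segmenterConfig()) {
  stopifnot(inherits(config, "SegmenterConfig"))
  params <- withSeed(config$seed,
                     unetInit(3L, config$base, config$depth, out_ch = 1L))
  new("GrainSegmenter", params = params, config = unclass(config),
      history = data.frame())
}

# load (image, mask) pairs resized to the network resolution
loadSegPairs <- function(manifest, size) {
  rec <- manifestRecords(manifest)
  if (nrow(rec) == 0) stop("empty manifest")
  if (any(is.na(rec$mask_path)))
    stop("all records need mask paths for segmentation training")
  lapply(seq_len(nrow(rec)), function(i) {
    list(x = resizeImage(readImageRGB(rec$image_path[i]), size) - 0.5,
         y = matrix(as.numeric(resizeImage(readMask(rec$mask_path[i]),
                                           size, mask = TRUE)), size, size))
  })
}

segLoss <- function(logits, target) {
  bce <- bceLogit(logits, array(target, dim(logits)))
  dic <- diceLogit(logits[, , 1], target)
  list(loss = bce$loss + dic$loss,
       dz = bce$dz + array(dic$dz, dim(logits)))
}

#' Train the segmentation network
#'
#' Adam on binary cross-entropy + soft Dice; the epoch with the best
#' validation loss is returned. Reproducible given the config seed.
#'
#' @param model an untrained (or warm) \code{\linkS4class{GrainSegmenter}}.
#' @param train_manifest,val_manifest \code{GrainManifest}s whose records
#'   have image and mask paths.
#' @param config optional override of \code{model@config}.
#' @param verbose print per-epoch progress.
#' @return the trained \code{GrainSegmenter} with filled \code{history}.
#' @export
trainSegmenter <- function(model, train_manifest, val_manifest,
                           config = NULL, verbose = FALSE) {
  stopifnot(is(model, "GrainSegmenter"))
  cfg <- if (is.null(config)) model@config else unclass(config)
  size <- cfg$input_size
  train <- loadSegPairs(train_manifest, size)
  val <- loadSegPairs(val_manifest, size)

  params <- model@params
  withSeed(cfg$seed + 1L, {
    state <- adamInit(params)
    best <- list(loss = Inf, params = params)
    hist <- vector("list", cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(length(train))
      tl <- 0
      for (i in ord) {
        fw <- unetForward(params, train[[i]]$x, cfg$depth)
        ls <- segLoss(fw$logits, train[[i]]$y)
        tl <- tl + ls$loss
        G <- clipGrads(unetBackward(params, fw$cache, cfg$depth, ls$dz))
        upd <- adamStep(params, G, state, lr = cfg$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      vl <- 0; vi <- 0
      for (v in val) {
        fw <- unetForward(params, v$x, cfg$depth)
        vl <- vl + segLoss(fw$logits, v$y)$loss
        vi <- vi + maskIoU(sigmoid(fw$logits[, , 1]) > 0.5, v$y > 0.5)
      }
      hist[[ep]] <- data.frame(epoch = ep,
                               train_loss = tl / length(train),
                               val_loss = vl / length(val),
                               val_iou = vi / length(val))
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f IoU %.3f", ep,
                        tl / length(train), vl / length(val),
                        vi / length(val)))
      if (vl / length(val) < best$loss)
        best <- list(loss = vl / length(val), params = params)
    }
    new("GrainSegmenter", params = best$params, config = cfg,
        history = do.call(rbind, hist))
  })
}

#' Predict a binary grain-region mask
#'
#' The image is resized to the network resolution, passed through the
#' network, thresholded (strictly: probability > threshold) and the mask is
#' resampled back to the image dimensions.
#'
#' @param object a \code{\linkS4class{GrainSegmenter}}.
#' @param image H x W x 3 numeric array in [0, 1].
#' @param threshold probability threshold (default 0.5); 0 gives
#'   all-foreground, 1 all-background.
#' @return integer H x W binary mask.
#' @export
setMethod("predictMask", "GrainSegmenter",
          function(object, image, threshold = 0.5) {
  cfg <- object@config
  x <- resizeImage(image, cfg$input_size) - 0.5
  fw <- unetForward(object@params, x, cfg$depth)
  p <- sigmoid(fw$logits[, , 1])
  m <- matrix(as.integer(p > threshold), nrow(p), ncol(p))
  resizeImage(m, dim(image)[1:2], mask = TRUE)
})

#' Intersection-over-union of two binary masks
#'
#' @param a,b binary masks of equal dimensions.
#' @return IoU in [0, 1]; two empty masks have IoU 1.
#' @export
maskIoU <- function(a, b) {
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Crop the grain region from an image
#'
#' Axis-aligned bounding box of the mask foreground, expanded by
#' \code{padding} pixels and clipped to the image bounds.
#'
#' @param image H x W x 3 array.
#' @param mask binary H x W matrix with at least one foreground pixel.
#' @param padding non-negative integer.
#' @return the cropped image array.
#' @examples
#' img <- array(runif(48), c(4, 4, 3))
#' msk <- matrix(0, 4, 4); msk[2:3, 2:3] <- 1
#' dim(cropGrainRegion(img, msk))
#' @export
cropGrainRegion <- function(image, mask, padding = 0L) {
  fg <- which(mask > 0, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("empty mask: nothing to crop")
  r0 <- max(1L, min(fg[, 1]) - padding)
  r1 <- min(nrow(mask), max(fg[, 1]) + padding)
  c0 <- max(1L, min(fg[, 2]) - padding)
  c1 <- min(ncol(mask), max(fg[, 2]) + padding)
  image[r0:r1, c0:c1, , drop = FALSE]
}
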