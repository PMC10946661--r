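#' @include filter.R features.R segmentation.R
NULL

# The four pigment-composition classifiers and the shared decision rules.
# All models emit labels through the same NP/A/M/AM code; the 4-class and
# 2-binary views are interconvertible without loss (pigmentFlags /
# flagsToLabel).

#' Map pigment scores to a label
#'
#' A pigment is flagged present iff its score is strictly greater than the
#' threshold; both at or below the threshold gives \code{NP}. Monotone:
#' raising a score never removes a pigment.
#'
#' @param scores numeric vector \code{c(p_anthocyanin, p_melanin)} or an
#'   n x 2 matrix, values in [0, 1].
#' @param threshold decision threshold (default 0.5, strict inequality).
#' @return character label(s) in \code{NP/A/M/AM}.
#' @examples
#' decideLabel(c(0.7, 0.2))   # "A"
#' decideLabel(c(0.5, 0.5))   # "NP": strictly-greater rule
#' @export
decideLabel <- function(scores, threshold = 0.5) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 2)
  stopifnot(ncol(scores) == 2, all(scores >= 0 & scores <= 1))
  flagsToLabel(scores[, 1] > threshold, scores[, 2] > threshold)
}

#' Aggregate a two-channel pigment mask into a label
#'
#' A pigment is present iff its channel's positive-pixel fraction of the
#' frame exceeds \code{min_fraction}. The default 0 is the any-pixel rule:
#' one positive pixel is enough.
#'
#' @param two_channel_mask H x W x 2 binary array (channel 1 anthocyanin,
#'   channel 2 melanin).
#' @param min_fraction minimum positive-pixel fraction (default 0).
#' @return one label in \code{NP/A/M/AM}.
#' @examples
#' m <- array(0L, c(4, 4, 2)); m[1, 1, 1] <- 1L
#' aggregatePixels(m)          # "A"
#' @export
aggregatePixels <- function(two_channel_mask, min_fraction = 0) {
  d <- dim(two_channel_mask)
  if (length(d) != 3 || d[3] != 2)
    stop("two_channel_mask must have exactly 2 channels")
  fr <- apply(two_channel_mask > 0, 3, mean)
  flagsToLabel(fr[1] > min_fraction, fr[2] > min_fraction)
}

# ---------------------------------------------------------------- RF13 ----

#' RF13Model: random forest on 13 principal components of colour descriptors
#'
#' The fitted pipeline stores the feature filter, the normalization
#' transform and the PCA basis, all estimated from training data only, plus
#' the forest.
#'
#' @slot filter a \code{\linkS4class{FeatureFilter}}.
#' @slot transform a \code{\linkS4class{FeatureTransform}}.
#' @slot reducer a \code{\linkS4class{PCAReducer}}.
#' @slot forest the fitted \code{randomForest}.
#' @slot config list of settings (tree count, k, seed).
#' @export
setClass("RF13Model", representation(filter = "FeatureFilter",
                                     transform = "FeatureTransform",
                                     reducer = "PCAReducer",
                                     forest = "ANY", config = "list"))

setMethod("show", "RF13Model", function(object) {
  cat("RF13Model:", ncol(object@reducer@rotation),
      "principal components of", sum(object@filter@keep),
      "retained descriptors,", object@config$ntree, "trees\n")
})

#' Train the RF13 classifier
#'
#' Filter -> z-normalize -> PCA to \code{k} components -> random forest on
#' the 4-class label. Deterministic given the seed.
#'
#' @param features numeric matrix (rows = images, columns = descriptors) or
#'   a \code{\linkS4class{GrainFeatures}}.
#' @param labels character labels in \code{NP/A/M/AM} (taken from the
#'   \code{GrainFeatures} colData when omitted).
#' @param ntree forest size (default 500).
#' @param k number of principal components (default 13).
#' @param seed integer seed.
#' @return an \code{\linkS4class{RF13Model}}.
#' @export
trainRF13 <- function(features, labels = NULL, ntree = 500, k = 13,
                      seed = 1) {
  if (is(features, "GrainFeatures")) {
    if (is.null(labels))
      labels <- SummarizedExperiment::colData(features)$pigment_label
    features <- featureMatrix(features)
  }
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  absent <- setdiff(pigmentLevels(), labels)
  if (length(absent))
    warning("class(es) absent from training labels: ",
            paste(absent, collapse = ", "))
  filt <- filterFeatures(features)
  norm <- normalizeFeatures(applyFilter(filt, features))
  red <- pcaReduce(norm$matrix, k = k)
  present <- intersect(pigmentLevels(), unique(labels))
  forest <- withSeed(seed, randomForest::randomForest(
    x = red$matrix, y = factor(labels, levels = present),
    ntree = ntree))
  new("RF13Model", filter = filt, transform = norm$transform,
      reducer = red$reducer, forest = forest,
      config = list(ntree = ntree, k = k, seed = seed))
}

rf13Representation <- function(object, features) {
  if (is(features, "GrainFeatures")) features <- featureMatrix(features)
  applyPCA(object@reducer,
           applyTransform(object@transform,
                          applyFilter(object@filter, features)))
}

#' @describeIn RF13Model pigment scores from forest votes
#'   (P(A) + P(AM), P(M) + P(AM)).
#' @param object an \code{RF13Model}.
#' @param newdata feature matrix or \code{GrainFeatures}.
#' @export
setMethod("predictScores", "RF13Model", function(object, newdata) {
  z <- rf13Representation(object, newdata)
  pr <- stats::predict(object@forest, z, type = "prob")
  full <- matrix(0, nrow(pr), 4,
                 dimnames = list(NULL, pigmentLevels()))
  full[, colnames(pr)] <- pr
  cbind(p_anthocyanin = full[, "A"] + full[, "AM"],
        p_melanin = full[, "M"] + full[, "AM"])
})

#' @describeIn RF13Model 4-class label prediction
#' @export
setMethod("predictLabel", "RF13Model", function(object, newdata) {
  z <- rf13Representation(object, newdata)
  as.character(stats::predict(object@forest, z))
})

# ------------------------------------------------------- CNN classifier ----

#' Classifier network configuration
#'
#' @param model_kind one of \code{"cnn"}, \code{"unet_classhead"},
#'   \code{"unet_classsegment"}.
#' @param input_size network resolution (divisible by 32 for the U-Net
#'   variants).
#' @param base,nstages,blocks width/depth of the residual classifier.
#' @param encoder_family U-Net encoder preset for the two U-Net variants.
#' @param epochs,learning_rate Adam settings; \code{epochs = NULL} picks
#'   the model-kind default.
#' @param batch_size images per gradient step for the residual classifier
#'   (0 = full batch); the U-Net variants use per-image steps.
#' @param head_steps full-batch steps of the final head refinement in the
#'   U-Net + classification-head model.
#' @param cls_steps full-batch classifier-shaping steps of the multi-task
#'   schedule.
#' @param lambda multi-task classification loss weight (default 1).
#' @param color_aug apply small colour jitter during the multi-task
#'   classifier phases (default TRUE).
#' @param decision_threshold score threshold (default 0.5).
#' @param seed integer seed.
#' @return list of class \code{ClassifierConfig}.
#' @export
classifierConfig <- function(model_kind = "cnn", input_size = 64L,
                             base = 8L, nstages = 3L, blocks = 2L,
                             encoder_family = "efficientnetb0",
                             epochs = NULL, learning_rate = 0.02,
                             batch_size = NULL, head_steps = 300L,
                             cls_steps = 120L, lambda = 1,
                             color_aug = TRUE,
                             decision_threshold = 0.5,
                             seed = 1L) {
  if (model_kind %in% c("unet_classhead", "unet_classsegment") &&
      input_size %% 32 != 0)
    stop("input_size must be divisible by 32 for U-Net variants")
  # kind-specific step defaults: the residual classifier learns from
  # full-batch steps over many epochs; the dense-supervision U-Net
  # variants converge in a few per-image epochs
  if (is.null(epochs))
    epochs <- switch(model_kind, cnn = 120L, unet_classhead = 10L,
                     unet_classsegment = 24L, 120L)
  if (is.null(batch_size))
    batch_size <- if (model_kind == "cnn") 0L else 1L
  structure(list(model_kind = model_kind,
                 input_size = as.integer(input_size),
                 base = as.integer(base), nstages = as.integer(nstages),
                 blocks = as.integer(blocks),
                 encoder_family = encoder_family,
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 head_steps = as.integer(head_steps),
                 cls_steps = as.integer(cls_steps),
                 augment = TRUE, color_aug = isTRUE(color_aug),
                 lambda = lambda,
                 decision_threshold = decision_threshold,
                 seed = as.integer(seed)),
            class = "ClassifierConfig")
}

#' CNNClassifier: residual network scoring the two pigments
#'
#' @slot params layer parameters.
#' @slot config the \code{\link{classifierConfig}} used.
#' @slot history per-epoch training loss.
#' @export
setClass("CNNClassifier", representation(params = "list", config = "list",
                                         history = "data.frame"))

setMethod("show", "CNNClassifier", function(object)
  cat("CNNClassifier (", paramCount(object@params), " parameters)\n",
      sep = ""))

# resize and centre at zero (network inputs are image - 0.5)
prepClsImages <- function(images, size)
  lapply(images, function(im) resizeImage(im, size) - 0.5)

#' Train the residual CNN classifier
#'
#' Inputs are dish-region crops (see \code{\link{cropGrainRegion}}),
#' resized to the network resolution. The two-unit sigmoid output head is
#' trained with per-output binary cross-entropy.
#'
#' @param images list of H x W x 3 arrays (cropped dish regions).
#' @param labels character labels in \code{NP/A/M/AM}.
#' @param config a \code{\link{classifierConfig}}.
#' @param verbose print per-epoch loss.
#' @return a fitted \code{\linkS4class{CNNClassifier}}.
#' @export
trainCNNClassifier <- function(images, labels,
                               config = classifierConfig("cnn"),
                               verbose = FALSE) {
  if (length(images) == 0) stop("empty training set")
  stopifnot(length(images) == length(labels))
  cfg <- unclass(config)
  xs <- prepClsImages(images, cfg$input_size)
  ts <- pigmentFlags(labels) * 1
  batch <- if (cfg$batch_size <= 0) length(xs) else cfg$batch_size
  withSeed(cfg$seed, {
    params <- resnetInit(3L, cfg$base, cfg$nstages, cfg$blocks, nout = 2L)
    state <- adamInit(params)
    hist <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(length(xs))
      tl <- 0; accG <- NULL; nb <- 0
      for (i in ord) {
        xi <- if (isTRUE(cfg$augment)) flipAug(xs[[i]]) else xs[[i]]
        fw <- resnetForward(params, xi, cfg$nstages, cfg$blocks)
        ls <- bceLogit(fw$logits, ts[i, ])
        tl <- tl + ls$loss
        G <- resnetBackward(params, fw$cache, ls$dz,
                            cfg$nstages, cfg$blocks)
        accG <- if (is.null(accG)) G else mapply(function(a, g)
          list(w = a$w + g$w, b = a$b + g$b), accG, G, SIMPLIFY = FALSE)
        nb <- nb + 1
        if (nb == batch || i == ord[length(ord)]) {
          accG <- lapply(accG, function(p)
            list(w = p$w / nb, b = p$b / nb))
          upd <- adamStep(params, clipGrads(accG), state,
                          lr = cfg$learning_rate)
          params <- upd$params; state <- upd$state
          accG <- NULL; nb <- 0
        }
      }
      hist[ep] <- tl / length(xs)
      if (verbose) message(sprintf("epoch %d: loss %.4f", ep, hist[ep]))
    }
    new("CNNClassifier", params = params, config = cfg,
        history = data.frame(epoch = seq_len(cfg$epochs),
                             train_loss = hist))
  })
}

#' @describeIn CNNClassifier pigment scores for images
#' @param object a \code{CNNClassifier}.
#' @param newdata one image array or a list of image arrays.
#' @export
setMethod("predictScores", "CNNClassifier", function(object, newdata) {
  if (!is.list(newdata)) newdata <- list(newdata)
  cfg <- object@config
  out <- t(vapply(newdata, function(im) {
    x <- resizeImage(im, cfg$input_size) - 0.5
    sigmoid(resnetForward(object@params, x, cfg$nstages,
                          cfg$blocks)$logits)
  }, numeric(2)))
  colnames(out) <- c("p_anthocyanin", "p_melanin")
  out
})

#' @describeIn CNNClassifier label prediction via the strict-threshold rule
#' @export
setMethod("predictLabel", "CNNClassifier", function(object, newdata) {
  decideLabel(predictScores(object, newdata),
              object@config$decision_threshold)
})

# ----------------------------------------------------------- multi-task ----

#' MultiTaskModel: joint segmentation + classification-head network
#'
#' One forward pass yields both a grain mask and pigment scores; the joint
#' loss is segmentation (BCE + Dice) plus \code{lambda} times the
#' classification BCE. The classification head global-average-pools the
#' encoder bottleneck.
#'
#' @slot params layer parameters.
#' @slot config the \code{\link{classifierConfig}} used.
#' @slot history per-epoch losses.
#' @export
setClass("MultiTaskModel", representation(params = "list", config = "list",
                                          history = "data.frame"))

setMethod("show", "MultiTaskModel", function(object)
  cat("MultiTaskModel (", object@config$encoder_family,
      "-style encoder, lambda = ", object@config$lambda, ")\n", sep = ""))

#' Train the multi-task segmentation + classification network
#'
#' Requires both supervision signals: region masks and pigment labels.
#'
#' @param images list of H x W x 3 arrays.
#' @param masks list of binary region masks (same order).
#' @param labels character labels in \code{NP/A/M/AM}.
#' @param config a \code{\link{classifierConfig}} with
#'   \code{model_kind = "unet_classhead"}.
#' @param verbose print per-epoch loss.
#' @return a fitted \code{\linkS4class{MultiTaskModel}}.
#' @export
trainMultiTask <- function(images, masks, labels,
                           config = classifierConfig("unet_classhead"),
                           verbose = FALSE) {
  if (length(images) == 0) stop("empty training set")
  if (is.null(masks) || length(masks) != length(images))
    stop("multi-task training requires a region mask per image")
  stopifnot(length(labels) == length(images))
  cfg <- unclass(config)
  preset <- unetPreset(cfg$encoder_family)
  size <- cfg$input_size
  xs <- prepClsImages(images, size)
  ys <- lapply(masks, function(m)
    matrix(as.numeric(resizeImage(m, size, mask = TRUE)), size, size))
  ts <- pigmentFlags(labels) * 1
  withSeed(cfg$seed, {
    params <- unetInit(3L, preset$base, preset$depth, out_ch = 1L,
                       head = 2L, residual_enc = TRUE)
    # phase 1 -- classifier shaping: the encoder + head are optimized on
    # the classification term with full-batch steps, exactly as the
    # stand-alone residual classifier is trained. This commits the
    # encoder bottleneck to carrying the colour-class signal before the
    # (easier) segmentation objective gets to shape the network.
    if (cfg$lambda > 0 && cfg$cls_steps > 0) {
      state <- adamInit(params)
      for (st in seq_len(cfg$cls_steps)) {
        lr <- cfg$learning_rate *
          if (st > 0.85 * cfg$cls_steps) 0.25
          else if (st > 0.6 * cfg$cls_steps) 0.5 else 1
        G <- NULL
        for (i in seq_along(xs)) {
          xi <- if (isTRUE(cfg$augment)) flipAug(xs[[i]]) else xs[[i]]
          if (isTRUE(cfg$color_aug)) xi <- colorAug(xi)
          fw <- unetEncForward(params, xi, preset$depth)
          ls <- bceLogit(fw$headLogits, ts[i, ])
          g <- unetEncBackward(params, fw$cache, preset$depth, ls$dz)
          G <- if (is.null(G)) g else mapply(function(a, b)
            list(w = a$w + b$w, b = a$b + b$b), G, g, SIMPLIFY = FALSE)
        }
        # level-1 stays at its random init: its dense random colour
        # projections are what the segmentation decoder later reads
        # through the full-resolution skip
        G <- G[!grepl("^enc1[a-z]", names(G))]
        G <- lapply(G, function(p) list(w = p$w / length(xs),
                                        b = p$b / length(xs)))
        upd <- adamStep(params, clipGrads(G), state, lr = lr)
        params <- upd$params; state <- upd$state
      }
    }
    # phase 2 -- segmentation: decoder and output layers are fitted with
    # per-image steps; the encoder fine-tunes at a much smaller learning
    # rate so the class information committed in phase 1 is preserved.
    # The skip connections give the decoder full-resolution features to
    # segment from.
    state <- adamInit(params)
    hist <- vector("list", cfg$epochs)
    encNames <- grep("^enc|^head", names(params), value = TRUE)
    for (ep in seq_len(cfg$epochs)) {
      lr <- cfg$learning_rate *
        if (ep > 0.85 * cfg$epochs) 0.25
        else if (ep > 0.6 * cfg$epochs) 0.5 else 1
      ord <- sample(length(xs))
      sl <- 0; cl <- 0
      for (i in ord) {
        pair <- if (isTRUE(cfg$augment)) flipAug(xs[[i]], ys[[i]])
                else list(x = xs[[i]], y = ys[[i]])
        fw <- unetForward(params, pair$x, preset$depth, head = TRUE)
        seg <- segLoss(fw$logits, pair$y)
        cls <- bceLogit(fw$headLogits, ts[i, ])
        sl <- sl + seg$loss; cl <- cl + cls$loss
        G <- clipGrads(unetBackward(params, fw$cache, preset$depth,
                                    seg$dz))
        G[names(G) %in% encNames] <- NULL
        upd <- adamStep(params, G, state, lr = lr)
        params <- upd$params; state <- upd$state
      }
      hist[[ep]] <- data.frame(epoch = ep, seg_loss = sl / length(xs),
                               cls_loss = cl / length(xs))
      if (verbose)
        message(sprintf("epoch %d: seg %.4f cls %.4f", ep,
                        sl / length(xs), cl / length(xs)))
    }
    # phase 3 -- head consolidation on the final features
    if (cfg$lambda > 0 && cfg$head_steps > 0)
      params <- refineHead(params, xs, ts, preset$depth,
                           cfg$head_steps, cfg$learning_rate)
    new("MultiTaskModel", params = params, config = cfg,
        history = if (length(hist)) do.call(rbind, hist)
                  else data.frame())
  })
}

# full-batch optimization of the classification term restricted to the
# head parameters, over cached bottleneck descriptors (plus flipped
# variants): the classification part of the joint loss with everything
# but the head frozen
refineHead <- function(params, xs, ts, depth, steps, lr, decay = 1e-3,
                       raw_enc = FALSE, color_aug = TRUE) {
  feats <- list()
  targs <- list()
  for (i in seq_along(xs)) {
    H <- dim(xs[[i]])[1]; W <- dim(xs[[i]])[2]
    variants <- list(xs[[i]],
                     xs[[i]][, rev(seq_len(W)), , drop = FALSE],
                     xs[[i]][rev(seq_len(H)), , , drop = FALSE],
                     xs[[i]][rev(seq_len(H)), rev(seq_len(W)), ,
                             drop = FALSE])
    if (H == W)
      variants <- c(variants, lapply(variants, aperm, c(2, 1, 3)))
    if (color_aug)
      variants <- c(variants, lapply(variants, colorAug))
    for (v in variants) {
      fw <- unetForward(params, v, depth, head = TRUE,
                        raw_enc = raw_enc)
      feats[[length(feats) + 1L]] <- fw$cache$headv
      targs[[length(targs) + 1L]] <- ts[i, ]
    }
  }
  fm <- do.call(rbind, feats)
  mu <- colMeans(fm)
  sg <- apply(fm, 2, stats::sd)
  sg[sg < 1e-8] <- 1
  feats <- lapply(feats, function(f) (f - mu) / sg)
  hp <- list(head = params$head)
  hstate <- adamInit(hp)
  for (st in seq_len(steps)) {
    G <- NULL
    for (j in seq_along(feats)) {
      z <- denseF(feats[[j]], hp$head)
      ls <- bceLogit(z, targs[[j]])
      g <- denseB(feats[[j]], hp$head, ls$dz)
      G <- if (is.null(G)) list(head = list(w = g$dw, b = g$db))
           else list(head = list(w = G$head$w + g$dw,
                                 b = G$head$b + g$db))
    }
    G$head$w <- G$head$w / length(feats) + decay * hp$head$w
    G$head$b <- G$head$b / length(feats)
    upd <- adamStep(hp, G, hstate, lr = lr)
    hp <- upd$params; hstate <- upd$state
  }
  # fold the feature standardization into the dense layer so the
  # prediction path stays a plain bottleneck-pool + dense head
  w <- sweep(hp$head$w, 2, sg, "/")
  params$head <- list(w = w, b = as.numeric(hp$head$b - w %*% mu))
  params
}

multiTaskForward <- function(object, image) {
  cfg <- object@config
  preset <- unetPreset(cfg$encoder_family)
  x <- resizeImage(image, cfg$input_size) - 0.5
  fw <- unetForward(object@params, x, preset$depth, head = TRUE)
  list(prob = sigmoid(fw$logits[, , 1]), scores = sigmoid(fw$headLogits))
}

#' @describeIn MultiTaskModel pigment scores from the classification head
#' @param object a \code{MultiTaskModel}.
#' @param newdata one image array or a list of arrays.
#' @export
setMethod("predictScores", "MultiTaskModel", function(object, newdata) {
  if (!is.list(newdata)) newdata <- list(newdata)
  out <- t(vapply(newdata, function(im) multiTaskForward(object, im)$scores,
                  numeric(2)))
  colnames(out) <- c("p_anthocyanin", "p_melanin")
  out
})

#' @describeIn MultiTaskModel label prediction
#' @export
setMethod("predictLabel", "MultiTaskModel", function(object, newdata) {
  decideLabel(predictScores(object, newdata),
              object@config$decision_threshold)
})

#' @describeIn MultiTaskModel grain-region mask from the segmentation output
#' @param image an H x W x 3 array.
#' @param threshold probability threshold.
#' @export
setMethod("predictMask", "MultiTaskModel",
          function(object, image, threshold = 0.5) {
  p <- multiTaskForward(object, image)$prob
  resizeImage(matrix(as.integer(p > threshold), nrow(p), ncol(p)),
              dim(image)[1:2], mask = TRUE)
})

# ---------------------------------------------------------- two-channel ----

#' TwoChannelModel: per-pixel pigment segmentation classifier
#'
#' A two-channel segmentation network in which channel 1 segments pixels of
#' anthocyanin-containing grain and channel 2 melanin-containing grain.
#' Image-level labels come from \code{\link{aggregatePixels}} (any-pixel
#' rule by default).
#'
#' @slot params layer parameters.
#' @slot config the \code{\link{classifierConfig}} used.
#' @slot history per-epoch training loss.
#' @export
setClass("TwoChannelModel", representation(params = "list",
                                           config = "list",
                                           history = "data.frame"))

setMethod("show", "TwoChannelModel", function(object)
  cat("TwoChannelModel (", object@config$encoder_family,
      "-style encoder)\n", sep = ""))

#' Build per-pixel pigment supervision from a region mask and a label
#'
#' Label-broadcast weak supervision: all grain pixels of an accession
#' inherit its pigment flags.
#'
#' @param mask binary region mask.
#' @param label the accession's \code{NP/A/M/AM} label.
#' @return H x W x 2 binary array.
#' @export
makePigmentMask <- function(mask, label) {
  fl <- pigmentFlags(label)
  out <- array(0, c(dim(mask), 2))
  out[, , 1] <- (mask > 0) * fl[1, "anthocyanin"]
  out[, , 2] <- (mask > 0) * fl[1, "melanin"]
  out
}

#' Train the two-channel pigment segmentation model
#'
#' @param images list of H x W x 3 arrays.
#' @param pigment_masks list of H x W x 2 arrays (see
#'   \code{\link{makePigmentMask}}).
#' @param config a \code{\link{classifierConfig}} with
#'   \code{model_kind = "unet_classsegment"}; the encoder default is the
#'   deeper residual-family preset.
#' @param verbose print per-epoch loss.
#' @return a fitted \code{\linkS4class{TwoChannelModel}}.
#' @export
trainTwoChannel <- function(images, pigment_masks,
                            config = classifierConfig("unet_classsegment",
                              encoder_family = "resnet34"),
                            verbose = FALSE) {
  if (length(images) == 0) stop("empty training set")
  stopifnot(length(pigment_masks) == length(images))
  bad <- vapply(pigment_masks, function(m)
    length(dim(m)) != 3 || dim(m)[3] != 2, logical(1))
  if (any(bad)) stop("pigment masks must have exactly 2 channels")
  cfg <- unclass(config)
  preset <- unetPreset(cfg$encoder_family)
  size <- cfg$input_size
  xs <- prepClsImages(images, size)
  ys <- lapply(pigment_masks, function(m) {
    out <- array(0, c(size, size, 2))
    out[, , 1] <- resizeImage(m[, , 1], size, mask = TRUE)
    out[, , 2] <- resizeImage(m[, , 2], size, mask = TRUE)
    out
  })
  withSeed(cfg$seed, {
    params <- unetInit(3L, preset$base, preset$depth, out_ch = 2L)
    state <- adamInit(params)
    hist <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      # step decay consolidates the late-emerging channel separation
      lr <- cfg$learning_rate *
        if (ep > 0.85 * cfg$epochs) 0.25
        else if (ep > 0.6 * cfg$epochs) 0.5 else 1
      ord <- sample(length(xs))
      tl <- 0
      for (i in ord) {
        pair <- if (isTRUE(cfg$augment)) flipAug(xs[[i]], ys[[i]])
                else list(x = xs[[i]], y = ys[[i]])
        fw <- unetForward(params, pair$x, preset$depth, raw_level1 = TRUE)
        bce <- bceLogit(fw$logits, pair$y)
        dic <- diceLogit(fw$logits, pair$y)
        tl <- tl + bce$loss + dic$loss
        G <- clipGrads(unetBackward(params, fw$cache, preset$depth,
                                    bce$dz + dic$dz, raw_level1 = TRUE))
        upd <- adamStep(params, G, state, lr = lr)
        params <- upd$params; state <- upd$state
      }
      hist[ep] <- tl / length(xs)
      if (verbose) message(sprintf("epoch %d: loss %.4f", ep, hist[ep]))
    }
    new("TwoChannelModel", params = params, config = cfg,
        history = data.frame(epoch = seq_len(cfg$epochs),
                             train_loss = hist))
  })
}

#' @describeIn TwoChannelModel two-channel pigment mask prediction
#' @param object a \code{TwoChannelModel}.
#' @param image an H x W x 3 array.
#' @param threshold per-pixel probability threshold.
#' @export
setMethod("predictMask", "TwoChannelModel",
          function(object, image, threshold = 0.5) {
  cfg <- object@config
  preset <- unetPreset(cfg$encoder_family)
  x <- resizeImage(image, cfg$input_size) - 0.5
  fw <- unetForward(object@params, x, preset$depth, raw_level1 = TRUE)
  p <- sigmoid(fw$logits)
  m <- array(0L, c(dim(image)[1:2], 2))
  for (ch in 1:2)
    m[, , ch] <- resizeImage(
      matrix(as.integer(p[, , ch] > threshold), nrow(p), ncol(p)),
      dim(image)[1:2], mask = TRUE)
  m
})

#' @describeIn TwoChannelModel image-level label via pixel aggregation
#' @param newdata one image array or a list of arrays.
#' @param min_fraction aggregation threshold (default 0: any-pixel rule).
#' @export
setMethod("predictLabel", "TwoChannelModel",
          function(object, newdata, min_fraction = 0) {
  if (!is.list(newdata)) newdata <- list(newdata)
  vapply(newdata, function(im)
    aggregatePixels(predictMask(object, im), min_fraction), character(1))
})
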