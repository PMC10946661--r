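# End-to-end orchestration: generate -> split -> (train-seg) -> features /
# crops -> train classifier -> predict -> evaluate, from one declarative
# YAML config, with per-stage derived seeds and structured logging.

pipelineDefaults <- function() list(
  seed = 1L,
  out_dir = NULL,
  generator = list(classes = c(NP = 3, A = 3, M = 3, AM = 3),
                   hulled_fraction = 0.5, image_size = 96L,
                   replicates = 3L, mode = "default",
                   noise_sigma = 0.015),
  split = list(fractions = c(0.6, 0.2, 0.2)),
  segmenter = list(enabled = FALSE, input_size = 96L, epochs = 4L,
                   encoder_family = "resnet18", learning_rate = 0.02),
  classifier = list(model_kind = "rf13", input_size = 64L,
                    epochs = NULL, learning_rate = 0.02, ntree = 500L,
                    k = 13L, lambda = 1,
                    encoder_family = "efficientnetb0",
                    decision_threshold = 0.5),
  evaluation = list(min_fraction = 0))

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

# FNV-1a over the ASCII serialization: stable run-manifest fingerprint
configHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, ascii = TRUE))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

stageLog <- function(stage, seed, t0, note = "") {
  message(sprintf("[%s] seed=%d elapsed=%.1fs %s", stage, seed,
                  as.numeric(Sys.time()) - t0, note))
}

runStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full grain-pigment pipeline
#'
#' Executes generation (or manifest loading), accession-level splitting,
#' optional segmenter training, feature extraction or cropping, classifier
#' training for the configured model kind, prediction on the test split,
#' and evaluation. All artifacts (manifest, predictions CSV, evaluation
#' JSON, run manifest with config hash) are written under the output
#' directory. Every stochastic stage derives its seed from the global seed
#' and the stage name, so two runs with the same config are identical.
#'
#' @param config a configuration list, or the path to a YAML file with the
#'   same structure; see \code{pipelineDefaults} in the package source for
#'   the sections (generator, split, segmenter, classifier, evaluation).
#' @param overrides optional named list merged over the config (CLI flags).
#' @return list with \code{manifest}, \code{model}, \code{predictions}
#'   (data.frame), \code{report} (an \code{\linkS4class{EvalReport}}) and
#'   \code{out_dir}.
#' @export
runPipeline <- function(config = list(), overrides = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- mergeConfig(pipelineDefaults(), config)
  if (!is.null(overrides)) cfg <- mergeConfig(cfg, overrides)
  if (is.null(cfg$out_dir)) cfg$out_dir <- tempfile("grainrun")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  t0 <- as.numeric(Sys.time())
  hcfg <- cfg
  hcfg$out_dir <- NULL          # the hash identifies the configuration
  hash <- configHash(hcfg)

  # ---- generate -----------------------------------------------------------
  genSeed <- stageSeed(seed, "generate")
  manifest <- runStage("generate", {
    g <- cfg$generator
    if (!is.null(cfg$data$manifest)) loadManifest(cfg$data$manifest)
    else generateDataset(unlist(g$classes),
                         renderConfig(image_size = g$image_size,
                                      replicates_per_accession =
                                        g$replicates,
                                      noise_sigma = g$noise_sigma),
                         seed = genSeed,
                         dir = file.path(cfg$out_dir, "data"),
                         hulledFraction = g$hulled_fraction,
                         mode = g$mode)
  })
  stageLog("generate", genSeed, t0, paste(nImages(manifest), "images"))

  # ---- split --------------------------------------------------------------
  splitSeed <- stageSeed(seed, "split")
  manifest <- runStage("split",
    stratifiedSplit(manifest, unlist(cfg$split$fractions),
                    seed = splitSeed))
  saveManifest(manifest, file.path(cfg$out_dir, "manifest_split.csv"))
  stageLog("split", splitSeed, t0,
           paste(capture.output(print(splitCounts(manifest)))[2],
                 collapse = ""))

  trainRec <- manifestRecords(manifestSplit(manifest, "train"))
  valRec <- manifestRecords(manifestSplit(manifest, "val"))
  testRec <- manifestRecords(manifestSplit(manifest, "test"))

  # ---- segmentation (optional) -------------------------------------------
  segmenter <- NULL
  if (isTRUE(cfg$segmenter$enabled)) {
    segSeed <- stageSeed(seed, "train-seg")
    segmenter <- runStage("train-seg", {
      sc <- segmenterConfig(cfg$segmenter$encoder_family,
                            cfg$segmenter$input_size,
                            cfg$segmenter$epochs,
                            learning_rate = cfg$segmenter$learning_rate,
                            seed = segSeed)
      trainSegmenter(buildSegmenter(sc), GrainManifest(trainRec),
                     GrainManifest(valRec))
    })
    stageLog("train-seg", segSeed, t0,
             sprintf("val IoU %.3f",
                     segmenter@history$val_iou[nrow(segmenter@history)]))
  }

  maskOf <- function(rec, i) {
    if (!is.na(rec$mask_path[i]) && is.null(segmenter))
      readMask(rec$mask_path[i])
    else if (!is.null(segmenter))
      predictMask(segmenter, readImageRGB(rec$image_path[i]))
    else stop("no mask source for ", rec$image_path[i])
  }

  # ---- classifier ---------------------------------------------------------
  kind <- cfg$classifier$model_kind
  clsSeed <- stageSeed(seed, paste0("train-", kind))
  cc <- cfg$classifier
  loadImgs <- function(rec) lapply(rec$image_path, readImageRGB)
  model <- runStage(paste0("train-", kind), switch(kind,
    rf13 = {
      feats <- extractFeatures(GrainManifest(trainRec), segmenter)
      trainRF13(feats, ntree = cc$ntree, k = cc$k, seed = clsSeed)
    },
    cnn = {
      imgs <- loadImgs(trainRec)
      crops <- lapply(seq_along(imgs), function(i)
        cropGrainRegion(imgs[[i]], maskOf(trainRec, i), padding = 2))
      trainCNNClassifier(crops, trainRec$pigment_label,
                         classifierConfig("cnn",
                           input_size = cc$input_size,
                           epochs = cc$epochs,
                           learning_rate = cc$learning_rate,
                           decision_threshold = cc$decision_threshold,
                           seed = clsSeed))
    },
    unet_classhead = {
      imgs <- loadImgs(trainRec)
      msks <- lapply(seq_len(nrow(trainRec)), function(i)
        maskOf(trainRec, i))
      trainMultiTask(imgs, msks, trainRec$pigment_label,
                     classifierConfig("unet_classhead",
                       input_size = cc$input_size, epochs = cc$epochs,
                       learning_rate = cc$learning_rate,
                       lambda = cc$lambda,
                       encoder_family = cc$encoder_family,
                       decision_threshold = cc$decision_threshold,
                       seed = clsSeed))
    },
    unet_classsegment = {
      imgs <- loadImgs(trainRec)
      pms <- lapply(seq_len(nrow(trainRec)), function(i)
        makePigmentMask(maskOf(trainRec, i), trainRec$pigment_label[i]))
      trainTwoChannel(imgs, pms,
                      classifierConfig("unet_classsegment",
                        input_size = cc$input_size, epochs = cc$epochs,
                        learning_rate = cc$learning_rate,
                        encoder_family = "resnet34",
                        decision_threshold = cc$decision_threshold,
                        seed = clsSeed))
    },
    stop("unknown model_kind '", kind, "'")))
  stageLog(paste0("train-", kind), clsSeed, t0)

  # ---- predict ------------------------------------------------------------
  predictions <- runStage("predict", {
    if (kind == "rf13") {
      feats <- extractFeatures(GrainManifest(testRec), segmenter)
      sc <- predictScores(model, feats)
      lab <- predictLabel(model, feats)
    } else if (kind == "cnn") {
      imgs <- loadImgs(testRec)
      crops <- lapply(seq_along(imgs), function(i)
        cropGrainRegion(imgs[[i]], maskOf(testRec, i), padding = 2))
      sc <- predictScores(model, crops)
      lab <- decideLabel(sc, cc$decision_threshold)
    } else if (kind == "unet_classhead") {
      imgs <- loadImgs(testRec)
      sc <- predictScores(model, imgs)
      lab <- decideLabel(sc, cc$decision_threshold)
    } else {
      imgs <- loadImgs(testRec)
      masks <- lapply(imgs, function(im) predictMask(model, im))
      # report the positive-pixel fraction per channel as the score
      sc <- t(vapply(masks, function(m) apply(m > 0, 3, mean), numeric(2)))
      lab <- vapply(masks, aggregatePixels,
                    min_fraction = cfg$evaluation$min_fraction,
                    character(1))
    }
    data.frame(image_path = testRec$image_path,
               p_anthocyanin = sc[, 1], p_melanin = sc[, 2],
               predicted_label = lab, true_label = testRec$pigment_label,
               hulled = testRec$hulled, stringsAsFactors = FALSE)
  })
  write.csv(predictions, file.path(cfg$out_dir, "predictions.csv"),
            row.names = FALSE)
  stageLog("predict", clsSeed, t0, paste(nrow(predictions), "images"))

  # ---- evaluate -----------------------------------------------------------
  report <- runStage("evaluate", {
    h <- predictions$hulled
    computeACC(predictions$predicted_label, predictions$true_label,
               hulled = if (length(unique(h)) == 2) h else NULL)
  })
  writeEvalReport(report, file.path(cfg$out_dir, "evaluation.json"))
  jsonlite::write_json(
    list(config_hash = hash, seed = seed,
         package_version = as.character(utils::packageVersion(
           "grainPigment")),
         stages = c("generate", "split",
                    if (isTRUE(cfg$segmenter$enabled)) "train-seg",
                    paste0("train-", kind), "predict", "evaluate")),
    file.path(cfg$out_dir, "run_manifest.json"), auto_unbox = TRUE)
  stageLog("evaluate", seed, t0, sprintf("ACC %.3f", report@pooled$acc))

  list(manifest = manifest, model = model, predictions = predictions,
       report = report, segmenter = segmenter, out_dir = cfg$out_dir,
       config_hash = hash)
}
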