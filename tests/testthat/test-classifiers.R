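test_that("decideLabel applies the strict-threshold rule exhaustively", {
  grid <- expand.grid(a = c(0, 0.25, 0.5, 0.55, 0.75, 1),
                      m = c(0, 0.25, 0.5, 0.55, 0.75, 1))
  lab <- decideLabel(as.matrix(grid))
  expected <- flagsToLabel(grid$a > 0.5, grid$m > 0.5)
  expect_equal(lab, expected)
  # spot checks from the rule definition
  expect_equal(decideLabel(c(0.7, 0.2)), "A")
  expect_equal(decideLabel(c(0.5, 0.5)), "NP")    # strict inequality
  expect_equal(decideLabel(c(0.9, 0.9)), "AM")
  expect_error(decideLabel(c(1.2, 0)), "scores")
})

test_that("decideLabel is monotone in each score", {
  set.seed(31)
  for (i in 1:50) {
    s <- runif(2)
    lab <- decideLabel(s)
    up <- pmin(s + runif(2, 0, 1 - 0), 1)
    labUp <- decideLabel(pmax(s, up))
    # raising scores never removes a pigment
    f0 <- pigmentFlags(lab); f1 <- pigmentFlags(labUp)
    expect_true(all(f1[f0]))
  }
})

test_that("aggregatePixels implements the any-pixel rule", {
  m <- array(0L, c(6, 6, 2))
  expect_equal(aggregatePixels(m), "NP")
  m[3, 3, 1] <- 1L
  expect_equal(aggregatePixels(m), "A")            # one pixel is enough
  m[1, 1, 2] <- 1L
  expect_equal(aggregatePixels(m), "AM")
  # a fraction threshold suppresses sparse positives: 1/36 ~ 2.8%
  expect_equal(aggregatePixels(m, min_fraction = 0.05), "NP")
  expect_error(aggregatePixels(matrix(0, 4, 4)), "2 channels")
  expect_error(aggregatePixels(array(0, c(4, 4, 3))), "2 channels")
})

test_that("the representation entering the forest is 13-dimensional", {
  set.seed(32)
  n <- 40
  lab <- rep(pigmentLevels(), each = 10)
  # descriptor-scale features: positive values on [0.1, 1]
  centers <- matrix(runif(4 * 30, 0.3, 0.9), 4, 30)
  x <- centers[match(lab, pigmentLevels()), ] +
    matrix(rnorm(n * 30, sd = 0.03), n)
  x <- pmin(pmax(x, 0.1), 1)
  x <- cbind(x, const = 1, dup = x[, 1] * 2)
  colnames(x) <- sprintf("d%02d", seq_len(ncol(x)))
  rf <- suppressWarnings(trainRF13(x, lab, ntree = 100, seed = 1))
  z <- grainPigment:::rf13Representation(rf, x)
  expect_equal(ncol(z), 13L)
  # well-separated classes are recovered on the training set
  expect_gte(mean(predictLabel(rf, x) == lab), 0.95)
  sc <- predictScores(rf, x)
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("RF13 predictions ignore filtered-out columns", {
  set.seed(33)
  lab <- rep(pigmentLevels(), each = 8)
  centers <- matrix(runif(4 * 20, 0.3, 0.9), 4, 20)
  x <- centers[match(lab, pigmentLevels()), ] +
    matrix(rnorm(32 * 20, sd = 0.04), 32)
  x <- pmin(pmax(x, 0.1), 1)
  colnames(x) <- sprintf("d%02d", seq_len(ncol(x)))
  x <- cbind(x, dead = 5)              # constant: dropped by rule 1
  rf <- suppressWarnings(trainRF13(x, lab, ntree = 50, k = 5, seed = 2))
  x2 <- x
  x2[, "dead"] <- rnorm(32)            # perturb only the dropped column
  expect_equal(predictLabel(rf, x2), predictLabel(rf, x))
})

test_that("RF13 training is invariant to row order given the seed", {
  set.seed(34)
  lab <- rep(c("NP", "M"), each = 10)
  x <- matrix(runif(20 * 15, 0.2, 0.6), 20)
  x[lab == "M", ] <- x[lab == "M", ] + 0.3
  colnames(x) <- sprintf("d%02d", 1:15)
  rf1 <- suppressWarnings(trainRF13(x, lab, ntree = 100, k = 3, seed = 7))
  ord <- sample(20)
  rf2 <- suppressWarnings(trainRF13(x[ord, ], lab[ord], ntree = 100,
                                    k = 3, seed = 7))
  xt <- matrix(runif(10 * 15, 0.2, 0.9), 10)
  colnames(xt) <- colnames(x)
  expect_equal(predictLabel(rf1, xt), predictLabel(rf2, xt))
  expect_warning(trainRF13(x, lab, ntree = 10, k = 2, seed = 1),
                 "absent")
})

test_that("classifier networks respect their output contracts", {
  cfg <- classifierConfig("cnn", epochs = 1)
  # untrained networks already emit scores in [0, 1]
  imgs <- list(array(runif(64 * 64 * 3), c(64, 64, 3)))
  cnn <- trainCNNClassifier(imgs, "A",
                            classifierConfig("cnn", epochs = 1, seed = 1))
  sc <- predictScores(cnn, imgs)
  expect_equal(dim(sc), c(1L, 2L))
  expect_true(all(sc >= 0 & sc <= 1))
  expect_error(trainCNNClassifier(list(), character(0), cfg), "empty")
  # width scaling changes parameter counts monotonically
  gp <- asNamespace("grainPigment")
  small <- gp$paramCount(gp$resnetInit(3, 8, 3, 2, 2))
  big <- gp$paramCount(gp$resnetInit(3, 16, 3, 2, 2))
  deeper <- gp$paramCount(gp$resnetInit(3, 8, 4, 2, 2))
  expect_lt(small, big)
  expect_lt(small, deeper)
})

test_that("multi-task forward returns a mask and two bounded scores", {
  sp <- sharedSplit64()
  rec <- sp$train[1:2, ]
  mt <- trainMultiTask(loadImages(rec), loadMasks(rec), rec$pigment_label,
                       classifierConfig("unet_classhead", input_size = 64,
                                        epochs = 1, cls_steps = 2,
                                        head_steps = 5, seed = 1))
  img <- readImageRGB(rec$image_path[1])
  m <- predictMask(mt, img)
  expect_equal(dim(m), dim(img)[1:2])
  sc <- predictScores(mt, img)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_error(trainMultiTask(loadImages(rec), NULL, rec$pigment_label),
               "mask")
})

test_that("lambda = 0 degenerates multi-task training to pure segmentation",
{
  sp <- sharedSplit64()
  rec <- sp$train[1:2, ]
  cfg <- classifierConfig("unet_classhead", input_size = 64, epochs = 1,
                          cls_steps = 50, head_steps = 100, lambda = 0,
                          seed = 3)
  mt <- trainMultiTask(loadImages(rec), loadMasks(rec),
                       rec$pigment_label, cfg)
  # with no classification weight the head keeps its initialization
  gp <- asNamespace("grainPigment")
  preset <- gp$unetPreset(cfg$encoder_family)
  init <- gp$withSeed(cfg$seed,
                      gp$unetInit(3L, preset$base, preset$depth,
                                  out_ch = 1L, head = 2L,
                                  residual_enc = TRUE))
  expect_identical(mt@params$head, init$head)
})

test_that("pigment-mask supervision is the label-broadcast of the region",
{
  msk <- matrix(0L, 5, 5); msk[2:3, 2:4] <- 1L
  pmA <- makePigmentMask(msk, "A")
  expect_equal(pmA[, , 1], msk + 0)
  expect_true(all(pmA[, , 2] == 0))
  pmAM <- makePigmentMask(msk, "AM")
  expect_equal(pmAM[, , 1], pmAM[, , 2])
  expect_true(all(makePigmentMask(msk, "NP") == 0))
})

test_that("two-channel training rejects malformed supervision", {
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  bad <- array(0, c(64, 64, 3))
  expect_error(trainTwoChannel(list(img), list(bad)), "2 channels")
  expect_error(trainTwoChannel(list(), list()), "empty")
})
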