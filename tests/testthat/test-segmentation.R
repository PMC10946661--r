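test_that("segmenter construction honors the architecture contract", {
  cfg <- segmenterConfig(input_size = 64, seed = 5)
  seg <- buildSegmenter(cfg)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  m <- predictMask(seg, img)
  expect_equal(dim(m), c(64L, 64L))            # output size = input size
  expect_true(all(m %in% c(0L, 1L)))
  # untrained probabilities lie strictly inside (0, 1): thresholds at the
  # extremes saturate the mask
  expect_true(all(predictMask(seg, img, threshold = 0) == 1L))
  expect_true(all(predictMask(seg, img, threshold = 1) == 0L))
  # identical seeds give identical initializations
  seg2 <- buildSegmenter(segmenterConfig(input_size = 64, seed = 5))
  expect_identical(seg@params, seg2@params)
  seg3 <- buildSegmenter(segmenterConfig(input_size = 64, seed = 6))
  expect_false(identical(seg@params, seg3@params))
  expect_error(segmenterConfig(input_size = 100), "divisible by 32")
})

test_that("a short training run reduces the loss and is reproducible", {
  m <- sharedDataset64()
  rec <- manifestRecords(m)
  tr <- GrainManifest(rec[1:6, ])
  va <- GrainManifest(rec[7:8, ])
  cfg <- segmenterConfig(input_size = 64, epochs = 2, seed = 1)
  fit <- trainSegmenter(buildSegmenter(cfg), tr, va)
  h <- fit@history
  expect_equal(nrow(h), 2L)
  expect_true(all(is.finite(h$train_loss)))
  expect_lt(h$train_loss[2], h$train_loss[1])
  expect_true(all(is.finite(h$val_iou)))
  # reproducibility of the whole run
  fit2 <- trainSegmenter(buildSegmenter(cfg), tr, va)
  expect_equal(fit@history, fit2@history, tolerance = 1e-12)
  expect_error(trainSegmenter(buildSegmenter(cfg),
                              GrainManifest(rec[0, ]), va), "empty")
})

test_that("cropGrainRegion matches an exhaustive coordinate scan", {
  set.seed(21)
  img <- array(runif(20 * 17 * 3), c(20, 17, 3))
  msk <- matrix(0L, 20, 17)
  msk[cbind(sample(3:18, 6), sample(2:16, 6))] <- 1L
  crop <- cropGrainRegion(img, msk, padding = 0)
  fg <- which(msk > 0, arr.ind = TRUE)
  expect_equal(dim(crop)[1:2],
               c(max(fg[, 1]) - min(fg[, 1]) + 1L,
                 max(fg[, 2]) - min(fg[, 2]) + 1L))
  expect_equal(crop[1, 1, ], img[min(fg[, 1]), min(fg[, 2]), ])

  # single pixel, zero padding: a 1 x 1 crop at that pixel
  one <- matrix(0L, 20, 17); one[7, 9] <- 1L
  c1 <- cropGrainRegion(img, one, padding = 0)
  expect_equal(dim(c1), c(1L, 1L, 3L))
  expect_equal(c1[1, 1, ], img[7, 9, ])

  # full-frame mask returns the whole image; padding clips at the border
  expect_equal(cropGrainRegion(img, matrix(1L, 20, 17), padding = 5), img)
  expect_error(cropGrainRegion(img, matrix(0L, 20, 17)), "empty mask")
})

test_that("maskIoU is exact on constructed masks", {
  a <- matrix(0L, 4, 4); a[1:2, 1:2] <- 1L
  b <- matrix(0L, 4, 4); b[2:3, 1:2] <- 1L
  expect_equal(maskIoU(a, b), 2 / 6)
  expect_equal(maskIoU(a, a), 1)
  expect_equal(maskIoU(a * 0, a * 0), 1)
  expect_equal(maskIoU(a, a * 0), 0)
})
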