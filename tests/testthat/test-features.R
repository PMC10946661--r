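test_that("the default registry has exactly 2,380 named descriptors", {
  nm <- descriptorNames()
  expect_length(nm, 2380L)
  expect_false(anyDuplicated(nm) > 0)
  img <- array(runif(24 * 24 * 3), c(24, 24, 3))
  msk <- matrix(rbinom(24 * 24, 1, 0.5), 24, 24)
  msk[1] <- 1L
  v <- extractDescriptors(img, msk)
  expect_length(v, 2380L)
  expect_true(all(is.finite(v)))
  expect_equal(names(v), nm)
})

test_that("a constant gray foreground gives degenerate statistics", {
  img <- array(0.5, c(10, 10, 3))
  msk <- matrix(1L, 10, 10)
  v <- extractDescriptors(img, msk)
  expect_equal(unname(v["RGB.R.mean"]), 0.5)
  expect_equal(unname(v["RGB.G.sd"]), 0)
  hist <- v[grep("^RGB\\.B\\.hist_", names(v))]
  expect_equal(sum(hist), 1)
  expect_equal(max(hist), 1)           # one bin holds all pixels
  expect_equal(unname(v["region.area_fraction"]), 1)
  expect_equal(unname(v["gray.dark_fraction"]), 0)
})

test_that("channel means match a per-pixel brute-force average", {
  set.seed(4)
  img <- array(runif(12 * 12 * 3), c(12, 12, 3))
  msk <- matrix(rbinom(144, 1, 0.4), 12, 12)
  msk[5, 5] <- 1L
  v <- extractDescriptors(img, msk)
  # independent pixel loop
  acc <- c(0, 0, 0); n <- 0
  for (r in 1:12) for (cl in 1:12) if (msk[r, cl] > 0) {
    acc <- acc + img[r, cl, ]
    n <- n + 1
  }
  expect_equal(unname(v[c("RGB.R.mean", "RGB.G.mean", "RGB.B.mean")]),
               acc / n, tolerance = 1e-12)
  # every histogram block sums to one
  for (pre in c("HSV.S", "Lab.L", "YCrCb.Cr")) {
    hist <- v[grep(paste0("^", pre, "\\.hist_"), names(v))]
    expect_equal(sum(hist), 1, tolerance = 1e-12)
  }
})

test_that("descriptors ignore background pixels entirely", {
  set.seed(5)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  msk <- matrix(0L, 16, 16); msk[4:9, 6:12] <- 1L
  v1 <- extractDescriptors(img, msk)
  img2 <- img
  bg <- which(msk == 0)
  for (ch in 1:3) {
    pl <- img2[, , ch]; pl[bg] <- runif(length(bg)); img2[, , ch] <- pl
  }
  expect_identical(v1, extractDescriptors(img2, msk))
})

test_that("invalid inputs are rejected", {
  img <- array(0.5, c(8, 8, 3))
  expect_error(extractDescriptors(img, matrix(0L, 8, 8)), "empty mask")
  expect_error(extractDescriptors(img[, , 1], matrix(1L, 8, 8)), "RGB")
  expect_error(extractDescriptors(img, matrix(1L, 4, 4)), "dimensions")
})

test_that("extractFeatures returns a well-formed GrainFeatures", {
  m <- sharedDataset64()
  rec <- manifestRecords(m)[1:4, ]
  gf <- extractFeatures(GrainManifest(rec))
  expect_s4_class(gf, "GrainFeatures")
  fm <- featureMatrix(gf)
  expect_equal(dim(fm), c(4L, 2380L))
  expect_equal(SummarizedExperiment::colData(gf)$pigment_label,
               rec$pigment_label)
})
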