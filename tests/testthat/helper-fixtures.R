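# Shared fixtures, generated once per test session and cached on disk in
# the session temp directory.

.fixtureCache <- new.env(parent = emptyenv())

# records-only manifest (no images on disk): accession/label arithmetic
makeRecords <- function(nPerClass, reps = 9L, hulledFraction = 0.5) {
  recs <- list()
  for (lab in names(nPerClass)) {
    n <- nPerClass[[lab]]
    nH <- round(n * hulledFraction)
    for (i in seq_len(n)) {
      id <- sprintf("%s_%03d", lab, i)
      recs[[length(recs) + 1L]] <- data.frame(
        accession_id = id, pigment_label = lab, hulled = i <= nH,
        replicate = seq_len(reps),
        image_path = sprintf("%s_%02d.png", id, seq_len(reps)),
        stringsAsFactors = FALSE)
    }
  }
  GrainManifest(do.call(rbind, recs))
}

# 16 accessions x 3 replicates at 64 px: the classifier-scale dataset
sharedDataset64 <- function() {
  if (is.null(.fixtureCache$ds64)) {
    dir <- file.path(tempdir(), "gp_ds64")
    if (!file.exists(file.path(dir, "manifest.csv")))
      generateDataset(c(NP = 4, A = 4, M = 4, AM = 4),
                      renderConfig(image_size = 64,
                                   replicates_per_accession = 3),
                      seed = 31, dir = dir, hulledFraction = 0.5)
    .fixtureCache$ds64 <- loadManifest(file.path(dir, "manifest.csv"))
  }
  .fixtureCache$ds64
}

# train/test split of the 64 px set at accession level (2 + 2 per class)
sharedSplit64 <- function() {
  rec <- manifestRecords(sharedDataset64())
  acc <- unique(rec$accession_id)
  trainAcc <- acc[rep(c(TRUE, FALSE, TRUE, FALSE), 4)]
  list(train = rec[rec$accession_id %in% trainAcc, ],
       test = rec[!rec$accession_id %in% trainAcc, ])
}

# 28 images at 128 px for segmentation recovery (20 train + 8 val)
sharedSegData128 <- function() {
  if (is.null(.fixtureCache$seg128)) {
    dir <- file.path(tempdir(), "gp_seg128")
    if (!file.exists(file.path(dir, "manifest.csv")))
      generateDataset(c(NP = 2, A = 2, M = 2, AM = 1),
                      renderConfig(image_size = 128,
                                   replicates_per_accession = 4),
                      seed = 21, dir = dir, hulledFraction = 0.5)
    .fixtureCache$seg128 <- loadManifest(file.path(dir, "manifest.csv"))
  }
  .fixtureCache$seg128
}

loadImages <- function(rec) lapply(rec$image_path, readImageRGB)
loadMasks <- function(rec) lapply(rec$mask_path, readMask)

cropSet <- function(rec, padding = 2) {
  lapply(seq_len(nrow(rec)), function(i)
    cropGrainRegion(readImageRGB(rec$image_path[i]),
                    readMask(rec$mask_path[i]), padding))
}
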