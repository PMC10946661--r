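# Accession-level stratified partitioning. The splitting unit is the
# accession: all replicates follow their accession into one split, so no
# accession can leak across splits. Strata are pigment class x hull status.
# Apportionment uses the largest-remainder rule at two levels: global split
# targets are fixed first (largest remainder on the total accession count),
# then per-stratum floors, then the remaining seats are assigned by largest
# per-stratum remainder subject to the global targets. On 79 accessions with
# fractions (0.6, 0.2, 0.2) this yields 47/16/16 for any seed and any
# stratum composition.

#' Stratified accession-level train/val/test split
#'
#' @param manifest a \code{\linkS4class{GrainManifest}}.
#' @param fractions positive numeric of length 3 summing to 1
#'   (train, val, test).
#' @param seed integer seed (shuffles accessions within strata and breaks
#'   remainder ties).
#' @param holdout optional character vector of accession ids designated as
#'   the holdout set; they are excluded from the fractions and assigned
#'   split \code{"holdout"}.
#' @return the manifest with its \code{split} column filled.
#' @examples
#' rec <- expand.grid(replicate = 1:9, accession_id = sprintf("a%02d", 1:10),
#'                    stringsAsFactors = FALSE)
#' rec$pigment_label <- rep(c("NP", "A"), each = 45)
#' rec$hulled <- TRUE
#' rec$image_path <- sprintf("%s_%d.png", rec$accession_id, rec$replicate)
#' m <- stratifiedSplit(GrainManifest(rec), seed = 1)
#' splitCounts(m)
#' @export
stratifiedSplit <- function(manifest, fractions = c(0.6, 0.2, 0.2),
                            seed = 1, holdout = NULL) {
  stopifnot(is(manifest, "GrainManifest"))
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be non-negative and sum to 1")
  rec <- manifestRecords(manifest)
  splits <- c("train", "val", "test")

  acc <- unique(rec[c("accession_id", "pigment_label", "hulled")])
  if (!is.null(holdout)) {
    unknown <- setdiff(holdout, acc$accession_id)
    if (length(unknown))
      stop("holdout accession(s) not in manifest: ",
           paste(unknown, collapse = ", "))
  }
  pool <- acc[!acc$accession_id %in% holdout, , drop = FALSE]
  n <- nrow(pool)
  if (n == 0) stop("no accessions left to split")

  targets <- largestRemainder(n, fractions)
  stratum <- paste(pool$pigment_label, ifelse(pool$hulled, "H", "h"),
                   sep = ".")
  strata <- split(seq_len(n), stratum)

  nonzeroBins <- sum(fractions > 0)
  small <- vapply(strata, length, 1L) < nonzeroBins
  if (any(small))
    warning("stratum/strata with fewer accessions than split bins: ",
            paste(names(strata)[small], collapse = ", "),
            "; assigned by rounding priority")

  withSeed(seed, {
    floors <- t(vapply(strata, function(ix)
      floor(length(ix) * fractions), numeric(3)))
    capacity <- targets - colSums(floors)
    rem <- t(vapply(strata, function(ix)
      length(ix) * fractions, numeric(3))) - floors
    seats <- vapply(strata, length, 1L) - rowSums(floors)

    # one seat at most per (stratum, split) cell in the main pass
    cells <- expand.grid(s = seq_along(strata), j = 1:3)
    cells$rem <- rem[cbind(cells$s, cells$j)]
    cells <- cells[sample(nrow(cells)), ]          # seeded tie-break
    cells <- cells[order(cells$rem, decreasing = TRUE), ]
    alloc <- floors
    for (i in seq_len(nrow(cells))) {
      s <- cells$s[i]; j <- cells$j[i]
      if (seats[s] > 0 && capacity[j] > 0) {
        alloc[s, j] <- alloc[s, j] + 1
        seats[s] <- seats[s] - 1
        capacity[j] <- capacity[j] - 1
      }
    }
    # rare dead-ends: give remaining seats to any split with capacity
    for (s in which(seats > 0)) while (seats[s] > 0) {
      j <- which(capacity > 0)[1]
      alloc[s, j] <- alloc[s, j] + 1
      seats[s] <- seats[s] - 1
      capacity[j] <- capacity[j] - 1
    }

    assign <- setNames(rep(NA_character_, n), pool$accession_id)
    for (s in seq_along(strata)) {
      ix <- strata[[s]]
      ix <- ix[sample(length(ix))]
      lab <- rep(splits, times = alloc[s, ])
      assign[pool$accession_id[ix]] <- lab
    }
    rec$split <- unname(assign[rec$accession_id])
    if (!is.null(holdout))
      rec$split[rec$accession_id %in% holdout] <- "holdout"
    GrainManifest(rec)
  })
}

#' Accession and image counts per split
#'
#' @param manifest a split \code{\linkS4class{GrainManifest}}.
#' @return data.frame with columns \code{split}, \code{accessions},
#'   \code{images}.
#' @export
splitCounts <- function(manifest) {
  rec <- manifestRecords(manifest)
  rec <- rec[!is.na(rec$split), , drop = FALSE]
  out <- do.call(rbind, lapply(split(rec, rec$split), function(d)
    data.frame(split = d$split[1],
               accessions = length(unique(d$accession_id)),
               images = nrow(d), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
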