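#' @include AllGenerics.R labels.R
NULL

#' GrainManifest: accession-level image manifest
#'
#' Holds one record per image: the accession it belongs to, the accession's
#' pigment label and hull status, the replicate index, image/mask paths and
#' (after partitioning) the split assignment. All replicates of an accession
#' share one pigment label, one hull flag and one split; the splitting unit
#' is always the accession, never the image.
#'
#' @slot records data.frame with columns \code{accession_id},
#'   \code{pigment_label}, \code{hulled}, \code{replicate},
#'   \code{image_path}, \code{mask_path}, \code{split}.
#' @export
setClass("GrainManifest", representation(records = "data.frame"))

manifestColumns <- function()
  c("accession_id", "pigment_label", "hulled", "replicate",
    "image_path", "mask_path", "split")

setValidity("GrainManifest", function(object) {
  rec <- object@records
  need <- manifestColumns()
  miss <- setdiff(need, names(rec))
  if (length(miss))
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(rec)) {
    bad <- !rec$pigment_label %in% pigmentLevels()
    if (any(bad)) return("pigment_label outside {NP, A, M, AM}")
    key <- paste(rec$accession_id, rec$replicate)
    if (anyDuplicated(key))
      return(paste("duplicated (accession, replicate):",
                   key[duplicated(key)][1]))
    perAcc <- split(rec, rec$accession_id)
    for (a in perAcc) {
      if (length(unique(a$pigment_label)) > 1 ||
          length(unique(a$hulled)) > 1)
        return(paste("inconsistent label/hull within accession",
                     a$accession_id[1]))
      sp <- unique(a$split[!is.na(a$split)])
      if (length(sp) > 1)
        return(paste("accession", a$accession_id[1],
                     "assigned to multiple splits"))
    }
  }
  TRUE
})

#' Construct a GrainManifest
#'
#' @param records data.frame of image records; a missing \code{split} column
#'   is added as \code{NA}, missing \code{mask_path} as \code{NA}.
#' @return a validated \code{GrainManifest}.
#' @examples
#' m <- GrainManifest(data.frame(
#'   accession_id = "acc1", pigment_label = "A", hulled = TRUE,
#'   replicate = 1:2, image_path = c("a.png", "b.png")))
#' nImages(m)
#' @export
GrainManifest <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(records$split)) records$split <- NA_character_
  if (is.null(records$mask_path)) records$mask_path <- NA_character_
  records$pigment_label <- as.character(records$pigment_label)
  records$hulled <- as.logical(records$hulled)
  records$replicate <- as.integer(records$replicate)
  records <- records[manifestColumns()]
  new("GrainManifest", records = records)
}

#' @describeIn GrainManifest number of image records
#' @param x a \code{GrainManifest}.
#' @export
setMethod("nImages", "GrainManifest", function(x) nrow(x@records))

#' @describeIn GrainManifest number of distinct accessions
#' @export
setMethod("nAccessions", "GrainManifest",
          function(x) length(unique(x@records$accession_id)))

#' @describeIn GrainManifest the records table
#' @export
setMethod("manifestRecords", "GrainManifest", function(x) x@records)

setMethod("show", "GrainManifest", function(object) {
  rec <- object@records
  cat("GrainManifest:", nrow(rec), "images,",
      length(unique(rec$accession_id)), "accessions\n")
  if (nrow(rec)) {
    cat("  classes: ",
        paste(sprintf("%s=%d", names(table(rec$pigment_label)),
                      table(rec$pigment_label)), collapse = " "), "\n")
    if (any(!is.na(rec$split))) {
      tb <- table(rec$split, useNA = "ifany")
      cat("  splits:  ",
          paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
    }
  }
})

#' Subset a manifest by split
#'
#' @param manifest a \code{GrainManifest} with split assignment.
#' @param split one of \code{"train"}, \code{"val"}, \code{"test"},
#'   \code{"holdout"}.
#' @return a \code{GrainManifest} with the matching records.
#' @export
manifestSplit <- function(manifest, split) {
  rec <- manifestRecords(manifest)
  GrainManifest(rec[!is.na(rec$split) & rec$split == split, , drop = FALSE])
}

#' Read a manifest from CSV
#'
#' Required columns: \code{accession_id}, \code{pigment_label},
#' \code{hulled}, \code{replicate}, \code{image_path}. Optional:
#' \code{mask_path}, \code{split}. A duplicate (accession, replicate) pair
#' or missing required column is an error.
#'
#' @param path CSV file path.
#' @return a \code{GrainManifest}.
#' @export
loadManifest <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("accession_id", "pigment_label", "hulled", "replicate",
            "image_path")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop("manifest ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("split", "mask_path"))
    if (col %in% names(rec)) {
      rec[[col]] <- as.character(rec[[col]])
      rec[[col]][rec[[col]] %in% ""] <- NA_character_
    }
  GrainManifest(rec)
}

#' Write a manifest to CSV
#'
#' Round-trips exactly through \code{\link{loadManifest}}.
#'
#' @param manifest a \code{GrainManifest}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
saveManifest <- function(manifest, path) {
  stopifnot(is(manifest, "GrainManifest"))
  write.csv(manifestRecords(manifest), path, row.names = FALSE, na = "")
  invisible(path)
}
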