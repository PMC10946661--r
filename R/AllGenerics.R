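#' @title Generics for grainPigment models and containers
#' @name grainPigment-generics
#' @keywords internal
NULL

#' Predict a grain-region (or pigment) mask for an image
#' @param object a fitted segmentation-capable model.
#' @param image an H x W x 3 numeric array in [0, 1].
#' @param ... method-specific arguments (e.g. \code{threshold}).
#' @return a binary mask (matrix, or H x W x C array for multi-channel
#'   models).
#' @export
setGeneric("predictMask", function(object, image, ...)
  standardGeneric("predictMask"))

#' Predict pigment presence scores
#' @param object a fitted classifier.
#' @param newdata model-specific input (images, feature matrix, ...).
#' @param ... method-specific arguments.
#' @return a numeric matrix with columns \code{p_anthocyanin},
#'   \code{p_melanin}, values in [0, 1].
#' @export
setGeneric("predictScores", function(object, newdata, ...)
  standardGeneric("predictScores"))

#' Predict 4-class pigment labels
#' @param object a fitted classifier.
#' @param newdata model-specific input.
#' @param ... method-specific arguments.
#' @return character vector of labels in \code{NP/A/M/AM}.
#' @export
setGeneric("predictLabel", function(object, newdata, ...)
  standardGeneric("predictLabel"))

#' Number of image records in a container
#' @param x a \code{GrainManifest}.
#' @return integer count.
#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))

#' Number of distinct accessions in a container
#' @param x a \code{GrainManifest}.
#' @return integer count.
#' @export
setGeneric("nAccessions", function(x) standardGeneric("nAccessions"))

#' Extract the records table
#' @param x a \code{GrainManifest}.
#' @return a \code{data.frame} of image records.
#' @export
setGeneric("manifestRecords", function(x) standardGeneric("manifestRecords"))
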