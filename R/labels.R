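#' Pigment class codes
#'
#' The four pigment-composition classes: \code{NP} (no pigments), \code{A}
#' (anthocyanins only), \code{M} (melanin only) and \code{AM} (both). The
#' 4-class code is bijective with the pair of binary presence flags.
#'
#' @return character vector of the four class codes, in canonical order.
#' @examples
#' pigmentLevels()
#' @export
pigmentLevels <- function() c("NP", "A", "M", "AM")

#' Convert pigment class codes to presence flags
#'
#' @param label character vector of class codes in \code{NP/A/M/AM}.
#' @return a logical matrix with columns \code{anthocyanin} and
#'   \code{melanin}, one row per label.
#' @examples
#' pigmentFlags(c("NP", "AM"))
#' @export
pigmentFlags <- function(label) {
  label <- as.character(label)
  bad <- !label %in% pigmentLevels()
  if (any(bad))
    stop("unknown pigment label(s): ", paste(unique(label[bad]), collapse = ", "))
  cbind(anthocyanin = label %in% c("A", "AM"),
        melanin     = label %in% c("M", "AM"))
}

#' Convert presence flags to pigment class codes
#'
#' @param anthocyanin logical vector, anthocyanins present.
#' @param melanin logical vector, melanin present.
#' @return character vector of class codes.
#' @examples
#' flagsToLabel(c(TRUE, FALSE), c(TRUE, FALSE))
#' @export
flagsToLabel <- function(anthocyanin, melanin) {
  stopifnot(length(anthocyanin) == length(melanin))
  ifelse(anthocyanin & melanin, "AM",
    ifelse(anthocyanin, "A", ifelse(melanin, "M", "NP")))
}
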