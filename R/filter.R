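# Feature filtering: three passes in fixed order.
#   rule 1: drop columns constant across all rows (identical for all images)
#   rule 2: drop columns whose value is <= 0.01 in strictly more than 20%
#           of rows (near-zero, uninformative histogram bins)
#   rule 3: greedy scan in registry order, dropping any column whose
#           |Spearman rho| >= 0.97 with an already-retained column
#           (first-retained-wins; average ranks for ties)
# Filtering is idempotent and fully deterministic.

#' FeatureFilter: retained-column mask plus filter report
#'
#' @slot keep logical vector over the input columns.
#' @slot report data.frame with one row per dropped column: \code{column},
#'   \code{rule}, \code{statistic}.
#' @export
setClass("FeatureFilter", representation(keep = "logical",
                                         report = "data.frame"))

setMethod("show", "FeatureFilter", function(object) {
  cat("FeatureFilter:", sum(object@keep), "of", length(object@keep),
      "columns retained\n")
  if (nrow(object@report))
    print(table(rule = object@report$rule))
})

#' Fit the three-rule feature filter
#'
#' @param x numeric matrix, rows = images, columns = named descriptors.
#' @param low_value rule-2 value threshold (default 0.01).
#' @param low_fraction rule-2 row-fraction threshold (default 0.2, strict).
#' @param rho_max rule-3 absolute Spearman correlation threshold
#'   (default 0.97).
#' @return a \code{\linkS4class{FeatureFilter}}.
#' @examples
#' m <- cbind(a = c(1, 1, 1), b = c(1, 2, 3), c = c(2, 4, 6))
#' filterFeatures(m)@keep
#' @export
filterFeatures <- function(x, low_value = 0.01, low_fraction = 0.2,
                           rho_max = 0.97) {
  x <- as.matrix(x)
  if (nrow(x) < 2)
    stop("need at least 2 rows to fit the filter (correlation undefined)")
  p <- ncol(x)
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("V", seq_len(p))
  keep <- rep(TRUE, p)
  report <- list()

  # rule 1: constant columns
  rng <- apply(x, 2, function(v) diff(range(v)))
  r1 <- which(rng == 0)
  for (j in r1) report[[length(report) + 1L]] <-
    data.frame(column = nm[j], rule = "constant", statistic = x[1, j])
  keep[r1] <- FALSE

  # rule 2: low values in too many rows
  frac <- colMeans(x <= low_value)
  r2 <- which(keep & frac > low_fraction)
  for (j in r2) report[[length(report) + 1L]] <-
    data.frame(column = nm[j], rule = "low_value", statistic = frac[j])
  keep[r2] <- FALSE

  # rule 3: greedy Spearman redundancy scan in column order
  cand <- which(keep)
  if (length(cand) > 1) {
    rk <- apply(x[, cand, drop = FALSE], 2, rank)   # average ranks for ties
    retained <- 1L
    for (ci in seq_along(cand)[-1]) {
      rho <- suppressWarnings(
        stats::cor(rk[, ci], rk[, retained, drop = FALSE]))
      worst <- max(abs(rho), na.rm = TRUE)
      if (worst >= rho_max) {
        j <- cand[ci]
        report[[length(report) + 1L]] <- data.frame(
          column = nm[j], rule = "spearman", statistic = worst)
        keep[j] <- FALSE
      } else retained <- c(retained, ci)
    }
  }

  report <- if (length(report)) do.call(rbind, report)
    else data.frame(column = character(0), rule = character(0),
                    statistic = numeric(0))
  new("FeatureFilter", keep = keep, report = report)
}

#' Apply a fitted filter
#'
#' @param filter a \code{\linkS4class{FeatureFilter}}.
#' @param x matrix with the same columns the filter was fitted on.
#' @return \code{x} with dropped columns removed.
#' @export
applyFilter <- function(filter, x) {
  stopifnot(is(filter, "FeatureFilter"), ncol(x) == length(filter@keep))
  x[, filter@keep, drop = FALSE]
}

#' FeatureTransform: stored z-normalization
#'
#' @slot center,scale per-column training means and SDs.
#' @export
setClass("FeatureTransform", representation(center = "numeric",
                                            scale = "numeric"))

#' Fit column-wise z-normalization
#'
#' Stores the training means and SDs so the identical transform can be
#' applied to validation/test/holdout rows.
#'
#' @param x filtered training matrix (constant columns already removed).
#' @return list with \code{matrix} (normalized training matrix) and
#'   \code{transform} (a \code{\linkS4class{FeatureTransform}}).
#' @export
normalizeFeatures <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0))
    stop("zero-SD column(s) present; run filterFeatures first")
  tr <- new("FeatureTransform", center = ctr, scale = scl)
  list(matrix = applyTransform(tr, x), transform = tr)
}

#' Apply a stored normalization transform
#'
#' @param transform a \code{\linkS4class{FeatureTransform}}.
#' @param x matrix with matching columns.
#' @return normalized matrix.
#' @export
applyTransform <- function(transform, x) {
  stopifnot(is(transform, "FeatureTransform"),
            ncol(x) == length(transform@center))
  scale(x, center = transform@center, scale = transform@scale)[, ,
                                                               drop = FALSE]
}

#' PCAReducer: stored principal-component basis
#'
#' @slot rotation loading matrix (columns = components).
#' @slot center training column means removed before projection.
#' @slot varianceExplained per-component explained-variance fractions
#'   (non-increasing).
#' @export
setClass("PCAReducer", representation(rotation = "matrix",
                                      center = "numeric",
                                      varianceExplained = "numeric"))

#' Fit a top-k PCA reduction
#'
#' @param x numeric training matrix (rows = images).
#' @param k number of components (default 13, the RF13 representation).
#' @return list with \code{matrix} (n x k scores), \code{reducer}
#'   (a \code{\linkS4class{PCAReducer}}).
#' @examples
#' x <- matrix(rnorm(60), 10)
#' out <- pcaReduce(x, k = 2)
#' dim(out$matrix)
#' @export
pcaReduce <- function(x, k = 13) {
  x <- as.matrix(x)
  if (k > min(nrow(x) - 1, ncol(x)))
    stop("k = ", k, " exceeds min(rows - 1, columns) = ",
         min(nrow(x) - 1, ncol(x)))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  red <- new("PCAReducer",
             rotation = pc$rotation[, seq_len(k), drop = FALSE],
             center = pc$center,
             varianceExplained = ve[seq_len(k)])
  list(matrix = pc$x[, seq_len(k), drop = FALSE], reducer = red)
}

#' Project rows onto a stored PCA basis
#'
#' @param reducer a \code{\linkS4class{PCAReducer}}.
#' @param x matrix with matching columns.
#' @return n x k score matrix.
#' @export
applyPCA <- function(reducer, x) {
  stopifnot(is(reducer, "PCAReducer"))
  sweep(as.matrix(x), 2, reducer@center) %*% reducer@rotation
}
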