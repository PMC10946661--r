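# Accuracy protocol: each image contributes two binary pigment-presence
# decisions (anthocyanin, melanin). Pooled over both decisions,
# ACC = (TP + TN) / (P + N) where P and N count true-present and
# true-absent decisions (P + N = 2 x images). Per-pigment accuracies and
# the 4-class confusion table are always reported alongside.

#' EvalReport: accuracy evaluation of pigment predictions
#'
#' @slot pooled list with \code{TP, TN, P, N, acc} over the pooled binary
#'   decisions.
#' @slot perPigment data.frame with per-pigment \code{TP, TN, FP, FN, acc}.
#' @slot confusion 4 x 4 count table (rows = truth NP/A/M/AM, columns =
#'   prediction).
#' @slot groupComparison data.frame of per-pigment rank-sum comparisons by
#'   hull status (empty when no groups were supplied).
#' @export
setClass("EvalReport", representation(pooled = "list",
                                      perPigment = "data.frame",
                                      confusion = "matrix",
                                      groupComparison = "data.frame"))

setMethod("show", "EvalReport", function(object) {
  p <- object@pooled
  cat(sprintf("EvalReport: ACC = %.3f (TP %d + TN %d) / (P %d + N %d)\n",
              p$acc, p$TP, p$TN, p$P, p$N))
  for (i in seq_len(nrow(object@perPigment)))
    cat(sprintf("  %-12s acc %.3f\n", object@perPigment$pigment[i],
                object@perPigment$acc[i]))
})

#' Pooled accuracy over the two binary pigment decisions
#'
#' @param predictions,truths equal-length character vectors of
#'   \code{NP/A/M/AM} labels (one per image).
#' @param hulled optional logical vector; when given, the hulled-vs-hulless
#'   rank-sum comparison of per-image correctness is included per pigment.
#' @return an \code{\linkS4class{EvalReport}}.
#' @examples
#' computeACC(c("A", "NP", "AM"), c("A", "M", "AM"))
#' @export
computeACC <- function(predictions, truths, hulled = NULL) {
  if (length(predictions) == 0) stop("empty input")
  if (length(predictions) != length(truths))
    stop("predictions and truths differ in length")
  pf <- pigmentFlags(predictions)
  tf <- pigmentFlags(truths)

  per <- do.call(rbind, lapply(c("anthocyanin", "melanin"), function(pg) {
    p <- pf[, pg]; t <- tf[, pg]
    data.frame(pigment = pg, TP = sum(p & t), TN = sum(!p & !t),
               FP = sum(p & !t), FN = sum(!p & t),
               acc = mean(p == t), stringsAsFactors = FALSE)
  }))
  TP <- sum(per$TP); TN <- sum(per$TN)
  P <- sum(tf); N <- sum(!tf)
  pooled <- list(TP = TP, TN = TN, P = P, N = N, acc = (TP + TN) / (P + N))

  grp <- data.frame(pigment = character(0), statistic = numeric(0),
                    p.value = numeric(0))
  if (!is.null(hulled)) {
    stopifnot(length(hulled) == length(truths))
    grp <- do.call(rbind, lapply(c("anthocyanin", "melanin"),
                                 function(pg) {
      correct <- as.numeric(pf[, pg] == tf[, pg])
      rs <- rankSumTest(correct[hulled], correct[!hulled])
      data.frame(pigment = pg, statistic = rs$statistic,
                 p.value = rs$p.value, stringsAsFactors = FALSE)
    }))
  }
  new("EvalReport", pooled = pooled, perPigment = per,
      confusion = confusion4Class(predictions, truths),
      groupComparison = grp)
}

#' 4-class confusion table
#'
#' @param predictions,truths character vectors of \code{NP/A/M/AM} labels.
#' @return 4 x 4 integer matrix, rows = truth, columns = prediction;
#'   entries sum to the number of images.
#' @examples
#' confusion4Class(c("A", "NP"), c("A", "A"))
#' @export
confusion4Class <- function(predictions, truths) {
  lv <- pigmentLevels()
  tb <- table(factor(truths, lv), factor(predictions, lv))
  m <- matrix(as.integer(tb), 4, 4, dimnames = list(truth = lv,
                                                    prediction = lv))
  m
}

#' Two-sided rank-sum (Mann-Whitney) test with exact tie-aware enumeration
#'
#' Exact when the pooled sample size is at most \code{exact_max}: the
#' two-sided p-value is computed by enumerating all group assignments of
#' the (average-rank) ranks. Above that, a tie-corrected normal
#' approximation is used. Suited to heavily tied data such as binary
#' correctness indicators.
#'
#' @param x,y numeric vectors (the two groups, both non-empty).
#' @param exact_max largest pooled n for exact enumeration (default 20).
#' @return list with \code{statistic} (rank sum of \code{x}, average ranks)
#'   and \code{p.value}.
#' @examples
#' rankSumTest(c(1, 1, 1, 0), c(0, 0, 1, 0))
#' @export
rankSumTest <- function(x, y, exact_max = 20) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  n <- n1 + n2
  r <- rank(c(x, y))            # average ranks for ties
  W <- sum(r[seq_len(n1)])
  EW <- n1 * (n + 1) / 2
  if (n <= exact_max) {
    sets <- combn(n, n1)
    sums <- colSums(matrix(r[sets], nrow = n1))
    p <- mean(abs(sums - EW) >= abs(W - EW) - 1e-12)
  } else {
    ties <- table(r)
    tiecor <- sum(ties^3 - ties) / (n * (n - 1))
    VW <- n1 * n2 / 12 * ((n + 1) - tiecor)
    if (VW == 0) {
      p <- 1
    } else {
      z <- (W - EW) / sqrt(VW)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(statistic = W, p.value = p)
}

#' Compare prediction correctness between two groups
#'
#' Two-sided rank-sum test on per-image binary correctness indicators
#' split by a group flag (e.g. hulled vs hulless).
#'
#' @param correct numeric/logical vector of per-image correctness.
#' @param group logical vector defining the two groups.
#' @return list with \code{statistic} and \code{p.value}.
#' @export
compareGroups <- function(correct, group) {
  stopifnot(length(correct) == length(group))
  if (!any(group) || all(group)) stop("both groups must be non-empty")
  rankSumTest(as.numeric(correct[group]), as.numeric(correct[!group]))
}

#' Serialize an EvalReport to JSON
#'
#' @param report an \code{\linkS4class{EvalReport}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEvalReport <- function(report, path) {
  stopifnot(is(report, "EvalReport"))
  obj <- list(pooled = report@pooled,
              per_pigment = report@perPigment,
              confusion = list(levels = pigmentLevels(),
                               counts = unname(apply(report@confusion, 1,
                                                     as.integer,
                                                     simplify = FALSE))),
              group_comparison = report@groupComparison)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an EvalReport from JSON
#'
#' @param path JSON path written by \code{\link{writeEvalReport}}.
#' @return an \code{\linkS4class{EvalReport}}.
#' @export
readEvalReport <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  conf <- obj$confusion$counts
  if (is.list(conf)) conf <- do.call(rbind, conf)
  conf <- matrix(as.integer(conf), 4, 4)
  dimnames(conf) <- list(truth = obj$confusion$levels,
                         prediction = obj$confusion$levels)
  grp <- as.data.frame(obj$group_comparison)
  if (!nrow(grp)) grp <- data.frame(pigment = character(0),
                                    statistic = numeric(0),
                                    p.value = numeric(0))
  new("EvalReport", pooled = obj$pooled,
      perPigment = as.data.frame(obj$per_pigment),
      confusion = conf, groupComparison = grp)
}
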