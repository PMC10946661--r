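test_that("perfect predictions give ACC 1 and a diagonal confusion", {
  lab <- c("NP", "A", "M", "AM", "A")
  r <- computeACC(lab, lab)
  expect_equal(r@pooled$acc, 1)
  expect_equal(r@pooled$P + r@pooled$N, 2L * length(lab))
  expect_true(all(r@confusion[upper.tri(r@confusion)] == 0))
  expect_true(all(r@confusion[lower.tri(r@confusion)] == 0))
})

test_that("pooled ACC matches a brute-force tally of all binary decisions",
{
  set.seed(13)
  for (rep in 1:5) {
    truth <- sample(pigmentLevels(), 20, replace = TRUE)
    pred <- sample(pigmentLevels(), 20, replace = TRUE)
    r <- computeACC(pred, truth)
    # enumerate the 40 decisions one by one
    tp <- tn <- p <- n <- 0
    for (i in 1:20) for (pg in c("anthocyanin", "melanin")) {
      t <- pigmentFlags(truth[i])[1, pg]
      q <- pigmentFlags(pred[i])[1, pg]
      if (t) p <- p + 1 else n <- n + 1
      if (t && q) tp <- tp + 1
      if (!t && !q) tn <- tn + 1
    }
    expect_equal(r@pooled$TP, tp)
    expect_equal(r@pooled$TN, tn)
    expect_equal(r@pooled$acc, (tp + tn) / (p + n))
    # pooled ACC is the mean of the two per-pigment accuracies
    expect_equal(r@pooled$acc, mean(r@perPigment$acc))
    # confusion row sums conserve per-class truth counts
    expect_equal(unname(rowSums(r@confusion)),
                 unname(as.vector(table(factor(truth, pigmentLevels())))))
  }
})

test_that("computeACC validates its inputs", {
  expect_error(computeACC(character(0), character(0)), "empty")
  expect_error(computeACC(c("A", "M"), "A"), "length")
})

test_that("a single misclassified image lands in one confusion cell", {
  cm <- confusion4Class("NP", "A")
  expect_equal(cm["A", "NP"], 1L)
  expect_equal(sum(cm), 1L)
})

test_that("rank-sum p-values match exhaustive permutation enumeration", {
  # 8 all-correct vs 8 all-wrong
  x <- rep(1, 8); y <- rep(0, 8)
  rs <- rankSumTest(x, y)
  # independent oracle: enumerate every assignment of the pooled ranks
  pooled <- c(x, y)
  rk <- rank(pooled)
  n1 <- length(x)
  EW <- n1 * (length(pooled) + 1) / 2
  obs <- sum(rk[seq_len(n1)])
  sets <- combn(length(pooled), n1)
  ws <- apply(sets, 2, function(ix) sum(rk[ix]))
  pExact <- mean(abs(ws - EW) >= abs(obs - EW) - 1e-12)
  expect_equal(rs$p.value, pExact)
  expect_lt(rs$p.value, 0.001)

  # partially tied case
  set.seed(2)
  a <- rbinom(7, 1, 0.8); b <- rbinom(6, 1, 0.3)
  rs2 <- rankSumTest(a, b)
  pooled <- c(a, b); rk <- rank(pooled); n1 <- 7
  EW <- n1 * 14 / 2
  obs <- sum(rk[1:7])
  ws <- apply(combn(13, 7), 2, function(ix) sum(rk[ix]))
  expect_equal(rs2$p.value, mean(abs(ws - EW) >= abs(obs - EW) - 1e-12))
})

test_that("identical groups give no separation and swapping is symmetric", {
  x <- c(1, 0, 1, 1, 0)
  rs <- rankSumTest(x, x)
  expect_gte(rs$p.value, 0.99)
  a <- c(1, 1, 1, 0); b <- c(0, 1, 0, 0)
  expect_equal(rankSumTest(a, b)$p.value, rankSumTest(b, a)$p.value)
  expect_error(rankSumTest(numeric(0), x), "non-empty")
})

test_that("large samples use the tie-corrected normal approximation", {
  set.seed(7)
  a <- rbinom(30, 1, 0.9); b <- rbinom(30, 1, 0.4)
  rs <- rankSumTest(a, b)
  ref <- suppressWarnings(wilcox.test(a, b, correct = FALSE))
  expect_equal(rs$p.value, ref$p.value, tolerance = 1e-8)
})

test_that("group comparison is wired into computeACC", {
  set.seed(9)
  truth <- sample(pigmentLevels(), 30, replace = TRUE)
  pred <- truth
  flip <- 1:10
  pred[flip] <- sample(pigmentLevels(), 10, replace = TRUE)
  hulled <- rep(c(TRUE, FALSE), 15)
  r <- computeACC(pred, truth, hulled = hulled)
  expect_equal(nrow(r@groupComparison), 2L)
  expect_true(all(r@groupComparison$p.value >= 0 &
                  r@groupComparison$p.value <= 1))
})

test_that("EvalReport round-trips through JSON", {
  set.seed(10)
  truth <- sample(pigmentLevels(), 15, replace = TRUE)
  pred <- sample(pigmentLevels(), 15, replace = TRUE)
  r <- computeACC(pred, truth, hulled = rep(c(TRUE, FALSE), c(8, 7)))
  path <- tempfile(fileext = ".json")
  writeEvalReport(r, path)
  r2 <- readEvalReport(path)
  expect_equal(r2@pooled, r@pooled)
  expect_equal(r2@perPigment, r@perPigment)
  expect_equal(unname(r2@confusion), unname(r@confusion))
  expect_equal(r2@groupComparison, r@groupComparison)
})
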