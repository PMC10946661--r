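# independent brute-force application of the three filtering rules
filterOracle <- function(x, low = 0.01, frac = 0.2, rho = 0.97) {
  p <- ncol(x)
  keep <- rep(TRUE, p)
  for (j in seq_len(p)) if (length(unique(x[, j])) == 1) keep[j] <- FALSE
  for (j in seq_len(p)) if (keep[j] && mean(x[, j] <= low) > frac)
    keep[j] <- FALSE
  retained <- integer(0)
  for (j in seq_len(p)) {
    if (!keep[j]) next
    drop <- FALSE
    for (r in retained) {
      if (abs(cor(rank(x[, j]), rank(x[, r]))) >= rho) { drop <- TRUE;
        break }
    }
    if (drop) keep[j] <- FALSE else retained <- c(retained, j)
  }
  keep
}

test_that("the three rules fire in order on designed columns", {
  x <- cbind(const = rep(2, 6),
             lowv = c(0, 0.005, 0.01, 0.5, 0.004, 0),   # 5/6 <= 0.01
             a = c(1, 2, 3, 4, 5, 6),
             doubled = 2 * c(1, 2, 3, 4, 5, 6),          # rank-identical
             b = c(2, 1, 4, 3, 6, 5))
  f <- filterFeatures(x)
  expect_equal(unname(f@keep), c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(f@report$rule[f@report$column == "const"], "constant")
  expect_equal(f@report$rule[f@report$column == "lowv"], "low_value")
  expect_equal(f@report$rule[f@report$column == "doubled"], "spearman")
})

test_that("retained columns match the brute-force oracle on toy matrices", {
  set.seed(11)
  for (rep in 1:8) {
    x <- matrix(round(runif(5 * 4), 2), 5, 4)
    x[, sample(4, 1)] <- rep(round(runif(1), 2), 5)   # plant a constant
    if (rep %% 2 == 0) x[, 2] <- x[, 3] * 3           # plant redundancy
    colnames(x) <- paste0("c", 1:4)
    f <- suppressWarnings(filterFeatures(x))
    expect_equal(unname(f@keep), unname(filterOracle(x)),
                 info = paste("case", rep))
  }
})

test_that("filtering is idempotent and deterministic", {
  set.seed(3)
  x <- matrix(runif(40 * 30), 40, 30)
  x[, 5] <- 1; x[, 9] <- x[, 2] * 2 + 1
  colnames(x) <- sprintf("f%02d", 1:30)
  f1 <- filterFeatures(x)
  y <- applyFilter(f1, x)
  f2 <- filterFeatures(y)
  expect_true(all(f2@keep))
  expect_identical(f1@keep, filterFeatures(x)@keep)
  expect_error(filterFeatures(x[1, , drop = FALSE]), "at least 2 rows")
})

test_that("rule 2 uses a strict fraction threshold", {
  # value <= 0.01 in exactly 20% of rows: kept (strictly more required)
  x <- cbind(edge = c(0.005, rep(0.5, 4)), keepme = 1:5)
  f <- filterFeatures(x)
  expect_true(f@keep[1])
  # 40% of rows: dropped
  x2 <- cbind(edge = c(0.005, 0.002, rep(0.5, 3)), keepme = 1:5)
  expect_false(filterFeatures(x2)@keep[1])
})

test_that("normalization stores and reapplies training statistics", {
  set.seed(6)
  x <- matrix(rnorm(20 * 5, mean = 3, sd = 2), 20, 5)
  out <- normalizeFeatures(x)
  expect_equal(unname(colMeans(out$matrix)), rep(0, 5), tolerance = 1e-9)
  expect_equal(unname(apply(out$matrix, 2, sd)), rep(1, 5),
               tolerance = 1e-9)
  # stored transform reproduces the normalized training matrix
  expect_equal(applyTransform(out$transform, x), out$matrix)
  # a new row equal to the training means maps to zero
  mu <- matrix(colMeans(x), 1)
  expect_equal(as.vector(applyTransform(out$transform, mu)), rep(0, 5),
               tolerance = 1e-12)
  expect_error(normalizeFeatures(cbind(x, 7)), "zero-SD")
})

test_that("PCA reduction matches a direct eigendecomposition", {
  set.seed(8)
  x <- matrix(rnorm(10 * 6), 10, 6)
  out <- pcaReduce(x, k = 6)
  ev <- eigen(cov(x))$values
  compVar <- apply(out$matrix, 2, var)
  expect_equal(unname(compVar), ev, tolerance = 1e-9)
  expect_equal(sum(out$reducer@varianceExplained), 1, tolerance = 1e-9)
  expect_true(all(diff(out$reducer@varianceExplained) <= 1e-12))

  red <- pcaReduce(x, k = 2)
  expect_equal(dim(red$matrix), c(10L, 2L))
  # stored basis projects new rows identically
  expect_equal(applyPCA(red$reducer, x), red$matrix)
  expect_error(pcaReduce(x, k = 9), "exceeds")
})
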