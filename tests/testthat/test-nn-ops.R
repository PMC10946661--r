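# numeric gradient checks for the compiled kernels and both network
# architectures, on tiny tensors
gp <- asNamespace("grainPigment")

numGrad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

test_that("convolution backward matches numeric gradients", {
  set.seed(42)
  for (cse in list(c(k = 3, pad = 1, s = 1), c(k = 3, pad = 1, s = 2),
                   c(k = 1, pad = 0, s = 1))) {
    k <- cse["k"]; pad <- cse["pad"]; s <- cse["s"]
    x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
    w <- matrix(rnorm(k * k * 2 * 3) * 0.3, k * k * 2, 3)
    b <- rnorm(3)
    y <- gp$nn_conv2d(x, w, b, k, pad, s)
    dy <- array(rnorm(length(y)), dim(y))
    g <- gp$nn_conv2d_bw(x, w, dy, k, pad, s)
    fx <- function(xx) sum(gp$nn_conv2d(xx, w, b, k, pad, s) * dy)
    fw <- function(ww) sum(gp$nn_conv2d(x, matrix(ww, nrow(w)), b,
                                        k, pad, s) * dy)
    expect_lt(max(abs(g$dx - numGrad(fx, x))), 1e-7)
    expect_lt(max(abs(g$dw - matrix(numGrad(fw, as.vector(w)),
                                    nrow(w)))), 1e-7)
    expect_equal(as.vector(g$db), apply(dy, 3, sum), tolerance = 1e-10)
  }
})

test_that("pooling and upsampling backward match numeric gradients", {
  set.seed(43)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  mp <- gp$nn_maxpool2(x)
  dy <- array(rnorm(length(mp$y)), dim(mp$y))
  g <- gp$nn_maxpool2_bw(dy, mp$idx, 8L, 8L)
  expect_lt(max(abs(g - numGrad(function(xx)
    sum(gp$nn_maxpool2(xx)$y * dy), x))), 1e-7)

  up <- gp$nn_upsample2(x)
  expect_equal(dim(up), c(16L, 16L, 2L))
  dyu <- array(rnorm(length(up)), dim(up))
  gu <- gp$nn_upsample2_bw(dyu)
  expect_lt(max(abs(gu - numGrad(function(xx)
    sum(gp$nn_upsample2(xx) * dyu), x))), 1e-7)
})

test_that("U-Net forward/backward gradients check out end to end", {
  set.seed(44)
  depth <- 2
  pp <- gp$withSeed(1, gp$unetInit(2, base = 2, depth = depth,
                                   out_ch = 1, head = 2))
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  t <- matrix(rbinom(64, 1, 0.5), 8, 8)
  tt <- c(1, 0)
  lossAll <- function(pp) {
    fw <- gp$unetForward(pp, x, depth, head = TRUE)
    gp$segLoss(fw$logits, t)$loss + gp$bceLogit(fw$headLogits, tt)$loss
  }
  fw <- gp$unetForward(pp, x, depth, head = TRUE)
  seg <- gp$segLoss(fw$logits, t)
  cls <- gp$bceLogit(fw$headLogits, tt)
  G <- gp$unetBackward(pp, fw$cache, depth, seg$dz, dhead = cls$dz)
  for (nm in c("enc1a", "enc3b", "up1", "dec2a", "final", "head")) {
    pcopy <- pp
    fnum <- function(v) { pcopy[[nm]]$w[1] <- v; lossAll(pcopy) }
    ng <- (fnum(pp[[nm]]$w[1] + 1e-5) - fnum(pp[[nm]]$w[1] - 1e-5)) / 2e-5
    expect_lt(abs(G[[nm]]$w[1] - ng), 1e-6)
  }
})

test_that("residual classifier gradients check out end to end", {
  set.seed(45)
  pp <- gp$withSeed(2, gp$resnetInit(2, base = 4, nstages = 2,
                                     blocks = 2, nout = 2))
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  lossR <- function(pp) {
    fw <- gp$resnetForward(pp, x, 2, 2)
    gp$bceLogit(fw$logits, c(1, 0))$loss
  }
  fw <- gp$resnetForward(pp, x, 2, 2)
  ls <- gp$bceLogit(fw$logits, c(1, 0))
  G <- gp$resnetBackward(pp, fw$cache, ls$dz, 2, 2)
  for (nm in c("stem", "s1b1c1", "s2b1sc", "fc")) {
    pcopy <- pp
    fnum <- function(v) { pcopy[[nm]]$w[1] <- v; lossR(pcopy) }
    ng <- (fnum(pp[[nm]]$w[1] + 1e-5) - fnum(pp[[nm]]$w[1] - 1e-5)) / 2e-5
    expect_lt(abs(G[[nm]]$w[1] - ng), 1e-6)
  }
})

test_that("residual-encoder U-Net gradients check out", {
  set.seed(46)
  depth <- 2
  pp <- gp$withSeed(3, gp$unetInit(2, base = 2, depth = depth, out_ch = 1,
                                   head = 2, residual_enc = TRUE))
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  tt <- c(0, 1)
  lossE <- function(pp) {
    fw <- gp$unetEncForward(pp, x, depth)
    gp$bceLogit(fw$headLogits, tt)$loss
  }
  fw <- gp$unetEncForward(pp, x, depth)
  ls <- gp$bceLogit(fw$headLogits, tt)
  G <- gp$unetEncBackward(pp, fw$cache, depth, ls$dz)
  for (nm in c("enc1c1", "enc2sc", "enc3c2", "head")) {
    pcopy <- pp
    fnum <- function(v) { pcopy[[nm]]$w[1] <- v; lossE(pcopy) }
    ng <- (fnum(pp[[nm]]$w[1] + 1e-5) - fnum(pp[[nm]]$w[1] - 1e-5)) / 2e-5
    expect_lt(abs(G[[nm]]$w[1] - ng), 1e-6)
  }
})

test_that("losses are consistent with their gradients", {
  set.seed(47)
  z <- array(rnorm(5 * 5 * 2), c(5, 5, 2))
  t <- array(rbinom(50, 1, 0.4), c(5, 5, 2))
  for (lossfun in list(gp$bceLogit, gp$diceLogit)) {
    ls <- lossfun(z, t)
    ng <- numGrad(function(zz) lossfun(zz, t)$loss, z)
    expect_lt(max(abs(ls$dz - ng)), 1e-6)
  }
})
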