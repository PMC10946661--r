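# Dense-tensor network plumbing shared by all network models: parameter
# initialization, conv/relu blocks with hand-derived backward passes over
# the compiled kernels, global average pooling, dense layers, Adam, and the
# segmentation/classification losses. Tensors are H x W x C arrays;
# convolution weights are (k*k*Cin) x Cout matrices (row index
# c*k*k + ky*k + kx); dense weights are nout x nin.

convParam <- function(k, cin, cout)
  list(w = matrix(stats::rnorm(k * k * cin * cout,
                               sd = sqrt(2 / (k * k * cin))),
                  k * k * cin, cout),
       b = numeric(cout))

denseParam <- function(nin, nout)
  list(w = matrix(stats::rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin),
       b = numeric(nout))

# conv + per-pixel channel normalization + leaky ReLU forward/backward
# with cache. Normalizing across channels at each spatial location keeps
# single-image training stable at aggressive learning rates while
# preserving the relative channel magnitudes that carry colour
# information; output layers (relu = FALSE) are plain convolutions.
leakySlope <- 0.1
inEps <- 1e-5

cbrF <- function(x, p, k = 3, pad = 1, stride = 1, relu = TRUE,
                 norm = TRUE) {
  fw <- nn_conv2d_fw(x, p$w, p$b, k, pad, stride)
  z <- fw$y
  if (!relu)
    return(list(y = z, z = z, x = x, col = fw$col, dims = dim(x)))
  if (!norm)
    return(list(y = z * ((z > 0) + leakySlope * (z <= 0)), z = z, x = x,
                col = fw$col, dims = dim(x)))
  nl <- nn_cnorm_leaky(z, inEps, leakySlope)
  list(y = nl$y, n = nl$n, sdv = nl$sdv, z = z, x = x, col = fw$col,
       dims = dim(x))
}

cbrB <- function(cache, p, dy, k = 3, pad = 1, stride = 1, relu = TRUE,
                 norm = TRUE, dzRaw = NULL) {
  bw <- function(dz) nn_conv2d_bw_col(cache$col, p$w, dz,
                                      cache$dims[1], cache$dims[2],
                                      cache$dims[3], k, pad, stride)
  if (!relu) return(bw(dy))
  if (!norm) {
    dz <- dy * ((cache$z > 0) + leakySlope * (cache$z <= 0))
    if (!is.null(dzRaw)) dz <- dz + dzRaw
    return(bw(dz))
  }
  dz <- nn_cnorm_leaky_bw(cache$n, cache$sdv, dy, leakySlope)
  if (!is.null(dzRaw)) dz <- dz + dzRaw
  bw(dz)
}

gapF <- function(x) {
  d <- dim(x)
  colMeans(matrix(x, d[1] * d[2], d[3]))
}

gapB <- function(dv, dims)
  array(rep(dv / (dims[1] * dims[2]), each = dims[1] * dims[2]), dims)

denseF <- function(v, p) as.vector(p$w %*% v + p$b)

denseB <- function(v, p, dz)
  list(dw = dz %o% v, db = dz, dv = as.vector(crossprod(p$w, dz)))

concat3 <- function(a, b) {
  out <- array(0, c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# numerically stable binary cross-entropy on logits, mean over elements
bceLogit <- function(z, t) {
  loss <- mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
  list(loss = loss, dz = (sigmoid(z) - t) / length(z))
}

# soft Dice on logits, averaged over channels
diceLogit <- function(z, t, eps = 1) {
  flat <- length(dim(z)) < 3
  if (flat) { z <- array(z, c(dim(z), 1)); t <- array(t, c(dim(t), 1)) }
  p <- sigmoid(z)
  C <- dim(p)[3]
  loss <- 0
  dz <- array(0, dim(p))
  for (ch in seq_len(C)) {
    pc <- p[, , ch]; tc <- t[, , ch]
    num <- 2 * sum(pc * tc) + eps
    den <- sum(pc) + sum(tc) + eps
    loss <- loss + 1 - num / den
    dLdp <- -(2 * tc * den - num) / den^2
    dz[, , ch] <- dLdp * pc * (1 - pc)
  }
  if (flat) dz <- dz[, , 1]
  list(loss = loss / C, dz = dz / C)
}

# random dihedral transform: horizontal/vertical flips and transpose
# (paired tensors transform together). Dish images have no preferred
# orientation, so all eight symmetries are label-preserving.
flipAug <- function(x, y = NULL) {
  fh <- stats::runif(1) < 0.5
  fv <- stats::runif(1) < 0.5
  tp <- stats::runif(1) < 0.5 && dim(x)[1] == dim(x)[2]
  fl <- function(a) {
    three <- length(dim(a)) == 3
    if (fh) a <- if (three) a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
            else a[, rev(seq_len(ncol(a))), drop = FALSE]
    if (fv) a <- if (three) a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
            else a[rev(seq_len(nrow(a))), , drop = FALSE]
    if (tp) a <- if (three) aperm(a, c(2, 1, 3)) else t(a)
    a
  }
  if (is.null(y)) fl(x) else list(x = fl(x), y = fl(y))
}

# small global colour jitter on a centred image (x is image - 0.5):
# per-channel gain and a brightness offset at the scale of the
# accession-level palette variation, so classifier heads generalize
# across accessions rather than memorizing exact palettes
colorAug <- function(x, gain = 0.06, offset = 0.03) {
  g <- 1 + stats::runif(3, -gain, gain)
  o <- stats::runif(1, -offset, offset)
  for (ch in 1:3)
    x[, , ch] <- clamp((x[, , ch] + 0.5) * g[ch] + o) - 0.5
  x
}

# global-norm gradient clipping
clipGrads <- function(G, clip = 1) {
  gn <- sqrt(sum(vapply(G, function(p)
    sum(p$w^2) + sum(p$b^2), numeric(1))))
  if (gn > clip)
    G <- lapply(G, function(p) list(w = p$w * clip / gn,
                                    b = p$b * clip / gn))
  G
}

adamInit <- function(params) {
  zero <- lapply(params, function(p) lapply(p, function(a) a * 0))
  list(m = zero, v = zero, t = 0)
}

adamStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    if (is.null(params[[nm]])) next
    for (f in names(grads[[nm]])) {
      g <- grads[[nm]][[f]]
      m <- beta1 * state$m[[nm]][[f]] + (1 - beta1) * g
      v <- beta2 * state$v[[nm]][[f]] + (1 - beta2) * g * g
      state$m[[nm]][[f]] <- m
      state$v[[nm]][[f]] <- v
      params[[nm]][[f]] <- params[[nm]][[f]] -
        lr * (m / c1) / (sqrt(v / c2) + eps)
    }
  }
  list(params = params, state = state)
}

# fold a backward-pass gradient pair into the gradient accumulator
gAdd <- function(G, nm, dw, db) {
  if (is.null(G[[nm]])) G[[nm]] <- list(w = dw, b = db)
  else { G[[nm]]$w <- G[[nm]]$w + dw; G[[nm]]$b <- G[[nm]]$b + db }
  G
}

paramCount <- function(params)
  sum(vapply(params, function(p) sum(vapply(p, length, 1L)), 1L))

paramChecksum <- function(params)
  sum(vapply(params, function(p) sum(vapply(p, function(a)
    sum(abs(a)), 1)), 1))
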