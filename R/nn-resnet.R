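# Compact residual classifier: stem conv + max-pool, then stages of
# residual blocks (two 3x3 convs with an additive identity/projection
# shortcut), channel count doubling and spatial halving at every stage
# boundary, global average pooling and one dense output layer producing one
# logit per pigment.

resnetInit <- function(in_ch = 3L, base = 16L, nstages = 4L,
                       blocks = 2L, nout = 2L) {
  pp <- list(stem = convParam(3, in_ch, base))
  for (s in seq_len(nstages)) {
    cs <- base * 2^(s - 1)
    cin <- if (s == 1) base else base * 2^(s - 2)
    for (b in seq_len(blocks)) {
      nm <- sprintf("s%db%d", s, b)
      bin <- if (b == 1) cin else cs
      pp[[paste0(nm, "c1")]] <- convParam(3, bin, cs)
      pp[[paste0(nm, "c2")]] <- convParam(3, cs, cs)
      if (b == 1 && (s > 1 || cin != cs))
        pp[[paste0(nm, "sc")]] <- convParam(1, bin, cs)
    }
  }
  pp$fc <- denseParam(base * 2^(nstages - 1), nout)
  pp$fc$w <- pp$fc$w * 0.1        # damped head init: moderate logits
  pp
}

resBlockF <- function(x, pp, nm, stride) {
  c1 <- cbrF(x, pp[[paste0(nm, "c1")]], stride = stride)
  c2 <- cbrF(c1$y, pp[[paste0(nm, "c2")]], relu = FALSE)
  proj <- !is.null(pp[[paste0(nm, "sc")]])
  sc <- if (proj)
    cbrF(x, pp[[paste0(nm, "sc")]], k = 1, pad = 0, stride = stride,
         relu = FALSE)
  else list(z = x)
  s <- c2$z + sc$z
  list(y = s * ((s > 0) + leakySlope * (s <= 0)), s = s, c1 = c1, c2 = c2, sc = sc, proj = proj,
       stride = stride)
}

resBlockB <- function(cache, pp, nm, dy, G) {
  ds <- dy * ((cache$s > 0) + leakySlope * (cache$s <= 0))
  b2 <- cbrB(cache$c2, pp[[paste0(nm, "c2")]], ds, relu = FALSE)
  G <- gAdd(G, paste0(nm, "c2"), b2$dw, b2$db)
  b1 <- cbrB(cache$c1, pp[[paste0(nm, "c1")]], b2$dx,
             stride = cache$stride)
  G <- gAdd(G, paste0(nm, "c1"), b1$dw, b1$db)
  dx <- b1$dx
  if (cache$proj) {
    bs <- cbrB(cache$sc, pp[[paste0(nm, "sc")]], ds, k = 1, pad = 0,
               stride = cache$stride, relu = FALSE)
    G <- gAdd(G, paste0(nm, "sc"), bs$dw, bs$db)
    dx <- dx + bs$dx
  } else dx <- dx + ds
  list(dx = dx, G = G)
}

resnetForward <- function(pp, x, nstages = 4L, blocks = 2L) {
  cache <- list()
  st <- cbrF(x, pp$stem)
  cache$stem <- st
  mp <- nn_maxpool2(st$y)
  cache$poolidx <- mp$idx
  cache$pooldim <- dim(st$y)
  h <- mp$y
  for (s in seq_len(nstages)) for (b in seq_len(blocks)) {
    nm <- sprintf("s%db%d", s, b)
    stride <- if (s > 1 && b == 1) 2L else 1L
    bk <- resBlockF(h, pp, nm, stride)
    cache[[nm]] <- bk
    h <- bk$y
  }
  v <- gapF(h)
  cache$gapv <- v
  cache$hdim <- dim(h)
  list(logits = denseF(v, pp$fc), cache = cache)
}

resnetBackward <- function(pp, cache, dlogits, nstages = 4L, blocks = 2L) {
  G <- list()
  gf <- denseB(cache$gapv, pp$fc, dlogits)
  G <- gAdd(G, "fc", gf$dw, gf$db)
  dh <- gapB(gf$dv, cache$hdim)
  for (s in rev(seq_len(nstages))) for (b in rev(seq_len(blocks))) {
    nm <- sprintf("s%db%d", s, b)
    out <- resBlockB(cache[[nm]], pp, nm, dh, G)
    dh <- out$dx
    G <- out$G
  }
  dst <- nn_maxpool2_bw(dh, cache$poolidx, cache$pooldim[1],
                        cache$pooldim[2])
  gs <- cbrB(cache$stem, pp$stem, dst)
  G <- gAdd(G, "stem", gs$dw, gs$db)
  G
}
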