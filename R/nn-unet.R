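# Compact encoder-decoder (U-Net-style) network: an encoder of stacked
# conv3x3+ReLU pairs with 2x2 max-pooling, a decoder of nearest upsampling
# + conv, skip connections concatenated at matching resolutions, a 1x1
# sigmoid output head, and an optional classification head (global average
# pooling of the encoder bottleneck into a dense layer). Same-padding
# convolutions keep the output spatial size equal to the input.

# encoder-family presets: width/depth of the compact implementation
unetPreset <- function(family = c("resnet18", "resnet34", "efficientnetb0")) {
  family <- match.arg(family)
  switch(family,
         resnet18       = list(base = 8L,  depth = 5L),
         resnet34       = list(base = 10L, depth = 5L),
         efficientnetb0 = list(base = 8L,  depth = 5L))
}

unetInit <- function(in_ch = 3L, base = 8L, depth = 5L, out_ch = 1L,
                     head = 0L, cap = 8L * base, residual_enc = FALSE) {
  # channel growth capped: keeps the deep levels compact without losing
  # receptive field
  ch <- pmin(base * 2^(seq_len(depth + 1) - 1), cap)
  pp <- list()
  for (i in seq_len(depth + 1)) {
    cin <- if (i == 1) in_ch else ch[i - 1]
    if (residual_enc) {
      # residual encoder blocks (conv-conv + projection shortcut): the
      # gradient highways that make the encoder trainable as a classifier
      pp[[paste0("enc", i, "c1")]] <- convParam(3, cin, ch[i])
      pp[[paste0("enc", i, "c2")]] <- convParam(3, ch[i], ch[i])
      if (cin != ch[i])
        pp[[paste0("enc", i, "sc")]] <- convParam(1, cin, ch[i])
    } else {
      pp[[paste0("enc", i, "a")]] <- convParam(3, cin, ch[i])
      pp[[paste0("enc", i, "b")]] <- convParam(3, ch[i], ch[i])
    }
  }
  for (i in seq_len(depth)) {
    pp[[paste0("up", i)]]       <- convParam(3, ch[i + 1], ch[i])
    pp[[paste0("dec", i, "a")]] <- convParam(3, 2 * ch[i], ch[i])
    pp[[paste0("dec", i, "b")]] <- convParam(3, ch[i], ch[i])
  }
  pp$final <- convParam(1, ch[1], out_ch)
  pp$final$w <- pp$final$w * 0.25      # damped output init: moderate logits
  if (head > 0) {
    pp$head <- denseParam(ch[depth + 1], head)
    pp$head$w <- pp$head$w * 0.25
  }
  pp
}

unetForward <- function(pp, x, depth, head = FALSE, raw_level1 = FALSE,
                        raw_enc = FALSE) {
  # raw_level1: level-1 convolutions (encoder and decoder) run without
  # per-pixel normalization, so absolute colour amplitudes survive into
  # the full-resolution skip path and the per-pixel output head --
  # required when individual pixels must be classified by colour.
  # raw_enc: the whole encoder runs without normalization, so the pooled
  # bottleneck stays input-dependent for the classification head.
  cache <- list(skip = vector("list", depth + 1))
  residual <- !is.null(pp$enc1c1)
  h <- x
  for (i in seq_len(depth + 1)) {
    if (residual) {
      bk <- resBlockF(h, pp, paste0("enc", i), 1L)
      cache[[paste0("encblk", i)]] <- bk
      out <- bk$y
    } else {
      nrm <- !(raw_enc || (raw_level1 && i == 1))
      c1 <- cbrF(h, pp[[paste0("enc", i, "a")]], norm = nrm)
      c2 <- cbrF(c1$y, pp[[paste0("enc", i, "b")]], norm = nrm)
      cache[[paste0("enc", i, "a")]] <- c1
      cache[[paste0("enc", i, "b")]] <- c2
      out <- c2$y
    }
    cache$skip[[i]] <- out
    if (i <= depth) {
      mp <- nn_maxpool2(out)
      cache[[paste0("poolidx", i)]] <- mp$idx
      cache[[paste0("pooldim", i)]] <- dim(out)
      h <- mp$y
    } else h <- out
  }
  headLogits <- NULL
  if (head) {
    v <- gapF(h)
    cache$headv <- v
    cache$bottdim <- dim(h)
    headLogits <- denseF(v, pp$head)
  }
  for (i in rev(seq_len(depth))) {
    up <- nn_upsample2(h)
    uc <- cbrF(up, pp[[paste0("up", i)]])
    cache[[paste0("up", i)]] <- uc
    cat1 <- concat3(cache$skip[[i]], uc$y)
    nrm <- !(raw_level1 && i == 1)
    d1 <- cbrF(cat1, pp[[paste0("dec", i, "a")]], norm = nrm)
    d2 <- cbrF(d1$y, pp[[paste0("dec", i, "b")]], norm = nrm)
    cache[[paste0("dec", i, "a")]] <- d1
    cache[[paste0("dec", i, "b")]] <- d2
    cache[[paste0("nskip", i)]] <- dim(cache$skip[[i]])[3]
    h <- d2$y
  }
  fin <- cbrF(h, pp$final, k = 1, pad = 0, relu = FALSE)
  cache$final <- fin
  list(logits = fin$z, headLogits = headLogits, cache = cache)
}

unetBackward <- function(pp, cache, depth, dlogits, dhead = NULL,
                         raw_level1 = FALSE, raw_enc = FALSE) {
  G <- list()
  g <- cbrB(cache$final, pp$final, dlogits, k = 1, pad = 0, relu = FALSE)
  G <- gAdd(G, "final", g$dw, g$db)
  dh <- g$dx
  dskip <- vector("list", depth + 1)
  for (i in seq_len(depth)) {     # reverse of the forward decoder loop
    nm2 <- paste0("dec", i, "b"); nm1 <- paste0("dec", i, "a")
    nrm <- !(raw_level1 && i == 1)
    b2 <- cbrB(cache[[nm2]], pp[[nm2]], dh, norm = nrm)
    G <- gAdd(G, nm2, b2$dw, b2$db)
    b1 <- cbrB(cache[[nm1]], pp[[nm1]], b2$dx, norm = nrm)
    G <- gAdd(G, nm1, b1$dw, b1$db)
    ns <- cache[[paste0("nskip", i)]]
    dcat <- b1$dx
    dskip[[i]] <- dcat[, , seq_len(ns), drop = FALSE]
    dup <- dcat[, , ns + seq_len(dim(dcat)[3] - ns), drop = FALSE]
    nmu <- paste0("up", i)
    bu <- cbrB(cache[[nmu]], pp[[nmu]], dup)
    G <- gAdd(G, nmu, bu$dw, bu$db)
    dh <- nn_upsample2_bw(bu$dx)
  }
  dskip[[depth + 1]] <- dh
  if (!is.null(dhead)) {
    gh <- denseB(cache$headv, pp$head, dhead)
    G <- gAdd(G, "head", gh$dw, gh$db)
    dskip[[depth + 1]] <- dskip[[depth + 1]] + gapB(gh$dv, cache$bottdim)
  }
  residual <- !is.null(pp$enc1c1)
  for (i in rev(seq_len(depth + 1))) {
    if (residual) {
      out <- resBlockB(cache[[paste0("encblk", i)]], pp,
                       paste0("enc", i), dskip[[i]], G)
      G <- out$G
      dxi <- out$dx
    } else {
      nm2 <- paste0("enc", i, "b"); nm1 <- paste0("enc", i, "a")
      nrm <- !(raw_enc || (raw_level1 && i == 1))
      b2 <- cbrB(cache[[nm2]], pp[[nm2]], dskip[[i]], norm = nrm)
      G <- gAdd(G, nm2, b2$dw, b2$db)
      b1 <- cbrB(cache[[nm1]], pp[[nm1]], b2$dx, norm = nrm)
      G <- gAdd(G, nm1, b1$dw, b1$db)
      dxi <- b1$dx
    }
    if (i > 1) {
      dpool <- nn_maxpool2_bw(dxi, cache[[paste0("poolidx", i - 1)]],
                              cache[[paste0("pooldim", i - 1)]][1],
                              cache[[paste0("pooldim", i - 1)]][2])
      dskip[[i - 1]] <- dskip[[i - 1]] + dpool
    }
  }
  G
}


# encoder + classification-head only (no decoder): used by the
# classifier-shaping phase of multi-task training
unetEncForward <- function(pp, x, depth) {
  cache <- list()
  residual <- !is.null(pp$enc1c1)
  h <- x
  for (i in seq_len(depth + 1)) {
    if (residual) {
      bk <- resBlockF(h, pp, paste0("enc", i), 1L)
      cache[[paste0("encblk", i)]] <- bk
      out <- bk$y
    } else {
      c1 <- cbrF(h, pp[[paste0("enc", i, "a")]])
      c2 <- cbrF(c1$y, pp[[paste0("enc", i, "b")]])
      cache[[paste0("enc", i, "a")]] <- c1
      cache[[paste0("enc", i, "b")]] <- c2
      out <- c2$y
    }
    if (i <= depth) {
      mp <- nn_maxpool2(out)
      cache[[paste0("poolidx", i)]] <- mp$idx
      cache[[paste0("pooldim", i)]] <- dim(out)
      h <- mp$y
    } else h <- out
  }
  cache$headv <- gapF(h)
  cache$bottdim <- dim(h)
  list(headLogits = denseF(cache$headv, pp$head), cache = cache)
}

unetEncBackward <- function(pp, cache, depth, dhead) {
  G <- list()
  gh <- denseB(cache$headv, pp$head, dhead)
  G <- gAdd(G, "head", gh$dw, gh$db)
  d <- gapB(gh$dv, cache$bottdim)
  residual <- !is.null(pp$enc1c1)
  for (i in rev(seq_len(depth + 1))) {
    if (residual) {
      out <- resBlockB(cache[[paste0("encblk", i)]], pp,
                       paste0("enc", i), d, G)
      G <- out$G
      dxi <- out$dx
    } else {
      nm2 <- paste0("enc", i, "b"); nm1 <- paste0("enc", i, "a")
      b2 <- cbrB(cache[[nm2]], pp[[nm2]], d)
      G <- gAdd(G, nm2, b2$dw, b2$db)
      b1 <- cbrB(cache[[nm1]], pp[[nm1]], b2$dx)
      G <- gAdd(G, nm1, b1$dw, b1$db)
      dxi <- b1$dx
    }
    if (i > 1)
      d <- nn_maxpool2_bw(dxi, cache[[paste0("poolidx", i - 1)]],
                          cache[[paste0("pooldim", i - 1)]][1],
                          cache[[paste0("pooldim", i - 1)]][2])
  }
  G
}
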