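# 3D U-Net internals: seeded initialisation, forward/backward passes through
# the encoder-decoder, the soft-Dice + binary-cross-entropy loss, and Adam.
# Convolutions run through the compiled vol2col kernels; everything here is
# deterministic given the R RNG state.

convLayerInit <- function(cin, cout, kernel = 27L) {
  # He-normal initialisation for ReLU networks
  w <- array(rnorm(kernel * cin * cout, 0, sqrt(2 / (kernel * cin))),
             if (kernel == 27L) c(3, 3, 3, cin, cout) else c(cin, cout))
  list(W = w, b = numeric(cout))
}

levelFilters <- function(baseFilters, level) baseFilters * 2L^(level - 1L)

initUnetWeights <- function(inChannels, outChannels, levels, baseFilters) {
  enc <- vector("list", levels)
  for (l in seq_len(levels)) {
    f <- levelFilters(baseFilters, l)
    cin <- if (l == 1L) inChannels else levelFilters(baseFilters, l - 1L)
    enc[[l]] <- list(conv1 = convLayerInit(cin, f), conv2 = convLayerInit(f, f))
  }
  dec <- if (levels > 1L) vector("list", levels - 1L) else list()
  for (l in rev(seq_len(levels - 1L))) {
    f <- levelFilters(baseFilters, l)
    dec[[l]] <- list(
      up = convLayerInit(levelFilters(baseFilters, l + 1L), f),
      conv1 = convLayerInit(2L * f, f),
      conv2 = convLayerInit(f, f))
  }
  final <- convLayerInit(baseFilters, outChannels, kernel = 1L)
  # start the output near the background prior: lesions occupy a few percent
  # of a patch at most, and a neutral 0.5 start can trap small networks in a
  # saturated all-background state
  final$b[] <- -2
  list(enc = enc, dec = dec, final = final)
}

conv1x1Forward <- function(x, layer) {
  d <- dim(x)
  n <- prod(d[1:3])
  y <- matrix(x, n, d[4]) %*% layer$W
  y <- sweep(y, 2, layer$b, "+")
  array(y, c(d[1:3], ncol(layer$W)))
}

conv1x1Backward <- function(x, layer, dy) {
  d <- dim(x)
  n <- prod(d[1:3])
  xm <- matrix(x, n, d[4])
  dym <- matrix(dy, n, dim(dy)[4])
  list(dx = array(dym %*% t(layer$W), d),
       dw = crossprod(xm, dym), db = colSums(dym))
}

catChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

unetForward <- function(weights, x, levels) {
  cache <- list(enc = vector("list", levels), dec = list(), x = x)
  h <- x
  for (l in seq_len(levels)) {
    cc <- list(in1 = h)
    pre1 <- .conv3d_forward(h, weights$enc[[l]]$conv1$W, weights$enc[[l]]$conv1$b)
    a1 <- pmax(pre1, 0); dim(a1) <- dim(pre1)
    cc$mask1 <- pre1 > 0; cc$in2 <- a1
    pre2 <- .conv3d_forward(a1, weights$enc[[l]]$conv2$W, weights$enc[[l]]$conv2$b)
    a2 <- pmax(pre2, 0); dim(a2) <- dim(pre2)
    cc$mask2 <- pre2 > 0; cc$skip <- a2
    if (l < levels) {
      pooled <- .maxpool3d_forward(a2)
      cc$argmax <- pooled$argmax
      cc$poolInDim <- dim(a2)
      h <- pooled$y
    } else h <- a2
    cache$enc[[l]] <- cc
  }
  if (levels > 1L) {
    cache$dec <- vector("list", levels - 1L)
    for (l in rev(seq_len(levels - 1L))) {
      cc <- list()
      up <- .upsample3d_forward(h)
      cc$upIn <- up
      preU <- .conv3d_forward(up, weights$dec[[l]]$up$W, weights$dec[[l]]$up$b)
      aU <- pmax(preU, 0); dim(aU) <- dim(preU)
      cc$maskU <- preU > 0
      skip <- cache$enc[[l]]$skip
      cat1 <- catChannels(skip, aU)
      cc$in1 <- cat1; cc$nSkip <- dim(skip)[4]
      pre1 <- .conv3d_forward(cat1, weights$dec[[l]]$conv1$W,
                              weights$dec[[l]]$conv1$b)
      a1 <- pmax(pre1, 0); dim(a1) <- dim(pre1)
      cc$mask1 <- pre1 > 0; cc$in2 <- a1
      pre2 <- .conv3d_forward(a1, weights$dec[[l]]$conv2$W,
                              weights$dec[[l]]$conv2$b)
      a2 <- pmax(pre2, 0); dim(a2) <- dim(pre2)
      cc$mask2 <- pre2 > 0
      h <- a2
      cache$dec[[l]] <- cc
    }
  }
  cache$finalIn <- h
  logits <- conv1x1Forward(h, weights$final)
  list(logits = logits, cache = cache)
}

unetBackward <- function(weights, cache, dlogits, levels) {
  grads <- list(enc = vector("list", levels),
                dec = if (levels > 1L) vector("list", levels - 1L) else list())
  fb <- conv1x1Backward(cache$finalIn, weights$final, dlogits)
  grads$final <- list(W = fb$dw, b = fb$db)
  dh <- fb$dx
  dskip <- vector("list", levels)  # gradient flowing into each encoder skip
  if (levels > 1L) {
    for (l in seq_len(levels - 1L)) {
      cc <- cache$dec[[l]]
      dpre2 <- dh * cc$mask2
      b2 <- .conv3d_backward(cc$in2, weights$dec[[l]]$conv2$W, dpre2)
      dpre1 <- b2$dx * cc$mask1
      b1 <- .conv3d_backward(cc$in1, weights$dec[[l]]$conv1$W, dpre1)
      nS <- cc$nSkip
      dcat <- b1$dx
      dskip[[l]] <- dcat[, , , seq_len(nS), drop = FALSE]
      daU <- dcat[, , , nS + seq_len(dim(dcat)[4] - nS), drop = FALSE]
      dpreU <- daU * cc$maskU
      bU <- .conv3d_backward(cc$upIn, weights$dec[[l]]$up$W, dpreU)
      grads$dec[[l]] <- list(
        up = list(W = bU$dw, b = bU$db),
        conv1 = list(W = b1$dw, b = b1$db),
        conv2 = list(W = b2$dw, b = b2$db))
      dh <- .upsample3d_backward(bU$dx)  # into the level-(l+1) output
    }
  }
  for (l in rev(seq_len(levels))) {
    cc <- cache$enc[[l]]
    if (l < levels) {
      da2 <- .maxpool3d_backward(dh, cc$argmax, cc$poolInDim)
      da2 <- da2 + dskip[[l]]
    } else da2 <- dh
    dpre2 <- da2 * cc$mask2
    b2 <- .conv3d_backward(cc$in2, weights$enc[[l]]$conv2$W, dpre2)
    dpre1 <- b2$dx * cc$mask1
    b1 <- .conv3d_backward(cc$in1, weights$enc[[l]]$conv1$W, dpre1)
    grads$enc[[l]] <- list(conv1 = list(W = b1$dw, b = b1$db),
                           conv2 = list(W = b2$dw, b = b2$db))
    dh <- b1$dx
  }
  grads
}

sigmoidStable <- function(z) 1 / (1 + exp(-z))

# soft-Dice + binary cross-entropy, equal weights; returns loss and d/dlogits
diceBceLoss <- function(logits, target, eps = 1) {
  p <- sigmoidStable(logits)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  n <- length(p)
  bce <- -mean(target * log(pc) + (1 - target) * log(1 - pc))
  dbce <- (p - target) / n
  d <- dim(p)
  nc <- d[4]
  nvox <- prod(d[1:3])
  pm <- matrix(p, nvox, nc)
  tm <- matrix(target, nvox, nc)
  sp <- colSums(pm); st <- colSums(tm); spt <- colSums(pm * tm)
  dicePerChannel <- (2 * spt + eps) / (sp + st + eps)
  diceLoss <- 1 - mean(dicePerChannel)
  ddice_dp <- matrix(0, nvox, nc)
  for (c in seq_len(nc)) {
    denom <- (sp[c] + st[c] + eps)
    ddice_dp[, c] <- -(2 * tm[, c] * denom - (2 * spt[c] + eps)) / denom^2 / nc
  }
  dp <- array(ddice_dp, d)
  dlogits <- dbce + dp * p * (1 - p)
  list(loss = bce + diceLoss, dice = mean(dicePerChannel), dlogits = dlogits)
}

# elementwise tree walk over nested weight lists (leaves: numeric arrays)
mapTree <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]]))
    return(stats::setNames(
      lapply(seq_along(trees[[1]]),
             function(i) do.call(mapTree, c(list(f), lapply(trees, `[[`, i)))),
      names(trees[[1]])))
  do.call(f, trees)
}

zerosLike <- function(w) mapTree(function(x) { x[] <- 0; x }, w)

adamStep <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     epsilon = 1e-8) {
  state$t <- state$t + 1
  state$m <- mapTree(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- mapTree(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v,
                     grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  weights <- mapTree(function(w, m, v)
    w - lr * (m / bc1) / (sqrt(v / bc2) + epsilon),
    weights, state$m, state$v)
  list(weights = weights, state = state)
}
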