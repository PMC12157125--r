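## Layer-level forward and backward passes. Layers operate on column-major
## arrays whose last dimension indexes samples; dense layers operate on
## (N x features) matrices after an explicit flatten. Convolutions and max
## pooling call the compiled im2col/GEMM kernels; batch normalisation,
## dense algebra and activations stay in R where BLAS already does the
## heavy lifting. Every layer returns the cache its backward pass needs.

reluFwd <- function(x) {
  x[x < 0] <- 0
  x
}

## -- batch normalisation over channels ------------------------------------
## x is reshaped to a (positions x channels*N) matrix; statistics pool over
## positions and samples per channel.
bnForward <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  nd <- length(d)
  C <- d[nd - 1L]
  N <- d[nd]
  P <- prod(d[-c(nd - 1L, nd)])
  m <- matrix(x, P, C * N)
  cm <- matrix(colMeans(m), C, N)
  mu <- rowMeans(cm)
  cv <- matrix(colMeans(m * m), C, N)
  va <- rowMeans(cv) - mu^2
  sdv <- sqrt(va + eps)
  xhat <- (m - rep(mu, each = P)) / rep(sdv, each = P)
  y <- xhat * rep(gamma, each = P) + rep(beta, each = P)
  dim(y) <- d
  list(y = y, xhat = xhat, sdv = sdv, dims = d, P = P, C = C, N = N)
}

bnBackward <- function(cache, gamma, dy) {
  P <- cache$P; C <- cache$C; N <- cache$N
  dm <- matrix(dy, P, C * N)
  prodm <- dm * cache$xhat
  chMean <- function(m) rowMeans(matrix(colMeans(m), C, N))
  dgamma <- chMean(prodm) * P * N
  dbeta <- chMean(dm) * P * N
  mdy <- chMean(dm)
  mdyx <- chMean(prodm)
  dx <- (rep(gamma / cache$sdv, each = P)) *
    (dm - rep(mdy, each = P) - cache$xhat * rep(mdyx, each = P))
  dim(dx) <- cache$dims
  dx
}

## -- single-layer dispatch -------------------------------------------------

layerForward <- function(layer, params, x) {
  kind <- layer$kind
  N <- dim(x)[length(dim(x))]
  if (kind == "conv2d" || kind == "conv3d") {
    W <- params[[layer$W]]
    b <- params[[layer$b]]
    k <- layer$kernel
    y <- if (kind == "conv2d")
      conv2d_fwd(x, dim(x), W, b, k[1], k[2], layer$stride, layer$pad)
    else
      conv3d_fwd(x, dim(x), W, b, k[1], k[2], k[3], layer$stride, layer$pad)
    dim(y) <- c(layer$outShape, N)
    mask <- NULL
    if (identical(layer$activation, "relu")) {
      mask <- y > 0
      y <- reluFwd(y)
    }
    list(y = y, cache = list(x = x, mask = mask))
  } else if (kind == "maxpool2d" || kind == "maxpool3d") {
    k <- layer$kernel
    r <- if (kind == "maxpool2d")
      maxpool2d_fwd(x, dim(x), k[1], k[2], layer$stride, layer$pad)
    else
      maxpool3d_fwd(x, dim(x), k[1], k[2], k[3], layer$stride, layer$pad)
    y <- r$y
    dim(y) <- c(layer$outShape, N)
    list(y = y, cache = list(argmax = r$argmax,
                             inSize = prod(dim(x)[-length(dim(x))]),
                             outSize = prod(layer$outShape), N = N,
                             inDims = dim(x)))
  } else if (kind == "flatten") {
    K <- prod(layer$outShape)
    y <- t(matrix(x, K, N))
    list(y = y, cache = list(inDims = dim(x)))
  } else if (kind == "dense") {
    W <- params[[layer$W]]
    b <- params[[layer$b]]
    y <- x %*% W + rep(b, each = nrow(x))
    mask <- NULL
    if (identical(layer$activation, "relu")) {
      mask <- y > 0
      y <- reluFwd(y)
    }
    list(y = y, cache = list(x = x, mask = mask))
  } else if (kind == "gap3d") {
    d <- dim(x)
    C <- d[4]
    P <- prod(d[1:3])
    y <- t(matrix(colMeans(matrix(x, P, C * N)), C, N))
    list(y = y, cache = list(inDims = d, P = P))
  } else if (kind == "resblock3d") {
    resblockForward(layer, params, x)
  } else stop("unknown layer kind: ", kind)
}

layerBackward <- function(layer, params, cache, dy) {
  kind <- layer$kind
  grads <- list()
  if (kind == "conv2d" || kind == "conv3d") {
    if (!is.null(cache$mask)) dy <- dy * cache$mask
    W <- params[[layer$W]]
    k <- layer$kernel
    r <- if (kind == "conv2d")
      conv2d_bwd(cache$x, dim(cache$x), W, dy, k[1], k[2],
                 layer$stride, layer$pad)
    else
      conv3d_bwd(cache$x, dim(cache$x), W, dy, k[1], k[2], k[3],
                 layer$stride, layer$pad)
    dx <- r$dx
    dim(dx) <- dim(cache$x)
    grads[[layer$W]] <- r$dW
    grads[[layer$b]] <- r$db
    list(dx = dx, grads = grads)
  } else if (kind == "maxpool2d" || kind == "maxpool3d") {
    dx <- maxpool_bwd(dy, cache$argmax, cache$inSize, cache$outSize,
                      cache$N)
    dim(dx) <- cache$inDims
    list(dx = dx, grads = grads)
  } else if (kind == "flatten") {
    dx <- array(t(dy), dim = cache$inDims)
    list(dx = dx, grads = grads)
  } else if (kind == "dense") {
    if (!is.null(cache$mask)) dy <- dy * cache$mask
    W <- params[[layer$W]]
    grads[[layer$W]] <- crossprod(cache$x, dy)
    grads[[layer$b]] <- colSums(dy)
    list(dx = dy %*% t(W), grads = grads)
  } else if (kind == "gap3d") {
    C <- cache$inDims[4]
    dx <- array(rep(as.vector(t(dy)), each = cache$P) / cache$P,
                dim = cache$inDims)
    list(dx = dx, grads = grads)
  } else if (kind == "resblock3d") {
    resblockBackward(layer, params, cache, dy)
  } else stop("unknown layer kind: ", kind)
}

## -- pre-activation residual block ----------------------------------------
## out = conv2(relu(bn2(conv1(relu(bn1(x)))))) + shortcut, where the
## shortcut is the identity or, when downsampling / widening, a 1x1x1
## projection of the pre-activated input with the block's stride.

resblockForward <- function(layer, params, x) {
  N <- dim(x)[length(dim(x))]
  bn1 <- bnForward(x, params[[layer$g1]], params[[layer$be1]])
  a1 <- reluFwd(bn1$y)
  m1 <- a1 > 0
  y1 <- conv3d_fwd(a1, dim(a1), params[[layer$W1]], params[[layer$b1]],
                   3L, 3L, 3L, layer$stride, 1L)
  dim(y1) <- c(layer$midShape, N)
  bn2 <- bnForward(y1, params[[layer$g2]], params[[layer$be2]])
  a2 <- reluFwd(bn2$y)
  m2 <- a2 > 0
  y2 <- conv3d_fwd(a2, dim(a2), params[[layer$W2]], params[[layer$b2]],
                   3L, 3L, 3L, 1L, 1L)
  dim(y2) <- c(layer$outShape, N)
  if (layer$project) {
    sc <- conv3d_fwd(a1, dim(a1), params[[layer$Wp]], params[[layer$bp]],
                     1L, 1L, 1L, layer$stride, 0L)
    dim(sc) <- c(layer$outShape, N)
  } else sc <- x
  list(y = y2 + sc,
       cache = list(bn1 = bn1, m1 = m1, a1 = a1, y1 = y1, bn2 = bn2,
                    m2 = m2, a2 = a2))
}

resblockBackward <- function(layer, params, cache, dy) {
  grads <- list()
  ## main branch: conv2 <- relu/bn2 <- conv1
  r2 <- conv3d_bwd(cache$a2, dim(cache$a2), params[[layer$W2]], dy,
                   3L, 3L, 3L, 1L, 1L)
  grads[[layer$W2]] <- r2$dW
  grads[[layer$b2]] <- r2$db
  da2 <- r2$dx
  dim(da2) <- dim(cache$a2)
  da2 <- da2 * cache$m2
  dy1 <- bnBackward(cache$bn2, params[[layer$g2]], da2)
  grads[[layer$g2]] <- attrOrBn(cache$bn2, params[[layer$g2]], da2, "g")
  grads[[layer$be2]] <- attrOrBn(cache$bn2, params[[layer$g2]], da2, "b")
  r1 <- conv3d_bwd(cache$a1, dim(cache$a1), params[[layer$W1]], dy1,
                   3L, 3L, 3L, layer$stride, 1L)
  grads[[layer$W1]] <- r1$dW
  grads[[layer$b1]] <- r1$db
  da1 <- r1$dx
  dim(da1) <- dim(cache$a1)
  ## shortcut branch
  if (layer$project) {
    rp <- conv3d_bwd(cache$a1, dim(cache$a1), params[[layer$Wp]], dy,
                     1L, 1L, 1L, layer$stride, 0L)
    grads[[layer$Wp]] <- rp$dW
    grads[[layer$bp]] <- rp$db
    dsc <- rp$dx
    dim(dsc) <- dim(cache$a1)
    da1 <- da1 + dsc
  }
  da1 <- da1 * cache$m1
  dx <- bnBackward(cache$bn1, params[[layer$g1]], da1)
  grads[[layer$g1]] <- attrOrBn(cache$bn1, params[[layer$g1]], da1, "g")
  grads[[layer$be1]] <- attrOrBn(cache$bn1, params[[layer$g1]], da1, "b")
  if (!layer$project) dx <- dx + dy
  list(dx = dx, grads = grads)
}

## gamma/beta gradients from a bn cache (kept separate so bnBackward stays
## a pure input-gradient routine)
attrOrBn <- function(cache, gamma, dy, which) {
  P <- cache$P; C <- cache$C; N <- cache$N
  dm <- matrix(dy, P, C * N)
  chSum <- function(m) rowSums(matrix(colSums(m), C, N))
  if (which == "g") chSum(dm * cache$xhat) else chSum(dm)
}
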