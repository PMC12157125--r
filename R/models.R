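## Architecture builders with verifiable shape contracts. Each builder
## composes layer descriptors over its declared input shape, records the
## per-layer output sizes, and asserts the trace against the reference
## architecture table it reproduces, failing with the offending layer
## named if a stride or padding choice drifts. Rectifier activations
## follow every convolution and hidden dense layer; final outputs (the
## scalar score or the feature vector handed to the integration head) are
## linear. The residual blocks use pre-activation batch normalisation.

outSpatial <- function(s, k, stride, pad) (s + 2L * pad - k) %/% stride + 1L

fmtShape <- function(shape) paste(shape, collapse = "x")

## Compose layer descriptors, filling shapes and parameter names.
composeLayers <- function(inputShape, specs) {
  shape <- as.integer(inputShape)
  layers <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    L <- sp
    L$name <- paste0("L", i, "_", sp$kind)
    if (sp$kind %in% c("conv2d", "conv3d")) {
      nsp <- length(shape) - 1L
      sps <- vapply(shape[seq_len(nsp)], outSpatial, integer(1),
                    k = sp$kernel[1], stride = sp$stride, pad = sp$pad)
      L$inChannels <- shape[nsp + 1L]
      L$outShape <- c(sps, sp$filters)
      L$W <- paste0(L$name, ".W")
      L$b <- paste0(L$name, ".b")
    } else if (sp$kind %in% c("maxpool2d", "maxpool3d")) {
      nsp <- length(shape) - 1L
      sps <- vapply(shape[seq_len(nsp)], outSpatial, integer(1),
                    k = sp$kernel[1], stride = sp$stride, pad = sp$pad)
      L$outShape <- c(sps, shape[nsp + 1L])
    } else if (sp$kind == "flatten") {
      L$outShape <- prod(shape)
    } else if (sp$kind == "dense") {
      L$inUnits <- prod(shape)
      L$outShape <- sp$units
      L$W <- paste0(L$name, ".W")
      L$b <- paste0(L$name, ".b")
    } else if (sp$kind == "gap3d") {
      L$outShape <- shape[4]
    } else if (sp$kind == "resblock3d") {
      L$inChannels <- shape[4]
      sps <- shape[1:3] %/% sp$stride
      L$midShape <- c(sps, sp$filters)
      L$outShape <- c(sps, sp$filters)
      L$project <- (sp$stride != 1L) || (shape[4] != sp$filters)
      L$W1 <- paste0(L$name, ".W1"); L$b1 <- paste0(L$name, ".b1")
      L$W2 <- paste0(L$name, ".W2"); L$b2 <- paste0(L$name, ".b2")
      L$g1 <- paste0(L$name, ".g1"); L$be1 <- paste0(L$name, ".be1")
      L$g2 <- paste0(L$name, ".g2"); L$be2 <- paste0(L$name, ".be2")
      if (L$project) {
        L$Wp <- paste0(L$name, ".Wp"); L$bp <- paste0(L$name, ".bp")
      }
    } else stop("unknown layer kind: ", sp$kind)
    layers[[i]] <- L
    shape <- as.integer(L$outShape)
  }
  layers
}

newNetwork <- function(name, inputShape, specs, expectedTrace = NULL) {
  layers <- composeLayers(inputShape, specs)
  if (!is.null(expectedTrace)) {
    got <- vapply(layers, function(L) fmtShape(L$outShape), character(1))
    bad <- which(got != expectedTrace)
    if (length(bad))
      stop("shape trace mismatch at layer ", layers[[bad[1]]]$name,
           ": got ", got[bad[1]], ", expected ", expectedTrace[bad[1]])
  }
  last <- layers[[length(layers)]]
  new("NetworkSpec", name = name, inputShape = as.integer(inputShape),
      layers = layers, parameters = list(),
      outputDim = as.integer(prod(last$outShape)))
}

conv2dSpec <- function(filters, kernel, stride = 1L, pad = 0L,
                       activation = "relu")
  list(kind = "conv2d", filters = as.integer(filters),
       kernel = rep(as.integer(kernel), 2L), stride = as.integer(stride),
       pad = as.integer(pad), activation = activation)

conv3dSpec <- function(filters, kernel, stride = 1L, pad = 0L,
                       activation = "relu")
  list(kind = "conv3d", filters = as.integer(filters),
       kernel = rep(as.integer(kernel), 3L), stride = as.integer(stride),
       pad = as.integer(pad), activation = activation)

maxpool2dSpec <- function(kernel, stride, pad = 0L)
  list(kind = "maxpool2d", kernel = rep(as.integer(kernel), 2L),
       stride = as.integer(stride), pad = as.integer(pad))

maxpool3dSpec <- function(kernel, stride, pad = 0L)
  list(kind = "maxpool3d", kernel = rep(as.integer(kernel), 3L),
       stride = as.integer(stride), pad = as.integer(pad))

denseSpec <- function(units, activation = "relu")
  list(kind = "dense", units = as.integer(units), activation = activation)

resblockSpec <- function(filters, stride = 1L)
  list(kind = "resblock3d", filters = as.integer(filters),
       stride = as.integer(stride))

checkInputShape <- function(inputShape, expected, what) {
  if (!identical(as.integer(inputShape), as.integer(expected)))
    stop(what, " requires input shape ", fmtShape(expected),
         ", got ", fmtShape(inputShape))
}

#' CNN scorer for the two-class simulation designs
#'
#' Builds the reference architecture for the 28x28 grayscale simulations:
#' conv(32, 5x5, same) -> maxpool(2x2, stride 2) -> conv(64, 5x5, same)
#' -> maxpool(2x2, stride 2) -> flatten(3136) -> dense(1024) ->
#' dense(128) -> dense(1), emitting one log relative-hazard score per
#' image.
#'
#' @param inputShape per-sample input dimensions; must be `c(28, 28, 1)`.
#' @param seed seed for [initializeParameters()]; `NULL` leaves the
#'   network uninitialised.
#' @return a [NetworkSpec-class].
#' @export
buildSimNetAB <- function(inputShape = c(28L, 28L, 1L), seed = NULL) {
  checkInputShape(inputShape, c(28L, 28L, 1L), "the two-class sim net")
  net <- newNetwork(
    "simnet_ab", inputShape,
    list(conv2dSpec(32L, 5L, pad = 2L), maxpool2dSpec(2L, 2L),
         conv2dSpec(64L, 5L, pad = 2L), maxpool2dSpec(2L, 2L),
         list(kind = "flatten"), denseSpec(1024L), denseSpec(128L),
         denseSpec(1L, activation = "linear")),
    expectedTrace = c("28x28x32", "14x14x32", "14x14x64", "7x7x64",
                      "3136", "1024", "128", "1"))
  if (!is.null(seed)) net <- initializeParameters(net, seed)
  net
}

#' CNN scorer for the nodule-image two-task design
#'
#' The same convolutional trunk as [buildSimNetAB()] applied to 32x32 RGB
#' input, with dense sizes 100 -> 10 -> 1. The single output is used
#' twice: raw as the log relative hazard and through the sigmoid link as
#' the disease probability.
#'
#' @param inputShape must be `c(32, 32, 3)`.
#' @inheritParams buildSimNetAB
#' @return a [NetworkSpec-class].
#' @export
buildSimNetC <- function(inputShape = c(32L, 32L, 3L), seed = NULL) {
  checkInputShape(inputShape, c(32L, 32L, 3L), "the nodule sim net")
  net <- newNetwork(
    "simnet_c", inputShape,
    list(conv2dSpec(32L, 5L, pad = 2L), maxpool2dSpec(2L, 2L),
         conv2dSpec(64L, 5L, pad = 2L), maxpool2dSpec(2L, 2L),
         list(kind = "flatten"), denseSpec(100L), denseSpec(10L),
         denseSpec(1L, activation = "linear")),
    expectedTrace = c("32x32x32", "16x16x32", "16x16x64", "8x8x64",
                      "4096", "100", "10", "1"))
  if (!is.null(seed)) net <- initializeParameters(net, seed)
  net
}

#' 3D AlexNet-style feature extractor for CT nodule crops
#'
#' Reproduces the printed output size of every layer of the 3D AlexNet
#' reference stack on 96x96x96x1 crops, ending
#' flatten(16384) -> dense(4096) -> dense(128). The table leaves strides
#' and paddings unstated; they are inferred per layer to reproduce the
#' spatial trace 48 -> 23 -> 23 -> 11 -> 9 -> 9 -> 4 (first convolution
#' stride 2 with same padding, 3x3x3 pools with stride 2 and no padding)
#' and the builder asserts the resulting trace.
#'
#' @param inputShape must be `c(96, 96, 96, 1)`.
#' @inheritParams buildSimNetAB
#' @return a [NetworkSpec-class] emitting 128-dimensional crop features.
#' @export
buildAlex3D <- function(inputShape = c(96L, 96L, 96L, 1L), seed = NULL) {
  checkInputShape(inputShape, c(96L, 96L, 96L, 1L), "Alex3D")
  net <- newNetwork(
    "alex3d", inputShape,
    list(conv3dSpec(96L, 3L, stride = 2L, pad = 1L),
         maxpool3dSpec(3L, 2L),
         conv3dSpec(256L, 5L, pad = 2L),
         maxpool3dSpec(3L, 2L),
         conv3dSpec(384L, 3L, pad = 0L),
         conv3dSpec(256L, 3L, pad = 1L),
         maxpool3dSpec(3L, 2L),
         list(kind = "flatten"),
         denseSpec(4096L),
         denseSpec(128L, activation = "linear")),
    expectedTrace = c("48x48x48x96", "23x23x23x96", "23x23x23x256",
                      "11x11x11x256", "9x9x9x384", "9x9x9x256",
                      "4x4x4x256", "16384", "4096", "128"))
  if (!is.null(seed)) net <- initializeParameters(net, seed)
  net
}

#' 3D VGG16-style feature extractor for CT nodule crops
#'
#' Thirteen same-padded 3x3x3 convolutions in five blocks separated by
#' 3x3x3 stride-2 pools (padding 1, so each pool exactly halves the
#' spatial side), then flatten(13824) -> dense(4096) -> dense(4096) ->
#' dense(128).
#'
#' @param inputShape must be `c(96, 96, 96, 1)`.
#' @inheritParams buildSimNetAB
#' @return a [NetworkSpec-class] emitting 128-dimensional crop features.
#' @export
buildVgg163D <- function(inputShape = c(96L, 96L, 96L, 1L), seed = NULL) {
  checkInputShape(inputShape, c(96L, 96L, 96L, 1L), "VGG16-3D")
  cfg <- list(c(64L, 2L), c(128L, 2L), c(256L, 3L), c(512L, 3L),
              c(512L, 3L))
  specs <- list()
  tr <- character(0)
  side <- 96L
  for (blk in cfg) {
    for (r in seq_len(blk[2])) {
      specs <- c(specs, list(conv3dSpec(blk[1], 3L, pad = 1L)))
      tr <- c(tr, fmtShape(c(rep(side, 3), blk[1])))
    }
    specs <- c(specs, list(maxpool3dSpec(3L, 2L, pad = 1L)))
    side <- side %/% 2L
    tr <- c(tr, fmtShape(c(rep(side, 3), blk[1])))
  }
  specs <- c(specs, list(list(kind = "flatten"), denseSpec(4096L),
                         denseSpec(4096L),
                         denseSpec(128L, activation = "linear")))
  tr <- c(tr, "13824", "4096", "4096", "128")
  net <- newNetwork("vgg16_3d", inputShape, specs, expectedTrace = tr)
  if (!is.null(seed)) net <- initializeParameters(net, seed)
  net
}

#' 3D ResNet-18-style feature extractor for CT nodule crops
#'
#' Stem convolution (7x7x7, 64 channels, stride 2) and 3x3x3 stride-2 max
#' pool, followed by four stages of two pre-activation residual blocks
#' with 64/128/256/512 channels -- the first block of stages 2-4
#' downsampling with stride 2 via a 1x1x1 projection shortcut -- then
#' global average pooling to 512 features and a dense layer to 128.
#' Identity-shortcut blocks preserve shape; downsampling blocks halve
#' each spatial dimension.
#'
#' @param inputShape must be `c(96, 96, 96, 1)`.
#' @inheritParams buildSimNetAB
#' @return a [NetworkSpec-class] emitting 128-dimensional crop features.
#' @export
buildResNet183D <- function(inputShape = c(96L, 96L, 96L, 1L),
                            seed = NULL) {
  checkInputShape(inputShape, c(96L, 96L, 96L, 1L), "ResNet18-3D")
  net <- newNetwork(
    "resnet18_3d", inputShape,
    list(conv3dSpec(64L, 7L, stride = 2L, pad = 3L),
         maxpool3dSpec(3L, 2L, pad = 1L),
         resblockSpec(64L), resblockSpec(64L),
         resblockSpec(128L, stride = 2L), resblockSpec(128L),
         resblockSpec(256L, stride = 2L), resblockSpec(256L),
         resblockSpec(512L, stride = 2L), resblockSpec(512L),
         list(kind = "gap3d"),
         denseSpec(128L, activation = "linear")),
    expectedTrace = c("48x48x48x64", "24x24x24x64", "24x24x24x64",
                      "24x24x24x64", "12x12x12x128", "12x12x12x128",
                      "6x6x6x256", "6x6x6x256", "3x3x3x512", "3x3x3x512",
                      "512", "128"))
  if (!is.null(seed)) net <- initializeParameters(net, seed)
  net
}

#' Seeded variance-scaled parameter initialisation
#'
#' Weights draw from a centred normal with variance `2 / fanIn` for
#' rectified layers and `1 / fanIn` for linear outputs; biases start at
#' zero, batch-normalisation scales at one.
#'
#' @param net a [NetworkSpec-class].
#' @param seed integer seed.
#' @return the network with its parameter container filled.
#' @export
initializeParameters <- function(net, seed = 1L) {
  set.seed(as.integer(seed))
  params <- list()
  initW <- function(K, F, act) {
    sdv <- sqrt((if (identical(act, "relu")) 2 else 1) / K)
    matrix(rnorm(K * F, sd = sdv), K, F)
  }
  for (L in net@layers) {
    if (L$kind %in% c("conv2d", "conv3d")) {
      K <- prod(L$kernel) * L$inChannels
      params[[L$W]] <- initW(K, L$filters, L$activation)
      params[[L$b]] <- numeric(L$filters)
    } else if (L$kind == "dense") {
      params[[L$W]] <- initW(L$inUnits, L$units, L$activation)
      params[[L$b]] <- numeric(L$units)
    } else if (L$kind == "resblock3d") {
      K1 <- 27L * L$inChannels
      K2 <- 27L * L$filters
      params[[L$W1]] <- initW(K1, L$filters, "relu")
      params[[L$b1]] <- numeric(L$filters)
      params[[L$W2]] <- initW(K2, L$filters, "relu")
      params[[L$b2]] <- numeric(L$filters)
      params[[L$g1]] <- rep(1, L$inChannels)
      params[[L$be1]] <- numeric(L$inChannels)
      params[[L$g2]] <- rep(1, L$filters)
      params[[L$be2]] <- numeric(L$filters)
      if (L$project) {
        params[[L$Wp]] <- initW(L$inChannels, L$filters, "linear")
        params[[L$bp]] <- numeric(L$filters)
      }
    }
  }
  net@parameters <- params
  net
}

#' Forward pass of a network
#'
#' @param net an initialised [NetworkSpec-class].
#' @param x numeric array with per-sample dimensions equal to the
#'   network's input shape and samples along the last dimension (a lone
#'   sample may omit it), or an [ImageSet-class].
#' @param keepCache keep per-layer caches for [networkGradients()].
#' @return a list with `output` (a length-N score vector when the output
#'   dimension is 1, otherwise an N x outputDim matrix) and, when
#'   requested, `caches`.
#' @export
networkForward <- function(net, x, keepCache = FALSE) {
  if (is(x, "ImageSet")) x <- x@images
  if (!length(net@parameters))
    stop("network has no parameters; call initializeParameters() first")
  inShape <- net@inputShape
  if (length(dim(x)) == length(inShape)) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (!identical(as.integer(d[-length(d)]), inShape))
    stop("input shape ", fmtShape(d[-length(d)]),
         " does not match network input ", fmtShape(inShape))
  caches <- if (keepCache) vector("list", length(net@layers)) else NULL
  for (i in seq_along(net@layers)) {
    r <- layerForward(net@layers[[i]], net@parameters, x)
    x <- r$y
    if (keepCache) caches[[i]] <- r$cache
  }
  out <- if (net@outputDim == 1L) as.numeric(x) else x
  list(output = out, caches = caches)
}

#' Backward pass: parameter gradients
#'
#' Given the caches of a forward pass and the gradient of a scalar loss
#' with respect to the network output, accumulates gradients for every
#' parameter.
#'
#' @param net the network used in the forward pass.
#' @param caches `caches` from `networkForward(..., keepCache = TRUE)`.
#' @param dOutput numeric gradient, length N (or N x outputDim matrix).
#' @return named list of gradients matching `net@parameters`.
#' @export
networkGradients <- function(net, caches, dOutput) {
  if (!is.matrix(dOutput)) dOutput <- matrix(dOutput, ncol = net@outputDim)
  dy <- dOutput
  grads <- list()
  for (i in rev(seq_along(net@layers))) {
    r <- layerBackward(net@layers[[i]], net@parameters, caches[[i]], dy)
    caches[[i]] <- NULL          # release activation memory as we go
    dy <- r$dx
    for (nm in names(r$grads)) grads[[nm]] <- r$grads[[nm]]
  }
  grads
}

#' @export
setMethod("shapeTrace", "NetworkSpec", function(x) {
  data.frame(
    layer = vapply(x@layers, function(L) L$kind, character(1)),
    kernels = vapply(x@layers, function(L)
      if (!is.null(L$filters)) as.integer(L$filters) else NA_integer_,
      integer(1)),
    kernel = vapply(x@layers, function(L)
      if (!is.null(L$kernel)) fmtShape(L$kernel) else "", character(1)),
    output = vapply(x@layers, function(L) fmtShape(L$outShape),
                    character(1)),
    stringsAsFactors = FALSE)
})

#' @export
setMethod("parameterCount", "NetworkSpec", function(x) {
  if (length(x@parameters))
    return(sum(vapply(x@parameters, length, numeric(1))))
  ## uninitialised: count from the layer descriptors
  tot <- 0
  for (L in x@layers) {
    if (L$kind %in% c("conv2d", "conv3d"))
      tot <- tot + prod(L$kernel) * L$inChannels * L$filters + L$filters
    else if (L$kind == "dense")
      tot <- tot + L$inUnits * L$units + L$units
    else if (L$kind == "resblock3d") {
      tot <- tot + 27 * L$inChannels * L$filters + L$filters +
        27 * L$filters * L$filters + L$filters +
        2 * L$inChannels + 2 * L$filters
      if (L$project) tot <- tot + L$inChannels * L$filters + L$filters
    }
  }
  tot
})

#' @export
setMethod("show", "NetworkSpec", function(object) {
  cat("NetworkSpec '", object@name, "': input ",
      fmtShape(object@inputShape), ", ", length(object@layers),
      " layers, ", format(parameterCount(object), big.mark = ","),
      " parameters", if (length(object@parameters)) "" else
        " (uninitialised)", "\n", sep = "")
  print(shapeTrace(object), row.names = FALSE)
})

## ---------------------------------------------------------------- crops

#' Five-crop feature integration head
#'
#' Builds the integration stage that turns the five per-crop 128-feature
#' vectors (the top five nodule proposals of one patient) into a single
#' log relative hazard: a shared dense 128 -> 32 rectified layer applied
#' to each crop, a per-crop maximum over the 32 units, concatenation of
#' the five maxima into one 5-vector, and a final dense 5 -> 1 output.
#'
#' @param nCrops number of crops; the reference design uses 5.
#' @param featureDim per-crop feature length; the reference design
#'   uses 128.
#' @param seed seed for parameter initialisation.
#' @return an integration head (list with class `"integrationHead"`).
#' @export
buildIntegrationHead <- function(nCrops = 5L, featureDim = 128L,
                                 seed = 1L) {
  set.seed(as.integer(seed))
  head <- list(nCrops = as.integer(nCrops),
               featureDim = as.integer(featureDim),
               W1 = matrix(rnorm(featureDim * 32L,
                                 sd = sqrt(2 / featureDim)),
                           featureDim, 32L),
               b1 = numeric(32L),
               W2 = matrix(rnorm(nCrops, sd = sqrt(1 / nCrops)), nCrops, 1L),
               b2 = 0)
  class(head) <- "integrationHead"
  head
}

#' Integrate per-crop features into one hazard score
#'
#' @param head an integration head from [buildIntegrationHead()].
#' @param features a `featureDim x nCrops` matrix (or
#'   `featureDim x nCrops x N` array) of crop features.
#' @return scalar score (length-N vector for an array input). The
#'   intermediate shapes per sample are 128x5 -> 32x5 -> 1x5 -> 1.
#' @export
integrateCrops <- function(head, features) {
  stopifnot(inherits(head, "integrationHead"))
  d <- dim(features)
  if (length(d) == 2L) {
    dim(features) <- c(d, 1L)
    d <- dim(features)
  }
  if (d[1] != head$featureDim || d[2] != head$nCrops)
    stop("expected ", head$featureDim, " features for exactly ",
         head$nCrops, " crops, got ", fmtShape(d[1:2]))
  N <- d[3]
  out <- numeric(N)
  for (n in seq_len(N)) {
    a <- reluFwd(crossprod(head$W1, features[, , n]) + head$b1)  # 32 x 5
    m <- apply(a, 2L, max)                                       # 1 x 5
    out[n] <- sum(head$W2 * m) + head$b2
  }
  out
}

#' @rdname integrateCrops
#' @param dOutput gradient of the loss w.r.t. each sample's score.
#' @return `integrateCropsGrad` returns gradients for `W1`, `b1`, `W2`,
#'   `b2` and the input features.
#' @export
integrateCropsGrad <- function(head, features, dOutput) {
  stopifnot(inherits(head, "integrationHead"))
  d <- dim(features)
  if (length(d) == 2L) {
    dim(features) <- c(d, 1L)
    d <- dim(features)
  }
  N <- d[3]
  gW1 <- 0 * head$W1; gb1 <- 0 * head$b1
  gW2 <- 0 * head$W2; gb2 <- 0
  dF <- array(0, dim = d)
  for (n in seq_len(N)) {
    f <- features[, , n]
    pre <- crossprod(head$W1, f) + head$b1
    a <- reluFwd(pre)
    argm <- apply(a, 2L, which.max)
    m <- a[cbind(argm, seq_len(head$nCrops))]
    g <- dOutput[n]
    gW2 <- gW2 + g * m
    gb2 <- gb2 + g
    dm <- g * head$W2[, 1]                     # per-crop max gradient
    ## route through the selected unit of each crop, gated by its relu
    da <- matrix(0, 32L, head$nCrops)
    sel <- cbind(argm, seq_len(head$nCrops))
    da[sel] <- dm * (pre[sel] > 0)
    gW1 <- gW1 + f %*% t(da)
    gb1 <- gb1 + rowSums(da)
    dF[, , n] <- head$W1 %*% da
  }
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, dFeatures = dF)
}
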