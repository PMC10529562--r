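# The 12-layer 1-D residual classifier. Tensors are (batch, time, channels)
# arrays; convolutions are im2col matrix products with same-padding. Weighted
# main-path layers: 3 blocks x 3 convolutions + 2 strided 1x1 downsampling
# convolutions + 1 fully connected = 12 (projection shortcuts, as usual, are
# not counted).

conv1dFw <- function(X, W, k, stride = 1L) {
  d <- dim(X); B <- d[1]; Tin <- d[2]; Cin <- d[3]
  Tout <- as.integer(ceiling(Tin / stride))
  padTotal <- max((Tout - 1L) * stride + k - Tin, 0L)
  padL <- padTotal %/% 2L
  Xp <- array(0, c(B, Tin + padTotal, Cin))
  Xp[, padL + seq_len(Tin), ] <- X
  Xc <- matrix(0, B * Tout, k * Cin)
  baseIdx <- (seq_len(Tout) - 1L) * stride
  for (i in seq_len(k)) {
    sl <- Xp[, baseIdx + i, , drop = FALSE]
    dim(sl) <- c(B * Tout, Cin)
    Xc[, ((i - 1L) * Cin + 1L):(i * Cin)] <- sl
  }
  Y <- Xc %*% W
  dim(Y) <- c(B, Tout, ncol(W))
  list(Y = Y, cache = list(Xc = Xc, dims = d, Tout = Tout, padL = padL,
                           padTotal = padTotal, k = k, stride = stride))
}

conv1dBw <- function(dY, W, cache) {
  B <- cache$dims[1]; Tin <- cache$dims[2]; Cin <- cache$dims[3]
  Tout <- cache$Tout; k <- cache$k; stride <- cache$stride
  dY2 <- dY; dim(dY2) <- c(B * Tout, ncol(W))
  dW <- crossprod(cache$Xc, dY2)
  dXc <- dY2 %*% t(W)
  dXp <- array(0, c(B, Tin + cache$padTotal, Cin))
  baseIdx <- (seq_len(Tout) - 1L) * stride
  for (i in seq_len(k)) {
    sl <- dXc[, ((i - 1L) * Cin + 1L):(i * Cin), drop = FALSE]
    dim(sl) <- c(B, Tout, Cin)
    dXp[, baseIdx + i, ] <- dXp[, baseIdx + i, , drop = FALSE] + sl
  }
  list(dX = dXp[, cache$padL + seq_len(Tin), , drop = FALSE], dW = dW)
}

bnFw <- function(X, g, be, rm, rv, training, momentum = 0.9, eps = 1e-5) {
  d <- dim(X); N <- d[1] * d[2]; C <- d[3]
  Xm <- X; dim(Xm) <- c(N, C)
  if (training && N > 1) {
    mu <- colMeans(Xm)
    va <- colMeans(sweep(Xm, 2, mu)^2)
    rm <- momentum * rm + (1 - momentum) * mu
    rv <- momentum * rv + (1 - momentum) * va
  } else {
    mu <- rm; va <- rv
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(Xm, 2, mu), 2, istd, "*")
  Ym <- sweep(sweep(xhat, 2, g, "*"), 2, be, "+")
  dim(Ym) <- d
  list(Y = Ym, rm = rm, rv = rv, cache = list(xhat = xhat, istd = istd,
                                              dims = d))
}

bnBw <- function(dY, g, cache) {
  d <- cache$dims; N <- d[1] * d[2]; C <- d[3]
  dYm <- dY; dim(dYm) <- c(N, C)
  dg <- colSums(dYm * cache$xhat)
  dbe <- colSums(dYm)
  dxhat <- sweep(dYm, 2, g, "*")
  dXm <- sweep(
    dxhat * N - matrix(colSums(dxhat), N, C, byrow = TRUE) -
      cache$xhat * matrix(colSums(dxhat * cache$xhat), N, C, byrow = TRUE),
    2, cache$istd / N, "*")
  dim(dXm) <- d
  list(dX = dXm, dg = dg, dbe = dbe)
}

# conv -> batch norm -> optional rectifier, with parameter names derived
# from `nm` ("W_<nm>", "g_<nm>", "be_<nm>", buffers "run_m_<nm>"/"run_v_<nm>").
cbrFw <- function(p, nm, X, k, stride, training, relu = TRUE) {
  cv <- conv1dFw(X, p[[paste0("W_", nm)]], k, stride)
  bn <- bnFw(cv$Y, p[[paste0("g_", nm)]], p[[paste0("be_", nm)]],
             p[[paste0("run_m_", nm)]], p[[paste0("run_v_", nm)]], training)
  p[[paste0("run_m_", nm)]] <- bn$rm
  p[[paste0("run_v_", nm)]] <- bn$rv
  Y <- if (relu) bn$Y * (bn$Y > 0) else bn$Y
  list(p = p, Y = Y,
       cache = list(conv = cv$cache, bn = bn$cache,
                    Z = if (relu) bn$Y else NULL))
}

cbrBw <- function(p, nm, dY, cache, grads) {
  if (!is.null(cache$Z)) dY <- dY * (cache$Z > 0)
  bb <- bnBw(dY, p[[paste0("g_", nm)]], cache$bn)
  grads[[paste0("g_", nm)]] <- bb$dg
  grads[[paste0("be_", nm)]] <- bb$dbe
  cb <- conv1dBw(bb$dX, p[[paste0("W_", nm)]], cache$conv)
  grads[[paste0("W_", nm)]] <- cb$dW
  list(dX = cb$dX, grads = grads)
}

resnetLayout <- function(channels, kernelSizes) {
  layers <- list()
  cin <- 1L
  for (b in seq_along(channels)) {
    cout <- channels[b]
    for (j in seq_along(kernelSizes)) {
      layers[[sprintf("b%dc%d", b, j)]] <-
        list(k = kernelSizes[j], cin = if (j == 1) cin else cout, cout = cout)
    }
    if (cin != cout)
      layers[[sprintf("b%ds", b)]] <- list(k = 1L, cin = cin, cout = cout)
    if (b < length(channels))
      layers[[sprintf("d%d", b)]] <- list(k = 1L, cin = cout, cout = cout)
    cin <- cout
  }
  layers
}

initResnetParams <- function(channels, kernelSizes, nClasses, seed) {
  layers <- resnetLayout(channels, kernelSizes)
  withSeed(deriveSeed(seed, 5), {
    p <- list()
    for (nm in names(layers)) {
      l <- layers[[nm]]
      fanIn <- l$k * l$cin
      p[[paste0("W_", nm)]] <- matrix(stats::rnorm(fanIn * l$cout,
                                                   sd = sqrt(2 / fanIn)),
                                      fanIn, l$cout)
      p[[paste0("g_", nm)]] <- rep(1, l$cout)
      p[[paste0("be_", nm)]] <- rep(0, l$cout)
      p[[paste0("run_m_", nm)]] <- rep(0, l$cout)
      p[[paste0("run_v_", nm)]] <- rep(1, l$cout)
    }
    cLast <- channels[length(channels)]
    p$Wfc <- matrix(stats::rnorm(cLast * nClasses, sd = sqrt(1 / cLast)),
                    cLast, nClasses)
    p$bfc <- rep(0, nClasses)
    p
  })
}

#' Build the 12-layer 1-D residual classifier
#'
#' Three residual blocks with 64, 128 and 128 channels, each stacking three
#' 1-D convolutions of kernel lengths 8, 5 and 3 with batch normalization and
#' rectifiers, identity shortcuts (1x1 projections where channel counts
#' change), a strided 1x1 downsampling convolution after each of the first
#' two blocks, then global average pooling and a fully connected softmax
#' layer.
#'
#' @param inputLength Samples per beat; must survive two halvings (>= 4).
#' @param nClasses Output units; default 16.
#' @param channels Channels per block; default `c(64, 128, 128)`.
#' @param kernelSizes Kernel lengths within each block; default `c(8, 5, 3)`.
#' @param seed Seed for weight initialization.
#' @return An untrained [ResNetwork-class].
#' @examples
#' net <- buildResNetwork(inputLength = 64)
#' layerCount(net)  # 12
#' @export
buildResNetwork <- function(inputLength = 260, nClasses = 16,
                            channels = c(64, 128, 128),
                            kernelSizes = c(8, 5, 3), seed = 1) {
  inputLength <- as.integer(inputLength)
  if (inputLength < 4)
    stop("inputLength must survive two downsamplings (>= 4)", call. = FALSE)
  if (nClasses < 2 || any(channels < 1) || any(kernelSizes < 1))
    stop("invalid network specification", call. = FALSE)
  params <- initResnetParams(as.integer(channels), as.integer(kernelSizes),
                             as.integer(nClasses), seed)
  new("ResNetwork", inputLength = inputLength,
      channels = as.integer(channels), kernelSizes = as.integer(kernelSizes),
      nClasses = as.integer(nClasses), params = params,
      history = data.frame(), trained = FALSE)
}

#' @describeIn layerCount block convolutions + downsampling convolutions +
#'   final fully connected layer
#' @export
setMethod("layerCount", "ResNetwork", function(object)
  length(object@channels) * length(object@kernelSizes) +
    (length(object@channels) - 1L) + 1L)

resnetForward <- function(p, X, channels, kernelSizes, training) {
  if (is.matrix(X)) { d <- dim(X); dim(X) <- c(d[1], d[2], 1L) }
  caches <- list()
  cin <- 1L
  for (b in seq_along(channels)) {
    cout <- channels[b]
    Xin <- X
    out <- X
    for (j in seq_along(kernelSizes)) {
      nm <- sprintf("b%dc%d", b, j)
      st <- cbrFw(p, nm, out, kernelSizes[j], 1L, training,
                  relu = j < length(kernelSizes))
      p <- st$p
      caches[[nm]] <- st$cache
      out <- st$Y
    }
    if (cin != cout) {
      nm <- sprintf("b%ds", b)
      sc <- cbrFw(p, nm, Xin, 1L, 1L, training, relu = FALSE)
      p <- sc$p
      caches[[nm]] <- sc$cache
      short <- sc$Y
    } else short <- Xin
    S <- out + short
    X <- S * (S > 0)
    caches[[sprintf("b%dsum", b)]] <- S
    caches[[sprintf("b%dproj", b)]] <- cin != cout
    if (b < length(channels)) {
      nm <- sprintf("d%d", b)
      ds <- cbrFw(p, nm, X, 1L, 2L, training, relu = TRUE)
      p <- ds$p
      caches[[nm]] <- ds$cache
      X <- ds$Y
    }
    cin <- cout
  }
  d <- dim(X)
  gap <- colMeans(aperm(X, c(2, 1, 3)))          # (B, C): mean over time
  if (is.null(dim(gap))) gap <- matrix(gap, nrow = 1)
  logits <- sweep(gap %*% p$Wfc, 2, p$bfc, "+")
  caches$gap <- gap
  caches$gapDims <- d
  list(p = p, P = softmaxRows(logits), caches = caches)
}

resnetStep <- function(p, X, y, channels, kernelSizes) {
  fw <- resnetForward(p, X, channels, kernelSizes, training = TRUE)
  p <- fw$p
  caches <- fw$caches
  B <- nrow(X)
  Y1 <- matrix(0, B, ncol(fw$P))
  Y1[cbind(seq_len(B), y + 1L)] <- 1
  dLogits <- (fw$P - Y1) / B
  grads <- list(Wfc = crossprod(caches$gap, dLogits), bfc = colSums(dLogits))
  dGap <- dLogits %*% t(p$Wfc)
  d <- caches$gapDims
  dX <- array(rep(dGap / d[2], each = 1), c(d[1], 1L, d[3]))[, rep(1, d[2]), ,
                                                             drop = FALSE]
  for (b in rev(seq_along(channels))) {
    if (b < length(channels)) {
      nm <- sprintf("d%d", b)
      bw <- cbrBw(p, nm, dX, caches[[nm]], grads)
      grads <- bw$grads
      dX <- bw$dX
    }
    S <- caches[[sprintf("b%dsum", b)]]
    dS <- dX * (S > 0)
    # main path
    dMain <- dS
    for (j in rev(seq_along(kernelSizes))) {
      nm <- sprintf("b%dc%d", b, j)
      bw <- cbrBw(p, nm, dMain, caches[[nm]], grads)
      grads <- bw$grads
      dMain <- bw$dX
    }
    # shortcut
    if (caches[[sprintf("b%dproj", b)]]) {
      nm <- sprintf("b%ds", b)
      bw <- cbrBw(p, nm, dS, caches[[nm]], grads)
      grads <- bw$grads
      dShort <- bw$dX
    } else dShort <- dS
    dX <- dMain + dShort
  }
  list(params = p, loss = crossEntropy(fw$P, y), grads = grads,
       nCorrect = sum(max.col(fw$P) - 1L == y))
}

#' @describeIn predictProba inference-mode forward pass of the ResNet
#' @export
setMethod("predictProba", "ResNetwork", function(object, newdata) {
  X <- asBeatMatrix(newdata)
  if (ncol(X) != object@inputLength)
    stop("input length ", ncol(X), " does not match the network's ",
         object@inputLength, call. = FALSE)
  resnetForward(object@params, X, object@channels, object@kernelSizes,
                training = FALSE)$P
})

#' @describeIn trainModel train the ResNet
#' @export
setMethod("trainModel", "ResNetwork", function(object, dataset, config) {
  X <- asBeatMatrix(dataset)
  y <- if (is(dataset, "BeatDataset")) beatLabels(dataset)
       else stop("dataset must be a BeatDataset", call. = FALSE)
  if (any(y < 0) || any(y >= object@nClasses))
    stop("labels outside 0..", object@nClasses - 1L, call. = FALSE)
  res <- runTraining(
    object@params, X, y, config,
    stepFn = function(p, Xb, yb)
      resnetStep(p, Xb, yb, object@channels, object@kernelSizes),
    predictFn = function(p, Xb)
      resnetForward(p, Xb, object@channels, object@kernelSizes, FALSE)$P
  )
  object@params <- res$params
  object@history <- res$history
  object@trained <- TRUE
  object
})
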