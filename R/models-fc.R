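# The 5-layer fully connected reference classifier: an input
# batch-normalization stage, four rectified hidden layers of 256 units with
# dropout 0.30, and a 16-unit softmax output — five weighted layers.

initFcParams <- function(inputUnits, hiddenUnits, nHidden, nClasses, seed) {
  withSeed(deriveSeed(seed, 3), {
    p <- list(
      gamma = rep(1, inputUnits), beta = rep(0, inputUnits),
      runMean = rep(0, inputUnits), runVar = rep(1, inputUnits)
    )
    fanIn <- inputUnits
    for (l in seq_len(nHidden)) {
      p[[paste0("W", l)]] <- matrix(stats::rnorm(fanIn * hiddenUnits,
                                                 sd = sqrt(2 / fanIn)),
                                    fanIn, hiddenUnits)
      p[[paste0("b", l)]] <- rep(0, hiddenUnits)
      fanIn <- hiddenUnits
    }
    lout <- nHidden + 1L
    p[[paste0("W", lout)]] <- matrix(stats::rnorm(fanIn * nClasses,
                                                  sd = sqrt(1 / fanIn)),
                                     fanIn, nClasses)
    p[[paste0("b", lout)]] <- rep(0, nClasses)
    p
  })
}

#' Build the 5-layer fully connected classifier
#'
#' Input units equal the samples per beat (260 for the default window); four
#' hidden layers of `hiddenUnits` rectified units with dropout follow, then a
#' softmax output layer with one unit per class. The input is standardized in
#' batches by a batch-normalization stage (trainable scale/shift, running
#' statistics at inference). Weights use He initialization under the given
#' seed, so the built model is usable (and deterministic) before training.
#'
#' @param inputUnits Samples per beat; default 260.
#' @param nClasses Output units; default 16.
#' @param hiddenUnits Units per hidden layer; default 256.
#' @param nHidden Hidden layer count; default 4.
#' @param dropout Hidden-layer dropout probability; default 0.30.
#' @param seed Seed for weight initialization.
#' @return An untrained [FcNetwork-class].
#' @examples
#' net <- buildFcNetwork(inputUnits = 260)
#' layerCount(net)  # 5
#' @export
buildFcNetwork <- function(inputUnits = 260, nClasses = 16,
                           hiddenUnits = 256, nHidden = 4, dropout = 0.30,
                           seed = 1) {
  inputUnits <- as.integer(inputUnits)
  if (inputUnits < 1) stop("inputUnits must be >= 1", call. = FALSE)
  if (dropout < 0 || dropout >= 1)
    stop("dropout must be in [0, 1)", call. = FALSE)
  if (nHidden < 1 || hiddenUnits < 1 || nClasses < 2)
    stop("invalid network specification", call. = FALSE)
  params <- initFcParams(inputUnits, as.integer(hiddenUnits),
                         as.integer(nHidden), as.integer(nClasses), seed)
  new("FcNetwork", inputUnits = inputUnits,
      hiddenUnits = as.integer(hiddenUnits), nHidden = as.integer(nHidden),
      nClasses = as.integer(nClasses), dropout = dropout, params = params,
      history = data.frame(), trained = FALSE)
}

# Forward pass; training mode applies batch statistics + dropout (consuming
# RNG) and returns the caches needed for backprop.
fcForward <- function(p, X, nHidden, dropout, training) {
  eps <- 1e-5
  B <- nrow(X)
  if (training && B > 1) {
    mu <- colMeans(X)
    va <- colMeans(sweep(X, 2, mu)^2)
    p$runMean <- 0.9 * p$runMean + 0.1 * mu
    p$runVar <- 0.9 * p$runVar + 0.1 * va
  } else {
    mu <- p$runMean
    va <- p$runVar
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(X, 2, mu), 2, istd, "*")
  A <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  acts <- vector("list", nHidden)
  masks <- vector("list", nHidden)
  for (l in seq_len(nHidden)) {
    Z <- sweep(A %*% p[[paste0("W", l)]], 2, p[[paste0("b", l)]], "+")
    R <- Z * (Z > 0)
    if (training && dropout > 0) {
      mask <- matrix(stats::runif(length(R)) >= dropout, nrow(R)) / (1 - dropout)
      R <- R * mask
      masks[[l]] <- mask
    }
    acts[[l]] <- list(A = A, Z = Z)
    A <- R
  }
  lout <- nHidden + 1L
  logits <- sweep(A %*% p[[paste0("W", lout)]], 2, p[[paste0("b", lout)]], "+")
  list(p = p, P = softmaxRows(logits), Afinal = A, acts = acts,
       masks = masks, xhat = xhat, istd = istd)
}

fcStep <- function(p, X, y, nHidden, dropout) {
  fw <- fcForward(p, X, nHidden, dropout, training = TRUE)
  p <- fw$p
  B <- nrow(X)
  Y <- matrix(0, B, ncol(fw$P))
  Y[cbind(seq_len(B), y + 1L)] <- 1
  dLogits <- (fw$P - Y) / B
  grads <- list()
  lout <- nHidden + 1L
  grads[[paste0("W", lout)]] <- t(fw$Afinal) %*% dLogits
  grads[[paste0("b", lout)]] <- colSums(dLogits)
  dA <- dLogits %*% t(p[[paste0("W", lout)]])
  for (l in rev(seq_len(nHidden))) {
    if (!is.null(fw$masks[[l]])) dA <- dA * fw$masks[[l]]
    dZ <- dA * (fw$acts[[l]]$Z > 0)
    grads[[paste0("W", l)]] <- t(fw$acts[[l]]$A) %*% dZ
    grads[[paste0("b", l)]] <- colSums(dZ)
    dA <- dZ %*% t(p[[paste0("W", l)]])
  }
  # input batch-norm scale/shift gradients (dX is not needed)
  grads$gamma <- colSums(dA * fw$xhat)
  grads$beta <- colSums(dA)
  list(params = p, loss = crossEntropy(fw$P, y), grads = grads,
       nCorrect = sum(max.col(fw$P) - 1L == y))
}

#' @describeIn layerCount hidden layers + output layer (the input
#'   normalization stage carries no dense weights)
#' @export
setMethod("layerCount", "FcNetwork", function(object)
  object@nHidden + 1L)

#' Dense parameter count of a model
#'
#' Total number of weight-matrix and bias entries across the fully connected
#' layers (the input normalization stage's scale/shift are excluded). For the
#' default 260-input network this is
#' `(260*256 + 256) + 3*(256*256 + 256) + (256*16 + 16)`.
#'
#' @param model An [FcNetwork-class].
#' @return Integer parameter count.
#' @export
parameterCount <- function(model) {
  stopifnot(is(model, "FcNetwork"))
  nms <- grep("^[Wb][0-9]+$", names(model@params), value = TRUE)
  sum(vapply(model@params[nms], length, 0L))
}

#' @describeIn predictProba inference-mode forward pass of the FC network
#' @export
setMethod("predictProba", "FcNetwork", function(object, newdata) {
  X <- asBeatMatrix(newdata)
  if (ncol(X) != object@inputUnits)
    stop("input length ", ncol(X), " does not match the network's ",
         object@inputUnits, " input units", call. = FALSE)
  fw <- fcForward(object@params, X, object@nHidden, object@dropout,
                  training = FALSE)
  fw$P
})

#' @describeIn trainModel train the FC network
#' @export
setMethod("trainModel", "FcNetwork", function(object, dataset, config) {
  X <- asBeatMatrix(dataset)
  y <- if (is(dataset, "BeatDataset")) beatLabels(dataset)
       else stop("dataset must be a BeatDataset", call. = FALSE)
  if (any(y < 0) || any(y >= object@nClasses))
    stop("labels outside 0..", object@nClasses - 1L, call. = FALSE)
  res <- runTraining(
    object@params, X, y, config,
    stepFn = function(p, Xb, yb)
      fcStep(p, Xb, yb, object@nHidden, object@dropout),
    predictFn = function(p, Xb)
      fcForward(p, Xb, object@nHidden, object@dropout, FALSE)$P
  )
  object@params <- res$params
  object@history <- res$history
  object@trained <- TRUE
  object
})

#' @describeIn history FC training history
#' @export
setMethod("history", "FcNetwork", function(object) object@history)

#' @describeIn history ResNet training history
#' @export
setMethod("history", "ResNetwork", function(object) object@history)
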