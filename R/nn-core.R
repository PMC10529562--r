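# Shared neural-network machinery: numerically stable softmax, cross-entropy,
# the Adam optimizer, and the seeded minibatch training loop used by both
# reference classifiers. Parameters live in flat named lists of numeric
# arrays; buffer entries (running batch-norm statistics, names starting with
# "run") are updated in the forward pass and skipped by the optimizer.

softmaxRows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

crossEntropy <- function(P, y) {
  -mean(log(pmax(P[cbind(seq_len(nrow(P)), y + 1L)], 1e-12)))
}

adamInit <- function(params, trainable) {
  m <- lapply(params[trainable], function(x) x * 0)
  list(m = m, v = m, t = 0L)
}

adamStep <- function(params, grads, state, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(state$m)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Minibatch loop shared by both models. stepFn(params, X, y) must return
# list(params, loss, grads, nCorrect); predictFn(params, X) a probability
# matrix. Everything random (shuffling, dropout inside stepFn) runs under a
# stream derived from config@seed.
runTraining <- function(params, X, y, config, stepFn, predictFn) {
  stopifnot(is(config, "TrainConfig"))
  m <- nrow(X)
  batch <- min(config@batchSize, m)
  trainable <- names(params)[!startsWith(names(params), "run")]
  state <- adamInit(params, trainable)
  histRows <- list()
  withSeed(deriveSeed(config@seed, 7), {
    valIdx <- integer(0)
    if (config@validationFraction > 0) {
      nVal <- max(1L, floor(config@validationFraction * m))
      valIdx <- sample(m, nVal)
    }
    trIdx <- setdiff(seq_len(m), valIdx)
    for (epoch in seq_len(config@maxEpochs)) {
      ord <- sample(trIdx)
      losses <- numeric(0)
      correct <- 0L
      for (start in seq(1, length(ord), by = batch)) {
        sel <- ord[start:min(start + batch - 1L, length(ord))]
        st <- stepFn(params, X[sel, , drop = FALSE], y[sel])
        if (!is.finite(st$loss))
          stop("training diverged: non-finite loss at epoch ", epoch,
               call. = FALSE)
        params <- st$params
        up <- adamStep(params, st$grads, state, config@learningRate)
        params <- up$params
        state <- up$state
        losses <- c(losses, st$loss)
        correct <- correct + st$nCorrect
      }
      row <- data.frame(epoch = epoch, loss = mean(losses),
                        accuracy = correct / length(ord))
      if (length(valIdx)) {
        Pv <- predictFn(params, X[valIdx, , drop = FALSE])
        row$val_loss <- crossEntropy(Pv, y[valIdx])
        row$val_accuracy <- mean(max.col(Pv) - 1L == y[valIdx])
      }
      histRows[[epoch]] <- row
    }
  })
  list(params = params, history = do.call(rbind, histRows))
}

asBeatMatrix <- function(newdata) {
  if (is(newdata, "BeatDataset")) beatMatrix(newdata)
  else if (is.vector(newdata)) matrix(newdata, nrow = 1)
  else as.matrix(newdata)
}
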