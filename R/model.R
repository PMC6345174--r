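#' Configure the encoder-decoder model
#'
#' The generator is a feedforward record encoder (sparse visit vector to a
#' dense state of the decoder's dimensionality, pretrained as one half of an
#' autoencoder), a word-embedding matrix trained from scratch with the
#' padding row frozen at zero, a single-layer LSTM whose initial hidden and
#' cell states are both set to the encoded record, and a softmax output
#' projection. Training minimises per-token cross-entropy of next-word
#' prediction under teacher forcing with Adam.
#'
#' @param recordDim dimension of the binary visit vector.
#' @param vocabSize vocabulary size (special tokens included).
#' @param hiddenDim LSTM cell size; also the encoded-record dimension.
#' @param wordEmbedDim word-embedding dimension.
#' @param learningRate Adam learning rate (default 0.001).
#' @param batchSize mini-batch size (default 512 pairs).
#' @param patience early stopping fires when validation loss fails to
#'   decrease for this many consecutive epochs (default 2).
#' @param maxEpochs hard epoch cap.
#' @param pretrainEpochs autoencoder pretraining epochs for the record
#'   encoder (0 disables pretraining).
#' @param seed master seed for initialisation and shuffling.
#' @return a `ModelConfig` list.
#' @export
modelConfig <- function(recordDim, vocabSize, hiddenDim = 32L,
                        wordEmbedDim = 16L, learningRate = 0.001,
                        batchSize = 512L, patience = 2L, maxEpochs = 30L,
                        pretrainEpochs = 15L, seed = 1L) {
  structure(list(recordDim = as.integer(recordDim),
                 vocabSize = as.integer(vocabSize),
                 hiddenDim = as.integer(hiddenDim),
                 wordEmbedDim = as.integer(wordEmbedDim),
                 learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 patience = as.integer(patience),
                 maxEpochs = as.integer(maxEpochs),
                 pretrainEpochs = as.integer(pretrainEpochs),
                 seed = as.integer(seed)),
            class = "ModelConfig")
}

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

initLSTMParams <- function(config) {
  H <- config$hiddenDim; D <- config$wordEmbedDim
  V <- config$vocabSize; Rd <- config$recordDim
  E <- matrix(stats::runif((V + 1L) * D, -0.05, 0.05), V + 1L, D)
  E[1L, ] <- 0                                   # padding row frozen
  b <- rep(0, 4L * H)
  b[(H + 1L):(2L * H)] <- 1                      # forget-gate bias
  list(Wenc = glorot(Rd, H), benc = rep(0, H),
       E = E, Wx = glorot(D, 4L * H), Wh = glorot(H, 4L * H), b = b,
       Wout = glorot(H, V), bout = rep(0, V))
}

# Adam optimiser over a named list of arrays
adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  params[["E"]][1L, ] <- 0                       # keep padding row at zero
  list(params = params, state = state)
}

#' Pretrain the record encoder as an autoencoder
#'
#' Trains `record -> tanh encoding -> sigmoid reconstruction` with
#' elementwise binary cross-entropy and keeps the encoder half as the
#' initial record-encoder weights of the full model.
#'
#' @param records binary record matrix (rows = visits) or a
#'   [PairedCorpus-class].
#' @param config a [modelConfig()]; `hiddenDim` sets the bottleneck width.
#' @param epochs training epochs (defaults to `config$pretrainEpochs`).
#' @param batchSize autoencoder mini-batch size.
#' @return list with `Wenc`, `benc`, the decoder half (`Wdec`, `bdec`) and
#'   the final mean reconstruction cross-entropy `reconError`.
#' @export
pretrainRecordEncoder <- function(records, config, epochs = NULL,
                                  batchSize = 4096L) {
  if (is(records, "PairedCorpus")) records <- recordMatrix(records)
  n <- nrow(records)
  if (n == 0L) stopf("no records to pretrain on")
  Rd <- ncol(records); H <- config$hiddenDim
  if (H >= Rd) warnf("hidden dimension %d >= record dimension %d: no compression", H, Rd)
  epochs <- epochs %||% config$pretrainEpochs
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(deriveSeed(config$seed, "autoencoder"))

  params <- list(W1 = glorot(Rd, H), b1 = rep(0, H),
                 W2 = glorot(H, Rd), b2 = rep(0, Rd))
  opt <- adamInit(params)
  lastErr <- NA_real_
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    errSum <- 0; nSeen <- 0
    for (start in seq(1L, n, by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1L, n)]
      X <- as.matrix(records[idx, , drop = FALSE])
      enc <- tanh(sweep(X %*% params$W1, 2L, params$b1, `+`))
      z <- sweep(enc %*% params$W2, 2L, params$b2, `+`)
      p <- 1 / (1 + exp(-z))
      eps <- 1e-12
      errSum <- errSum - sum(X * log(p + eps) + (1 - X) * log(1 - p + eps))
      nSeen <- nSeen + length(X)
      dz <- (p - X) / length(X)
      gW2 <- crossprod(enc, dz); gb2 <- colSums(dz)
      denc <- dz %*% t(params$W2) * (1 - enc^2)
      gW1 <- crossprod(X, denc); gb1 <- colSums(denc)
      upd <- adamStepPlain(params, list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2),
                           opt, lr = 0.005)
      params <- upd$params; opt <- upd$state
    }
    lastErr <- errSum / nSeen
  }
  list(Wenc = params$W1, benc = params$b1, Wdec = params$W2,
       bdec = params$b2, reconError = lastErr)
}

# Adam without the embedding-row pinning (for plain feedforward nets)
adamStepPlain <- function(params, grads, state, lr, beta1 = 0.9,
                          beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# teacher-forcing tensors: decoder input [SOS content] and target
# [content EOS], both width maxWords + 1
corpusTensors <- function(corpus) {
  s <- corpus@sequences
  w <- ncol(s)
  list(input = s[, -w, drop = FALSE], target = s[, -1L, drop = FALSE])
}

lstmGrad <- function(params, Rmat, input, target, wantGrad = TRUE) {
  out <- lstm_grad_cpp(params$E, params$Wenc, params$benc, params$Wx,
                       params$Wh, params$b, params$Wout, params$bout,
                       Rmat, input, target, wantGrad)
  if (wantGrad)
    out$grads <- list(Wenc = out$gWenc, benc = as.numeric(out$gbenc),
                      E = out$gE, Wx = out$gWx, Wh = out$gWh,
                      b = as.numeric(out$gb), Wout = out$gWout,
                      bout = as.numeric(out$gbout))
  out
}

batchedLoss <- function(params, corpus, batchSize = 4096L) {
  tensors <- corpusTensors(corpus)
  n <- length(corpus)
  lossSum <- 0; tokSum <- 0
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    out <- lstmGrad(params,
                    as.matrix(corpus@records[idx, , drop = FALSE]),
                    tensors$input[idx, , drop = FALSE],
                    tensors$target[idx, , drop = FALSE], wantGrad = FALSE)
    lossSum <- lossSum + out$loss * out$ntok
    tokSum <- tokSum + out$ntok
  }
  lossSum / tokSum
}

# early-stopping decision: position of the best epoch and the epoch after
# which training stops ("fails to decrease" = not strictly below the best
# so far, for `patience` consecutive epochs)
patienceStop <- function(valLosses, patience) {
  best <- Inf; bestEpoch <- 0L; streak <- 0L
  for (ep in seq_along(valLosses)) {
    if (valLosses[ep] < best) {
      best <- valLosses[ep]; bestEpoch <- ep; streak <- 0L
    } else {
      streak <- streak + 1L
      if (streak >= patience) return(list(stopAfter = ep, best = bestEpoch))
    }
  }
  list(stopAfter = length(valLosses), best = bestEpoch)
}

#' Train the chief-complaint generator
#'
#' End-to-end teacher-forced training of the record-conditioned LSTM with
#' Adam, preceded by autoencoder pretraining of the record encoder. Stops
#' when validation loss fails to decrease for `config$patience` consecutive
#' epochs (or at `config$maxEpochs`) and restores the weights of the best
#' validation epoch.
#'
#' @param train,validation [PairedCorpus-class] training and validation
#'   splits (see [splitCorpus()]).
#' @param config a [modelConfig()].
#' @param verbose print per-epoch losses.
#' @return a [CCModel-class].
#' @export
trainModel <- function(train, validation, config, verbose = FALSE) {
  n <- length(train)
  if (n == 0L) stopf("empty training corpus")
  batchSize <- config$batchSize
  if (batchSize > n) {
    warnf("batch size %d exceeds corpus size %d; clamping", batchSize, n)
    batchSize <- n
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  params <- initLSTMParams(config)
  if (config$pretrainEpochs > 0L) {
    pre <- pretrainRecordEncoder(recordMatrix(train), config)
    params$Wenc <- pre$Wenc
    params$benc <- pre$benc
  }
  opt <- adamInit(params)
  tensors <- corpusTensors(train)

  log <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                    validationLoss = numeric(0))
  bestParams <- params; bestLoss <- Inf; streak <- 0L
  for (ep in seq_len(config$maxEpochs)) {
    ord <- sample.int(n)
    lossSum <- 0; tokSum <- 0
    for (start in seq(1L, n, by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1L, n)]
      out <- lstmGrad(params,
                      as.matrix(train@records[idx, , drop = FALSE]),
                      tensors$input[idx, , drop = FALSE],
                      tensors$target[idx, , drop = FALSE])
      upd <- adamStep(params, out$grads, opt, lr = config$learningRate)
      params <- upd$params; opt <- upd$state
      lossSum <- lossSum + out$loss * out$ntok
      tokSum <- tokSum + out$ntok
    }
    valLoss <- batchedLoss(params, validation)
    log <- rbind(log, data.frame(epoch = ep, trainLoss = lossSum / tokSum,
                                 validationLoss = valLoss))
    if (verbose)
      message(sprintf("epoch %d: train %.4f validation %.4f", ep,
                      lossSum / tokSum, valLoss))
    if (valLoss < bestLoss) {
      bestLoss <- valLoss; bestParams <- params; streak <- 0L
    } else {
      streak <- streak + 1L
      if (streak >= config$patience) break
    }
  }
  config$maxWords <- train@maxWords
  config <- unclass(config)
  new("CCModel", params = bestParams, config = config,
      schema = train@schema, vocabulary = train@vocabulary, log = log)
}

#' Next-word probabilities for a record and a prefix
#'
#' Runs the record through the encoder and the prefix through the decoder
#' and returns the model's distribution over the next token. The padding
#' index carries no output unit, so it receives zero mass by construction.
#'
#' @param model a [CCModel-class].
#' @param record a binary visit vector (length `totalDim(schema)`).
#' @param prefix integer vector of vocabulary indices beginning with the
#'   start token (index 1).
#' @return named numeric vector over the vocabulary, summing to 1.
#' @export
stepProbabilities <- function(model, record, prefix) {
  if (length(prefix) == 0L || prefix[1L] != 1L)
    stopf("prefix must begin with the start token (index 1)")
  maxLen <- (model@config$maxWords %||% 18L) + 1L
  if (length(prefix) > maxLen)
    stopf("prefix longer than the maximum sequence length")
  p <- model@params
  enc <- tanh(matrix(record, 1L) %*% p$Wenc + matrix(p$benc, 1L))
  h <- enc; c <- enc
  for (tok in prefix) {
    st <- lstm_step_cpp(p$E, p$Wx, p$Wh, p$b, p$Wout, p$bout,
                        as.integer(tok), h, c)
    h <- st$h; c <- st$c
    logits <- st$logits
  }
  z <- logits[1L, ] - max(logits[1L, ])
  probs <- exp(z) / sum(exp(z))
  names(probs) <- model@vocabulary@tokens
  probs
}

#' Save and load a trained model
#'
#' The checkpoint is a single R serialization holding the weights together
#' with the configuration, schema and vocabulary, so a run can be
#' reconstructed from the artifact alone.
#'
#' @param model a [CCModel-class] (or [CCClassifier-class]).
#' @param path checkpoint file.
#' @return `loadModel` returns the restored object.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  validObject(obj)
  obj
}
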