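#' Two-by-two word-by-stratum contingency table
#'
#' Counts of records whose complaint contains a word, in an exposed and an
#' unexposed stratum of a discrete variable. A record counts once however
#' often the word occurs in its complaint.
#'
#' @param exposedWith,exposedTotal,unexposedWith,unexposedTotal
#'   non-negative counts, `with <= total` per stratum.
#' @return a `ContingencyTable` list.
#' @export
contingencyTable <- function(exposedWith, exposedTotal, unexposedWith,
                             unexposedTotal) {
  v <- c(exposedWith, exposedTotal, unexposedWith, unexposedTotal)
  if (any(v < 0)) stopf("counts must be non-negative")
  if (exposedWith > exposedTotal || unexposedWith > unexposedTotal)
    stopf("'with' count exceeds stratum total")
  structure(list(exposedWith = exposedWith, exposedTotal = exposedTotal,
                 unexposedWith = unexposedWith,
                 unexposedTotal = unexposedTotal),
            class = "ContingencyTable")
}

#' Tabulate word occurrence against a discrete variable
#'
#' @param records a record frame (with a `complaint` column) or a
#'   [PairedCorpus-class].
#' @param word the token to count (whole-token match after tokenization).
#' @param variable schema variable name.
#' @param stratumA,stratumB the exposed and unexposed codes.
#' @param texts optional character vector overriding the complaint text
#'   (e.g. synthetic complaints generated from the same records).
#' @param schema required when `records` is a record frame.
#' @return a [contingencyTable()].
#' @export
wordVariableTable <- function(records, word, variable, stratumA, stratumB,
                              texts = NULL, schema = NULL) {
  if (is(records, "PairedCorpus")) {
    schema <- records@schema
    texts <- texts %||% rawText(records)
    v <- schema@variables
    if (!variable %in% v$name) stopf("unknown variable '%s'", variable)
    off <- blockOffsets(schema)[variable]
    card <- v$cardinality[v$name == variable]
    for (code in c(stratumA, stratumB))
      if (code < 0L || code >= card)
        stopf("stratum code %d out of range for '%s'", code, variable)
    inA <- as.vector(records@records[, off + stratumA + 1L]) != 0
    inB <- as.vector(records@records[, off + stratumB + 1L]) != 0
  } else {
    if (is.null(schema)) stopf("schema required for record-frame input")
    texts <- texts %||% records$complaint
    inA <- recordInStratum(records, schema, variable, stratumA)
    inB <- recordInStratum(records, schema, variable, stratumB)
  }
  if (length(texts) != length(inA))
    stopf("texts (%d) and records (%d) differ in length",
          length(texts), length(inA))
  has <- vapply(tokenizeText(texts), function(tt) word %in% tt, logical(1))
  contingencyTable(sum(has & inA), sum(inA), sum(has & inB), sum(inB))
}

#' Risk and odds ratios from a 2x2 table
#'
#' `riskRatio = (a / t1) / (b / t2)` and
#' `oddsRatio = (a / (t1 - a)) / (b / (t2 - b))` for exposed counts
#' `a / t1` and unexposed counts `b / t2`. A zero cell in the unexposed
#' stratum (or a saturated exposed stratum) makes the corresponding ratio
#' infinite; the result carries explicit infinity flags rather than a
#' silent continuity correction. Setting `haldane` adds 0.5 to every cell
#' first (the Haldane-Anscombe correction used for interval work).
#'
#' @param table a [contingencyTable()].
#' @param haldane apply the +0.5 correction.
#' @return a `RatioResult` list with `riskRatio`, `oddsRatio`,
#'   `riskInfinite`, `oddsInfinite`.
#' @examples
#' ratios(contingencyTable(207, 2234, 48, 4009))
#' @export
ratios <- function(table, haldane = FALSE) {
  stopifnot(inherits(table, "ContingencyTable"))
  a <- table$exposedWith; t1 <- table$exposedTotal
  b <- table$unexposedWith; t2 <- table$unexposedTotal
  if (t1 == 0 || t2 == 0) stopf("stratum total of 0")
  if (haldane) {
    a <- a + 0.5; b <- b + 0.5; t1 <- t1 + 1; t2 <- t2 + 1
  }
  riskInf <- b == 0
  rr <- if (riskInf) Inf else (a / t1) / (b / t2)
  oddsInf <- b == 0 || t1 - a == 0
  or <- if (t2 - b == 0 && !oddsInf) 0 else
    if (oddsInf) Inf else (a / (t1 - a)) / (b / (t2 - b))
  structure(list(riskRatio = rr, oddsRatio = or,
                 riskInfinite = riskInf, oddsInfinite = oddsInf),
            class = "RatioResult")
}

#' Configure the GRU diagnosis classifier
#'
#' @param vocabSize vocabulary size.
#' @param nClasses number of diagnosis codes.
#' @param hiddenDim GRU hidden size.
#' @param wordEmbedDim embedding dimension.
#' @param learningRate,batchSize,patience,maxEpochs,seed as in
#'   [modelConfig()].
#' @param validationFrac internal validation share for early stopping.
#' @return a `ClassifierConfig` list.
#' @export
classifierConfig <- function(vocabSize, nClasses, hiddenDim = 32L,
                             wordEmbedDim = 16L, learningRate = 0.001,
                             batchSize = 256L, patience = 2L,
                             maxEpochs = 30L, validationFrac = 0.15,
                             seed = 1L) {
  structure(list(vocabSize = as.integer(vocabSize),
                 nClasses = as.integer(nClasses),
                 hiddenDim = as.integer(hiddenDim),
                 wordEmbedDim = as.integer(wordEmbedDim),
                 learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 patience = as.integer(patience),
                 maxEpochs = as.integer(maxEpochs),
                 validationFrac = validationFrac,
                 seed = as.integer(seed)),
            class = "ClassifierConfig")
}

# content-token matrix (no specials) + last position, from corpus sequences
# or raw text
classifierInputs <- function(sentences, vocabulary, maxWords = 18L) {
  seqs <- encodeText(sentences, vocabulary, maxWords, skipUnknown = TRUE)
  content <- seqs[, -1L, drop = FALSE]           # drop <s>
  content[content == 2L] <- 0L                   # drop </s>
  lastPos <- pmax(1L, rowSums(content > 0L))
  list(input = content, lastPos = as.integer(lastPos))
}

# primary diagnosis per corpus row: lowest-index set bit of the diagnosis
# block (the bit encoding is unordered, so "first listed" is not
# recoverable from a vectorized record; pass labels explicitly when the
# record frame is available)
primaryDiagnosis <- function(corpus) {
  off <- blockOffsets(corpus@schema)["diagnosis"]
  card <- corpus@schema@variables$cardinality[
    corpus@schema@variables$name == "diagnosis"]
  block <- corpus@records[, (off + 1L):(off + card), drop = FALSE]
  idx <- apply(as.matrix(block) != 0, 1L, function(r)
    if (any(r)) which(r)[1L] - 1L else NA_integer_)
  as.integer(idx)
}

#' Train the GRU chief-complaint classifier
#'
#' Word embedding + single gated-recurrent-unit layer + softmax over
#' diagnosis codes, trained with cross-entropy and Adam, early-stopped on
#' an internal validation split exactly like the generator.
#'
#' @param corpus a [PairedCorpus-class].
#' @param config a [classifierConfig()]; defaults are derived from the
#'   corpus when `NULL`.
#' @param labels integer diagnosis codes, one per pair (`NA` rows are
#'   dropped); when `NULL`, the lowest-index set diagnosis bit is used.
#' @param verbose print per-epoch losses.
#' @return a [CCClassifier-class].
#' @export
trainCCClassifier <- function(corpus, config = NULL, labels = NULL,
                              verbose = FALSE) {
  labels <- labels %||% primaryDiagnosis(corpus)
  keep <- which(!is.na(labels))
  if (!length(keep)) stopf("no labelled records")
  labels <- as.integer(labels[keep])
  texts <- rawText(corpus)[keep]
  vocab <- corpus@vocabulary
  card <- corpus@schema@variables$cardinality[
    corpus@schema@variables$name == "diagnosis"]
  if (length(unique(labels)) < 2L) stopf("single-class corpus")
  config <- config %||% classifierConfig(vocabSize = vocabSize(vocab),
                                         nClasses = card)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  inputs <- classifierInputs(texts, vocab, corpus@maxWords)
  n <- length(labels)
  nVal <- max(1L, round(n * config$validationFrac))
  perm <- sample.int(n)
  valIdx <- perm[seq_len(nVal)]
  trIdx <- perm[-seq_len(nVal)]

  H <- config$hiddenDim; D <- config$wordEmbedDim
  V <- config$vocabSize; C <- config$nClasses
  params <- list(E = matrix(stats::runif((V + 1L) * D, -0.05, 0.05), V + 1L, D),
                 Wx = glorot(D, 2L * H), Wh = glorot(H, 2L * H),
                 b = rep(0, 2L * H), Wxn = glorot(D, H), Whn = glorot(H, H),
                 bn = rep(0, H), Wout = glorot(H, C), bout = rep(0, C))
  params$E[1L, ] <- 0
  opt <- adamInit(params)
  batchSize <- min(config$batchSize, length(trIdx))

  gruLoss <- function(idx, wantGrad = TRUE) {
    gru_grad_cpp(params$E, params$Wx, params$Wh, params$b, params$Wxn,
                 params$Whn, params$bn, params$Wout, params$bout,
                 inputs$input[idx, , drop = FALSE], inputs$lastPos[idx],
                 labels[idx] + 1L, wantGrad)
  }

  log <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                    validationLoss = numeric(0))
  bestParams <- params; bestLoss <- Inf; streak <- 0L
  for (ep in seq_len(config$maxEpochs)) {
    ord <- sample(trIdx)
    lossSum <- 0; nSeen <- 0
    for (start in seq(1L, length(ord), by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1L, length(ord))]
      out <- gruLoss(idx)
      grads <- list(E = out$gE, Wx = out$gWx, Wh = out$gWh,
                    b = as.numeric(out$gb), Wxn = out$gWxn, Whn = out$gWhn,
                    bn = as.numeric(out$gbn), Wout = out$gWout,
                    bout = as.numeric(out$gbout))
      upd <- adamStep(params, grads, opt, lr = config$learningRate)
      params <- upd$params; opt <- upd$state
      lossSum <- lossSum + out$loss * length(idx)
      nSeen <- nSeen + length(idx)
    }
    valLoss <- gruLoss(valIdx, wantGrad = FALSE)$loss
    log <- rbind(log, data.frame(epoch = ep, trainLoss = lossSum / nSeen,
                                 validationLoss = valLoss))
    if (verbose)
      message(sprintf("classifier epoch %d: train %.4f validation %.4f",
                      ep, lossSum / nSeen, valLoss))
    if (valLoss < bestLoss) {
      bestLoss <- valLoss; bestParams <- params; streak <- 0L
    } else {
      streak <- streak + 1L
      if (streak >= config$patience) break
    }
  }
  config$maxWords <- corpus@maxWords
  config <- unclass(config)
  new("CCClassifier", params = bestParams, config = config,
      classes = seq_len(card) - 1L, vocabulary = vocab, log = log)
}

#' Predict diagnosis codes for complaint text
#'
#' @param classifier a [CCClassifier-class].
#' @param sentences character vector; out-of-vocabulary tokens are skipped.
#' @return integer vector of predicted codes.
#' @export
predictClassifier <- function(classifier, sentences) {
  p <- classifier@params
  inputs <- classifierInputs(sentences, classifier@vocabulary,
                             classifier@config$maxWords %||% 18L)
  probs <- gru_forward_cpp(p$E, p$Wx, p$Wh, p$b, p$Wxn, p$Whn, p$bn,
                           p$Wout, p$bout, inputs$input, inputs$lastPos)
  classifier@classes[max.col(probs, "first")]
}

#' Weighted-macro classifier scores
#'
#' Support-weighted one-vs-rest sensitivity, PPV and F1 from the multiclass
#' confusion matrix: each class's metric is weighted by its share of the
#' true labels, so classes absent from the truth contribute nothing. A
#' class that is never predicted has PPV 0 by convention.
#'
#' @param classifier a [CCClassifier-class], or `NULL` when `predicted` is
#'   given directly.
#' @param sentences complaint texts to classify (ignored when `predicted`
#'   is supplied).
#' @param trueCodes integer vector of true diagnosis codes.
#' @param predicted optional precomputed predictions.
#' @return a `ClassifierReport` list: `sens`, `ppv`, `f1`, `perClass`.
#' @export
scoreClassifier <- function(classifier, sentences, trueCodes,
                            predicted = NULL) {
  predicted <- predicted %||% predictClassifier(classifier, sentences)
  if (length(predicted) != length(trueCodes))
    stopf("predictions (%d) and truth (%d) differ in length",
          length(predicted), length(trueCodes))
  classes <- sort(unique(trueCodes))
  per <- lapply(classes, function(cl) {
    support <- sum(trueCodes == cl)
    tp <- sum(trueCodes == cl & predicted == cl)
    npred <- sum(predicted == cl)
    sens <- tp / support
    ppv <- if (npred == 0) 0 else tp / npred
    f1 <- if (sens + ppv == 0) 0 else 2 * sens * ppv / (sens + ppv)
    data.frame(class = cl, support = support, sens = sens, ppv = ppv,
               f1 = f1)
  })
  per <- do.call(rbind, per)
  w <- per$support / sum(per$support)
  structure(list(sens = sum(w * per$sens), ppv = sum(w * per$ppv),
                 f1 = sum(w * per$f1), perClass = per),
            class = "ClassifierReport")
}

#' Classifier scores on authentic vs generated complaints
#'
#' Scores the classifier on the authentic test complaints ("original" row)
#' and on synthetic complaints generated from the same records under each
#' sampling scheme, mirroring the comparison used to check that generated
#' text preserves the text-diagnosis relationship.
#'
#' @param model a [CCModel-class] generator.
#' @param classifier a [CCClassifier-class].
#' @param testCorpus a [PairedCorpus-class].
#' @param samplingConfigs named list of [samplingConfig()]s.
#' @param labels optional integer truth codes (default: lowest set
#'   diagnosis bit; rows without a diagnosis are dropped).
#' @return data.frame with one row per scheme plus the original row.
#' @export
validityComparison <- function(model, classifier, testCorpus,
                               samplingConfigs, labels = NULL) {
  labels <- labels %||% primaryDiagnosis(testCorpus)
  keep <- which(!is.na(labels))
  corpus <- testCorpus[keep]
  labels <- as.integer(labels[keep])
  rows <- list()
  orig <- scoreClassifier(classifier, rawText(corpus), labels)
  rows[["original"]] <- data.frame(scheme = "original", sens = orig$sens,
                                   ppv = orig$ppv, f1 = orig$f1)
  for (nm in names(samplingConfigs)) {
    synth <- generateCorpus(model, corpus, samplingConfigs[[nm]])
    sc <- scoreClassifier(classifier, synth, labels)
    rows[[nm]] <- data.frame(scheme = nm, sens = sc$sens, ppv = sc$ppv,
                             f1 = sc$f1)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
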