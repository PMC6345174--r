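# Shared fixtures, built once per test run. The benchmark pipeline
# (50k simulated pairs, one trained generator, one trained classifier)
# is expensive, so it is cached and shared across test files.

fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, build) {
  if (!exists(name, envir = fixtureCache))
    assign(name, build(), envir = fixtureCache)
  get(name, envir = fixtureCache)
}

benchmarkSim <- function() cachedFixture("sim", function() {
  cfg <- simulationConfig(seed = 11L)
  out <- generatePairs(cfg)
  out$config <- cfg
  out
})

benchmarkCorpus <- function() cachedFixture("corpus", function() {
  sim <- benchmarkSim()
  prep <- preprocessText(sim$records, sim$config$schema)
  parts <- splitCorpus(prep$corpus, seed = 101L)
  list(prep = prep, parts = parts)
})

benchmarkModel <- function() cachedFixture("model", function() {
  bc <- benchmarkCorpus()
  config <- modelConfig(recordDim = totalDim(simSchema()),
                        vocabSize = vocabSize(bc$prep$vocabulary),
                        seed = 5L)
  suppressWarnings(trainModel(bc$parts$train, bc$parts$validation, config))
})

benchmarkSynthetic <- function() cachedFixture("synthetic", function() {
  generateCorpus(benchmarkModel(), benchmarkCorpus()$parts$validation,
                 samplingConfig("greedy"))
})

benchmarkClassifier <- function() cachedFixture("classifier", function() {
  bc <- benchmarkCorpus()
  cfg <- classifierConfig(vocabSize = vocabSize(bc$prep$vocabulary),
                          nClasses = 12L, seed = 21L)
  trainCCClassifier(bc$parts$train, cfg)
})

benchmarkEmbeddings <- function() cachedFixture("embeddings", function() {
  trainWordEmbeddings(rawText(benchmarkCorpus()$parts$train),
                      dimension = 50L, window = 5L, minCount = 5L,
                      epochs = 5L, seed = 2L)
})

# a tiny memorizable corpus: ten distinct records with distinct sentences
memorizableCorpus <- function() {
  sentences <- c("chest pain", "abd pain", "fall at home", "od by ems",
                 "preg spotting", "short of breath", "elevated bp",
                 "etoh today", "neck pain", "fever chills")
  fr <- data.frame(age_group = rep(0:4, 2), gender = rep(0:1, 5),
                   diagnosis = as.character(0:9), hospital = 0L,
                   complaint = sentences, stringsAsFactors = FALSE)
  preprocessText(fr, simSchema(), minFreq = 1L)$corpus
}

overfitModel <- function() cachedFixture("overfit", function() {
  corpus <- memorizableCorpus()
  cfg <- modelConfig(recordDim = totalDim(simSchema()),
                     vocabSize = vocabSize(corpusVocabulary(corpus)),
                     hiddenDim = 24L, wordEmbedDim = 12L,
                     learningRate = 0.02, batchSize = 10L,
                     patience = 1000L, maxEpochs = 500L,
                     pretrainEpochs = 0L, seed = 2L)
  suppressWarnings(trainModel(corpus, corpus, cfg))
})

# per-record membership in a stratum, from corpus record bits
corpusStratum <- function(corpus, variable, code) {
  off <- synthcc:::blockOffsets(corpusSchema(corpus))[variable]
  as.vector(recordMatrix(corpus)[, off + code + 1L]) != 0
}

# ---- hand-built Markov model -------------------------------------------
# LSTM weights constructed so that next-token probabilities equal the rows
# of a known transition matrix P (indexed over vocabulary indices; row 1 =
# after the start token), independent of the record. Gate biases force
# input/output gates to ~1 and the forget gate to ~0, so the hidden state
# is an injective image of the previous token's one-hot embedding.
markovModel <- function(P, recordDim = 3L) {
  V <- nrow(P)
  stopifnot(ncol(P) == V, V >= 3L)
  toks <- c(sosToken(), eosToken(), paste0("w", seq_len(V - 2L)))
  vocab <- new("Vocabulary", tokens = toks,
               frequencies = c(NA, NA, rep(10L, V - 2L)), minFreq = 1L)
  H <- V; D <- V
  a <- tanh(tanh(2))
  E <- matrix(0, V + 1L, D)
  for (i in seq_len(V)) E[i + 1L, i] <- 1
  Wx <- matrix(0, D, 4L * H)
  Wx[, 3L * H + seq_len(H)] <- 2 * diag(V)
  b <- c(rep(30, H), rep(-30, H), rep(30, H), rep(0, H))
  logP <- log(P)
  logP[is.infinite(logP)] <- -1e4
  params <- list(Wenc = matrix(0, recordDim, H), benc = rep(0, H), E = E,
                 Wx = Wx, Wh = matrix(0, H, 4L * H), b = b,
                 Wout = logP / a, bout = rep(0, V))
  schema <- buildSchema("x", recordDim)
  cfg <- list(recordDim = recordDim, vocabSize = V, hiddenDim = H,
              wordEmbedDim = D, maxWords = 18L)
  new("CCModel", params = params, config = cfg, schema = schema,
      vocabulary = vocab, log = data.frame())
}

randomToyModel <- function(recordDim = 6L, V = 12L, H = 8L, D = 5L,
                           seed = 1L) {
  toks <- c(sosToken(), eosToken(), paste0("w", seq_len(V - 2L)))
  vocab <- new("Vocabulary", tokens = toks,
               frequencies = c(NA, NA, rep(10L, V - 2L)), minFreq = 1L)
  cfg <- modelConfig(recordDim = recordDim, vocabSize = V, hiddenDim = H,
                     wordEmbedDim = D, seed = seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  params <- synthcc:::initLSTMParams(cfg)
  # non-degenerate random transitions
  params$Wout <- matrix(rnorm(H * V), H, V)
  params$Wx <- matrix(rnorm(D * 4L * H) * 0.5, D, 4L * H)
  cfg$maxWords <- 18L
  new("CCModel", params = params, config = unclass(cfg), schema = buildSchema("x", recordDim),
      vocabulary = vocab, log = data.frame())
}

# exhaustive search for the most probable sequence under a transition
# matrix P (the independent oracle for beam search): sequences over the
# non-end tokens, ended by the end token or truncated at maxLen
enumerateBest <- function(P, maxLen) {
  V <- nrow(P)
  alphabet <- setdiff(seq_len(V), 2L)
  best <- list(seq = integer(0), lp = -Inf)
  recurse <- function(prefix, lp, prev) {
    lpEnd <- lp + log(P[prev, 2L])
    if (lpEnd > best$lp ||
        (lpEnd == best$lp && length(prefix) < length(best$seq))) {
      best$seq <<- prefix; best$lp <<- lpEnd
    }
    if (length(prefix) == maxLen) {
      if (lp > best$lp) { best$seq <<- prefix; best$lp <<- lp }
      return(invisible())
    }
    for (tok in alphabet)
      if (P[prev, tok] > 0)
        recurse(c(prefix, tok), lp + log(P[prev, tok]), tok)
  }
  recurse(integer(0), 0, 1L)
  best
}

# independent brute-force n-gram counter (deliberately different
# representation from the package implementation)
naiveGramList <- function(tokens, maxOrder) {
  out <- character(0)
  L <- length(tokens)
  for (n in seq_len(maxOrder)) {
    if (L < n) break
    for (s in seq_len(L - n + 1L))
      out <- c(out, paste(tokens[s:(s + n - 1L)], collapse = "\r"))
  }
  out
}

naiveNgramScores <- function(ref, cand, maxOrder = 4L) {
  rg <- naiveGramList(strsplit(tolower(ref), " +")[[1L]], maxOrder)
  cg <- naiveGramList(strsplit(tolower(cand), " +")[[1L]], maxOrder)
  matched <- 0
  for (g in unique(cg)) matched <- matched + min(sum(rg == g), sum(cg == g))
  ppv <- if (length(cg)) matched / length(cg) else 0
  sens <- if (length(rg)) matched / length(rg) else 0
  f1 <- if (ppv + sens == 0) 0 else 2 * ppv * sens / (ppv + sens)
  c(ppv = ppv, sens = sens, f1 = f1)
}

# small record frame fixture over the simulator schema
tinyRecordFrame <- function() {
  data.frame(
    age_group = c(0L, 1L, 4L, 2L, 3L, 4L),
    gender = c(0L, 1L, 0L, 1L, 0L, 1L),
    diagnosis = c("0", "2;5", "4", NA, "7", "2"),
    hospital = c(0L, 1L, 0L, 1L, NA, 0L),
    complaint = c("chest pain", "fall at home", "preg with cramping",
                  "chest pain", "etoh", "fall at home"),
    stringsAsFactors = FALSE)
}
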