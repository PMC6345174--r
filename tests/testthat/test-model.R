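test_that("autoencoder pretraining reconstructs one-hot records", {
  set.seed(8)
  codes <- sample.int(10L, 500L, TRUE) - 1L
  X <- matrix(0, 500, 10)
  X[cbind(1:500, codes + 1L)] <- 1
  cfg <- modelConfig(recordDim = 10L, vocabSize = 5L, hiddenDim = 8L,
                     seed = 3L)
  pre <- pretrainRecordEncoder(X, cfg, epochs = 300L, batchSize = 500L)
  enc <- tanh(sweep(X %*% pre$Wenc, 2, pre$benc, `+`))
  recon <- sweep(enc %*% pre$Wdec, 2, pre$bdec, `+`)
  expect_gte(mean(max.col(recon) == codes + 1L), 0.95)
  expect_lt(pre$reconError, 0.1)
  # encoder output dimensionality and the all-zero record edge case
  expect_equal(ncol(enc), 8L)
  z <- tanh(matrix(pre$benc, 1))
  expect_true(all(is.finite(z)))
})

test_that("early stopping follows the two-epoch patience rule", {
  s <- synthcc:::patienceStop(c(2.0, 1.5, 1.6, 1.7), patience = 2L)
  expect_equal(s$stopAfter, 4L)
  expect_equal(s$best, 2L)
  s2 <- synthcc:::patienceStop(c(2.0, 1.9, 1.8), patience = 2L)
  expect_equal(s2$stopAfter, 3L)
  expect_equal(s2$best, 3L)
  # "fails to decrease" means not strictly lower than the best so far
  s3 <- synthcc:::patienceStop(c(1.0, 1.0, 1.0), patience = 2L)
  expect_equal(s3$stopAfter, 3L)
  expect_equal(s3$best, 1L)
})

test_that("training beats the uniform-model cross-entropy bound", {
  model <- overfitModel()
  V <- vocabSize(corpusVocabulary(memorizableCorpus()))
  expect_lt(model@log$trainLoss[1], log(V) + 0.05)
  expect_lt(min(model@log$validationLoss), 0.05)
})

test_that("an overfit model memorizes its training sentences", {
  corpus <- memorizableCorpus()
  model <- overfitModel()
  out <- generateCorpus(model, corpus, samplingConfig("greedy"))
  expect_identical(out, rawText(corpus))
})

test_that("step probabilities normalize, are pure, and exclude padding", {
  model <- benchmarkModel()
  rec <- as.numeric(recordMatrix(benchmarkCorpus()$parts$validation)[1, ])
  p1 <- stepProbabilities(model, rec, prefix = 1L)
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_true(all(p1 >= 0))
  expect_equal(length(p1), vocabSize(corpusVocabulary(
    benchmarkCorpus()$parts$validation)))
  p2 <- stepProbabilities(model, rec, prefix = 1L)
  expect_identical(p1, p2)
  expect_error(stepProbabilities(model, rec, prefix = 3L), "start token")
  expect_error(stepProbabilities(model, rec, prefix = rep(1L, 40L)),
               "longer")
})

test_that("hand-built weights reproduce a known transition table", {
  P <- rbind(c(0, 0.1, 0.6, 0.2, 0.1),    # after <s>
             c(0, 1.0, 0,   0,   0),      # after </s> (never queried)
             c(0, 0.2, 0.1, 0.4, 0.3),    # after w1
             c(0, 0.7, 0.1, 0.1, 0.1),    # after w2
             c(0, 0.4, 0.3, 0.2, 0.1))    # after w3
  model <- markovModel(P)
  rec <- c(1, 0, 0)
  expect_equal(unname(stepProbabilities(model, rec, 1L)), P[1, ],
               tolerance = 1e-8)
  expect_equal(unname(stepProbabilities(model, rec, c(1L, 3L))), P[3, ],
               tolerance = 1e-8)
  expect_equal(unname(stepProbabilities(model, rec, c(1L, 3L, 5L))), P[5, ],
               tolerance = 1e-8)
})

test_that("checkpoints round-trip bit-for-bit", {
  model <- overfitModel()
  path <- file.path(tempdir(), "ckpt.rds")
  saveModel(model, path)
  back <- loadModel(path)
  expect_identical(back@params, model@params)
  rec <- as.numeric(recordMatrix(memorizableCorpus())[3, ])
  expect_identical(stepProbabilities(model, rec, c(1L, 3L)),
                   stepProbabilities(back, rec, c(1L, 3L)))
})

test_that("training under a fixed seed is reproducible", {
  corpus <- memorizableCorpus()
  cfg <- modelConfig(recordDim = totalDim(simSchema()),
                     vocabSize = vocabSize(corpusVocabulary(corpus)),
                     hiddenDim = 8L, wordEmbedDim = 6L, batchSize = 10L,
                     maxEpochs = 5L, pretrainEpochs = 2L, seed = 7L)
  m1 <- suppressWarnings(trainModel(corpus, corpus, cfg))
  m2 <- suppressWarnings(trainModel(corpus, corpus, cfg))
  expect_identical(m1@params, m2@params)
  expect_identical(m1@log, m2@log)
})

test_that("oversized batches are clamped with a warning", {
  corpus <- memorizableCorpus()
  cfg <- modelConfig(recordDim = totalDim(simSchema()),
                     vocabSize = vocabSize(corpusVocabulary(corpus)),
                     hiddenDim = 8L, wordEmbedDim = 6L, batchSize = 512L,
                     maxEpochs = 2L, pretrainEpochs = 0L, seed = 7L)
  expect_warning(trainModel(corpus, corpus, cfg), "clamp")
})

test_that("conditioning on the record moves token probabilities", {
  # for the benchmark model, the female-exclusive token is less probable
  # under every male record than its maximum under female records
  model <- benchmarkModel()
  val <- benchmarkCorpus()$parts$validation
  female <- which(corpusStratum(val, "gender", 0L))[1:40]
  male <- which(corpusStratum(val, "gender", 1L))[1:40]
  pPreg <- function(i) {
    rec <- as.numeric(recordMatrix(val)[i, ])
    stepProbabilities(model, rec, 1L)[["preg"]]
  }
  pf <- vapply(female, pPreg, 0)
  pm <- vapply(male, pPreg, 0)
  expect_lt(max(pm), max(pf))
})
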