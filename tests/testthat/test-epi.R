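test_that("word-variable tables count records, not token multiplicity", {
  fr <- data.frame(
    age_group = c(4L, 4L, 4L, 0L, 0L, 0L),
    gender = 0L, diagnosis = "2", hospital = 0L,
    complaint = c("fall fall at home", "no injury", "fall again",
                  "fall once", "nothing", "resting"),
    stringsAsFactors = FALSE)
  tab <- wordVariableTable(fr, "fall", "age_group", 4L, 0L,
                           schema = simSchema())
  expect_equal(tab$exposedWith, 2L)      # double "fall" counts once
  expect_equal(tab$exposedTotal, 3L)
  expect_equal(tab$unexposedWith, 1L)
  expect_equal(tab$unexposedTotal, 3L)
  expect_error(wordVariableTable(fr, "fall", "height", 4L, 0L,
                                 schema = simSchema()), "unknown variable")
  expect_error(wordVariableTable(fr, "fall", "age_group", 9L, 0L,
                                 schema = simSchema()), "out of range")
})

test_that("an empty corpus yields an all-zero table", {
  fr <- data.frame(age_group = integer(0), gender = integer(0),
                   diagnosis = character(0), hospital = integer(0),
                   complaint = character(0), stringsAsFactors = FALSE)
  tab <- wordVariableTable(fr, "fall", "age_group", 4L, 0L,
                           schema = simSchema())
  expect_equal(unlist(tab, use.names = FALSE), c(0L, 0L, 0L, 0L))
})

test_that("corpus tables agree with the simulator's planted truth", {
  sim <- benchmarkSim()
  as <- sim$truth$association
  tab <- wordVariableTable(sim$records, "fall", "age_group", 4L, 0L,
                           schema = simSchema())
  # exposure stratum matches the recount exactly
  expect_equal(tab$exposedWith, as$exposedWith)
  expect_equal(tab$exposedTotal, as$exposedTotal)
})

test_that("ratios reproduce the fall-by-age arithmetic", {
  r1 <- ratios(contingencyTable(207, 2234, 48, 4009))
  expect_equal(r1$riskRatio, (207 / 2234) / (48 / 4009))
  expect_equal(round(r1$riskRatio, 2), 7.74)
  expect_equal(round(r1$oddsRatio, 2), 8.43)
  r2 <- ratios(contingencyTable(229, 2234, 27, 4009))
  expect_equal(round(r2$riskRatio, 2), 15.22)
  # equal proportions give unit ratios
  r3 <- ratios(contingencyTable(10, 100, 30, 300))
  expect_equal(r3$riskRatio, 1)
  expect_equal(r3$oddsRatio, 1)
})

test_that("zero cells flag infinity; the Haldane switch removes it", {
  r <- ratios(contingencyTable(5, 10, 0, 20))
  expect_true(r$riskInfinite && r$oddsInfinite)
  expect_equal(r$riskRatio, Inf)
  rh <- ratios(contingencyTable(5, 10, 0, 20), haldane = TRUE)
  expect_true(is.finite(rh$oddsRatio))
  expect_error(ratios(contingencyTable(0, 0, 1, 10)), "total of 0")
  expect_error(contingencyTable(5, 3, 0, 1), "exceeds")
})

test_that("ratios agree with an independent 2x2 calculator", {
  set.seed(21)
  for (i in 1:1000) {
    t1 <- sample(2:200, 1); t2 <- sample(2:200, 1)
    a <- sample(1:(t1 - 1), 1); b <- sample(1:(t2 - 1), 1)
    r <- ratios(contingencyTable(a, t1, b, t2))
    expect_equal(r$riskRatio, (a * t2) / (b * t1), tolerance = 1e-12)
    expect_equal(r$oddsRatio, (a * (t2 - b)) / (b * (t1 - a)),
                 tolerance = 1e-12)
  }
})

test_that("weighted-macro scores match a hand-computed confusion matrix", {
  truth <- c(1, 1, 2, 2, 3, 3)
  pred <- c(1, 1, 1, 2, 3, 3)  # confusion [[2,0,0],[1,1,0],[0,0,2]]
  rep <- scoreClassifier(NULL, NULL, truth, predicted = pred)
  expect_equal(rep$sens, (2 / 6) * 1 + (2 / 6) * 0.5 + (2 / 6) * 1)
  expect_equal(rep$ppv, (2 / 6) * (2 / 3) + (2 / 6) * 1 + (2 / 6) * 1)
  perfect <- scoreClassifier(NULL, NULL, truth, predicted = truth)
  expect_equal(c(perfect$sens, perfect$ppv, perfect$f1), c(1, 1, 1))
  # degenerate all-one-class predictions: unpredicted classes get ppv 0
  onecl <- scoreClassifier(NULL, NULL, truth, predicted = rep(1, 6))
  expect_equal(onecl$perClass$ppv, c(1 / 3, 0, 0))
  expect_error(scoreClassifier(NULL, NULL, truth, predicted = pred[1:3]),
               "differ")
})

test_that("a separable corpus is classified nearly perfectly", {
  # each code has a disjoint template vocabulary
  words <- matrix(letters[1:24], 4, 6)
  set.seed(2)
  n <- 1200L
  code <- sample.int(6L, n, TRUE) - 1L
  complaint <- vapply(code + 1L, function(cl)
    paste(sample(words[, cl], 3), collapse = " "), "")
  fr <- data.frame(age_group = 0L, gender = 0L,
                   diagnosis = as.character(code), hospital = 0L,
                   complaint = complaint, stringsAsFactors = FALSE)
  sc <- buildSchema(c("age_group", "gender", "diagnosis", "hospital"),
                    c(5L, 2L, 6L, 2L),
                    multiValued = c(FALSE, FALSE, TRUE, FALSE))
  corpus <- preprocessText(fr, sc, minFreq = 1L)$corpus
  cfg <- classifierConfig(vocabSize = vocabSize(corpusVocabulary(corpus)),
                          nClasses = 6L, hiddenDim = 24L,
                          learningRate = 0.01, maxEpochs = 40L, seed = 4L)
  clf <- trainCCClassifier(corpus, cfg)
  rep <- scoreClassifier(clf, rawText(corpus),
                         synthcc:::primaryDiagnosis(corpus))
  expect_gte(rep$f1, 0.99)

  # determinism under a fixed seed
  clf2 <- trainCCClassifier(corpus, cfg)
  expect_identical(clf@params, clf2@params)

  # shuffled labels collapse to about the majority-class baseline
  set.seed(9)
  shuffled <- sample(code)
  cfgS <- classifierConfig(vocabSize = vocabSize(corpusVocabulary(corpus)),
                           nClasses = 6L, hiddenDim = 24L,
                           learningRate = 0.01, maxEpochs = 10L, seed = 4L)
  clfS <- trainCCClassifier(corpus, cfgS, labels = shuffled)
  repS <- scoreClassifier(clfS, rawText(corpus), shuffled)
  expect_lt(repS$f1, 0.45)
})

test_that("single-class corpora are rejected", {
  fr <- data.frame(age_group = 0L, gender = 0L, diagnosis = "3",
                   hospital = 0L,
                   complaint = rep(c("head ache", "arm pain"), 10),
                   stringsAsFactors = FALSE)
  corpus <- preprocessText(fr, simSchema(), minFreq = 1L)$corpus
  expect_error(trainCCClassifier(corpus), "single-class")
})

test_that("validity comparison has one row per scheme plus the original", {
  model <- benchmarkModel()
  clf <- benchmarkClassifier()
  test <- benchmarkCorpus()$parts$test[1:400]
  out <- validityComparison(model, clf, test,
                            list(greedy = samplingConfig("greedy"),
                                 prob1 = samplingConfig("probabilistic",
                                                        temperature = 1,
                                                        seed = 3L)))
  expect_equal(nrow(out), 3L)
  expect_equal(out$scheme[1], "original")
  expect_true(all(out$f1 >= 0 & out$f1 <= 1))
})

test_that("a memorizing generator makes synthetic rows equal the original", {
  # generator that reproduces its training sentences exactly
  corpus <- memorizableCorpus()
  model <- overfitModel()
  cfg <- classifierConfig(vocabSize = vocabSize(corpusVocabulary(corpus)),
                          nClasses = 12L, hiddenDim = 12L,
                          maxEpochs = 5L, seed = 3L)
  clf <- trainCCClassifier(corpus, cfg)
  out <- validityComparison(model, clf, corpus,
                            list(greedy = samplingConfig("greedy")))
  expect_equal(out$f1[out$scheme == "greedy"],
               out$f1[out$scheme == "original"])
})
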