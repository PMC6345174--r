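test_that("n-gram scores match hand-worked examples", {
  expect_equal(unname(ngramScores("chest pain", "chest pain")), c(1, 1, 1))
  # candidate n-grams: blood, pressure, "blood pressure" (3, all matched);
  # reference n-grams: 3 + 2 + 1 = 6, matched 3
  s <- ngramScores("high blood pressure", "blood pressure")
  expect_equal(unname(s), c(1, 0.5, 2 / 3))
  expect_equal(unname(ngramScores("head ache", "leg pain")), c(0, 0, 0))
  # clipped counting: repetition is not rewarded; candidate pools 6
  # n-grams (3 + 2 + 1) of which 2 unigrams and 1 bigram match
  s2 <- ngramScores("pain pain", "pain pain pain")
  expect_equal(s2[["ppv"]], 0.5)
})

test_that("clipped counts and symmetry hold", {
  # ppv(a, b) == sens(b, a) over random token pairs
  set.seed(12)
  alphabet <- letters[1:6]
  for (i in 1:50) {
    a <- paste(sample(alphabet, sample(1:8, 1), TRUE), collapse = " ")
    b <- paste(sample(alphabet, sample(1:8, 1), TRUE), collapse = " ")
    expect_equal(ngramScores(a, b)[["ppv"]], ngramScores(b, a)[["sens"]])
  }
})

test_that("empty candidates are flagged and scored 0", {
  s <- ngramScores("chest pain", "")
  expect_equal(as.vector(s), c(0, 0, 0))
  expect_true(isTRUE(attr(s, "undefined")))
})

test_that("corpus scores are unweighted means of per-pair scores", {
  refs <- c("chest pain", "head ache")
  cands <- c("chest pain", "stomach bug")
  out <- corpusNgramScores(refs, cands)
  expect_equal(out$ppv, 0.5)
  expect_equal(out$sens, 0.5)
  expect_equal(out$f1, 0.5)
  all1 <- corpusNgramScores(refs, refs)
  expect_equal(c(all1$ppv, all1$sens, all1$f1), c(1, 1, 1))
  expect_error(corpusNgramScores(refs, cands[1]), "differ")
})

test_that("corpus n-gram scores equal an independent brute-force counter", {
  set.seed(77)
  alphabet <- c("pain", "chest", "fall", "x", "days", "od", "bp", "left")
  refs <- character(1000); cands <- character(1000)
  for (i in 1:1000) {
    refs[i] <- paste(sample(alphabet, sample(1:9, 1), TRUE), collapse = " ")
    cands[i] <- paste(sample(alphabet, sample(1:9, 1), TRUE), collapse = " ")
  }
  mine <- corpusNgramScores(refs, cands)
  naive <- t(mapply(naiveNgramScores, refs, cands))
  expect_equal(mine$ppv, mean(naive[, "ppv"]), tolerance = 1e-12)
  expect_equal(mine$sens, mean(naive[, "sens"]), tolerance = 1e-12)
  expect_equal(mine$f1, mean(naive[, "f1"]), tolerance = 1e-12)
  expect_true(all(mine$perPair >= 0 & mine$perPair <= 1))
})

test_that("TF-IDF cosine score matches a hand computation", {
  refs <- c("a b", "a c", "d")
  cands <- c("a b", "b c", "d")
  # document frequencies over the references: a 2, all others 1;
  # pair 2: ref vector (a: ln 1.5, c: ln 3, "a c": ln 3),
  #         cand vector (b: ln 3, c: ln 3, "b c": ln 3); only c overlaps
  cos2 <- log(3)^2 /
    (sqrt(log(1.5)^2 + 2 * log(3)^2) * sqrt(3 * log(3)^2))
  expect_equal(ciderScore(refs, cands), mean(c(1, cos2, 1)),
               tolerance = 1e-12)
  # identical corpora score exactly 1
  expect_equal(ciderScore(refs, refs), 1)
  # zero overlap contributes 0
  expect_equal(ciderScore(c("a b", "c d"), c("x y", "c d")),
               mean(c(0, 1)), tolerance = 1e-12)
  expect_error(ciderScore("a", "a"), "at least 2")
})

test_that("all n-gram metrics live on the unit interval", {
  set.seed(3)
  refs <- replicate(60, paste(sample(letters[1:5], sample(1:6, 1), TRUE),
                              collapse = " "))
  cands <- replicate(60, paste(sample(letters[1:5], sample(1:6, 1), TRUE),
                               collapse = " "))
  out <- corpusNgramScores(refs, cands)
  cd <- ciderScore(refs, cands)
  expect_true(all(c(out$ppv, out$sens, out$f1, cd) >= 0))
  expect_true(all(c(out$ppv, out$sens, out$f1, cd) <= 1))
})

test_that("embedding similarity behaves on planted vectors", {
  W <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 0))
  emb <- new("WordEmbeddings", vectors = W, meta = list())
  expect_equal(embeddingSimilarity("a c", "a c", emb), 1)
  expect_equal(embeddingSimilarity("a", "b", emb), 0)
  expect_error(embeddingSimilarity("zz", "a", emb), "reference")
})

test_that("related abbreviations score above zero without n-gram overlap", {
  emb <- benchmarkEmbeddings()
  expect_equal(ngramScores("od", "overdose")[["f1"]], 0)
  expect_gt(embeddingSimilarity("od", "overdose", emb), 0)
})

test_that("full evaluation reports all metric columns", {
  refs <- c("chest pain", "fall at home", "od")
  out <- evaluateGeneration(refs, refs)
  expect_equal(out$f1, 1)
  expect_equal(out$cider, 1)
  expect_true(is.na(out$embeddingSimilarity))
})
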