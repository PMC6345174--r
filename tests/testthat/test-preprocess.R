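simpleFrame <- function(complaints) {
  n <- length(complaints)
  data.frame(age_group = rep(0L, n), gender = rep(0L, n),
             diagnosis = rep("0", n), hospital = rep(0L, n),
             complaint = complaints, stringsAsFactors = FALSE)
}

test_that("rare-token filter drops pairs using raw-corpus frequencies", {
  fr <- simpleFrame(c(rep("chest pain", 20), rep("zzq pain", 9)))
  out <- preprocessText(fr, simSchema(), minFreq = 10L)
  expect_equal(unname(out$removed["byFrequency"]), 9L)
  expect_equal(length(out$corpus), 20L)
  expect_setequal(setdiff(tokens(out$vocabulary), c("<s>", "</s>")),
                  c("chest", "pain"))
  # frequencies recorded are raw-corpus counts, all >= minFreq
  f <- out$vocabulary@frequencies[-(1:2)]
  expect_true(all(f >= 10L))
  expect_equal(sort(f), c(20L, 29L))
})

test_that("length filter drops complaints longer than maxWords", {
  long <- paste(rep("sore", 19), collapse = " ")
  fr <- simpleFrame(c(rep("sore arm", 12), long))
  out <- preprocessText(fr, simSchema(), minFreq = 10L, maxWords = 18L)
  expect_equal(unname(out$removed["byLength"]), 1L)
  expect_equal(length(out$corpus), 12L)
})

test_that("a clean corpus passes through unchanged", {
  fr <- simpleFrame(rep(c("head ache", "head pain"), 10))
  out <- preprocessText(fr, simSchema(), minFreq = 10L)
  expect_equal(sum(out$removed), 0L)
  expect_equal(length(out$corpus), 20L)
  expect_equal(rawText(out$corpus), fr$complaint)
})

test_that("sequences carry specials, suffix padding, constant width", {
  fr <- simpleFrame(rep(c("a b c", "a"), 10))
  out <- preprocessText(fr, simSchema(), minFreq = 1L)
  s <- sequenceMatrix(out$corpus)
  expect_true(all(s[, 1] == 1L))              # <s> first
  expect_equal(ncol(s), 18L + 2L)
  # </s> right after content, zeros after
  lens <- lengths(regmatches(rawText(out$corpus),
                             gregexpr("\\S+", rawText(out$corpus))))
  expect_true(all(s[cbind(seq_len(nrow(s)), lens + 2L)] == 2L))
  expect_true(all(apply(s, 1, function(r) {
    z <- which(r == 0L)
    length(z) == 0L || all(z == seq(min(z), ncol(s)))
  })))
  # vocabulary ordered by descending frequency then lexicographic
  expect_equal(tokens(out$vocabulary),
               c("<s>", "</s>", "a", "b", "c"))
})

test_that("vocabulary indices are deterministic across rebuilds", {
  fr <- simpleFrame(rep(c("b a", "a c", "c b"), 8))
  v1 <- preprocessText(fr, simSchema(), minFreq = 1L)$vocabulary
  v2 <- preprocessText(fr, simSchema(), minFreq = 1L)$vocabulary
  expect_identical(tokens(v1), tokens(v2))
  # equal frequencies -> lexicographic ties
  expect_equal(tokens(v1)[-(1:2)], sort(tokens(v1)[-(1:2)]))
})

test_that("empty corpora and all-filtered corpora are rejected", {
  fr <- simpleFrame(c("unique one", "another two"))
  expect_error(preprocessText(fr, simSchema(), minFreq = 10L), "survive")
  fr$complaint[1] <- " "
  expect_error(preprocessText(fr, simSchema(), minFreq = 1L), "nonempty")
})

test_that("corpus splitting is exhaustive, disjoint, capped and seeded", {
  fr <- simpleFrame(rep(c("head ache", "arm pain", "leg pain", "rib pain"),
                        250))
  corpus <- preprocessText(fr, simSchema(), minFreq = 1L)$corpus
  parts <- splitCorpus(corpus, trainFrac = 0.75, testSize = 50000L,
                       seed = 7L)
  expect_equal(length(parts$train), 750L)
  expect_equal(length(parts$validation), 250L)
  expect_equal(length(parts$test), 250L)          # capped at validation size
  # disjoint and exhaustive partition
  expect_equal(length(parts$train) + length(parts$validation), 1000L)

  again <- splitCorpus(corpus, trainFrac = 0.75, testSize = 50000L,
                       seed = 7L)
  expect_identical(rawText(again$train), rawText(parts$train))
  expect_identical(again$testIndex, parts$testIndex)

  small <- splitCorpus(corpus, testSize = 100L, seed = 7L)
  expect_equal(length(small$test), 100L)
  expect_error(splitCorpus(corpus, trainFrac = 1.2), "trainFrac")
})

test_that("encode and decode round-trip text under a vocabulary", {
  fr <- simpleFrame(rep(c("neck pain", "neck stiffness today"), 10))
  out <- preprocessText(fr, simSchema(), minFreq = 1L)
  enc <- encodeText(c("neck stiffness", "pain today"), out$vocabulary)
  expect_equal(decodeSequences(enc, out$vocabulary),
               c("neck stiffness", "pain today"))
  expect_error(encodeText("neck xyz", out$vocabulary), "outside")
  expect_equal(decodeSequences(encodeText("neck xyz", out$vocabulary,
                                          skipUnknown = TRUE),
                               out$vocabulary), "neck")
})
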