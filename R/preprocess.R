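#' Preprocess chief-complaint text and build a paired corpus
#'
#' Applies the standard cleaning pass: lowercase and whitespace-tokenize the
#' complaints, drop every pair whose complaint contains a token with raw
#' corpus frequency below `minFreq` (this is what removes rare misspellings,
#' abbreviations and residual names), drop every pair longer than `maxWords`
#' content words, then integer-encode each surviving complaint as
#' start token + content + end token, zero-padded to a constant width.
#' Token frequencies are computed once, on the raw corpus, and the two
#' filters are applied in that order in a single pass.
#'
#' @param records a record frame with one column per schema variable plus a
#'   `complaint` character column (see [vectorizeRecords()]).
#' @param schema a [RecordSchema-class].
#' @param minFreq minimum raw-corpus token frequency (default 10).
#' @param maxWords maximum complaint length in content words (default 18).
#' @return a list with elements
#'   \describe{
#'     \item{corpus}{a [PairedCorpus-class] of the surviving pairs;}
#'     \item{vocabulary}{the shared [Vocabulary-class];}
#'     \item{removed}{named integer vector: pairs removed `byFrequency` and
#'       `byLength`.}
#'   }
#' @export
preprocessText <- function(records, schema, minFreq = 10L, maxWords = 18L) {
  if (!"complaint" %in% names(records))
    stopf("record frame needs a 'complaint' column")
  text <- as.character(records$complaint)
  if (any(is.na(text) | !nzchar(trimws(text))))
    stopf("every pair must have nonempty complaint text")
  toks <- tokenizeText(text)

  freq <- table(unlist(toks, use.names = FALSE))
  tokenFreq <- as.integer(freq)
  names(tokenFreq) <- names(freq)

  hasRare <- vapply(toks, function(tt) any(tokenFreq[tt] < minFreq), logical(1))
  tooLong <- lengths(toks) > maxWords
  keep <- !hasRare & !tooLong
  removed <- c(byFrequency = sum(hasRare),
               byLength = sum(tooLong & !hasRare))
  if (!any(keep)) stopf("no pairs survive preprocessing")

  vocabulary <- buildVocabulary(tokenFreq, minFreq)
  kept <- toks[keep]
  sequences <- encodeSequences(kept, vocabulary, maxWords)
  recs <- vectorizeRecords(records[keep, , drop = FALSE], schema)

  corpus <- new("PairedCorpus", records = recs, sequences = sequences,
                rawText = vapply(kept, paste, "", collapse = " "),
                schema = schema, vocabulary = vocabulary,
                maxWords = as.integer(maxWords))
  list(corpus = corpus, vocabulary = vocabulary, removed = removed)
}

# vocabulary indices: 1 = <s>, 2 = </s>, then descending raw frequency,
# ties broken lexicographically
buildVocabulary <- function(tokenFreq, minFreq) {
  keep <- tokenFreq[tokenFreq >= minFreq]
  ord <- order(-keep, names(keep), method = "radix")
  new("Vocabulary",
      tokens = c(sosToken(), eosToken(), names(keep)[ord]),
      frequencies = c(NA_integer_, NA_integer_, as.integer(keep)[ord]),
      minFreq = as.integer(minFreq))
}

# integer-encode token lists as [SOS content EOS 0...] rows
encodeSequences <- function(tokenLists, vocabulary, maxWords) {
  width <- maxWords + 2L
  n <- length(tokenLists)
  lens <- lengths(tokenLists)
  idx <- match(unlist(tokenLists, use.names = FALSE), vocabulary@tokens)
  if (anyNA(idx)) stopf("token outside the vocabulary: '%s'",
                        unlist(tokenLists)[which(is.na(idx))[1L]])
  out <- matrix(0L, n, width)
  out[, 1L] <- 1L                       # <s>
  rows <- rep.int(seq_len(n), lens)
  cols <- sequence(lens) + 1L
  out[cbind(rows, cols)] <- as.integer(idx)
  out[cbind(seq_len(n), lens + 2L)] <- 2L  # </s>
  out
}

#' Tokenize and integer-encode free text under an existing vocabulary
#'
#' Tokens absent from the vocabulary make the sentence unencodable and raise
#' an error unless `skipUnknown` is set, in which case they are dropped.
#'
#' @param text character vector.
#' @param vocabulary a [Vocabulary-class].
#' @param maxWords content-word cap (longer sentences are truncated).
#' @param skipUnknown drop out-of-vocabulary tokens instead of erroring.
#' @return integer matrix in the corpus sequence layout.
#' @export
encodeText <- function(text, vocabulary, maxWords = 18L, skipUnknown = FALSE) {
  toks <- tokenizeText(text)
  toks <- lapply(toks, function(tt) {
    known <- tt %in% vocabulary@tokens
    if (!all(known) && !skipUnknown)
      stopf("token outside the vocabulary: '%s'", tt[!known][1L])
    utils::head(tt[known], maxWords)
  })
  encodeSequences(toks, vocabulary, maxWords)
}

#' Decode integer sequences back to text
#'
#' @param sequences integer matrix in the corpus layout (or a single vector).
#' @param vocabulary a [Vocabulary-class].
#' @return character vector of detokenized sentences (specials and padding
#'   removed).
#' @export
decodeSequences <- function(sequences, vocabulary) {
  if (is.vector(sequences)) sequences <- matrix(sequences, nrow = 1L)
  apply(sequences, 1L, function(row) {
    row <- row[row > 2L]               # drop padding and specials
    paste(vocabulary@tokens[row], collapse = " ")
  })
}

#' Split a corpus into training, validation and test sets
#'
#' A seeded random `trainFrac` / `1 - trainFrac` partition into training and
#' validation pairs; the test set is a seeded subsample of the validation
#' set of size `min(testSize, validation size)`, kept small so that decoding
#' experiments stay cheap.
#'
#' @param corpus a [PairedCorpus-class] with at least 4 pairs.
#' @param trainFrac fraction assigned to training (default 0.75).
#' @param testSize test subsample cap (default 50000).
#' @param seed integer seed making the partition reproducible.
#' @return list with [PairedCorpus-class] elements `train`, `validation`,
#'   `test`, plus `testIndex` (positions of the test pairs within the
#'   validation set).
#' @export
splitCorpus <- function(corpus, trainFrac = 0.75, testSize = 50000L, seed = 1L) {
  if (trainFrac <= 0 || trainFrac >= 1) stopf("trainFrac must lie in (0, 1)")
  n <- length(corpus)
  if (n < 4L) stopf("corpus too small to split (%d pairs)", n)
  nTrain <- round(n * trainFrac)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  perm <- sample.int(n)
  trainIdx <- sort(perm[seq_len(nTrain)])
  valIdx <- sort(perm[-seq_len(nTrain)])
  nTest <- min(as.integer(testSize), length(valIdx))
  set.seed(deriveSeed(seed, "test"))
  testPos <- sort(sample.int(length(valIdx), nTest))
  list(train = corpus[trainIdx],
       validation = corpus[valIdx],
       test = corpus[valIdx[testPos]],
       testIndex = testPos)
}
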