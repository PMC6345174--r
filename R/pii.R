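#' Train skipgram word embeddings on a complaint corpus
#'
#' Skipgram with negative sampling, trained by minibatch SGD with a
#' linearly decaying learning rate; negatives are drawn from the
#' unigram^0.75 distribution. Single-threaded and fully deterministic
#' given the seed.
#'
#' @param texts character vector of sentences.
#' @param dimension embedding dimension (default 100).
#' @param window symmetric context window (default 5).
#' @param minCount minimum token count for inclusion (default 5).
#' @param negatives negative samples per positive pair.
#' @param epochs passes over the pair list.
#' @param learningRate initial SGD step size.
#' @param seed RNG seed.
#' @return a [WordEmbeddings-class].
#' @export
trainWordEmbeddings <- function(texts, dimension = 100L, window = 5L,
                                minCount = 5L, negatives = 5L, epochs = 5L,
                                learningRate = 0.025, seed = 1L) {
  toks <- tokenizeText(texts)
  counts <- table(unlist(toks, use.names = FALSE))
  counts <- counts[counts >= minCount]
  if (length(counts) < 2L) stopf("vocabulary smaller than 2 after minCount")
  vocab <- sort(names(counts))
  cnt <- as.numeric(counts[vocab])
  V <- length(vocab)

  flat <- match(unlist(toks, use.names = FALSE), vocab)
  sid <- rep.int(seq_along(toks), lengths(toks))
  keep <- !is.na(flat)
  flat <- flat[keep]; sid <- sid[keep]

  centers <- integer(0); contexts <- integer(0)
  n <- length(flat)
  for (d in seq_len(window)) {
    if (n <= d) break
    i <- seq_len(n - d)
    ok <- sid[i] == sid[i + d]
    centers <- c(centers, flat[i][ok], flat[i + d][ok])
    contexts <- c(contexts, flat[i + d][ok], flat[i][ok])
  }
  nPairs <- length(centers)
  if (nPairs == 0L) stopf("no co-occurrence pairs (sentences too short?)")

  negCdf <- cumsum(cnt^0.75 / sum(cnt^0.75))
  Win <- sgns_train_cpp(centers, contexts, V, as.integer(dimension),
                        negCdf, as.integer(negatives), as.integer(epochs),
                        learningRate, as.integer(seed))
  rownames(Win) <- vocab
  new("WordEmbeddings", vectors = Win,
      meta = list(dimension = as.integer(dimension),
                  window = as.integer(window),
                  minCount = as.integer(minCount),
                  negatives = as.integer(negatives),
                  epochs = as.integer(epochs), seed = as.integer(seed)))
}

#' Cosine nearest neighbours of a token
#'
#' @param embeddings a [WordEmbeddings-class].
#' @param token query token.
#' @param k number of neighbours.
#' @return character vector of the `k` most cosine-similar tokens
#'   (excluding the query), most similar first.
#' @export
nearestNeighbors <- function(embeddings, token, k = 100L) {
  W <- embeddings@vectors
  if (!token %in% rownames(W)) stopf("token '%s' not in the embedding vocabulary", token)
  Wn <- W / sqrt(rowSums(W^2))
  Wn[!is.finite(Wn)] <- 0
  sims <- as.vector(Wn %*% Wn[token, ])
  names(sims) <- rownames(W)
  sims <- sims[names(sims) != token]
  names(sort(sims, decreasing = TRUE))[seq_len(min(k, length(sims)))]
}

#' Iterative embedding-based name discovery
#'
#' Starting from one or more known names, repeatedly retrieves the cosine
#' nearest neighbours of every name found so far, labels the candidates
#' with the oracle, and adds confirmed names, until a pass adds nothing
#' new. The oracle stands in for the manual check of the neighbour lists:
#' in tests it is membership in the planted name list; interactively it
#' can prompt a human.
#'
#' @param embeddings a [WordEmbeddings-class].
#' @param seedNames nonempty character vector of known names (must be in
#'   the embedding vocabulary).
#' @param k neighbours retrieved per name (default 100).
#' @param oracle function(token) -> logical: is this token a name?
#' @return list with `names` (the closed list, seeds included) and
#'   `iterations`.
#' @export
discoverNames <- function(embeddings, seedNames, k = 100L, oracle) {
  if (length(seedNames) == 0L) stopf("seedNames must be nonempty")
  missing <- setdiff(seedNames, rownames(embeddings@vectors))
  if (length(missing))
    stopf("seed name '%s' not in the embedding vocabulary", missing[1L])
  known <- unique(seedNames)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    cands <- unique(unlist(lapply(known, function(nm)
      nearestNeighbors(embeddings, nm, k))))
    cands <- setdiff(cands, known)
    confirmed <- cands[vapply(cands, function(tk) isTRUE(oracle(tk)), logical(1))]
    if (length(confirmed) == 0L) break
    known <- c(known, confirmed)
  }
  list(names = known, iterations = iterations)
}

#' Count complaints containing any of a set of names
#'
#' Complaint-level counting: a sentence counts once however many name
#' tokens it contains.
#'
#' @param sentences character vector.
#' @param names character vector of name tokens.
#' @return integer count.
#' @export
countNameComplaints <- function(sentences, names) {
  if (length(names) == 0L || length(sentences) == 0L) return(0L)
  sum(vapply(tokenizeText(sentences), function(tt) any(tt %in% names),
             logical(1)))
}

#' Authentic-vs-synthetic name audit
#'
#' Counts the complaints containing any known name in an authentic corpus
#' and in the synthetic corpus generated from the same records. The
#' working hypothesis of the audit is that low-frequency name tokens are
#' improbable under the trained model, so likelihood-seeking decoding
#' drops them and the synthetic count is zero.
#'
#' @param authentic,synthetic parallel character vectors of complaints.
#' @param names the name list (e.g. from [discoverNames()]).
#' @param iterations optional iteration count to carry in the report.
#' @return a `NameAudit` list: `names`, `iterations`, `authenticCount`,
#'   `syntheticCount`.
#' @export
piiReport <- function(authentic, synthetic, names, iterations = NA_integer_) {
  structure(list(names = names, iterations = iterations,
                 authenticCount = countNameComplaints(authentic, names),
                 syntheticCount = countNameComplaints(synthetic, names)),
            class = "NameAudit")
}

#' Write embeddings in word2vec text format
#'
#' First line `"<n> <dim>"`, then one token and its space-separated vector
#' per line.
#'
#' @param embeddings a [WordEmbeddings-class].
#' @param path destination file.
#' @return `readEmbeddings` returns the [WordEmbeddings-class].
#' @export
writeEmbeddings <- function(embeddings, path) {
  W <- embeddings@vectors
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(W), ncol(W)), con)
  writeLines(paste(rownames(W),
                   apply(W, 1L, function(r) paste(format(r, digits = 17),
                                                  collapse = " "))), con)
  invisible(path)
}

#' @rdname writeEmbeddings
#' @export
readEmbeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(lines[1L], " ")[[1L]])
  parts <- strsplit(lines[-1L], " +")
  W <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(hdr[2L])))
  rownames(W) <- vapply(parts, `[[`, "", 1L)
  new("WordEmbeddings", vectors = W, meta = list(source = path))
}
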