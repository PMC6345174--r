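#' Variable-length n-gram overlap scores for one sentence pair
#'
#' Pools n-grams of every order `1 .. min(maxOrder, sentence length)` into
#' a single clipped count (a candidate n-gram is credited at most its
#' reference multiplicity) rather than combining per-order scores, so that
#' very short complaints are not rated harshly just for having few
#' high-order n-grams. PPV is the matched share of candidate n-grams,
#' sensitivity the matched share of reference n-grams, and F1 their
#' harmonic mean.
#'
#' @param reference,candidate sentences (character scalars or token
#'   vectors).
#' @param maxOrder largest n-gram order (default 4).
#' @return named numeric vector `c(ppv, sens, f1)`; an empty candidate
#'   yields 0 for all three with an `undefined` attribute flag.
#' @examples
#' ngramScores("high blood pressure", "blood pressure")
#' @export
ngramScores <- function(reference, candidate, maxOrder = 4L) {
  ref <- asTokens(reference)
  cand <- asTokens(candidate)
  if (length(cand) == 0L || length(ref) == 0L) {
    out <- c(ppv = 0, sens = 0, f1 = 0)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  refBag <- ngramBag(ref, maxOrder)
  candBag <- ngramBag(cand, maxOrder)
  shared <- intersect(names(refBag), names(candBag))
  matched <- sum(pmin(refBag[shared], candBag[shared]))
  ppv <- matched / sum(candBag)
  sens <- matched / sum(refBag)
  f1 <- if (ppv + sens == 0) 0 else 2 * ppv * sens / (ppv + sens)
  c(ppv = ppv, sens = sens, f1 = f1)
}

asTokens <- function(x) {
  if (length(x) == 1L && is.character(x)) tokenizeText(x)[[1L]] else
    as.character(x)
}

# named count vector over all n-grams of orders 1..min(maxOrder, length)
ngramBag <- function(tokens, maxOrder) {
  L <- length(tokens)
  grams <- unlist(lapply(seq_len(min(maxOrder, L)), function(n) {
    if (L < n) return(character(0))
    vapply(seq_len(L - n + 1L), function(s)
      paste(tokens[s:(s + n - 1L)], collapse = " "), "")
  }))
  tab <- table(grams)
  out <- as.numeric(tab)
  names(out) <- names(tab)
  out
}

#' Corpus-level n-gram overlap scores
#'
#' The unweighted mean of the per-pair [ngramScores()].
#'
#' @param references,candidates parallel character vectors.
#' @param maxOrder largest n-gram order.
#' @return list with `ppv`, `sens`, `f1` (corpus means) and a `perPair`
#'   matrix.
#' @export
corpusNgramScores <- function(references, candidates, maxOrder = 4L) {
  if (length(references) != length(candidates))
    stopf("references (%d) and candidates (%d) differ in length",
          length(references), length(candidates))
  if (length(references) == 0L) stopf("empty pair list")
  perPair <- t(mapply(function(r, s) ngramScores(r, s, maxOrder),
                      references, candidates))
  rownames(perPair) <- NULL
  m <- colMeans(perPair)
  list(ppv = m[["ppv"]], sens = m[["sens"]], f1 = m[["f1"]],
       perPair = perPair)
}

#' Modified consensus TF-IDF cosine score
#'
#' For each reference-candidate pair, both sentences are represented as
#' TF-IDF vectors over pooled variable-length n-grams (orders
#' `1 .. min(maxOrder, sentence length)`); IDF is `ln(N / df)` with
#' document frequency counted over the reference corpus and floored at 1.
#' The score is the mean cosine similarity across pairs. One reference per
#' candidate; no length penalty. A pair with a zero-norm vector (every
#' shared n-gram has IDF 0) contributes 0.
#'
#' @inheritParams corpusNgramScores
#' @return mean cosine similarity in `[0, 1]`.
#' @export
ciderScore <- function(references, candidates, maxOrder = 4L) {
  if (length(references) != length(candidates))
    stopf("references and candidates differ in length")
  N <- length(references)
  if (N < 2L) stopf("TF-IDF weighting needs at least 2 pairs")
  refBags <- lapply(references, function(r) ngramBag(asTokens(r), maxOrder))
  candBags <- lapply(candidates, function(s) ngramBag(asTokens(s), maxOrder))
  df <- table(unlist(lapply(refBags, names)))
  idfOf <- function(grams) {
    d <- as.numeric(df[grams])
    d[is.na(d) | d < 1] <- 1
    log(N / d)
  }
  sims <- vapply(seq_len(N), function(i) {
    rb <- refBags[[i]]; cb <- candBags[[i]]
    grams <- union(names(rb), names(cb))
    idf <- idfOf(grams)
    rv <- ifelse(grams %in% names(rb), rb[grams], 0) * idf
    cv <- ifelse(grams %in% names(cb), cb[grams], 0) * idf
    nr <- sqrt(sum(rv^2)); nc <- sqrt(sum(cv^2))
    if (nr == 0 || nc == 0) return(0)
    sum(rv * cv) / (nr * nc)
  }, 0)
  mean(sims)
}

#' Embedding similarity between two sentences
#'
#' Cosine similarity of the mean word vectors; nonzero even with no n-gram
#' overlap, which is the point: abbreviation pairs like "od" / "overdose"
#' score 0 on any n-gram metric yet are nearly synonymous.
#'
#' @param reference,candidate sentences.
#' @param embeddings a [WordEmbeddings-class].
#' @return cosine similarity in `[-1, 1]`.
#' @export
embeddingSimilarity <- function(reference, candidate, embeddings) {
  meanVec <- function(x, side) {
    tt <- asTokens(x)
    tt <- tt[tt %in% rownames(embeddings@vectors)]
    if (length(tt) == 0L)
      stopf("every %s token is outside the embedding vocabulary", side)
    colMeans(embeddings@vectors[tt, , drop = FALSE])
  }
  a <- meanVec(reference, "reference")
  b <- meanVec(candidate, "candidate")
  sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

#' Full text-quality report for a generated corpus
#'
#' Corpus n-gram PPV / sensitivity / F1, the modified TF-IDF cosine score,
#' and (when embeddings are supplied) the mean embedding similarity over
#' pairs where both sentences have in-vocabulary tokens.
#'
#' @inheritParams corpusNgramScores
#' @param embeddings optional [WordEmbeddings-class].
#' @return named list of corpus scores (a metric-report row).
#' @export
evaluateGeneration <- function(references, candidates, embeddings = NULL,
                               maxOrder = 4L) {
  ng <- corpusNgramScores(references, candidates, maxOrder)
  out <- list(ppv = ng$ppv, sens = ng$sens, f1 = ng$f1,
              cider = ciderScore(references, candidates, maxOrder),
              embeddingSimilarity = NA_real_)
  if (!is.null(embeddings)) {
    sims <- mapply(function(r, s) {
      v <- try(embeddingSimilarity(r, s, embeddings), silent = TRUE)
      if (inherits(v, "try-error")) NA_real_ else v
    }, references, candidates)
    out$embeddingSimilarity <- mean(sims, na.rm = TRUE)
  }
  out
}
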