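#' Configure a sampling scheme for generation
#'
#' Three schemes implement the generation step rule: `greedy` takes the
#' highest-probability token at each step, `probabilistic` samples from the
#' temperature-rescaled distribution `softmax(logits / t)`, and `beam`
#' keeps the `k` highest log-probability partial sequences and returns the
#' `k` best complete ones (raw summed log-probabilities, no length
#' normalisation). Ties are broken toward the lowest vocabulary index
#' everywhere, so greedy and beam decoding are fully deterministic.
#'
#' @param scheme `"greedy"`, `"probabilistic"` or `"beam"`.
#' @param temperature positive sampling temperature (probabilistic only);
#'   `t -> 0` approaches greedy, `t = 1` samples the model distribution.
#' @param k beam width (beam only).
#' @param maxLen maximum generated content length in tokens.
#' @param seed RNG seed (probabilistic only).
#' @return a `SamplingConfig` list.
#' @export
samplingConfig <- function(scheme = c("greedy", "probabilistic", "beam"),
                           temperature = 1.0, k = 5L, maxLen = 18L,
                           seed = 1L) {
  scheme <- match.arg(scheme)
  if (temperature <= 0) stopf("temperature must be positive")
  if (k < 1L) stopf("beam width must be at least 1")
  structure(list(scheme = scheme, temperature = temperature,
                 k = as.integer(k), maxLen = as.integer(maxLen),
                 seed = as.integer(seed)),
            class = "SamplingConfig")
}

encodeRecordsDense <- function(model, records) {
  if (is(records, "PairedCorpus")) records <- recordMatrix(records)
  if (is.null(dim(records))) records <- matrix(records, nrow = 1L)
  records <- as.matrix(records)
  if (ncol(records) != model@config$recordDim)
    stopf("records have %d columns but the checkpoint schema has %d",
          ncol(records), model@config$recordDim)
  tanh(sweep(records %*% model@params$Wenc, 2L, model@params$benc, `+`))
}

logSoftmaxRows <- function(logits) {
  m <- logits[cbind(seq_len(nrow(logits)), max.col(logits, "first"))]
  z <- logits - m
  z - log(rowSums(exp(z)))
}

# batched greedy / temperature decoding; returns content token lists and
# summed log-probabilities (end token included when emitted)
decodeBatch <- function(model, Rmat, scheme, temperature, maxLen, seed) {
  p <- model@params
  n <- nrow(Rmat)
  if (n == 0L) return(list(tokens = list(), logProb = numeric(0)))
  enc <- tanh(sweep(Rmat %*% p$Wenc, 2L, p$benc, `+`))
  h <- enc; c <- enc
  prev <- rep(1L, n)                       # <s>
  active <- seq_len(n)
  seqs <- vector("list", n)
  logProb <- numeric(n)
  if (scheme == "probabilistic") {
    V <- ncol(p$Wout)
    U <- upper.tri(matrix(0, V, V), diag = TRUE)
  }
  for (step in seq_len(maxLen + 1L)) {
    st <- lstm_step_cpp(p$E, p$Wx, p$Wh, p$b, p$Wout, p$bout,
                        prev, h, c)   # prev is aligned with `active`
    logp <- logSoftmaxRows(st$logits)
    if (scheme == "greedy") {
      pick <- max.col(st$logits, "first")
    } else {
      pr <- exp(logSoftmaxRows(st$logits / temperature))
      cum <- pr %*% U
      u <- stats::runif(length(active))
      pick <- 1L + as.integer(rowSums(cum < u))
      pick[pick > ncol(pr)] <- ncol(pr)    # numerical guard
    }
    # past maxLen content tokens only the end token may still score
    scored <- pick == 2L | step <= maxLen
    logProb[active[scored]] <- logProb[active[scored]] +
      logp[cbind(seq_along(active), pick)][scored]
    addTok <- which(pick != 2L & step <= maxLen)
    for (j in addTok)
      seqs[[active[j]]] <- c(seqs[[active[j]]], pick[j])
    ended <- pick == 2L | step == maxLen + 1L
    if (all(ended)) break
    keep <- which(!ended)
    active <- active[keep]
    h <- st$h[keep, , drop = FALSE]
    c <- st$c[keep, , drop = FALSE]
    prev <- pick[keep]
  }
  list(tokens = lapply(seqs, function(x) as.integer(x %||% integer(0))),
       logProb = logProb)
}

decodeResult <- function(model, tokenLists, logProb) {
  structure(list(
    sequences = tokenLists,
    text = vapply(tokenLists, function(tt)
      paste(model@vocabulary@tokens[tt], collapse = " "), ""),
    logProb = logProb), class = "DecodeResult")
}

#' Greedy decoding for one record
#'
#' Picks the argmax token at each step (ties to the lowest vocabulary
#' index) until the end token or `maxLen` content tokens.
#'
#' @param model a [CCModel-class].
#' @param record binary visit vector.
#' @param config a [samplingConfig()]; only `maxLen` is used.
#' @return a `DecodeResult`: list with `sequences` (list of integer content
#'   token vectors), `text`, and `logProb`.
#' @export
greedyDecode <- function(model, record, config = samplingConfig("greedy")) {
  Rmat <- matrix(record, nrow = 1L)
  out <- decodeBatch(model, Rmat, "greedy", 1.0, config$maxLen, 0L)
  decodeResult(model, out$tokens, out$logProb)
}

#' Temperature sampling for one record
#'
#' Samples each token from `softmax(logits / t)`; seeded and reproducible.
#'
#' @inheritParams greedyDecode
#' @param config a [samplingConfig()] with `temperature` and `seed`.
#' @return a `DecodeResult`.
#' @export
probDecode <- function(model, record,
                       config = samplingConfig("probabilistic")) {
  if (config$temperature <= 0) stopf("temperature must be positive")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)
  Rmat <- matrix(record, nrow = 1L)
  out <- decodeBatch(model, Rmat, "probabilistic", config$temperature,
                     config$maxLen, config$seed)
  decodeResult(model, out$tokens, out$logProb)
}

#' Beam-search decoding for one record
#'
#' Maintains the `k` highest raw log-probability partial sequences;
#' sequences emitting the end token retire to a finished pool at their
#' final score and the beam refills from unfinished candidates. Returns the
#' top `k` finished sequences (falling back to unfinished ones truncated at
#' `maxLen`), sorted by descending log-probability.
#'
#' @inheritParams greedyDecode
#' @param config a [samplingConfig()] with beam width `k`.
#' @return a `DecodeResult` with up to `k` sequences.
#' @export
beamDecode <- function(model, record, config = samplingConfig("beam")) {
  p <- model@params
  k <- config$k
  maxLen <- config$maxLen
  enc <- encodeRecordsDense(model, record)
  h <- enc; c <- enc
  beams <- list(integer(0))
  scores <- 0
  prev <- 1L
  finished <- list(); finScores <- numeric(0)
  for (step in seq_len(maxLen + 1L)) {
    st <- lstm_step_cpp(p$E, p$Wx, p$Wh, p$b, p$Wout, p$bout,
                        prev, h, c)
    logp <- logSoftmaxRows(st$logits)
    cand <- sweep(logp, 1L, scores, `+`)          # k' x V
    flat <- as.vector(t(cand))                    # beam-major, token minor
    tokenIdx <- rep(seq_len(ncol(cand)), times = nrow(cand))
    beamIdx <- rep(seq_len(nrow(cand)), each = ncol(cand))
    ord <- order(-flat, tokenIdx, beamIdx)
    newBeams <- list(); newScores <- numeric(0)
    newH <- NULL; newC <- NULL; newPrev <- integer(0)
    for (pos in seq_along(ord)) {
      ci <- ord[pos]
      tok <- tokenIdx[ci]; b <- beamIdx[ci]
      if (tok == 2L) {
        # an end-token candidate retires only from within the step's top k;
        # the live beam then refills from lower-ranked unfinished candidates
        if (pos <= k) {
          finished[[length(finished) + 1L]] <- beams[[b]]
          finScores <- c(finScores, flat[ci])
        }
      } else if (length(newBeams) < k && step <= maxLen) {
        newBeams[[length(newBeams) + 1L]] <- c(beams[[b]], tok)
        newScores <- c(newScores, flat[ci])
        newH <- rbind(newH, st$h[b, , drop = FALSE])
        newC <- rbind(newC, st$c[b, , drop = FALSE])
        newPrev <- c(newPrev, tok)
      }
      if (length(newBeams) >= k && pos >= k) break
    }
    if (step > maxLen || length(newBeams) == 0L) {
      # anything still unfinished competes truncated at maxLen
      if (length(finished) < k && length(beams) && step > maxLen) {
        for (b in seq_along(beams)) {
          finished[[length(finished) + 1L]] <- beams[[b]]
          finScores <- c(finScores, scores[b])
        }
      }
      break
    }
    beams <- newBeams; scores <- newScores
    h <- newH; c <- newC; prev <- newPrev
  }
  if (length(finished) == 0L) {
    finished <- beams; finScores <- scores
  }
  ord <- order(-finScores)[seq_len(min(k, length(finScores)))]
  decodeResult(model, finished[ord], finScores[ord])
}

#' Generate synthetic complaints for a set of records
#'
#' Runs the 4-step generation loop (encode the record, feed the start
#' token, sample the next token under the configured scheme, repeat until
#' the end token or the length cap) for every record and returns one
#' detokenized lowercase sentence per record, aligned with input order.
#' For beam search the best-scoring sequence is returned.
#'
#' @param model a [CCModel-class].
#' @param records binary record matrix, [PairedCorpus-class], or a single
#'   record vector.
#' @param config a [samplingConfig()].
#' @param verbose log progress.
#' @return character vector of sentences.
#' @export
generateCorpus <- function(model, records, config = samplingConfig("greedy"),
                           verbose = FALSE) {
  if (is(records, "PairedCorpus")) records <- recordMatrix(records)
  if (is.null(dim(records))) records <- matrix(records, nrow = 1L)
  records <- as.matrix(records)
  n <- nrow(records)
  if (n == 0L) return(character(0))
  if (ncol(records) != model@config$recordDim)
    stopf("records have %d columns but the checkpoint expects %d",
          ncol(records), model@config$recordDim)
  if (config$scheme %in% c("greedy", "probabilistic")) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(config$seed)
    out <- decodeBatch(model, records, config$scheme, config$temperature,
                       config$maxLen, config$seed)
    res <- decodeResult(model, out$tokens, out$logProb)
    if (verbose) message(sprintf("generated %d sentences (%s)", n, config$scheme))
    return(res$text)
  }
  txt <- character(n)
  for (i in seq_len(n)) {
    txt[i] <- beamDecode(model, records[i, ], config)$text[1L]
    if (verbose && i %% 500L == 0L)
      message(sprintf("beam-decoded %d / %d records", i, n))
  }
  txt
}
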