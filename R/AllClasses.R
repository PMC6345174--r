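#' @import methods
#' @importFrom Matrix sparseMatrix rowSums colSums t
#' @importClassesFrom Matrix Matrix
NULL

#' Padding index and special tokens
#'
#' Token index 0 is reserved for padding and never denotes a real token;
#' `"<s>"` and `"</s>"` mark sequence start and end and always occupy
#' vocabulary indices 1 and 2.
#'
#' @return `padIndex()` returns the integer 0; `sosToken()` and `eosToken()`
#'   return the special token strings.
#' @export
padIndex <- function() 0L

#' @rdname padIndex
#' @export
sosToken <- function() "<s>"

#' @rdname padIndex
#' @export
eosToken <- function() "</s>"

#' RecordSchema: the discrete-variable layout of a visit record
#'
#' An ordered set of discrete variables, each with a fixed number of coded
#' values `0 .. cardinality - 1`. Concatenating one indicator block per
#' variable gives the sparse binary visit vector consumed by the model; the
#' block for a missing variable is all zeros, and multi-valued variables
#' (typically discharge diagnosis) may set several bits in their block.
#'
#' @slot variables a `data.frame` with columns `name`, `cardinality`,
#'   `multiValued`, `missingAllowed`; row order fixes the block order.
#' @slot totalDim total length of the concatenated binary vector
#'   (the sum of the cardinalities).
#' @aliases RecordSchema
#' @exportClass RecordSchema
setClass("RecordSchema",
  representation(variables = "data.frame", totalDim = "integer"))

setValidity("RecordSchema", function(object) {
  v <- object@variables
  need <- c("name", "cardinality", "multiValued", "missingAllowed")
  if (!all(need %in% names(v)))
    return(sprintf("variables must have columns %s", paste(need, collapse = ", ")))
  if (nrow(v) == 0L) return("schema has no variables")
  if (anyDuplicated(v$name)) return("duplicate variable name")
  if (any(v$cardinality < 1L)) return("non-positive cardinality")
  if (object@totalDim != sum(v$cardinality))
    return("totalDim does not equal the sum of cardinalities")
  TRUE
})

#' Vocabulary: the token-index bijection of a processed corpus
#'
#' Token `i` of the `tokens` slot has integer index `i`; index 0 is reserved
#' for padding and is not a token. Indices 1 and 2 always hold the
#' start-of-sequence and end-of-sequence strings; content tokens follow in
#' descending training-corpus frequency (ties broken lexicographically), so
#' vocabulary construction is deterministic.
#'
#' @slot tokens character vector of tokens; position = index.
#' @slot frequencies integer vector of raw-corpus occurrence counts
#'   (`NA` for the two special tokens).
#' @slot minFreq the minimum-frequency threshold used to build the vocabulary.
#' @aliases Vocabulary
#' @exportClass Vocabulary
setClass("Vocabulary",
  representation(tokens = "character", frequencies = "integer",
                 minFreq = "integer"))

setValidity("Vocabulary", function(object) {
  if (length(object@tokens) < 2L) return("vocabulary must contain the special tokens")
  if (!identical(object@tokens[1:2], c(sosToken(), eosToken())))
    return("indices 1 and 2 must hold the start and end tokens")
  if (anyDuplicated(object@tokens)) return("duplicate token")
  if (length(object@frequencies) != length(object@tokens))
    return("frequencies and tokens differ in length")
  f <- object@frequencies[-(1:2)]
  if (length(f) && any(!is.na(f) & f < object@minFreq))
    return("content token below the min-frequency threshold")
  TRUE
})

#' PairedCorpus: aligned record-sentence pairs
#'
#' Each pair holds the sparse binary record vector, the integer-encoded
#' chief complaint (start token, up to `maxWords` content tokens, end token,
#' zero-padded to a constant width), and the raw lowercased text. All three
#' components are parallel; the schema and vocabulary are shared.
#'
#' @slot records a sparse binary matrix, one row per pair,
#'   `totalDim(schema)` columns.
#' @slot sequences integer matrix, one row per pair, constant width
#'   `maxWords + 2`; entries are vocabulary indices, 0-padding only as a
#'   suffix.
#' @slot rawText character vector of the preprocessed complaint text.
#' @slot schema the [RecordSchema-class] the records are encoded under.
#' @slot vocabulary the shared [Vocabulary-class].
#' @slot maxWords maximum content length (tokens, excluding specials).
#' @aliases PairedCorpus
#' @exportClass PairedCorpus
setClass("PairedCorpus",
  representation(records = "Matrix", sequences = "matrix",
                 rawText = "character", schema = "RecordSchema",
                 vocabulary = "Vocabulary", maxWords = "integer"))

setValidity("PairedCorpus", function(object) {
  n <- nrow(object@records)
  if (nrow(object@sequences) != n || length(object@rawText) != n)
    return("records, sequences and rawText must be parallel")
  if (ncol(object@records) != object@schema@totalDim)
    return("record width does not match the schema")
  if (ncol(object@sequences) != object@maxWords + 2L)
    return("sequence width must be maxWords + 2")
  idx <- object@sequences
  if (length(idx) && (min(idx) < 0L || max(idx) > length(object@vocabulary@tokens)))
    return("sequence entries must be padding or valid vocabulary indices")
  if (n > 0L) {
    # padding strictly a suffix: a zero may never precede a non-zero
    bad <- rowSums((idx[, -ncol(idx), drop = FALSE] == 0L) &
                   (idx[, -1L, drop = FALSE] != 0L)) > 0
    if (any(bad)) return("padding must only appear as a suffix")
  }
  TRUE
})

#' CCModel: a trained record-conditioned chief-complaint generator
#'
#' Holds the weights of the encoder-decoder network: the feedforward record
#' encoder, the word-embedding matrix (padding row frozen at zero), the
#' single-layer LSTM decoder, and the softmax output projection; plus the
#' configuration, schema, vocabulary and training log needed to reuse it.
#'
#' @slot params named list of weight matrices (`Wenc`, `benc`, `E`, `Wx`,
#'   `Wh`, `b`, `Wout`, `bout`).
#' @slot config the [modelConfig()] list the model was trained under.
#' @slot schema,vocabulary the data space the model is bound to.
#' @slot log per-epoch training/validation losses and the stopping decision.
#' @aliases CCModel
#' @exportClass CCModel
setClass("CCModel",
  representation(params = "list", config = "list", schema = "RecordSchema",
                 vocabulary = "Vocabulary", log = "data.frame"))

setValidity("CCModel", function(object) {
  p <- object@params
  need <- c("Wenc", "benc", "E", "Wx", "Wh", "b", "Wout", "bout")
  if (!all(need %in% names(p)))
    return(sprintf("params must contain %s", paste(need, collapse = ", ")))
  H <- ncol(p$Wenc)
  V <- length(object@vocabulary@tokens)
  if (nrow(p$E) != V + 1L) return("embedding matrix must have V + 1 rows (padding row first)")
  if (any(p$E[1L, ] != 0)) return("padding embedding row must be zero")
  if (ncol(p$Wx) != 4L * H || ncol(p$Wh) != 4L * H)
    return("LSTM gate width must be 4 * hidden_dim")
  if (ncol(p$Wout) != V) return("output projection must cover the vocabulary")
  TRUE
})

#' CCClassifier: a GRU diagnosis classifier over chief-complaint text
#'
#' A word-embedding + single gated-recurrent-layer + softmax network mapping
#' a tokenized complaint to one diagnosis code, used to check that generated
#' text preserves the text-diagnosis relationship.
#'
#' @slot params named list of weight matrices (`E`, `Wx`, `Wh`, `b`
#'   for the gates, `Wxn`, `Whn`, `bn` for the candidate state, `Wout`,
#'   `bout`).
#' @slot config training configuration list.
#' @slot classes integer vector of diagnosis codes, in output-unit order.
#' @slot vocabulary the [Vocabulary-class] the classifier tokenizes under.
#' @slot log per-epoch loss trace.
#' @aliases CCClassifier
#' @exportClass CCClassifier
setClass("CCClassifier",
  representation(params = "list", config = "list", classes = "integer",
                 vocabulary = "Vocabulary", log = "data.frame"))

#' WordEmbeddings: dense word vectors trained on a complaint corpus
#'
#' Skipgram-with-negative-sampling vectors used for the embedding-similarity
#' metric and the nearest-neighbour name audit.
#'
#' @slot vectors numeric matrix, one row per token (rownames are the tokens).
#' @slot meta list of training metadata (dimension, window, min count, seed).
#' @aliases WordEmbeddings
#' @exportClass WordEmbeddings
setClass("WordEmbeddings",
  representation(vectors = "matrix", meta = "list"))

setValidity("WordEmbeddings", function(object) {
  if (is.null(rownames(object@vectors))) return("vectors must have token rownames")
  if (anyDuplicated(rownames(object@vectors))) return("duplicate token")
  TRUE
})
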