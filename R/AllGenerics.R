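#' Accessors for schema, vocabulary and corpus objects
#'
#' @param x,object a [RecordSchema-class], [Vocabulary-class],
#'   [PairedCorpus-class] or [WordEmbeddings-class] object, as applicable.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("totalDim", function(x) standardGeneric("totalDim"))

#' @rdname accessors
#' @export
setMethod("totalDim", "RecordSchema", function(x) x@totalDim)

#' @rdname accessors
#' @export
setGeneric("variableNames", function(x) standardGeneric("variableNames"))

#' @rdname accessors
#' @export
setMethod("variableNames", "RecordSchema", function(x) x@variables$name)

#' @rdname accessors
#' @export
setGeneric("vocabSize", function(x) standardGeneric("vocabSize"))

#' @rdname accessors
#' @export
setMethod("vocabSize", "Vocabulary", function(x) length(x@tokens))

#' @rdname accessors
#' @export
setGeneric("tokens", function(x) standardGeneric("tokens"))

#' @rdname accessors
#' @export
setMethod("tokens", "Vocabulary", function(x) x@tokens)

#' @rdname accessors
#' @export
setMethod("tokens", "WordEmbeddings", function(x) rownames(x@vectors))

#' @rdname accessors
#' @export
setGeneric("recordMatrix", function(x) standardGeneric("recordMatrix"))

#' @rdname accessors
#' @export
setMethod("recordMatrix", "PairedCorpus", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("sequenceMatrix", function(x) standardGeneric("sequenceMatrix"))

#' @rdname accessors
#' @export
setMethod("sequenceMatrix", "PairedCorpus", function(x) x@sequences)

#' @rdname accessors
#' @export
setGeneric("rawText", function(x) standardGeneric("rawText"))

#' @rdname accessors
#' @export
setMethod("rawText", "PairedCorpus", function(x) x@rawText)

#' @rdname accessors
#' @export
setGeneric("corpusSchema", function(x) standardGeneric("corpusSchema"))

#' @rdname accessors
#' @export
setMethod("corpusSchema", "PairedCorpus", function(x) x@schema)

#' @rdname accessors
#' @export
setGeneric("corpusVocabulary", function(x) standardGeneric("corpusVocabulary"))

#' @rdname accessors
#' @export
setMethod("corpusVocabulary", "PairedCorpus", function(x) x@vocabulary)

#' @rdname accessors
#' @export
setMethod("length", "PairedCorpus", function(x) nrow(x@records))

#' Subset a paired corpus
#'
#' @param x a [PairedCorpus-class].
#' @param i integer or logical index over pairs.
#' @param j,...,drop ignored.
#' @return a [PairedCorpus-class] containing the selected pairs.
#' @export
setMethod("[", "PairedCorpus", function(x, i, j, ..., drop = FALSE) {
  new("PairedCorpus",
      records = x@records[i, , drop = FALSE],
      sequences = x@sequences[i, , drop = FALSE],
      rawText = x@rawText[i],
      schema = x@schema, vocabulary = x@vocabulary, maxWords = x@maxWords)
})

setMethod("show", "RecordSchema", function(object) {
  v <- object@variables
  cat(sprintf("RecordSchema: %d variables, total dimension %d\n",
              nrow(v), object@totalDim))
  flags <- paste0(ifelse(v$multiValued, " multi", ""),
                  ifelse(v$missingAllowed, "", " required"))
  cat(sprintf("  %-24s [0, %d]%s\n", v$name, v$cardinality - 1L, flags), sep = "")
})

setMethod("show", "Vocabulary", function(object) {
  cat(sprintf("Vocabulary: %d tokens (incl. 2 specials), min frequency %d\n",
              length(object@tokens), object@minFreq))
  head <- utils::head(object@tokens[-(1:2)], 8L)
  if (length(head)) cat("  top tokens:", paste(head, collapse = " "), "\n")
})

setMethod("show", "PairedCorpus", function(object) {
  cat(sprintf(
    "PairedCorpus: %d record-sentence pairs\n  record dim %d | vocabulary %d | padded width %d (max %d content words)\n",
    length(object), object@schema@totalDim, vocabSize(object@vocabulary),
    ncol(object@sequences), object@maxWords))
  if (length(object) > 0L)
    cat(sprintf("  e.g. \"%s\"\n", object@rawText[1L]))
})

setMethod("show", "CCModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "CCModel: record encoder %d -> %d, LSTM hidden %d, embeddings %d, vocabulary %d\n",
    cfg$recordDim, cfg$hiddenDim, cfg$hiddenDim, cfg$wordEmbedDim,
    vocabSize(object@vocabulary)))
  if (nrow(object@log))
    cat(sprintf("  trained %d epochs, best validation loss %.4f (epoch %d)\n",
                max(object@log$epoch), min(object@log$validationLoss),
                object@log$epoch[which.min(object@log$validationLoss)]))
})

setMethod("show", "CCClassifier", function(object) {
  cat(sprintf("CCClassifier: GRU hidden %d over %d classes, vocabulary %d\n",
              object@config$hiddenDim, length(object@classes),
              vocabSize(object@vocabulary)))
})

setMethod("show", "WordEmbeddings", function(object) {
  cat(sprintf("WordEmbeddings: %d tokens x %d dimensions (skipgram, window %d)\n",
              nrow(object@vectors), ncol(object@vectors),
              object@meta$window %||% NA_integer_))
})
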