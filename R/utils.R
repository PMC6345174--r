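`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tokenize complaint text
#'
#' Lowercases and splits on whitespace. Punctuation is deliberately kept:
#' chief complaints are terse and tokens like `"x"` (as in "pain x 3 days")
#' or embedded ICD fragments carry signal.
#'
#' @param text character vector of complaints.
#' @return list of character vectors, one per complaint.
#' @export
tokenizeText <- function(text) {
  strsplit(trimws(tolower(text)), "\\s+")
}

# deterministic integer sub-seed derived from a master seed and a stage label,
# kept below 2^31
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1103L + h) %% 2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
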