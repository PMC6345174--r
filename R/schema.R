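#' Build a discrete-variable schema
#'
#' Defines the ordered layout of the sparse binary visit vector: one
#' indicator block per variable, block length equal to the variable's
#' cardinality, blocks concatenated in the order given.
#'
#' @param name character vector of unique variable names.
#' @param cardinality integer vector of coded-value counts; variable codes
#'   run `0 .. cardinality - 1`.
#' @param multiValued logical; may a record carry several codes for this
#'   variable (e.g. discharge diagnosis)? Recycled.
#' @param missingAllowed logical; may the variable be absent (its block is
#'   then all zeros)? Recycled.
#' @return a [RecordSchema-class].
#' @examples
#' buildSchema(c("age", "gender"), c(5L, 2L))
#' @export
buildSchema <- function(name, cardinality, multiValued = FALSE,
                        missingAllowed = TRUE) {
  if (length(name) == 0L) stopf("schema needs at least one variable")
  if (length(name) != length(cardinality))
    stopf("name and cardinality differ in length")
  if (anyDuplicated(name)) stopf("duplicate variable name: %s",
                                 name[duplicated(name)][1L])
  cardinality <- as.integer(cardinality)
  if (any(is.na(cardinality) | cardinality < 1L))
    stopf("cardinality must be a positive integer for every variable")
  vars <- data.frame(name = as.character(name),
                     cardinality = cardinality,
                     multiValued = rep_len(as.logical(multiValued), length(name)),
                     missingAllowed = rep_len(as.logical(missingAllowed), length(name)),
                     stringsAsFactors = FALSE)
  new("RecordSchema", variables = vars, totalDim = sum(cardinality))
}

#' The default ED visit schema
#'
#' Nine discrete variables typical of a syndromic-surveillance ED feed:
#' 5-year age group (codes 0-22), gender (0-5), mode of arrival (0-7),
#' hospital (0-43), disposition without and with transfer (0-11, 0-7),
#' month (0-11), year (0-1), and multi-valued CCS-style discharge diagnosis
#' (0-283). The concatenated binary vector has 399 dimensions.
#'
#' @return a [RecordSchema-class] of total dimension 399.
#' @export
edVisitSchema <- function() {
  buildSchema(
    name = c("age_group", "gender", "arrival_mode", "hospital",
             "disposition", "disposition_transfer", "month", "year",
             "diagnosis"),
    cardinality = c(23L, 6L, 8L, 44L, 12L, 8L, 12L, 2L, 284L),
    multiValued = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    missingAllowed = TRUE)
}

# start offset (0-based) of each variable's block
blockOffsets <- function(schema) {
  card <- schema@variables$cardinality
  off <- cumsum(c(0L, card[-length(card)]))
  names(off) <- schema@variables$name
  off
}

# normalise one record's codes for a variable to an integer vector
# (accepts NA, integers, or ";"-separated strings)
parseCodes <- function(x) {
  if (length(x) == 0L || (length(x) == 1L && is.na(x))) return(integer(0))
  if (is.character(x)) {
    x <- trimws(unlist(strsplit(x, ";", fixed = TRUE)))
    x <- x[nzchar(x)]
    if (length(x) == 0L) return(integer(0))
    out <- suppressWarnings(as.integer(x))
    if (anyNA(out)) stopf("unparseable code '%s'", x[which(is.na(out))[1L]])
    return(out)
  }
  as.integer(x[!is.na(x)])
}

checkCodes <- function(codes, name, card, multi, missingOk) {
  if (length(codes) == 0L) {
    if (!missingOk) stopf("variable '%s' may not be missing", name)
    return(invisible(codes))
  }
  if (!multi && length(codes) > 1L)
    stopf("variable '%s' is single-valued but has %d codes", name, length(codes))
  if (any(codes < 0L | codes >= card))
    stopf("code %d out of range [0, %d] for variable '%s'",
          codes[codes < 0L | codes >= card][1L], card - 1L, name)
  invisible(codes)
}

#' Vectorize records into sparse binary visit vectors
#'
#' Each single-valued variable contributes a one-hot block, a multi-valued
#' variable a multi-hot block, and a missing variable an all-zero block; the
#' blocks are concatenated in schema order.
#'
#' @param records a record frame: `data.frame` with one column per schema
#'   variable (integer codes; multi-valued codes as `";"`-separated strings
#'   or list columns; `NA` for missing). Extra columns (e.g. `complaint`)
#'   are ignored.
#' @param schema a [RecordSchema-class].
#' @return a sparse binary matrix (`Matrix::sparseMatrix`) with one row per
#'   record and `totalDim(schema)` columns.
#' @examples
#' sc <- buildSchema(c("age", "gender"), c(5L, 2L))
#' vectorizeRecords(data.frame(age = c(4L, NA), gender = c(0L, 1L)), sc)
#' @export
vectorizeRecords <- function(records, schema) {
  v <- schema@variables
  missingCols <- setdiff(v$name, names(records))
  if (length(missingCols))
    stopf("record frame lacks schema column(s): %s",
          paste(missingCols, collapse = ", "))
  n <- nrow(records)
  off <- blockOffsets(schema)
  ri <- list(); ci <- list()
  for (k in seq_len(nrow(v))) {
    col <- records[[v$name[k]]]
    if (is.numeric(col) && !v$multiValued[k]) {
      # fast path: one (or zero) integer code per record
      codes <- as.integer(col)
      obs <- !is.na(codes)
      if (!v$missingAllowed[k] && any(!obs))
        stopf("variable '%s' may not be missing", v$name[k])
      bad <- obs & (codes < 0L | codes >= v$cardinality[k])
      if (any(bad))
        stopf("code %d out of range [0, %d] for variable '%s' (row %d)",
              codes[bad][1L], v$cardinality[k] - 1L, v$name[k], which(bad)[1L])
      ri[[k]] <- which(obs)
      ci[[k]] <- codes[obs] + off[k] + 1L
    } else {
      codes <- lapply(col, parseCodes)
      for (r in seq_len(n)) {
        ok <- try(checkCodes(codes[[r]], v$name[k], v$cardinality[k],
                             v$multiValued[k], v$missingAllowed[k]),
                  silent = TRUE)
        if (inherits(ok, "try-error"))
          stopf("row %d: %s", r, conditionMessage(attr(ok, "condition")))
      }
      lens <- lengths(codes)
      ri[[k]] <- rep.int(seq_len(n), lens)
      ci[[k]] <- unlist(codes, use.names = FALSE) + off[k] + 1L
    }
  }
  Matrix::sparseMatrix(i = unlist(ri), j = unlist(ci), x = 1,
                       dims = c(n, schema@totalDim))
}

#' @rdname vectorizeRecords
#' @param record a single-row record frame or a named list of codes.
#' @return `vectorizeRecord` returns a plain numeric 0/1 vector.
#' @export
vectorizeRecord <- function(record, schema) {
  if (!is.data.frame(record)) {
    record <- lapply(record, function(x)
      if (length(x) > 1L) paste(x, collapse = ";") else x)
    record <- as.data.frame(record, stringsAsFactors = FALSE)
  }
  as.numeric(vectorizeRecords(record, schema)[1L, ])
}

#' Decode a binary visit vector back to per-variable codes
#'
#' The inverse of [vectorizeRecord()] for complete records: every set bit is
#' mapped back to its (variable, code) pair.
#'
#' @param bits numeric/integer 0-1 vector of length `totalDim(schema)`.
#' @param schema a [RecordSchema-class].
#' @return named list of integer code vectors (empty = missing).
#' @export
devectorizeRecord <- function(bits, schema) {
  if (length(bits) != schema@totalDim)
    stopf("expected a vector of length %d, got %d", schema@totalDim, length(bits))
  v <- schema@variables
  off <- blockOffsets(schema)
  out <- vector("list", nrow(v))
  names(out) <- v$name
  for (k in seq_len(nrow(v))) {
    block <- bits[(off[k] + 1L):(off[k] + v$cardinality[k])]
    codes <- which(block != 0) - 1L
    if (!v$multiValued[k] && length(codes) > 1L)
      stopf("variable '%s' has several set bits but is single-valued", v$name[k])
    out[[k]] <- codes
  }
  out
}

# per-record membership in a stratum of a schema variable, from a record frame
recordInStratum <- function(records, schema, variable, code) {
  v <- schema@variables
  if (!variable %in% v$name) stopf("unknown variable '%s'", variable)
  card <- v$cardinality[v$name == variable]
  if (code < 0L || code >= card)
    stopf("stratum code %d out of range [0, %d] for '%s'", code, card - 1L, variable)
  col <- records[[variable]]
  vapply(col, function(x) code %in% parseCodes(x), logical(1))
}
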