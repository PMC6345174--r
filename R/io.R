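#' Read visit records from CSV or JSON-lines
#'
#' The record frame convention is one column per schema variable (integer
#' codes; multi-valued variables as `";"`-separated code strings in CSV or
#' arrays in JSON-lines; empty / `NA` / missing keys mean missing) plus a
#' `complaint` text column. Codes are validated against the schema; a
#' malformed row is reported with its row number.
#'
#' @param path file to read.
#' @param schema a [RecordSchema-class] used for validation.
#' @param format `"auto"` (by extension: `.csv` vs `.jsonl`/`.ndjson`),
#'   `"csv"` or `"jsonl"`.
#' @return a validated record frame (`data.frame`).
#' @export
readRecords <- function(path, schema, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(jsonl|ndjson)$", path)) "jsonl" else "csv"
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) {
      df <- data.frame()
    } else {
      rows <- lapply(seq_along(lines), function(i) {
        rec <- try(jsonlite::fromJSON(lines[i]), silent = TRUE)
        if (inherits(rec, "try-error"))
          stopf("line %d: unparseable JSON", i)
        lapply(rec, function(x)
          if (length(x) > 1L) paste(x, collapse = ";") else
            if (length(x) == 0L || is.null(x)) NA_character_ else as.character(x))
      })
      cols <- unique(unlist(lapply(rows, names)))
      df <- as.data.frame(
        lapply(stats::setNames(cols, cols), function(cn)
          vapply(rows, function(r) r[[cn]] %||% NA_character_, "")),
        stringsAsFactors = FALSE)
    }
  }
  if (nrow(df) == 0L) {
    warnf("empty record file: %s", path)
    return(df)
  }
  unknown <- setdiff(names(df), c(schema@variables$name, "complaint"))
  if (length(unknown))
    stopf("unknown column(s): %s", paste(unknown, collapse = ", "))
  for (nm in schema@variables$name) {
    if (!nm %in% names(df)) next
    if (!schema@variables$multiValued[schema@variables$name == nm]) {
      suppressWarnings(num <- as.integer(df[[nm]]))
      bad <- which(!is.na(df[[nm]]) & nzchar(df[[nm]]) & is.na(num))
      if (length(bad))
        stopf("row %d: unparseable code '%s' for variable '%s'",
              bad[1L], df[[nm]][bad[1L]], nm)
      num[!is.na(df[[nm]]) & !nzchar(df[[nm]])] <- NA_integer_
      df[[nm]] <- num
    } else {
      df[[nm]][!is.na(df[[nm]]) & !nzchar(df[[nm]])] <- NA_character_
    }
  }
  vectorizeRecords(df, schema)   # validation with row numbers
  df
}

#' Write visit records to CSV or JSON-lines
#'
#' @param records a record frame.
#' @param path destination file.
#' @inheritParams readRecords
#' @return `path`, invisibly.
#' @export
writeRecords <- function(records, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(jsonl|ndjson)$", path)) "jsonl" else "csv"
  if (format == "csv") {
    utils::write.csv(records, path, row.names = FALSE, quote = TRUE, na = "")
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (i in seq_len(nrow(records))) {
      row <- lapply(records[i, , drop = FALSE], function(x) x[[1L]])
      row <- row[!vapply(row, function(x) length(x) == 1L && is.na(x), logical(1))]
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' Serialize a schema to YAML and back
#'
#' @param schema a [RecordSchema-class].
#' @param path YAML file.
#' @return `writeSchema` returns `path` invisibly; `readSchema` returns the
#'   [RecordSchema-class].
#' @export
writeSchema <- function(schema, path) {
  v <- schema@variables
  yaml::write_yaml(list(variables = lapply(seq_len(nrow(v)), function(k)
    list(name = v$name[k], cardinality = v$cardinality[k],
         multiValued = v$multiValued[k], missingAllowed = v$missingAllowed[k]))),
    path)
  invisible(path)
}

#' @rdname writeSchema
#' @export
readSchema <- function(path) {
  y <- yaml::read_yaml(path)
  v <- y$variables
  buildSchema(vapply(v, `[[`, "", "name"),
              vapply(v, `[[`, 1L, "cardinality"),
              vapply(v, `[[`, TRUE, "multiValued"),
              vapply(v, `[[`, TRUE, "missingAllowed"))
}

#' Serialize a vocabulary to TSV and back
#'
#' Columns `token`, `index`, `frequency`; the min-frequency threshold is
#' kept in a `#` comment on the first line.
#'
#' @param vocabulary a [Vocabulary-class].
#' @param path TSV file.
#' @return `writeVocabulary` returns `path` invisibly; `readVocabulary` the
#'   [Vocabulary-class].
#' @export
writeVocabulary <- function(vocabulary, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# minFreq\t%d", vocabulary@minFreq), con)
  utils::write.table(
    data.frame(token = vocabulary@tokens,
               index = seq_along(vocabulary@tokens),
               frequency = vocabulary@frequencies),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVocabulary
#' @export
readVocabulary <- function(path) {
  first <- readLines(path, n = 1L)
  minFreq <- as.integer(sub("^# minFreq\t", "", first))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          quote = "", comment.char = "",
                          stringsAsFactors = FALSE)
  df <- df[order(df$index), ]
  new("Vocabulary", tokens = as.character(df$token),
      frequencies = as.integer(df$frequency), minFreq = minFreq)
}

#' Write and read a processed corpus
#'
#' A corpus is stored as three plain-text artifacts sharing a filename stem:
#' `<stem>.jsonl` (one pair per line: 0-based indices of the set record
#' bits, the token-index sequence without trailing padding, and the raw
#' text; the first line is a small header), `<stem>.vocab.tsv` and
#' `<stem>.schema.yaml`. Writing then reading reproduces the corpus
#' bit-exactly.
#'
#' @param corpus a [PairedCorpus-class].
#' @param stem path stem (no extension).
#' @return `writeCorpus` returns `stem` invisibly; `readCorpus` the
#'   [PairedCorpus-class].
#' @export
writeCorpus <- function(corpus, stem) {
  writeSchema(corpus@schema, paste0(stem, ".schema.yaml"))
  writeVocabulary(corpus@vocabulary, paste0(stem, ".vocab.tsv"))
  con <- file(paste0(stem, ".jsonl"), open = "wt")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(
    list(maxWords = corpus@maxWords, nPairs = length(corpus)),
    auto_unbox = TRUE), con)
  rec <- corpus@records
  seqs <- corpus@sequences
  txt <- corpus@rawText
  for (i in seq_len(length(corpus))) {
    s <- seqs[i, ]
    writeLines(jsonlite::toJSON(list(
      bits = I(which(rec[i, ] != 0) - 1L),
      tokens = I(s[s != 0L]),
      text = jsonlite::unbox(txt[i])), digits = NA), con)
  }
  invisible(stem)
}

#' @rdname writeCorpus
#' @export
readCorpus <- function(stem) {
  schema <- readSchema(paste0(stem, ".schema.yaml"))
  vocabulary <- readVocabulary(paste0(stem, ".vocab.tsv"))
  lines <- readLines(paste0(stem, ".jsonl"), warn = FALSE)
  header <- jsonlite::fromJSON(lines[1L])
  n <- header$nPairs
  width <- header$maxWords + 2L
  seqs <- matrix(0L, n, width)
  txt <- character(n)
  ri <- vector("list", n); ci <- vector("list", n)
  for (i in seq_len(n)) {
    p <- jsonlite::fromJSON(lines[i + 1L])
    ci[[i]] <- as.integer(p$bits) + 1L
    ri[[i]] <- rep.int(i, length(p$bits))
    tk <- as.integer(p$tokens)
    if (length(tk)) seqs[i, seq_along(tk)] <- tk
    txt[i] <- p$text
  }
  rec <- Matrix::sparseMatrix(i = unlist(ri), j = unlist(ci), x = 1,
                              dims = c(n, totalDim(schema)))
  new("PairedCorpus", records = rec, sequences = seqs, rawText = txt,
      schema = schema, vocabulary = vocabulary,
      maxWords = as.integer(header$maxWords))
}
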