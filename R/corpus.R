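#' Tokenize an utterance
#'
#' Lowercases and splits an utterance on whitespace. No stemming is applied
#' and punctuation is kept if present: transcripts of child-directed speech
#' are usually already plain lowercase word sequences, and silently merging
#' "book"/"books" would change the action space. See [normalize_token()] for
#' the optional suffix-stripping normalizer.
#'
#' @param text A single utterance string.
#' @return A character vector of word tokens; the empty string yields a
#'   zero-length vector.
#' @examples
#' tokenize_utterance("ahhah look we can read books david")
#' @export
tokenize_utterance <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- strsplit(trimws(tolower(text)), "\\s+")[[1]]
  tokens[nzchar(tokens)]
}

#' Optional plural-stripping token normalizer
#'
#' Off by default everywhere. Strips a final "s" from tokens longer than
#' three characters so that e.g. "books" and "book" compare equal as actions.
#' Word identity is otherwise exact-token; this toggle exists because
#' transcribed caregiver speech freely mixes singular and plural forms of
#' the same object name.
#'
#' @param tokens Character vector of tokens.
#' @return Character vector of normalized tokens.
#' @export
normalize_token <- function(tokens) {
  long <- nchar(tokens) > 3L & endsWith(tokens, "s") & !endsWith(tokens, "ss")
  tokens[long] <- substr(tokens[long], 1L, nchar(tokens[long]) - 1L)
  tokens
}

#' Build a situation corpus
#'
#' A corpus is a tibble with one row per learning situation: an utterance
#' (list-column of word tokens), the set of visible object labels, the single
#' jointly-attended object, and optionally one prosodic pitch-prominence
#' value per word (Hz). The ordered set of all object labels, in first
#' occurrence order, is kept as the `object_inventory` attribute.
#'
#' @param words List of character vectors, one utterance per situation.
#' @param objects List of character vectors: visible object labels.
#' @param attended Character vector: the attended object per situation.
#' @param prosody Optional list of numeric vectors aligned with `words`.
#' @return A tibble of class `xsit_corpus` with columns `id`, `words`,
#'   `objects`, `attended` and (if supplied) `prosody`.
#' @export
new_corpus <- function(words, objects, attended, prosody = NULL) {
  stopifnot(is.list(words), is.list(objects), is.character(attended))
  n <- length(words)
  stopifnot(length(objects) == n, length(attended) == n)
  corpus <- tibble::tibble(
    id = seq_len(n),
    words = lapply(words, as.character),
    objects = lapply(objects, as.character),
    attended = attended
  )
  if (!is.null(prosody)) {
    stopifnot(is.list(prosody), length(prosody) == n)
    corpus$prosody <- lapply(prosody, as.numeric)
  }
  validate_corpus(corpus)
}

#' @rdname new_corpus
#' @param corpus A data frame with the corpus columns above.
#' @export
validate_corpus <- function(corpus) {
  stopifnot(is.data.frame(corpus))
  needed <- c("id", "words", "objects", "attended")
  missing_cols <- setdiff(needed, names(corpus))
  if (length(missing_cols) > 0L) {
    stop("corpus is missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  n <- nrow(corpus)
  if (n > 0L && !identical(as.integer(corpus$id), seq_len(n))) {
    stop("situation ids must be consecutive 1..P", call. = FALSE)
  }
  for (i in seq_len(n)) {
    w <- corpus$words[[i]]
    if (length(w) < 1L) {
      stop("situation ", i, ": utterance must contain at least one word",
        call. = FALSE
      )
    }
    if (!(corpus$attended[[i]] %in% corpus$objects[[i]])) {
      stop(
        "situation ", i, ": attended object '", corpus$attended[[i]],
        "' is not among the visible objects",
        call. = FALSE
      )
    }
    if ("prosody" %in% names(corpus) && !is.null(corpus$prosody[[i]]) &&
      length(corpus$prosody[[i]]) != length(w)) {
      stop("situation ", i, ": prosody length differs from utterance length",
        call. = FALSE
      )
    }
  }
  inventory <- unique(unlist(corpus$objects, use.names = FALSE))
  structure(
    tibble::as_tibble(corpus),
    object_inventory = inventory,
    class = c("xsit_corpus", class(tibble::tibble()))
  )
}

#' Object inventory of a corpus
#'
#' @param corpus An `xsit_corpus`.
#' @return Character vector of all object labels in first-occurrence order.
#' @export
object_inventory <- function(corpus) {
  inv <- attr(corpus, "object_inventory")
  if (is.null(inv)) inv <- unique(unlist(corpus$objects, use.names = FALSE))
  inv
}

#' Read and write situation corpora
#'
#' Corpora are stored as UTF-8 JSON lines, one situation per line:
#' `{"id": 1, "utterance": [...], "objects": [...], "attended": "...",`
#' `"prosody": [...]}` with `prosody` optional. `write_corpus()` followed by
#' `read_corpus()` reproduces the corpus exactly, including full-precision
#' prosodic values.
#'
#' @param path File path.
#' @return `read_corpus()` returns an `xsit_corpus`; `write_corpus()`
#'   invisibly returns `path`.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  records <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
      error = function(e) {
        stop("line ", i, ": cannot parse corpus record (", conditionMessage(e),
          ")",
          call. = FALSE
        )
      }
    )
    for (fld in c("id", "utterance", "objects", "attended")) {
      if (is.null(rec[[fld]])) {
        stop("line ", i, ": missing field '", fld, "'", call. = FALSE)
      }
    }
    records[[i]] <- rec
  }
  has_prosody <- any(vapply(records, function(r) !is.null(r$prosody), logical(1)))
  corpus <- tibble::tibble(
    id = vapply(records, function(r) as.integer(r$id), integer(1)),
    words = lapply(records, function(r) as.character(r$utterance)),
    objects = lapply(records, function(r) as.character(r$objects)),
    attended = vapply(records, function(r) as.character(r$attended), character(1))
  )
  if (has_prosody) {
    corpus$prosody <- lapply(records, function(r) {
      if (is.null(r$prosody)) NULL else as.numeric(r$prosody)
    })
  }
  validate_corpus(corpus)
}

#' @rdname read_corpus
#' @param corpus An `xsit_corpus`.
#' @export
write_corpus <- function(corpus, path) {
  corpus <- validate_corpus(corpus)
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    rec <- list(
      id = corpus$id[[i]],
      utterance = corpus$words[[i]],
      objects = corpus$objects[[i]],
      attended = corpus$attended[[i]]
    )
    if ("prosody" %in% names(corpus) && !is.null(corpus$prosody[[i]])) {
      rec$prosody <- corpus$prosody[[i]]
    }
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Build the vocabulary of a corpus
#'
#' The vocabulary grows incrementally: scanning situations front to back,
#' each token not seen before is appended. The result is a tibble mapping
#' each distinct word type to its (1-based) action/column index.
#'
#' @param corpus An `xsit_corpus` (or any data frame with a `words`
#'   list-column).
#' @return A tibble of class `xsit_vocab` with columns `word` and `index`.
#' @export
build_vocabulary <- function(corpus) {
  tokens <- unlist(corpus$words, use.names = FALSE)
  words <- unique(tokens)
  structure(
    tibble::tibble(word = words, index = seq_along(words)),
    class = c("xsit_vocab", class(tibble::tibble()))
  )
}

#' Look up vocabulary indices for tokens
#'
#' @param vocab An `xsit_vocab`.
#' @param tokens Character vector of word tokens.
#' @return Integer vector of 1-based indices.
#' @export
vocab_index <- function(vocab, tokens) {
  idx <- match(tokens, vocab$word)
  if (anyNA(idx)) {
    stop("token(s) not in vocabulary: ",
      paste(unique(tokens[is.na(idx)]), collapse = ", "),
      call. = FALSE
    )
  }
  idx
}

#' Gold-standard lexicons
#'
#' A gold lexicon is the reference set of word-object pairs a learned lexicon
#' is scored against. Multi-referent words are permitted (one word row per
#' referent, e.g. "bird" paired with both bird and duck). On disk it is a
#' headerless two-column TSV, `word<TAB>object`.
#'
#' @param word,object Character vectors of equal length.
#' @return A tibble of class `xsit_gold` with columns `word` and `object`.
#' @export
gold_lexicon <- function(word, object) {
  stopifnot(length(word) == length(object), length(word) >= 1L)
  pairs <- dplyr::distinct(tibble::tibble(
    word = as.character(word),
    object = as.character(object)
  ))
  structure(pairs, class = c("xsit_gold", class(tibble::tibble())))
}

#' @rdname gold_lexicon
#' @param path File path.
#' @export
read_gold_lexicon <- function(path) {
  rows <- readr::read_tsv(path,
    col_names = c("word", "object"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(rows) == 0L || anyNA(rows$word) || anyNA(rows$object)) {
    stop("malformed gold lexicon: every row needs word<TAB>object",
      call. = FALSE
    )
  }
  gold_lexicon(rows$word, rows$object)
}

#' @rdname gold_lexicon
#' @param gold An `xsit_gold`.
#' @export
write_gold_lexicon <- function(gold, path) {
  readr::write_tsv(gold[, c("word", "object")], path, col_names = FALSE)
  invisible(path)
}

#' @rdname gold_lexicon
#' @export
gold_words <- function(gold) unique(gold$word)
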