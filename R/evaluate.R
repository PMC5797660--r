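#' Extract the word-object matrix from a fit
#'
#' @param x An `xsit_fit` (tabular, neural, or co-occurrence baseline) or a
#'   plain objects x words matrix.
#' @return Numeric matrix, objects as rows, word tokens as columns.
#' @export
qw_matrix <- function(x) {
  if (is.matrix(x)) {
    return(x)
  }
  if (!is.null(x$QW)) {
    return(x$QW)
  }
  stop("cannot extract a word-object matrix from this object", call. = FALSE)
}

#' Row-normalize a word-object matrix
#'
#' Divides each object's row by its own maximum, so every object's best
#' word scores exactly 1 and values are comparable across objects. All-zero
#' rows stay all-zero.
#'
#' @param qw An `xsit_fit` or objects x words matrix.
#' @return The normalized matrix (same shape and dimnames).
#' @export
normalize_qw <- function(qw) {
  values <- qw_matrix(qw)
  mx <- apply(values, 1L, max)
  scale <- ifelse(mx == 0, 1, mx)
  values / scale
}

#' Confusion matrix of gold words against all objects
#'
#' One row per gold-standard word, one column per object, holding that
#' word's column of the row-normalized word-object matrix. Visualizes which
#' objects compete for each gold word.
#'
#' @param nqw A normalized objects x words matrix (see [normalize_qw()]).
#' @param gold An `xsit_gold`.
#' @param vocab An `xsit_vocab`.
#' @return Numeric matrix, `length(gold_words(gold))` x `nrow(nqw)`.
#' @export
confusion_matrix <- function(nqw, gold, vocab) {
  words <- gold_words(gold)
  missing_words <- setdiff(words, vocab$word)
  if (length(missing_words) > 0L) {
    stop("gold word(s) not in vocabulary: ",
      paste(missing_words, collapse = ", "),
      call. = FALSE
    )
  }
  cm <- t(nqw[, vocab_index(vocab, words), drop = FALSE])
  rownames(cm) <- words
  colnames(cm) <- rownames(nqw)
  cm
}

#' Select each word's referent object
#'
#' For each word, the object whose row-normalized value for that word is
#' maximal (ties broken toward the first object row).
#'
#' @param nqw A normalized objects x words matrix.
#' @param words Character vector of words to resolve.
#' @param vocab An `xsit_vocab`.
#' @return A tibble with columns `word`, `object`, `value`.
#' @export
select_referent <- function(nqw, words, vocab) {
  idx <- vocab_index(vocab, words)
  rows <- vapply(idx, function(j) which.max(nqw[, j]), integer(1))
  tibble::tibble(
    word = words,
    object = rownames(nqw)[rows],
    value = nqw[cbind(rows, idx)]
  )
}

#' Threshold a normalized word-object matrix into a lexicon
#'
#' Keeps every (word, object) pair whose normalized value is at least
#' `threshold` (inclusive).
#'
#' @param nqw A normalized objects x words matrix.
#' @param threshold Real threshold.
#' @return A tibble with columns `word`, `object`, `value`.
#' @export
extract_lexicon <- function(nqw, threshold) {
  keep <- which(nqw >= threshold, arr.ind = TRUE)
  out <- tibble::tibble(
    word = colnames(nqw)[keep[, "col"]],
    object = rownames(nqw)[keep[, "row"]],
    value = nqw[keep]
  )
  dplyr::arrange(out, .data$word, .data$object)
}

#' Score a lexicon against the gold standard
#'
#' Precision is the fraction of predicted pairs that are gold pairs, recall
#' the fraction of gold pairs predicted, and F the harmonic mean. Pairs -
#' not words - are counted, so a multi-referent gold word contributes one
#' unit per referent; `recall_denominator = "words"` instead counts a gold
#' word as recalled when any of its pairs is predicted.
#'
#' @param lexicon A data frame with `word` and `object` columns.
#' @param gold An `xsit_gold`.
#' @param threshold Optional threshold to record alongside the scores.
#' @param recall_denominator `"pairs"` (default) or `"words"`.
#' @return A one-row tibble: `threshold`, `precision`, `recall`, `f_score`,
#'   `n_lexicon`, `n_correct`.
#' @export
score_lexicon <- function(lexicon, gold, threshold = NA_real_,
                          recall_denominator = c("pairs", "words")) {
  recall_denominator <- match.arg(recall_denominator)
  pred <- unique(paste(lexicon$word, lexicon$object, sep = "\r"))
  ref <- unique(paste(gold$word, gold$object, sep = "\r"))
  hits <- intersect(pred, ref)
  precision <- if (length(pred) == 0L) 0 else length(hits) / length(pred)
  recall <- if (recall_denominator == "pairs") {
    length(hits) / length(ref)
  } else {
    hit_words <- unique(sub("\r.*$", "", hits))
    length(hit_words) / length(gold_words(gold))
  }
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  tibble::tibble(
    threshold = threshold, precision = precision, recall = recall,
    f_score = f, n_lexicon = length(pred), n_correct = length(hits)
  )
}

#' Sweep lexicon thresholds and find the best F-score
#'
#' Extracts and scores a lexicon at every threshold. Recall is
#' non-increasing in the threshold; the best row maximizes F-score, ties
#' broken toward the lowest threshold.
#'
#' @param nqw A normalized objects x words matrix (or an `xsit_fit`, which
#'   is normalized first).
#' @param gold An `xsit_gold`.
#' @param thresholds Increasing numeric vector (default 0, 0.01, ..., 1).
#' @param recall_denominator Passed to [score_lexicon()].
#' @return A tibble of class `xsit_sweep`, one row per threshold, with the
#'   best row available via [best_scores()].
#' @export
threshold_sweep <- function(nqw, gold, thresholds = seq(0, 1, by = 0.01),
                            recall_denominator = c("pairs", "words")) {
  stopifnot(length(thresholds) >= 1L)
  recall_denominator <- match.arg(recall_denominator)
  if (!is.matrix(nqw)) nqw <- normalize_qw(nqw)
  thresholds <- sort(thresholds)
  curve <- purrr::map_dfr(thresholds, function(th) {
    score_lexicon(extract_lexicon(nqw, th), gold,
      threshold = th,
      recall_denominator = recall_denominator
    )
  })
  best <- which.max(curve$f_score) # which.max takes the first (lowest) tie
  structure(
    curve,
    best = curve[best, ],
    class = c("xsit_sweep", class(tibble::tibble()))
  )
}

#' @rdname threshold_sweep
#' @param sweep An `xsit_sweep`.
#' @export
best_scores <- function(sweep) attr(sweep, "best")

#' Co-occurrence baseline
#'
#' The association baseline: entry (object, word) counts the situations in
#' which the word occurs in the utterance while the object is attended
#' (or, with `count = "visible"`, merely visible). The result feeds the
#' same normalize/sweep pipeline as the learned matrices.
#'
#' @param corpus An `xsit_corpus`.
#' @param vocab An `xsit_vocab`.
#' @param count `"attended"` (default) or `"visible"`.
#' @return An object of class `c("xsit_cooc", "xsit_fit")` with a `QW`
#'   count matrix.
#' @export
cooc_baseline <- function(corpus, vocab = build_vocabulary(corpus),
                          count = c("attended", "visible")) {
  count <- match.arg(count)
  corpus <- validate_corpus(corpus)
  objects <- object_inventory(corpus)
  qw <- matrix(0,
    nrow = length(objects), ncol = nrow(vocab),
    dimnames = list(objects, vocab$word)
  )
  for (i in seq_len(nrow(corpus))) {
    widx <- vocab_index(vocab, unique(corpus$words[[i]]))
    rows <- if (count == "attended") {
      corpus$attended[[i]]
    } else {
      corpus$objects[[i]]
    }
    qw[rows, widx] <- qw[rows, widx] + 1
  }
  structure(
    list(
      algorithm = "cooc", QW = qw,
      counts = table(factor(corpus$attended, levels = objects)),
      vocab = vocab, objects = objects
    ),
    class = c("xsit_cooc", "xsit_fit")
  )
}

#' Referent-selection accuracy against a planted or gold lexicon
#'
#' The fraction of gold words whose [select_referent()] object matches a
#' gold referent of that word.
#'
#' @param fit An `xsit_fit` (or normalized matrix).
#' @param gold An `xsit_gold`.
#' @param vocab An `xsit_vocab`; taken from the fit when available.
#' @return A single number in \[0, 1\].
#' @export
referent_accuracy <- function(fit, gold, vocab = fit$vocab) {
  nqw <- if (is.matrix(fit)) fit else normalize_qw(fit)
  sel <- select_referent(nqw, gold_words(gold), vocab)
  ok <- vapply(seq_len(nrow(sel)), function(k) {
    sel$object[[k]] %in% gold$object[gold$word == sel$word[[k]]]
  }, logical(1))
  mean(ok)
}
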