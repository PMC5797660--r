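#' Binary bag-of-words state encoding
#'
#' Encodes an utterance as a binary vector over the vocabulary: 1 at the
#' index of every word type present, 0 elsewhere. Repeated tokens still
#' yield a single 1. This is the "attentional" input representation for all
#' learners.
#'
#' @param words Character vector of utterance tokens (or a one-row corpus
#'   slice, from which `words[[1]]` is taken).
#' @param vocab An `xsit_vocab` covering all tokens.
#' @return Numeric vector of length `nrow(vocab)`.
#' @export
encode_binary <- function(words, vocab) {
  words <- situation_tokens(words)
  v <- numeric(nrow(vocab))
  v[vocab_index(vocab, unique(words))] <- 1
  v
}

#' 75th-percentile of a pitch track
#'
#' Linear interpolation between closest order statistics
#' (`stats::quantile(type = 7)`); the convention is fixed here so prosodic
#' features are reproducible across platforms.
#'
#' @param values Non-empty numeric vector.
#' @return The 75th percentile.
#' @export
percentile75 <- function(values) {
  if (length(values) == 0L) stop("percentile75: empty sequence", call. = FALSE)
  unname(stats::quantile(values, probs = 0.75, type = 7, names = FALSE))
}

#' Prosodic prominence feature of a word within its utterance
#'
#' The difference between the 75th-percentile pitch of the word and of the
#' whole utterance (Hz). Words prosodically highlighted by the caregiver
#' (typically the one naming the attended object) score high; adding a
#' constant to both tracks leaves the feature unchanged.
#'
#' @param word_pitch Non-empty numeric pitch track of the word.
#' @param utterance_pitch Non-empty numeric pitch track of the utterance.
#' @return A single numeric feature value.
#' @export
prosodic_feature <- function(word_pitch, utterance_pitch) {
  if (length(word_pitch) == 0L || length(utterance_pitch) == 0L) {
    stop("prosodic_feature: empty pitch track", call. = FALSE)
  }
  percentile75(word_pitch) - percentile75(utterance_pitch)
}

#' Prosodic state encoding
#'
#' Encodes an utterance as a real vector over the vocabulary: at each
#' present word's index the word's prosodic prominence value, 0 elsewhere.
#' If a word occurs more than once with distinct prosody, the maximum value
#' is kept (prominence is the signal of interest). This is the
#' "attentional-prosodic" input representation.
#'
#' @param words Character vector of utterance tokens (or a one-row corpus
#'   slice).
#' @param prosody Numeric vector of per-word prominence values, same length
#'   as `words`; taken from the corpus row when `words` is a slice.
#' @param vocab An `xsit_vocab` covering all tokens.
#' @return Numeric vector of length `nrow(vocab)`.
#' @export
encode_prosodic <- function(words, prosody = NULL, vocab) {
  if (is.data.frame(words) && is.null(prosody)) {
    prosody <- if ("prosody" %in% names(words)) words$prosody[[1]] else NULL
  }
  words <- situation_tokens(words)
  if (is.null(prosody)) {
    stop(
      "no prosody available for this situation; ",
      "use the binary encoding instead",
      call. = FALSE
    )
  }
  stopifnot(length(prosody) == length(words))
  v <- numeric(nrow(vocab))
  idx <- vocab_index(vocab, words)
  agg <- tapply(prosody, idx, max) # max over occurrences, negatives included
  v[as.integer(names(agg))] <- as.numeric(agg)
  v
}

situation_tokens <- function(words) {
  if (is.data.frame(words)) {
    stopifnot(nrow(words) == 1L)
    return(words$words[[1]])
  }
  as.character(words)
}
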