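#' Reward configuration for attended-object transitions
#'
#' The agent's internal reward encodes the novel-name-nameless-category
#' constraint across consecutive situations: choosing the *same* word while
#' attention stays on the *same* object, or a *different* word when
#' attention moves to a *different* object, is consistent and rewarded;
#' anything else is punished. The executable pseudocode uses magnitudes
#' (100, -1); `unit_mode` switches to the didactic (1, -1) pair.
#'
#' @param r_match Reward for a consistent transition (default 100).
#' @param r_mismatch Reward for an inconsistent transition (default -1).
#' @param unit_mode If `TRUE`, use (1, -1) regardless of the magnitudes.
#' @return A list of class `xsit_reward_config`.
#' @export
reward_config <- function(r_match = 100, r_mismatch = -1, unit_mode = FALSE) {
  if (isTRUE(unit_mode)) {
    r_match <- 1
    r_mismatch <- -1
  }
  stopifnot(r_match > r_mismatch)
  structure(
    list(r_match = r_match, r_mismatch = r_mismatch, unit_mode = isTRUE(unit_mode)),
    class = "xsit_reward_config"
  )
}

#' Candidate actions of a situation
#'
#' The agent's actions are internal word choices: one candidate per distinct
#' word type in the current utterance. A seven-word utterance with no
#' repeats yields seven candidate actions.
#'
#' @param words Character vector of utterance tokens (or a one-row corpus
#'   slice).
#' @param vocab An `xsit_vocab` covering the tokens.
#' @return Integer vector of vocabulary indices (1-based), in utterance
#'   order, duplicates removed.
#' @export
action_space <- function(words, vocab) {
  words <- situation_tokens(words)
  vocab_index(vocab, unique(words))
}

#' Transition reward from consecutive attended objects and word choices
#'
#' @param prev_attended,curr_attended Attended object labels of the two
#'   consecutive situations.
#' @param prev_word,curr_word The agent's chosen word (vocabulary index or
#'   token) in each situation; compared by word-type equality.
#' @param cfg A [reward_config()].
#' @return `cfg$r_match` when (same object and same word) or (different
#'   object and different word); `cfg$r_mismatch` otherwise.
#' @export
compute_reward <- function(prev_attended, prev_word, curr_attended, curr_word,
                           cfg = reward_config()) {
  same_object <- isTRUE(as.character(prev_attended) == as.character(curr_attended))
  same_word <- isTRUE(prev_word == curr_word)
  if (same_object == same_word) cfg$r_match else cfg$r_mismatch
}

#' Discounted return of a reward sequence
#'
#' `sum(gamma^(j - 1) * rewards[j])`: the future discounted reward from the
#' first element of `rewards` onwards.
#'
#' @param rewards Non-empty numeric vector, in temporal order.
#' @param gamma Discount factor in \[0, 1\].
#' @return A single number.
#' @export
discounted_return <- function(rewards, gamma) {
  stopifnot(length(rewards) >= 1L, gamma >= 0, gamma <= 1)
  sum(gamma^(seq_along(rewards) - 1) * rewards)
}

#' Run one interaction episode under a fixed policy
#'
#' Sequences the corpus in order; at each consecutive situation pair the
#' policy chooses a word in each utterance and the transition is scored by
#' [compute_reward()]. The first situation has no predecessor, so a corpus
#' of P situations yields P - 1 transitions.
#'
#' @param corpus An `xsit_corpus`.
#' @param vocab An `xsit_vocab` covering all tokens.
#' @param policy `function(candidates, situation)` returning one vocabulary
#'   index from `candidates`.
#' @param cfg A [reward_config()].
#' @return A list with `transitions` (a tibble with columns `step`,
#'   `attended`, `action`, `next_attended`, `next_action`, `reward`) and
#'   `total_reward`.
#' @export
run_episode <- function(corpus, vocab, policy, cfg = reward_config()) {
  p <- nrow(corpus)
  cands <- lapply(seq_len(p), function(i) action_space(corpus$words[[i]], vocab))
  actions <- vapply(
    seq_len(p),
    function(i) as.integer(policy(cands[[i]], corpus[i, ])),
    integer(1)
  )
  if (p < 2L) {
    return(list(
      transitions = tibble::tibble(
        step = integer(), attended = character(), action = integer(),
        next_attended = character(), next_action = integer(), reward = numeric()
      ),
      total_reward = 0
    ))
  }
  i <- seq_len(p - 1L)
  rewards <- vapply(i, function(k) {
    compute_reward(
      corpus$attended[[k]], actions[[k]],
      corpus$attended[[k + 1L]], actions[[k + 1L]], cfg
    )
  }, numeric(1))
  list(
    transitions = tibble::tibble(
      step = i,
      attended = corpus$attended[i],
      action = actions[i],
      next_attended = corpus$attended[i + 1L],
      next_action = actions[i + 1L],
      reward = rewards
    ),
    total_reward = sum(rewards)
  )
}
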