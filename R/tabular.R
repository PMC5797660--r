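#' Hyperparameters for the tabular learners
#'
#' Defaults follow the empirical settings used throughout: learning rate
#' 0.001, discount 0.99, exploration 0.99 (held fixed for tabular learners;
#' annealing is a neural-learner feature), trace decay 0.9 for
#' SARSA-lambda, 10,000 episodes.
#'
#' @param alpha Learning rate (> 0).
#' @param gamma Discount factor in \[0, 1\].
#' @param epsilon Exploration probability in \[0, 1\], fixed across episodes.
#' @param lambda Eligibility-trace decay in \[0, 1\] (SARSA-lambda only).
#' @param episodes Number of full in-order passes over the corpus.
#' @param seed RNG seed (table initialization and action selection).
#' @return A list of class `xsit_tabular_params`.
#' @export
tabular_params <- function(alpha = 0.001, gamma = 0.99, epsilon = 0.99,
                           lambda = 0.9, episodes = 10000L, seed = 1L) {
  stopifnot(
    alpha > 0, gamma >= 0, gamma <= 1, epsilon >= 0, epsilon <= 1,
    lambda >= 0, lambda <= 1, episodes >= 0
  )
  structure(
    list(
      alpha = alpha, gamma = gamma, epsilon = epsilon, lambda = lambda,
      episodes = as.integer(episodes), seed = as.integer(seed)
    ),
    class = "xsit_tabular_params"
  )
}

#' Epsilon-greedy action selection over a candidate set
#'
#' With probability `epsilon` a uniform draw from `candidates`; otherwise
#' the candidate maximizing `q_row`, ties broken toward the lowest index so
#' greedy selection is deterministic.
#'
#' @param q_row Numeric vector of action values (full vocabulary row).
#' @param candidates Non-empty integer vector of admissible word indices.
#' @param epsilon Exploration probability in \[0, 1\].
#' @return One element of `candidates`.
#' @export
epsilon_greedy <- function(q_row, candidates, epsilon) {
  if (length(candidates) == 0L) {
    stop("epsilon_greedy: empty candidate set", call. = FALSE)
  }
  if (epsilon > 0 && stats::runif(1) < epsilon) {
    return(candidates[sample.int(length(candidates), 1L)])
  }
  candidates[which.max(q_row[candidates])]
}

greedy_action <- function(q_row, candidates) {
  candidates[which.max(q_row[candidates])]
}

#' One-step temporal-difference updates
#'
#' `q_learning_update()` applies
#' `Q(s,a) <- Q(s,a) + alpha * (r + gamma * max_a' Q(s',a') - Q(s,a))`
#' with the maximum restricted to the next situation's candidate words;
#' `sarsa_update()` bootstraps on the actually-chosen next action instead.
#' Exactly one entry of the table changes.
#'
#' @param Q Numeric matrix, situations x vocabulary.
#' @param s,s_next Situation (row) indices.
#' @param a,a_next Word (column) indices.
#' @param r Reward.
#' @param next_candidates Integer vector of the next utterance's candidate
#'   word indices (Q-learning only).
#' @param params A [tabular_params()].
#' @return The updated matrix.
#' @export
q_learning_update <- function(Q, s, a, r, s_next, next_candidates, params) {
  target <- r + params$gamma * max(Q[s_next, next_candidates])
  Q[s, a] <- Q[s, a] + params$alpha * (target - Q[s, a])
  Q
}

#' @rdname q_learning_update
#' @export
sarsa_update <- function(Q, s, a, r, s_next, a_next, params) {
  target <- r + params$gamma * Q[s_next, a_next]
  Q[s, a] <- Q[s, a] + params$alpha * (target - Q[s, a])
  Q
}

#' SARSA-lambda update with replacing eligibility traces
#'
#' Computes the temporal-difference error
#' `delta = r + gamma * Q(s',a') - Q(s,a)` once, sets the current pair's
#' trace to 1 (replacing traces), updates *every* entry by
#' `alpha * delta * e`, then decays all traces by `gamma * lambda`. With
#' `lambda = 0` the realized increments coincide with plain SARSA.
#'
#' @inheritParams q_learning_update
#' @param e Numeric trace matrix, same shape as `Q`, all zeros at episode
#'   start.
#' @return A list with updated `Q` and `e`.
#' @export
sarsa_lambda_update <- function(Q, e, s, a, r, s_next, a_next, params) {
  delta <- r + params$gamma * Q[s_next, a_next] - Q[s, a]
  e[s, a] <- 1
  Q <- Q + params$alpha * delta * e
  e <- e * (params$gamma * params$lambda)
  list(Q = Q, e = e)
}

#' Word-object value matrix built as running means
#'
#' The lexicon readout: an objects x words matrix where row j is the
#' arithmetic mean of all value vectors contributed while object j was
#' attended, with a per-object visit count.
#'
#' @param objects Character vector of object labels (rows).
#' @param words Character vector of word tokens (columns).
#' @return A list of class `xsit_qw` with `values` and `counts`.
#' @export
new_qwmatrix <- function(objects, words) {
  values <- matrix(0, nrow = length(objects), ncol = length(words),
    dimnames = list(objects, words)
  )
  structure(
    list(values = values, counts = stats::setNames(integer(length(objects)), objects)),
    class = "xsit_qw"
  )
}

#' @rdname new_qwmatrix
#' @param qw An `xsit_qw`.
#' @param attended Attended object label.
#' @param contribution Numeric vector of length `ncol(qw$values)`.
#' @export
update_qw <- function(qw, attended, contribution) {
  j <- match(attended, rownames(qw$values))
  if (is.na(j)) {
    stop("update_qw: unknown object label '", attended, "'", call. = FALSE)
  }
  qw$counts[[j]] <- qw$counts[[j]] + 1L
  qw$values[j, ] <- qw$values[j, ] +
    (contribution - qw$values[j, ]) / qw$counts[[j]]
  qw
}

#' Train a tabular learner on a situation corpus
#'
#' Runs Q-learning, SARSA, or SARSA-lambda over a situations x vocabulary
#' value table for `params$episodes` full in-order passes. Action selection
#' is epsilon-greedy over each utterance's candidate words with epsilon held
#' fixed; the Q table is initialized uniform random in \[0, 1) under the run
#' seed; the word-object matrix `QW` accumulates, for every visited
#' situation, the state's value row masked to the utterance's words, folded
#' into the attended object's running mean. The whole run is deterministic
#' under `params$seed`.
#'
#' @param corpus An `xsit_corpus`.
#' @param vocab An `xsit_vocab`; defaults to [build_vocabulary()] of the
#'   corpus.
#' @param algorithm `"qlearn"`, `"sarsa"`, or `"sarsa_lambda"`.
#' @param params A [tabular_params()].
#' @param reward_cfg A [reward_config()].
#' @return An object of class `c("xsit_tabular", "xsit_fit")` with elements
#'   `Q` (situations x words), `QW` (objects x words), `counts`,
#'   `reward_history` (one total per episode), `vocab`, `objects`,
#'   `algorithm`, `params`, `reward_cfg`.
#' @export
train_tabular <- function(corpus, vocab = build_vocabulary(corpus),
                          algorithm = c("qlearn", "sarsa", "sarsa_lambda"),
                          params = tabular_params(),
                          reward_cfg = reward_config()) {
  algorithm <- match.arg(algorithm)
  corpus <- validate_corpus(corpus)
  withr::with_seed(
    params$seed,
    train_tabular_impl(corpus, vocab, algorithm, params, reward_cfg)
  )
}

train_tabular_impl <- function(corpus, vocab, algorithm, params, reward_cfg) {
  p <- nrow(corpus)
  n <- nrow(vocab)
  objects <- object_inventory(corpus)
  cands <- lapply(corpus$words, function(w) vocab_index(vocab, unique(w)))
  attended <- corpus$attended

  Q <- matrix(stats::runif(p * n), nrow = p, ncol = n)
  qw <- new_qwmatrix(objects, vocab$word)
  history <- numeric(params$episodes)
  use_traces <- algorithm == "sarsa_lambda"
  on_policy <- algorithm %in% c("sarsa", "sarsa_lambda")

  for (ep in seq_len(params$episodes)) {
    total <- 0
    if (use_traces) e <- matrix(0, nrow = p, ncol = n)
    a <- if (p >= 1L) epsilon_greedy(Q[1L, ], cands[[1L]], params$epsilon)
    if (p >= 2L) {
      for (i in seq_len(p - 1L)) {
        nxt <- i + 1L
        a_next <- if (on_policy) {
          epsilon_greedy(Q[nxt, ], cands[[nxt]], params$epsilon)
        } else {
          greedy_action(Q[nxt, ], cands[[nxt]])
        }
        r <- compute_reward(attended[[i]], a, attended[[nxt]], a_next, reward_cfg)
        total <- total + r
        if (algorithm == "qlearn") {
          Q <- q_learning_update(Q, i, a, r, nxt, cands[[nxt]], params)
        } else if (algorithm == "sarsa") {
          Q <- sarsa_update(Q, i, a, r, nxt, a_next, params)
        } else {
          upd <- sarsa_lambda_update(Q, e, i, a, r, nxt, a_next, params)
          Q <- upd$Q
          e <- upd$e
        }
        contribution <- numeric(n)
        contribution[cands[[i]]] <- Q[i, cands[[i]]]
        qw <- update_qw(qw, attended[[i]], contribution)
        a <- if (on_policy) {
          a_next
        } else {
          epsilon_greedy(Q[nxt, ], cands[[nxt]], params$epsilon)
        }
      }
    }
    history[[ep]] <- total
  }

  structure(
    list(
      algorithm = algorithm, Q = Q, QW = qw$values, counts = qw$counts,
      reward_history = history, vocab = vocab, objects = objects,
      params = params, reward_cfg = reward_cfg
    ),
    class = c("xsit_tabular", "xsit_fit")
  )
}
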