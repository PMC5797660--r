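#' Hyperparameters for the neural learners
#'
#' Defaults follow the empirical settings used throughout: learning rate
#' 0.001, discount 0.99, epsilon annealed linearly from 0.99 to 0.0001 over
#' the configured episodes and held there, two hidden layers of 200 sigmoid
#' units with a softmax output head, replay capacity 50, minibatch 10,
#' target-network sync every 4 steps. The weight-initialization half-range
#' defaults to 0.01: symmetric near-zero starts keep the sigmoids in their
#' responsive region.
#'
#' @param alpha Learning rate (> 0).
#' @param gamma Discount factor in \[0, 1\].
#' @param epsilon_start,epsilon_end Linear annealing schedule endpoints.
#' @param H Hidden units per hidden layer.
#' @param J Replay/storage capacity (NFQ and DQN).
#' @param minibatch DQN minibatch size (<= J).
#' @param C Target-network sync period in gradient steps (DQN).
#' @param episodes Number of full in-order passes over the corpus; also the
#'   annealing horizon.
#' @param seed RNG seed.
#' @param init_scale Weights drawn uniform in \[-init_scale, init_scale\].
#' @param anneal_episodes Annealing horizon; defaults to `episodes`.
#' @param double_dqn Use the strict double estimator (online-network argmax
#'   evaluated under the target network) instead of the target-network max.
#' @return A list of class `xsit_neural_params`.
#' @export
neural_params <- function(alpha = 0.001, gamma = 0.99,
                          epsilon_start = 0.99, epsilon_end = 0.0001,
                          H = 200L, J = 50L, minibatch = 10L, C = 4L,
                          episodes = 300L, seed = 1L, init_scale = 0.01,
                          anneal_episodes = episodes, double_dqn = FALSE) {
  stopifnot(
    alpha >= 0, gamma >= 0, gamma <= 1,
    epsilon_start >= 0, epsilon_start <= 1,
    epsilon_end >= 0, epsilon_end <= 1,
    H >= 1, J >= 1, minibatch >= 1, minibatch <= J, C >= 1,
    episodes >= 0, init_scale >= 0
  )
  structure(
    list(
      alpha = alpha, gamma = gamma,
      epsilon_start = epsilon_start, epsilon_end = epsilon_end,
      H = as.integer(H), J = as.integer(J), minibatch = as.integer(minibatch),
      C = as.integer(C), episodes = as.integer(episodes),
      seed = as.integer(seed), init_scale = init_scale,
      anneal_episodes = as.integer(anneal_episodes),
      double_dqn = isTRUE(double_dqn)
    ),
    class = "xsit_neural_params"
  )
}

#' Linearly annealed exploration rate
#'
#' Linear from `epsilon_start` at episode 1 to `epsilon_end` at episode
#' `anneal_episodes`, clamped at `epsilon_end` thereafter.
#'
#' @param episode Episode ordinal (>= 1).
#' @param params A [neural_params()].
#' @return The exploration probability for that episode.
#' @export
anneal_epsilon <- function(episode, params) {
  stopifnot(episode >= 1)
  horizon <- max(params$anneal_episodes, 1L)
  if (episode >= horizon) {
    if (episode == 1L) {
      return(params$epsilon_start)
    }
    return(params$epsilon_end)
  }
  params$epsilon_start +
    (episode - 1) / (horizon - 1) * (params$epsilon_end - params$epsilon_start)
}

#' Initialize a Q-network
#'
#' A four-layer perceptron N -> H -> H -> N: two sigmoid hidden layers and a
#' softmax output head, so the network concentrates value on one word per
#' utterance. Weights and biases are drawn uniform in
#' \[-init_scale, init_scale\] from the current RNG state.
#'
#' @param N Input/output dimension (vocabulary size).
#' @param params A [neural_params()].
#' @return A list of class `xsit_qnetwork` with weight matrices `W1`
#'   (N x H), `W2` (H x H), `W3` (H x N) and bias vectors `b1`, `b2`, `b3`.
#' @export
init_network <- function(N, params = neural_params()) {
  stopifnot(N >= 1)
  H <- params$H
  s <- params$init_scale
  runif_mat <- function(nr, nc) {
    matrix(stats::runif(nr * nc, -s, s), nrow = nr, ncol = nc)
  }
  structure(
    list(
      W1 = runif_mat(N, H), b1 = stats::runif(H, -s, s),
      W2 = runif_mat(H, H), b2 = stats::runif(H, -s, s),
      W3 = runif_mat(H, N), b3 = stats::runif(N, -s, s),
      N = as.integer(N), H = as.integer(H)
    ),
    class = "xsit_qnetwork"
  )
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  ez <- exp(z)
  ez / rowSums(ez)
}

# states: list of list(idx = integer, val = numeric) sparse input vectors.
# Layer 1 exploits utterance sparsity: an utterance touches only a handful
# of vocabulary rows of W1.
sparse_layer1 <- function(net, states) {
  B <- length(states)
  W1 <- net$W1
  Z1 <- matrix(net$b1, nrow = B, ncol = net$H, byrow = TRUE)
  for (b in seq_len(B)) {
    s <- states[[b]]
    if (length(s$idx) > 0L) {
      Z1[b, ] <- Z1[b, ] + crossprod(W1[s$idx, , drop = FALSE], s$val)
    }
  }
  Z1
}

# The softmax head normalizes over each state's candidate words - the
# utterance's word types, the only admissible actions - so the network
# assigns high value to one word per utterance. Off-candidate entries are 0.
# `masks` defaults to each sparse state's support.
forward_batch <- function(net, states, masks = NULL) {
  if (is.null(masks)) masks <- lapply(states, `[[`, "idx")
  A1 <- sigmoid(sparse_layer1(net, states))
  A2 <- sigmoid(A1 %*% net$W2 + rep(net$b2, each = nrow(A1)))
  Z3 <- A2 %*% net$W3 + rep(net$b3, each = nrow(A1))
  Q <- matrix(0, nrow = nrow(Z3), ncol = ncol(Z3))
  for (b in seq_len(nrow(Z3))) {
    mask <- masks[[b]]
    if (length(mask) == 0L) mask <- seq_len(ncol(Z3))
    z <- Z3[b, mask]
    ez <- exp(z - max(z))
    Q[b, mask] <- ez / sum(ez)
  }
  list(A1 = A1, A2 = A2, Q = Q)
}

# single-state forward, avoiding batch-path allocations
forward_one <- function(net, s, mask = s$idx) {
  z1 <- if (length(s$idx) > 0L) {
    drop(crossprod(net$W1[s$idx, , drop = FALSE], s$val)) + net$b1
  } else {
    net$b1
  }
  a1 <- 1 / (1 + exp(-z1))
  a2 <- 1 / (1 + exp(-(drop(crossprod(net$W2, a1)) + net$b2)))
  z3 <- drop(crossprod(net$W3, a2)) + net$b3
  if (length(mask) == 0L) mask <- seq_along(z3)
  zm <- z3[mask]
  ez <- exp(zm - max(zm))
  q <- numeric(net$N)
  q[mask] <- ez / sum(ez)
  q
}

as_sparse_state <- function(state) {
  if (is.list(state) && !is.null(state$idx)) {
    return(list(idx = as.integer(state$idx), val = as.numeric(state$val)))
  }
  idx <- which(state != 0)
  list(idx = idx, val = as.numeric(state[idx]))
}

#' Forward pass of a Q-network
#'
#' The softmax head normalizes over the state's candidate words - by
#' default the nonzero support of the encoding, i.e. the utterance's word
#' types, which are the only admissible actions - so value concentrates on
#' one word per utterance. Entries outside the candidate set are 0. A state
#' with no nonzero entry (or an explicit full-range `candidates`) falls
#' back to the whole vocabulary.
#'
#' @param net An `xsit_qnetwork`.
#' @param state Numeric state vector of length `net$N` (a binary or
#'   prosodic utterance encoding).
#' @param candidates Optional integer indices overriding the softmax
#'   support.
#' @return Value vector of length `net$N`: positive on the candidate set,
#'   summing to 1, zero elsewhere.
#' @export
forward <- function(net, state, candidates = NULL) {
  if (!is.list(state) && length(state) != net$N) {
    stop("forward: state has length ", length(state), ", expected ", net$N,
      call. = FALSE
    )
  }
  sp <- as_sparse_state(state)
  masks <- if (is.null(candidates)) NULL else list(as.integer(candidates))
  drop(forward_batch(net, list(sp), masks)$Q)
}

# One gradient-descent step on the mean squared error, over the batch, of
# the chosen actions' outputs against constant targets. The loss gradient
# enters only through each chosen action's softmax output; the other
# outputs feel it via the softmax coupling. Layer-1 updates touch only the
# vocabulary rows present in each state.
qnet_grad_step <- function(net, states, actions, targets, alpha, masks = NULL) {
  B <- length(states)
  fwd <- forward_batch(net, states, masks)
  qa <- fwd$Q[cbind(seq_len(B), actions)]
  g <- -2 * (targets - qa) / B
  # softmax Jacobian (within each state's candidate mask):
  # d qa / d z3_j = qa * ((j == a) - q_j); off-mask entries of Q are 0
  delta3 <- -(g * qa) * fwd$Q
  delta3[cbind(seq_len(B), actions)] <- delta3[cbind(seq_len(B), actions)] + g * qa
  delta2 <- tcrossprod(delta3, net$W3) * (fwd$A2 * (1 - fwd$A2))
  delta1 <- tcrossprod(delta2, net$W2) * (fwd$A1 * (1 - fwd$A1))
  net$W3 <- net$W3 - alpha * crossprod(fwd$A2, delta3)
  net$b3 <- net$b3 - alpha * colSums(delta3)
  net$W2 <- net$W2 - alpha * crossprod(fwd$A1, delta2)
  net$b2 <- net$b2 - alpha * colSums(delta2)
  for (b in seq_len(B)) {
    s <- states[[b]]
    if (length(s$idx) > 0L) {
      net$W1[s$idx, ] <- net$W1[s$idx, ] -
        alpha * tcrossprod(s$val, delta1[b, ])
    }
  }
  net$b1 <- net$b1 - alpha * colSums(delta1)
  net
}

qnet_loss <- function(net, states, actions, targets, masks = NULL) {
  B <- length(states)
  fwd <- forward_batch(net, states, masks)
  qa <- fwd$Q[cbind(seq_len(B), actions)]
  mean((targets - qa)^2)
}

#' Experience transitions and replay buffers
#'
#' A transition records one consecutive-situation step: the utterance state,
#' chosen word, next state, next chosen word, the candidate word indices of
#' the next utterance (targets are maximized over these), and the reward.
#' The replay buffer is a bounded FIFO of capacity `J`: once full, pushing
#' evicts the oldest transition.
#'
#' @param state,next_state Numeric state vectors (dense, length N).
#' @param action,next_action Vocabulary word indices.
#' @param reward Transition reward.
#' @param candidates Integer indices of the current utterance's candidate
#'   words (the softmax support at `state`); defaults to the state's
#'   nonzero support.
#' @param next_candidates Integer indices of the next utterance's candidate
#'   words; defaults to the next state's nonzero support.
#' @return `transition()`: a list of class `xsit_transition`.
#' @export
transition <- function(state, action, next_state, next_action, reward,
                       candidates = NULL, next_candidates = NULL) {
  state <- as_sparse_state(state)
  next_state <- as_sparse_state(next_state)
  if (is.null(candidates)) candidates <- state$idx
  if (is.null(next_candidates)) next_candidates <- next_state$idx
  structure(
    list(
      state = state, action = as.integer(action),
      candidates = as.integer(candidates),
      next_state = next_state,
      next_action = as.integer(next_action),
      next_candidates = as.integer(next_candidates), reward = reward
    ),
    class = "xsit_transition"
  )
}

#' @rdname transition
#' @param capacity Buffer capacity `J`.
#' @export
replay_buffer <- function(capacity) {
  stopifnot(capacity >= 1)
  structure(
    list(items = vector("list", 0L), capacity = as.integer(capacity)),
    class = "xsit_replay_buffer"
  )
}

#' @rdname transition
#' @param buffer An `xsit_replay_buffer`.
#' @param tr An `xsit_transition`.
#' @export
buffer_push <- function(buffer, tr) {
  buffer$items <- c(buffer$items, list(tr))
  excess <- length(buffer$items) - buffer$capacity
  if (excess > 0L) buffer$items <- buffer$items[-seq_len(excess)]
  buffer
}

#' @rdname transition
#' @export
buffer_size <- function(buffer) length(buffer$items)

#' One online Q-network gradient step
#'
#' Sets the constant target `r + gamma * Q(s', a'; theta)` under the current
#' network and takes one gradient-descent step on the squared error of the
#' chosen action's output.
#'
#' @param net An `xsit_qnetwork`.
#' @param tr An [transition()].
#' @param params A [neural_params()].
#' @return The updated network.
#' @export
qnn_step <- function(net, tr, params) {
  target <- tr$reward + params$gamma *
    forward_one(net, tr$next_state, tr$next_candidates)[tr$next_action]
  qnet_grad_step(
    net, list(tr$state), tr$action, target, params$alpha,
    masks = list(tr$candidates)
  )
}

#' One neural-fitted-Q regression step over the stored batch
#'
#' Recomputes the target `r_j + gamma * Q(s'_j, a'_j; theta)` for every
#' stored transition under the current network, then takes one gradient
#' step on the mean squared error over the whole batch. With a single
#' stored transition this equals [qnn_step()].
#'
#' @param net An `xsit_qnetwork`.
#' @param buffer A non-empty [replay_buffer()].
#' @param params A [neural_params()].
#' @return The updated network.
#' @export
nfq_step <- function(net, buffer, params) {
  if (buffer_size(buffer) == 0L) {
    stop("nfq_step: empty transition store", call. = FALSE)
  }
  items <- buffer$items
  next_states <- lapply(items, `[[`, "next_state")
  next_actions <- vapply(items, `[[`, integer(1), "next_action")
  rewards <- vapply(items, `[[`, numeric(1), "reward")
  qnext <- forward_batch(net, next_states, lapply(items, `[[`, "next_candidates"))$Q
  targets <- rewards +
    params$gamma * qnext[cbind(seq_along(items), next_actions)]
  qnet_grad_step(
    net, lapply(items, `[[`, "state"),
    vapply(items, `[[`, integer(1), "action"), targets, params$alpha,
    masks = lapply(items, `[[`, "candidates")
  )
}

#' One deep-Q-network step with experience replay and a target network
#'
#' Samples a uniform minibatch from the replay buffer; per sample the
#' target is `r_j + gamma * max` of the *target* network's values at the
#' next state, restricted to that situation's candidate words (or, with
#' `params$double_dqn`, the online network's argmax evaluated under the
#' target network); takes one gradient step on the minibatch mean squared
#' error; and every `params$C` calls copies the online parameters into the
#' target network. With an underfull buffer the update is skipped.
#'
#' @param net Online `xsit_qnetwork`.
#' @param target Target `xsit_qnetwork` (a parameter copy of `net`).
#' @param buffer A [replay_buffer()].
#' @param params A [neural_params()].
#' @param step_counter Number of completed gradient steps so far.
#' @return A list with `net`, `target`, `stepped` (logical: did an update
#'   run) and the incremented `step_counter`.
#' @export
dqn_step <- function(net, target, buffer, params, step_counter = 0L) {
  if (buffer_size(buffer) < params$minibatch) {
    return(list(
      net = net, target = target, stepped = FALSE,
      step_counter = step_counter
    ))
  }
  pick <- sample.int(buffer_size(buffer), params$minibatch)
  items <- buffer$items[pick]
  next_states <- lapply(items, `[[`, "next_state")
  next_masks <- lapply(items, `[[`, "next_candidates")
  rewards <- vapply(items, `[[`, numeric(1), "reward")
  q_target_next <- forward_batch(target, next_states, next_masks)$Q
  boot <- if (params$double_dqn) {
    q_online_next <- forward_batch(net, next_states, next_masks)$Q
    vapply(seq_along(items), function(b) {
      cand <- items[[b]]$next_candidates
      astar <- cand[which.max(q_online_next[b, cand])]
      q_target_next[b, astar]
    }, numeric(1))
  } else {
    vapply(seq_along(items), function(b) {
      max(q_target_next[b, items[[b]]$next_candidates])
    }, numeric(1))
  }
  targets <- rewards + params$gamma * boot
  net <- qnet_grad_step(
    net, lapply(items, `[[`, "state"),
    vapply(items, `[[`, integer(1), "action"), targets, params$alpha,
    masks = lapply(items, `[[`, "candidates")
  )
  step_counter <- step_counter + 1L
  if (step_counter %% params$C == 0L) target <- net
  list(net = net, target = target, stepped = TRUE, step_counter = step_counter)
}

#' Train a neural learner on a situation corpus
#'
#' Runs the online Q-network (`"qnn"`), neural fitted Q (`"nfq"`), or deep
#' Q-network (`"dqn"`) for `params$episodes` full in-order passes over the
#' corpus. The network input is the utterance encoding only (binary
#' bag-of-words or prosodic prominence); the attended object enters through
#' the reward and the word-object matrix bookkeeping. Action selection is
#' epsilon-greedy over the current utterance's candidate words with epsilon
#' annealed across episodes. After each situation's update the fresh
#' softmax output for the current state is folded into the attended
#' object's `QW` row as a running mean. Deterministic under `params$seed`.
#'
#' @param corpus An `xsit_corpus` (with a `prosody` column for
#'   `encoding = "prosodic"`).
#' @param vocab An `xsit_vocab`; defaults to [build_vocabulary()].
#' @param algorithm `"qnn"`, `"nfq"`, or `"dqn"`.
#' @param encoding `"binary"` or `"prosodic"`.
#' @param params A [neural_params()].
#' @param reward_cfg A [reward_config()].
#' @return An object of class `c("xsit_neural", "xsit_fit")` with elements
#'   `net`, `QW`, `counts`, `reward_history`, `vocab`, `objects`,
#'   `algorithm`, `encoding`, `params`, `reward_cfg`.
#' @export
train_neural <- function(corpus, vocab = build_vocabulary(corpus),
                         algorithm = c("qnn", "nfq", "dqn"),
                         encoding = c("binary", "prosodic"),
                         params = neural_params(),
                         reward_cfg = reward_config()) {
  algorithm <- match.arg(algorithm)
  encoding <- match.arg(encoding)
  corpus <- validate_corpus(corpus)
  if (encoding == "prosodic" &&
    (!"prosody" %in% names(corpus) || any(vapply(corpus$prosody, is.null, logical(1))))) {
    stop(
      "prosodic encoding requires a prosody value per word in every ",
      "situation; generate with prosody_mode = TRUE or use binary encoding",
      call. = FALSE
    )
  }
  withr::with_seed(
    params$seed,
    train_neural_impl(corpus, vocab, algorithm, encoding, params, reward_cfg)
  )
}

train_neural_impl <- function(corpus, vocab, algorithm, encoding, params,
                              reward_cfg) {
  p <- nrow(corpus)
  n <- nrow(vocab)
  objects <- object_inventory(corpus)
  attended <- corpus$attended
  cands <- lapply(corpus$words, function(w) vocab_index(vocab, unique(w)))
  states <- lapply(seq_len(p), function(i) {
    dense <- if (encoding == "binary") {
      encode_binary(corpus$words[[i]], vocab)
    } else {
      encode_prosodic(corpus$words[[i]], corpus$prosody[[i]], vocab)
    }
    as_sparse_state(dense)
  })

  net <- init_network(n, params)
  target <- net
  buffer <- replay_buffer(params$J)
  qw_values <- matrix(0, nrow = length(objects), ncol = n,
    dimnames = list(objects, vocab$word)
  )
  qw_counts <- stats::setNames(integer(length(objects)), objects)
  att_row <- match(attended, objects)
  history <- numeric(params$episodes)
  step_counter <- 0L

  for (ep in seq_len(params$episodes)) {
    eps <- anneal_epsilon(ep, params)
    total <- 0
    if (p >= 2L) {
      for (i in seq_len(p - 1L)) {
        nxt <- i + 1L
        q_s <- forward_one(net, states[[i]], cands[[i]])
        a <- epsilon_greedy(q_s, cands[[i]], eps)
        # next action for the reward: greedy under the value estimate the
        # algorithm bootstraps with (target network for DQN, online net
        # otherwise)
        value_net <- if (algorithm == "dqn") target else net
        q_next <- forward_one(value_net, states[[nxt]], cands[[nxt]])
        a_next <- greedy_action(q_next, cands[[nxt]])
        r <- compute_reward(attended[[i]], a, attended[[nxt]], a_next, reward_cfg)
        total <- total + r
        tr <- structure(
          list(
            state = states[[i]], action = as.integer(a),
            candidates = cands[[i]],
            next_state = states[[nxt]], next_action = as.integer(a_next),
            next_candidates = cands[[nxt]], reward = r
          ),
          class = "xsit_transition"
        )
        if (algorithm == "qnn") {
          net <- qnet_grad_step(
            net, states[i], a,
            r + params$gamma * q_next[a_next], params$alpha,
            masks = cands[i]
          )
        } else if (algorithm == "nfq") {
          buffer <- buffer_push(buffer, tr)
          net <- nfq_step(net, buffer, params)
        } else {
          buffer <- buffer_push(buffer, tr)
          upd <- dqn_step(net, target, buffer, params, step_counter)
          net <- upd$net
          target <- upd$target
          step_counter <- upd$step_counter
        }
        # fold the post-update softmax output for the current state into
        # the attended object's running-mean row (same arithmetic as
        # update_qw(), kept in-place here for speed)
        q_up <- forward_one(net, states[[i]], cands[[i]])
        j <- att_row[[i]]
        qw_counts[[j]] <- qw_counts[[j]] + 1L
        qw_values[j, ] <- qw_values[j, ] + (q_up - qw_values[j, ]) / qw_counts[[j]]
      }
    }
    history[[ep]] <- total
  }

  structure(
    list(
      algorithm = algorithm, encoding = encoding, net = net,
      QW = qw_values, counts = qw_counts, reward_history = history,
      vocab = vocab, objects = objects, params = params,
      reward_cfg = reward_cfg
    ),
    class = c("xsit_neural", "xsit_fit")
  )
}
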