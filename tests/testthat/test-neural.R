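test_that("network initialization is seeded and softmax-normalized", {
  params <- neural_params(H = 7, seed = 5)
  n1 <- withr::with_seed(5, init_network(12, params))
  n2 <- withr::with_seed(5, init_network(12, params))
  expect_identical(n1, n2)
  # a one-word utterance has a single candidate: all value mass on it
  out <- forward(n1, encode_binary("w3", tibble::tibble(
    word = paste0("w", 1:12), index = 1:12
  )))
  expect_equal(sum(out), 1, tolerance = 1e-9)
  expect_equal(out[3], 1)
  expect_true(all(out[-3] == 0))
  # widening the candidate set spreads positive mass over it only
  wide <- forward(n1, encode_binary("w3", tibble::tibble(
    word = paste0("w", 1:12), index = 1:12
  )), candidates = c(2L, 3L, 7L))
  expect_equal(sum(wide), 1, tolerance = 1e-9)
  expect_true(all(wide[c(2, 3, 7)] > 0))
  expect_true(all(wide[-c(2, 3, 7)] == 0))
})

test_that("zero-scale initialization yields the uniform output", {
  params <- neural_params(H = 4, init_scale = 0)
  net <- withr::with_seed(1, init_network(6, params))
  state <- c(1, 0, 1, 0, 0, 1)
  # uniform over the utterance's candidate words
  expect_equal(forward(net, state), c(1, 0, 1, 0, 0, 1) / 3, tolerance = 1e-12)
  # and over the whole vocabulary when every word is a candidate
  expect_equal(forward(net, state, candidates = 1:6), rep(1 / 6, 6),
    tolerance = 1e-12
  )
})

test_that("forward outputs sum to one for random networks and states", {
  for (seed in 1:5) {
    net <- small_net(seed, N = 11, H = 6)
    state <- withr::with_seed(seed + 100, stats::rnorm(11))
    out <- forward(net, state)
    expect_equal(sum(out), 1, tolerance = 1e-9)
    expect_true(all(out > 0))
  }
  expect_error(forward(small_net(), rep(1, 5)), "length")
})

test_that("backprop matches central finite differences", {
  net <- small_net(3, N = 8, H = 5)
  states <- list(
    xsitlearn:::as_sparse_state(c(1, 0, 1, 0, 0, 1, 0, 0)),
    xsitlearn:::as_sparse_state(c(0, 2.5, 0, 0, -1.25, 0, 0, 1))
  )
  actions <- c(3L, 5L)
  targets <- c(2, -0.5)
  alpha <- 1
  stepped <- xsitlearn:::qnet_grad_step(net, states, actions, targets, alpha)
  oracle <- numeric_gradient(net, states, actions, targets)
  for (name in c("W1", "b1", "W2", "b2", "W3", "b3")) {
    analytic <- (net[[name]] - stepped[[name]]) / alpha
    denom <- pmax(abs(oracle[[name]]), 1e-4)
    expect_lt(max(abs(analytic - oracle[[name]]) / denom), 1e-5)
  }
})

test_that("qnn step reduces its own loss and is deterministic", {
  net <- small_net(7)
  tr <- transition(
    state = c(1, 0, 0, 1, 0, 0, 0, 0), action = 1L,
    next_state = c(0, 1, 0, 0, 0, 0, 1, 0), next_action = 2L,
    reward = 100
  )
  params <- neural_params(H = 5, alpha = 0.01)
  target_value <- tr$reward +
    params$gamma * xsitlearn:::forward_one(net, tr$next_state)[tr$next_action]
  before <- xsitlearn:::qnet_loss(net, list(tr$state), tr$action, target_value)
  up1 <- qnn_step(net, tr, params)
  up2 <- qnn_step(net, tr, params)
  expect_identical(up1, up2)
  after <- xsitlearn:::qnet_loss(up1, list(tr$state), tr$action, target_value)
  expect_lte(after, before)

  frozen <- neural_params(H = 5, alpha = 0)
  expect_identical(qnn_step(net, tr, frozen), net)
})

test_that("nfq over a single stored transition equals a qnn step", {
  net <- small_net(9)
  tr <- transition(
    state = c(0, 1, 0, 0, 1, 0, 0, 0), action = 2L,
    next_state = c(1, 0, 0, 0, 0, 0, 0, 1), next_action = 1L,
    reward = -1
  )
  params <- neural_params(H = 5, alpha = 0.05)
  buffer <- buffer_push(replay_buffer(10), tr)
  expect_equal(nfq_step(net, buffer, params), qnn_step(net, tr, params))
  expect_identical(nfq_step(net, buffer, neural_params(H = 5, alpha = 0)), net)
  expect_error(nfq_step(net, replay_buffer(3), params), "empty")
})

test_that("nfq batch regression reduces the batch loss for small alpha", {
  net <- small_net(11)
  params <- neural_params(H = 5, alpha = 0.01)
  buffer <- replay_buffer(20)
  trs <- withr::with_seed(2, lapply(1:6, function(k) {
    transition(
      state = as.numeric(stats::runif(8) < 0.3), action = sample.int(8, 1),
      next_state = as.numeric(stats::runif(8) < 0.3),
      next_action = sample.int(8, 1),
      reward = sample(c(100, -1), 1)
    )
  }))
  for (tr in trs) buffer <- buffer_push(buffer, tr)
  batch_loss <- function(n) {
    items <- buffer$items
    targets <- vapply(items, function(tr) {
      tr$reward + params$gamma *
        xsitlearn:::forward_one(n, tr$next_state)[tr$next_action]
    }, numeric(1))
    xsitlearn:::qnet_loss(
      n, lapply(items, `[[`, "state"),
      vapply(items, `[[`, integer(1), "action"), targets
    )
  }
  before <- batch_loss(net)
  stepped <- nfq_step(net, buffer, params)
  expect_lte(batch_loss(stepped), before)
})

test_that("replay buffer is a bounded FIFO", {
  buffer <- replay_buffer(5)
  mk <- function(k) {
    transition(
      state = c(k, 0), action = 1L, next_state = c(0, k),
      next_action = 2L, reward = k
    )
  }
  for (k in 1:9) buffer <- buffer_push(buffer, mk(k))
  expect_identical(buffer_size(buffer), 5L)
  kept <- vapply(buffer$items, `[[`, numeric(1), "reward")
  expect_identical(kept, as.numeric(5:9)) # oldest four evicted, order kept
})

test_that("dqn step syncs the target every C steps and masks targets", {
  net <- small_net(13)
  params <- neural_params(H = 5, alpha = 0.05, minibatch = 2, J = 10, C = 1)
  buffer <- replay_buffer(10)
  trs <- withr::with_seed(4, lapply(1:4, function(k) {
    transition(
      state = as.numeric(stats::runif(8) < 0.4), action = sample.int(8, 1),
      next_state = as.numeric(stats::runif(8) < 0.4),
      next_action = sample.int(8, 1),
      reward = sample(c(100, -1), 1), next_candidates = sample.int(8, 3)
    )
  }))
  for (tr in trs) buffer <- buffer_push(buffer, tr)
  stale <- small_net(99)
  out <- withr::with_seed(1, dqn_step(net, stale, buffer, params, 0L))
  expect_true(out$stepped)
  expect_identical(out$target, out$net) # C = 1: target synced to online

  # underfull buffer skips the update
  skip_out <- dqn_step(net, stale, replay_buffer(10),
    neural_params(H = 5, minibatch = 2, J = 10), 0L
  )
  expect_false(skip_out$stepped)
  expect_identical(skip_out$net, net)

  # gamma = 0 reduces targets to rewards: identical to gamma-0 nfq on the
  # same sampled transitions when the minibatch covers the whole buffer
  p0 <- neural_params(H = 5, alpha = 0.05, minibatch = 4, J = 10, C = 10, gamma = 0)
  d0 <- withr::with_seed(2, dqn_step(net, stale, buffer, p0, 0L))
  n0 <- nfq_step(net, buffer, p0)
  expect_equal(d0$net, n0, tolerance = 1e-8)
})

test_that("epsilon anneals linearly and clamps at the end value", {
  params <- neural_params(episodes = 101)
  expect_equal(anneal_epsilon(1, params), 0.99)
  expect_equal(anneal_epsilon(51, params), (0.99 + 0.0001) / 2)
  expect_equal(anneal_epsilon(101, params), 0.0001)
  expect_equal(anneal_epsilon(5000, params), 0.0001)
  expect_equal(anneal_epsilon(1, neural_params(episodes = 1)), 0.99)
})

test_that("neural training is seed-deterministic and records history", {
  gen <- generate_corpus(small_gen_config(seed = 23))
  vocab <- build_vocabulary(gen$corpus)
  params <- neural_params(H = 10, episodes = 3, seed = 2)
  for (algorithm in c("qnn", "nfq", "dqn")) {
    f1 <- train_neural(gen$corpus, vocab, algorithm, "binary", params)
    f2 <- train_neural(gen$corpus, vocab, algorithm, "binary", params)
    expect_identical(f1$net, f2$net)
    expect_identical(f1$QW, f2$QW)
    expect_length(f1$reward_history, 3L)
    # softmax head: every QW row is a mean of probability vectors over
    # candidate words, so it sums to 1 with entries in [0, 1)
    visited <- f1$counts > 0
    expect_true(all(f1$QW[visited, ] >= 0 & f1$QW[visited, ] < 1))
    expect_equal(unname(rowSums(f1$QW[visited, , drop = FALSE])),
      rep(1, sum(visited)),
      tolerance = 1e-9
    )
  }
  empty <- train_neural(
    gen$corpus, vocab, "qnn", "binary",
    neural_params(H = 10, episodes = 0, seed = 2)
  )
  expect_length(empty$reward_history, 0L)
})

test_that("prosodic training demands prosody", {
  gen <- generate_corpus(small_gen_config(seed = 24))
  expect_error(
    train_neural(
      gen$corpus,
      algorithm = "qnn", encoding = "prosodic",
      params = neural_params(H = 5, episodes = 1)
    ),
    "prosod"
  )
})

test_that("late-training reward exceeds early reward on a learnable corpus", {
  for (algorithm in c("qnn", "nfq", "dqn")) {
    improved <- vapply(1:3, function(seed) {
      gen <- generate_corpus(small_gen_config(seed = 30 + seed))
      fit <- train_neural(
        gen$corpus,
        algorithm = algorithm, encoding = "binary",
        params = neural_params(H = 15, episodes = 30, seed = seed)
      )
      g <- glance(fit)
      g$reward_last_decile > g$reward_first_decile
    }, logical(1))
    expect_true(all(improved))
  }
})
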