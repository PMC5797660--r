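# Fixtures are built in code so every test starts from a known corpus.

# Deterministic 2-object / 2-word alternating corpus: each utterance is
# exactly the attended object's name, so the planted lexicon is the unique
# consistent labelling.
make_micro_corpus <- function(p = 40) {
  att <- rep(c("ball", "cup"), length.out = p)
  word <- ifelse(att == "ball", "ba", "ku")
  corpus <- new_corpus(
    words = as.list(word),
    objects = rep(list(c("ball", "cup")), p),
    attended = att
  )
  list(
    corpus = corpus,
    gold = gold_lexicon(c("ba", "ku"), c("ball", "cup")),
    vocab = build_vocabulary(corpus)
  )
}

# The two-situation worked example: book attended twice among four visible
# objects, seven- and six-word utterances.
make_worked_example <- function() {
  objects <- c("book", "bird", "rattle", "face")
  new_corpus(
    words = list(
      tokenize_utterance("ahhah look we can read books david"),
      tokenize_utterance("its a look and see book")
    ),
    objects = list(objects, objects),
    attended = c("book", "book")
  )
}

# Small learnable generator config for desk-scale training tests.
small_gen_config <- function(seed = 7, prosody = FALSE, ...) {
  gen_config(
    n_objects = 5, n_referent_words = 6, n_filler_words = 40,
    n_situations = 80, max_visible = 3, p_referent_word = 0.8,
    prosody_mode = prosody, seed = seed, ...
  )
}

expect_tibble_cols <- function(x, cols) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(cols %in% names(x)))
}

# finite-difference oracle over all Q-network parameters
numeric_gradient <- function(net, states, actions, targets, h = 1e-6) {
  loss_at <- function(n) xsitlearn:::qnet_loss(n, states, actions, targets)
  grads <- list()
  for (name in c("W1", "b1", "W2", "b2", "W3", "b3")) {
    g <- net[[name]]
    g[] <- 0
    for (k in seq_along(g)) {
      up <- net
      up[[name]][k] <- up[[name]][k] + h
      down <- net
      down[[name]][k] <- down[[name]][k] - h
      g[k] <- (loss_at(up) - loss_at(down)) / (2 * h)
    }
    grads[[name]] <- g
  }
  grads
}

small_net <- function(seed = 1, N = 8, H = 5, init_scale = 0.5) {
  params <- neural_params(H = H, init_scale = init_scale, seed = seed)
  withr::with_seed(seed, init_network(N, params))
}
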