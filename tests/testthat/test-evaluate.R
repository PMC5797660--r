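toy_nqw <- function() {
  matrix(c(1, 0.3, 0.4, 1),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("o1", "o2"), c("w1", "w2"))
  )
}

test_that("normalization divides each object row by its own maximum", {
  qw <- matrix(c(2, 4, 0, 0, 3, 1),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("a", "b", "c"), c("w1", "w2"))
  )
  nqw <- normalize_qw(qw)
  expect_equal(unname(nqw["a", ]), c(0.5, 1))
  expect_equal(unname(nqw["b", ]), c(0, 0)) # all-zero row stays zero
  expect_equal(unname(nqw["c", ]), c(1, 1 / 3))
  # idempotent once every row peaks at 1
  expect_equal(normalize_qw(nqw), nqw)
})

test_that("normalization is scale-invariant per row and peaks at 1", {
  qw <- withr::with_seed(41, matrix(stats::runif(35), nrow = 5,
    dimnames = list(paste0("o", 1:5), paste0("w", 1:7))
  ))
  nqw <- normalize_qw(qw)
  expect_equal(unname(apply(nqw, 1, max)), rep(1, 5))
  scaled <- qw * c(10, 0.2, 3, 7, 100)
  expect_equal(normalize_qw(scaled), nqw)
})

test_that("confusion matrix slices gold-word columns across objects", {
  nqw <- toy_nqw()
  gold <- gold_lexicon(c("w1", "w2"), c("o1", "o2"))
  vocab <- tibble::tibble(word = c("w1", "w2"), index = 1:2)
  cm <- confusion_matrix(nqw, gold, vocab)
  expect_identical(dim(cm), c(2L, 2L))
  expect_equal(cm["w1", ], c(o1 = 1, o2 = 0.4))
  expect_equal(cm["w2", ], c(o1 = 0.3, o2 = 1))
  expect_true(all(cm >= 0 & cm <= 1))
  one <- confusion_matrix(nqw, gold_lexicon("w2", "o1"), vocab)
  expect_identical(dim(one), c(1L, 2L))
  expect_error(
    confusion_matrix(nqw, gold_lexicon("nope", "o1"), vocab),
    "nope"
  )
})

test_that("referent selection takes the argmax object, first row on ties", {
  nqw <- matrix(c(0.2, 0.9, 0.1, 0.5, 0.5, 0.5),
    ncol = 2,
    dimnames = list(c("a", "b", "c"), c("w1", "w2"))
  )
  vocab <- tibble::tibble(word = c("w1", "w2"), index = 1:2)
  sel <- select_referent(nqw, c("w1", "w2"), vocab)
  expect_identical(sel$object, c("b", "a")) # 0.9 wins; tie goes to first row
  expect_error(select_referent(nqw, "w9", vocab), "w9")
})

test_that("lexicon extraction applies an inclusive threshold", {
  nqw <- toy_nqw()
  expect_identical(nrow(extract_lexicon(nqw, 1.5)), 0L)
  full <- extract_lexicon(nqw, 0)
  expect_identical(nrow(full), 4L) # >= 0 keeps the full cross product
  mid <- extract_lexicon(nqw, 0.5)
  expect_identical(
    dplyr::arrange(mid[, c("word", "object")], word),
    tibble::tibble(word = c("w1", "w2"), object = c("o1", "o2"))
  )
  edge <- extract_lexicon(nqw, 0.4)
  expect_true(any(edge$word == "w1" & edge$object == "o2")) # boundary kept
})

test_that("precision, recall and F follow the worked arithmetic", {
  gold <- gold_lexicon(paste0("w", 1:4), paste0("o", 1:4))
  predicted <- tibble::tibble(
    word = c("w1", "w2", "w3", "w9", "w4"),
    object = c("o1", "o2", "o3", "o9", "o8")
  )
  scores <- score_lexicon(predicted, gold)
  expect_equal(scores$precision, 0.6)
  expect_equal(scores$recall, 0.75)
  expect_equal(scores$f_score, 2 / 3)

  perfect <- score_lexicon(gold, gold)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f_score, 1)

  none <- score_lexicon(tibble::tibble(word = character(), object = character()), gold)
  expect_equal(none$precision, 0)
  expect_equal(none$recall, 0)
  expect_equal(none$f_score, 0)
})

test_that("recall denominator can count gold words instead of pairs", {
  gold <- gold_lexicon(c("bird", "bird", "book"), c("bird", "duck", "book"))
  predicted <- tibble::tibble(word = c("bird", "book"), object = c("bird", "book"))
  by_pairs <- score_lexicon(predicted, gold)
  by_words <- score_lexicon(predicted, gold, recall_denominator = "words")
  expect_equal(by_pairs$recall, 2 / 3)
  expect_equal(by_words$recall, 1)
})

test_that("scores agree with an independent set-arithmetic oracle", {
  words <- paste0("w", 1:12)
  objects <- paste0("o", 1:6)
  withr::with_seed(55, {
    for (rep in seq_len(300)) {
      gold <- gold_lexicon(
        sample(words, 5, replace = TRUE),
        sample(objects, 5, replace = TRUE)
      )
      predicted <- unique(tibble::tibble(
        word = sample(words, sample(0:8, 1), replace = TRUE),
        object = sample(objects, 1)
      ))
      scores <- score_lexicon(predicted, gold)
      # oracle: count pair matches by exhaustive double loop
      hits <- 0L
      for (i in seq_len(nrow(predicted))) {
        for (j in seq_len(nrow(gold))) {
          if (predicted$word[i] == gold$word[j] &&
            predicted$object[i] == gold$object[j]) {
            hits <- hits + 1L
            break
          }
        }
      }
      p <- if (nrow(predicted) == 0) 0 else hits / nrow(predicted)
      r <- hits / nrow(gold)
      f <- if (p + r > 0) 2 * p * r / (p + r) else 0
      expect_equal(scores$precision, p)
      expect_equal(scores$recall, r)
      expect_equal(scores$f_score, f)
    }
  })
})

test_that("threshold sweep has non-increasing recall and finds the toy peak", {
  nqw <- toy_nqw()
  gold <- gold_lexicon(c("w1", "w2"), c("o1", "o2"))
  sweep <- threshold_sweep(nqw, gold, thresholds = seq(0, 1, by = 0.01))
  expect_identical(nrow(sweep), 101L)
  expect_true(all(diff(sweep$recall) <= 0))
  best <- best_scores(sweep)
  expect_equal(best$f_score, 1)
  # F = 1 holds from the first grid point above the 0.4 off-diagonal entry
  # up to 1; the tie rule reports the lowest such threshold
  expect_equal(best$threshold, 0.41)
  expect_equal(sweep$f_score[sweep$threshold == 0.5], 1)
  single <- threshold_sweep(nqw, gold, thresholds = 0.7)
  expect_identical(nrow(single), 1L)
  expect_equal(best_scores(single)$threshold, 0.7)
})

test_that("referent selection is inside the lexicon at admissible thresholds", {
  gen <- generate_corpus(small_gen_config(seed = 44))
  vocab <- build_vocabulary(gen$corpus)
  nqw <- normalize_qw(cooc_baseline(gen$corpus, vocab))
  sel <- select_referent(nqw, gold_words(gen$gold), vocab)
  for (th in c(0.2, 0.6, 1)) {
    lex <- extract_lexicon(nqw, th)
    for (k in seq_len(nrow(sel))) {
      if (sel$value[k] >= th) {
        expect_true(any(lex$word == sel$word[k] & lex$object == sel$object[k]))
      }
    }
  }
})

test_that("co-occurrence baseline counts attended co-occurrences exactly", {
  corpus <- new_corpus(
    words = list(c("big", "duck", "duck"), c("big", "ring"), c("duck", "go")),
    objects = list(c("duck", "ring"), c("ring", "duck"), c("duck", "ring")),
    attended = c("duck", "ring", "duck")
  )
  vocab <- build_vocabulary(corpus)
  qw <- qw_matrix(cooc_baseline(corpus, vocab))
  expect_equal(qw["duck", "duck"], 2) # type count, not token count
  expect_equal(qw["duck", "big"], 1)
  expect_equal(qw["ring", "big"], 1)
  expect_equal(qw["ring", "duck"], 0)

  # brute-force recount over a generated corpus
  gen <- generate_corpus(small_gen_config(seed = 45))
  gvocab <- build_vocabulary(gen$corpus)
  gqw <- qw_matrix(cooc_baseline(gen$corpus, gvocab))
  for (obj in object_inventory(gen$corpus)) {
    rows <- which(gen$corpus$attended == obj)
    oracle <- sum(lengths(lapply(gen$corpus$words[rows], unique)))
    expect_equal(unname(sum(gqw[obj, ])), oracle)
  }

  # visible-object counting counts every co-present object
  vis <- qw_matrix(cooc_baseline(corpus, vocab, count = "visible"))
  expect_equal(vis["ring", "duck"], 2)
})

test_that("noiseless corpora give the baseline a perfect best F", {
  gen <- generate_corpus(gen_config(
    n_objects = 5, n_referent_words = 5, n_filler_words = 0,
    n_situations = 120, max_visible = 3, p_referent_word = 1,
    p_other_gold = 0, utterance_length = c(1, 1), seed = 46
  ))
  vocab <- build_vocabulary(gen$corpus)
  sweep <- threshold_sweep(cooc_baseline(gen$corpus, vocab), gen$gold)
  expect_equal(best_scores(sweep)$f_score, 1)
})

test_that("tidy and glance expose the fit in broom shapes", {
  micro <- make_micro_corpus()
  fit <- train_tabular(
    micro$corpus, micro$vocab, "qlearn",
    tabular_params(episodes = 10, seed = 2)
  )
  td <- tidy(fit)
  expect_tibble_cols(td, c("object", "word", "value", "normalized"))
  expect_identical(nrow(td), 4L) # 2 objects x 2 words
  gl <- glance(fit)
  expect_identical(gl$episodes, 10L)
  expect_identical(gl$algorithm, "qlearn")
})
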