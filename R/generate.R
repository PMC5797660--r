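#' Configuration for the synthetic caregiver-infant corpus generator
#'
#' The generator emulates the structure of transcribed mother-infant play
#' sessions: short utterances (a few tokens), up to `max_visible` objects in
#' view per scene, exactly one jointly-attended object, and a planted gold
#' lexicon whose words name the attended object in only a fraction of
#' utterances. Filler words follow a Zipf-like skew so that, as in real
#' child-directed speech, the corpus is dominated by frequent but irrelevant
#' tokens.
#'
#' @param n_objects Number of object labels (M).
#' @param n_referent_words Number of planted gold words; may exceed
#'   `n_objects`, in which case several words share a referent.
#' @param n_filler_words Number of non-referent vocabulary words.
#' @param n_situations Number of situations (P).
#' @param max_visible Maximum objects per scene (attended object included).
#' @param p_referent_word Probability that the attended object's gold word
#'   occurs in the utterance. Transcript studies put the empirical rate near
#'   0.23 (`preset = "hard"`); the default 0.7 yields corpora learnable at
#'   desk scale.
#' @param utterance_length Length-2 integer vector, min/max tokens per
#'   utterance.
#' @param p_other_gold Probability that a non-referent token slot reuses a
#'   gold word of some *other* object, creating cross-situational
#'   confusability.
#' @param filler_distribution `"zipf"` (exponent 1, default) or `"uniform"`
#'   filler frequencies.
#' @param prosody_mode Generate per-word prosodic prominence values?
#' @param prominence_mean,prominence_sd Normal distribution (Hz) of the
#'   pitch-percentile difference at referent-word positions.
#' @param baseline_sd Spread (Hz) of the zero-mean pitch difference at
#'   non-referent positions.
#' @param p_stay Probability that the next situation keeps the same
#'   attended object (Markov attention persistence). Caregiver-infant play
#'   dwells on a toy across consecutive utterances, and the
#'   consistency-based reward is informative exactly on such same-object
#'   transitions; the symmetric chain keeps the long-run attended
#'   frequencies uniform.
#' @param p_misattention Probability the annotated attended object is a
#'   random visible object instead of the true one (0 = paper's setting).
#' @param seed RNG seed making generation deterministic.
#' @param preset `"default"` or `"hard"` (`p_referent_word = 0.23`).
#' @return A list of class `xsit_gen_config`.
#' @export
gen_config <- function(n_objects = 17,
                       n_referent_words = 37,
                       n_filler_words = 380,
                       n_situations = 600,
                       max_visible = 7,
                       p_referent_word = 0.7,
                       utterance_length = c(2L, 6L),
                       p_other_gold = 0.2,
                       filler_distribution = c("zipf", "uniform"),
                       p_stay = 0.6,
                       prosody_mode = FALSE,
                       prominence_mean = 30,
                       prominence_sd = 10,
                       baseline_sd = 10,
                       p_misattention = 0,
                       seed = 1L,
                       preset = c("default", "hard")) {
  preset <- match.arg(preset)
  if (preset == "hard") p_referent_word <- 0.23
  filler_distribution <- match.arg(filler_distribution)
  stopifnot(
    n_objects >= 1, n_referent_words >= n_objects, n_filler_words >= 0,
    n_situations >= 1, max_visible >= 1,
    p_referent_word >= 0, p_referent_word <= 1,
    p_other_gold >= 0, p_other_gold <= 1,
    p_misattention >= 0, p_misattention <= 1,
    p_stay >= 0, p_stay < 1,
    length(utterance_length) == 2, utterance_length[1] >= 1,
    utterance_length[2] >= utterance_length[1],
    prominence_sd >= 0, baseline_sd >= 0
  )
  structure(
    list(
      n_objects = as.integer(n_objects),
      n_referent_words = as.integer(n_referent_words),
      n_filler_words = as.integer(n_filler_words),
      n_situations = as.integer(n_situations),
      max_visible = as.integer(max_visible),
      p_referent_word = p_referent_word,
      utterance_length = as.integer(utterance_length),
      p_other_gold = p_other_gold,
      filler_distribution = filler_distribution,
      p_stay = p_stay,
      prosody_mode = isTRUE(prosody_mode),
      prominence_mean = prominence_mean,
      prominence_sd = prominence_sd,
      baseline_sd = baseline_sd,
      p_misattention = p_misattention,
      seed = as.integer(seed)
    ),
    class = "xsit_gen_config"
  )
}

#' Generate a synthetic situation corpus with a planted gold lexicon
#'
#' Each situation draws 1..`max_visible` visible objects uniformly and one
#' attended object among them; with probability `p_referent_word` one of the
#' attended object's planted gold words is inserted at a random utterance
#' position; remaining slots are fillers (Zipf-skewed by default) or,
#' with probability `p_other_gold`, gold words of other objects. Every gold
#' word maps to exactly one planted object. Generation is deterministic
#' under `config$seed`.
#'
#' @param config An [gen_config()] object.
#' @return A list with elements `corpus` (an `xsit_corpus`) and `gold`
#'   (an `xsit_gold`).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "xsit_gen_config"))
  withr::with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  m <- config$n_objects
  objects <- sprintf("obj%02d", seq_len(m))
  gold_word_tokens <- sprintf("gw%02d", seq_len(config$n_referent_words))
  # every object gets at least one gold word; extras assigned round-robin
  gold_object <- objects[((seq_len(config$n_referent_words) - 1L) %% m) + 1L]
  gold <- gold_lexicon(gold_word_tokens, gold_object)
  fillers <- if (config$n_filler_words > 0) {
    sprintf("f%03d", seq_len(config$n_filler_words))
  } else {
    character(0)
  }
  filler_w <- if (length(fillers) > 0) {
    w <- switch(config$filler_distribution,
      zipf = 1 / seq_along(fillers),
      uniform = rep(1, length(fillers))
    )
    w / sum(w)
  } else {
    numeric(0)
  }

  p <- config$n_situations
  words <- vector("list", p)
  vis <- vector("list", p)
  attended <- character(p)
  prosody <- if (config$prosody_mode) vector("list", p) else NULL
  gold_by_object <- split(gold$word, gold$object)

  prev_att <- sample(objects, 1L)
  dwell_word <- NA_character_ # the name used for the current attention dwell
  for (i in seq_len(p)) {
    stayed <- i > 1L && stats::runif(1) < config$p_stay
    att <- if (stayed) prev_att else sample(objects, 1L)
    if (!stayed || is.na(dwell_word)) {
      # a new attention episode picks which of the object's names the
      # caregiver uses; child-directed speech repeats it within the dwell
      ref_words <- gold_by_object[[att]]
      dwell_word <- if (length(ref_words) > 1L) sample(ref_words, 1L) else ref_words
    }
    prev_att <- att
    l <- min(sample.int(config$max_visible, 1L), m)
    scene <- c(att, sample(setdiff(objects, att), l - 1L))
    scene <- sample(scene) # shuffle so the attended object has no fixed slot
    if (config$p_misattention > 0 && stats::runif(1) < config$p_misattention) {
      att <- sample(scene, 1L)
    }
    d <- sample(seq(config$utterance_length[1], config$utterance_length[2]), 1L)
    utt <- character(d)
    is_ref <- logical(d)
    for (k in seq_len(d)) {
      if (config$p_other_gold > 0 && stats::runif(1) < config$p_other_gold &&
        config$n_referent_words > length(gold_by_object[[att]])) {
        others <- setdiff(gold$word, gold_by_object[[att]])
        utt[[k]] <- sample(others, 1L)
      } else if (length(fillers) > 0) {
        utt[[k]] <- sample(fillers, 1L, prob = filler_w)
      } else {
        utt[[k]] <- sample(gold$word, 1L)
      }
    }
    if (stats::runif(1) < config$p_referent_word) {
      pos <- sample.int(d, 1L)
      utt[[pos]] <- dwell_word
      is_ref[[pos]] <- TRUE
    }
    words[[i]] <- utt
    vis[[i]] <- scene
    attended[[i]] <- att
    if (config$prosody_mode) {
      prosody[[i]] <- generate_prosody(utt, is_ref, config)
    }
  }
  corpus <- new_corpus(words, vis, attended, prosody = prosody)
  list(corpus = corpus, gold = gold)
}

#' Generate per-word prosodic prominence values
#'
#' Referent-word positions are sampled from
#' Normal(`prominence_mean`, `prominence_sd`); all other positions from
#' Normal(0, `baseline_sd`). Values play the role of the per-word
#' pitch-percentile difference (Hz): the word naming the attended object
#' carries higher pitch than the rest of the utterance.
#'
#' @param words Character vector of utterance tokens.
#' @param is_referent Logical vector marking referent-word positions.
#' @param config An [gen_config()] object.
#' @return Numeric vector, one prominence value per token. Uses the current
#'   RNG state; seed externally (e.g. [withr::with_seed()]) for
#'   reproducibility.
#' @export
generate_prosody <- function(words, is_referent, config) {
  stopifnot(length(words) == length(is_referent))
  d <- length(words)
  out <- stats::rnorm(d, mean = 0, sd = config$baseline_sd)
  n_ref <- sum(is_referent)
  if (n_ref > 0) {
    out[is_referent] <- stats::rnorm(n_ref,
      mean = config$prominence_mean,
      sd = config$prominence_sd
    )
  }
  out
}
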