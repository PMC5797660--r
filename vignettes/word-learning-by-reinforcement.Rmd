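---
title: "Cross-situational word learning by reinforcement: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-situational word learning by reinforcement: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xsitlearn)
```

## The learning problem

A pre-verbal infant hears short caregiver utterances while several objects
are in view. No single situation reveals which word names which object: the
utterance contains function words and names of absent things, and several
objects compete for reference. Two social signals cut the ambiguity down:

* **joint attention** — the one object caregiver and infant jointly attend
  to, annotated per situation; and
* **prosodic prominence** — caregivers pronounce the word naming the
  attended object with higher pitch than the rest of the utterance.

`xsitlearn` models the learner as a reinforcement-learning agent. A
*situation* is an utterance (word tokens), the set of visible object
labels, the attended object, and optionally one prosodic value per word.
The agent's action is **internal**: it picks one word of the current
utterance as its hypothesis for the attended object's name. The action does
not change the environment; what it changes is the agent's reward on the
next transition.

## Reward: novel names for novel objects

For consecutive situations $i$ and $i+1$ with attended objects $o^i$,
$o^{i+1}$ and chosen words $a^i$, $a^{i+1}$:

$$
r_i = \begin{cases}
 r_\text{match} & (o^i = o^{i+1} \wedge a^i = a^{i+1})
   \lor (o^i \neq o^{i+1} \wedge a^i \neq a^{i+1}) \\
 r_\text{mismatch} & \text{otherwise.}
\end{cases}
$$

Keeping the same word while attention stays put, or switching words when
attention moves, is *consistent* — this encodes the novel-name–nameless-
category bias (new words go with new referents). The didactic presentation
of this rule uses $(+1, -1)$; the executable procedures use $(+100, -1)$.
Both are available through `reward_config()`: the default is
$(100, -1)$, and `unit_mode = TRUE` reproduces the $(\pm 1)$ variant. The
first situation of an episode has no predecessor and produces no reward.

Word equality here is vocabulary-word-type equality: actions are word
types, not utterance positions.

## Learners

All six learners share the interaction loop (one *episode* is a full
in-order pass over the corpus; `epsilon`-greedy selection over the current
utterance's candidate word types) and the readout described below.

**Tabular** (`train_tabular()`): a situations-by-vocabulary table $Q(s,a)$,
initialized uniform random in $[0,1)$ under the run seed.

* *Q-learning*: $Q(s,a) \mathrel{+}= \alpha\,(r + \gamma \max_{a'} Q(s',a') - Q(s,a))$,
  the maximum restricted to the next utterance's candidate words.
* *SARSA*: bootstraps on the actually-chosen next action.
* *SARSA-$\lambda$*: replacing eligibility traces; the TD error updates
  every recently-visited pair, traces decay by $\gamma\lambda$ and reset at
  episode start. At $\lambda = 0$ its per-step increments equal SARSA's
  bitwise, which the tests assert.

Exploration stays fixed at `epsilon = 0.99` for tabular learners;
annealing is a neural-learner feature. Greedy ties break toward the lowest
word index so runs are deterministic.

**Neural** (`train_neural()`): a four-layer perceptron
$N \to H \to H \to N$ (sigmoid, sigmoid, softmax; $H = 200$ by default)
maps the utterance encoding to a value per vocabulary word.

* *Q-NN*: online; one gradient step per situation on the squared error of
  the chosen action's output against the constant target
  $r + \gamma\,Q(s', a'; \theta)$.
* *NFQ*: stores the most recent $J = 50$ transitions and takes one
  gradient step per situation on the mean squared error over the whole
  store, with targets recomputed under the current network. The network is
  not reset between fits.
* *DQN*: experience replay (capacity $J = 50$, uniform minibatches of 10)
  plus a target network synced every $C = 4$ gradient steps; per-sample
  targets are $r + \gamma \max_{a'} Q(s', a'; \theta^p)$ with the maximum
  over the next utterance's candidates under the *target* parameters. A
  strict double estimator (online argmax, target evaluation) is available
  via `double_dqn = TRUE`. Underfull buffers skip the update.

Defaults follow the reference settings: $\alpha = 0.001$, $\gamma = 0.99$,
$\varepsilon$ annealed linearly from 0.99 to 0.0001 over the configured
episodes and held there.

### The softmax head is normalized over the utterance's words

The network head deserves its own section because it is the one place
where this package interprets rather than transcribes. The output layer is
a softmax "so that the agent has higher value for one word per utterance" —
and the only admissible actions in a situation are the word types of its
utterance. We therefore normalize the softmax over the *current
utterance's candidate words*; entries for absent words are zero.
`forward()` defaults to the nonzero support of the state encoding and
accepts an explicit `candidates` argument.

The alternative — softmax over the whole vocabulary — is degenerate in
this setting, and measurably so. Gradients flow only through chosen
actions; with rewards overwhelmingly positive (under the $(100,-1)$
scheme, most transitions are different-object/different-word and pay
$+100$), every chosen word's output is pushed up and essentially nothing
is pushed down. The vocabulary-wide softmax then converges to a
state-independent winner-take-all: one globally-popular word carries all
mass for *every* input, all rows of the word-object matrix become
identical, and referent selection stays at chance while reward still
looks healthy. Masking removes the pathology: competition is between the
words actually available in the situation, cold-start probabilities are
$\sim 1/d$ (utterance length) rather than $1/N$, and the readout below
becomes informative.

### Gradient details

The loss for a (mini)batch is the mean over samples of
$(Q_\text{target} - Q(s, a; \theta))^2$, targets treated as constants.
The gradient passes through the chosen action's softmax output with the
full softmax Jacobian (other outputs feel it through the coupling term),
then through the sigmoid hidden layers. Layer-1 forward and backward
touch only the vocabulary rows of words present in the utterance, which
is what makes pure-R training loops practical. The test suite checks the
analytic gradient against central finite differences at relative
tolerance $10^{-5}$ on small networks.

Weights initialize uniform in $\pm$`init_scale` (default 0.01) under the
run seed. The literature this implementation follows prints an
initialization interval of $[10^{-2}, 10^2]$, which would saturate every
sigmoid from the first forward pass; we read it as a typo for magnitudes
around $10^{-2}$ and expose the half-range through `init_scale` so either
reading can be run.

## The word-object matrix and lexicon readout

During training, after each situation's update the fresh output vector for
the current state is folded into the attended object's row of an
objects-by-words matrix `QW` as a running mean (`update_qw()`); tabular
learners contribute the state's Q-row masked to the utterance's words.
Because neural outputs are probability vectors over the utterance's words,
a neural `QW` row is an attention-gated average of word preferences — a
reward-weighted soft co-occurrence table.

Evaluation then proceeds by (`normalize_qw()`, Eq.-style):
row-normalizing each object's row by its maximum; slicing gold-word
columns into a confusion matrix; selecting each word's referent as the
argmax object of its normalized column (`select_referent()`); and
thresholding the normalized matrix into a lexicon scored by
precision/recall/F against the gold pairs (`score_lexicon()`,
`threshold_sweep()`). Membership is inclusive (value $\ge$ threshold);
best-F ties report the lowest threshold. Precision and recall count
*pairs*, so a multi-referent word contributes one unit per referent;
`recall_denominator = "words"` switches to word counting. The
co-occurrence baseline (`cooc_baseline()`) feeds raw attended-object
co-occurrence counts through the same pipeline.

One consequence of the inclusive rule worth knowing: on the didactic
$2\times 2$ matrix $((1, 0.4), (0.3, 1))$ with grid $0, 0.01, \ldots, 1$,
perfect F holds for every threshold from 0.41 upward, so the reported
best threshold is 0.41 — the lowest of the tied grid points — even though
0.5 is the natural midpoint one might quote.

## The synthetic corpus generator

`gen_config()` / `generate_corpus()` plant a gold lexicon and emulate the
structure of transcribed caregiver-infant play:

* up to `max_visible` objects per scene (default 7), exactly one attended;
* the attended object's gold word occurs in the utterance with probability
  `p_referent_word` (default 0.7; the empirical rate in transcribed play
  sessions is nearer 0.23, available as `preset = "hard"` — learnable only
  with far more data than desk-scale tests use);
* utterances of 2–6 tokens (mean ≈ 4, matching transcript statistics of
  roughly 2,500 tokens over 600-odd utterances);
* fillers drawn with a Zipf skew (exponent 1), so a few function-word-like
  tokens dominate, plus a `p_other_gold = 0.2` chance per slot of reusing
  another object's gold word — the "many frequent but irrelevant pairs"
  regime that defeats naive co-occurrence counting;
* **attention persistence**: the attended object follows a sticky Markov
  chain (`p_stay = 0.6`; the long-run marginal stays uniform). Caregivers
  dwell on a toy across consecutive utterances, and the consistency reward
  is informative exactly on same-object transitions — with independent
  draws those occur at rate $1/M$ and the reward degenerates to "pay +100
  for almost anything", after which no learner can separate referents from
  fillers. Set `p_stay = 0` to reproduce the independent regime;
* **dwell-consistent naming**: when an object has several planted names
  (37 words over 17 objects gives every object at least two), the
  caregiver's name for it is drawn once per attention dwell and repeated
  until attention moves. Resampling the name per situation would make the
  consistency rule *punish* referent choices (same object, different
  synonym) and reward locking onto a shared filler word — the opposite of
  real child-directed speech, where repetition of the object's name within
  an episode is pervasive;
* with `prosody_mode = TRUE`, referent-word positions draw prominence from
  Normal(`prominence_mean` = 30 Hz, `prominence_sd` = 10 Hz) and all other
  positions from Normal(0, `baseline_sd` = 10 Hz), mimicking the
  75th-percentile pitch difference between a word and its utterance.

What the generator does **not** emulate: syntax, multi-word referents,
verb/function-word semantics, attention annotation errors (unless
`p_misattention > 0`), and the long-tailed utterance-length and
object-frequency distributions of real transcripts. Passing tests on
synthetic corpora therefore show that the learners recover plantable
structure under controlled ambiguity — not that they would match any
particular transcript-derived score.

## Encodings

`encode_binary()` marks present word types with 1. `encode_prosodic()`
places each word's prosodic feature at its index (duplicated words keep
their maximum feature — prominence is the signal of interest). The
prosodic feature of a word is the difference between the 75th-percentile
pitch of the word and of its utterance (`prosodic_feature()`), with the
percentile convention fixed to linear interpolation between order
statistics (`stats::quantile` type 7). Zero-filling marks absent words in
both encodings.

## Problem sizes used by the test suite

Checks that train learners run at sizes chosen to keep the default suite
fast while preserving the qualitative contrasts:

* referent recovery: 17 objects, 37 gold words, 380 fillers, 600
  situations, at most 4 distractor objects, DQN with $H = 200$, $J = 50$,
  minibatches of 10, $C = 4$, 300 episodes;
* prosodic-vs-binary comparison: 8 objects, 12 gold words, 80 fillers,
  200 situations, $H = 50$, 80 episodes, median best-F over 5 seeds;
* micro-corpus recovery: 2 objects / 2 words / 40 situations, 500
  episodes, all three tabular learners. Each utterance is exactly the
  attended object's name; with richer utterances the 2-object consistency
  game admits a symmetric swapped labelling as a second fixed point, and
  which one a run converges to would depend on the seed.

## Numerical and degenerate-input choices

* Greedy ties: lowest word index (tabular and neural alike).
* All-zero rows in `normalize_qw()` stay zero; referent selection ties
  break toward the first object row.
* A corpus of one situation trains without rewards and yields an empty
  history; `episodes = 0` returns the seeded initial state untouched.
* Every source of randomness (table/network init, exploration, minibatch
  sampling, generation) runs under a single seed via `withr::with_seed`,
  so any fit is bit-reproducible from its configuration; `cmd_train()`
  reruns write byte-identical `qw.tsv`.
* Serialized corpora, matrices and networks are plain text (JSON lines,
  TSV, JSON) at full double precision.

## Known limitations

* The $(100, -1)$ reward asymmetry means inconsistent choices are barely
  punished relative to the reward for consistent ones; learning leans
  almost entirely on the positive arm. The `unit_mode` rewards remove the
  asymmetry but learn more slowly at these scales.
* NFQ's full-store regression per situation makes it the slowest learner
  per episode at scale.
* Tabular learners index states by situation ordinal, so their tables do
  not generalize across corpora and their recovery degrades on large
  vocabularies; that mirrors their role as baselines for the neural
  learners.
* Prosodic values are inputs (or synthesized); no audio processing is
  attempted.
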