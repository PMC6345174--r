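---
title: "Generating synthetic chief complaints from structured ED records"
author: "synthcc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating synthetic chief complaints from structured ED records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and data model

`synthcc` builds a record-conditioned language model for emergency
department (ED) chief complaints and the measurement apparatus needed to
decide whether its output is usable: text-quality metrics, epidemiological
validity checks, and a personal-name audit. Everything operates on
*record-sentence pairs*: the discrete variables of one ED visit, expanded
to a sparse binary vector, paired with one short free-text complaint.

A `RecordSchema` fixes the variable order and cardinalities; the package
ships a typical nine-variable ED layout (`edVisitSchema()`, 399 binary
dimensions) and a small four-variable simulator schema (`simSchema()`, 21
dimensions). Note that published descriptions of comparable feeds sometimes
state a slightly larger vector (403) than the sum of the printed coded
ranges (399); the package derives the dimension from the schema, so any
extra "unknown" categories can be added explicitly if a feed carries them.

Missing variables are all-zero blocks rather than explicit missing levels.
That choice keeps the encoding faithful to multi-hot diagnosis blocks
(where "no bits set" genuinely occurs) at the cost of making "missing" and
"no information" indistinguishable to the model.

## Preprocessing

Complaints are lowercased and whitespace-tokenized. Punctuation is kept:
chief complaints are terse, and tokens such as `x` ("pain x 3 days") or
embedded ICD fragments carry signal. Two filters run in a single pass, in
this order, with frequencies computed once on the raw corpus:

1. drop every pair whose complaint contains a token with raw-corpus
   frequency below 10 — this is what removes rare misspellings,
   abbreviations, and most residual names;
2. drop every pair longer than 18 content words.

Because frequencies are not recomputed after removal, a kept token's
frequency in the *surviving* corpus may dip below the threshold; the
guaranteed invariant is that every vocabulary token had frequency ≥ 10 in
the original corpus, and the tests assert exactly that. The length filter
counts content words only; the start/end markers appended afterwards do not
count against the limit. Vocabulary indices are assigned by descending raw
frequency with lexicographic tie-breaks, so builds are deterministic;
index 0 is reserved for padding, indices 1 and 2 for the start and end
markers. Stored sequences are `[start, content, end]` zero-padded to a
constant width; the decoder input/target pair is the standard
teacher-forcing shift of that layout.

`splitCorpus()` makes a seeded 75/25 train/validation partition and keeps a
seeded subsample (default cap 50,000) of the validation pairs as the test
set used for decoding experiments, which keeps generation-time evaluation
affordable.

## The generator

The network is deliberately minimal, in the image-captioning lineage:

* **Record encoder** — one feedforward layer, `tanh`, mapping the sparse
  record to the LSTM state size. It is pretrained as the encoder half of an
  autoencoder (sigmoid reconstruction, elementwise binary cross-entropy);
  the decoder half is discarded after pretraining.
* **Word embeddings** — trained from scratch with the model; the padding
  row is pinned at zero throughout training.
* **Decoder** — a single-layer LSTM with forget/input/output gates. Both
  the initial hidden state and the initial cell state are set to the
  encoded record; with only one layer this is the simplest way to expose
  the record to both information paths, and it leaves the encoder
  responsible for choosing what to store. The forget-gate bias is
  initialised at 1 (a standard stabilisation), other biases at 0, weights
  Glorot-uniform, embeddings uniform on ±0.05.
* **Output** — a dense projection to the vocabulary followed by softmax.
  Padding has no output unit, so it receives zero probability by
  construction.

Training is teacher-forced cross-entropy with Adam at learning rate 0.001
in mini-batches of 512 pairs (clamped with a warning on smaller corpora).
After each epoch the full validation loss is computed; training stops when
it has failed to be strictly lower than the best value for 2 consecutive
epochs, or at `maxEpochs`, and the best epoch's weights are restored. One
master seed drives initialisation and shuffling; there is no dropout, so
runs are reproducible.

Default sizes are `hiddenDim = 32`, `wordEmbedDim = 16`. These are
desk-scale defaults chosen for the bundled simulator (vocabulary of a few
hundred); for a multi-million-pair corpus with a vocabulary in the tens of
thousands both would be raised (256/128 is a reasonable starting point) —
they are plain configuration values, not baked in. The forward/backward
passes are implemented in RcppArmadillo; the optimiser and training loop
are plain R.

## Decoding

Three schemes implement the generation loop (encode record, feed start
token, pick next token, repeat until end token or 18 tokens):

* **Greedy** — argmax at each step. Ties break toward the lowest
  vocabulary index, making the decoder fully deterministic.
* **Temperature sampling** — draws from `softmax(logits / t)`; `t -> 0`
  recovers greedy, `t = 1` samples the model's own distribution. Seeded.
* **Beam search** — keeps the `k` best partial sequences by raw summed
  log-probability (no length normalisation, matching the "most likely
  overall" reading; this makes wide beams favour short, generic
  completions, which is part of the phenomenon under study). An end-token
  candidate retires to a finished pool only when it ranks within the
  step's top `k`; the live beam refills from lower-ranked unfinished
  candidates. The result is the top `k` finished sequences, falling back
  to unfinished ones truncated at the length cap. With `k = 1` this
  reduces exactly to greedy decoding, and with exhaustive width it equals
  brute-force enumeration — both are tested. Note that the best finished
  score is *not* guaranteed to be monotone in `k` (a wider beam can
  displace the prefixes a narrower beam would have kept); the tests assert
  only the always-true dominance properties.

`generateCorpus()` returns one detokenized sentence per record, aligned
with input order; greedy and temperature decoding are batched across
records, beam search runs per record.

## Text-quality metrics

Standard n-gram metrics rate very short sentences harshly, so the package
pools *variable-length* n-grams: all orders `1 .. min(4, sentence length)`
enter one clipped count (a candidate n-gram is credited at most its
reference multiplicity). PPV is the matched share of candidate n-grams,
sensitivity the matched share of reference n-grams, F1 their harmonic mean
per pair, averaged unweighted over pairs. Pooling across orders (rather
than a BLEU-style geometric mean over per-order scores) is the design
choice that keeps two-word complaints from scoring 0 just for having no
4-grams.

The consensus score represents each sentence as a TF-IDF vector over the
same pooled n-grams. IDF is `ln(N / df)` with document frequency counted
over the reference corpus and floored at 1 (a candidate n-gram never seen
in any reference gets the maximal IDF rather than a division by zero).
Each pair contributes the cosine of its two vectors; a zero-norm vector
contributes 0. There is exactly one reference per candidate, so no
multi-reference consensus averaging and no length penalty are applied.
Both metrics are validated against independent brute-force implementations
to 1e-12.

Embedding similarity — cosine of the two sentences' mean word vectors —
covers the blind spot of every n-gram metric: pairs like "od" / "overdose"
score 0 on overlap yet are nearly synonymous. All-out-of-vocabulary
sentences raise an error rather than silently scoring 0.

## Epidemiological validity

`wordVariableTable()` counts records (not token occurrences) whose
complaint contains a word, in two strata of a discrete variable;
`ratios()` turns the 2×2 table into a risk ratio and an odds ratio. Zero
cells yield an explicit infinity flag; a Haldane-Anscombe (+0.5) variant
is available for interval work rather than silently correcting. Published
fall-by-age counts reproduce the expected arithmetic: 207/2234 vs 48/4009
gives risk ratio 7.74 (odds ratio 8.43), and 229/2234 vs 27/4009 gives
15.22 — "nearly 8" and "about 15 times more likely" are ambiguous between
the two ratio types, so both are always reported.

The diagnosis classifier is a word-embedding + single-GRU + softmax
network trained with the same optimiser and early-stopping rule as the
generator. Multi-code records are labelled with a single primary code: the
pipelines pass the first listed code explicitly from the record frame;
when only a vectorized corpus is available the lowest-index set bit is
used, because the bit encoding is unordered (this convention is stated on
the function and matters only for the fraction of records with several
codes). Scores are support-weighted one-vs-rest ("weighted macro")
sensitivity, PPV and F1; a class never predicted has PPV 0 by convention.
`validityComparison()` scores the classifier on authentic test complaints
and on synthetic complaints generated from the same records under each
sampling scheme.

## PII audit

Skipgram-with-negative-sampling word vectors (dimension 100, window 5,
min count 5, 5 negatives — conventional word2vec defaults) are trained by
sequential per-pair SGD in C++ with its own seeded RNG, so results are
exactly reproducible. `discoverNames()` iterates the audit loop: retrieve
the 100 cosine nearest neighbours of every known name, label candidates
with an oracle, add confirmed names, stop when a pass adds nothing. The
oracle abstraction replaces the manual check of neighbour lists so the
loop is testable (in tests: membership in the simulator's planted name
list; the CLI offers an interactive mode that prompts a human). Cosine
similarity is used for neighbour retrieval (normalised vectors).
`piiReport()` then counts complaints containing any discovered name in the
authentic corpus and in the synthetic corpus generated from the same
records. The audit's working hypothesis — low-frequency name tokens are
improbable under the model, so likelihood-seeking decoding never emits
them — is exactly what the benchmark checks.

## The simulator: what it emulates, and what it does not

`generatePairs()` produces corpora with planted, recountable structure:

* **Templates** — 12 diagnosis groups with a handful of terse ED-style
  complaint templates each (all ≤ 16 words, so name injection can never
  push a complaint past the 18-word filter). A record's diagnosis and
  template are sampled *jointly*, which makes rule arithmetic exact.
* **Exclusivity** — templates containing a rule's token get weight 0
  outside the allowed stratum, so e.g. "preg" occurs for 0 male-coded
  records with probability 1. Weights are set so about 1% of female
  records carry the token.
* **Association** — joint weights of templates containing "fall" are
  multiplied by 8 for the oldest age code. Because weight multiplication
  acts directly on selection odds, the planted complaint-level odds ratio
  equals 8 in expectation (the realized value is recounted into
  `PlantedTruth` and checked against a Woolf 95% interval at n = 50,000).
  The realized *risk* ratio is necessarily smaller (about 6 at these base
  rates), which is why the odds ratio is the planted quantity.
* **Names** — 20 surname tokens appended as "dr <name>" to randomly chosen
  complaints at exact target counts (default 10–30, i.e. above the
  vocabulary cutoff, so the model does see them); the shared "dr" cue
  gives the embedding space a name cluster for the discovery loop to find.
* **Noise** — each token is corrupted (adjacent-character swap) with
  probability 0.005, creating the low-frequency misspellings that the
  frequency filter and the generator should both remove.
* **Missingness** — 15% of diagnosis blocks and 2% of hospital codes are
  blanked, mirroring the incompleteness of real feeds.

Demographics are sampled independently (five age groups at
0.22/0.22/0.20/0.18/0.18, two genders at 0.5/0.5, uniform hospitals, 20%
secondary-diagnosis rate) — values chosen once as plausible for an ED
population with enough mass in the oldest stratum to estimate the planted
ratio precisely.

What the simulator does *not* emulate: clinically realistic language
diversity (a few dozen templates vs tens of thousands of real phrasings),
marginal distributions of any real feed, correlated demographics,
multi-token names, or non-name PII. Consequently, passing benchmarks here
establishes that the *mechanisms* work — exclusivity is learned,
associations are preserved and typically amplified, low-frequency tokens
are dropped — not that any particular real-data score would be attained.
Real-data metric values depend on corpus scale and diversity and are out
of reach at desk scale.

## Numerical and operational choices

* Ties everywhere break toward the lowest vocabulary index; all decoders
  are deterministic given their seed.
* Softmax is computed with max-subtraction; log-probabilities are clamped
  at `log(1e-12)` in the loss only.
* Temperature rescales logits (equivalently `p^(1/t)` renormalised).
* Degenerate inputs: empty candidate sentences score 0 with an explicit
  flag; a single-pair corpus is rejected by the TF-IDF score (IDF needs a
  corpus); all-OOV sentences error in embedding similarity; stratum totals
  of 0 error in `ratios()`.
* Checkpoints are single-file R serializations of the whole model object
  (weights + config + schema + vocabulary), so a run is reconstructible
  from its artifact directory; every pipeline command also writes its
  resolved settings and the package version next to its outputs.

## Problem sizes used in the bundled checks

The standard benchmark is 50,000 simulated pairs (about 37,000 training
pairs after filtering and the split), a 32-unit model trained to the
30-epoch cap, and greedy generation for all ~12,000 held-out records; the
classifier and the skipgram embeddings train on the same split. Decoder
cross-checks run on hand-built transition-table models where exact
enumeration is feasible, and metric oracles run on 1,000 random sentence
pairs. Scheme-ordering comparisons are evaluated on 4,000 held-out pairs,
where the observed greedy-over-beam margin (~0.006 F1) is stable; on very
small subsets the ordering drowns in sampling noise.

## Known limitations

* The generator is record-conditioned only; it cannot produce information
  absent from the discrete variables, and it systematically drops rare
  words — useful for de-identification, harmful for outbreak-detection
  use cases that look for novel terms.
* Association amplification means synthetic text overstates common
  word-variable relationships relative to the authentic corpus; crude
  ratios estimated from synthetic text should be treated as directional.
* The name audit covers single-token names planted in complaint text; it
  is not a general clinical de-identifier (no dates, identifiers, or
  multi-token names).
* "First listed" diagnosis is unrecoverable from a vectorized record; see
  the classifier-labelling convention above.
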