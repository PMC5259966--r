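---
title: "Amino-acid n-gram language models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amino-acid n-gram language models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protlang)
```

## The model

`protlang` treats a protein P = (a₁, …, a_L) over the 20 canonical amino
acids as a sentence in a language and asks which of two languages — the
human proteome or the non-human proteome — more plausibly produced it. Each
language is an order-n Markov (n-gram) model: the probability of each
residue depends only on the previous n−1 residues,

$$P(P \mid H) \;\approx\; \prod_{i=n}^{L}
  P(a_i \mid a_{i-n+1} \dots a_{i-1},\, H),$$

and each conditional probability is estimated from a training corpus by
maximum likelihood as a ratio of n-gram counts. The decision rule is the
two-class Bayes comparison on the posterior log-odds

$$s(P) = \bigl[\log P(H) + \log P(P \mid H)\bigr] -
         \bigl[\log P(NH) + \log P(P \mid NH)\bigr],$$

with priors estimated as the corpus-size fractions; the evidence term is
shared and cancels. A query is called human when s(P) exceeds a margin
(default 0, the bare inequality).

Two modeling points deserve emphasis because the literature sometimes
typesets them loosely:

1. **Products, not sums.** The chain-rule factorization of a sequence
   likelihood is a product of conditional probabilities. Some presentations
   of biological n-gram models typeset this as a sum; a sum of
   probabilities is not a probability of the sequence and breaks the Bayes
   comparison. `protlang` computes the product, as a sum of *logarithms*,
   which is also the numerically stable choice: a length-300 protein has a
   likelihood around e⁻⁴⁰⁰, far below double-precision underflow if
   multiplied naively.

2. **The denominator that normalizes.** The count estimator divides the
   n-gram count by a context count. Counting all (n−1)-windows includes
   each sequence's *trailing* context, which never extends to an n-gram;
   dividing by that count leaves each conditional distribution summing to
   slightly less than 1. `protlang` therefore uses the left-prefix marginal
   Σ_r C(context·r) as the denominator, which normalizes exactly; the raw
   (n−1)-window counts are retained in the count tables for diagnostics.
   The normalization property is enforced by tests to 1e−9 for every
   context.

## Tunable parameters

- **Order n** (default 3). Proteome-scale corpora (≈ 7 × 10⁷ residues)
  support n = 3 comfortably: 20³ = 8000 trigram contexts. The order is
  never hard-coded; `select_order()` chooses it by held-out perplexity, and
  the simulator experiments below use n = 2 against memory-1 generating
  chains (an order-m chain is matched by an (m+1)-gram model).
- **Smoothing** (default add-k with k = 0.01). Pure maximum likelihood
  assigns probability zero to unseen n-grams, so a single novel trigram
  makes a query's likelihood zero under one class and the log-odds ±∞ — or
  undecidable when it happens under both. Additive smoothing
  (count + k) / (context + 20k) keeps every distribution strictly positive
  while perturbing well-observed probabilities by ≈ k/context, negligible
  for contexts seen hundreds of times. `method = "none"` reproduces the
  literal count-ratio estimator; zero-probability factors then yield a
  −∞ sentinel (never an exception), and a query unscoreable under both
  models is flagged rather than silently labeled.
- **Prefix handling** (default `truncate`). The order-n approximation
  scores positions n…L and discards the first n−1 positions.
  `prefix = "chain"` instead scores positions 1…n−1 with the stored
  lower-order models so the full chain rule telescopes; it also makes
  sequences shorter than n scoreable. The difference is at most n−1 factors
  and is immaterial for proteins of typical length, but `chain` is used
  internally by `select_order()` so that every candidate order scores the
  same held-out positions.
- **Margin** (default 0). How much better than even the posterior must be
  before a query is called human. The bare rule is margin 0; a screening
  application that wants "high-probability" calls can raise it. Exact zero
  log-odds is always labeled `tie`: symmetric inputs must give symmetric
  outputs, and an arbitrary tie-break would violate the model-swap
  antisymmetry that the tests enforce exactly.
- **Length confounding.** The log-odds of an n-gram ratio grows linearly
  with L, so long sequences reach extreme scores. Reports carry both the
  raw `log_odds` (which the decision uses) and `log_odds_per_pos`
  (log-odds per scored position), the comparable quantity across lengths.
- **Identity threshold** (default 0.9 in the training pipeline). Redundancy
  filtering before training prevents large duplicated families from
  dominating the count tables, and priors are computed from the
  *post*-filtering corpus sizes, matching the pipeline order of the
  filter-then-count convention (a `prior_counts = "pre_dedup"` switch
  exists for sensitivity analysis).

## Residue sanitization

Real Swiss-Prot entries contain non-canonical codes (B, Z, X, U, O, J) and
annotation characters. The default policy `drop` removes such characters
and keeps the sequence, preserving maximal training data while keeping the
20-letter event space closed; `reject` makes any non-canonical residue an
error (naming the residue and position); `map_x` first maps to the
ambiguity code X and then removes X before modeling — the same retained
residues as `drop`, but substitutions and removals are reported separately.
Records emptied by sanitization are omitted and counted in the corpus's
sanitization report. Case is always folded to upper; lowercase masking is
not meaningful for proteins.

## The identity measure and greedy clustering

`pairwise_identity()` counts identical aligned positions in the optimal
global alignment under match = 1, mismatch = 0, gap = 0 scoring and divides
by the shorter sequence's length. With free gaps and mismatches the optimal
score equals the longest common subsequence, which makes the measure exact,
symmetric and testable against a textbook dynamic program (the test suite
does exactly that). This is the shorter-sequence convention of CD-HIT-style
filters in spirit, not a bit-for-bit CD-HIT reimplementation — the
contract here is a *deterministic* de-duplication stage, and CD-HIT's
banded heuristics are deliberately out of scope. `greedy_cluster()` visits
sequences longest-first (ties by id); each joins the first representative
at or above the threshold, else founds a cluster, so no two representatives
reach the threshold. Above a configurable corpus size (default 5000) a
k-mer containment prefilter (k = 5, 10% shared-k-mer floor) skips hopeless
alignments; it can only skip a merge, never force one, so the
representative invariant survives.

One consequence of the LCS-based measure worth knowing: unrelated random
sequences score well above their point-mutation identity (≈ 0.3–0.45 for
20-letter sequences, ≈ 0.65 for 4-letter ones), because the alignment is
free to gap. At the 0.9 threshold used for de-duplication this is harmless;
thresholds below ≈ 0.5 on reduced alphabets will merge unrelated sequences
by design of the measure.

## What the simulator emulates — and what it does not

`chain_spec()` defines a fully known generating process: an alphabet, a
Markov memory m (0 = i.i.d.), a transition matrix and an initial context
distribution (default: the stationary distribution, computed by a linear
solve; reducible chains are rejected with the stray contexts named). This
gives closed-form targets: `chain_entropy_rate()` is the stationary-
weighted transition entropy, and exp(entropy rate) is the perplexity floor
for any model on long samples. Every draw is seeded — corpora derive
per-sequence substreams from one root seed — so all experiments are
bit-reproducible.

The simulator emulates exactly the statistical structure the n-gram model
assumes: stationary short-memory dependence. It does **not** emulate real
proteins — no domain architecture, no substitution-matrix relatedness, no
indels, no length/composition coupling, no homologous families (except the
explicit near-duplicate fixtures built for the clustering tests). Passing
the synthetic benchmarks therefore demonstrates that the estimator,
scorer and decision rule are *correct* (they recover known truth), not that
human/non-human screening achieves any particular accuracy on real
proteomes — that depends on how separated the real corpora are, which only
real data can say.

## Study conditions for the built-in experiments

The test suite and `scripts/acceptance.R` run the following fixed designs
(reduced 4-letter alphabet, chosen so the brute-force oracles stay exact
and exhaustive):

- **Oracle equivalence**: 200 randomized instances (≤ 5 sequences, lengths
  ≤ 12, orders ≤ 3, both smoothing methods); counts, conditional
  probabilities, log-likelihoods and posterior decisions must match an
  independent window-sliding / Bayes-enumeration oracle to 1e−12.
- **Parameter recovery**: an asymmetric memory-1 chain, 1000 sequences of
  length 200; the order-2 model's conditional probabilities must be within
  0.02 of the truth (max-abs), and the error must shrink from the
  10-sequence fit.
- **Perplexity bridge**: 500 training + 150 held-out sequences of length
  300 from the same chain; held-out perplexity of the matched-order model
  within 2% of exp(entropy rate).
- **Two-class benchmark**: two memory-1 chains with identical stationary
  composition but opposed transition preferences (self-repeat 0.7 vs
  cyclic-successor 0.7), 100 sequences per class of length 300; margin-0
  accuracy must exceed 0.95, and accuracy is non-decreasing in training-set
  size over {10, 100, 1000} within simulation noise. The chains differ by
  ≈ 1.2 nats of per-position Kullback–Leibler divergence, so 300-residue
  sequences are separated by hundreds of nats and accuracy saturates at 1;
  the benchmark validates the machinery rather than probing the
  small-sample frontier.
- **Redundancy fixture**: two founder sequences of length 120 over the full
  alphabet, five members each with ≤ 5% point substitutions; clustering at
  0.9 must yield exactly 2 representatives, and the representative count
  must be monotone in the threshold.

These sizes keep the full suite under a minute on one CPU while leaving
each statistical margin wide (e.g. the recovery error at the stated design
is ≈ 0.005, a quarter of the 0.02 bound).

## Numerical and degenerate-input choices

- All likelihood math is in natural-log space; −∞ is the sentinel for an
  impossible sequence, NaN log-odds marks a query impossible under both
  models (`unscoreable`, labeled `tie`).
- Per-context normalization is asserted to 1e−9; oracle agreement to
  1e−12; prior-shift and antisymmetry identities hold exactly in floating
  point because swapped computations reuse identical terms.
- The unigram model's single context is the empty string; it is
  special-cased both in probability lookup (R cannot index by an empty
  name) and in the JSON schema (object keys cannot be empty), which is why
  model files are validated on load.
- Ties in report ordering are broken lexicographically by id; greedy
  clustering breaks length ties by id — every ordering in the package is
  total, so reruns are byte-identical, which the tests assert on the model
  files and TSV reports.
- A corpus whose sequences are all shorter than the order yields an empty
  count table with a warning at counting time and an explicit error at
  scoring time (or lower-order scoring under `prefix = "chain"`).

## A small worked run

```{r example}
ab <- c("A", "C", "D", "E")
tm <- matrix(0.1, 4, 4, dimnames = list(ab, ab)); diag(tm) <- 0.7
spec <- chain_spec(tm, order = 1)
co <- generate_labeled_corpora(spec, spec, 20, length = 100, seed = 42)
m <- train_ngram_model(co[[1]], 2, smoothing_config("add_k", 0.01),
                       alphabet = ab)
round(sapply(ab, function(ctx) conditional_prob(m, ctx, ab)), 3)
c(perplexity = perplexity(m, co[[2]]),
  floor = exp(chain_entropy_rate(spec)))
```

## Known limitations

- The identity measure is LCS-based, not banded-alignment-based; it is
  exact but quadratic, so corpora of tens of thousands of sequences rely on
  the k-mer prefilter for throughput.
- No backoff/interpolated/Kneser–Ney smoothing; add-k is sufficient for the
  corpus sizes the model targets, and fancier smoothing would change the
  estimator away from the count-ratio contract.
- Scores are posterior log-odds, not calibrated probabilities or e-values;
  ranking and thresholding are supported, significance statements are not.
- Two classes only.
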