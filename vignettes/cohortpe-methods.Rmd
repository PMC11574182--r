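---
title: "Model and analysis methods in cohortpe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and analysis methods in cohortpe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cohortpe)
```

This vignette documents the model equations, the analysis conventions and
the design decisions behind the package's defaults.

## 1. The lexicon and stimulus-design statistics

A lexicon (`as_lexicon()`) is a tibble of words, each with a
segment-level transcription in which `-` marks syllable boundaries, and a
usage-frequency count. Two matching rules operate on it:

* **Syllabified matching** (`first_syllable_cohort()`): a word matches a
  first syllable when the segments before its first boundary equal it
  exactly. A monosyllable matches only when its whole form equals the
  syllable, so in the example below `tang` belongs to the /t a N/ cohort
  while `tank` does not.
* **Positional prefix matching** (`prefix_cohort()`): the incremental
  simulator matches heard segments position for position across the whole
  transcription, boundary tokens included.

The conditional probability of a second syllable given a first is the
frequency ratio

$$
p(\mathrm{Syl_2} \mid \mathrm{Syl_1}) =
\frac{\sum_i \mathrm{freq}(\mathrm{word}_i \ni \mathrm{Syl_1\,Syl_2})}
     {\sum_j \mathrm{freq}(\mathrm{word}_j \ni \mathrm{Syl_1})},
$$

implemented by `conditional_syllable_probability()`. Surprisal is its
negative logarithm, and predictive uncertainty is the Shannon entropy
$-\sum_k p_k \log p_k$ over the attested continuations
(`syllable_surprisal()`, `syllable_entropy()`). Entropy is zero exactly
when a single continuation carries all the probability mass.

```{r lexicon}
lex <- as_lexicon(tibble::tibble(
  word          = c("bingo", "tango", "tangle", "tang", "tank"),
  transcription = c("b I N - g @U", "t a N - g @U", "t a N - g l=",
                    "t a N", "t a N k"),
  frequency     = c(210, 7, 69, 58, 60)))
conditional_syllable_probability(lex, "b I N", "g @U")
conditional_syllable_probability(lex, "t a N", "g @U")
syllable_entropy(lex, "t a N")
```

## 2. The acoustic model

Each segment carries a fixed-length acoustic feature vector; pairwise
Euclidean distances between the vectors (`segment_distance_matrix()`)
express acoustic confusability. The boundary token, treated as
perceptually unambiguous, is appended with the largest observed
phoneme-to-phoneme distance. A temperature-controlled softmax converts
distances into row-stochastic sensory evidence:

$$
p(\mathrm{segment}_j \mid \mathrm{heard}\ i) =
\frac{e^{-d_{ij} T}}{\sum_k e^{-d_{ik} T}}.
$$

Large $T$ approaches one-hot rows (minimal sensory uncertainty); $T \to 0$
approaches uniform rows (maximal uncertainty). The likelihood of a word
given heard segments is the product rule over positions
(`word_evidence()`): $\prod_k \mathrm{evidence}[\mathrm{heard}_k,
\mathrm{word}_k]$.

### Synthetic features

The bundled generator (`generate_segment_features()`) draws one vector per
segment as a Gaussian *class centre* plus within-class jitter
(`n_feature_classes = 8`, `feature_within_sd = 0.3` by default). Real
acoustic features are far more confusable within a phonetic class (place
or manner neighbours) than across classes; clustering reproduces that
graded structure, which matters for the dissociation below. With
independent identically distributed vectors instead, all segments are
nearly equidistant and no single temperature exhibits all of the
qualitative condition orderings at once.

## 3. The recognition simulator

At each input prefix the posterior over words is recomputed afresh
(`posterior_update()`):

$$
p(\mathrm{word}_i \mid \mathrm{evidence}) =
\frac{p(\mathrm{word}_i)\, p(\mathrm{evidence} \mid \mathrm{word}_i)}
     {\sum_j p(\mathrm{word}_j)\, p(\mathrm{evidence} \mid \mathrm{word}_j)},
$$

with priors proportional to frequency. The next-segment prediction sums
posteriors over words sharing the same next segment
(`segment_prediction()`); words that end at the current position
contribute to no entry, so the prediction can sum to less than one. Two
readouts combine the prediction with the evidence row of the segment
actually heard:

* `sharpened_signal()`: elementwise product, renormalised to sum to one;
* `prediction_error()`: evidence minus prediction, unnormalised.

Univariate linking functions stand in for overall response magnitude:
summed absolute prediction error, the mean of log-transformed sharpened
probabilities (floor $10^{-12}$), and the Shannon entropy of the
sharpened distribution.

### The divergence point and the 2 x 2 design

Items come in sets of cross-spliced pairs: each word (Match) has a
pseudoword partner (Mismatch) whose second syllable is the set's other
Syl2 type. Both share their first syllable and the Syl2 onset segment, so
the *divergence point* — the first segment at which the pseudoword
deviates — is the second segment of Syl2. First syllables either predict
their continuation uniquely (Strong) or compete with several words
(Weak). `run_condition_simulation()` evaluates both representations for
every item at its divergence point and summarises:

* per-item univariate readouts;
* within-condition Euclidean pattern distances between item
  representations, with *reciprocal pairs* excluded
  (`reciprocal_pair_mask()`): within a set and congruency class, pairs
  whose second syllables differ are exactly those in which one item's
  prediction is the other's input, evoking similar but opposite
  prediction errors whose encoding polarity is unknown.

The headline statistic is the interaction contrast
$(\mathrm{Strong}-\mathrm{Weak} \mid \mathrm{Mismatch}) -
(\mathrm{Strong}-\mathrm{Weak} \mid \mathrm{Match})$: positive
(a cross-over) for prediction errors, non-positive for sharpened signals.

```{r simulation}
pl <- run_divergence_simulation(t_grid = NULL)
glance(pl$simulation)
```

### Choice of the default temperature

The temperature is a free parameter of the sensory model, exposed
everywhere and defaulting to `default_temperature()` = 0.5. At this
moderate-uncertainty point of the default class-structured features the
full set of qualitative orderings holds simultaneously: the
prediction-error cross-over, sharpened Match > Mismatch with no
cross-over, and the univariate orderings (Mismatch > Match,
Strong+Match < Weak+Match) for both readouts. The default sweep grid
`default_temperature_grid()` spans two orders of magnitude
($10^{-1.5}$ to $10^{0.5}$); under high uncertainty (low $T$) the
Match-condition prediction-error distances reverse to Strong > Weak,
and the reversal disappears toward the top of the grid
(`uncertainty_sweep()` reports these flags per temperature).

## 4. Pattern analysis (RSA)

* `euclidean_rdm()` — Euclidean distances between pattern rows.
* `crossnobis_rdm()` — cross-validated Mahalanobis distances, averaged
  over ordered fold pairs $a \neq b$:
  $(x_i^a - x_j^a)' \Sigma^{-1} (x_i^b - x_j^b)$. Cross-validation makes
  the estimator unbiased around zero for identical patterns, so values
  may legitimately be negative and are not floored.
  `shrinkage_covariance()` supplies a regularised noise covariance.
* `phonetic_rdm()` / `levenshtein_phonetic_dissimilarity()` — unit-cost
  edit distance over segment labels, divided by the longer syllable
  length.
* `rdm_correlation()` — Spearman correlation over unmasked upper-triangle
  pairs, clipped to $\pm(1-10^{-10})$ and Fisher-z transformed.

## 5. Group-level sensor statistics

* `reject_outlier_epochs()` — epochs whose time- and channel-averaged
  power exceeds the reference mean by 2 SD (condition-specific,
  `"magnitude"` mode) or 3 SD (pooled, `"pattern"` mode), computed per
  subject, are set to `NA`.
* `select_sensors()` — the 20 sensors (by default) with the largest
  time-averaged evoked power.
* `cluster_permutation_test()` — one-sample $t$ at every timepoint;
  contiguous same-signed supra-threshold runs form clusters scored by
  summed $t$; the null distribution is the maximum absolute cluster sum
  over whole-subject sign flips, giving family-wise error control; the
  cluster $p$ is $(1 + \#\{\mathrm{null} \ge |t_{\mathrm{sum}}|\}) /
  (1 + n_{\mathrm{perm}})$.
* `within_subject_se()` — Cousineau-centred (subtract the subject mean,
  add the grand mean) standard errors with the Morey correction
  $\sqrt{C/(C-1)}$.

## 6. Synthetic neural data and mechanism recovery

`generate_neural_dataset()` projects each item's divergence-point
representation through a fixed random linear embedding into sensor space,
scales the embedded patterns to unit average norm, switches them on with
a smooth half-sine inside a 100–300 ms response window, multiplies by
`snr`, and adds unit Gaussian noise (repetitions share the signal, not
the noise). `run_mechanism_recovery()` then plays the analysis back
blind: outlier rejection, window-averaged per-subject patterns, Euclidean
RDMs, and correlation with the two candidate model RDMs; the generating
mechanism is decoded as the better-correlating model. At the default
`snr = 0.5` decoding is reliable; as `snr` approaches zero it falls to
chance.

## 7. Reproducibility conventions

Every stochastic routine takes an explicit integer seed and restores the
caller's RNG state. Generators are pure functions of their parameter
objects. Pipeline output directories include the generating tables
(lexicon, inventory, features, design) and a `provenance.json` recording
package version, R version and full configuration, sufficient to re-run
bit-identically.
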