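---
title: "Quantifying word beauty: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying word beauty: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wordbeauty)
```

## The problem and the modelling stance

Single words carry aesthetic value: German speakers reliably judge some
words beautiful and others ugly.  `wordbeauty` operationalizes a strictly
*corpus-computable* account of this judgment: every predictor is derived
from a frequency lexicon, the word form itself, or a wordnet-style is-a
taxonomy — never from human ratings.  The package therefore has three
layers: feature extraction, a classification study, and per-feature
statistics, plus a synthetic-data generator that supplies study inputs
with known ground truth.

The modelling assumptions are deliberately spartan.  Word beauty is
treated as a binary label; features act jointly through a nonparametric
tree ensemble (no linearity or additivity assumed); and semantic content
enters only through graph distances in an is-a hierarchy, so any taxonomy
with a unique root can be substituted for the shipped synthetic one.

## The eight features

| feature | definition | unit / range |
|---|---|---|
| `n_syllables` | vowel nuclei after greedy diphthong merging (ei, ai, au, eu, äu, ie) | count ≥ 1 |
| `sonority` | mean per-letter sonority rank | 1–5 |
| `length` | letters | count |
| `surprisal` | −log₂(count / total tokens) | bits |
| `neighborhood_n` | same-length lexicon words at Hamming distance 1 | count |
| `similarity` | mean relatedness to all other targets | 0–1 |
| `valence` | mean relatedness to positive minus negative affect labels (18/18) | signed |
| `ap` | same contrast against the 62/62 aesthetic vocabulary | signed |

Design notes on the less obvious ones:

* **Syllables.**  The counter is a transparent vowel-group rule with a
  German diphthong table, chosen over a hyphenation dictionary so that
  every behaviour is auditable in tests; the relatedness of the rule to
  real German syllabification is good for the synthetic vocabulary the
  package generates, which is built from exactly these syllable shapes.
  A different backend can be swapped in by replacing `count_syllables()`.
* **Sonority.**  The scale maps every letter (umlauts and ß included) to
  a manner class with ranks plosive 1, fricative 2, nasal 3, liquid 4,
  glide 4.5, vowel 5.  A word's score is the plain arithmetic mean, so
  the composition property "word score = mean of letter scores" is exact
  and testable.  The ranks are configurable but must stay strictly
  increasing from plosive to vowel.
* **Surprisal** uses *relative* frequency, making values invariant to
  corpus size; "count = total" gives 0 bits.
* **Relatedness** between lemmas is `1 − d/(2·depth)` where `d` is the
  shortest undirected path between their concept nodes (minimized over
  all node pairs when a lemma attaches to several) and `depth` is the
  maximum root distance.  This is a Leacock–Chodorow-flavoured
  normalization without the logarithm, keeping the value exactly in
  [0, 1] with 1 iff two lemmas share a node.  A `1/(1+d)` path kernel is
  available via `method = "path"`.
* **Word similarity is label-blind**: it averages over *all* other
  targets, not within-group, because it is a classifier input; the
  within-group question is answered post hoc by the ANOVA module.
* **Label sets are data, not code.**  The shipped YAML holds 18/18
  valence labels and 62/62 aesthetic labels (words such as *anmut*,
  *freude* versus *ekel*, *fäulnis*).  They are editable study inputs;
  nothing in the package depends on their identity, only on the
  positive/negative split being disjoint and resolvable in the taxonomy.
  Unresolvable labels are dropped with one warning; an empty side is an
  error, since the contrast would be undefined.

## The classification study

The classifier is an ensemble of extremely randomized trees: at each
split a random subset of features is considered and one uniformly random
threshold is drawn per candidate feature; trees are grown to purity on
the full sample (no bootstrap).  Two named parameter sets are declared:
`set1` (100 trees, ⌊√8⌋ = 2 candidate features per split) and `set2`
(1000 trees, all 8 features).  Training uses the **raw** feature matrix —
trees are invariant to monotone rescaling, so standardization would be
cosmetic; the z-scored view exists for the statistics module, where group
means on the z scale are the reported effect sizes.

Evaluation follows three routes:

1. **Train-on-all confusion matrix.**  With unbounded depth,
   single-observation leaves and distinct rows this is diagonal by
   construction; it is reported as a sanity check of that property, not
   as a performance claim.
2. **Stratified k-fold ROC/AUC** (default k = 5; k must not exceed the
   minority class count so every fold contains both classes).  Scores are
   the fraction of trees voting beautiful; the ROC is a threshold sweep
   and the AUC its trapezoidal area, which equals the Mann–Whitney
   concordant-pair statistic, ties counted half — the equality is
   enforced by test oracles.
3. **Label-permutation null** (default 5 runs): labels are reshuffled,
   the entire CV repeated, and the per-run mean AUCs reported.  The
   permuted labelings are stored in the result so that tests can verify
   the labels really moved.

Seeding is hierarchical: one master seed fans out through a fixed
integer stream into fold assignment, per-fold tree construction and
per-run permutations, so every stage is bit-reproducible and no two
stages share a stream.

## Per-feature statistics

`one_way_anova()` wraps the standard linear-model decomposition and adds
the effect sizes the study reports: R² = SSb/SStot and
R²adj = 1 − (1 − R²)(n − 1)/(n − g).  For two groups F equals the squared
pooled-variance t statistic, which is why the "group difference in a
linear regression" question is answered by the same code path.  Raw
p-values are reported without multiple-testing correction across the
eight features, and the serialized report says so explicitly.  Degenerate
inputs (a single group, zero within-group variance with equal means,
n < 3, constant columns for correlations) are rejected with errors rather
than returning NaN.

A useful identity: after pooled z-scoring, group means obey
n₁m₁ + n₂m₂ = 0.  With groups of 75 and 55 a beautiful-group mean of
0.25 therefore *forces* an ugly-group mean of −0.25·75/55 ≈ −0.341, and
an overall unit variance then fixes F(1,128) ≈ 12.0 and R²adj ≈ 0.079.
`scripts/acceptance.R` performs exactly this reconstruction.

## What the synthetic generator emulates

`generate_study()` produces the complete input bundle at a chosen master
seed:

* **Word forms** are syllable-built (onset cluster, vowel or diphthong
  nucleus, optional coda, occasional geminates).  Group sonority targets
  (defaults 3.12 beautiful / 2.9 ugly) are hit by solving the
  consonant-class mixture analytically from the target mean rank; mean
  length (default 12 letters) sets the syllable-count distribution.  The
  two template constants (3.5 letters per syllable; vowel-letter share
  0.358) were measured once from the template itself.  Length carries no
  group effect by default, and syllable count tracks length with
  R² ≈ 0.5 because the two are generated jointly by the same template.
* **Frequencies** follow a Zipf law: ranks are assigned at random and
  counts drawn as 1 + Poisson(10·n/rankˢ), exponent s = 1 by default.
* **Neighborhoods**: a fifth of the filler vocabulary is rewritten as
  single-letter same-class substitutions of existing words, so
  Coltheart's N has realistic variance instead of collapsing to zero for
  long unique strings.
* **The taxonomy** is a rooted tree with two *mirrored* semantic pole
  subtrees and one neutral subtree.  Positive aesthetic labels occupy
  nodes of one pole and negative labels the mirrored nodes of the other,
  making the geometry exactly symmetric: a word attached inside a pole is
  strictly closer to that pole's labels.  Beautiful words attach to their
  congruent pole with congruence probability π, ugly words vice versa.
  Attachment is *stratified*: exactly round(π·n) words per group (those
  with the smallest pre-drawn uniforms) attach congruently.  This removes
  attachment sampling noise from the injected effect — important because
  at π = 0.5 the no-signal control must actually carry no signal, and an
  iid coin would leak a per-seed group association through finite-sample
  imbalance.  Valence labels are scattered in positive/negative pairs
  across all subtrees, giving the valence feature variance but no
  built-in group signal and essentially no AP correlation.

**Calibration.**  The AP effect is parameterized as a target z-mean
separation (default 0.58, i.e. group z-means 0.245/−0.335 under the
pooled-standardization constraint).  π is found by bisection (40
iterations on [0.5, 1]) against the measured beautiful-group z-mean;
because the uniforms and candidate nodes are fixed before the search, the
measured effect is a monotone step function of π and the search is
deterministic.  `ap_noise = 0` forces π = 1 (perfect separation, AUC 1
downstream); `ap_effect = 0` forces π = 0.5.

**What it does not emulate:** real German morphology and orthotactics
beyond syllable shape; polysemy (each synthetic word attaches to one
node, only labels and homographs may share nodes); frequency–meaning
correlations; and any rating-based ground truth.  Passing tests on
synthetic data show that the pipeline recovers *injected* structure, not
that the features capture human beauty judgments.

## Numerical and testing choices

* Tolerances: importances sum to 1 within 1e-9; the z-scoring identity is
  checked to 1e-9; oracle equivalences (Hamming scan, concordant pairs,
  sums of squares, BFS distances) are exact to machine precision.
* Stochastic study-level checks (the permutation null band
  [0.45, 0.55] and the no-signal control band [0.4, 0.6]) are evaluated
  on the *average of four replicate experiments* at consecutive seeds: a
  single 5-run permutation grand mean has a Monte-Carlo sd near 0.03 and
  a single 130-word null-study CV AUC near 0.08, so one draw would be an
  underpowered test of a chance-level claim.  The bands themselves are
  unchanged.
* Problem sizes used by the suite: studies of 130 target words in
  lexica of 300–2000 forms, taxonomies of ~330 nodes, parameter recovery
  averaged over 20 seeds; these sizes make the full suite run in about a
  minute while keeping every group-level standard error well inside the
  tested tolerances.
* Ties in ROC thresholds are resolved by trapezoidal interpolation
  (equivalently, half credit per tied pair).  Fold assignment uses
  stratified sampling, so per-fold class proportions differ from the
  global ones by at most one item.
* Degenerate inputs fail loudly everywhere: cycles and multi-root edge
  lists name the offending cycle or roots, malformed resource rows name
  their line number, vowel-less words and unclassifiable characters name
  the character, empty intersections advise a resource mismatch.

## Known limitations

* The relatedness measure is purely path-based; information-content
  measures (Resnik, Lin) would need corpus-annotated node frequencies,
  which the resource format does not carry.
* Sonority is computed per letter, not per phoneme; digraphs (sch, ch)
  are scored letter-wise.  This is faithful to the orthographic stance of
  the package but diverges from phonological sonority for some clusters.
* The importance ranking is descriptive: impurity importances are known
  to favour high-cardinality features and carry no inferential error
  bars.
* With 130 observations the cross-validated AUC itself has a sampling sd
  of several hundredths; conclusions should rest on the permutation null
  and the ANOVA effect sizes, not on a single AUC decimal.
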