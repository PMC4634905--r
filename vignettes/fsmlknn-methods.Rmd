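---
title: "Multi-label side-effect prediction with FS-MLKNN: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-label side-effect prediction with FS-MLKNN: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsmlknn)
```

## The problem

A marketed drug typically induces many adverse reactions at once, and the
label catalogues used in pharmacovigilance contain hundreds to thousands of
side-effect terms, almost all of them absent for any given drug.  Predicting
a drug's side-effect profile is therefore a *multi-label* classification
problem with severe label imbalance: the input is a binary descriptor vector
(presence/absence of chemical substructures, protein targets, enzymes,
transporters, pathways or indications) and the output is a binary vector
over the side-effect vocabulary, not a single class.

`fsmlknn` implements a complete pipeline for this setting: the MLKNN
Bayesian nearest-neighbour learner, a two-stage feature-selection wrapper
around it (FS-MLKNN), a weighted-scoring ensemble over descriptor families,
the standard multi-label evaluation suite, and a seeded synthetic-data
generator used to validate every stage.

## MLKNN

For each side-effect term $l$, MLKNN combines a smoothed class prior with
the likelihood of the observed neighbourhood.  Writing $y_i(l) \in \{0,1\}$
for the training labels, $n$ for the number of training drugs, $k$ for the
neighbourhood size and $s > 0$ for the smoothing factor:

$$P(H_1^l) = \frac{s + \sum_{i=1}^n y_i(l)}{2s + n}, \qquad
  P(H_0^l) = 1 - P(H_1^l)$$

Each training drug's $k$ nearest neighbours (itself excluded) are found
under Euclidean distance on the binary vectors — which orders pairs exactly
as Hamming distance — and the membership count $C_i(l) \in \{0..k\}$ is the
number of neighbours carrying term $l$.  The likelihood of seeing exactly
$j$ positive neighbours is estimated separately among drugs that carry the
term ($c_1[j]$) and drugs that do not ($c_0[j]$):

$$P(E_j^l \mid H_b^l) = \frac{s + c_b[j]}{s(k+1) + \sum_{j'=0}^{k} c_b[j']}$$

For a query drug with count $C_t(l)$ the package reports the normalised
posterior
$$\mathrm{score}(t,l) =
  \frac{P(H_1^l)\,P(E_{C_t(l)}^l \mid H_1^l)}
       {\sum_{b\in\{0,1\}} P(H_b^l)\,P(E_{C_t(l)}^l \mid H_b^l)}$$
as a continuous score in $(0,1)$; the MAP label is score $> 0.5$, with an
exact posterior tie resolved to 0.  The continuous score is what the
ranking metrics and AUPR need; the MAP rule only yields the hard labels
used by Hamming loss.

**Defaults.** `k = 5`, `s = 1`.  These are the conventional MLKNN settings;
both are exposed in `mlknn_config()` along with the distance (`euclidean`,
`jaccard`, `cosine`).  Ties between equidistant neighbours are broken
toward the lower training-row index, which makes every fit reproducible but
means the neighbour relation (not the fitted estimator) can depend on row
order when binary profiles coincide.

## FS-MLKNN: two-stage feature selection

Descriptor families are wide (e.g. 881 substructure keys) and most
dimensions are irrelevant to any side effect, which both slows the
neighbour search and degrades it.  FS-MLKNN selects dimensions in two
stages:

1. **Mutual-information filter.**  Every dimension $v$ is scored by its
   strongest pairwise association with any label,
   $I(v; D) = \max_j I(v; d_j)$, using plug-in MI on the empirical 2×2
   table (log base 2; zero cells contribute 0).  Dimensions with score
   $> \sigma$ are kept; $\sigma = 0.001$ by default.  The filter is a
   coarse screen: at a few hundred drugs the empirical MI of even an
   independent pair is of order $1/(2n\ln 2) \approx 0.002$, and the
   per-dimension score is a maximum over many labels, so almost all
   dimensions pass at the default threshold and the real pruning is done
   by the wrapper stage.  (Should nothing pass, the top tenth of
   dimensions by score is retained with a warning.)
2. **GA wrapper.**  Subsets of the candidates are encoded as binary
   chromosomes and a generational GA maximises the internal 5-fold
   cross-validated micro-AUPR of MLKNN restricted to the subset.  The
   internal folds are drawn once per run from the seed, so chromosome
   fitness is deterministic and cacheable; the all-zero chromosome is
   assigned fitness 0.

The final model consists of **five MLKNN submodels**, one per internal
fold, each trained on that fold's 4/5 training portion restricted to the
chosen dimensions; predictions are the average of the five submodels'
scores.  The same folds drive the GA fitness and the submodels.

## The genetic algorithm

`ga_maximize()` is a seeded generational GA with rank-based fitness scaling
(expectation $\propto 1/\sqrt{\text{rank}}$), stochastic-universal-sampling
parent selection, elitism of 2, uniform (scattered) crossover applied to a
0.8 fraction of the non-elite offspring, and per-gene mutation (flip
probability 0.01 for binary chromosomes).  Population 100 and a cap of 60
generations are the defaults, matching the reference protocol.

**Termination.**  The search stops when the best fitness has improved by
less than `fitness_tolerance` (default $10^{-6}$) over the last
`stall_generations` generations.  The window defaults to 50 — the
stall-generation limit conventional in GA toolboxes.  This matters: with a
1-generation window the GA stops the first time a generation fails to
improve the elite, which under elitism happens within a handful of
generations and reduces the wrapper to a best-of-random-subsets draw.  In
our planted-recovery experiments the 1-generation window recovered a median
3/5 of planted dimensions, the 50-generation window 4/5.  Callers who want
the aggressive behaviour can set `stall_generations = 1`.

**Weight (simplex) encoding.**  For ensemble weights the chromosome is a
non-negative vector summing to 1.  Crossover is a per-gene uniform blend of
the parents; mutation adds Gaussian noise (sd 0.1); after every operation
negatives are clipped to 0 and the vector renormalised (an all-zero vector
is repaired to uniform).  The initial population contains the simplex
corners (one-hot weightings) and centre as deterministic anchors, so the GA
can always fall back to the single best base predictor or plain averaging;
this makes the weight search robust when one base dominates.

## Weighted-scoring ensemble

One FS-MLKNN model is fitted per descriptor family (all sharing one seeded
internal fold partition) and used as a base predictor.  The ensemble score
is the linear combination $\sum_i w_i S_i$ with simplex weights.  Weights
are tuned by the GA on the bases' *out-of-fold* scores: submodel $f$ of
each base scores exactly the drugs of internal fold $f$, giving every
training drug a prediction from a model that never saw it.  Fitting weights
on these (rather than resubstitution scores) avoids rewarding overfit
bases.  With a single feature type the weight is fixed at 1.

## Evaluation protocol

`evaluate_scores()` implements the merged (micro) protocol: all drug-label
pairs are pooled into one ranking.

* **micro AUPR** — non-interpolated step AUPR (average-precision form);
  the primary metric, because with ~95 % negative pairs ROC AUC is
  systematically optimistic.  Tied score blocks accumulate true positives
  at a uniform rate, which reduces to the usual step formula for distinct
  scores.
* **micro AUC** — rank-sum form with midrank tie correction.
* **Hamming loss** — disagreement rate of the MAP labels.
* **one-error, coverage, ranking loss, average precision** — the classic
  instance-wise ranking metrics; ranks are deterministic (ties by label
  index), coverage is reported unnormalised (0 .. q−1), drugs with no
  positive label are skipped where the metric is undefined and contribute
  0 to coverage.
* **per-label AUPR** (`per_label_aupr()`) is undefined (NA) for terms with
  no positive drug; `compare_methods()` gives the three-way win/tie/loss
  counts between two methods over the defined terms.
* **top-N recall** (`topn_recall()`) — fraction of a drug's known side
  effects recovered among its N top-scored terms, the quantity that
  matters when the ranked list is used to prioritise wet-lab verification.

`run_cv()` evaluates by repeat: per repeat the pooled out-of-fold score
matrix is evaluated once, and metrics are aggregated as mean ± sd across
repeats.  Feature selection and weight tuning run inside each outer
training set only; a guard aborts if a test drug ever reaches a training
structure.

## Synthetic benchmarks

`generate_dataset()` draws datasets with the structure the method assumes:
independent Bernoulli binary feature dimensions; a small planted subset of
dimensions wired to randomly chosen labels (a drug carrying a planted
dimension fires each wired label with probability `association_strength`,
otherwise the label fires at `label_base_rate`); and a final symmetric
`noise_rate` flip.  The ground-truth record (planted dimensions and the
dimension→label map) lets tests score selection recall exactly, and
`expected_label_prevalence()` gives the analytic prevalence used to
calibrate the generator.

The default spec — 200 drugs, three feature types of 50 dimensions with 5
planted each, 30 labels, base rate 0.05, strength 0.6, noise 0.02 — is the
reference condition for the planted-recovery checks: it reproduces the
qualitative regime of the real benchmarks (sparse features, imbalanced
labels, a minority of informative dimensions) at a size where the full
MI + GA + 5-fold pipeline runs in minutes.

What the generator does **not** emulate: correlated substructure blocks,
label co-occurrence structure beyond shared planted dimensions, and
real-world label noise that is asymmetric (unobserved true side effects).
Passing the synthetic checks therefore demonstrates correctness of the
machinery and recoverability of planted signal, not performance on any
particular pharmacological corpus.

## Problem sizes used by the test-suite and acceptance script

Cross-validation-level checks (FS-MLKNN vs MLKNN direction, ensemble vs
best base, weight allocation) use a reduced condition chosen once: 100
drugs, three feature types of 25 dimensions (5 planted each — all families
informative, mirroring the benchmark datasets where every descriptor family
carries signal), 15 labels, and a GA of population 30 × 15 generations for
both the wrapper and the weight search.  The weight-allocation check uses
one informative plus two pure-noise families instead, where the correct
allocation is known.  Planted-recovery checks use the full default spec and
the reference GA settings (population 100, max 60 generations, tolerance
1e-6).  These sizes are the package's chosen benchmark conditions; medians
over five seeds are reported so single-seed GA noise does not dominate.

## Numerical and degenerate-input choices

* Probabilities from the smoothed estimators are strictly inside $(0,1)$
  and posterior rows sum to 1 algebraically; tests assert this to 1e-12.
* Neighbour ties: lower training-row index; top-N cutoff ties: lower label
  index; AUC ties: midranks.  All rankings are therefore deterministic.
* `micro_aupr()` errors on an all-negative truth (undefined quantity)
  rather than returning a sentinel; `per_label_aupr()` returns NA per
  undefined label instead, since skipping labels is part of that protocol.
* Drugs present in a feature table but absent from the label table are
  dropped with a warning during `align_bundle()` (benchmark files differ in
  coverage); an empty intersection is an error.
* `fit_fs_mlknn()` requires at least 10 drugs (5 internal folds with a
  non-trivial training portion); `k` must stay below the fold training
  size.
* All randomness (fold draws, GA, generator) flows from explicit integer
  seeds; identical seed + config reproduces every number bit-for-bit.

## Known limitations

* MLKNN treats labels independently given the neighbourhood; label
  correlations are only captured implicitly through shared neighbours.
* The GA wrapper's fitness is a 5-fold estimate on the training set; with
  small training sets its variance is substantial, and chosen subsets vary
  across folds (this is visible in the per-fold dimension counts reported
  by `dim_frequency()`).
* Euclidean distance on binary vectors ignores feature sparsity; Jaccard or
  cosine alternatives are provided but not used by the reference protocol.
* The ensemble can trail its best base when most families are uninformative
  — weight mass spread over noise bases generalises slightly worse; with
  informative families it reliably improves, which is the regime the method
  targets.
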