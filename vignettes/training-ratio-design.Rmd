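---
title: "Designing the inactive:active training ratio for virtual screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing the inactive:active training ratio for virtual screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsratio)
library(dplyr)
```

## The problem

Ligand-based virtual screening trains a binary classifier on confirmed
actives and presumed inactives, then applies it to a large compound
library. Two design parameters that the screener controls — the
inactive:active (IN/A) training ratio and, indirectly, the size of the
library being screened — interact strongly:

* **Recall** (`TP / (TP + FN)`) only involves the test actives. For a
  fixed trained model and fixed test actives it cannot change when decoys
  are added to the library, and it *decreases* as the training ratio grows,
  because negative-heavy training pushes the decision boundary toward the
  active class.
* **Precision** (`TP / (TP + FP)`) involves the false positives drawn from
  the library, so it *deteriorates* as the library grows (more opportunities
  for FPs at a fixed FP rate) and *improves* with the training ratio (more
  negatives teach the model what to reject).
* **MCC**, the Matthews correlation coefficient
  `(TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, balances the two and
  typically peaks at an intermediate ratio — and the peak moves toward
  larger ratios as the library grows, because the precision term carries
  more weight when there are more decoys to mistake.

Training with very large negative sets is expensive, so `vsratio`
implements a *cost-effectiveness* rule for choosing the ratio: for each
library size, compute each ratio's MCC loss `delta = best_mcc − mcc(ratio)`
over the ratio grid and return the **smallest** ratio with
`delta ≤ threshold` (default threshold 0.03). `threshold_profile()` shows
how the recommendation shrinks as the tolerated loss grows; the profile is
provably monotone.

## Curation conventions

Activity records arrive as Ki, pKi or IC50 measurements. Everything is
standardized to Ki in nM: Ki passes through, pKi maps to `10^(9 − pKi)` nM,
and IC50 is divided by 2 (the Kalliokoski heterogeneous-assay conversion).
A compound is *active* when its Ki is strictly below 100 nM; a compound at
exactly 100 nM is inactive. Compounds outside the strict 200–700 Da window
are discarded, and duplicate structures are collapsed to the first
occurrence (the structure string is the key, falling back to the compound
id).

Two conventions are ours rather than standard: repeated measurements for
one compound are merged by the **median** of the standardized Ki values
(robust to a discordant assay; the mean would let one outlier flip the
activity label), and measurement types are pooled before the median rather
than preferring Ki over IC50 (with the IC50/2 conversion applied, the
standardized values are commensurable, and pooling uses all evidence).

## The experiment grid

`experiment_design()` defaults encode the study conditions: 17 training
ratios `{0.5, 1, 2, 4, 7, 10, 15, 20, 25, 30, 40, 50, 60, 70, 80, 90, 100}`,
8 library sizes `{5k, 10k, 25k, 50k, 75k, 100k, 200k, 400k}`, 10 trials per
cell, and an 18% training fraction for actives. From a pool of 1101 actives
the split reserves `round(0.18 × 1101) = 198` for training and merges the
remaining 903 into every screening library.

Structural guarantees, all asserted by tests:

* the positive training set is drawn **once** and fixed across every cell;
* training negatives (`round(ratio × 198)`, round-half-to-even) and test
  decoys are drawn *without replacement from disjoint parts* of the decoy
  pool, fresh for every trial — no compound is ever on both sides;
* every cell derives its seed from the experiment's base seed and a stable
  hash of its `(ratio, library size, trial)` triple, so any cell can be
  reproduced in isolation and the whole grid is bit-reproducible.

Whether a real screening campaign would draw each library size as a nested
subset of one decoy superset or independently is not observable from
published results; we draw independently per trial (nested draws would
correlate the size axis and understate between-size variance).

## Classifiers

Two classifiers are implemented natively because they are fully specified
and small enough to hand-verify — they double as oracles for the harness:

* **Bernoulli naive Bayes** with add-one (Laplace) smoothing:
  `p(c|x) ∝ prior(c) · Π_j θ_jc^{x_j}(1−θ_jc)^{1−x_j}`. A posterior of
  exactly 0.5 resolves to *inactive* — the conservative call when a
  screening hit costs money to follow up. The decision function is linear
  in the bits, which is how `predict()` evaluates it.
* **1-nearest-neighbour** under Euclidean distance. On binary vectors the
  squared Euclidean distance *is* the Hamming distance, so the compiled
  kernel packs fingerprints into 64-bit words and compares popcounts;
  distance ties resolve to the lowest training-row index. An exhaustive R
  implementation cross-checks it in the tests.

Three more algorithms are adapters over established implementations,
configured to the conventional defaults for this kind of study: an SVM
(kernlab, C = 1, normalized polynomial kernel
`K'(x,y) = K(x,y)/√(K(x,x)K(y,y))` with `K = (⟨x,y⟩+1)^2`; the degree is a
config key because tools differ on the default), a pruned decision tree
(rpart — a CART-family stand-in for C4.5-style learners; its pruning is
cost-complexity rather than error-based, which we accept since tree
internals are not what this package studies), and a random forest
(randomForest, 10 trees, unlimited depth). Hard labels only: the
evaluation is of classifications, not rankings, so no AUROC-style measures
appear.

## The synthetic populations

Real studies draw actives from a bioactivity database and decoys from a
commercial catalogue; offline we emulate the *statistical* structure of
that data, not its chemistry. `make_chemotypes()` builds `k` template bit
patterns (chemotype scaffolds); an active is a uniformly chosen template
with independent per-bit flip noise; a decoy is either a background
molecule (independent sparse bits) or, with probability
`near_active_fraction`, a *hard* near-active decoy — a template copy with
wider flip noise. The generator is seeded by a single master seed with
fixed per-stream offsets, so actives, decoys and splits come from
reproducible, non-overlapping streams.

Defaults (frozen as the package's study conditions, chosen so the
populations occupy the regime real screening data occupies):

| parameter | default | meaning |
|---|---|---|
| `k` | 8 | chemotype count of a moderately diverse target |
| `d` | 166 | keyed-fingerprint width |
| `template_density` | 0.30 | fraction of bits set in a scaffold |
| `active_flip_prob` | 0.22 | within-chemotype diversity of actives |
| `decoy_bit_probs` | 0.15 | background decoy bit rate (sparser than actives) |
| `near_active_fraction` | 0.08 | hard-decoy contamination of the library |
| `near_active_flip_prob` | 0.35 | how far hard decoys sit from the scaffold |

The noise levels are the load-bearing choice, and they were selected by
analysis, not taste: for a near-active decoy to be a *curable* false
positive, the distance from hard decoys to the active cloud
(`≈ d·(f_a + f_n − 2 f_a f_n)` in expected Hamming terms) must exceed what
a growing sample of training negatives can reach (the extreme-value
envelope of the background-negative distances, which tightens like the
minimum of `~200·ratio` draws). With flip probabilities much below
0.22/0.35 the hard decoys sit irrecoverably inside the active cloud and
precision never responds to the training ratio; with the chosen values the
crossover happens *inside* the 0.5–100 ratio range, which is precisely the
phenomenon under study. At 8% contamination, a 20k library carries ~1600
hard decoys against 903 test actives, so precision (not recall) limits
performance at scale — the regime reported for real libraries.

What the generator does **not** emulate: real fingerprints have strongly
correlated bits (substructures imply one another), heavy-tailed bit
frequencies, and decoys that form their own scaffold clusters; actives per
target number hundreds, not the thousands a generative model could make;
and similarity is graded by shared substructure, not symmetric bit noise.
Passing tests on synthetic data therefore demonstrate that the *harness,
metrics and optimizer* behave as specified and that the qualitative
ratio/library-size phenomenology emerges from a minimal generative model —
they do not certify classifier performance numbers on any real target.

`similarity_density(actives, screen, s)` — the fraction of the library
within Tanimoto `s` of any active — is the dial that summarizes library
hardness; the default `s = 0.7` is the conventional "same series" level,
and the tests exercise the monotonicity of the density in both `s` and the
contamination fraction. Two all-zero fingerprints have Tanimoto 1 by
convention (identical objects), avoiding 0/0 while keeping reflexivity.

## Numerical and degenerate-input conventions

* MCC and precision return 0 (flagged `degenerate`) when a denominator
  vanishes — the no-skill value, which keeps trial averages defined.
* MCC is evaluated with factored square roots, exact in doubles for counts
  to 10^7.
* Cell aggregation is the **mean of per-trial metrics**, not the metric of
  pooled counts (the two differ; a constructed example in the tests shows
  it), with the per-cell standard deviation retained.
* PR-trajectory quadrants split at recall = precision = 0.5: quarter I is
  the good corner, IV high-recall/low-precision, III the reverse — the
  labels are an interpretation since "quarters" have no standard numeric
  definition.
* Ties for the best MCC resolve toward the smaller (cheaper) ratio, and the
  best MCC is the maximum over the ratio grid itself, with no interpolation
  between grid points.

## A worked example

A deliberately small grid so the vignette stays cheap; the acceptance
script runs the full scaled-down conditions.

```{r example, eval = FALSE}
model <- make_chemotypes(k = 8, d = 166, seed = 1)
actives <- sample_actives(model, 1101, seed = 2)
decoys <- sample_decoys(model, 45000, seed = 3)

design <- experiment_design(
  ratio_grid = c(0.5, 2, 10, 40, 100),
  library_sizes = c(5000L, 20000L),
  n_trials = 5, base_seed = 4
)
ex <- run_experiment(actives, decoys, design)
tidy(ex)          # per-cell trial means
glance(ex)        # one-row summary
ex$recommendations

plot_performance(ex)
plot_pr_trajectory(ex)
plot_cost_effectiveness(ex)
```

## Problem sizes used by the test-suite

The packaged checks run the experiment at 5 ratios × {5k, 20k} libraries ×
5 trials with the native classifier pair, plus ten 2-trial replicates of
the 1-NN arm for the library-size effect on the recommended ratio. These
sizes keep the full suite under ten minutes on a single core while
leaving every qualitative contrast (ratio trends, size penalty, optimizer
shift) far outside noise; the replicate count and per-replicate trial
count trade against each other, and a sign statistic per replicate is
robust to using 2 trials.

## Known limitations

* The chemotype generative model is exchangeable across bits; any method
  exploiting bit correlation structure will look artificially weak on it.
* The C4.5-style tree adapter uses CART pruning, not error-based pruning.
* `run_experiment()` executes cells serially; cells are independent, so
  callers can shard the design across processes by splitting the ratio or
  size grid, but the package does not manage workers itself.
* Recommendations are only as fine as the ratio grid; if the true optimum
  sits between grid points the reported ratio is the nearest grid member
  satisfying the threshold.
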