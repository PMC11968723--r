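---
title: "Wrapper gene selection with Eagle Prey Optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrapper gene selection with Eagle Prey Optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(eposelect)
library(dplyr)
```

## The problem

Microarray and RNA-seq classification problems routinely present a few dozen
to a few hundred samples described by thousands of genes. Most genes are
irrelevant to the phenotype, and many informative ones are mutually
redundant. Wrapper feature selection searches the space of gene subsets
directly, scoring each candidate subset by the cross-validated accuracy of a
classifier trained on it. The search space is `2^p - 1` subsets, so for any
realistic `p` the search needs a global stochastic optimizer.

`eposelect` implements Eagle Prey Optimization (EPO), a population
metaheuristic modelled on an eagle's hunt, as that optimizer, together with
everything around it that a gene-selection study needs: a composite fitness,
classifier adapters, honest error estimation (0.632+ bootstrap), paired
significance tests, a synthetic data generator with planted ground truth,
and ARFF/CSV input and output.

## The optimizer

A population of `n_pop` candidate solutions lives in a box-bounded
continuous space. Each iteration every candidate is moved by one of four
update rules and the move is kept only when it improves the candidate's
fitness (greedy replacement), so the best fitness trajectory is
non-decreasing by construction.

The hunt has two phases. During the first `phase_split` fraction of
iterations (default 2/3) the rules are exploratory:

* **Expanded exploration** surveys the selected region around the best
  position: `best * gamma + (mean - best) * beta`, with `beta ~ U(0, 1)`
  fresh per move and `gamma` the exploration parameter.
* **Narrowed exploration** tightens a spiral around promising prey:
  `best * F(D) + rand + (Y - X) * beta`, where `rand` is a uniformly chosen
  population member, `F(D)` a Levy-flight step, and `(X, Y)` spiral
  coefficients with per-dimension angle `Theta_i = a * pi * beta_i` and
  radius `r_i = Theta_i + SC * beta_i`, each normalized by its maximum
  absolute entry.

Afterwards the rules exploit:

* **Slow swoop**: `0.1 * (best - mean) - 0.2 * beta * (mean - pos) + pos`;
  the constants 0.1 and 0.2 are fixed adjustment parameters.
* **Forced swoop**: `QF(t) * best - 2 beta * pos - 2 gamma * F(D) + 2 beta`
  with the quality function `QF(t) = t^((2 beta - 1) / (1 - T)^2)`.

Before the first iteration a single refinement pass applies the
search-space-selection rule `best + alpha * beta * (mean - pos)` to every
candidate. The Levy step uses the Mantegna sampler,
`0.01 * u * omega / |v|^(1/b)` with `u ~ N(0, omega^2)`, `v ~ N(0, 1)` and
`b = 1.5`; `omega` is the standard Levy-stable scale for exponent `b`.
Normal draws for `u` and `v` are a deliberate design choice: uniform draws
on (0, 1) produce no heavy tail, which would defeat the purpose of a flight
distribution. The heavy tail gives occasional long jumps that escape local
optima.

Two documented readings were required where the method's published
description is ambiguous, and both are exposed as explicit choices:
`mean` is the per-dimension mean of the *current population* (recomputed
each iteration), not a running mean of historical bests; and the phase
schedule (which rule fires when) follows the two-thirds convention of this
optimizer family, with the two rules of each phase chosen with equal
probability per candidate. An adaptive exploration factor
`W(t) = w_max - (w_max - w_min) t / T` (defaults 0.9 to 0.4) is computed
and recorded per iteration as a diagnostic of the exploration/exploitation
balance; no update equation consumes it, and the cognitive/social
coefficients sometimes quoted for optimizers of this family likewise have
no defined role in the update rules, so neither enters the core. Bounds are
enforced by clamping after every move — the simplest fully reproducible
policy.

```{r sphere}
sphere <- function(x) -sum(x^2)
res <- run_epo(sphere, n_dim = 5, lower = -5, upper = 5,
               config = epo_config(n_pop = 30, n_iter = 100, seed = 1))
glance(res)
```

All randomness flows from one seed: every stochastic symbol (phase coin,
`beta` draws, Levy `u`/`v`, the random-member index, mutation flips)
consumes the same seeded stream in a fixed order, so a run is reproducible
bit-for-bit, which the test suite asserts.

## From positions to gene subsets

A continuous position is binarized through a sigmoid transfer: gene `j` is
selected iff `sigmoid(pos_j) > transfer_threshold` (strictly greater, so a
position of exactly zero at the default threshold 0.5 is unselected — a
deterministic tie rule). If nothing passes, the gene with the largest
position is selected, so no mask is ever empty. Positions live in
`[-4, 4]`, wide enough to saturate the sigmoid at both ends.

The composite fitness of a mask `s` is

`f(s) = alpha * A + (1 - alpha) * (1 - Ns / Nt) - W * P(s)`

* `A` — stratified k-fold cross-validated accuracy (default 5 folds) of the
  wrapped classifier on the selected genes, computed on the training
  partition. The fold assignment is fixed once per run, which makes fitness
  a deterministic function of the mask and lets the selector cache repeated
  masks exactly. The 0.632+ bootstrap is deliberately *not* used inside the
  search loop: running `B` bootstrap fits inside every fitness call would
  multiply the cost of the whole search by `B`; it is reserved for final
  reported performance.
* `(1 - Ns / Nt)` — the sparsity reward; `alpha` (default 0.9) makes
  accuracy dominate while still penalizing bloated subsets.
* `P(s)` — mean absolute pairwise Pearson correlation among selected genes
  (0 for a singleton; Spearman available), weighted by `W` (default 0.1).

The defaults `alpha = 0.9` and `W = 0.1` are the package's own choice,
made so that accuracy dominates; both are ordinary config fields, and the
accuracy-vs-compactness trade-off is meant to be steered per study through
`alpha`, `W` and `transfer_threshold` rather than hidden behind fixed
constants.

A genetic-style mutation operator assists the continuous search: once per
iteration each candidate's mask has every bit flipped independently with
probability `p(t) = rate_max - (rate_max - rate_min) * t / T` (defaults 0.1
to 0.01 — the same linear-decay shape as the exploration factor, which is
the only adaptive schedule the method defines), and the mutant is adopted
only if it scores strictly higher. Mutants are realized in position space
by flipping the sign of the mutated coordinates, which crosses the sigmoid
threshold exactly. Early, coarse mutation diversifies; late, fine mutation
is an efficient local search that sheds genes whose removal costs no
accuracy.

```{r select}
d <- generate_expression(synthetic_spec(
  n_instances = 60, n_genes = 10, n_informative = 3, n_redundant = 0,
  effect_size = 2, seed = 42
))
sel <- select_genes(d, classifier = classifier_spec("knn"),
                    epo = epo_config(n_pop = 30, n_iter = 100, seed = 1))
glance(sel)
```

On instances small enough to enumerate (at most 20 genes), an exhaustive
oracle evaluates every non-empty subset with the identical fitness and fold
assignment, providing the ground truth the optimizer is tested against;
ties go to the lexicographically smallest mask. A budget-fair baseline,
`random_search()`, draws masks uniformly (each gene included with
probability 1/2) under the same evaluation budget an EPO run actually
spent, including its mutation evaluations.

## Classifiers

Five learners are wrapped behind one adapter: a CART decision tree, a
100-tree random forest, k-nearest neighbours (k = 5), an RBF-kernel SVM
(C = 1), and a single-hidden-layer backpropagation network (32 units,
weight decay 0.01). No hyperparameter settings are canonical for this
method, so the defaults are the standard ones of the underlying
implementations and every one is overridable in `classifier_spec()`. The
distance- and margin-based learners (kNN, SVM, MLP) standardize features
with train-fitted moments; trees consume raw values. One published
description of the decision-tree learner conflates it with gradient
boosting; the package implements a plain CART tree and documents the
discrepancy rather than guessing.

## Error estimation

`kfold_error()` gives the stratified k-fold 0-1-loss estimate. For small
samples the 0.632+ bootstrap is preferable:

```{r boot}
est <- bootstrap_632plus(d, classifier_spec("knn"), B = 50, seed = 1)
glance(est)
```

`B` bootstrap resamples are drawn with replacement; the leave-one-out
bootstrap error averages, per instance, the losses of models whose
resample excluded it (instances contained in every resample are excluded
from the average, with a count kept). The no-information rate `Gamma`
evaluates the full-data model over all target/predictor pairings; the
relative overfitting rate `R = (err_B - err_resub) / (Gamma - err_resub)`
is clipped to `[0, 1]` — without clipping the blend weight can leave
`[0.632, 1]` — and defined as 0 when `Gamma` equals the resubstitution
error. The blend weight `w = 0.632 / (1 - 0.368 R)` then mixes
`(1 - w) * err_resub + w * err_B`. The loss is 0-1 throughout: the task is
classification, and on 0/1-encoded binary labels 0-1 loss coincides with
squared error. `B` defaults to 50, a standard desk-scale choice. The
constant 0.632 is the large-`n` limit `1 - e^{-1}` of the expected
fraction of distinct instances in a resample, which the test suite
re-derives by Monte Carlo.

Confusion-matrix metrics (accuracy, precision, recall, F1, specificity,
AUC) are computed from predictions; with more than two classes the
label-based metrics are macro averages over one-vs-rest reductions and AUC
is the macro one-vs-rest rank-statistic AUC, since single printed values
for multiclass problems require *some* averaging convention and macro is
the least class-size-sensitive. Undefined ratios are reported as 0 and
flagged rather than dropped. `paired_tests()` wraps the paired t-test,
Wilcoxon signed-rank test (exact up to 25 non-zero differences), Cohen's d
on paired differences, and the 95% CI of the mean difference, with the
degenerate branches (all-zero or zero-variance differences) flagged
explicitly.

## Synthetic data with planted truth

Public microarray benchmarks have no ground truth about which genes
matter, so recovery cannot be scored on them. The generator plants
structure on a standard-normal log-intensity scale:

* `n_informative` genes are class-conditionally normal with class means
  spaced `effect_size` standard deviations apart (default 2.0 — a strong
  but realistic microarray-scale separation);
* `n_redundant` genes are correlated copies of random informative parents
  (population correlation `redundancy_rho`, default 0.9), standardized
  through the parent's theoretical marginal moments so the correlation is
  exact in the model;
* remaining genes are independent standard-normal noise.

Labels are allocated deterministically to the requested proportions
(largest remainder) and shuffled, which keeps stratified folds feasible at
small `n`. The default planted structure (10 informative, 20 redundant) is
an invented convention — real datasets' truth is unknown. Eight presets
reproduce the (genes, instances, classes) shapes of widely used microarray
benchmarks, from 2,000 x 60 x 2 up to 24,481 x 97 x 2.

What the generator does *not* emulate: batch effects, missingness,
probe-level artifacts, heavy-tailed intensity distributions, or gene-gene
correlation beyond the planted copies. Tests passing on this generator
demonstrate that the machinery recovers planted signal under clean
conditions; they do not certify performance on real arrays.

## Validation experiments and problem sizes

The test suite runs five experiments whose scale was chosen for a desktop
machine; all are deterministic under their recorded seeds.

* **Sphere benchmark** — 5 dimensions, population 30, 100 iterations,
  20 seeds; the optimizer reaches the optimum to well below 0.1 and every
  best-fitness history is monotone.
* **Oracle equivalence** — 10 genes (3 informative, effect 2.0, n = 60,
  kNN, `alpha = 0.9`, `W = 0.1`): the oracle enumerates all 1,023 subsets,
  and EPO (population 30, 100 iterations) reaches at least 99% of the
  oracle's fitness in at least 4 of 5 seeds.
* **Planted-gene recovery** — 500 genes, 10 informative, effect 2.0,
  n = 100, 5 seeds, population 30, 150 iterations. This experiment asks
  for *compact* recovery, so it configures the fitness accordingly:
  `transfer_threshold = 0.90` biases the search toward small subsets (the
  standard subset-size control in sigmoid-transfer wrappers when
  p >> n), `redundancy_weight = 0` because the planted informative genes
  are mutually correlated by construction (each carries the same class
  signal, r about 0.5), so a redundancy penalty would reward discarding
  exactly the genes the experiment scores, and `mutation_rate_min = 0.002`
  so late mutation proposes single-bit refinements, the most efficient
  way to shed accuracy-neutral noise genes. Mean recall of planted genes
  and the selected fraction are scored against 0.7 and 0.2, and the
  selected subset must beat the all-genes accuracy.
* **Budget-fair dominance** — the same 500-gene conditions, 10 paired
  seeds, population 15, 40 iterations per run; random search receives
  exactly the evaluation count each EPO run spent, and the paired Wilcoxon
  test on per-seed best fitness must reject at 0.05.
* **Bootstrap constants** — the mean distinct-instance fraction of
  2,000 resamples of size 200, against `1 - e^{-1}`; and the blend weight
  at `R = 0`, against 0.632 exactly.

One boundary case deviates from a strict reading of the optimizer's
contract: `run_epo()` accepts `n_iter = 0` and returns the best of the
initial population, so that a zero-iteration selection degrades gracefully
instead of erroring.

## Known limitations

* Wrapper fitness overfits its inner folds: noise genes that happen to
  help the fixed fold assignment can survive selection. Reporting must use
  the 0.632+ estimator (or an untouched partition), never the inner
  accuracy.
* With interchangeable informative genes, accuracy saturates before all of
  them are selected; fitness then prefers dropping some of them, capping
  recall below 1 by design rather than by search failure.
* The five-learner roster re-fits from scratch on every fitness call;
  wrapping very slow learners (large MLPs, big forests) inside
  `select_genes()` is possible but expensive.
* Complexity per run is `O(I * N * (Nt + Ns * M))` for `I` iterations,
  population `N`, `Nt` genes, `Ns` selected genes and `M` training
  instances — linear in each, but the constant is a full classifier fit.
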