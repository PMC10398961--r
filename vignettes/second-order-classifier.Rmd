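---
title: "Second-order classification of sparse clinical examination tables"
author: "clinfm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Second-order classification of sparse clinical examination tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinfm)
```

## The problem

Routine hospital examinations produce a wide, sparse table: several hundred
laboratory and physiological items, of which each patient has only a subset
measured. The task addressed here is early risk prediction of subclinical
atherosclerosis (SA) — arterial disease before overt symptoms — from such a
table, cast as binary classification: patient $n$ has item vector
$x_n \in \mathbb{R}^M$ (with most entries unmeasured) and label
$y_n \in \{0, 1\}$, where 1 marks an SA diagnosis.

Three properties of this data shape the whole design:

* **Heterogeneous units.** Items range over several orders of magnitude
  (fractions of a unit to thousands), so raw values cannot share one model
  scale.
* **Heavy, structural missingness.** Different patients receive different
  examination panels; a missing cell means "not measured", not "zero".
* **Interactions matter.** Laboratory items act together (e.g. glucose
  tolerance measurements jointly with lipid panels); a purely linear score
  misses pairwise structure, but fitting all $\binom{L}{2}$ pairwise weights
  independently is hopeless at clinical sample sizes.

## The model

The classifier combines a first-order linear term with a factorized
second-order (pairwise) term — the factorization-machine parameterization.
For a selected, normalized feature vector $s \in [0,1]^L$:

$$ E = \sum_{i=1}^L w_i s_i + b, \qquad
   R = \sum_{i<j} \langle v_i, v_j \rangle \, s_i s_j, $$

with $w \in \mathbb{R}^L$, $b \in \mathbb{R}$, and latent factors
$V \in \mathbb{R}^{L \times K}$ (row $v_i$ for feature $i$). The logit is
$O = E + R$, the probability $P = \sigma(O)$, and the hard label is 1
exactly when $P \ge 0.5$ (the boundary goes to the positive class, so a
completely uninformative patient is flagged rather than cleared).

Factorization makes the pairwise term both estimable and cheap: every
interaction weight is an inner product of $K$-dimensional factors
($K \ll L$), and the identity

$$ R = \tfrac12 \sum_{k=1}^K \Big[ \big(\textstyle\sum_i v_{ik} s_i\big)^2
     - \textstyle\sum_i v_{ik}^2 s_i^2 \Big] $$

evaluates it in $O(LK)$ instead of $O(L^2)$. The package computes the two
bracketed pieces as the "square of the cross features" and the
"cross of the squared features" and halves their difference; a brute-force
$O(L^2)$ oracle verifies this identity to $10^{-9}$ relative error in the
test suite. With a single feature there are no pairs and $R = 0$ exactly.

Zero-imputed (missing) features drop out of *both* terms — a key reason the
imputation policy below is coherent with the model.

## Preprocessing

**Min-max normalization.** Each item is affinely mapped to $[0,1]$ using
the minimum and maximum of its *measured* cells:
$z = (x - \min) / (\max - \min)$. Statistics are fitted on training
patients only (per cross-validation fold, by default) and applied to
held-out patients with clipping into $[0,1]$; a constant item maps to 0.
Missing cells are imputed to 0 *after* normalization and stay flagged in
the missingness mask. An unmeasured item therefore contributes nothing to
either model term — it is silent, not evidence.

One consequence worth knowing: zero-imputation is only "silent" for
multiplicative terms. If an item has a strong linear effect, an unmeasured
cell effectively replaces that item's contribution by its value at $z = 0$
rather than at its typical value, which caps attainable accuracy as
missingness grows. The recoverability tests in the suite therefore use
complete tables, and that cap is a property real deployments share.

**ANOVA F selection.** Items are ranked by the one-way two-group ANOVA F
statistic $F = \mathrm{MS}_{\text{between}} / \mathrm{MS}_{\text{within}}$
($df_1 = 1$; $df_2 = n - 2$ with $n$ the item's measured count), computed
over measured cells only, and by the survival function (upper tail
probability) of the corresponding F distribution. The top $L$ items are
kept; ties break toward the lower original index so selection is
deterministic. Degenerate items resolve deterministically: separated group
means with zero within-group variance rank first ($F = \infty$); equal
means with zero variance, and items measured in only one group, get
$F = 0$ (the latter with a warning). With two groups $F$ is the squared
pooled-variance two-sample $t$, so this is the classical univariate filter,
not a multiple-testing procedure — tail probabilities are ranks, and no
correction is applied or needed.

## Training

Parameters are fitted by mini-batch Adam on the logit-scale binary
cross-entropy, $\ell(O, y) = \log(1 + e^{-(2y-1)O})$, evaluated in the
stable form $\max(O,0) - Oy + \log(1 + e^{-|O|})$ so logits of magnitude
$10^3$ do not overflow. Gradients are closed-form (and checked against
central finite differences at $10^{-5}$ relative error):

* $\partial O / \partial w_i = s_i$, $\partial O / \partial b = 1$,
* $\partial O / \partial v_{ik} = s_i (S V)_k - v_{ik} s_i^2$,

chained with $\partial \ell / \partial O = P - y$ and averaged over the
batch.

Defaults (all configurable via `trainConfig()`): learning rate 0.01, batch
size 32 (the final short batch is used, not dropped, so small cohorts train
deterministically), at most 200 epochs, $K = 10$ latent factors. Factors
initialize as $N(0, 0.01^2)$ under the configured seed — zero first-order
start is exact, and small factors break the symmetry of the interaction
term without inflating it; weights and bias start at 0. Epoch shuffling
uses the same seeded generator, so identical seed and data give
bit-identical trajectories.

**Early stopping.** When a validation set is supplied, training keeps the
parameters at the best validation loss and stops after 20 epochs without
improvement. Inside cross-validation the monitor must not be the test fold
(that would leak), so `crossValidate()` carves a stratified 10% slice out
of the training folds. For component benchmarking (ablation and the
acceptance measurements) the package instead trains for a fixed epoch
budget (`valFraction = 0`): the interaction term characteristically shows a
long validation plateau before it starts to pay off, and patience-based
stopping would truncate exactly the component under study.

## Evaluation

`confusionCounts()` / `classMetrics()` implement the standard definitions
with class 1 (SA) positive: accuracy $(TP+TN)/N$, precision $TP/(TP+FP)$,
recall $TP/(TP+FN)$, and F1 the harmonic mean of precision and recall.
Ratios with zero denominators report 0 with a warning instead of NaN so a
degenerate fold cannot poison a summary.

`crossValidate()` runs stratified 5-fold CV: each class is shuffled with
the seeded generator and dealt across folds within $\pm 1$ sample, with
leftover samples rotated so overall fold sizes also differ by at most one
(714 balanced patients split 143/143/143/143/142). Normalization and
selection are refitted inside every fold by default;
`selectionScope = "global"` reproduces a single cohort-wide item set when a
fixed item list is the goal, at the cost of mild selection leakage. Metrics
are reported per fold with mean and interquartile range (fold-mean
reporting); pooled-prediction reporting over all held-out patients is
available as an option — the two differ slightly because the harmonic mean
of fold-wise F1 values is not the F1 of pooled counts.

`ablate()` cross-validates three variants under identical folds: factors
frozen at zero (first-order only), weights and bias frozen at zero
(interaction only), and the full model, then reports relative improvements
$100 (m_{\text{full}} - m_{\text{ref}}) / m_{\text{ref}}$ per metric. The
reference row defaults to the interaction-only variant and can be set to
the per-metric best component (`reference = "best"`).

`searchFeatureNumber()` implements a coarse-then-fine scan of the feature
count $L$: steps of 10 until mean CV accuracy falls more than `tol`
(default 0.01, the quantification of a "noticeable" drop) below its running
maximum, then unit steps over the bracket around the best coarse value;
ties go to the smaller $L$. The search logic accepts an injectable
evaluator, so the tests verify it against exhaustive search on synthetic
accuracy landscapes without paying for real CV at every $L$.

## The synthetic generator

No patient-level clinical dataset can ship with the package, so
`simulateExamTable()` generates tables with the statistical structure the
pipeline assumes, sized after a realistic cohort: 357 patients per
diagnosis group and 350 items by default, with heavy missingness
(default rate 0.5).

* **Values.** Item $j$ is $|N(\mu_j, \sigma_j)|$ with per-item scale
  $\mu_j$ log-uniform over $[10^{-2}, 10^3]$ and $\sigma_j = \mu_j/2$ —
  nonnegative values on wildly different scales, which is exactly what the
  normalization layer exists for.
* **Labels.** The logit is built from planted effects on *standardized
  normalized* values $a_j$ (z-scores, over the generated pool, of the
  min-max normalized values): selected items contribute
  $\pm\beta \, a_j$ and selected distinct pairs contribute
  $\pm\gamma \, a_i a_j$, plus $N(0, \texttt{noiseSd})$ noise. Effect
  sizes are therefore scale-free logit units per standard deviation, and
  centering makes pairwise effects (near-)orthogonal to linear signal —
  an interaction-only table genuinely requires the second-order term,
  which is what makes the ablation property testable.
* **Balance and missingness.** Patients are generated until both groups
  reach the requested size and the first `nPerClass` of each are kept, so
  balance is exact by construction; `classBalance()` provides the same
  guarantee for imported cohorts by seeded majority subsampling. Cells are
  then masked completely at random at the requested rate, never leaving an
  item with no measured patient.

What the generator does *not* emulate: real panel structure (missingness
in real data is blockwise by ordered panel, not cell-wise at random),
inter-item correlation within a panel, heavy-tailed or discrete laboratory
values, label noise from diagnostic workup, and any clinically meaningful
item identity. Passing tests on synthetic tables therefore demonstrate
that the machinery recovers the kinds of signal it models — not that it
will reach any particular accuracy on hospital data.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations for a
desk-scale run: interaction-recovery checks use 400 patients per class
with 8 items and 2 planted pairs (effect size 4–5, the "strong" regime
where the Bayes-optimal accuracy is comfortably above 0.8); no-signal
checks use 200 per class; linear-recovery checks use 300 per class with
10 of 20 items informative at effect size 3. Training for these
measurements runs a fixed 60–300 epochs as noted above. Exactness claims
(the $O(LK)$ identity, gradient checks, metric identities, fold
partitions, archive round trips) are tested at tolerances between
$10^{-5}$ and bit-identity.

Other numerical decisions, collected in one place: the decision boundary
$P = 0.5$ classifies as positive; constant items normalize to 0 rather
than erroring; out-of-range held-out values clip; F-statistic ties break
by item index; the model archive serializes doubles at 17 significant
digits so read/write round trips are bit-exact; and every random choice
(simulation, subsampling, fold assignment, initialization, shuffling,
validation split) flows from explicit integer seeds.

## Limitations

* Zero-imputation is principled for the multiplicative term but biases
  linear contributions of unmeasured items toward their minimum; with
  informative (non-random) missingness this is a real modelling gap.
* The univariate F filter cannot select items whose effect is purely
  interactive (no marginal group separation); when interactions are the
  target, select generously or skip filtering ($L = M$).
* Training the interaction term at learning rate 0.01 needs hundreds of
  epochs when the true pairwise weights are large relative to the feature
  scale — patience-based stopping can undercut it (see Training).
* No regularization is implemented; at very small $n$ with large $L$ and
  $K$, the second-order term will overfit.
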