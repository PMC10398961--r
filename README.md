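# clinfm — second-order classification of sparse clinical examination tables

`clinfm` is an R package for early risk prediction from routine clinical
examination tables: several hundred laboratory and physiological items, of
which each patient has only a subset measured, with a binary diagnosis label
(the motivating application is subclinical atherosclerosis screening in a
high-risk hepatology cohort). It is aimed at biostatisticians and clinical
data scientists who have a wide, sparse patient-by-item matrix and want an
interaction-aware classifier with a fully reproducible pipeline around it.

## The model

The core is a factorization-machine (second-order) binary classifier. For a
selected, min-max-normalized feature vector $s \in [0,1]^L$:

$$O \;=\; \underbrace{\textstyle\sum_i w_i s_i + b}_{\text{first-order}}
 \;+\; \underbrace{\textstyle\sum_{i<j} \langle v_i, v_j\rangle s_i s_j}_{\text{second-order}},
 \qquad P = \sigma(O), \qquad \hat y = \mathbb{1}[P \ge 0.5],$$

with latent factors $V \in \mathbb{R}^{L\times K}$ so that all pairwise
interaction weights are rank-$K$ inner products. The interaction term is
evaluated in $O(LK)$ via
$\tfrac12\sum_k[(\sum_i v_{ik}s_i)^2 - \sum_i v_{ik}^2 s_i^2]$.
Training is mini-batch Adam (batch 32, learning rate 0.01 by default) on the
logit-scale binary cross-entropy, with closed-form gradients.

Around the model the package provides, as separately usable functions:
exact class balancing; per-item min-max normalization over measured cells
with zero-imputation of missing cells; univariate ANOVA-F feature ranking
with survival-function tail probabilities and top-L selection; stratified
k-fold cross-validation; component ablation (first-order-only /
interaction-only / full) with relative-improvement reporting; a
coarse-then-fine search over the feature count L; a synthetic
examination-table generator with planted linear and pairwise effects and
known ground truth; a CSV/JSON/YAML artifact layer (feature tables, model
archives, run manifests); and a command-line front end
(`exec/clinfm`, subcommands `simulate`, `balance`, `train`, `predict`,
`cv`, `ablate`, `search-l`).

Data live in Bioconductor-style S4 containers: `ExaminationTable` extends
`SummarizedExperiment` (items as rows, patients as columns, assays `exam`
and `missing`), and `NormalizedExamTable`, `FeatureRanking`, `FMParams`,
`FMModel` carry the derived state with validity checks and accessors.

## Worked example

```r
library(clinfm)

sim <- simulateExamTable(nPerClass = 150, nItems = 40,
                         nInformativeLinear = 10, nInteractionPairs = 3,
                         linearEffectSize = 2, interactionEffectSize = 3,
                         missingRate = 0.2, seed = 42)
sim$table
#> class: ExaminationTable
#> dim: 40 300
#> assays(2): exam missing
#> labels: 150 positive / 150 negative; missing cells: 19.9%

cv <- crossValidate(sim$table, L = 20,
                    config = trainConfig(seed = 42, maxEpochs = 150),
                    seed = 42)
cv
#> 5-fold stratified CV (L = 20, fold scope, fold-mean reporting)
#>      accuracy precision recall     f1
#> mean   0.6267    0.6433 0.5467 0.5884
#> IQR    0.0667    0.0610 0.1333 0.1084

mod <- fitModel(sim$table, L = 20,
                config = trainConfig(seed = 42, maxEpochs = 150))
head(predictRisk(mod, sim$table), 3)
#>   sample_id       e     r      o      p yhat
#> 1     S0001 -0.6824 3.709 3.0271 0.9538    1
#> 2     S0002 -0.9958 1.711 0.7155 0.6716    1
#> 3     S0003 -1.8186 6.219 4.4002 0.9879    1

sum(itemNames(mod) %in% sprintf("item_%03d", sim$truth$linearItems))
#> [1] 10
```

Reading the output: the 300-patient table is exactly balanced by
construction; cross-validated mean accuracy on this deliberately noisy,
20%-missing fixture is 0.63 (chance is 0.5), per-fold spread is summarized
by the interquartile range; `predictRisk` reports the first-order score
`e`, interaction score `r`, logit `o = e + r`, probability `p`, and hard
label. The last line shows the ANOVA-F filter recovered all 10 planted
informative items among its 20 selections. The same pipeline runs from the
shell:

```sh
clinfm simulate --n-per-class 357 --n-items 350 --seed 1 --out cohort.csv
clinfm cv --input cohort.csv --l 30 --out-dir run --seed 1
clinfm predict --input cohort.csv --model run/model.json --out preds.csv
```

Every run writes a `manifest.yaml` (resolved configuration, seeds, input
MD5, fold assignment); `replayRun()` on a manifest reproduces the metric
reports and model archive byte for byte.

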