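---
title: "Multi-trait deep-learning genomic prediction for mixed phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait deep-learning genomic prediction for mixed phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpmixnet)
```

## The problem

Breeding programs score selection candidates for traits of very different
measurement types: grain yield is continuous, lodging or disease presence is
binary, and scores such as grain color or rust severity are ordinal. Standard
genomic selection machinery (GBLUP and its multi-trait extensions) handles
continuous traits well, but mixed continuous/binary/ordinal trait vectors are
awkward for linear mixed models. `gpmixnet` implements a multi-trait
densely connected neural network with *heterogeneous output heads* — one head
per trait, with the activation and loss matched to the trait's type — so a
single model can be trained jointly on a mixed trait vector (the MTDLMP
model), alongside its univariate counterpart (UDL, one single-output network
per trait) for comparison.

## The model

### Genomic features

Let the trial contain $J$ lines evaluated in $I$ environments, with $n$
(line, environment) records. From the marker dosage matrix (QC-filtered and
mode-imputed) we build the genomic relationship matrix by VanRaden's first
method,

$$G = \frac{W W'}{2 \sum_k p_k (1 - p_k)},$$

with $W$ the column-centered dosage matrix and $p_k$ the observed allele
frequency of marker $k$. The network input is not the raw markers but a
Cholesky transform of the incidence structure: with $Q$ the upper triangular
factor satisfying $Q'Q = G$, and $Z_E$, $Z_G$, $Z_{GE}$ the 0/1 incidence
matrices of environments, lines and environment-line cells,

$$Z_G^\ast = Z_G Q', \qquad
  Z_{GE}^\ast = Z_{GE} (I_I \otimes Q'), \qquad
  X = [\,Z_E \mid Z_G^\ast \mid Z_{GE}^\ast\,].$$

The transform is chosen so that the induced covariances reproduce the usual
genomic model: $Z_G^\ast Z_G^{\ast\prime} = Z_G G Z_G'$ and
$Z_{GE}^\ast Z_{GE}^{\ast\prime} = Z_{GE} (I_I \otimes G) Z_{GE}'$. In other
words, a linear model on $X$ with i.i.d. coefficients is equivalent to a
GBLUP with main genetic effects and environment-specific (G×E) genetic
effects; the network generalizes this by learning nonlinear functions of the
same features. The `interaction_mode` switch ("I" vs "WI") includes or
excludes the $Z_{GE}^\ast$ block. The Kronecker product is never materialized:
each row of $Z_{GE}$ selects a single (environment, line) cell, so the
corresponding row of $Z_{GE}^\ast$ is just a row of $Q'$ placed in the
record's environment block (columns are environment-major: cell $(i, j)$ maps
to column $(i-1)J + j$).

### Network and losses

Hidden layers (1, 2 or 3, all with the same unit count $U$) use ReLU
activations with inverted dropout after each layer. Each trait $t$ has its
own affine head on the last hidden layer:

* continuous — ReLU activation, squared-error loss on the *standardized*
  scale (each training fold's mean and sample SD; predictions are mapped
  back);
* binary — sigmoid activation, binary cross-entropy, labels {1,2} encoded
  as 0/1;
* ordinal with $K$ categories — softmax activation over $K$ logits,
  categorical cross-entropy against indicator targets.

The total loss is the unweighted sum of per-trait mean losses. The losses
themselves follow directly from the stated activations; equal weighting is
the common multi-task default, and pre-standardizing continuous traits keeps
the scales roughly comparable. Ordinal traits are treated as nominal (softmax
with indicator targets); no ordinal-aware link is used.

One consequence of the ReLU output activation for continuous traits deserves
a note: on the standardized scale the head cannot emit negative values, so
predictions below the training mean saturate at the mean after
destandardization. This mildly attenuates the observed-vs-predicted
correlation (for a perfectly fit standard-normal signal the attenuation
factor is about 0.79) but we retain it as the stated design.

Training uses mini-batch Adam (learning rate 0.001, batch size 32 by
default), Glorot-uniform initialization, and a single seeded RNG stream per
training run, so identical seeds give bit-identical weights and loss traces
on a fixed BLAS. With `epochs = 0` the seeded initialization is returned
unchanged. Probabilities are clipped to $[10^{-7}, 1-10^{-7}]$ before logs.
Decoding: binary probability $\ge 0.5$ maps to category 2; ordinal arg-max
with ties resolved to the lowest category.

### Tuning

The grid covers epochs 1–100 and units 10–490 in steps of 20 (the
`"reduced"` preset — epochs {10, 50, 100}, units {10, 50} — keeps test suites
desk-scale). Twenty percent of each outer-training set is split off as an
inner validation set; for each unit candidate a single network is trained for
the largest epoch candidate and the validation loss is read off the per-epoch
trace at every candidate epoch. This is exactly equivalent to retraining per
epoch value (epoch-nested training passes through all smaller epochs) at a
fraction of the cost, and mirrors how per-epoch validation monitoring is used
in practice. Ties break to the smaller unit count, then the smaller epoch
count. After selection, the network is re-trained on the *full*
outer-training set with the chosen $(U^\ast, E^\ast)$ — whether to re-train
or reuse the tuned model was an open choice; re-training uses all available
training records and is the conventional protocol. The number of hidden
layers is never tuned; it is an experimental factor fixed per run.

### Cross-validation and metrics

The outer loop is a fivefold partition of the (line, environment) *cells*,
not of lines: a line typically has records in training for some environments
while its remaining cells are test records. This is the CV2 setting of
incomplete multi-environment trials — the breeder has seen the line
somewhere, just not everywhere. Folds are uniform random with sizes differing
by at most one; no stratification is applied by default (an option exists).
Per fold and per trait-environment combination we compute Pearson correlation
(continuous) or the fraction of correctly classified cases, PCCC, reported in
[0, 1] (categorical), and report the unweighted fold average (APC / PCCC).
Undefined correlations (constant vector, fewer than 3 test pairs in a cell)
are recorded as missing with a warning and excluded from the average, with
the valid-fold count retained.

Leakage control is structural: fold assignment depends only on record
identity; standardization statistics, tuning and training see only
outer-training records. The test suite verifies this by poisoning the
phenotype values of one fold's test records and asserting the fold's tuning
choices and predictions are unchanged.

## What the simulator emulates

`simulate_markers()` draws biallelic dosages as binomial(2, f) per line with
marker frequencies uniform on `maf_range` — Hardy–Weinberg genotypes with no
linkage disequilibrium, population structure, dominance or epistasis.
`simulate_multitrait_phenotypes()` draws line genetic values for all traits
jointly from a matrix-normal distribution with line covariance $G$ (computed
from the simulated markers) and trait covariance equal to the configured
genetic correlation matrix — the standard infinitesimal model, matched
exactly to the feature construction the model uses. Each environment adds a
main effect (SD `env_effect_sd`, default 1) and an independent G×E genetic
deviation with variance `gxe_variance_ratio` (default 0.2, a moderate level
typical of multi-environment wheat trials) times the main genetic variance.
Residual noise is calibrated so that each trait's latent-scale heritability —
total genetic variance (main + G×E) over within-environment phenotypic
variance — equals the configured $h^2$. Categorical traits are produced by
liability thresholding: empirical quantiles (linear-interpolation convention)
computed *within each environment*, values equal to a threshold assigned to
the lower category. A trait with $h^2 = 0$ still has genetic values drawn
(and reported in the truth table) but they receive zero weight in the
phenotype, so the null case remains testable.

The default configuration is the reference world used by the acceptance
tests: 500 lines, 1000 markers, 3 environments, two continuous traits and one
3-category ordinal trait, all $h^2 = 0.8$ with pairwise genetic correlation
0.8, and 80% of the line-by-environment grid observed. A green end-to-end
test on this world establishes that the pipeline recovers strong additive
signal under ideal assumptions; it does *not* establish performance on real
GBS data with LD, structure, or genotyping error.

One interaction between simulator and QC deserves attention: the marker QC
defaults include a heterozygosity filter (> 10% heterozygous calls removes
the marker) appropriate for inbred wheat lines genotyped by sequencing, where
high heterozygosity indicates technical error. Hardy–Weinberg simulated
genotypes are outbred-like (expected heterozygosity $2f(1-f)$ up to 0.5), so
applying that filter to simulated data would remove essentially every marker.
Runs on simulated data therefore set `max_het = 1` (or `qc = NULL`); this is
a structural property of the simulated world, not a tuning choice.

## Numerical choices

* **Cholesky jitter.** `chol()` is attempted on $G$ as-is; on failure
  (duplicated or near-duplicate lines are common) $10^{-6} I$ is added,
  escalating tenfold to at most $10^{-2}$, after which an error reports the
  smallest eigenvalue.
* **GRM formula.** VanRaden method 1; the de facto standard. Heterozygosity
  for QC is the fraction of dosage-1 calls among non-missing calls — the only
  definition available from dosage data.
* **Imputation.** Per-marker mode, ties to the smaller dosage for
  determinism. LD-aware imputation is out of scope.
* **Seeds.** A single master seed drives fold assignment and every derived
  tuning/training seed through a deterministic fold-and-multiply map, so runs
  are reproducible end to end; reports agree to well under $10^{-6}$ per
  entry on a fixed backend.
* **Input scaling.** Columns of $X$ are *not* rescaled by default (only
  continuous responses are standardized); `scale_inputs = TRUE` is available.
* **Degenerate inputs.** Constant training vectors for a continuous trait,
  training folds missing a category, phenotyped lines absent from the marker
  table, monomorphic marker sets, and empty QC survivors all raise immediate,
  named errors rather than propagating silently.

## Known limitations

* Records must have complete trait vectors for training; how partially
  missing trait vectors were handled in the original multi-trait setting is
  unspecified, so we reject them explicitly rather than guess.
* Dropout is applied after hidden layers only, never to the input layer.
* No convolutional/recurrent variants, no GPU paths, no significance testing
  between models (per-fold metrics are exposed so any paired test can be
  applied downstream).
* The simulator omits LD, population stratification and non-additive genetic
  architecture; accuracy estimates on simulated data are optimistic.
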