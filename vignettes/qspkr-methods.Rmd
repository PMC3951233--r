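---
title: "QSPkR modelling with award/penalty descriptor selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QSPkR modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qspkr)
```

This vignette is the package's own account of the science it
implements: the model and its assumptions, the parameters that matter,
the places where the published description of the procedure is
ambiguous and what this package does there, and what the synthetic
benchmarks do and do not demonstrate.

## The modelling problem

Given a table of *n* compounds by *D* numeric molecular descriptors
(typically *n* ≈ 40 and *D* ≈ 1,500 — far more descriptors than
compounds) and one measured pharmacokinetic parameter per compound
(clearance, volume of distribution, or plasma protein binding), build
a model that predicts the parameter for new compounds. Two stages:
a wrapper feature selection that reduces the descriptor set to at most
15 columns, and a small neural network regression on the selected
columns. Everything operates on min–max normalized values
`dd ∈ [0,1]` (descriptors) and `dp ∈ [0,1]` (PK), with the observed
minima and maxima retained to map predictions back to original units.

Normalization is computed over the *full* compound set before any
train/test split, following the reference procedure. This leaks the
test compounds' ranges into training; `minmax_normalize(scope_rows =)`
offers a training-fold-only variant, but the leaky whole-set default
is kept for fidelity and is what all reported numbers use.

## The award/penalty fitness

A chromosome is a binary mask over descriptors. For every unordered
compound pair and every included descriptor the pair contributes
`−Penalty` if the pair's normalized PK values differ by at least
ε, and `Award − |dd_ik − dd_jk|` otherwise (defaults
Award = Penalty = 5, ε = 0.1); the chromosome's fitness is the sum
over all pairs and included descriptors. The intuition: a descriptor
is rewarded exactly when it is *similar* on compound pairs that are
*similar* in the PK parameter.

Two structural properties of this function drive every design decision
downstream:

1. **Additivity.** The contribution of descriptor *k* is independent
   of which other descriptors are included, so each descriptor has a
   fixed marginal score *m_k* and `Fitness(c) = Σ_{k∈c} m_k`. The
   implementation precomputes the marginals once per dataset and
   scores a whole population with one matrix–vector product; the unit
   tests verify bit-for-bit equality with a naive triple loop.

2. **Uniformly negative marginals.** With Award = Penalty and a
   within-ε pair fraction *f* well below one half,
   `m_k ≈ n_pairs · (f·Award − (1−f)·Penalty) − Σ_award |Δdd_k| < 0`
   for *every* descriptor. The dissimilar-PK branch never looks at the
   descriptor values, so a discriminative descriptor can reduce its
   penalty burden by at most `f · n_pairs · E|Δdd|` relative to a
   decoy — a gap of a few percent of the marginal's magnitude.

Property 2 is also why the procedure terminates the way it does:
fitness increases as descriptors are removed, so gene counts shrink
generation by generation, and the stated gene limit (15) exists "to
prevent the complete abolition of the genes". The interesting output
is the *composition* of the subset at the moment the limit is reached.

One bookkeeping note: for 39 compounds there are C(39,2) = 741
unordered pairs; the reference text states 703 (= C(38,2)), which we
cannot reconcile. The package enumerates all unordered pairs of the
supplied compounds.

The prose description of the penalty ("the penalty value was
allocated") can also be read as once per pair rather than once per
pair *and* per included descriptor; the summation formula indexes the
contribution by descriptor, so the per-descriptor reading is the
default, and `ga_control(penalty_per_pair = TRUE)` switches to the
prose reading (checked against its own brute-force oracle in the
tests).

## Why survivor selection cannot use the raw fitness

The genetic operators are fixed by the procedure: fair-coin
initialization of 500 chromosomes, single-point crossover applied with
probability 1 (break point uniform over the interior positions, so
both segments are non-empty), and mutation that draws one gene
position uniformly and flips it with probability 0.1. No selection
scheme is specified. The obvious default — binary tournament on raw
fitness with elitism — was implemented first (`selection = "fitness"`)
and fails in a structural, reproducible way:

* A chromosome's fitness is `Σ m_k` with every `|m_k|` large and the
  informative-vs-decoy gap small, so comparisons between chromosomes
  are decided almost entirely by *how many* descriptors they carry.
* Which descriptors survive the shrinkage is then genetic hitchhiking:
  on planted-truth synthetic data the recovered fraction of
  informative descriptors is barely above the random-subset baseline.
* At *D* = 1,481 the shrinkage itself is too slow: after the
  population converges, gene removals fix at roughly one per
  generation (mutation supplies ~`0.1·500·g/D` removal candidates per
  generation and weak tournament pressure wastes most of them), and
  the best chromosome still carries far more than 15 genes when the
  500-generation safety cap is hit.

The default scheme (`selection = "penalized"`) therefore ranks
chromosomes by a size-penalized per-descriptor score

    score(c) = −Fitness(c) / g  +  λ · ln g ,      g = |c|,  lower is better,

with `λ = size_penalty · sd(m)` (default multiplier 1.5, `sd(m)` the
standard deviation of the per-descriptor marginals, a quantity the
data itself supplies). The first term is the average cost per included
descriptor — a size-free measure of subset quality; the second is an
information-criterion-style complexity penalty. A first-order
expansion shows a single-gene removal improves the score exactly when
the gene's cost exceeds `(mean cost of the subset) − λ`: removals of
bulk descriptors (within ~1.5 SD of the subset mean) are always
accepted, so subsets keep shrinking at every scale with no stall,
while a descriptor whose marginal is an outlier — better than the bulk
by clearly more than λ — is never profitably removed and, if lost to
early drift, is re-admitted the next time mutation re-proposes it
(additions pay `+λ/g` and are accepted only for such outliers). The
ordering of removals is thus approximately greedy worst-first, which
is exactly what makes the final ≤ 15 survivors the best-scoring
descriptors rather than a random residue.

Generation structure: children are bred from the top
`breeding_fraction` (default 10%) of the ranking by uniform sampling,
then crossover and mutation exactly as specified; the next population
is the best `population_size` chromosomes among parents and children
("plus" selection, which makes the best score monotone), with
duplicate genotypes down-ranked so the survivor set keeps distinct
lineages for crossover to recombine. Identical fitness values are
used as the duplicate fingerprint — cheap, and a false merge of two
genuinely different equal-fitness chromosomes costs only a little
diversity.

Ties anywhere are broken toward fewer genes, then lexicographically
smaller bit strings, matching the procedure's parsimony pressure and
making runs reproducible. All randomness flows through R's RNG from a
single seed; the draw order (initialization, then per generation:
parent indices, per pair crossover-acceptance/break-point, per child
mutation position/acceptance) is fixed, so runs are bit-reproducible.

On planted-truth data the test suite verifies the consequences: mean
recall of planted descriptors ≥ 0.6 over ten seeds at 40 × 200
(observed near 1), and gene-limit termination within the
500-generation cap at the full 39 × 1,481 scale.

## The network and its trainer

The regression stage is a three-layer feed-forward network: the
selected descriptors (≤ 15 inputs), one hidden layer (default 4 tanh
units — with ~33 training compounds a larger layer mostly memorizes),
and a single logistic output neuron, with a bias in each layer.
Logistic output is the natural choice because targets are normalized
into [0, 1]; a linear output is available by flag.

Training is Levenberg–Marquardt: per epoch, compute the residuals
`r = y − ŷ` and the analytic Jacobian `J = ∂ŷ/∂θ` (back-propagated
chain-rule derivatives; verified against central finite differences to
better than 1e−6 relative error), solve `(JᵀJ + μI) Δ = Jᵀr`, and
accept the step only if the sum of squared errors decreases —
`μ` shrinks by 0.1 on acceptance and grows by 10 on rejection (up to
20 retries per epoch, hard stop at `μ > 1e10`). One epoch is one such
accepted-or-finally-rejected update of the full batch; there is no
mini-batching (33 rows) and no early stopping — the epoch count is
fixed at 50. The damping makes the normal equations solvable even
with more parameters (69 at 15 inputs) than training rows. SSE over
accepted steps is non-increasing by construction, and at large μ the
step direction collapses to the gradient direction (both are tested).
A plain batch gradient-descent trainer is included as a secondary
option (`optimizer = "gd"`).

## Metrics and validation

* **R** is implemented exactly as printed: `1 − SSE/SST`, the
  coefficient-of-determination form, with no square root; it is 1 for
  perfect prediction, 0 for mean prediction, and can be negative.
  Because published tables do not always distinguish this quantity
  from the product-moment correlation, `pearson_r` is reported
  alongside it everywhere. Which one a given published table shows is
  documented as unresolved, not guessed.
* **RMSE** is computed on denormalized predictions, i.e. in the PK
  parameter's own units (mL/min/kg, L/kg, %); normalized-scale RMSE is
  logged as well.
* **NRMSE** divides the RMSE by the observed range of the parameter,
  and the identity `NRMSE · (max − min) = RMSE` is enforced to 1e−10
  in the tests, as is invariance of NRMSE under affine rescaling of
  the measurement scale.

Validation is repeated random sub-sampling: each repeat draws a
uniform 33/6 train/test partition (the 33:39 proportion is kept for
other compound counts), trains a fresh network on the training fold,
and scores the held-out fold. Per-repeat metrics are reported with
their mean ± sd, and the *aggregate* metrics are computed on the
pooled predicted/observed pairs of all repeats — with only 6 test
compounds per split, per-repeat R is far too noisy to summarize alone.
Each split also carries a Brown–Forsythe (median-centered Levene)
variance-homogeneity p-value and a Welch t-test p-value comparing
train and test PK values, mirroring the reference protocol's split
check; Welch is the default because 33-vs-6 group sizes make the
pooled-variance assumption gratuitous (a pooled option exists).

The descriptor subset is selected once, on all compounds, before the
validation splits — again following the reference procedure. The
selection therefore sees the test compounds' PK values, and the
validation estimates the performance of the *pipeline given the
selection*, not of the full selection+fit pipeline on unseen data.
`ga_control(fitness_rows = )` restricts the fitness to a training fold
for users who want the stricter protocol.

## The synthetic benchmark

Real inputs for this method (a published PK compilation and a
proprietary descriptor matrix) are not redistributable, so the package
generates its own with known ground truth:

* **PK values** come from five equal-mass clusters with centers evenly
  spaced on the unit interval and within-cluster sd 0.02, mapped to a
  clearance-like 1–50 mL/min/kg range. Clustering is essential, not
  cosmetic: the award branch only fires for pairs within ε = 0.1, and
  with 5 clusters about 18% of pairs qualify — inside the band the
  fitness needs to say anything at all. (Uniformly spread PK values at
  n ≈ 39 would leave almost no award pairs; the run_ga degenerate-case
  warning covers the extreme.)
* **Informative descriptors** (default 10) are monotone transforms of
  the latent PK value — identity, square and logistic links cycled —
  plus Gaussian noise (sd 0.05), so their pairwise distances track PK
  distances and the network stage sees non-linear shapes.
* **Decoys** are i.i.d. uniform.

What passing on this generator shows: the selection recovers
descriptors whose pairwise geometry matches the fitness's assumption,
at the reference scale, under moderate noise; the network can turn
them into accurate held-out predictions. What it does not show: real
descriptor blocks are strongly inter-correlated, have heavy-tailed and
discrete marginals, and real PK–structure relationships are weaker and
confounded — recovery rates and R values here are upper bounds of a
benign regime, not forecasts for laboratory data.

## Numerical choices and degenerate inputs

* Constant descriptor columns cannot be min–max scaled; they are
  mapped to 0, flagged, and excluded from selection (a constant
  carries no pairwise information).
* Missing values are never handled silently: an explicit step drops
  the affected columns (default) or mean-imputes, with a message.
* Fitness marginals are accumulated with R's long-double `sum()`/BLAS
  paths; equality with the naive loop is asserted exactly, not within
  a tolerance, over randomized small instances.
* A dataset in which no pair falls within ε yields a warning (every
  descriptor is purely penalized; the run still terminates via the
  size penalty's floor, `λ ≥ 1e-8·(1+|mean m|)`, which keeps shrink
  pressure alive even when `sd(m) = 0`).
* An empty chromosome is not a candidate model; its selection score is
  +∞, and an all-zero chromosome's raw fitness is 0 (the empty sum).
* Gradient checks use `max |J − J_fd| / max(1, |J_fd|)` with central
  differences at h = 1e−6.

## Problem sizes used by the test suite

The suite exercises the full reference scale where the contract is
about scale — 500 × 1,481 populations, one complete GA run and two
complete pipeline runs on a 39 × 1,481 dataset, 100,000 mutation
applications — and small instances (≤ 40 compounds, ≤ 200 descriptors)
everywhere else, keeping the whole suite in the low minutes on one
CPU. These sizes are the package's own testing choices.

## Known limitations

* The fitness, as printed, never rewards a descriptor for
  *discriminating* compounds with different PK values; selection
  quality rests entirely on the award branch. This is a property of
  the method being implemented, preserved deliberately, and is why the
  survivor ranking needed the size-penalized score to function.
* One PK parameter per fit; multi-parameter studies loop the pipeline.
* The LM trainer is dense and in-memory — appropriate for ≤ 15 inputs
  and tens of compounds, not for thousands of either.
* `predict()` extrapolates linearly outside the training descriptor
  ranges (normalized values may leave [0, 1]); predictions for
  compounds outside the training chemistry should not be trusted, as
  with any QSPkR model.
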