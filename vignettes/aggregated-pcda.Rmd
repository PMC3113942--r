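---
title: "Aggregated PCDA: model, cross-validation scheme, and design choices"
author: "pcdagg maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregated PCDA: model, cross-validation scheme, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcdagg)
```

## The problem

Omics classification problems — gene expression arrays, SELDI-TOF serum
proteomics, NMR metabolomics — routinely present a few dozen samples
described by hundreds to thousands of features. Two things break in this
regime. First, classical Fisher linear discriminant analysis (FLDA) is
undefined: with more features $n$ than samples $m$ the within-class
scatter matrix $S_w$ is singular and $S_w^{-1} S_b$ does not exist.
Second, any cross-validation error estimate is itself a random variable
of the particular partition used, and with small $m$ that partition
noise is large: rerunning the same analysis with a different fold
assignment can change the headline misclassification rate
substantially.

`pcdagg` addresses both. Principal component discriminant analysis
(PCDA) projects the data onto a low-dimensional PCA score space in
which $S_w$ is invertible and runs FLDA there. The partition noise is
addressed by *aggregation*: the nested cross-validation is repeated
over many random partitions and the resulting classifiers vote.

## The model

Given training data $A \in \mathbb{R}^{m \times n}$ with $r$ classes of
sizes $m_i$ and index sets $M_i$, class centroids $\bar{x}_i$ and
global centroid $\bar{x}$:

$$
S_b = \sum_{i=1}^r m_i (\bar{x}_i - \bar{x})(\bar{x}_i - \bar{x})^{\top},
\qquad
S_w = \sum_{i=1}^r \sum_{j \in M_i} (x_j - \bar{x}_i)(x_j - \bar{x}_i)^{\top}.
$$

FLDA's discriminating directions $d$ maximize the Rayleigh quotient
$d^\top S_b d \,/\, d^\top S_w d$; they are the leading eigenvectors of
$S_w^{-1} S_b$, of which at most $r - 1$ are informative (the rank of
$S_b$). PCDA first maps the scaled data onto the top $a$ principal
components and forms both scatter matrices in the score space, where
$S_w$ is invertible whenever $a \le m - r$ (in generic position).
`fitPCDA()` enforces that bound.

Numerically the generalized eigenproblem is solved through a Cholesky
factor of $S_w$ rather than a literal inverse — mathematically
identical, better conditioned. For two classes the single direction is
obtained from the equivalent closed form $S_w^{-1}(\bar{x}_1 -
\bar{x}_2)$ through the same factor. Directions are normalized to unit
length and their sign fixed so the largest-magnitude entry is positive;
both conventions are arbitrary mathematically and fixing them makes
every result bit-reproducible.

**Decision rule.** A sample is assigned to the class whose projected
centroid is nearest (Euclidean distance in the discriminant space),
with exact ties going to the first class in stored label order. Equal
class priors are assumed throughout; class imbalance is handled only
through stratification of the folds.

## Pretreatment

Auto-scaling (mean-center each feature, divide by its standard
deviation, $m-1$ denominator) is the default; mean-centering-only and
no scaling are available. All statistics are fitted on training rows
only and then applied frozen to validation or test rows — inside every
inner fold as well, so no held-out sample ever leaks into the model
that scores it. A feature with zero training variance cannot be
autoscaled; it is dropped with a warning rather than inflated with an
epsilon, because a constant feature carries no discriminant information
while epsilon-padding distorts the PCA.

Spectral profiles measured at varying overall intensity can be brought
to a common scale with `medianNormalize()` (each row divided by its own
median), applied *before* scaling when both are requested.
`kennardStone()` provides the deterministic max–min representative
train/test splitter, optionally per class with proportional quotas so
the split preserves class ratios.

## The double cross-validation scheme

Choosing $a$ on the same folds that report the error is optimistic.
`doubleCV()` therefore nests two loops:

* **outer loop** — stratified $K$-fold (default $K = 10$); each fold in
  turn is held out untouched;
* **inner loop** — on the remaining $K-1$ parts, a $(K-1)$-fold
  stratified cross-validation scores every candidate component count;
  the candidate with the smallest inner error wins, ties broken toward
  the smallest count (parsimony);
* the model refitted on all $K-1$ parts at the winning $a^{*}$ predicts
  the held-out fold; pooling all held-out predictions gives the
  cross-validation error.

Stratification deals each class round-robin into folds after a seeded
shuffle, so per class the fold counts differ by at most one. $K$ may
not exceed the smallest class size — beyond that a fold would lack a
class — and the package refuses such configurations up front.

**Candidate grid.** By default candidates are $1 \ldots \min(20,\,
m_{\text{inner-train}} - r)$, wide enough for the small-sample regimes
this method targets while keeping $S_w$ invertible; any grid can be
supplied in `runConfig()`.

## Aggregation, margins, stability

`aggregatePCDA()` repeats the whole double CV $R$ times (default 51)
with derived seeds `seed + 1 … seed + R`, so any replicate can be
reproduced in isolation. For the aggregated cross-validation error each
sample receives **exactly one vote per replicate — from the outer-fold
model that held it out**. Any other member model saw that sample during
training, so letting it vote would bias the estimate; this choice keeps
the aggregate error honest. The aggregated label is the majority vote,
ties again to the first class.

The per-sample **margin** is the fraction of correct votes minus the
fraction of incorrect votes, i.e. $2 p_{\text{correct}} - 1 \in
[-1, 1]$. Margins near zero flag samples the classifier flips on across
partitions — the unstable samples that make the aggregate itself
unstable; a margin of 1 means unanimously correct.

For **test samples** (never seen by any member), `predict()` on an
ensemble pools all $R \times K$ member models by default; a
replicate-level variant (one intra-replicate majority vote per
replicate, then $R$ votes) is available via `level = "replicate"`. The
model-level default uses strictly more information and is the
documented default; both are exposed because the voting population at
test time is a genuine design choice.

`stabilityCurve()` answers "how many replicates are enough?": it reuses
the single stream of $R$ fitted replicates and recomputes the
aggregated error from the first $g$ votes only, for each $g$ in a grid
(canonically 20 to 1000 by 20). Nothing is refitted. In practice the
curve settles within 50–200 replicates; the package's own stability
check verifies, at reduced scale, that the error fluctuation beyond 100
aggregations is no larger than before 100.

## Rank-product feature ranking

Each member model back-projects its discriminant direction through the
PCA loadings into feature space (`discriminantDirections()`), giving
one coefficient per feature; an $R \times K$ ensemble yields $R \times
K$ such vectors (e.g. $100 \times 10 = 1000$). Within each vector
features are ranked by **absolute coefficient** (rank 1 = largest
magnitude — discriminant sign is arbitrary, so magnitude is the
discriminative weight; whether ranking should instead be signed is not
decidable from the method's description, and the choice is flagged
here). `rankProducts()` combines each feature's ranks across vectors by
the mean of log ranks — monotone-equivalent to the literal product of
ranks but immune to overflow at thousands of features times thousands
of vectors (the equivalence is unit-tested against exact products).
Features with the smallest rank products are the most consistently
discriminative. No permutation-based significance is attached; the
package stops at the ranking.

## The simulation design

`paramsFromReference()` turns any auto-scaled two-class reference data
set into simulator parameters: class means $u_1, u_2$ are kept as the
simulated means $v_1, v_2$ (preserving the separability of the
reference), and both classes share the pooled within-class covariance
$\Omega = ((m_1{-}1)\Omega_1 + (m_2{-}1)\Omega_2)/(m_1{+}m_2{-}2)$. A
covariance estimated from fewer samples than features is singular;
$\Omega$ is kept in factor form $F F^\top$ (eigenvectors scaled by root
eigenvalues, negative eigenvalues clipped at zero) and
`simulateClasses()` draws $v_i + F z$ with standard-normal $z$ — an
exact draw from the degenerate Gaussian, with no artificial full-rank
noise added. The canonical design simulates 100 objects per class from
a 590-feature serum-proteomics reference, a 200 × 590 matrix. This
realization (means kept, covariance pooled) is isolated in
`paramsFromReference()` so an alternative construction can be swapped
in one place.

`learningCurve()` implements the sampling protocol around it: for
training sizes (canonically 12, 30, 50, 75, 100) and a fixed test size
(100), repeatedly draw stratified train and test sets, run a single
double-CV PCDA and an aggregated one, and summarize cross-validation
and test errors by mean and standard deviation over repeats (error bars
as the standard deviation of the mean). Seeds are fixed per draw so
single and aggregated runs face identical selections. One adaptation:
at training size 12 a 10-fold stratified split is impossible (each
class has 6 members), so the protocol caps $K$ at the smallest class
size of the draw; this is the package's own resolution of an
under-determined corner, chosen over abandoning stratification.

`plantedSignalData()` is the fully synthetic counterpart — identity
covariance, class means differing by `shift` on the first
`nInformative` features — whose Bayes error
$\Phi(-\text{shift}\sqrt{k}/2)$ is known in closed form. It deliberately
omits features of real spectra: no correlation structure, no
heteroscedasticity, no baseline artifacts. Tests that pass on it
demonstrate the machinery (selection honesty, error stabilization,
ranking recovery), not performance on real spectra. One consequence of
the identity covariance is worth spelling out: with $m$ samples and
$n \gg m$ features, a planted mean-shift is recoverable by PCA only if
its induced covariance spike exceeds roughly $1 + \sqrt{n/m}$; below
that threshold PCDA behaves as a very weak, near-chance learner, and —
as with any majority vote over weak learners — aggregation then brings
little or no reliable benefit. Benchmarks of the aggregation gain
should therefore plant a detectable signal, as the covariance
structure inherited from real data typically is.

## Seeds and determinism

Every stochastic step flows from one user seed: replicate $t$ of an
ensemble runs at `seed + t`; nested stages (inner fold shuffles,
learning-curve draws) derive seeds through a fixed 32-bit Lehmer-style
mix so streams do not collide. The RNG state is restored after every
seeded operation, so package calls never disturb the caller's stream.
Identical data, configuration and seed reproduce every result — and
every written report — byte for byte. Reports deliberately carry no
wall-clock timestamp for that reason.

## Numerical choices and degenerate inputs

* Within-scatter singularity (component count too high for the fold
  sizes) is refused with an instruction to lower the count, not
  regularized away — shrinkage LDA is out of scope.
* In the inner loop the PCA is fitted once per fold at the largest
  candidate and smaller candidates reuse its leading submatrices
  (score truncation); this is exact, not an approximation, and is
  what makes repeated-split aggregation affordable.
* When features outnumber samples by more than 2:1 the PCA is computed
  from the sample-space Gram matrix rather than a direct SVD —
  identical subspace, much cheaper.
* Vote ties, centroid-distance ties and rank ties all resolve
  deterministically (first class in stored order / lowest feature
  index).
* Missing values are rejected at load time; the method has no
  imputation step.

## Problem sizes used by the test suite

The package's checks run the full machinery at reduced scale so the
complete suite stays fast: null-label honesty at 60 samples × 50
features over 100 seeded runs; aggregation benefit at 60 × 500 with 10
informative features, $R = 25$, 25 seeds; stability at $R = 200$ over a
20–200 grid, 10 runs; rank-product recovery at 60 × 500, $R = 10$, 20
seeds; the learning curve at sizes {12, 30, 50} × 10 repeats with
$R = 11$. These mirror the canonical settings ($K = 10$ outer / 9
inner, $R = 51$ or more, grid to 1000) in structure while keeping each
run to minutes.

## Limitations

* Multi-class problems work mechanically (LDA supplies up to $r-1$
  directions) but the aggregation behavior has only been characterized
  for two classes; rank products pool a single chosen discriminant
  column.
* Aggregation cannot rescue a very weak base learner: voting amplifies
  a systematically wrong classifier, and at very small sample sizes
  (around 12 training samples) the inner selection itself is starved.
* Equal priors are baked into the decision rule; strongly imbalanced
  problems are only handled through stratification.
* No significance calibration is attached to rank products or margins.
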