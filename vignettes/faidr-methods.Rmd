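---
title: "Multiple-instance inference of IDR function: model and methods"
author: "faidr package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-instance inference of IDR function: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faidr)
```

## The problem

Intrinsically disordered regions (IDRs) carry sequence-distributed
molecular features — physicochemical properties, compositions, repeats,
short linear motifs — rather than alignable positional conservation.
Functional annotations, however, are almost always recorded at the
*protein* level, and a protein frequently contains several predicted
IDRs. If we knew which IDR carried a function, relating feature vectors
to annotations would be ordinary supervised classification. We do not,
so `faidr` treats the identity of the responsible IDR as a hidden
variable: a classic multiple-instance learning problem in which proteins
are bags and IDRs are instances.

## The model

Each IDR $j$ of protein $i$ has a feature vector $Z_{ij}$ of $m$
molecular features. The per-IDR probability of a function is logistic,

$$h(Z_{ij}) = \frac{1}{1 + e^{-(Z_{ij} b + b_0)}},$$

with one coefficient per feature. The binary protein label $Y_i$ is
assumed to be generated by exactly one responsible IDR, indicated by the
hidden one-hot variable $X_{ij}$. Marginalizing $X$ with an
uninformative prior $P(X_{ij}=1) = 1/r_i$ over the $r_i$ IDRs of the
protein gives the marginal likelihood

$$P(Y \mid Z, b) = \prod_{i=1}^{n} \sum_{j=1}^{r_i} P(X_{ij}=1)\,
h(Z_{ij})^{Y_i}\,(1-h(Z_{ij}))^{1-Y_i}.$$

`marginalLogLikelihood()` evaluates this directly; the unit tests verify
it against brute-force enumeration over all joint hidden assignments.

### EM with penalized, truncated IRLS M-steps

Fitting maximizes the marginal likelihood under an elastic-net penalty
by expectation–maximization (`fitFaidr()`):

* **E-step** (`eStep()`): by Bayes' theorem,
  $\langle X_{ij}\rangle \propto Y_i h(Z_{ij}) + (1-Y_i)(1-h(Z_{ij}))$,
  normalized within each protein.
* **M-step**: maximize the expected complete log-likelihood, which is a
  logistic regression over all IDR rows in which each row carries its
  protein's label weighted by $\langle X_{ij}\rangle$. The quadratic
  weight of the iteratively-reweighted-least-squares (IRLS) update is
  then exactly $w_{ij} = \langle X_{ij}\rangle\,h(Z_{ij})(1-h(Z_{ij}))$
  (`irlsWeights()`). We run a fixed, deliberately truncated number of
  IRLS iterations per M-step (five by default), each solving its
  penalized weighted least-squares subproblem exactly by coordinate
  descent (compiled code under `src/`), warm-started from the previous
  round.

Responsibilities are initialized uniformly at $1/r_i$, so every IDR of a
protein starts equally down-weighted.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lambda` | 0.2 | elastic-net strength on the glmnet scale (observation weights normalized to sum to the number of rows); strong sparsity suited to functions with few positives |
| `alpha` | 0.99 | L1/L2 mixing; the 1% ridge stabilizes IRLS when positives are few relative to features |
| `irlsIterations` | 5 | IRLS passes per M-step; the M-step is truncated, not run to convergence |
| `maxEmIterations` | 100 | EM round cap |
| `emTolerance` | 1e-4 | stop when no responsibility moves more than this |
| `weightFloor` | 1e-8 | replacement for IRLS weights that underflow to 0 at saturated probabilities |
| `minPositives` | 5 | refuse to fit rarer functions |

Design choices the underlying formulation leaves open, fixed here and
exercised by tests:

* **Intercept**: included, unpenalized (the glmnet convention).
* **Standardization**: off by default. The intended inputs are
  evolutionary-signature Z-scores or single-species features already
  scaled to zero mean and unit variance; internal re-standardization
  would double-scale them. `faidrControl(standardize = TRUE)` enables it
  for raw inputs.
* **EM stopping**: max absolute responsibility change below `emTolerance`,
  or the round cap; the penalized marginal log-likelihood (marginal
  log-likelihood per protein minus the penalty) is recorded each round in
  `objectiveTrace`, and tests assert it never decreases.
* **Warm starts**: each M-step starts from the previous coefficients.
  With truncated inner iterations this stabilizes the trajectory and
  makes the single-IDR case collapse *exactly* onto one run of
  `weightedPenalizedLogistic()`.
* **Numerical clamps**: linear predictors are clipped to ±700 before
  exponentiation; logarithm arguments are floored at 1e-12.

### Prediction

`predictIdr()` applies the logistic model to each IDR row independently.
For an unseen protein the E-step posterior is unavailable ($Y$ is what
we want to predict), so `predictProtein()` uses the uninformative prior:
the protein score is the plain average of its IDR probabilities, a convex
combination that the tests check exactly.

## Feature–function associations

The penalized fit is a selector, not an estimator: coefficients are
shrunk. To measure direction and strength of association,
`refitTstats()` refits an *unpenalized* logistic regression on the
selected features only and reports Wald t-statistics; unselected
features are assigned exactly 0. For multi-IDR proteins the refit rows
are weighted by the final responsibilities, concentrating each protein's
label mass on the IDR the model believes carries the function (a
max-responsibility-row alternative is available via `rows =
"max-responsibility"`). Quasi-separation — diagnosed by saturated linear
predictors, since `glm()` can "converge" with astronomically inflated
standard errors — returns capped statistics `sign(coef) * 50` and a flag.

Per-function vectors assemble into an `AssociationMatrix`
(`assembleMatrix()`), are filtered to features with at least one
t-statistic of 3 or more (`filterFeatures()`; signed by default, the
literal reading of "3 or greater", with an absolute-value mode), and are
clustered by average linkage under uncentered correlation distance
$d = 1 - \sum x_i y_i / (\lVert x\rVert\,\lVert y\rVert)$
(`hierarchicalCluster()`, `writeClusteredTable()` emits a CDT-like table
for tree viewers). Uncentered correlation is used rather than Pearson
because the sign pattern of a t-statistic profile is meaningful; vectors
are deliberately not centered. The agglomeration itself is standard
`stats::hclust`; the distance weighting scheme of the Cluster 3.0
program ("calculate weights") is not reproduced.

## Evaluation protocols

* `aucScore()` / `rocCurve()`: rank-based (Mann–Whitney) AUC with
  midrank tie handling, identical to the trapezoidal area of the ROC
  curve; verified against brute-force concordant-pair counting.
* `proteinCv()`: five-fold cross-validation partitioning *proteins*
  (never splitting a protein's IDRs across folds), simple random folds by
  default to mirror the usual protocol, with an optional stratified mode
  for rare annotations. Functions with fewer than 20 positives are
  refused by default.
* `heldoutIdrEval()`: holds out 20% of proteins, trains only on
  protein-level labels of the rest, then scores *held-out IDRs*
  individually against independent IDR-level ground truth (e.g.
  experimental sites mapped into IDR coordinate intervals with
  `mapSitesToIdrs()`; containment is strict, 1-based, inclusive). This
  tests whether protein-level supervision localizes function to the
  right region of unseen proteins.

## Sequence features and signatures

`seqfeatures` provides the single-sequence calculators behind the worked
examples: standard-code DNA translation (internal stops are errors, one
terminal stop is stripped), isoelectric point by bisection of the
Henderson–Hasselbalch net charge over pH 0–14, mean Kyte–Doolittle
hydropathy, composition fractions, and non-overlapping consensus-motif
counts (`"S/T-P"` notation). The pI uses the classic Bjellqvist/ExPASy
side-chain pKa set with constant termini pKa (N-terminus 7.5,
C-terminus 3.55); this table reproduces the printed pI values of the
Cox15 IDR variants shipped in `inst/extdata/` to within 0.05 pH units,
whereas variants of the table with residue-specific N-terminal pKa do
not, which is why it is the default. The table is an argument, not a
constant. Net charge is strictly decreasing in pH, so bisection finds
the unique root; tests assert both.

`featureCatalog()` is a data-driven registry of 82 default molecular
features (20 residue fractions, 12 physicochemical class fractions,
Kyte–Doolittle mean, pI, net charge, length, 30 repeat counts, 16
consensus motifs). Summarizing each feature by its mean and log sample
variance across an ortholog set (`orthologSignature()`) yields the
164-column evolutionary-signature layout; dividing observed summaries by
a simulated null's spread (`signatureZscore()`, sample n−1 variance)
turns them into Z-scores. Variances are floored at 1e-8 before the log
so invariant features stay finite. The catalog is a reconstruction of
the feature *families* used with evolutionary signatures, not a verbatim
copy of any published list; users can pass their own catalog everywhere.

## The synthetic generator

`generateSynthetic()` draws data with exactly the structure the model
assumes: IDR counts uniform on 1–4, i.i.d. standard-normal features
(mimicking Z-scores; an exchangeable-correlation option `rho` stresses
the selector), a uniformly drawn responsible IDR, and Bernoulli labels
through that IDR's features only — by default 2000 proteins, 164
features, 10 true effects of magnitude 2 with random signs, intercept
−1. It emulates the dimensionality and sparsity of signature data but
*not* feature correlation, heterogeneous annotation prevalence, or IDR
boundary uncertainty in real proteomes; passing tests therefore
demonstrate correctness of the machinery, not real-data performance.

One property of these defaults deserves emphasis. With 10 independent
effects of ±2 the linear predictor has standard deviation
$\sqrt{40} \approx 6.3$: labels are nearly deterministic in
$\mathrm{sign}(\eta)$, and each individual feature's marginal covariance
with the label — which is what sets the LASSO entry threshold — is only
about 0.13 for single-IDR data and 0.08 for multi-IDR bags, below the
default penalty's threshold $\alpha\lambda = 0.198$. At `lambda = 0.2`
the fit on these defaults therefore selects nothing, and no effect size
rescues a support of 10 (the marginal covariance is bounded by
$\approx 0.4/\sqrt{\text{support}}$). Likewise, even the *true*
coefficients identify the generating IDR among multi-IDR positives only
~62% of the time under this process, since a non-responsible IDR can
have the higher probability by chance. The default λ earns its keep on
real, correlated features; on this independent-feature generator,
demonstrations of support recovery and responsibility identification use
a smaller explicit `lambda` (0.05 in the tests and the acceptance
script), where recovery is essentially perfect (recall and sign
agreement 1.0 at n = 800–2000).

Problem sizes used by the test suite and `scripts/acceptance.R` — 120 to
2000 proteins, 8 to 164 features — were chosen so each check exercises
the regime it is about (EM dynamics, sparsity, ranking) while the whole
suite stays comfortably fast; all are stated in the code next to the
checks they support.

## Known limitations

* The responsible-IDR assumption is one-per-protein; distributed
  functions (several contributing IDRs) are outside the model.
* The uninformative prior is fixed; no informative prior over which IDR
  is responsible is implemented.
* `lambda` is fixed rather than path-selected by cross-validation, by
  design.
* The feature catalog computes single-sequence features; simulating IDR
  evolution to build true evolutionary null distributions is out of
  scope — `signatureZscore()` consumes null draws produced elsewhere.
* Quasi-separated refits report a capped, direction-only t-statistic.
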