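---
title: "Balanced sparse logistic models for binary metabolomic profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced sparse logistic models for binary metabolomic profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsum)
```

## The data model

Untargeted tandem mass spectrometry reduces a biological sample to a
binary vector: entry *t* is 1 if molecular feature *t* (a
library-matched compound or a clustered MS/MS spectrum) was detected,
and 0 otherwise. `metsum` works entirely on such presence/absence
tables. Feature extraction — spectral library search, spectral
clustering — is upstream and out of scope; the package takes the
binarization as given. Quantitative intensities are deliberately not
used: on these tasks presence/absence is the more robust signal, as
intensity features bias models toward abundant molecules.

Two analyses share one mathematical core.

**Phenotype classification.** Given samples $x^t \in \{0,1\}^p$ with
class labels $y^t$, a standard L1-penalized logistic regression
minimizes $\sum_t L(f(x^t), y^t) + \lambda\lVert\beta\rVert_1$.
Repository-scale cohorts are heavily imbalanced (often >90% of
host-associated samples are healthy controls), so the plain sum lets
the majority class dominate. The *balanced* objective reweights each
sample by the inverse of its class multiplicity:

$$\min_\beta \; \sum_{t=1}^{T} \frac{L(f(x^t),\,y^t)}{b^t}
  + \lambda\,\mathrm{pen}(\beta),
  \qquad b^t = \#\{s : y^s = y^t\},$$

so every class contributes total loss mass exactly 1. The L1 penalty
drives most coefficients to zero; the surviving features are readable
as candidate biomarkers — which is what makes protocol artifacts
auditable at all.

**Ingredient decomposition.** A complex sample (a prepared dish, an
environmental mixture) is modelled by the *union assumption*: its
binary profile is approximately the union of its raw ingredients'
profiles. With a reference library $D \in \{0,1\}^{T\times n}$ (columns
= candidate ingredients) and a query profile $c \in \{0,1\}^T$, the
abundance vector $x$ minimizes

$$\sum_{t=1}^{T}
  \frac{\mathrm{CE}\!\big(c^t,\,\sigma((Dx)^t)\big)}{b^t}
  + \lambda \lVert x\rVert_1,$$

where $\sigma(z) = 1/(1+e^{-z})$,
$\mathrm{CE}(y,\hat y) = -y\log\hat y - (1-y)\log(1-\hat y)$, and
$b^t$ counts the entries of $c$ sharing the value $c^t$. This is
exactly a weighted L1 logistic regression with design $D$ and response
$c$ and no intercept. The balancing is essential here too: almost all
of $c$ is zeros, and unweighted cross-entropy would be minimized by
explaining the absences and ignoring the detections. With both values
present the weights sum to 2 (mass 1 per value class), which gives the
useful analytic anchor that the objective at $x=0$ is exactly
$2\log 2$.

The penalty is swept until the minimizer has exactly $k$ nonzero
entries ($k = 5$ by default); those ingredients, ranked by coefficient,
are the prediction.

## The solver

Both problems are solved by one deterministic proximal-gradient engine
(FISTA with adaptive restart) for

$$\textstyle\min_x \sum_t w_t\,
  \mathrm{CE}(y_t, \sigma(a_t^\top x + b)) + \mathrm{pen}(x),$$

with an L1 prox step or a smooth L2 term, an optional unpenalized
intercept, and an optional nonnegativity constraint. The step size is
$1/L$ with $L$ the Lipschitz constant of the weighted-loss gradient,
computed as $\tfrac14\sigma_{\max}^2(\sqrt{W}[A\,|\,\mathbf 1])$ by
power iteration from a fixed starting vector. Convergence is declared
when the relative objective change drops below `tol` (default 1e-10);
non-convergence raises a typed error carrying the best iterate. There
is no randomized initialization anywhere, so refitting with identical
inputs is bit-for-bit reproducible — the property the
remove-and-retrain audit relies on.

Numerical choices worth knowing:

* the loss is evaluated in the stable form
  $\max(a,0) - ya + \log(1+e^{-|a|})$, so arbitrarily large scores
  cannot overflow;
* inside `cross_entropy()`, probabilities are clamped to
  $[10^{-12}, 1-10^{-12}]$ to keep boundary values finite;
* a coefficient counts as nonzero when
  $|x_i| > 10^{-6}\max(1, \max_j |x_j|)$ — a relative threshold, since
  "nonzero" is otherwise undefined for an iterative solver.

## The λ-path search

The stopping rule is a *support size*, not a penalty value, so the
search is over λ. The L1 optimality condition at the origin gives the
critical value in closed form,
$\lambda_{\max} = \max_i |(D^\top(w \odot (0.5 - c)))_i|$, above which
the solution is identically zero (for the nonnegative mode the
one-sided condition $\max_i(-g_i)$ applies). The search starts there,
descends geometrically by factor 0.8 with warm starts until at least
$k$ coefficients are active, then bisects geometrically between the
bracketing penalties for at most 60 steps to land on exactly $k$.
Convexity makes warm starts a pure speed-up. Every $(\lambda,
\text{support size})$ visited is recorded in `path_log`. If the support
size jumps past $k$ between bracketing penalties — possible when
several ingredients enter together — the documented fallback takes the
visited solution with the smallest support $\ge k$, ranks it by
coefficient, truncates to $k$, and flags the result. An all-zero query
has zero gradient toward every ingredient; it is flagged degenerate and
returns an empty selection rather than an arbitrary one.

Ties are deterministic throughout: selection orders by descending
coefficient then lexicographic ingredient ID; prediction breaks score
ties toward the earliest class in vocabulary order; biomarker ranking
breaks magnitude ties lexicographically.

## Sign of the abundances

The printed objective is unconstrained, and the default solver follows
it. That has a consequence worth understanding: for an ingredient whose
features are *absent* from the query, the optimum is typically
*negative* (a negative coefficient pushes those features' predicted
probabilities toward zero), which the grid-search oracle confirms on
toy problems. Selection ranks by signed coefficient, so such
ingredients are never chosen — large positive coefficients mean
presence. For users who want the abundance reading to be literal, a
nonnegativity-constrained mode (`nonneg = TRUE`) is provided; on the
toy problems its inactive ingredients sit exactly at zero.

## Classifier design

* **Multiclass scheme:** one-vs-rest, with the multiclass balance
  weights applied inside every binary subproblem. This keeps one
  coefficient vector per class, which is the object the biomarker audit
  reads. A multinomial softmax variant was considered and not built:
  it obscures the per-class coefficient reading that motivates the
  method and would add solver machinery without changing any behaviour
  this package tests.
* **Intercept:** included and unpenalized, standard logistic-regression
  practice; with all-zero queries the intercepts alone decide.
* **Penalty strength:** there is no canonical value; the default 0.01
  suits binary features on cohorts of tens-to-hundreds of samples, and
  `strength = "auto"` selects over the geometric grid
  $10^{-3},\dots,10^0$ by stratified cross-validated *balanced*
  accuracy (consistent with the weighting's intent), deterministically
  for a fixed seed.
* **Artifact handling is semi-automatic by design.** The report ranks
  coefficients and can flag known internal-standard IDs, but removal
  happens only through an explicit blocklist: no automatic rule can
  distinguish a protocol artifact from a genuine biomarker, only
  provenance knowledge can.

## What the synthetic generator does and does not emulate

The generator produces the three structures the methods assume, with
truth records for testing:

* `make_library()` — ingredient profiles with exact support sizes and a
  controlled shared fraction. Sharing is implemented as a common core
  (a fraction `overlap` of every support), which realizes the pairwise
  overlap exactly rather than in expectation; it is the simplest
  mechanism that stresses attribution of shared molecules.
* `make_complex()` — union of $k$ uniformly chosen ingredients with
  independent Bernoulli noise: detected features drop out with
  probability `dropout`, absent ones appear spuriously with probability
  `spurious`. The union assumption itself specifies no noise model, so
  the simplest one is used and its rates are exposed.
* `make_cohort()` — class-specific signal features over a Bernoulli
  background, optional deterministic "internal standard" features tied
  to a dataset ID, and deterministic feature-role blocks so that a
  second cohort with the confounder planted in a different class forms
  a protocol-shifted test set. The default class mix (90/10) mirrors
  the >90% majority-class imbalance of real repository cohorts.

Real data differ in ways these fixtures do not capture: feature
presence is correlated (shared biosynthetic pathways, adducts and
in-source fragments of one molecule), noise is not independent across
features, ingredient profiles vary between batches of the same food,
and annotation lists are incomplete. Passing tests therefore
demonstrate that the algorithms are implemented correctly and behave as
designed under their own assumptions — not that those assumptions hold
for any particular real cohort.

## Problem sizes used in the checks

The package's own validation runs at desk scale, chosen to exercise
every code path: libraries of 40 ingredients × 800 features with
support 20 (disjoint and 20%-shared variants), 20 noise-free and 50
noisy dishes, cohorts of 80 samples × 200 features for the
batch-effect story, and exhaustive grid-search oracles on problems with
2–3 ingredients and ≤ 20 features (a dense $[-3,3]^d$ grid at step
0.05 grows as $121^d$, which bounds the oracle's reach). The
repository-scale matrices the methods target (tens of thousands of
features, thousands of reference profiles) are sparse; the
MatrixMarket dialect of `read_feature_table()` exists for them.

## Known limitations

* The λ search assumes the support size is weakly monotone in λ. This
  holds in every tested run (and is asserted on `path_log`), but lasso
  paths can in principle violate it; the bisection-with-fallback
  handles the benign jump case, not adversarial non-monotonicity.
* Abundances are ordinal evidence, not calibrated proportions; nothing
  maps $x$ to mass fractions.
* One-vs-rest scores are not calibrated probabilities across classes;
  only the argmax is meaningful.
* With `overlap` near 1 the decomposition is unidentifiable by
  construction; the generator permits such settings for stress testing
  but recovery claims apply to the tested regimes.
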