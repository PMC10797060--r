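---
title: "Network models of multimorbidity and health outcomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network models of multimorbidity and health outcomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mminet)
```

# The problem

Persons living with spinal cord injury commonly experience many concurrent
secondary health conditions (SHCs) — pressure ulcers, urinary tract
infections, spasticity, depression, and pre-existing comorbidities such as
diabetes or heart disease. A multimorbidity index (MMI) counts how many of
30 such conditions a survey respondent reports; the count is strongly
associated with unmet healthcare needs, lower physical and mental health
status, and lower quality of life. `mminet` implements a network-analytic
workflow over such survey data:

1. code the raw survey responses and score the index;
2. screen every item against five health outcomes with standard bivariate
   tests;
3. estimate three pairwise Markov random field (MRF) networks over items
   and outcomes — a Gaussian graphical model (GGM), an Ising model, and a
   mixed graphical model (MGM) — each with L1 regularization and EBIC model
   selection;
4. summarize node importance (strength, expected influence, betweenness)
   and quantify its bootstrap stability (CS-coefficients);
5. derive a reduced index by removing items that are isolated in the
   fitted networks *and* null in the bivariate screen;
6. compare full and reduced indices side by side in outcome regressions.

Because community survey datasets of this kind are typically restricted,
the package ships a synthetic-cohort generator with planted network
structure, so every stage of the workflow is testable end to end against a
known truth.

# Survey coding and the index

Each SHC item is coded 1 (present) or 0 (absent); respondents answering
"do not know" are coded 0 — they are treated as not having the condition.
The index score is the plain sum of the coded items, so the 30-item form
ranges over 0–30 and a reduced k-item form over 0–k; a respondent with any
missing item gets a missing score. Two ordinal outcomes are dichotomized
before any binary-outcome analysis: the 6-point life-satisfaction rating at
5 (ratings 5–6 are "satisfied") and the 5-point overall quality-of-life
rating at 4 by default. The QoL cut is a parameter (`qol_cut`) because the
instrument's published description fixes only the satisfaction cut; we cut
at the top two ratings to mirror the satisfaction logic, consistent with
item means typically sitting in the upper-middle of the scale.

Missingness is handled by complete-case analysis per operation: every test,
fit and regression drops the rows with missing values among its own
variables only. Sex, lesion completeness and living setting enter models as
0/1 dummies (male = 1, incomplete = 1, own home = 1), and odds ratios are
reported as `exp(beta)` with Wald intervals. Days since injury enters in
days, unscaled.

# The three network estimators

All three estimators return a symmetric edge-weight matrix with zero
diagonal; an edge encodes conditional dependence between two nodes given
all others.

**EBIC.** Model selection throughout uses the extended Bayesian information
criterion

\[ \mathrm{EBIC}_\gamma = -2\,\ell + k \ln n + 2 \gamma k \ln p^*, \]

where \(k\) is the number of selected parameters and \(p^*\) the number of
*candidate* parameters: the \(p-1\) candidate predictors for a nodewise
regression, and the \(p(p-1)/2\) candidate edges for the whole-network GGM
(which makes the GGM penalty the usual \(\approx 4\gamma E \ln p\) form).
Ties are broken toward the sparser model. Defaults are \(\gamma = 0.5\) for
the GGM and \(\gamma = 0.25\) for the Ising and mixed models, the common
defaults in the psychometric-network literature; both are arguments.

**Penalty paths.** Each fit uses 100 log-spaced penalties from the smallest
value that gives an empty model down to 1/100 of it (a standard
glmnet-style path). Intercepts are never penalized; continuous responses
use least squares with an L1 penalty on slopes only.

**GGM.** The graphical lasso (blockwise coordinate descent, implemented in
C++) is run on the sample Pearson correlation matrix over the penalty path.
The path is used to *propose* candidate edge patterns; each distinct
pattern is then rescored by the EBIC of its pattern-constrained Gaussian
maximum likelihood (computed by the same coordinate-descent engine with an
elementwise penalty: zero on allowed edges, effectively infinite
elsewhere). This "relaxed" rescoring matters: scoring the penalized
solutions directly lets the shrinkage of strong true edges keep improving
the likelihood along the path, which drags selection into dense models —
in our planted-truth simulations it admitted ~40% false (tiny) edges at
n = 5000, whereas the refit selection recovers the exact planted pattern.
The selected pattern's constrained MLE precision matrix \(K\) is reported
as partial correlations \(w_{ij} = -K_{ij}/\sqrt{K_{ii}K_{jj}}\), which lie
in \([-1, 1]\). Binary 0/1 columns are admitted as-is (Pearson
correlations on coded values); no polychoric correction is attempted, and
this is a known approximation of the workflow.

**Ising.** Each binary node is regressed on all others by L1-penalized
logistic regression (via glmnet), with the EBIC on the penalized
likelihood selecting each node's neighbour set — the eLasso convention.
Directional coefficients are symmetrized by the AND rule: an edge exists
only if both nodewise selections kept the pair, with weight the mean of
the two coefficients (an OR rule is available, in which a missing
direction contributes 0 to the mean). Continuous variables (the component
summary scores, age) are excluded from this model by construction.

**MGM.** Nodewise regressions — linear for continuous nodes (standardized
first), logistic for binary nodes — with AND-rule symmetrization. Only
binary and continuous nodes are supported. For the *Gaussian* responses
the candidate supports proposed by the lasso path are rescored by their
OLS refit, for the same reason as in the GGM; the binomial fits keep the
penalized-likelihood convention, which we measured to be accurate for them
(false-discovery proportion ≈ 0.01 on planted truths at n = 5000).

**Node sets in the pipeline.** The GGM runs on the 30 items plus all five
outcomes (ordinal outcomes dichotomized); the Ising model on the binary
nodes only; the MGM additionally includes age as a continuous node.

# Centrality and stability

Strength is \(\sum_j |w_{ij}|\), expected influence the signed sum
\(\sum_j w_{ij}\) (one-step version, matching its usual one-sentence
definition), and betweenness counts geodesics through a node with edge
lengths \(1/|w_{ij}|\) and fractional credit over tied geodesics (the
Brandes convention, computed via igraph). Raw and z-standardized values
are both reported because published centrality panels are ambiguous about
which they plot; a metric with zero spread gets z-scores of 0 and a flag.

Stability follows the standard bootstrap workflow for psychometric networks, implemented here directly:

* **Edge accuracy** — nonparametric row resampling, refitting, percentile
  95% intervals per edge; two edges (or two nodes' centralities) differ
  significantly iff the bootstrap interval of their difference excludes 0.
  Resamples on which a refit fails are dropped and counted; more than 10%
  failures flags the report unstable.
* **CS-coefficient** — for each drop proportion q in {0.05, ..., 0.75},
  case-dropped subsamples are refit and the correlation between subsample
  and full-sample metric vectors recorded (Pearson, but Spearman for
  betweenness, which is heavily tied and zero-inflated). CS is the largest
  q such that at *every* grid point up to q at least 95% of subsamples
  correlate ≥ 0.7 with the original — the standard "CS (cor = 0.7)"
  definition, with the prefix requirement guarding against non-monotone
  curve noise. An entirely absent signal (constant metric vector) makes
  the correlation undefined; such curves are flagged and CS is missing
  rather than silently 0.

Defaults are B = 1000 edge resamples and B = 250 per drop-grid point; the
test suite and the acceptance script run reduced profiles (B = 50–120) and
state so here: those sizes were chosen to keep the full validation suite at
desk scale while leaving the qualitative contrasts (stable strong-signal
large-n fixtures vs unstable weak-signal small-n fixtures) unambiguous.

# The short-form derivation

Candidate items for removal must be *bivariate-null* — not significant
(α = 0.05, two-sided, no multiplicity correction, matching the source
workflow) against any of the five outcomes — and, under the default rule,
isolated (zero degree) in at least one fitted network. The default
`null_and_any_isolated` rule treats bivariate nullity as necessary and
network isolation as corroborating: isolation alone can reflect estimator
sparsity at a given sample size rather than clinical irrelevance, whereas
an item that also shows no marginal association with any outcome is a safe
removal candidate. `null_only` and `isolated_in_all`
rules are available, and the rule used is recorded in the report. With
multiple cohorts the per-cohort removal sets are unioned into one
generalized index.

The exact-zero isolation criterion is appropriate because every estimator
returns exact zeros for unselected edges (soft-thresholding in the lasso
and glasso); no tolerance is involved.

# The synthetic-cohort generator

`generate_cohort()` emulates the structure of a community SCI survey:

* **Items.** 30 binary SHCs drawn by Gibbs sampling from a planted 0/1
  Ising truth (single chain, 200 burn-in sweeps, thinning 5). The default
  truth plants five isolated comorbidity items (cancer, DVT, diabetes,
  high blood pressure, liver disease), an autonomic-dysreflexia hub with
  seven moderate edges, a strong elbow/wrist–shoulder pair, and moderate
  positive couplings elsewhere; fields are set by a mean-field correction
  targeting item prevalences near 0.35 (giving index means near 10, in the
  range reported for such surveys).
* **Outcomes.** Each outcome's linear predictor carries `outcome_effect`
  times the centered count of *network-connected* items with the harmful
  sign (more conditions: more unmet care need, lower PCS/MCS, lower
  satisfaction). The default effect, 0.174 per condition on the logit
  scale, matches the reported logistic coefficient of the full index on
  the unmet-care-need outcome. A shared latent links the satisfaction and
  QoL ratings (their strong edge), a shared latent correlates the two
  component scores, and depression additionally lowers the mental score —
  all auxiliary effects scale with `outcome_effect`, so setting it to 0
  severs every item–outcome link. Ordinal ratings arise by thresholding
  standardized latents at fixed normal quantiles.
* **Covariates.** Age, sex, lesion completeness, living setting, and days
  since injury are drawn independently with survey-like margins.

Because the isolated items are excluded from the outcome predictors, they
are genuinely null against all five outcomes, and the pipeline's expected
removal set is unambiguous. The generator is exactly reproducible given
the seed. It deliberately does **not** emulate: item-specific marginal
prevalences beyond order of magnitude, missing data (the generator is
complete-case; missingness handling is exercised separately), informative
covariate–item dependence, or the 0/1-vs-ordinal mix of real instruments.
Passing tests therefore demonstrate correctness of the machinery and
qualitative reproduction of the published regimes, not reproduction of the
restricted survey's numbers.

# Numerical choices and degenerate inputs

* Graphical-lasso convergence: outer/inner tolerances scale with the mean
  absolute off-diagonal correlation; soft-thresholding yields exact zeros,
  and an edge is absent only when both directional coordinates vanish.
* The implied precision matrix of a Gaussian truth must be positive
  definite; the sampler rejects it otherwise, naming the smallest
  eigenvalue.
* Chi-square tests use no continuity correction (the Fisher fallback
  already guards small expected counts); the t-test/Mann–Whitney switch
  uses Shapiro–Wilk at α = 0.05 per group, capped at 5000 observations.
  Test selection depends only on expected counts or normality, never on
  observed significance.
* Zero-variance inputs: screening returns a flagged degenerate result with
  a missing p-value; estimators refuse constant columns by name.
* EBIC ties break toward the larger penalty (sparser model).
* Logistic fits flag suspected complete separation (non-convergence with
  |beta| > 15) as an error rather than reporting meaningless Wald
  intervals.

# Known limitations

* The GGM treats coded binary items as continuous (Pearson input);
  polychoric/tetrachoric variants are out of scope.
* Categorical nodes with more than two levels are unsupported in the MGM.
* No directed or causal structure is estimated; all models are undirected
  MRFs fitted to cross-sectional data.
* The bivariate screen applies no multiple-testing correction, matching
  common practice in this survey literature. A consequence, visible in our
  own end-to-end
  simulations, is that a genuinely null item clears all five outcome tests
  only with probability ≈ 0.95 per effective test, so a five-item null set
  is recovered *exactly* in roughly half of synthetic cohorts at n = 4000;
  single chance significances are the dominant failure mode. A screening
  correction would change this but would depart from the workflow being
  implemented.

# Problem sizes used in validation

The shipped validation suite uses: p = 10 planted truths at n = 5000 over
100 seeds for edge recovery (sensitivity ≥ 0.9, false discovery ≤ 0.1 per
family); CS contrasts at n = 4000 (planted |w| = 0.35, "strong") vs
n = 300 (|w| = 0.25, "weak") with B = 50 subsamples per drop-grid point;
and 40 full-pipeline runs at n = 4000 for the short-form recovery and
index-agreement checks. These sizes are the package's validation design
choices; all are parameters of the exported functions.
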