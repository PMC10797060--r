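# mminet

Network analysis of multimorbidity and health outcomes in spinal-cord-injury
(SCI) survey cohorts.

People living with SCI report many concurrent secondary health conditions
(SHCs) — pressure ulcers, urinary tract infections, spasticity, autonomic
dysreflexia, depression, plus pre-existing comorbidities. A multimorbidity
index (MMI) counts the conditions present among 30 binary items; higher
counts predict unmet healthcare needs, lower SF-12 physical/mental component
scores (PCS-12/MCS-12), and lower life-satisfaction and quality-of-life
ratings. `mminet` is for researchers who want to go beyond the count: it
estimates the *conditional dependence network* over items and outcomes,
quantifies which items matter, and derives a shorter index from the network
structure.

## What it computes

Three pairwise Markov random fields over the survey variables, all with L1
regularization and extended-BIC model selection
(EBIC = −2ℓ + k·ln n + 2γ·k·ln p, sparser models at larger γ):

* **GGM** — graphical lasso on the Pearson correlation matrix; candidate
  edge patterns from the penalty path are rescored by their constrained
  Gaussian maximum likelihood, and edges are partial correlations
  w_ij = −K_ij/√(K_ii·K_jj) ∈ [−1, 1];
* **Ising** — nodewise L1 logistic regressions (eLasso) on the binary
  nodes, AND-rule symmetrization with coefficient averaging;
* **MGM** — mixed nodewise regressions (linear for standardized continuous
  nodes, logistic for binary), AND rule.

On a fitted network it reports strength (Σ|w|), one-step expected influence
(Σw), and betweenness (geodesics with edge length 1/|w|), plus bootstrap
machinery: percentile edge intervals, edge/centrality difference tests, and
case-dropping **CS-coefficients** — the largest case-drop proportion at
which subsample centralities still correlate ≥ 0.7 with the original in
≥ 95% of subsamples.

The short-form pipeline combines per-model *isolated* items (zero degree)
with the *bivariate null set* (items non-significant against all five
outcomes at α = 0.05 by chi-square/Fisher or t/Mann–Whitney, chosen by
expected counts / normality) to remove items, then compares the full and
reduced indices in linear (PCS/MCS) and logistic (unmet care need,
satisfaction, QoL) regressions with odds ratios exp(β) and Wald intervals.

A synthetic-cohort generator with a planted Ising truth (five isolated
comorbidities, an autonomic-dysreflexia hub, a strong elbow/wrist–shoulder
pair, outcome effects driven by the connected-item count) stands in for the
restricted survey data and makes every stage testable against known
structure.

## Worked example

```r
library(mminet)

cohort <- generate_cohort(cohort_config(n = 1500, seed = 42))
result <- run_pipeline(pipeline_config(cohort))

result$shortform
#> <shortform_report> rule:null_and_any_isolated
#>   removed (4): Can, Dia, DVT, HBP
#>   retained index: MMI-26

result$comparison$synthetic$agreement[, 1:3]
#>   outcome sign_match sig_match
#> 1   FNCNR       TRUE      TRUE
#> 2     PCS       TRUE      TRUE
#> 3     MCS       TRUE      TRUE
#> 4   LiSAT       TRUE      TRUE
#> 5     QoL       TRUE      TRUE

ct <- result$cohorts$synthetic$centrality$ising
head(ct[order(-ct$strength), c("node", "strength", "betweenness")], 3)
#>    node strength betweenness
#> 1    AD     4.00         210
#> 33  QoL     2.09          24
#> 24   SP     1.71          24
```

Reading the output: four of the five planted isolated comorbidities
(cancer, diabetes, DVT, high blood pressure) were both isolated in at least
one fitted network and null on all five outcome screens, so they were
removed; liver disease survived this particular n = 1500 draw because one
of its five screening tests crossed α = 0.05 by chance — exactly the
behaviour the uncorrected screen implies. The reduced 26-item index agrees
with the full index in sign and significance on every outcome model, and
the planted hub (autonomic dysreflexia, `AD`) dominates strength and
betweenness in the Ising network. At n = 4000 the removal set typically
equals the planted five and the retained index is the 25-item form.

`write_pipeline(result, "results/")` serializes every stage (networks as
JSON + edge CSVs, screens and centralities as CSV, the short-form report
and run manifest as JSON). A thin CLI with `simulate`, `fit` and
`shortform` subcommands is installed at `inst/cli/mminet.R`.

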