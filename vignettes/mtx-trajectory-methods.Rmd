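---
title: "Modelling methotrexate response trajectories in JIA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling methotrexate response trajectories in JIA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtxtraj)
```

## The scientific problem

Methotrexate (MTX) is the first-line disease-modifying drug in juvenile
idiopathic arthritis (JIA), yet it helps only about half of the children
who start it, and "response" is far from homogeneous: the four JADAS71
disease-activity components — active joint count (AJC, 0–71), physician
global assessment (PGA, 0–100 mm), parent global evaluation (PGE,
0–100 mm) and ESR (mm/h) — can improve quickly, slowly, transiently, or
diverge from one another.  Binary response criteria such as ACR Pedi 30
collapse this heterogeneity into yes/no labels.  `mtxtraj` instead models
the joint longitudinal course of all four components over the 14 months
after MTX initiation and classifies children into latent trajectory
clusters.

## The model

Let $y_{iot}$ be child $i$'s value of outcome $o$ at month $t$,
transformed as $\log(1+y)$.  A $K$-group multivariate group-based
trajectory model (GBTM) assumes each child belongs to one latent group
$k$ with probability $\pi_k$, and that within a group the observed
components are independent given group membership, each following a
censored-normal (Tobit) distribution around a polynomial mean:

$$\mu_{kot} = \sum_{p=0}^{P} \beta_{kop}\, t^p, \qquad
  y^*_{iot} \sim N(\mu_{kot},\ \sigma_o^2),\qquad
  y_{iot} = \min(\max(y^*_{iot}, lo_o),\ hi_o).$$

Observations at a bound contribute the tail mass
($\Phi((lo-\mu)/\sigma)$ below, $1-\Phi((hi-\mu)/\sigma)$ above) rather
than a density.  The bounds are $lo_o = 0$ for every component and
$hi_o = \log(1+71)$, $\log(1+100)$, $\log(1+100)$, $\log(1+200)$ for
AJC, PGA, PGE and ESR.  Residual scales $\sigma_o$ are per-outcome and
shared across groups, the convention of the canonical GBTM software;
this keeps the grid of models comparable and parsimonious.

The observed-data likelihood multiplies, within child and group, the
censored-normal contributions of every observed (outcome, month) pair —
partially recorded visits therefore still contribute through their
observed components — and mixes over groups:

$$\ell = \sum_i \log \sum_k \pi_k \prod_{(o,t)\ obs}
  f_{ko}(y_{iot}).$$

Maximisation is by EM.  The E-step computes posterior memberships
$p_{ik}$ with a log-sum-exp guard; the M-step updates $\pi$ in closed
form, performs guarded Newton updates of each group-by-outcome Tobit
polynomial regression (the censored-normal log-likelihood is concave in
the mean coefficients, and step-halving enforces the generalised-EM
ascent property exactly), and refreshes each $\sigma_o$ by a bracketed
line search.  Every tested instance therefore has a non-decreasing
log-likelihood trace, which the test suite asserts.

When group membership should depend on a per-child covariate (used for
cohorts whose follow-up length could drive assignment, e.g. registries
collecting only two visits), the mixing proportions become a
multinomial-logit function of the covariate and the M-step takes one
guarded Newton step on those coefficients per iteration.

### Starting values and local optima

Finite mixtures of trajectories are multimodal, and the dominant failure
mode we observed is a basin in which the large persistent-disease
cluster is split while two genuinely distinct clusters merge.  Three
devices address this:

* k-means starts on per-child *profile* features (each outcome's mean
  within the nominal 0/3/6/12-month visit bins), plus perturbed and
  fresh-restart variants, `n_starts` in total;
* **stepwise (ladder) fitting**: the model with $K$ groups also receives
  starts built by splitting each group of the best $K-1$-group solution
  in two; `run_grid()` chains fits in ascending $K$ so the ladder is fit
  once per polynomial order;
* short burn-in EM on every start (`short_iter`, default 30
  iterations), after which the two most promising runs are polished to
  convergence (relative tolerance `tol = 1e-6`, `max_iter = 500`).

Fits are deterministic given `seed` and `n_starts`.  Groups are
relabelled in decreasing share order; posterior ties at assignment go to
the lowest group index.

### Model selection

The specification grid crosses polynomial orders 1–3 with 1–10 groups.
A fit is *admissible* when every group holds at least 1% of the cohort,
every group's mean posterior probability among its assigned children
(AvePP) is at least 70%, and the relative entropy
$1 - H/(n\log K)$ is at least 0.5 (defined as 1 when $K = 1$; AvePP is
computed per group, the stricter of the two readings of the rule).
Among admissible fits the BIC nearest zero wins, with BIC on the
penalised log-likelihood scale $\ell - \tfrac{1}{2}\,
\#\mathrm{params}\,\log n$, using children as the independent units;
the observation-count version is reported alongside.  The number of free
parameters is $(K-1)$ mixing terms (times $1+q$ with $q$ membership
covariates), $K \cdot 4 \cdot (P+1)$ trajectory coefficients, and four
residual scales.  The final "clinical relevance" choice is a human step:
`run_grid(override=)` can force a different admissible entry but is
never applied automatically.

## Preprocessing rules

Raw visit tables carry integer day offsets from MTX initiation.  The
pipeline applies, in order:

1. **Pre-baseline window** — visits more than three months (operationalised
   as 92 days, calendar-safe) before MTX start are dropped; a visit
   within that window is re-set to day 0 only when no true day-0 visit
   exists, keeping the latest candidate and logging conflicts.
2. **Biologic censoring** — visits strictly after the day of biologic
   initiation are removed; same-day data are kept.
3. **Month grid** — days divide by 30.4375 (the mean Gregorian month) and
   round half-up; follow-up is capped at 14 months so that late
   "one-year" visits are retained.
4. **Eligibility** — children in apparent clinically inactive disease at
   baseline (no active joints, or JADAS10 ≤ 1.0, the published
   inactive-disease cut-off, either criterion sufficing) are excluded,
   as are children who never have all four JADAS components recorded at
   a single visit.  When the input carries the relevant columns,
   missing MTX dates and biologic initiation within 30 days of MTX
   start are excluded first.  Exclusions are tallied per rule,
   first-match attribution, and conserve the input count.
5. **Model frame** — outcomes are `log1p`-transformed; duplicate
   (child, month, outcome) observations collapse by the mean of the
   transformed values, because the model wants one observation per cell
   and the source of duplicates is administrative rather than clinical.

The JADAS10 used for the inactive-disease screen truncates active joints
at 10 and converts the two global scales from mm to cm; its ESR term is
$\min(\max((\mathrm{ESR}-20)/10,\,0),\,10)$.

## The synthetic cohort generator

Registry data behind the original analyses are access-controlled, so the
package ships a generator that emulates their structure and serves as
the test bed for the whole pipeline.  Each child draws a latent cluster
from six templates — fast improver, slow improver, improve–relapse,
persistent disease, persistent PGA, persistent PGE — with default mixing
proportions 11 : 16 : 7 : 44 : 8 : 13 (the published discovery shares;
they print as percentages summing to 99, so the defaults are the
proportional normalisation).  Template means are quadratics on the
log1p scale, committed as constants calibrated once so that month-0
medians sit near typical registry baselines (about 5 active joints,
40 mm globals, 16–29 mm/h ESR) and the six shapes reproduce the
qualitative patterns: parallel fast or slow improvement, improvement
then relapse, global persistence, and persistence of exactly one global
assessment while everything else resolves, with ESR declining modestly
and similarly everywhere.

Noise is added *on the log1p scale* and the draw — not the mean — is
clamped into the instrument bounds, then back-transformed and rounded to
native resolution (integer joints, mm, mm/h; CHAQ to 1/8 units).  The
generator and estimator therefore share one data-generating story (a
censored normal around a polynomial), which is what makes parameter
recovery a well-posed test.  Two deliberate departures from that story
remain, mimicking real data: native-scale rounding, and evaluation of
the mean at the jittered visit day rather than the rounded analysis
month.

Visits follow the nominal 0/90/180/365-day schedule with Gaussian
jitter (SD 10 days); non-baseline visits are skipped with probability
0.15; components go missing with per-outcome probabilities
(0.05/0.15/0.15/0.10) echoing the availability gradient of registry
baseline tables, either completely at random (default) or with
log-odds increasing in the current latent disease level
(`missing_mechanism = "mar"`).  Every child keeps at least one fully
recorded JADAS visit, the analysis inclusion rule.  Biologic switching
uses a per-cluster discrete monthly hazard calibrated to the published
14-month switching proportions where stated (38% persistent disease, 9%
fast improver, 8% persistent PGE) and interpolated for the others;
baseline covariates (age, sex, ethnicity, ILAR category) follow the
registry marginals, with mild cluster shifts (younger improvers, lower
white-ethnicity odds in persistent PGE) matching the direction of the
published associations.

What passing recovery tests does **not** show: robustness to informative
missingness beyond the MAR option, to unmodelled within-child
correlation (real children are not conditionally independent given a
polynomial), to visit schedules other than the UK registry pattern, or
to outcome distributions that are skewed on the log1p scale.

## Response scoring and characterization

ACR Pedi 30/90 at six months (window 4–8, nominal 6) and one year
(window 10–14, nominal 12) uses the six core outcome variables (PGA,
PGE, CHAQ, AJC, limited joint count, ESR): response requires ≥30% (or
≥90%) improvement in at least three variables with at most one variable
worsening by more than 30%.  Percent change from a zero baseline counts
as no change when the follow-up is also zero and as unbounded worsening
otherwise, preserving the criterion's intent.  Within a window the
complete assessment nearest the nominal month wins, ties to the earlier
month.  Scoring is complete-case: the multiply-imputed variant of the
original workflow is out of scope here, and cluster-level proportions
carry Wilson score intervals (chosen over Wald for small clusters).

Cluster characterization uses multinomial logistic regression
(`nnet::multinom`) against the largest (persistent-disease) reference
cluster, univariable and multivariable, with a collinearity screen
(|r| > 0.8 drops the member with less available data), Wald intervals,
and a separation flag for diverging coefficients; predictive ability is
summarised by one-vs-rest AUCs computed by the mid-rank Mann–Whitney
formula.  Time to biologic therapy is compared across clusters with
Kaplan–Meier curves and a K-sample log-rank test
(`survival::survfit`/`survdiff`, p from $\chi^2_{K-1}$).

## Numerical choices and degenerate inputs

* Censored-density tails use `pnorm(log.p = TRUE)`; inverse-Mills ratios
  are formed on the log scale, so group separation of many SDs does not
  overflow.
* Newton updates are step-halved (up to 8 times) and never accept a
  decrease of their objective; the $\sigma$ line search never accepts a
  decrease either, and $\sigma$ is floored at 0.02.
* A group whose posterior weight falls below $P + 2$ observations stops
  updating its coefficients and the fit is flagged (`empty_groups`)
  rather than erroring; all-starts non-convergence returns the best
  attempt with `converged = FALSE`.
* `pct_change(0, >0)` is `Inf` by decision, `0/0` is 0; negative inputs
  error.
* With bounds at infinity the censored density reduces exactly to the
  Gaussian, which the tests assert.

## Problem sizes used by the shipped checks

The packaged validation works at the discovery scale where the claim
demands it and smaller where it does not: cluster-number selection and
mixing-proportion recovery run on n = 657 synthetic children (the
discovery cohort size) with a quadratic K = 1..8 grid; the
parameter-recovery property runs three seeds at n = 400; pipeline
determinism runs at n = 150 with a compact grid.  The acceptance script
averages five independent n = 657 replicates.  These sizes were chosen
so each check exercises the regime it speaks for while the whole suite
stays comfortably reproducible on a laptop.

## Known limitations

* One polynomial order for all outcomes and groups per model; the
  original description leaves open whether orders could differ by
  outcome, and per-outcome orders are not implemented.
* Standard errors for trajectory coefficients are not produced (nothing
  downstream uses them); random-effects growth mixtures are explicitly
  out of scope.
* The exact entropy diagnostic used by different GBTM implementations
  varies; the relative-entropy form above is the one implemented.
* Complete-case ACR scoring understates evaluable children relative to
  the imputation-based original.
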