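---
title: "Embedding-sum proxy adjustment for unmeasured confounding in claims data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedding-sum proxy adjustment for unmeasured confounding in claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The method

Administrative inpatient claims record what was diagnosed, prescribed and
performed, but rarely how sick the patient was. Since first-day treatment
intensity responds to severity, the admission-day code set is an indirect
severity measurement. `claimvec` operationalises that observation in three
steps.

**Code embeddings.** Every admission's codes form one unordered document.
Skip-gram with negative sampling (SGNS) learns, for each code $c$, an
input vector $w_c \in \mathbb{R}^k$ by maximising

$$\log \sigma(u_{c'}^\top w_c) \;+\; \sum_{j=1}^{m}
\mathbb{E}_{n_j \sim P_n}\!\left[\log \sigma(-u_{n_j}^\top w_c)\right]$$

over observed (code, neighbouring-code) pairs, with $m = 5$ negatives from
the unigram$^{0.75}$ noise distribution $P_n$. Codes that co-occur across
admissions (a loop diuretic, a natriuretic-peptide assay, a heart-failure
diagnosis) end up close in the $k$-dimensional space. Only the input
matrix is released; the context matrix is discarded on save.

**Patient compression.** A patient's admission-day (day-1) codes
$C_i$ are summed, $x_i = \sum_{c \in C_i} w_c$, repeated codes counted
with multiplicity (`dedupe = FALSE`; an optional mean mode exists for
sensitivity analyses). This is linear — the vector of a pooled multiset is
the sum of the parts — and codes missing from the weight table contribute
nothing but are counted.

**Propensity adjustment.** The $k$ components of $x_i$ enter a
main-effects logistic propensity model as $k$ separate linear terms. Four
models are compared: Model 1 (none), Model 2 (measured confounders +
age/sex), Model 3 ($x_i$ + age/sex), Model 4 (union). Matching is greedy
1:1 nearest-neighbour without replacement, treated units in random seeded
order, restricted to a caliper of `caliper_fraction` (default 0.01, "1% of
the standardised deviation") times the SD of the propensity score. Effects
are risk differences (mean differences for length of stay) over matched
pairs, with percentile-bootstrap CIs resampling pairs.

## Design choices that were genuinely open

* **Caliper scale.** "1% of the standardised deviation" does not say
  whether the SD is taken on the probability or the logit scale. The
  default is the probability scale (`scale = "probability"`); the common
  logit-scale alternative is one argument away. With 200 balanced
  covariates the probability-scale caliper is conservative (tight), which
  costs matched pairs but never loosens balance.
* **Bootstrap unit.** Whether a matched analysis should resample pairs or
  patients is unstated in most applied work; pairs are resampled here
  (the matched design is the inference unit), patients (within arm) when
  no matching was done.
* **Tie-breaking.** Equidistant controls are resolved to the lowest
  patient id, making matching fully deterministic given the seed.
* **Window.** The context window is the whole document capped at 10
  tokens each side; admission code sets have no order, so token order is
  reshuffled every epoch and the window sees random neighbours. Training
  is single-threaded and bit-reproducible by design (own xorshift RNG,
  seeded from the config).
* **`epochs = 0`** is accepted and returns the random initialisation —
  useful as a baseline when checking that training improves the SGNS
  objective, which `sgns_objective()` evaluates exactly (the noise
  expectation is computed over the full noise distribution rather than
  sampled).
* **Separation.** Propensity fits flag (quasi-)separation — non-converged
  IRLS or fitted probabilities within $10^{-8}$ of the boundary — and
  refall back to a lightly ridge-penalised fit ($\lambda = 10^{-3}$,
  intercept unpenalised) so that degenerate replicates do not abort a
  simulation; the event is logged. Collinear columns are dropped
  (aliased to zero) as in ordinary GLM practice.
* **Degenerate inputs.** Zero pooled SD with equal means gives SMD 0,
  with unequal means `NA` plus a warning; all-identical risk scores
  collapse the quartile bins with a warning; patients with no matched
  day-1 code get the zero vector with a warning.

## The simulation study

Real severity-confounded cohorts cannot show that an estimator is
unbiased, because the truth is unknown. The simulation therefore
manufactures a known truth from the cohort itself:

1. treatment is re-randomised Bernoulli(0.5), so the true risk difference
   is exactly 0;
2. a prognostic model (composite of in-hospital death and ADL dependency
   on the measured confounders) is fit once, before the replicate loop,
   and its predicted risks are cut into quartiles Q1–Q4;
3. each replicate samples controls equally across quartiles (default
   10,000; 2,000 at the reduced scale used in the tests) and treated
   patients with quartile weights from a scenario grid interpolating
   linearly between $(0.4, 0.3, 0.2, 0.1)$ and $(0.1, 0.2, 0.3, 0.4)$ —
   the treated arm is made progressively healthier or sicker than the
   controls, injecting confounding of known sign and magnitude that is,
   by construction, a function of the Model-2 covariates (so Model 2 is
   the true adjustment model);
4. Models 1–4 are applied and the risk difference, its CI, coverage of 0,
   SMDs over the prognostic covariates, and the matched c-statistic of
   the reference (Model 4) specification are recorded. For Model 1 the
   "matched" cohort is the unmatched replicate cohort, so its c-statistic
   reads the injected imbalance directly.

A master seed spawns one child seed per (scenario, replicate); any
replicate is reproducible in isolation. Replicates with zero matched
pairs are excluded and counted.

The subsample bootstrap comparison (`bootstrap_compare()`) mirrors the
application setting: each of `n_boot` iterations draws a 20% subsample
without replacement (the fraction is configurable), runs every model end
to end for every outcome, and summarises each model's paired difference
from the Model-4 reference in estimates and CI widths.

## What the generator emulates — and what it does not

The synthetic cohort (`generator_spec()` / `generate_cohort()`) draws a
latent severity $s \sim N(0,1)$ per patient and makes everything else
conditionally independent given $s$:

* **Codes.** Cluster locations $m_1, \dots, m_{10}$ sit equally spaced on
  $[-2, 2]$; each of the (Poisson, mean 12, floor 2) day-1 codes picks a
  cluster with weight $\exp\{-(m_j - s)^2 / (2 \cdot 0.4^2)\}$ and a
  token uniformly inside it; stays of two days or more add further codes
  (mean 6) on days 2–7. Severity thus shows up in which codes co-occur,
  not in marginal token frequencies — the relational regime in which an
  embedding can act as a severity proxy while bag-of-code indicators stay
  high-dimensional.
* **Measured confounders.** Age, consciousness level (0–3), admission ADL
  score, systolic blood pressure, hypertension and log-BNP load on $s$
  with noise chosen so that jointly they recover $s$ with correlation
  about 0.9, giving the prognostic model an apparent AUC near 0.87 and a
  composite outcome rate near 30% — the regime reported for real
  heart-failure admission cohorts.
* **Treatment and outcomes.** Treatment logit $\gamma s$ (the confounding
  dial: $\gamma = 0$ is randomised; the study conditions use
  $\gamma = 1$); death, ADL dependency and readmission are Bernoulli with
  severity slopes 1.6, 2.4 and 0.6; length of stay is log-normal. A
  planted 2% of same-day discharges exercises the exclusion rules.

Passing tests on this generator show that the pipeline recovers a
*relational, single-factor* severity signal. Real claims differ in ways
the generator deliberately omits: multi-factor severity, direct
code-outcome effects, hospital-level clustering, realistic (Zipfian,
fee-schedule-structured) code frequencies, drug quantities, and temporal
structure beyond day 1. Results here bound what the method can do in the
clean case; they do not certify performance on any particular real
database.

## Problem sizes and numerical settings

The study-scale checks run at n = 20,000 patients, V = 500 tokens,
k = 200, with a 5-point scenario grid and 20 replicates per scenario and
per-replicate bootstrap CIs at 200 resamples; unit tests use a 2,500
patient cohort with k = 16. These sizes give Monte-Carlo error comfortably
inside the asserted tolerances (the median risk difference over 20
replicates of 2,000 + 2,000 patients has standard error about 0.004)
while keeping a full run in minutes on one CPU. Logistic fits use IRLS
(`glm.fit`) with the ridge fallback above; AUCs are exact rank statistics
with ties counted half; interpolated scenario weights are renormalised
only by construction (the endpoint vectors are returned exactly).

## Known limitations

* The embedding-sum proxy absorbs only confounding that is expressible
  through code co-occurrence; idiosyncratic noise in the measured
  confounders is invisible to Model 3 (visible in the simulation as
  Model 3's residual bias in extreme scenarios — smaller than Model 1's,
  larger than Model 2's).
* $k$ is fixed at 200 by convention; sensitivity to $k$ is unexplored
  here (it is a config parameter throughout).
* Greedy matching without replacement depends on the processing order;
  the seed pins it down but an optimal-matching variant is out of scope.
* The matched c-statistic refits a 200-plus-covariate model inside the
  matched cohort; with small matched cohorts its optimism pushes it
  slightly above 0.5 even under perfect balance.
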