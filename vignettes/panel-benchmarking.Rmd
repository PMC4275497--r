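---
title: "Benchmarking volunteer web-panel quota surveys: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking volunteer web-panel quota surveys: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelbench)
```

## The problem

Volunteer (opt-in) web panels are pools of self-selected people who take
online surveys for incentives. Surveys fielded on such panels fill quota
cells (e.g. age group within sex) rather than drawing a probability
sample, so nothing guarantees that panelists resemble the population on
variables *not* used as quotas — least of all on the sensitive behaviors
and opinions such surveys are often commissioned to measure. `panelbench`
packages the machinery needed to study this problem quantitatively: a
synthetic-population generator with *known, planted* selection
mechanisms, a quota-recruitment simulator, two procedures for choosing
additional ("modified") quota variables, poststratification weighting,
an odds-ratio benchmarking battery with bootstrap inference, and a
cluster-robust consistency test between two panels. Because the truth is
known by construction, every estimator in the chain can be validated by
simulation — something impossible with real panel data, where the
selection mechanism is unobservable.

## The synthetic population

Covariates live on an explicit joint cell grid. Each covariate is
declared with categories and marginal probabilities; unless a joint
table is supplied, covariates are independent and the grid probability
is the product of marginals. Working on a finite grid (a few thousand
cells for the default nine covariates) is a deliberate choice: every
marginal or conditional quantity downstream has an *exact enumeration
counterpart* (`enumerate_prevalence()`), which the test suite uses as an
oracle.

Outcomes are generated conditionally on covariates:

* **binary** outcomes from a logistic model,
  $\mathrm{logit}\,P(Y=1) = \beta_0 + \sum_v \beta_{v}[x_v]$, with
  per-category effects;
* **ordinal** (5-point) outcomes from a proportional-odds cumulative
  logit model, $\mathrm{logit}\,P(Y \le k) = \theta_k - \eta$, with
  strictly increasing thresholds. Category 3 of the default 5-point
  scale is the neutral point ("neither agree nor disagree"), which the
  satisficing measure `neutral_share()` relies on.

Each outcome carries two tags: administration mode in the reference
survey (CAPI, interviewer-administered, vs CASI, self-completed) and
question type (behavior vs opinion). The tags are labels for grouping
summaries only — no mode-specific measurement error is generated. A real
panel comparison cannot separate selection bias from mode effects; the
generator deliberately plants *only* selection bias, so that passing
tests demonstrate the estimation chain recovers selection bias when it
is the sole mechanism. They say nothing about disentangling mode
effects, which would require a measurement model we declined to guess.

Two logistic selection mechanisms complete the data-generating process:

* a **response model** giving each person a probability-survey response
  propensity; the probability sample is drawn by independent (Poisson)
  sampling with inclusion probabilities proportional to it. The
  stratified, clustered field designs of real surveys are not simulated:
  design effects are orthogonal to the comparison machinery under test,
  and no downstream estimator assumes clustering.
* a **joining model** giving each person a volunteer-panel joining
  propensity. Its linear predictor may include *outcome* terms
  (coefficient times the outcome value), which plants non-ignorable
  selection bias: panel membership then depends on what people would
  answer, not just who they are. This is the mechanism that quota
  controls and poststratification cannot, even in principle, fully
  correct — the package's central object of study.

Outcomes are independent given covariates by default. An optional shared
person-level logit offset (`latent_sd`) induces within-person
correlation across outcomes; it exists for the consistency-test module,
whose sandwich variance must be validated against genuinely clustered
responses. Its default is 0.

The default configuration (`default_population()`) emulates a British
adult population aged 18–44: sex by three age bands (the younger band at
26.7% within sex), partnership status, London vs rest, age finished
full-time education, presence of under-18s, household size, drinking
frequency, and a 5-point tolerance attitude; 35 outcomes shaped like the
reference battery (9 behavior-CAPI, 18 behavior-CASI binary items, 5 + 3
ordinal opinion items), including one rare self-reported behavior with
marginal prevalence near 3%. The default joining model over-represents
the well-educated, frequent drinkers and the most tolerant attitude
category, under-represents 18–24-year-olds, and loads positively
(log-odds 0.8) on the rare CASI behavior. These coefficients were fixed
once, as a realistic stylization of volunteer-panel skew of the
magnitude reported in comparison studies; they are not fitted to
anything and the package never treats them as tunable.

## Quota recruitment

`build_quota_spec()` converts benchmark distributions into integer cell
targets by largest-remainder (Hamilton) apportionment, so targets sum
exactly to the total within every grouping. Groupings follow the field
convention: a cross like age-within-sex is controlled on the crossed
cells, not the margins.

`run_quota_survey()` streams panel members in seeded uniform random
order; a member is accepted iff every cell they fall into is open.
Screening happens before outcomes are observed: a member whose cell is
full is turned away, mirroring how omnibus-routed respondents are
excluded from a main questionnaire when their quota has filled.

Real agencies "relax" quotas when a panel cannot fill them, but
published accounts rarely say how. The package's policy is deterministic
and auditable: when the stream exhausts, release the cap of the single
unfilled cell with the largest absolute shortfall, reshuffle the
remaining members (a fresh re-invitation wave), and continue. One
extension proved necessary: with crossed groupings it can happen that
every unfilled cell has been released yet every remaining member is
blocked by an *exactly filled* cell of another grouping (shortfall
zero). In that state the policy releases the unrelaxed cell that blocks
the most remaining members. Without this rule the total target is
unreachable whenever the binding constraint sits in a different grouping
from the shortfall; with it, recruitment terminates either at the target
or at panel exhaustion, and every release is logged with the shortfall
that triggered it.

## Choosing modified quota variables

Two selection procedures are implemented, matching the two ways a
modified-quota design can be built depending on what the agency knows
about its panelists.

**Stepwise membership selection** stacks the probability sample with a
web sample and runs forward stepwise logistic regression on the
membership indicator. Entry is by likelihood-ratio test at `alpha`
(default 0.05): the LRT was preferred to the Wald test for stability at
moderate sample sizes, and categorical candidates enter as whole dummy
blocks with the block LRT governing entry. There is no AIC/BIC stopping
and no backward step — the procedure is a pure p-threshold forward
process. Afterwards a collinearity rule prunes entered variables: any
pair with Cramér's V above 0.5 loses its less significant member. The
0.5 threshold operationalizes the narrative rule actually used in
practice (education retained over economic activity "as the more
statistically significant"); V above 0.5 between two categorical
sociodemographics is rare enough that the rule fires only on genuinely
redundant pairs. By default the model is *not* conditioned on the basic
quota variables; a `forced` argument adds them to the base model for
users who prefer that reading.

**Bivariate screening** ranks candidate variables by the number of key
outcomes with which they are associated at `alpha` both crudely and
after adjusting for the basic quota variables (age group, partnership
status, region by default), using block LRTs from logistic models
(proportional-odds for ordinal outcomes). Requiring crude *and* adjusted
significance excludes candidates whose association is fully mediated by
variables already controlled.

Perfect separation on a candidate is detected (non-convergence or
runaway coefficients) and the candidate skipped with a warning rather
than entering with a meaningless p-value.

## Weighting

`poststratify()` multiplies each weight by target/current cell share
over the full cross of the declared variables and rescales to mean 1;
agreement with the margins is exact (to 1e-12 in the tests) and the
operation is idempotent. An empty cell with a nonzero target is a hard
error — silent collapsing would change the estimand. `rake()` runs
iterative proportional fitting over several margins (converged when the
largest relative weight change in a cycle is below 1e-10), used for the
probability sample's second (region) dimension. Web surveys are not
weighted by region, matching field practice where agencies do not
collect comparable regional data. No weight trimming is applied by
default; none is described in the reference methodology.

## Odds-ratio benchmarking

Every comparison is expressed as an odds ratio, chosen over absolute
differences because it weighs departures on rare and common outcomes
comparably. Two routes:

* **Aggregate benchmarks** (census-style constants): the OR of the
  survey's weighted proportion against the fixed benchmark proportion.
  Only the survey contributes variance; the delta method on the logit
  gives $\mathrm{var}(\log\mathrm{OR}) = 1/(n_\mathrm{eff}\,p(1-p))$
  with the Kish effective size $n_\mathrm{eff} = (\sum w)^2/\sum w^2$.
  Treating the benchmark as known is justified when its source is one to
  two orders of magnitude larger than the survey; the Kish
  approximation is standard and conservative. A boundary proportion is
  an error unless a continuity flag adds 0.5 to each implied cell.
* **Microdata benchmarks** (the probability survey itself): both samples
  are stacked with a membership indicator and the OR is the indicator's
  exponentiated coefficient from weighted binary logistic regression —
  which, with no other covariates, equals the weighted 2×2 cross-product
  ratio exactly, an identity the tests assert to 1e-6 over a thousand
  random tables. Ordinal outcomes get a single OR from a weighted
  proportional-odds model; proportionality is not tested, matching the
  one-OR-per-outcome reporting convention. If the cumulative-logit fit
  fails, the outcome falls back to a binary split at its declared cut
  with a warning. Variances are robust (sandwich) throughout, computed
  as $V\,(\sum_i s_i s_i^\top)\,V$ with $V$ the model-based covariance
  and $s_i$ the estimating-function contributions — algebraically HC0,
  verified identical to the standard implementation on logistic fits.

Non-ordered categorical outcomes are reduced to a declared binary split
before comparison, avoiding multiple ORs per variable.

The summary battery works on the **absolute OR**,
$\max(\mathrm{OR}, 1/\mathrm{OR})$ (an OR of 0.5 counts as 2.0), a
direction-free distance from 1. Per group (all outcomes, and each
mode × question-type block), `summarize_or_results()` reports the
unweighted mean and maximum of absolute ORs and the count of outcomes
significantly different from the benchmark at the 5% level. No
multiple-testing adjustment is applied — the count of unadjusted 5%-level
differences is itself the reporting convention being replicated.

## Bootstrap inference and its boundary behavior

`bootstrap_avg_abs_or()` resamples participants with replacement
independently within each input survey (sizes preserved),
re-poststratifies every resample, recomputes every OR, and takes the
standard deviation of the replicate average absolute ORs as the standard
error (default B = 100 replicates). An OR that cannot be computed in a
replicate (outcome constant in the resample) is dropped from that
replicate's average; if more than 10% of replicates are affected the SE
is flagged unreliable rather than silently reported.
`compare_avg_abs_or()` then tests a difference between two surveys'
averages with a normal approximation,
$z = (\bar a - \bar b)/\sqrt{se_a^2 + se_b^2}$.

One boundary property deserves emphasis. The absolute OR is a *folded*
statistic with its fold at OR = 1. When the truth sits exactly on the
fold — a survey with no selection bias at all — the bootstrap SD of the
average absolute OR over-estimates the true sampling SD by roughly a
third (the package's calibration study measures this directly), so the
normal-approximation difference test is conservative there: its null
rejection rate is nearer 2% than 5%. This is a property of the method
itself, consistent with the reference methodology's own caveat that the
average absolute OR is bounded below by 1 and unlikely to be normally
distributed. Away from the fold — absolute ORs of 1.3–2, the regime
where the method is actually used to compare surveys — the bootstrap SE
agrees with the empirical sampling SD (within 25% in the test suite) and
the test behaves as intended. Users comparing two surveys that are both
nearly unbiased should read a non-significant difference as expected
behavior, not evidence of equivalence.

For "the two basic surveys combined", the primary reading pools the two
samples (each keeping its own weights, jointly rescaled to mean 1) and
computes ORs on the pool; bootstrap resampling stays within each
original survey. The alternative reading — averaging the two surveys'
per-outcome absolute ORs — is available behind `method = "average"`.

## Cross-panel consistency

`gee_consistency_test()` asks whether two panel surveys give the same
response distributions across a shared question battery, accounting for
the fact that each person answers every question. Responses are stacked
long (person × question) and a logit-link marginal model is fitted by
ordinary maximum likelihood — the independence-working-correlation
estimating equations — with a sandwich variance clustered on person.
The independence working correlation is a deliberate choice: the
sandwich makes inference valid under arbitrary within-person
correlation, and nothing is gained here by modeling it. Three outputs:
per-question survey effects (from the model with question-specific
survey terms), a common-effect test (survey main effect only), and a
joint Wald test that all survey terms are zero — the primary "are the
panels consistent" statistic. No small-sample cluster adjustment is
applied, so with singleton clusters the variance reduces exactly to the
heteroskedasticity-robust form — an identity the tests assert to 1e-8.
Weights are not used: the test compares the two panels' raw output.

In the bundled replica all panels share one joining model, so the
consistency test should *not* reject there — the replica validates its
calibration, not its power to detect between-agency differences, which
would require panel-specific joining models.

## The end-to-end replica

`run_scenario()` composes everything in study order: generate the
population; draw and rake the probability sample (age-within-sex and
region); recruit three panels; run two basic quota surveys
(age-within-sex, partnership-within-sex, region); select modified quota
variables by stepwise membership selection (first modified survey) and
by omnibus pre-screen plus stepwise selection (second); run the two
modified quota surveys; poststratify all five samples to the exact
population margins for age within sex; and emit the
participant-characteristics summary (against exact population
benchmarks, excluding variables used as quotas), the outcome summary
(against the probability sample's microdata), the bootstrap comparison
of combined-basic vs each modified survey, and the consistency test.
Every stage draws its seed from the master seed by a fixed offset
scheme, so stages can be rerun in isolation and the whole bundle is
byte-reproducible.

The default scenario sizes follow the study conditions: a population of
100,000, a probability sample of 8,969, quota surveys of 2,000 each, an
omnibus pre-screen of 9,176, and B = 100 bootstrap replicates. The test
suite exercises the same composition at reduced sizes chosen to keep the
full suite fast while leaving every statistical check adequately
powered: populations of 6,250–20,000, surveys of 500–5,000, batteries of
7–20 outcomes, and B of 4–150 depending on what the test measures; the
Monte Carlo calibration studies use 200–500 replications each. These are
the package's own choices of problem size for its validation studies.

## Numerical choices and degenerate inputs

* Largest-remainder rounding breaks remainder ties by cell order
  (stable, documented, and immaterial at survey scale).
* `poststratify()` errors on empty nonzero-target cells, naming the
  cell; `rake()` warns if IPF has not converged within `max_iter`.
* Boundary proportions in aggregate ORs error unless the continuity
  flag is set; microdata ORs error when an outcome is constant in
  either sample.
* The stepwise selector treats non-convergent or separated candidate
  fits as skips-with-warning, never as entries.
* Quota streaming is deterministic given the seed; relaxation events
  are totally ordered and logged with their triggers.
* Config digests (stamped into every export) are a polynomial hash of
  the configuration's JSON serialization — collision resistance
  adequate for provenance checking, not cryptography.

## Known limitations

* Mode (measurement) effects are tags, not mechanisms; the package
  cannot be used to study CAPI/CASI/Web reporting differences.
* Panel attrition, conditioning (panel-fatigue) effects, incentives and
  invitation timing are out of scope; the joining propensity is the
  only panel mechanism.
* The probability sample is Poisson-sampled; design effects from
  stratified clustered field designs are not represented.
* The difference test for average absolute ORs is conservative when
  both surveys are nearly unbiased (see the bootstrap section).
* Benchmarks are treated as known constants; benchmark sampling error,
  negligible for census-scale sources, is not propagated.
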