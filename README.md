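# panelbench

Tools for quantifying selection bias in **volunteer web-panel quota
surveys** by benchmarking them against probability samples — on synthetic
populations where the selection mechanism is known by construction.

Opt-in web panels recruit self-selected volunteers and fill quota cells
(age within sex, partnership within sex, region) instead of drawing a
probability sample. Quotas guarantee the sample matches the population
on the quota variables and on nothing else. `panelbench` implements the
full methodology used to measure what that costs:

* a **synthetic population generator**: covariates on an explicit joint
  cell grid; binary outcomes from logistic models and 5-point opinion
  items from proportional-odds models, tagged by administration mode
  (CAPI/CASI) and question type (behavior/opinion); a logistic response
  mechanism for the probability survey; and a logistic **panel-joining
  mechanism** that may load on outcomes themselves, planting
  non-ignorable selection bias that no quota scheme can remove;
* a **quota recruitment simulator** with basic and modified quota
  schemes, omnibus pre-screening, a deterministic, fully logged
  quota-relaxation policy, and fill-rate reporting;
* two **modified-quota variable selectors**: forward stepwise logistic
  regression on a sample-membership indicator (likelihood-ratio entry at
  p < 0.05, Cramér's-V collinearity pruning) and a bivariate association
  screen with adjustment for the basic quota variables;
* **poststratification** to external margins (exact on the cell cross)
  and raking over multiple margins;
* an **odds-ratio benchmarking battery**: ORs of each survey against
  aggregate benchmarks (delta method, Kish effective sample size) or
  against probability-sample microdata (weighted logistic /
  proportional-odds regression with robust sandwich variances); the
  **absolute OR** `max(OR, 1/OR)` and its per-group average, largest
  value and 5%-significance counts; **bootstrap** standard errors for
  average absolute ORs and normal-approximation difference tests;
* a **cross-panel consistency test**: a marginal logistic model on
  person × question stacked responses with an independence working
  correlation and a person-clustered sandwich variance, reporting
  per-question effects and a joint Wald test.

The central summary statistic: for a survey $s$ and benchmark prevalence
$p_b$ of an outcome,

$$\mathrm{OR} = \frac{p_s/(1-p_s)}{p_b/(1-p_b)}, \qquad
|\mathrm{OR}| = \max(\mathrm{OR},\, 1/\mathrm{OR}),$$

and a survey's overall bias is the unweighted mean of $|\mathrm{OR}|$
across the outcome battery (an OR of 0.5 counts as 2.0).

## Worked example

Generate a population, recruit a volunteer panel, run an age-sex/region
quota survey of 2,000, poststratify, and benchmark its outcomes against
a raked probability sample of 4,000:

```r
library(panelbench)

cfg    <- default_population(n = 50000, outcomes = default_outcomes(3, 6, 2, 1))
pop    <- generate_population(cfg, seed = 2026)
census <- true_benchmarks(pop, list(c("sex", "age_group"), "region"))

natsal <- rake(draw_probability_sample(pop, 4000, seed = 1),
               census, list(c("sex", "age_group"), "region"))

panel <- recruit_panel(pop, seed = 2)
spec  <- build_quota_spec(census, list(c("sex", "age_group"), "region"), 2000)
ws    <- run_quota_survey(panel, spec, seed = 3)
head(fill_rate(ws$spec), 3)
#>        grouping         cell achieved target percent relaxed
#> 1 sex:age_group female|18-24      263    263     100   FALSE
#> 2 sex:age_group female|25-34      368    368     100   FALSE
#> 3 sex:age_group female|35-44      365    365     100   FALSE

web   <- poststratify(ws$sample, census, c("sex", "age_group"))
metas <- lapply(names(cfg$outcomes), function(nm) {
  sp <- cfg$outcomes[[nm]]
  outcome_meta(nm, sp$scale, sp$mode, sp$qtype)
})
res <- survey_vs_benchmarks(web, natsal, metas)

res[res$outcome == "samesex_partner_5y",
    c("outcome", "or", "ci_low", "ci_high", "p_value")]
#>              outcome       or   ci_low  ci_high      p_value
#> 9 samesex_partner_5y 1.962277 1.507217 2.554728 5.509683e-07

summarize_or_results(res)
#>           group avg_abs_or largest_abs_or n_sig n_total
#> 1           All   1.144131       1.962277     3      12
#> 2 Behavior CAPI   1.098400       1.172001     1       3
#> 3 Behavior CASI   1.218422       1.962277     2       6
#> 4  Opinion CAPI   1.049104       1.058123     0       2
#> 5  Opinion CASI   1.025628       1.025628     0       1
```

Reading the output: the quota cells were met exactly (the default panel
is large enough for basic quotas). The web survey nonetheless
over-reports the rare self-reported behavior by a factor of almost two
on the odds scale (OR 1.96, p < 1e-6): the default joining model loads
on that outcome, and neither the quotas nor the age-sex weighting can
correct selection on an outcome. The summary table shows the signature
pattern: average absolute OR furthest from 1 in the group containing
the planted non-ignorable outcome, and 3 of 12 outcomes significantly
different from the probability-sample benchmark at the 5% level.

The full study replica — five surveys, two selection procedures,
bootstrap comparisons, consistency test, CSV/JSON report bundle — is one
call:

```r
b <- run_scenario(scenario_config(seed = 1), out_dir = "out/")
```

or from a shell: `Rscript inst/cli/panelbench.R run --out out/ --seed 1`.

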