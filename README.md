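# pillpref

Patients routinely accept or abandon a therapy for reasons that have nothing
to do with its pharmacology: the pill is too large to swallow comfortably,
the color looks alarming, the copayment stings. `pillpref` quantifies these
preferences in money terms. It implements the full analysis pipeline for a
discrete choice experiment (DCE) on solid oral drug forms — medication form
(round tablet / long tablet / capsule), size (5/10/15 mm), color (white /
yellow / blue / red) and weekly copayment (5–20 PLN, analyzed in EUR at
1 PLN = 0.25 EUR) — across two treatment scenarios, chronic (e.g.
antihypertensive) and short-term (e.g. antibiotic). It is aimed at health
economists and outcomes researchers who want to design such experiments,
simulate them for power and recovery studies, and estimate
willingness-to-pay (WTP) distributions from forced-choice data.

## The model

Respondent *i*'s utility for alternative *j* in task *t* is specified
directly in **WTP space**:

```
U_ijt = alpha_i * (X_ijt' beta_i - c_ijt) + eps_ijt,    eps_ijt ~ i.i.d. Gumbel(0, 1)
```

where `X_ijt` is the 7-vector of dummy-coded attribute contrasts
(long tablet, capsule, medium, large, yellow, blue, red; base levels =
round tablet, small, white), `c_ijt` is the cost in EUR, `beta_i` is the
individual's WTP vector in EUR (normally distributed across the
population, independent components), and `alpha_i > 0` is an individual
scale — the negative of the preference-space cost coefficient — which is
lognormal. Choice probabilities are multinomial logit conditional on
`(beta_i, alpha_i)`; the unconditional panel likelihood integrates the
product of each respondent's task probabilities over the mixing
distribution. That integral has no closed form, so the log-likelihood is
simulated:

```
logL = sum_i log { (1/D) sum_d prod_t P(chosen_it | beta_i^d, alpha_i^d) }
```

with `D` scrambled Sobol quasi-Monte-Carlo draws per respondent
(default 10,000; desk-scale fits use 500), held fixed across optimizer
iterations and maximized by BFGS with the analytic score. The conditional
(fixed-coefficient) logit is the zero-variance special case and provides
start values, via the exact preference-space/WTP-space translation
`alpha = -a`, `beta = b / alpha`.

## Worked example

Reference coefficient tables for both scenarios ship with the package and
drive the reporting functions:

```r
library(pillpref)

tab <- wtp_summary(reference_wtp_estimates())
preferred_configuration(tab, "chronic")
#> # A tibble: 1 x 5
#>   scenario form    size  color  total_wtp_eur
#>   <chr>    <chr>   <chr> <chr>          <dbl>
#> 1 chronic  capsule small yellow          1.63
eur_to_pln(1.63)
#> [1] 6.52
attribute_importance(tab, "short_term")
#> # A tibble: 3 x 4
#>   attribute importance best_level  worst_level
#>   <chr>          <dbl> <chr>       <chr>
#> 1 size            4.61 small       large
#> 2 form            2.41 long_tablet round_tablet
#> 3 color           1.73 yellow      red
```

The chronic-treatment sweet spot is a small yellow capsule, worth a
1.63 EUR (6.52 PLN) weekly premium over a small white round tablet; for
short-term treatment the package reports a small yellow long tablet at
3.81 EUR. Size dominates both scenarios — moving from a small to a large
pill costs more WTP than any form or color change.

Simulation and estimation compose the same way:

```r
sim <- simulate_study(n_respondents = 200, seed = 2026)  # 6,400 choice rows
fit <- fit_mxl(sim, scenario = "chronic",
               spec = mxl_spec(n_draws = 200, scramble_seed = 1))
fit
#> <mxl_fit> WTP-space mixed logit, scenario: chronic
#>   200 respondents, 200 draws (scrambled_sobol), logLik = -498.822, converged: TRUE
#> # A tibble: 16 x 6
#>    term        type  estimate std_error statistic p_value
#>  1 long_tablet mean    0.848      0.982    0.863  0.388
#>  2 capsule     mean    1.66       2.09     0.797  0.425
#>  3 medium      mean   -4.23       1.66    -2.55   0.0109
#>  4 large       mean   -7.18       3.23    -2.22   0.0264
#>  ...
```

At a realistic survey size (200 respondents) the point estimates carry
wide standard errors — the medium/large size penalties are recovered as
significant, the subtler form and color effects are not. Recovery
sharpens with sample size: at 2,000 respondents every population mean is
recovered within sampling error (see the tests and the vignette).
`tidy()`, `glance()` and `autoplot()` work on every fitted object, and
`run_pipeline()` executes simulate → fit → report end to end from a YAML
config.

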