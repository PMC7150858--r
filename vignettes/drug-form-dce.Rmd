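---
title: "Willingness to pay for solid oral drug forms: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Willingness to pay for solid oral drug forms: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pillpref)
```

## The experiment and its encoding

`pillpref` analyzes forced binary choices between hypothetical solid oral
medications described by four attributes: form, size, color and weekly
copayment. Tablet shape ("round" vs "long") is meaningless for capsules,
so shape and form are merged into a single three-level attribute — round
tablet, long tablet, capsule — which keeps the dummy coding identifiable
and matches the two contrasts (long tablet vs round, capsule vs round)
that a fitted model can actually report. With base levels round tablet /
small / white mapped to the all-zero code, every alternative is a 7-vector
of 0/1 contrasts plus a cost. Copayment levels are 5/10/15/20 PLN;
cost enters all models in EUR (`copay_pln * 0.25`) so every non-cost
coefficient is read directly as EUR of willingness to pay.

Each respondent answers `2 * n_tasks_per_scenario` tasks (default 8
chronic-treatment + 8 short-term-treatment), presented in rounds of one
task per scenario in random order. There is no opt-out: one of the two
alternatives must be chosen.

### Task-set construction

The package samples profile pairs uniformly (without replacement of pairs)
from the 144-profile full factorial. Two safeguards apply. Identical-profile
pairs are impossible by construction. And because every respondent faces
the *same* task battery, a battery whose stacked within-task attribute
differences are column-rank-deficient would make some coefficients
unidentifiable at any sample size — with only 8 difference vectors per
scenario for 8 coefficients this happens frequently under naive uniform
sampling. `build_task_set()` therefore resamples, deterministically under
its seed, until the difference matrix has full rank (per scenario when at
least 8 tasks per scenario are requested, pooled otherwise). This is a
minimal validity condition, not a D-efficiency optimization; optimal
designs remain out of scope.

## The WTP-space mixed logit

Utility is money-metric: `U_ijt = alpha_i (X_ijt' beta_i - c_ijt) + eps_ijt`
with standard Gumbel errors. Conditional on the individual parameters the
choice probability is multinomial logit; the Gumbel scale is fixed at 1,
the individual scale `alpha_i` carries all scale variation. Across the
population:

* `beta_i ~ Normal(wtp_mean, diag(wtp_sd^2))` — each of the 7 contrasts has
  a population mean and standard deviation in EUR. Components are drawn
  independently: nothing in the target design identifies the correlation
  structure strongly, and the diagonal model is the minimal reading of
  "individual parameters follow specific distributions". (The estimator
  likewise fits a diagonal model; correlated random parameters are a
  non-goal.)
* `alpha_i = exp(scale_mu + scale_sigma * xi)`, `xi ~ N(0,1)` — the
  negative of the preference-space cost coefficient is lognormal, which
  enforces `alpha_i > 0` (higher cost can never raise utility). Simulating
  *directly* in WTP space avoids the implausible-ratio pathologies that
  arise when a preference-space estimate is divided post hoc.

The panel log-likelihood integrates each respondent's product of task
probabilities over `(beta_i, alpha_i)`. `simulated_loglik()` replaces the
integral by an average over `D` draws; `fit_mxl()` maximizes it.

### Numerical choices

* **Draws.** Scrambled Sobol quasi-Monte-Carlo points, mapped through the
  standard-normal inverse CDF. The generator uses Joe–Kuo direction
  numbers (dimensions 1–13) at 30-bit precision — everything stays inside
  R's 32-bit integer arithmetic — with randomization by a per-dimension
  random digital shift (XOR of 30 random bits), which preserves the
  digital-net equidistribution, plus a half-cell offset keeping all
  coordinates strictly inside (0, 1). The unscrambled sequence is
  verified in the tests against frozen reference points, and the moments
  of the transformed deviates are checked directly. Respondent *i* takes
  the *i*-th contiguous block of the sequence, so blocks are distinct
  across respondents and identical across optimizer iterations — draws
  are generated once per fit, as maximum simulated likelihood requires
  for a smooth objective. A `pseudo_random` scheme with the same
  interface serves as an independent cross-check. The default is
  `D = 10000`; desk-scale fits and the bundled experiments use
  `D = 500`, which the quadrature checks show is already accurate to
  well under the sampling noise at these problem sizes.
* **Underflow.** The task product is accumulated in log space
  (`sum(log P)`), and both the draw average and every probability use
  max-shifted `exp`, so long panels and extreme utilities cannot
  underflow; `choice_prob(c(1000, 0))` is exact.
* **Optimization.** BFGS on the packed vector (7 means, one sd per random
  contrast, `scale_mu`, `scale_sigma`) with the analytic score —
  validated against finite differences at 1e-6 relative tolerance in the
  tests. Start values: conditional-logit estimates translated to WTP
  space for the means, `0.1 * |mean|` (floored at 0.05) for the sds,
  `scale_mu = 0`, `scale_sigma = 0.1`. Mixing sds and `scale_sigma` are
  estimated unconstrained (sign-irrelevant under a symmetric mixing
  density) and reported as absolute values, the usual convention.
* **Inference.** Standard errors come from the inverse of a
  central-difference Hessian of the analytic score at the optimum,
  symmetrized; a non-positive-definite Hessian yields flagged (`NA`)
  standard errors rather than a failure. The convergence flag is honest:
  optimizer success *and* a gradient sup-norm below
  `1e-3 * (1 + |logL|)`.
* **Ties.** Exact utility ties in simulation resolve to the lower
  alternative index; with continuous Gumbel noise they are measure-zero.

The conditional logit (`fit_conditional_logit()`) is fitted through the
conditional logistic likelihood (`survival::clogit`), which coincides with
the two-alternative MNL likelihood; an in-package closed form
(`cl_loglik()`) provides the zero-variance oracle that the simulated
likelihood must reproduce exactly when all sds are zero, and a 64-node
Gauss–Hermite quadrature in the test suite provides an independent oracle
for the one-random-coefficient integral.

## What the generator emulates — and what it does not

`simulate_study()` defaults emulate the target study's conditions: 200
respondents, 8 + 8 tasks, two alternatives, no opt-out; covariates with
51% female, median age 48.8 (age = 18 + lognormal, coefficient of
variation 0.3 — the spread is not pinned down by the emulated sample
description, and only the median materially matters downstream), 51.5%
on chronic medication. The default ground truths are the package's
reference WTP tables per scenario, drawn independently per scenario to
mirror separately estimated per-scenario models. The reference tables do
not determine the scale distribution's parameters, so the generator uses
the neutral, identifiable `lognormal(0, 0.5)` (median scale 1) as its
fixed default.

Under these conditions many simulated choices are nearly deterministic
(money-metric utility gaps of several EUR at a median scale of 1). That
is a property of the preference structure itself, and it has a practical
consequence: *fixed-coefficient* logits on small simulated samples can
sit near separation, which is why some small-sample smoke tests use a
reduced scale. The mixed logit, which attributes those extreme choices
to heterogeneity, is well behaved at the study scale.

Not emulated: behavioral artifacts (lexicographic responding,
straight-lining, anchoring and ordering effects), opt-out behavior,
correlated WTP components, and the exact task battery of the original
questionnaire (only its shape and randomization scheme). Passing recovery
tests therefore demonstrates that the estimator inverts its own
data-generating process at the stated sizes — not that real survey data
are free of these artifacts.

An optional 7 x 3 `covariate_effects` matrix shifts mean WTP by female,
age (per decade, centered at 48.8) and chronic-medication status, which is
exactly the structure the observed-heterogeneity companion model
(`fit_interaction_model()`, conditional logit with all 21
contrast x covariate interactions) estimates; it is fitted in preference
space, where interaction signs are directly interpretable because
`alpha_i > 0`.

## Reporting conventions

`wtp_summary()` stars coefficients at the 10/5/1% two-sided normal
levels. `preferred_configuration()` maximizes summed contrast means over
all 36 form x size x color combinations relative to the all-base profile
(small white round tablet), ties toward base; with the reference chronic
means this yields a small yellow capsule at 0.96 + 0.67 = 1.63 EUR
(6.52 PLN at the fixed 0.25 EUR/PLN convention). With the reference
short-term means it yields a small yellow long tablet at
2.41 + 1.40 = 3.81 EUR; note that a headline figure of 3.61 EUR
(14.44 PLN) circulates for this quantity, which cannot be reconstructed
from the short-term coefficient column — the package reports the
table-derived 3.81 and does not force the headline value. Premiums are
weekly, like the underlying coefficients; no rescaling to
treatment-course units is attempted.

`attribute_importance()` needs an explicit operationalization, since
"importance" has no canonical definition for dummy-coded attributes. The
package uses the within-attribute range of mean WTP (base at 0), a
level-balance-insensitive choice recorded in the output's `measure`
attribute. Under this measure the short-term ordering is size > form >
color, while the *chronic* ordering is size > color > form (color range
0.67 − (−1.11) = 1.78 vs form range 0.96) — a blanket "size, form,
color" summary holds only for the short-term scenario, which is why the
measure travels with the output instead of being hidden.

One further documented discrepancy: the emulated survey's methods
describe sixteen choice tasks (8 + 8) while its discussion mentions
twelve; the package follows the methods description and makes
`tasks_per_scenario` configurable.

## Problem sizes and runtime

The bundled experiments are sized for a desk machine: the recovery
experiment simulates 2,000 respondents x 8 chronic tasks and fits with
`D = 500` (about five minutes on one core; all seven population means are
recovered well within three standard errors, the capsule contrast
scattering around its generating 0.96 EUR with a standard error of
roughly 0.1-0.5 EUR depending on the drawn task battery). The test suite's other fits
use 40–200 respondents and `D <= 200`; the quadrature agreement check
runs `D = 10000` on a 5-respondent fixture. A full `D = 10000` fit at
study scale is a matter of hours, not minutes, and is left to the user.

## Known limitations

* Only two-alternative forced-choice panels are supported by the
  estimator (the probability kernel `choice_prob()` is general).
* Random parameters are uncorrelated in both generator defaults and
  estimator; no latent-class or generalized-MNL variants.
* Standard errors are inverse-Hessian (a robust sandwich option would
  require per-respondent score aggregation across draws, not currently
  exposed).
* The preferred-configuration search uses point estimates only; it does
  not propagate coefficient uncertainty to the configuration choice.
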