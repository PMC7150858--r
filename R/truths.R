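#' Population ground truth for the WTP-space choice simulator
#'
#' Describes the population distribution of individual preferences in
#' willingness-to-pay space: each respondent i has a 7-vector of attribute
#' WTPs `beta_i ~ Normal(wtp_mean, diag(wtp_sd^2))` (EUR, independent across
#' contrasts) and a positive price-scale parameter
#' `alpha_i = exp(scale_mu + scale_sigma * xi)`, `xi ~ N(0,1)` -- i.e. the
#' negative of the preference-space cost coefficient is lognormal.
#'
#' @param wtp_mean Numeric 7-vector of mean WTPs (EUR), named or in the order
#'   of [attribute_scheme()]`$contrasts`.
#' @param wtp_sd Numeric 7-vector of WTP standard deviations (EUR, >= 0).
#' @param scale_mu,scale_sigma Lognormal parameters of the scale `alpha_i`
#'   (`scale_sigma >= 0`). Defaults `0` and `0.5` put the median scale at 1.
#' @return An object of class `population_truth`.
#' @seealso [chronic_truth()], [short_term_truth()] for ready-made reference
#'   populations; [draw_respondents()], [simulate_study()].
#' @export
population_truth <- function(wtp_mean, wtp_sd,
                             scale_mu = 0, scale_sigma = 0.5) {
  contrasts <- attribute_scheme()$contrasts
  stopifnot(length(wtp_mean) == 7L, length(wtp_sd) == 7L,
            is.numeric(scale_mu), is.numeric(scale_sigma),
            length(scale_mu) == 1L, length(scale_sigma) == 1L)
  if (any(wtp_sd < 0)) abort("population_truth(): wtp_sd must be >= 0")
  if (scale_sigma < 0) abort("population_truth(): scale_sigma must be >= 0")
  if (!is.null(names(wtp_mean))) wtp_mean <- wtp_mean[contrasts]
  if (!is.null(names(wtp_sd)))   wtp_sd   <- wtp_sd[contrasts]
  structure(
    list(wtp_mean = setNames(as.numeric(wtp_mean), contrasts),
         wtp_sd = setNames(as.numeric(wtp_sd), contrasts),
         scale_mu = as.numeric(scale_mu),
         scale_sigma = as.numeric(scale_sigma)),
    class = "population_truth"
  )
}

#' @export
print.population_truth <- function(x, ...) {
  cat("<population_truth> (WTP space, EUR)\n")
  print(tibble::tibble(term = names(x$wtp_mean),
                       mean = x$wtp_mean, sd = x$wtp_sd))
  cat(sprintf("scale: lognormal(mu = %g, sigma = %g); E[alpha] = %.3f\n",
              x$scale_mu, x$scale_sigma,
              exp(x$scale_mu + x$scale_sigma^2 / 2)))
  invisible(x)
}

#' Reference WTP estimates for solid oral drug forms
#'
#' The package's reference coefficient table: estimated population means and
#' standard deviations of weekly willingness to pay (EUR) for drug-form
#' contrasts among Polish outpatients, for a chronic-treatment (e.g.
#' antihypertensive) and a short-term-treatment (e.g. antibiotic) scenario.
#' These values drive the worked examples and are the default ground truth of
#' the synthetic-respondent generator, so that simulated studies resemble a
#' realistic preference structure: small pills strongly preferred, yellow the
#' best-liked color, capsules/long tablets valued over round tablets.
#'
#' @param scenario `"chronic"`, `"short_term"`, or `"both"` (default).
#' @return A tibble with columns `scenario`, `term` (contrast name), `mean`,
#'   `mean_se`, `sd`, `sd_se` (all EUR per week).
#' @export
reference_wtp_estimates <- function(scenario = c("both", "chronic", "short_term")) {
  scenario <- match.arg(scenario)
  contrasts <- attribute_scheme()$contrasts
  out <- dplyr::bind_rows(
    tibble::tibble(
      scenario = "short_term", term = contrasts,
      mean    = c(2.41, 1.92, -2.58, -4.61, 1.40, 0.06, -0.33),
      mean_se = c(0.15, 0.17, 0.14, 0.09, 0.15, 0.09, 0.14),
      sd      = c(0.69, 0.59, 0.99, 2.11, 0.02, 0.06, 0.55),
      sd_se   = c(0.10, 0.09, 0.15, 0.11, 0.11, 0.07, 0.08)
    ),
    tibble::tibble(
      scenario = "chronic", term = contrasts,
      mean    = c(0.46, 0.96, -2.63, -5.29, 0.67, -0.65, -1.11),
      mean_se = c(0.05, 0.06, 0.06, 0.13, 0.10, 0.06, 0.07),
      sd      = c(0.03, 0.35, 0.73, 2.34, 0.13, 0.01, 0.38),
      sd_se   = c(0.04, 0.07, 0.09, 0.30, 0.09, 0.06, 0.06)
    )
  )
  if (scenario != "both") out <- out[out$scenario == scenario, ]
  out
}

#' @rdname chronic_truth
#' @export
short_term_truth <- function(scale_mu = 0, scale_sigma = 0.5) {
  ref <- reference_wtp_estimates("short_term")
  population_truth(setNames(ref$mean, ref$term), setNames(ref$sd, ref$term),
                   scale_mu = scale_mu, scale_sigma = scale_sigma)
}

#' Reference simulation truths per treatment scenario
#'
#' Ready-made [population_truth()] objects whose WTP means and standard
#' deviations are the reference estimates of [reference_wtp_estimates()].
#' The scale distribution defaults to lognormal(0, 0.5) -- median scale 1,
#' a neutral, identifiable choice, since the implied scale moments are not
#' part of the reference table.
#'
#' @inheritParams population_truth
#' @return A `population_truth`.
#' @export
chronic_truth <- function(scale_mu = 0, scale_sigma = 0.5) {
  ref <- reference_wtp_estimates("chronic")
  population_truth(setNames(ref$mean, ref$term), setNames(ref$sd, ref$term),
                   scale_mu = scale_mu, scale_sigma = scale_sigma)
}

#' Socio-demographic covariate model
#'
#' Generator for the respondent covariates used by the interaction model:
#' `female ~ Bernoulli(p_female)`, `chronic_meds ~ Bernoulli(p_chronic)`, and
#' age drawn as 18 + lognormal, matched to the given median and coefficient
#' of variation (adult outpatients, age >= 18). Defaults emulate the study
#' population the package targets: 51% female, median age 48.8 years, 51.5%
#' taking chronic medication.
#'
#' @param p_female,p_chronic Probabilities in `[0, 1]`.
#' @param age_median Median age in years (> 18).
#' @param age_cv Coefficient of variation of the (age - 18) lognormal.
#' @return An object of class `covariate_model`.
#' @export
covariate_model <- function(p_female = 0.51, age_median = 48.8,
                            age_cv = 0.3, p_chronic = 0.515) {
  stopifnot(p_female >= 0, p_female <= 1, p_chronic >= 0, p_chronic <= 1,
            age_median > 18, age_cv > 0)
  structure(
    list(p_female = p_female, age_median = age_median,
         age_cv = age_cv, p_chronic = p_chronic),
    class = "covariate_model"
  )
}

#' Draw respondent covariates
#' @param model A [covariate_model()].
#' @param n Number of respondents.
#' @param seed Integer seed.
#' @return Tibble with `respondent_id`, `female`, `age`, `chronic_meds`.
#' @export
draw_covariates <- function(model = covariate_model(), n, seed = 1L) {
  stopifnot(inherits(model, "covariate_model"), n >= 1L)
  sdlog <- sqrt(log(1 + model$age_cv^2))
  meanlog <- log(model$age_median - 18)
  withr::with_seed(seed, {
    tibble::tibble(
      respondent_id = seq_len(n),
      female        = rbinom(n, 1L, model$p_female),
      age           = 18 + stats::rlnorm(n, meanlog, sdlog),
      chronic_meds  = rbinom(n, 1L, model$p_chronic)
    )
  })
}
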