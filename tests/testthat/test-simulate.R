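test_that("degenerate truth produces identical respondents", {
  truth <- population_truth(chronic_truth()$wtp_mean, rep(0, 7),
                            scale_mu = 0.3, scale_sigma = 0)
  resp <- draw_respondents(truth, n = 4, seed = 1)
  B <- as.matrix(resp[, paste0("beta_", attribute_scheme()$contrasts)])
  expect_true(all(apply(B, 2, function(x) diff(range(x)) == 0)))
  expect_equal(unname(B[1, ]), unname(truth$wtp_mean))
  expect_equal(resp$alpha, rep(exp(0.3), 4))
})

test_that("respondent draws reproduce the population moments", {
  truth <- chronic_truth()
  resp <- draw_respondents(truth, n = 1e5, seed = 42)
  B <- as.matrix(resp[, paste0("beta_", attribute_scheme()$contrasts)])
  mc_se <- truth$wtp_sd / sqrt(1e5)
  expect_true(all(abs(colMeans(B) - truth$wtp_mean) < 5 * mc_se + 1e-12))
  expect_true(all(abs(apply(B, 2, sd) - truth$wtp_sd) < 0.02))
  # lognormal moment formula for the scale
  expect_equal(mean(resp$alpha), exp(truth$scale_mu + truth$scale_sigma^2 / 2),
               tolerance = 0.01)
  expect_true(all(resp$alpha > 0))
})

test_that("invalid truths are rejected", {
  expect_error(population_truth(rep(0, 7), c(-1, rep(0, 6))), "wtp_sd")
  expect_error(population_truth(rep(0, 7), rep(0, 7), scale_sigma = -0.1),
               "scale_sigma")
})

test_that("simulated choice frequencies match the binary logit closed form", {
  # two profiles identical except copayment 5 vs 20 PLN; beta = 0, alpha = 1
  design <- tibble::tibble(
    scenario = "chronic", task = 1L, alt = 1:2,
    form = "round_tablet", size = "small", color = "white",
    copay_pln = c(5, 20)
  )
  truth <- population_truth(rep(0, 7), rep(0, 7), 0, 0)
  n <- 1e5
  resp <- draw_respondents(truth, n = n, seed = 1)
  sim <- simulate_choices(design, resp, seed = 2)
  freq <- mean(sim$chosen[sim$alt == 1L])
  p <- 1 / (1 + exp(-3.75))  # utility gap alpha * (5 - 1.25) EUR
  expect_equal(freq, p, tolerance = 4 * sqrt(p * (1 - p) / n) / p)
  # symmetric case: equal-cost identical-value alternatives split 50/50
  design$copay_pln <- c(5, 10)
  truth_flat <- population_truth(rep(0, 7), rep(0, 7), -20, 0) # alpha ~ 0
  resp_flat <- draw_respondents(truth_flat, n = n, seed = 3)
  sim_flat <- simulate_choices(design, resp_flat, seed = 4)
  expect_equal(mean(sim_flat$chosen[sim_flat$alt == 1L]), 0.5,
               tolerance = 0.02)
})

test_that("simulated studies have the configured shape and valid structure", {
  sim <- simulate_study(seed = 1)   # defaults: 200 respondents, 8 + 8 tasks
  expect_identical(nrow(sim), 200L * 16L * 2L)
  expect_silent(validate_choice_data(sim))
  expect_identical(length(unique(sim$respondent_id)), 200L)
  # forced choice: one chosen per task
  chosen_per_task <- tapply(sim$chosen,
                            paste(sim$respondent_id, sim$scenario, sim$task),
                            sum)
  expect_true(all(chosen_per_task == 1L))
  # covariates emulate the outpatient sample
  cov <- dplyr::distinct(sim, respondent_id, female, age, chronic_meds)
  expect_true(abs(mean(cov$female) - 0.51) < 0.11)   # binomial error, n = 200
  expect_true(abs(mean(cov$chronic_meds) - 0.515) < 0.11)
  expect_true(all(cov$age >= 18))
  expect_true(abs(median(cov$age) - 48.8) < 4)
})

test_that("study simulation is deterministic: same seed, same CSV bytes", {
  a <- withr::local_tempfile(fileext = ".csv")
  b <- withr::local_tempfile(fileext = ".csv")
  write_choice_data(simulate_study(n_respondents = 10, seed = 9), a)
  write_choice_data(simulate_study(n_respondents = 10, seed = 9), b)
  expect_identical(readLines(a), readLines(b))
  c2 <- withr::local_tempfile(fileext = ".csv")
  write_choice_data(simulate_study(n_respondents = 10, seed = 10), c2)
  expect_false(identical(readLines(a), readLines(c2)))
})

test_that("covariate effects shift mean WTP for the targeted groups", {
  E <- matrix(0, 7, 3)
  rownames(E) <- attribute_scheme()$contrasts
  E["large", 1] <- -1.5   # women dislike large pills more
  covs <- draw_covariates(covariate_model(), n = 4000, seed = 2)
  truth <- population_truth(chronic_truth()$wtp_mean, rep(0, 7), 0, 0)
  resp <- draw_respondents(truth, seed = 3, covariates = covs,
                           covariate_effects = E)
  gap <- mean(resp$beta_large[covs$female == 1]) -
    mean(resp$beta_large[covs$female == 0])
  expect_equal(gap, -1.5, tolerance = 1e-9)  # zero sd: exact shift
})
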