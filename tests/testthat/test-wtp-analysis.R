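test_that("significance stars follow the two-sided normal thresholds", {
  expect_identical(significance_stars(0.96, 0.06), "***")
  expect_identical(significance_stars(0.06, 0.09), "")
  expect_identical(significance_stars(0, 1), "")
  expect_identical(significance_stars(-0.33, 0.14), "**")
  expect_identical(significance_stars(1.7, 1), "*")
  expect_identical(significance_stars(1, NA_real_), "")
  # monotone in |estimate|/se
  z <- seq(0, 4, by = 0.1)
  stars <- nchar(significance_stars(z, 1))
  expect_true(all(diff(stars) >= 0))
})

test_that("the summary table is shaped and ordered like the result table", {
  tab <- wtp_summary(reference_wtp_estimates())
  expect_s3_class(tab, "wtp_summary")
  expect_identical(unique(tab$scenario), c("chronic", "short_term"))
  expect_identical(tab$term[tab$scenario == "chronic"],
                   attribute_scheme()$contrasts)
  chronic_capsule <- tab[tab$scenario == "chronic" & tab$term == "capsule", ]
  expect_identical(chronic_capsule$mean_stars, "***")
  blue_short <- tab[tab$scenario == "short_term" & tab$term == "blue", ]
  expect_identical(blue_short$mean_stars, "")
})

test_that("preferred configurations match brute force on any means", {
  sch <- attribute_scheme()
  brute_force <- function(means) {
    best <- NULL; best_total <- -Inf
    for (f in sch$attributes$form) for (s in sch$attributes$size)
      for (co in sch$attributes$color) {
        tot <- sum(means[intersect(c(f, s, co), names(means))])
        if (tot > best_total + 1e-12) {
          best_total <- tot; best <- c(f, s, co)
        }
      }
    list(levels = best, total = best_total)
  }
  tab <- wtp_summary(reference_wtp_estimates())
  for (scen in c("chronic", "short_term")) {
    pc <- preferred_configuration(tab, scen)
    means <- setNames(tab$mean[tab$scenario == scen & tab$attribute != "scale"],
                      tab$term[tab$scenario == scen & tab$attribute != "scale"])
    bf <- brute_force(means)
    expect_identical(c(pc$form, pc$size, pc$color), bf$levels)
    expect_equal(pc$total_wtp_eur, bf$total)
  }
  # randomized property check against the same oracle
  withr::with_seed(7, {
    for (i in 1:10) {
      means <- setNames(rnorm(7), sch$contrasts)
      fake <- tibble::tibble(scenario = "chronic", term = names(means),
                             attribute = "x", mean = means)
      pc <- preferred_configuration(fake, "chronic")
      expect_equal(pc$total_wtp_eur, brute_force(means)$total)
    }
  })
  # all-zero means: ties break to the base profile with total 0
  zero <- tibble::tibble(scenario = "chronic",
                         term = sch$contrasts, attribute = "x", mean = 0)
  pc0 <- preferred_configuration(zero, "chronic")
  expect_identical(c(pc0$form, pc0$size, pc0$color),
                   c("round_tablet", "small", "white"))
  expect_identical(pc0$total_wtp_eur, 0)
})

test_that("currency conversion is exact to the cent and invertible", {
  expect_identical(eur_to_pln(1.63), 6.52)
  expect_identical(eur_to_pln(0), 0)
  expect_identical(eur_to_pln(3.61), 14.44)
  expect_identical(pln_to_eur(6.52), 1.63)
  withr::with_seed(3, {
    x <- round(runif(50, 0, 20), 2)
    expect_equal(pln_to_eur(eur_to_pln(x)), x, tolerance = 0.005)
  })
})

test_that("attribute importance ranks by within-attribute WTP range", {
  tab <- wtp_summary(reference_wtp_estimates())
  imp_s <- attribute_importance(tab, "short_term")
  expect_identical(imp_s$attribute, c("size", "form", "color"))
  expect_equal(imp_s$importance, c(4.61, 2.41, 1.73))
  imp_c <- attribute_importance(tab, "chronic")
  expect_identical(imp_c$attribute[1], "size")
  expect_equal(imp_c$importance[1], 5.29)
  expect_match(attr(imp_c, "measure"), "range")
})

test_that("interaction fits recover covariate-driven preference shifts", {
  E <- matrix(0, 7, 3)
  rownames(E) <- attribute_scheme()$contrasts
  E["large", 1] <- -2.0   # female x large
  # moderate scale keeps choices stochastic enough for an interior MLE
  sim <- simulate_study(
    n_respondents = 1000,
    truth_chronic = population_truth(chronic_truth()$wtp_mean, rep(0, 7),
                                     log(0.5), 0),
    truth_short = population_truth(short_term_truth()$wtp_mean, rep(0, 7),
                                   log(0.5), 0),
    covariate_effects = E, seed = 31)
  fit <- fit_interaction_model(sim, scenario = "chronic")
  co <- tidy(fit)
  fl <- co[co$term == "large:female", ]
  expect_lt(fl$estimate, 0)
  expect_lt(fl$estimate + 1.96 * fl$std_error, 0)  # significantly negative
  # a null interaction stays within its confidence band
  null_term <- co[co$term == "yellow:chronic_meds", ]
  expect_lt(abs(null_term$statistic), 4)
})

test_that("summary tables plot without error", {
  p <- ggplot2::autoplot(wtp_summary(reference_wtp_estimates()))
  expect_s3_class(p, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p))
})

test_that("degenerate covariates are rejected", {
  sim <- simulate_study(n_respondents = 10, seed = 3)
  sim$female <- 1L
  expect_error(fit_interaction_model(sim, scenario = "chronic"), "constant")
  sim2 <- simulate_study(n_respondents = 10, covariates = NULL, seed = 3)
  expect_error(fit_interaction_model(sim2), "missing covariate")
})
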