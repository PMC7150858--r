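test_that("choice probabilities are exact, normalized and overflow-safe", {
  expect_equal(choice_prob(c(0, 0)), c(0.5, 0.5))
  # alpha = 1, beta = 0, costs 1.25 vs 5.00 EUR
  expect_equal(round(choice_prob(c(-1.25, -5.00)), 4), c(0.9770, 0.0230))
  p <- choice_prob(c(1000, 0))
  expect_true(all(is.finite(p)))
  expect_equal(p[1], 1, tolerance = 1e-12)
  withr::with_seed(1, {
    for (i in 1:20) {
      v <- rnorm(sample(2:5, 1), sd = 10)
      p <- choice_prob(v)
      expect_true(all(p > 0))
      expect_lt(abs(sum(p) - 1), 1e-12)
      expect_equal(choice_prob(v + 123.4), p, tolerance = 1e-12)
    }
  })
})

test_that("raising an alternative's cost strictly lowers its probability", {
  v <- c(-1, -2)
  for (alpha in c(0.5, 1, 2)) {
    p0 <- choice_prob(alpha * v)[1]
    p1 <- choice_prob(alpha * (v - c(0.5, 0)))[1]  # alt 1 costs 0.5 EUR more
    expect_lt(p1, p0)
  }
})

test_that("zero mixing variance collapses the simulated likelihood to the MNL", {
  data <- load_fixture_data()
  beta <- chronic_truth()$wtp_mean
  zero <- setNames(rep(0, 7), names(beta))
  for (D in c(1L, 13L)) {
    ll_sim <- simulated_loglik(data, beta, zero, log(1.3), 0,
                               draws = mxl_spec(n_draws = D))
    expect_lt(abs(ll_sim - cl_loglik(data, beta, 1.3)), 1e-10)
  }
})

test_that("one respondent, one task, one draw gives a single log probability", {
  data <- tibble::tibble(
    respondent_id = 1L, scenario = "chronic", task = 1L, alt = 1:2,
    form = c("capsule", "round_tablet"), size = "small", color = "white",
    copay_pln = c(20, 5), chosen = c(1L, 0L)
  )
  beta <- setNames(c(0, 2, 0, 0, 0, 0, 0), attribute_scheme()$contrasts)
  zero <- setNames(rep(0, 7), names(beta))
  ll <- simulated_loglik(data, beta, zero, 0, 0,
                         draws = mxl_spec(n_draws = 1))
  # dv = alpha * (capsule WTP - cost gap) = 1 * (2 - 3.75)
  expect_equal(ll, plogis(2 - 3.75, log.p = TRUE), tolerance = 1e-12)
})

test_that("preference space and WTP space are behaviorally equivalent", {
  w <- preference_to_wtp(c(2, -1), -2)
  expect_equal(w$alpha, 2)
  expect_equal(w$beta, c(1, -0.5))
  back <- wtp_to_preference(w$beta, w$alpha)
  expect_identical(back$b, c(2, -1))
  expect_identical(back$a, -2)
  expect_error(preference_to_wtp(c(1, 2), 0.3), "negative")

  # identical likelihoods under both parameterizations on a fixture
  data <- load_fixture_data()
  sch <- attribute_scheme()
  b <- setNames(c(0.5, 1.2, -2.0, -4.5, 0.6, -0.4, -1.0), sch$contrasts)
  a <- -1.7
  enc <- encode_profiles(data, sch)
  v_pref <- drop(as.matrix(enc[, sch$contrasts]) %*% b) + enc$cost_eur * a
  key <- paste(enc$respondent_id, enc$scenario, enc$task)
  ll_pref <- sum(vapply(unique(key), function(k) {
    i <- which(key == k)
    log(choice_prob(v_pref[i])[enc$chosen[i] == 1L])
  }, numeric(1)))
  w <- preference_to_wtp(b, a)
  expect_lt(abs(ll_pref - cl_loglik(data, w$beta, w$alpha)), 1e-10)
})

test_that("the conditional logit matches an independent likelihood maximization", {
  # fixed-coefficient world with a moderate scale, so the MLE is interior
  truth <- population_truth(chronic_truth()$wtp_mean, rep(0, 7),
                            scale_mu = log(0.5), scale_sigma = 0)
  data <- simulate_study(n_respondents = 200, truth_chronic = truth,
                         truth_short = truth, covariates = NULL, seed = 61)
  fit <- fit_conditional_logit(data, scenario = "chronic")
  sch <- attribute_scheme()
  enc <- encode_profiles(data[data$scenario == "chronic", ], sch)
  X <- cbind(as.matrix(enc[, sch$contrasts]), enc$cost_eur)
  key <- paste(enc$respondent_id, enc$task)
  i1 <- which(!duplicated(key)); i2 <- i1 + 1L
  dX <- X[i1, ] - X[i2, ]
  y <- enc$chosen[i1]
  # independent oracle: direct maximization of the paired-logit likelihood
  nll <- function(th) {
    dv <- drop(dX %*% th)
    -sum(plogis(ifelse(y == 1L, dv, -dv), log.p = TRUE))
  }
  opt <- optim(rep(0, 8), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  expect_equal(-opt$value, fit$loglik, tolerance = 1e-6)
  expect_equal(unname(opt$par), fit$coefficients$estimate, tolerance = 1e-3)
})

test_that("a never-varying attribute makes the conditional logit reject", {
  design <- build_task_set(seed = 3)
  design$color <- "white"
  # collapsing color can leave some task pairs identical; drop those tasks
  key <- paste(design$form, design$size, design$color, design$copay_pln)
  grp <- paste(design$scenario, design$task)
  same <- tapply(key, grp, function(k) k[1] == k[2])
  design <- design[!(grp %in% names(same)[same]), ]
  resp <- draw_respondents(chronic_truth(), n = 30, seed = 1)
  sim <- simulate_choices(design[design$scenario == "chronic", ], resp, seed = 2)
  expect_error(fit_conditional_logit(sim), "singular")
})

test_that("simulated likelihood at the CL solution reproduces the CL loglik", {
  data <- small_study()
  fit <- fit_conditional_logit(data, scenario = "short_term")
  zero <- setNames(rep(0, 7), attribute_scheme()$contrasts)
  ll <- simulated_loglik(data, fit$wtp$beta, zero, log(fit$wtp$alpha), 0,
                         draws = mxl_spec(n_draws = 5),
                         scenario = "short_term")
  expect_lt(abs(ll - fit$loglik), 1e-8)
})

test_that("Sobol, pseudo-random and Gauss-Hermite integration agree", {
  data <- load_fixture_data()
  truth <- load_fixture_truth()
  beta <- truth$wtp_mean
  sdv <- setNames(rep(0, 7), names(beta)); sdv["large"] <- 2.0
  alpha_mu <- 0.2
  ll_gh <- gh_panel_loglik(data, beta, 2.0, "large", exp(alpha_mu))
  ll_sobol <- simulated_loglik(
    data, beta, sdv, alpha_mu, 0,
    draws = mxl_spec(n_draws = 10000L, random_attrs = "large",
                     scramble_seed = 2))
  ll_mc <- simulated_loglik(
    data, beta, sdv, alpha_mu, 0,
    draws = mxl_spec(n_draws = 1e6, draw_scheme = "pseudo_random",
                     random_attrs = "large", scramble_seed = 2))
  expect_lt(abs(ll_sobol - ll_gh), 1e-3)
  expect_lt(abs(ll_mc - ll_gh), 1e-3)
})

test_that("the analytic score matches finite differences", {
  data <- load_fixture_data()
  prep <- pillpref:::mxl_prep(data, attribute_scheme(), NULL)
  for (ra in list(attribute_scheme()$contrasts, c("capsule", "large"))) {
    spec <- mxl_spec(n_draws = 16, random_attrs = ra, scramble_seed = 4)
    draws <- make_draws(spec, length(prep$ids))
    th <- c(chronic_truth()$wtp_mean, rep(0.5, length(ra)), 0.1, 0.4)
    g <- pillpref:::msl_objective(th, prep, draws, ra)$gradient
    fd <- vapply(seq_along(th), function(j) {
      h <- 1e-6 * (1 + abs(th[j]))
      up <- th; up[j] <- up[j] + h
      dn <- th; dn[j] <- dn[j] - h
      (pillpref:::msl_objective(up, prep, draws, ra, FALSE)$loglik -
         pillpref:::msl_objective(dn, prep, draws, ra, FALSE)$loglik) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - fd) / (1 + abs(fd))), 1e-6)
  }
})

test_that("the simulated likelihood is invariant to respondent order", {
  data <- small_study()
  truth <- chronic_truth()
  spec <- mxl_spec(n_draws = 50, scramble_seed = 8)
  ll <- simulated_loglik(data, truth$wtp_mean, truth$wtp_sd, 0, 0.5,
                         draws = spec, scenario = "chronic")
  shuffled <- withr::with_seed(99, data[sample.int(nrow(data)), ])
  ll2 <- simulated_loglik(shuffled, truth$wtp_mean, truth$wtp_sd, 0, 0.5,
                          draws = spec, scenario = "chronic")
  expect_lt(abs(ll - ll2), 1e-9)
})

test_that("fitting zero-heterogeneity data recovers means with near-zero SDs", {
  truth0 <- population_truth(chronic_truth()$wtp_mean, rep(0, 7),
                             scale_mu = log(0.4), scale_sigma = 0)
  sim <- simulate_study(n_respondents = 150, truth_chronic = truth0,
                        truth_short = truth0, seed = 21)
  fit <- fit_mxl(sim, scenario = "chronic",
                 spec = mxl_spec(n_draws = 100, scramble_seed = 5))
  expect_s3_class(fit, "mxl_fit")
  expect_gte(fit$loglik, fit$loglik_start)   # ascent from start values
  co <- tidy(fit)
  means <- co[co$type == "mean", ]
  z <- abs(means$estimate - chronic_truth()$wtp_mean) / means$std_error
  expect_true(all(z[is.finite(z)] < 4))
  sds <- co[co$type == "sd", ]
  # true SDs are 0: estimates should be small relative to the mean scale
  expect_lt(median(sds$estimate), 0.5)
  g <- glance(fit)
  expect_identical(g$n_respondents, 150L)
  expect_identical(g$n_draws, 100L)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p))
})
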