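#' Conditional logit baseline for forced-choice data
#'
#' Fits the fixed-coefficient multinomial logit in preference space --
#' utility `X b + c a` with one coefficient vector shared by all
#' respondents -- via the conditional logistic likelihood (each
#' respondent x scenario x task is a stratum with one chosen alternative),
#' which for two-alternative forced choices is exactly the MNL likelihood.
#' This is the zero-heterogeneity special case of the mixed logit; its WTP
#' translation (`b / -a`, see [preference_to_wtp()]) supplies the default
#' start values of [fit_mxl()].
#'
#' @param data A choice dataset tibble.
#' @param scenario Optional scenario filter (`"chronic"` / `"short_term"`).
#' @param scheme An [attribute_scheme()].
#' @return An object of class `cl_fit` with a coefficient table (`tidy()`),
#'   fit statistics (`glance()`), the log-likelihood, and the WTP-space
#'   translation in `$wtp` when the cost coefficient is negative.
#' @export
fit_conditional_logit <- function(data, scenario = NULL,
                                  scheme = attribute_scheme()) {
  if (!is.null(scenario)) {
    scenario <- match.arg(scenario, c("chronic", "short_term"))
    data <- data[data$scenario == scenario, ]
  }
  data <- validate_choice_data(data, scheme)
  enc <- encode_profiles(data, scheme)
  enc$.stratum <- paste(enc$respondent_id, enc$scenario, enc$task, sep = ".")
  terms <- c(scheme$contrasts, "cost_eur")
  X <- as.matrix(enc[, terms])
  if (qr(scale(X, scale = FALSE))$rank < ncol(X)) {
    abort("fit_conditional_logit(): design matrix is singular (an attribute never varies or contrasts are collinear)")
  }
  f <- stats::as.formula(paste(
    "chosen ~", paste(terms, collapse = " + "), "+ strata(.stratum)"))
  # clogit resolves coxph()/strata() in the formula environment
  environment(f) <- asNamespace("survival")
  fit <- survival::clogit(f, data = enc, iter.max = 100)
  if (anyNA(stats::coef(fit))) {
    abort("fit_conditional_logit(): some coefficients inestimable (singular design or separation)")
  }
  new_cl_fit(fit, scenario = scenario %||% "all",
             n_respondents = length(unique(enc$respondent_id)))
}

new_cl_fit <- function(fit, scenario, n_respondents) {
  s <- summary(fit)$coefficients
  coefs <- tibble::tibble(
    term = rownames(s),
    estimate = unname(s[, "coef"]),
    std_error = unname(s[, "se(coef)"]),
    statistic = unname(s[, "z"]),
    p_value = unname(s[, "Pr(>|z|)"])
  )
  a <- coefs$estimate[coefs$term == "cost_eur"]
  wtp <- if (length(a) == 1L && a < 0) {
    b <- setNames(coefs$estimate[coefs$term != "cost_eur"],
                  coefs$term[coefs$term != "cost_eur"])
    preference_to_wtp(b, a)
  }
  structure(
    list(model = fit, coefficients = coefs,
         loglik = as.numeric(stats::logLik(fit)),
         n_respondents = n_respondents,
         n_tasks = fit$n / 2L, n_alternatives = 2L,
         scenario = scenario, wtp = wtp),
    class = "cl_fit"
  )
}

#' @export
print.cl_fit <- function(x, ...) {
  cat(sprintf("<cl_fit> conditional logit, scenario: %s\n", x$scenario))
  cat(sprintf("  %d respondents, %d tasks, logLik = %.3f\n",
              x$n_respondents, x$n_tasks, x$loglik))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.cl_fit <- function(x, ...) x$coefficients

#' @export
glance.cl_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, n_respondents = x$n_respondents,
    n_tasks = x$n_tasks, n_parameters = nrow(x$coefficients),
    AIC = -2 * x$loglik + 2 * nrow(x$coefficients)
  )
}

#' Translate between preference space and WTP space
#'
#' A preference-space utility `X b + c a` (cost coefficient `a < 0`) is
#' behaviorally equivalent to the WTP-space form
#' `alpha * (X beta - c)` with `alpha = -a` and `beta = b / alpha`:
#' both produce identical choice probabilities, so the likelihood is
#' invariant under the reparameterization. `wtp_to_preference()` is the
#' exact inverse.
#'
#' @param b Vector of preference-space attribute coefficients.
#' @param a Preference-space cost coefficient (must be negative).
#' @param beta Vector of WTPs (EUR).
#' @param alpha Positive scale.
#' @return A list with components `beta` and `alpha` (or `b` and `a`).
#' @examples
#' preference_to_wtp(c(2, -1), -2)
#' @export
preference_to_wtp <- function(b, a) {
  stopifnot(is.numeric(b), is.numeric(a), length(a) == 1L)
  if (!is.finite(a) || a >= 0) {
    abort("preference_to_wtp(): cost coefficient must be negative (WTP undefined)")
  }
  alpha <- -a
  list(beta = b / alpha, alpha = alpha)
}

#' @rdname preference_to_wtp
#' @export
wtp_to_preference <- function(beta, alpha) {
  stopifnot(alpha > 0)
  list(b = beta * alpha, a = -alpha)
}

#' Fit the WTP-space mixed logit by maximum simulated likelihood
#'
#' Estimates the population distribution of willingness to pay from
#' forced-choice data under the WTP-space mixed logit: individual WTP
#' vectors are normal with mean `wtp_mean` and independent standard
#' deviations `wtp_sd` (for the contrasts in `spec$random_attrs`), and the
#' individual scale is lognormal(`scale_mu`, `scale_sigma`), i.e. the
#' negative preference-space cost coefficient is lognormal. The simulated
#' log-likelihood averages the panel product of logit probabilities over
#' per-respondent blocks of scrambled-Sobol normal draws, held fixed across
#' optimizer iterations, and is maximized by BFGS with the analytic score.
#' Standard errors come from the inverse numerical Hessian at the optimum.
#' Mixing standard deviations are estimated unconstrained and reported as
#' absolute values.
#'
#' @param data A choice dataset tibble (two alternatives per task).
#' @param scenario Optional scenario filter; fit one scenario at a time as
#'   the two treatment contexts have separate preference structures.
#' @param spec An [mxl_spec()].
#' @param scheme An [attribute_scheme()].
#' @return An object of class `mxl_fit`; see `tidy()`, `glance()`,
#'   [autoplot.mxl_fit()].
#' @examples
#' \donttest{
#' sim <- simulate_study(n_respondents = 50, seed = 1)
#' fit <- fit_mxl(sim, scenario = "chronic", spec = mxl_spec(n_draws = 100))
#' tidy(fit)
#' }
#' @export
fit_mxl <- function(data, scenario = NULL, spec = mxl_spec(),
                    scheme = attribute_scheme()) {
  stopifnot(inherits(spec, "mxl_spec"))
  prep <- mxl_prep(data, scheme, scenario)
  n <- length(prep$ids)
  draws <- make_draws(spec, n)
  contrasts <- scheme$contrasts

  start <- spec$start
  if (is.null(start)) {
    cl <- fit_conditional_logit(data, scenario, scheme)
    if (is.null(cl$wtp)) {
      abort("fit_mxl(): conditional-logit start values unavailable (non-negative cost coefficient); supply spec$start")
    }
    start <- list(
      wtp_mean = cl$wtp$beta[contrasts],
      wtp_sd = setNames(pmax(0.1 * abs(cl$wtp$beta[contrasts]), 0.05),
                        contrasts),
      scale_mu = 0, scale_sigma = 0.1
    )
  }
  theta0 <- mxl_pack(ensure_named(start$wtp_mean),
                     ensure_named(start$wtp_sd),
                     start$scale_mu, start$scale_sigma, spec$random_attrs)

  negll <- function(th) -msl_objective(th, prep, draws, spec$random_attrs,
                                       want_grad = FALSE)$loglik
  neggr <- function(th) -msl_objective(th, prep, draws, spec$random_attrs,
                                       want_grad = TRUE)$gradient
  loglik_start <- -negll(theta0)
  opt <- optim(theta0, fn = negll, gr = neggr, method = "BFGS",
               control = list(maxit = spec$maxit, reltol = spec$reltol))
  theta <- opt$par
  final <- msl_objective(theta, prep, draws, spec$random_attrs,
                         want_grad = TRUE)
  grad_norm <- max(abs(final$gradient))
  converged <- opt$convergence == 0 &&
    grad_norm < 1e-3 * (1 + abs(final$loglik))

  H <- grad_hessian(function(th)
    -msl_objective(th, prep, draws, spec$random_attrs)$gradient, theta)
  vcov <- tryCatch(solve(H), error = function(e) NULL)
  se <- if (!is.null(vcov) && all(diag(vcov) > 0)) sqrt(diag(vcov))
        else rep(NA_real_, length(theta))

  par <- mxl_unpack(theta, spec$random_attrs, contrasts)
  kr <- length(spec$random_attrs)
  terms <- c(contrasts, spec$random_attrs, "scale_mu", "scale_sigma")
  types <- c(rep("mean", 7L), rep("sd", kr), "scale", "scale")
  est <- c(par$wtp_mean, abs(par$wtp_sd[spec$random_attrs]),
           par$scale_mu, par$scale_sigma)
  coefs <- tibble::tibble(
    term = terms, type = types, estimate = unname(est),
    std_error = unname(se),
    statistic = unname(est / se),
    p_value = 2 * stats::pnorm(-abs(est / se))
  )
  structure(
    list(coefficients = coefs, vcov = vcov,
         wtp_mean = par$wtp_mean,
         wtp_sd = setNames(abs(par$wtp_sd), contrasts),
         scale_mu = par$scale_mu, scale_sigma = abs(par$scale_sigma),
         loglik = final$loglik, loglik_start = loglik_start,
         converged = converged, gradient_norm = grad_norm,
         n_respondents = n, n_tasks = prep$n_tasks,
         n_alternatives = 2L, spec = spec, scenario = prep$scenario,
         start = start, counts = opt$counts,
         optim_convergence = opt$convergence),
    class = "mxl_fit"
  )
}

# central-difference Jacobian of an analytic gradient, symmetrized
grad_hessian <- function(gr, theta, h = 1e-4 * (1 + abs(theta))) {
  k <- length(theta)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    up <- theta; up[j] <- up[j] + h[j]
    dn <- theta; dn[j] <- dn[j] - h[j]
    H[, j] <- (gr(up) - gr(dn)) / (2 * h[j])
  }
  (H + t(H)) / 2
}

#' @export
print.mxl_fit <- function(x, ...) {
  cat(sprintf("<mxl_fit> WTP-space mixed logit, scenario: %s\n", x$scenario))
  cat(sprintf("  %d respondents, %d draws (%s), logLik = %.3f, converged: %s\n",
              x$n_respondents, x$spec$n_draws, x$spec$draw_scheme,
              x$loglik, x$converged))
  print(x$coefficients, n = nrow(x$coefficients))
  invisible(x)
}

#' @export
tidy.mxl_fit <- function(x, ...) x$coefficients

#' @export
glance.mxl_fit <- function(x, ...) {
  k <- nrow(x$coefficients)
  tibble::tibble(
    logLik = x$loglik, n_respondents = x$n_respondents,
    n_parameters = k, n_draws = x$spec$n_draws,
    draw_scheme = x$spec$draw_scheme, converged = x$converged,
    AIC = -2 * x$loglik + 2 * k,
    BIC = -2 * x$loglik + log(x$n_respondents) * k
  )
}
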