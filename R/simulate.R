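#' Draw synthetic respondents from a population truth
#'
#' Samples individual WTP vectors `beta_i ~ N(wtp_mean, diag(wtp_sd^2))` and
#' scale parameters `alpha_i ~ lognormal(scale_mu, scale_sigma)`.
#' Optionally, covariate shifts move each respondent's mean WTP:
#' `beta_i = wtp_mean + E %*% (female, (age - 48.8)/10, chronic_meds) + wtp_sd * z`,
#' where `E` is a 7 x 3 effects matrix in EUR (used to study the
#' socio-demographic interaction model; zero by default).
#'
#' @param truth A [population_truth()].
#' @param n Number of respondents (ignored when `covariates` is supplied).
#' @param seed Integer seed.
#' @param covariates Optional tibble from [draw_covariates()].
#' @param covariate_effects Optional 7 x 3 matrix (rows = contrasts, columns
#'   = `female`, `age_per_decade`, `chronic_meds`) of WTP shifts in EUR.
#' @return A tibble with `respondent_id`, one `beta_<contrast>` column per
#'   contrast, and `alpha`.
#' @export
draw_respondents <- function(truth, n = NULL, seed = 1L,
                             covariates = NULL, covariate_effects = NULL) {
  stopifnot(inherits(truth, "population_truth"))
  if (is.null(n)) {
    if (is.null(covariates)) abort("draw_respondents(): supply n or covariates")
    n <- nrow(covariates)
  }
  stopifnot(n >= 1L)
  contrasts <- names(truth$wtp_mean)
  mu <- matrix(truth$wtp_mean, nrow = n, ncol = 7L, byrow = TRUE)
  if (!is.null(covariate_effects)) {
    if (is.null(covariates)) {
      abort("draw_respondents(): covariate_effects requires covariates")
    }
    E <- as.matrix(covariate_effects)
    stopifnot(nrow(E) == 7L, ncol(E) == 3L)
    V <- cbind(covariates$female, (covariates$age - 48.8) / 10,
               covariates$chronic_meds)
    mu <- mu + V %*% t(E)
  }
  withr::with_seed(seed, {
    Z <- matrix(rnorm(n * 7L), nrow = n)
    xi <- rnorm(n)
  })
  beta <- mu + Z * matrix(truth$wtp_sd, nrow = n, ncol = 7L, byrow = TRUE)
  colnames(beta) <- paste0("beta_", contrasts)
  out <- tibble::tibble(respondent_id = seq_len(n))
  out <- dplyr::bind_cols(out, tibble::as_tibble(beta))
  out$alpha <- exp(truth$scale_mu + truth$scale_sigma * xi)
  out
}

#' Simulate forced choices for a task set
#'
#' Random-utility simulation: for each respondent and task, both
#' alternatives receive utility
#' `U = alpha_i * (X beta_i - cost_eur) + epsilon`, with i.i.d. standard
#' Gumbel errors (the logit normalization; `alpha_i` carries the scale), and
#' the alternative with maximal utility is chosen. Exact utility ties are
#' resolved toward the lower alternative index (Gumbel noise makes them
#' measure-zero).
#'
#' @param design A task-set tibble from [build_task_set()] (any subset of
#'   scenarios); one row per task-alternative.
#' @param respondents A tibble from [draw_respondents()].
#' @param scheme An [attribute_scheme()].
#' @param seed Integer seed for the Gumbel errors.
#' @return A choice dataset tibble: the design rows replicated per
#'   respondent, with `respondent_id` and `chosen` columns, passing
#'   [validate_choice_data()].
#' @export
simulate_choices <- function(design, respondents,
                             scheme = attribute_scheme(), seed = 1L) {
  stopifnot(nrow(design) >= 2L, nrow(respondents) >= 1L)
  enc <- encode_profiles(design, scheme)
  X <- contrast_matrix(enc, scheme)
  cost <- enc$cost_eur
  B <- t(as.matrix(respondents[, paste0("beta_", scheme$contrasts)]))
  alpha <- respondents$alpha
  n <- nrow(respondents)
  m <- nrow(design)
  # money-metric index per design row x respondent, scaled per respondent
  V <- (X %*% B - cost) * rep(alpha, each = m)
  withr::with_seed(seed, {
    eps <- -log(-log(matrix(runif(m * n), nrow = m)))
  })
  U <- V + eps
  grp <- paste(design$scenario, design$task, sep = "\r")
  first <- !duplicated(grp)             # design rows come in alt-1/alt-2 pairs
  i1 <- which(first)
  i2 <- which(!first)
  stopifnot(length(i1) == length(i2))
  chosen <- matrix(0L, nrow = m, ncol = n)
  pick1 <- U[i1, , drop = FALSE] >= U[i2, , drop = FALSE]
  chosen[i1, ][pick1] <- 1L
  chosen[i2, ][!pick1] <- 1L
  out <- tibble::tibble(
    respondent_id = rep(respondents$respondent_id, each = m),
    design[rep(seq_len(m), times = n), c("scenario", "task", "alt",
                                         "form", "size", "color", "copay_pln")],
    chosen = as.integer(chosen)
  )
  out
}

#' Simulate a complete two-scenario choice study
#'
#' End-to-end synthetic data generator: builds (or accepts) a task design,
#' draws respondent covariates and scenario-specific preference parameters,
#' and simulates every forced choice. Defaults emulate the study conditions
#' the package targets: 200 respondents, 8 chronic + 8 short-term tasks with
#' two alternatives each (6,400 rows), scenario truths from
#' [chronic_truth()] / [short_term_truth()] (independent draws per scenario,
#' mirroring separately estimated per-scenario models), and covariates from
#' [covariate_model()].
#'
#' @param n_respondents Number of respondents (default 200).
#' @param tasks_per_scenario Tasks per scenario (default 8).
#' @param truth_chronic,truth_short [population_truth()] objects.
#' @param covariates A [covariate_model()], or `NULL` to omit covariates.
#' @param covariate_effects Optional 7 x 3 WTP-shift matrix applied in both
#'   scenarios (see [draw_respondents()]).
#' @param design Optional task-set tibble overriding the randomized default.
#' @param scheme An [attribute_scheme()].
#' @param seed Master integer seed; all stage seeds derive from it.
#' @return A choice dataset tibble including covariate columns, with the
#'   ground-truth respondent parameters attached as attributes
#'   `respondents_chronic` and `respondents_short_term` and the design as
#'   attribute `design`.
#' @examples
#' sim <- simulate_study(n_respondents = 20, seed = 7)
#' nrow(sim)  # 20 * 16 * 2 = 640
#' @export
simulate_study <- function(n_respondents = 200L,
                           tasks_per_scenario = 8L,
                           truth_chronic = chronic_truth(),
                           truth_short = short_term_truth(),
                           covariates = covariate_model(),
                           covariate_effects = NULL,
                           design = NULL,
                           scheme = attribute_scheme(),
                           seed = 1L) {
  seeds <- derive_seeds(seed, 6L)
  if (is.null(design)) {
    design <- build_task_set(scheme, tasks_per_scenario, seed = seeds[1L])
  }
  covs <- if (!is.null(covariates)) {
    draw_covariates(covariates, n_respondents, seed = seeds[2L])
  }
  resp_c <- draw_respondents(truth_chronic, n_respondents, seed = seeds[3L],
                             covariates = covs,
                             covariate_effects = covariate_effects)
  resp_s <- draw_respondents(truth_short, n_respondents, seed = seeds[4L],
                             covariates = covs,
                             covariate_effects = covariate_effects)
  des_c <- design[design$scenario == "chronic", ]
  des_s <- design[design$scenario == "short_term", ]
  dat <- dplyr::bind_rows(
    simulate_choices(des_c, resp_c, scheme, seed = seeds[5L]),
    simulate_choices(des_s, resp_s, scheme, seed = seeds[6L])
  )
  dat <- dplyr::arrange(dat, .data$respondent_id, .data$scenario, .data$task,
                        .data$alt)
  if (!is.null(covs)) {
    dat <- dplyr::left_join(dat, covs, by = "respondent_id")
  }
  dat <- validate_choice_data(dat, scheme)
  attr(dat, "design") <- design
  attr(dat, "respondents_chronic") <- resp_c
  attr(dat, "respondents_short_term") <- resp_s
  dat
}

# deterministic stage seeds below 2^31, derived from one master seed
derive_seeds <- function(seed, k) {
  withr::with_seed(seed, sample.int(.Machine$integer.max, k))
}
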