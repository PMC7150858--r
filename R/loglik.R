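#' Logit choice probabilities
#'
#' Multinomial-logit probabilities `exp(v_j) / sum_k exp(v_k)` for one choice
#' set, computed with a max-shift so arbitrarily large utilities do not
#' overflow. Probabilities are strictly positive, sum to one, and are
#' invariant to adding a constant to all utilities.
#'
#' @param v Numeric vector of utility indices (>= 2 alternatives).
#' @return Probability vector of the same length.
#' @examples
#' choice_prob(c(0, 0))
#' choice_prob(c(1000, 0))
#' @export
choice_prob <- function(v) {
  stopifnot(is.numeric(v), length(v) >= 2L, all(is.finite(v)))
  e <- exp(v - max(v))
  e / sum(e)
}

# ---- internal panel representation -----------------------------------------
#
# mxl_prep() reshapes an encoded choice dataset into per-respondent blocks
# ordered (task, chosen-first): for 2-alternative forced choices only the
# chosen-minus-other differences are needed by both the analytic and the
# simulated likelihood.
mxl_prep <- function(data, scheme = attribute_scheme(), scenario = NULL) {
  if (!is.null(scenario)) {
    scenario <- match.arg(scenario, c("chronic", "short_term"))
    data <- data[data$scenario == scenario, ]
    if (nrow(data) == 0L) {
      abort(sprintf("no rows for scenario '%s'", scenario))
    }
  }
  data <- validate_choice_data(data, scheme)
  enc <- encode_profiles(data, scheme)
  enc <- dplyr::arrange(enc, .data$respondent_id, .data$scenario, .data$task,
                        dplyr::desc(.data$chosen))
  X <- contrast_matrix(enc, scheme)
  cost <- enc$cost_eur
  i1 <- seq(1L, nrow(enc), by = 2L)   # chosen rows
  i2 <- i1 + 1L
  dX <- X[i1, , drop = FALSE] - X[i2, , drop = FALSE]
  dc <- cost[i1] - cost[i2]
  resp <- enc$respondent_id[i1]
  ids <- unique(resp)
  blocks <- lapply(ids, function(id) {
    rows <- which(resp == id)
    list(dX = dX[rows, , drop = FALSE], dc = dc[rows])
  })
  list(ids = ids, blocks = blocks, n_tasks = lengths(lapply(blocks, `[[`, "dc")),
       scenario = scenario %||% "all", n_rows = nrow(enc))
}

# pack/unpack the hyperparameter vector: (wtp_mean[7], wtp_sd[random],
# scale_mu, scale_sigma). Non-random contrasts have fixed coefficients.
mxl_pack <- function(wtp_mean, wtp_sd, scale_mu, scale_sigma, random_attrs,
                     contrasts = attribute_scheme()$contrasts) {
  c(wtp_mean[contrasts], wtp_sd[random_attrs], scale_mu, scale_sigma)
}

mxl_unpack <- function(theta, random_attrs,
                       contrasts = attribute_scheme()$contrasts) {
  k <- length(contrasts)
  r <- length(random_attrs)
  wtp_mean <- setNames(theta[seq_len(k)], contrasts)
  wtp_sd <- setNames(numeric(k), contrasts)
  wtp_sd[random_attrs] <- theta[k + seq_len(r)]
  list(wtp_mean = wtp_mean, wtp_sd = wtp_sd,
       scale_mu = theta[k + r + 1L], scale_sigma = theta[k + r + 2L])
}

#' Analytic conditional-logit log-likelihood
#'
#' The fixed-coefficient (zero-heterogeneity) log-likelihood in WTP space:
#' every respondent shares `beta` and `alpha`, and each task contributes
#' `log P(chosen)` under the logit formula. This closed form is the
#' zero-variance limit of the simulated likelihood and serves as its oracle.
#'
#' @param data A choice dataset tibble.
#' @param beta Named 7-vector of WTPs (EUR).
#' @param alpha Positive scale (utility per EUR).
#' @param scheme An [attribute_scheme()].
#' @param scenario Optional scenario filter.
#' @return The log-likelihood (scalar).
#' @export
cl_loglik <- function(data, beta, alpha, scheme = attribute_scheme(),
                      scenario = NULL) {
  stopifnot(alpha > 0)
  prep <- mxl_prep(data, scheme, scenario)
  beta <- if (!is.null(names(beta))) beta[scheme$contrasts] else beta
  ll <- 0
  for (b in prep$blocks) {
    dv <- alpha * (drop(b$dX %*% beta) - b$dc)
    ll <- ll + sum(plogis(dv, log.p = TRUE))
  }
  ll
}

#' Simulated mixed-logit log-likelihood
#'
#' The maximum-simulated-likelihood objective: for each respondent i and
#' draw d, individual parameters are materialized as
#' `beta_i^d = wtp_mean + wtp_sd * z_d` and
#' `alpha_i^d = exp(scale_mu + scale_sigma * z_d0)`, the probabilities of
#' the chosen alternatives are multiplied over the respondent's tasks (the
#' panel product), averaged over the D draws, logged, and summed over
#' respondents. The task product is accumulated in log space and the draw
#' average uses a max-shift, so long panels cannot underflow.
#'
#' @param data A choice dataset tibble (2 alternatives per task).
#' @param wtp_mean Named 7-vector of population mean WTPs (EUR).
#' @param wtp_sd Named 7-vector of population WTP standard deviations
#'   (entries for contrasts outside `random_attrs` are ignored and treated
#'   as 0).
#' @param scale_mu,scale_sigma Lognormal scale parameters.
#' @param draws Draw blocks from [make_draws()] (one per respondent, in
#'   respondent-id order), or an [mxl_spec()] from which to generate them.
#' @param random_attrs Contrasts with random coefficients (default all).
#' @param scheme An [attribute_scheme()].
#' @param scenario Optional scenario filter.
#' @return The simulated log-likelihood (scalar).
#' @export
simulated_loglik <- function(data, wtp_mean, wtp_sd, scale_mu, scale_sigma,
                             draws, random_attrs = attribute_scheme()$contrasts,
                             scheme = attribute_scheme(), scenario = NULL) {
  prep <- mxl_prep(data, scheme, scenario)
  if (inherits(draws, "mxl_spec")) {
    random_attrs <- draws$random_attrs
    draws <- make_draws(draws, length(prep$ids))
  }
  theta <- mxl_pack(ensure_named(wtp_mean), ensure_named(wtp_sd),
                    scale_mu, scale_sigma, random_attrs)
  msl_objective(theta, prep, draws, random_attrs, want_grad = FALSE)$loglik
}

ensure_named <- function(x, contrasts = attribute_scheme()$contrasts) {
  stopifnot(length(x) == length(contrasts))
  if (is.null(names(x))) names(x) <- contrasts
  x[contrasts]
}

# Core simulated log-likelihood and analytic score.
#
# For each respondent/draw the chosen-alternative probability of a
# 2-alternative task is plogis(dv) with dv = alpha * (dX beta - dc), the
# chosen-minus-other utility difference. The score uses
# dlogP/dbeta = alpha * (1 - P) dX and dlogP/dalpha = (1 - P) dm with
# m = dX beta - dc, chained through beta = mean + sd z, alpha =
# exp(mu + sigma z0); draw weights are the normalized per-draw panel
# likelihoods.
msl_objective <- function(theta, prep, draws, random_attrs,
                          want_grad = TRUE) {
  contrasts <- attribute_scheme()$contrasts
  par <- mxl_unpack(theta, random_attrs, contrasts)
  ridx <- match(random_attrs, contrasts)
  n <- length(prep$blocks)
  if (length(draws) < n) abort("msl_objective(): draws do not cover all respondents")
  kr <- length(random_attrs)
  ll <- 0
  grad <- if (want_grad) numeric(length(theta)) else NULL
  bad_id <- NULL
  for (i in seq_len(n)) {
    b <- prep$blocks[[i]]
    Z <- draws[[i]]                    # D x (kr + 1)
    D <- nrow(Z)
    Tn <- length(b$dc)
    # 7 x D individual WTP vectors
    B <- matrix(par$wtp_mean, nrow = 7L, ncol = D)
    if (kr > 0L) {
      B[ridx, ] <- B[ridx, , drop = FALSE] +
        par$wtp_sd[ridx] * t(Z[, seq_len(kr), drop = FALSE])
    }
    z0 <- Z[, kr + 1L]
    A <- exp(par$scale_mu + par$scale_sigma * z0)
    dM <- b$dX %*% B - b$dc            # T x D money-metric differences
    dV <- dM * rep(A, each = Tn)
    logP <- plogis(dV, log.p = TRUE)
    lid <- .colSums(logP, Tn, D)       # log panel likelihood per draw
    m <- max(lid)
    wraw <- exp(lid - m)
    sw <- sum(wraw)
    lli <- m + log(sw / D)
    if (!is.finite(lli)) { bad_id <- prep$ids[i]; break }
    ll <- ll + lli
    if (want_grad) {
      w <- wraw / sw                   # normalized draw weights
      Pneg <- plogis(-dV)              # 1 - P(chosen), T x D
      G <- crossprod(b$dX, Pneg)       # 7 x D: sum_t (1-P) dX
      Gm <- G * rep(A, each = 7L)
      g_mean <- drop(Gm %*% w)
      g_alpha <- .colSums(Pneg * dM, Tn, D)   # per-draw dll/dalpha
      g_mu <- sum(w * g_alpha * A)
      g_sigma <- sum(w * g_alpha * A * z0)
      g <- c(g_mean,
             if (kr > 0L) drop((Gm[ridx, , drop = FALSE] *
                                  t(Z[, seq_len(kr), drop = FALSE])) %*% w),
             g_mu, g_sigma)
      grad <- grad + g
    }
  }
  if (!is.null(bad_id)) {
    abort(sprintf("simulated log-likelihood non-finite for respondent %s",
                  format(bad_id)))
  }
  list(loglik = ll, gradient = grad)
}
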