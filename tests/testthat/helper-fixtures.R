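# shared fixtures and independent oracles for the test suite

fixture_file <- function(name) {
  system.file("extdata", name, package = "pillpref")
}

load_fixture_data <- function() {
  read_choice_data(fixture_file("fixture_data.csv"))
}

load_fixture_truth <- function() {
  y <- yaml::read_yaml(fixture_file("fixture_truth.yaml"))
  population_truth(unlist(y$wtp_mean), unlist(y$wtp_sd),
                   y$scale_mu, y$scale_sigma)
}

# small shared simulated study (identified 8+8 design)
small_study <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- simulate_study(n_respondents = 40, seed = 101)
    memo
  }
})

# Independent Gauss-Hermite evaluation of the panel log-likelihood when a
# single WTP coefficient is random (normal) and the scale alpha is fixed.
# Plain loops over respondents, tasks and quadrature nodes; shares no code
# with the simulated-likelihood path.
gh_panel_loglik <- function(data, wtp_mean, sd_value, random_attr, alpha,
                            n_nodes = 64, scenario = NULL,
                            scheme = attribute_scheme()) {
  if (!is.null(scenario)) data <- data[data$scenario == scenario, ]
  gh <- pracma::gaussHermite(n_nodes)
  enc <- encode_profiles(data, scheme)
  X <- as.matrix(enc[, scheme$contrasts])
  cost <- enc$cost_eur
  key <- paste(enc$respondent_id, enc$scenario, enc$task)
  ll <- 0
  for (id in unique(enc$respondent_id)) {
    L <- 0
    for (j in seq_len(n_nodes)) {
      beta <- wtp_mean
      beta[random_attr] <- beta[random_attr] + sd_value * sqrt(2) * gh$x[j]
      v <- alpha * (drop(X %*% beta) - cost)
      prod_p <- 1
      for (tk in unique(key[enc$respondent_id == id])) {
        k <- which(key == tk)
        p <- exp(v[k] - max(v[k]))
        p <- p / sum(p)
        prod_p <- prod_p * p[enc$chosen[k] == 1L]
      }
      L <- L + gh$w[j] * prod_p
    }
    ll <- ll + log(L / sqrt(pi))
  }
  ll
}
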