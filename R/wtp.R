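#' Significance stars from a two-sided normal test
#'
#' `***`, `**` and `*` mark significance at the 1%, 5% and 10% levels:
#' `|estimate / se|` compared with the corresponding two-sided normal
#' quantiles. Missing or non-positive standard errors yield no star.
#'
#' @param estimate,se Numeric vectors.
#' @return Character vector of star markers.
#' @export
significance_stars <- function(estimate, se) {
  z <- abs(estimate) / se
  dplyr::case_when(
    !is.finite(z)          ~ "",
    z > qnorm(1 - 0.01 / 2) ~ "***",
    z > qnorm(1 - 0.05 / 2) ~ "**",
    z > qnorm(1 - 0.10 / 2) ~ "*",
    TRUE                    ~ ""
  )
}

#' Per-scenario willingness-to-pay summary table
#'
#' Builds the package's standard result table -- one row per attribute
#' contrast and scenario with the estimated mean WTP (EUR), its standard
#' error and significance stars, the estimated population standard
#' deviation with the same, plus the scale-parameter rows of each fit.
#' Accepts named `mxl_fit` objects (`wtp_summary(chronic = fit1,
#' short_term = fit2)`) or a data frame already holding columns
#' `scenario`, `term`, `mean`, `mean_se`, `sd`, `sd_se` (e.g.
#' [reference_wtp_estimates()]), to which stars are added.
#'
#' @param ... Named `mxl_fit` objects (names are scenario labels), or a
#'   single data frame.
#' @return A tibble of class `wtp_summary` with columns `scenario`, `term`,
#'   `attribute`, `mean`, `mean_se`, `mean_stars`, `sd`, `sd_se`,
#'   `sd_stars`; scale-parameter rows carry attribute `"scale"`.
#' @examples
#' wtp_summary(reference_wtp_estimates())
#' @export
wtp_summary <- function(...) {
  inputs <- list(...)
  scheme <- attribute_scheme()
  if (length(inputs) == 1L && is.data.frame(inputs[[1L]])) {
    inputs <- inputs[[1L]]
  }
  if (is.data.frame(inputs)) {
    tab <- tibble::as_tibble(inputs)
    need <- c("scenario", "term", "mean", "mean_se", "sd", "sd_se")
    miss <- setdiff(need, names(tab))
    if (length(miss) > 0) {
      abort(paste0("wtp_summary(): data frame lacks column(s): ",
                   paste(miss, collapse = ", ")))
    }
  } else {
    if (is.null(names(inputs)) || any(names(inputs) == "")) {
      abort("wtp_summary(): name each fit by its scenario, e.g. wtp_summary(chronic = fit)")
    }
    tab <- purrr::imap_dfr(inputs, function(fit, scen) {
      stopifnot(inherits(fit, "mxl_fit"))
      co <- fit$coefficients
      mean_rows <- co[co$type == "mean", ]
      sd_rows <- co[co$type == "sd", ]
      out <- tibble::tibble(
        scenario = scen,
        term = mean_rows$term,
        mean = mean_rows$estimate,
        mean_se = mean_rows$std_error
      )
      out$sd <- sd_rows$estimate[match(out$term, sd_rows$term)]
      out$sd_se <- sd_rows$std_error[match(out$term, sd_rows$term)]
      scale_rows <- co[co$type == "scale", ]
      dplyr::bind_rows(out, tibble::tibble(
        scenario = scen, term = scale_rows$term,
        mean = scale_rows$estimate, mean_se = scale_rows$std_error,
        sd = NA_real_, sd_se = NA_real_
      ))
    })
  }
  tab$attribute <- dplyr::case_when(
    tab$term %in% c("long_tablet", "capsule") ~ "form",
    tab$term %in% c("medium", "large") ~ "size",
    tab$term %in% c("yellow", "blue", "red") ~ "color",
    TRUE ~ "scale"
  )
  tab$mean_stars <- significance_stars(tab$mean, tab$mean_se)
  tab$sd_stars <- significance_stars(tab$sd, tab$sd_se)
  term_order <- c(scheme$contrasts, setdiff(unique(tab$term), scheme$contrasts))
  tab <- dplyr::arrange(tab, .data$scenario,
                        match(.data$term, term_order))
  tab <- tab[, c("scenario", "term", "attribute", "mean", "mean_se",
                 "mean_stars", "sd", "sd_se", "sd_stars")]
  class(tab) <- c("wtp_summary", class(tab))
  tab
}

summary_means <- function(summary, scenario) {
  stopifnot(is.data.frame(summary))
  scenario <- match.arg(scenario, c("chronic", "short_term"))
  rows <- summary[summary$scenario == scenario &
                    summary$attribute != "scale", ]
  if (nrow(rows) == 0L) {
    abort(sprintf("summary contains no rows for scenario '%s'", scenario))
  }
  setNames(rows$mean, rows$term)
}

#' Most preferred drug configuration
#'
#' Exhaustive search over all form x size x color combinations (3 x 3 x 4 =
#' 36 with the default scheme) for the configuration maximizing total mean
#' WTP relative to the all-base profile (small white round tablet at equal
#' copayment); base levels contribute zero, so the base profile totals 0.
#' Ties are broken toward base levels.
#'
#' @param summary A [wtp_summary()] table (or any data frame with columns
#'   `scenario`, `term`, `attribute`, `mean`).
#' @param scenario Which scenario to search.
#' @param scheme An [attribute_scheme()].
#' @return A one-row tibble: `scenario`, `form`, `size`, `color`,
#'   `total_wtp_eur`.
#' @examples
#' preferred_configuration(wtp_summary(reference_wtp_estimates()), "chronic")
#' @export
preferred_configuration <- function(summary, scenario,
                                    scheme = attribute_scheme()) {
  means <- summary_means(summary, scenario)
  level_value <- function(level) {
    if (level %in% names(means)) means[[level]] else 0
  }
  grid <- tidyr::expand_grid(
    form = scheme$attributes$form,
    size = scheme$attributes$size,
    color = scheme$attributes$color
  )
  total <- purrr::pmap_dbl(grid, function(form, size, color) {
    level_value(form) + level_value(size) + level_value(color)
  })
  best <- which.max(total)   # grid lists base levels first => ties go to base
  tibble::tibble(
    scenario = scenario,
    form = grid$form[best], size = grid$size[best], color = grid$color[best],
    total_wtp_eur = total[best]
  )
}

#' Currency conversion between EUR and PLN
#'
#' Converts at the study's convention of 1 PLN = `rate` EUR (default 0.25),
#' rounding to 2 decimals (money).
#'
#' @param amount_eur,amount_pln Amounts to convert.
#' @param rate EUR per PLN (> 0).
#' @return Numeric vector of converted amounts.
#' @examples
#' eur_to_pln(1.63)  # 6.52
#' @export
eur_to_pln <- function(amount_eur, rate = 0.25) {
  stopifnot(rate > 0)
  round(amount_eur / rate, 2)
}

#' @rdname eur_to_pln
#' @export
pln_to_eur <- function(amount_pln, rate = 0.25) {
  stopifnot(rate > 0)
  round(amount_pln * rate, 2)
}

#' Attribute importance ranking
#'
#' Ranks attributes by the within-attribute range of mean WTP across their
#' levels, with the base level at 0 -- i.e. the money-metric gap between the
#' best and worst level of each attribute. The measure is recorded in the
#' `measure` attribute of the result. Note that importance orderings are
#' measure-dependent; the range measure can rank attributes differently
#' from impressionistic orderings based on single contrasts.
#'
#' @inheritParams preferred_configuration
#' @return A tibble (descending importance): `attribute`, `importance`
#'   (EUR), `best_level`, `worst_level`; metadata in `attr(, "measure")`.
#' @examples
#' attribute_importance(wtp_summary(reference_wtp_estimates()), "short_term")
#' @export
attribute_importance <- function(summary, scenario,
                                 scheme = attribute_scheme()) {
  means <- summary_means(summary, scenario)
  rows <- purrr::imap_dfr(scheme$attributes, function(levels, attr) {
    vals <- setNames(
      vapply(levels, function(l) if (l %in% names(means)) means[[l]] else 0,
             numeric(1)),
      levels)
    tibble::tibble(
      attribute = attr,
      importance = max(vals) - min(vals),
      best_level = names(vals)[which.max(vals)],
      worst_level = names(vals)[which.min(vals)]
    )
  })
  out <- dplyr::arrange(rows, dplyr::desc(.data$importance))
  attr(out, "measure") <-
    "within-attribute range of mean WTP across levels, base level at 0 (EUR)"
  attr(out, "scenario") <- scenario
  out
}

#' Conditional logit with socio-demographic interactions
#'
#' The observed-heterogeneity companion to the mixed logit: unobserved
#' preference heterogeneity is dropped (fixed coefficients) and every
#' attribute contrast is instead interacted with the respondent covariates
#' `female`, age (centered at 48.8, per decade) and `chronic_meds`. The
#' design matrix is the 7 contrasts + EUR cost + 21 interaction columns;
#' estimation is by conditional logistic likelihood on the forced-choice
#' strata. Interaction signs are directly inspectable (e.g. a negative
#' `large:female` coefficient means women dislike large pills more).
#'
#' @param data A choice dataset tibble with covariate columns `female`,
#'   `age`, `chronic_meds`.
#' @param scenario Optional scenario filter.
#' @param scheme An [attribute_scheme()].
#' @return A `cl_fit` whose coefficient table includes the interaction
#'   terms (named `<contrast>:<covariate>`).
#' @export
fit_interaction_model <- function(data, scenario = NULL,
                                  scheme = attribute_scheme()) {
  if (!is.null(scenario)) {
    scenario <- match.arg(scenario, c("chronic", "short_term"))
    data <- data[data$scenario == scenario, ]
  }
  data <- validate_choice_data(data, scheme)
  covs <- c("female", "age", "chronic_meds")
  miss <- setdiff(covs, names(data))
  if (length(miss) > 0) {
    abort(paste0("fit_interaction_model(): missing covariate column(s): ",
                 paste(miss, collapse = ", ")))
  }
  for (cv in covs) {
    if (length(unique(data[[cv]])) < 2L) {
      abort(sprintf(
        "fit_interaction_model(): covariate '%s' is constant across respondents",
        cv))
    }
  }
  enc <- encode_profiles(data, scheme)
  enc$.stratum <- paste(enc$respondent_id, enc$scenario, enc$task, sep = ".")
  enc$age_dec <- (enc$age - 48.8) / 10
  main <- c(scheme$contrasts, "cost_eur")
  inter <- as.vector(outer(scheme$contrasts, c("female", "age_dec", "chronic_meds"),
                           function(a, b) paste0(a, ":", b)))
  for (term in inter) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1L]]
    enc[[term]] <- enc[[parts[1L]]] * enc[[parts[2L]]]
  }
  X <- as.matrix(enc[, c(main, inter)])
  if (qr(scale(X, scale = FALSE))$rank < ncol(X)) {
    abort("fit_interaction_model(): design matrix is collinear")
  }
  f <- stats::as.formula(paste(
    "chosen ~", paste(c(main, paste0("`", inter, "`")), collapse = " + "),
    "+ strata(.stratum)"))
  environment(f) <- asNamespace("survival")
  fit <- survival::clogit(f, data = enc, iter.max = 100)
  if (anyNA(stats::coef(fit))) {
    abort("fit_interaction_model(): some coefficients inestimable")
  }
  out <- new_cl_fit(fit, scenario = scenario %||% "all",
                    n_respondents = length(unique(enc$respondent_id)))
  out$coefficients$term <- gsub("^`|`$", "", out$coefficients$term)
  out
}
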