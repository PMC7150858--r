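#' Run the full simulate-fit-report pipeline
#'
#' Executes the end-to-end analysis: build the task design, simulate the
#' two-scenario study, fit the WTP-space mixed logit per scenario, and write
#' a report. All artifacts land in `config$out_dir`: `design.csv`,
#' `data.csv`, `estimate_chronic.json`, `estimate_short_term.json`,
#' `summary.csv`, `report.md` and the resolved `config.yaml`. Every source
#' of randomness is keyed by the explicit seeds in the config, so an
#' identical config produces byte-identical outputs; the report embeds the
#' package version and a hash of the resolved config for provenance.
#'
#' @param config A named list, or path to a YAML file, with any of:
#'   `out_dir` (required), `n_respondents` (200), `tasks_per_scenario` (8),
#'   `n_draws` (500), `draw_scheme` (`"scrambled_sobol"`), `seed` (1; master
#'   seed for design/respondents/choices), `draw_seed` (1), `scenarios`
#'   (both), and optional truth overrides `truth_chronic` / `truth_short`
#'   (lists with `wtp_mean`, `wtp_sd`, `scale_mu`, `scale_sigma`).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list of output file paths plus the fitted objects.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$out_dir))
  defaults <- list(
    n_respondents = 200L, tasks_per_scenario = 8L, n_draws = 500L,
    draw_scheme = "scrambled_sobol", seed = 1L, draw_seed = 1L,
    scenarios = c("chronic", "short_term")
  )
  config <- modifyList(defaults, config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    say(name, "done in %.1fs", proc.time()[["elapsed"]] - t0)
    out
  }

  as_truth <- function(x, default) {
    if (is.null(x)) return(default)
    population_truth(unlist(x$wtp_mean), unlist(x$wtp_sd),
                     x$scale_mu %||% 0, x$scale_sigma %||% 0.5)
  }
  truth_c <- as_truth(config$truth_chronic, chronic_truth())
  truth_s <- as_truth(config$truth_short, short_term_truth())

  sim <- stage("simulate", simulate_study(
    n_respondents = config$n_respondents,
    tasks_per_scenario = config$tasks_per_scenario,
    truth_chronic = truth_c, truth_short = truth_s,
    seed = config$seed))
  design_path <- file.path(config$out_dir, "design.csv")
  readr::write_csv(attr(sim, "design"), design_path, progress = FALSE)
  data_path <- file.path(config$out_dir, "data.csv")
  write_choice_data(sim, data_path)
  say("simulate", "%d rows -> %s", nrow(sim), data_path)

  spec <- mxl_spec(n_draws = config$n_draws, draw_scheme = config$draw_scheme,
                   scramble_seed = config$draw_seed)
  fits <- list()
  est_paths <- character(0)
  for (scen in config$scenarios) {
    fit <- stage(paste0("fit_", scen), fit_mxl(sim, scenario = scen, spec = spec))
    say(paste0("fit_", scen), "logLik %.2f, converged %s, %d fn evals",
        fit$loglik, fit$converged, fit$counts[["function"]])
    p <- file.path(config$out_dir, paste0("estimate_", scen, ".json"))
    jsonlite::write_json(
      list(scenario = scen, coefficients = fit$coefficients,
           loglik = fit$loglik, converged = fit$converged,
           n_respondents = fit$n_respondents, n_draws = spec$n_draws,
           draw_scheme = spec$draw_scheme),
      p, auto_unbox = TRUE, digits = NA)
    fits[[scen]] <- fit
    est_paths <- c(est_paths, p)
  }

  summary <- stage("report", do.call(wtp_summary, fits))
  summary_path <- file.path(config$out_dir, "summary.csv")
  readr::write_csv(summary, summary_path, progress = FALSE)
  report_path <- file.path(config$out_dir, "report.md")
  writeLines(render_report(summary, config), report_path)
  config_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(config, config_path)
  say("report", "-> %s", report_path)

  invisible(list(
    data = data_path, design = design_path, estimates = est_paths,
    summary = summary_path, report = report_path, config = config_path,
    fits = fits, summary_table = summary
  ))
}

# hash of the analysis-relevant config: paths excluded so the same analysis
# in a different directory reports the same provenance hash
config_hash <- function(config) {
  keep <- setdiff(names(config), "out_dir")
  rlang::hash(config[sort(keep)])
}

render_report <- function(summary, config) {
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.2f", x))
  lines <- c(
    "# Willingness to pay for solid oral drug forms",
    "",
    sprintf("pillpref %s | config hash %s",
            as.character(utils::packageVersion("pillpref")),
            config_hash(config)),
    sprintf("seeds: master %d, draws %d | %d respondents | %d %s draws",
            config$seed, config$draw_seed, config$n_respondents,
            config$n_draws, config$draw_scheme),
    ""
  )
  for (scen in unique(summary$scenario)) {
    tab <- summary[summary$scenario == scen, ]
    lines <- c(lines,
      sprintf("## Scenario: %s", scen), "",
      "| Term | Mean (EUR) | SE | | SD (EUR) | SE | |",
      "|---|---|---|---|---|---|---|",
      sprintf("| %s | %s | %s | %s | %s | %s | %s |",
              tab$term, fmt(tab$mean), fmt(tab$mean_se), tab$mean_stars,
              fmt(tab$sd), fmt(tab$sd_se), tab$sd_stars),
      "")
    pc <- preferred_configuration(summary, scen)
    imp <- attribute_importance(summary, scen)
    lines <- c(lines,
      sprintf("Preferred configuration: %s, %s, %s (total premium %.2f EUR = %.2f PLN)",
              pc$form, pc$size, pc$color, pc$total_wtp_eur,
              eur_to_pln(pc$total_wtp_eur)),
      sprintf("Attribute importance (range of mean WTP): %s",
              paste(sprintf("%s (%.2f)", imp$attribute, imp$importance),
                    collapse = " > ")),
      "")
  }
  lines
}

#' Write tiny bundled fixtures
#'
#' Generates the small deterministic datasets used across the test suite: a
#' 5-respondent choice dataset with 4 tasks per scenario
#' (`fixture_data.csv`) and the generating truth (`fixture_truth.yaml`).
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return Invisibly, the two file paths.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- population_truth(
    wtp_mean = c(0.5, 1.0, -2.5, -5.0, 0.7, -0.6, -1.1),
    wtp_sd = c(0.1, 0.3, 0.7, 2.0, 0.1, 0.1, 0.4),
    scale_mu = 0, scale_sigma = 0.5
  )
  sim <- simulate_study(
    n_respondents = 5L, tasks_per_scenario = 4L,
    truth_chronic = truth, truth_short = truth, seed = seed)
  data_path <- file.path(dir, "fixture_data.csv")
  write_choice_data(sim, data_path)
  truth_path <- file.path(dir, "fixture_truth.yaml")
  yaml::write_yaml(
    list(wtp_mean = as.list(truth$wtp_mean), wtp_sd = as.list(truth$wtp_sd),
         scale_mu = truth$scale_mu, scale_sigma = truth$scale_sigma,
         seed = seed),
    truth_path)
  invisible(c(data = data_path, truth = truth_path))
}
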