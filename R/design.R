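#' Build a randomized choice-task set
#'
#' Constructs the forced-choice task battery shown to every respondent:
#' `n_tasks_per_scenario` tasks for the chronic-treatment scenario and the
#' same number for the short-term scenario (default 8 + 8 = 16), each task
#' presenting two alternatives. Profile pairs are sampled uniformly without
#' replacement from the full factorial of the scheme; pairs whose two
#' profiles are identical are impossible by construction. The presentation
#' order interleaves the two scenarios in randomly ordered pairs (one chronic
#' and one short-term task per round, their within-round order randomized),
#' recorded in the `position` column; `task` remains the 1..n index within
#' its scenario.
#'
#' Because all respondents face the same task battery, a task set whose
#' stacked within-task attribute differences are rank-deficient would leave
#' some coefficients unidentifiable no matter how many respondents are
#' interviewed. `build_task_set()` therefore resamples (deterministically,
#' under the seed) until the difference matrix of the 7 contrasts + cost
#' has full column rank -- per scenario when `n_tasks_per_scenario >= 8`,
#' pooled across scenarios when `2 * n_tasks_per_scenario >= 8`, and not
#' enforced for smaller (intentionally under-identified) task sets.
#'
#' @param scheme An [attribute_scheme()].
#' @param n_tasks_per_scenario Tasks per scenario (default 8).
#' @param seed Integer seed; the same seed reproduces the task set exactly.
#' @return A tibble with one row per task-alternative: `scenario`
#'   (`"chronic"` / `"short_term"`), `task`, `alt` (1 or 2), `position`
#'   (presentation order of the task), `form`, `size`, `color`, `copay_pln`.
#' @examples
#' design <- build_task_set(seed = 1)
#' dplyr::count(design, scenario)
#' @export
build_task_set <- function(scheme = attribute_scheme(),
                           n_tasks_per_scenario = 8L,
                           seed = 1L) {
  stopifnot(inherits(scheme, "attribute_scheme"),
            n_tasks_per_scenario >= 1L)
  profiles <- profile_grid(scheme)
  n_prof <- nrow(profiles)
  enc <- encode_profiles(profiles, scheme)
  XC <- cbind(contrast_matrix(enc, scheme), cost_eur = enc$cost_eur)
  identified <- function(pairs) {
    dX <- XC[pairs[, 1L], , drop = FALSE] - XC[pairs[, 2L], , drop = FALSE]
    per_scen <- n_tasks_per_scenario >= ncol(XC)
    if (per_scen) {
      idx <- seq_len(n_tasks_per_scenario)
      qr(dX[idx, , drop = FALSE])$rank == ncol(XC) &&
        qr(dX[-idx, , drop = FALSE])$rank == ncol(XC)
    } else if (nrow(dX) >= ncol(XC)) {
      qr(dX)$rank == ncol(XC)
    } else {
      TRUE
    }
  }
  withr::with_seed(seed, {
    n_tasks <- 2L * n_tasks_per_scenario
    repeat {
      pairs <- matrix(NA_integer_, nrow = n_tasks, ncol = 2L)
      seen <- character(0)
      k <- 1L
      while (k <= n_tasks) {
        p <- sort(sample.int(n_prof, 2L, replace = FALSE))
        key <- paste(p, collapse = "-")
        if (key %in% seen) next
        seen <- c(seen, key)
        # randomize which profile appears as alternative 1
        pairs[k, ] <- sample(p)
        k <- k + 1L
      }
      if (identified(pairs)) break
    }
    scenario <- rep(c("chronic", "short_term"), each = n_tasks_per_scenario)
    task <- rep(seq_len(n_tasks_per_scenario), times = 2L)
    # presentation rounds: one chronic + one short-term task, order randomized
    position <- integer(n_tasks)
    for (r in seq_len(n_tasks_per_scenario)) {
      slots <- c(2L * r - 1L, 2L * r)
      first_chronic <- sample(c(TRUE, FALSE), 1L)
      position[r] <- if (first_chronic) slots[1L] else slots[2L]
      position[n_tasks_per_scenario + r] <-
        if (first_chronic) slots[2L] else slots[1L]
    }
  })
  idx <- rep(seq_len(n_tasks), each = 2L)
  out <- tibble::tibble(
    scenario = scenario[idx],
    task     = task[idx],
    alt      = rep(1:2, times = n_tasks),
    position = position[idx],
    profiles[as.vector(t(pairs)), ]
  )
  dplyr::arrange(out, .data$position, .data$alt)
}
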