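#' Read and write long-format choice data
#'
#' Choice data are exchanged as plain CSV, one row per
#' respondent x scenario x task x alternative, with the header
#' `respondent_id,scenario,task,alt,form,size,color,copay_pln,chosen`
#' and optional per-respondent covariate columns `female,age,chronic_meds`.
#' `read_choice_data()` validates every structural invariant on read
#' (see [validate_choice_data()]); a write followed by a read reproduces the
#' dataset exactly, and writing the same dataset twice yields byte-identical
#' files.
#'
#' @param path File path.
#' @param data A choice dataset (tibble).
#' @param scheme An [attribute_scheme()] used for level validation.
#' @return `read_choice_data()` returns a validated tibble;
#'   `write_choice_data()` returns `path` invisibly.
#' @export
read_choice_data <- function(path, scheme = attribute_scheme()) {
  spec <- readr::cols(
    respondent_id = readr::col_integer(),
    scenario      = readr::col_character(),
    task          = readr::col_integer(),
    alt           = readr::col_integer(),
    form          = readr::col_character(),
    size          = readr::col_character(),
    color         = readr::col_character(),
    copay_pln     = readr::col_double(),
    chosen        = readr::col_integer(),
    .default      = readr::col_double()
  )
  data <- readr::read_csv(path, col_types = spec, progress = FALSE)
  validate_choice_data(data, scheme)
}

#' @rdname read_choice_data
#' @export
write_choice_data <- function(data, path, scheme = attribute_scheme()) {
  data <- validate_choice_data(data, scheme)
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Validate a long-format choice dataset
#'
#' Checks the structural invariants of forced-choice data: required columns
#' present; every attribute level listed in the scheme; `chosen` is 0/1 with
#' exactly one chosen row per respondent x scenario x task (forced choice, no
#' opt-out); exactly two alternatives per task that differ in at least one
#' attribute; covariates (if present) constant within respondent. Violations
#' are rejected with the offending row number.
#'
#' @inheritParams read_choice_data
#' @return The validated data, invisibly coerced to a tibble.
#' @export
validate_choice_data <- function(data, scheme = attribute_scheme()) {
  data <- tibble::as_tibble(data)
  need <- c("respondent_id", "scenario", "task", "alt",
            "form", "size", "color", "copay_pln", "chosen")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("choice data: missing column(s): ", paste(miss, collapse = ", ")))
  }
  bad <- !(data$scenario %in% c("chronic", "short_term"))
  if (any(bad)) {
    abort(sprintf("choice data: unknown scenario '%s' at row %d",
                  data$scenario[bad][1L], which(bad)[1L]))
  }
  for (a in c("form", "size", "color")) {
    bad <- !(data[[a]] %in% scheme$attributes[[a]])
    if (any(bad)) {
      abort(sprintf("choice data: unknown %s level '%s' at row %d",
                    a, as.character(data[[a]][bad][1L]), which(bad)[1L]))
    }
  }
  bad <- !(data$copay_pln %in% scheme$cost_levels_pln)
  if (any(bad)) {
    abort(sprintf("choice data: copayment %s PLN at row %d is not a design level (%s)",
                  format(data$copay_pln[bad][1L]), which(bad)[1L],
                  paste(scheme$cost_levels_pln, collapse = "/")))
  }
  bad <- !(data$chosen %in% c(0L, 1L))
  if (any(bad)) {
    abort(sprintf("choice data: chosen must be 0 or 1 (row %d)", which(bad)[1L]))
  }

  grp <- paste(data$respondent_id, data$scenario, data$task, sep = "\r")
  n_chosen <- tapply(data$chosen, grp, sum)
  if (any(n_chosen != 1L)) {
    off <- names(n_chosen)[n_chosen != 1L][1L]
    row <- which(grp == off)[1L]
    abort(sprintf(
      "choice data: task starting at row %d has %d chosen alternatives (exactly 1 required)",
      row, n_chosen[[off]]))
  }
  n_alt <- tapply(data$alt, grp, function(a) length(unique(a)))
  sz <- tapply(data$alt, grp, length)
  if (any(sz != 2L) || any(n_alt != 2L)) {
    off <- names(sz)[sz != 2L | n_alt != 2L][1L]
    abort(sprintf(
      "choice data: task starting at row %d must have exactly alternatives 1 and 2",
      which(grp == off)[1L]))
  }
  prof <- paste(data$form, data$size, data$color, data$copay_pln, sep = "\r")
  dup <- tapply(prof, grp, function(p) p[1L] == p[2L])
  if (any(dup)) {
    off <- names(dup)[dup][1L]
    abort(sprintf(
      "choice data: task starting at row %d presents two identical profiles",
      which(grp == off)[1L]))
  }
  for (cv in intersect(c("female", "age", "chronic_meds"), names(data))) {
    varying <- tapply(data[[cv]], data$respondent_id,
                      function(x) length(unique(x)) > 1L)
    if (any(varying)) {
      abort(sprintf("choice data: covariate '%s' varies within respondent %s",
                    cv, names(varying)[varying][1L]))
    }
  }
  data
}
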