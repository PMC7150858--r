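#' Attribute scheme for the drug-form choice experiment
#'
#' Defines the attribute/level universe of the experiment: medication form
#' (round tablet, long tablet, capsule -- tablet shape is not applicable to
#' capsules, so shape and form collapse into one 3-level attribute), size
#' (5 mm / 10 mm / 15 mm), color (white, yellow, blue, red) and the weekly
#' copayment in Polish zloty. The scheme fixes the dummy coding used by every
#' model in the package: each attribute's first level is the base and maps to
#' the all-zero code, giving exactly 7 dummy contrast columns
#' (`long_tablet`, `capsule`, `medium`, `large`, `yellow`, `blue`, `red`).
#' Cost enters all models in EUR (`copay_pln * pln_to_eur`) so that estimated
#' coefficients are directly interpretable as willingness to pay in EUR.
#'
#' @param pln_to_eur Conversion factor, EUR per PLN. Default 0.25.
#'
#' @return An object of class `attribute_scheme`: a list with elements
#'   `attributes` (named list of level vectors, base level first),
#'   `base_levels`, `contrasts` (the 7 dummy column names, in model order),
#'   `coding` (tibble mapping attribute/level to dummy column),
#'   `cost_levels_pln` and `pln_to_eur`.
#' @examples
#' sch <- attribute_scheme()
#' sch$contrasts
#' profile_grid(sch)
#' @export
attribute_scheme <- function(pln_to_eur = 0.25) {
  stopifnot(is.numeric(pln_to_eur), length(pln_to_eur) == 1L, pln_to_eur > 0)
  attributes <- list(
    form  = c("round_tablet", "long_tablet", "capsule"),
    size  = c("small", "medium", "large"),
    color = c("white", "yellow", "blue", "red")
  )
  coding <- purrr::imap_dfr(attributes, function(levels, attr) {
    tibble::tibble(
      attribute = attr,
      level     = levels,
      column    = c(NA_character_, levels[-1L])
    )
  })
  contrasts <- coding$column[!is.na(coding$column)]
  structure(
    list(
      attributes      = attributes,
      base_levels     = purrr::map_chr(attributes, 1L),
      contrasts       = contrasts,
      coding          = coding,
      cost_levels_pln = c(5, 10, 15, 20),
      pln_to_eur      = pln_to_eur
    ),
    class = "attribute_scheme"
  )
}

#' @export
print.attribute_scheme <- function(x, ...) {
  cat("<attribute_scheme>\n")
  for (a in names(x$attributes)) {
    cat(sprintf("  %-5s : %s (base: %s)\n", a,
                paste(x$attributes[[a]], collapse = ", "), x$base_levels[[a]]))
  }
  cat(sprintf("  copay : %s PLN (1 PLN = %.2f EUR)\n",
              paste(x$cost_levels_pln, collapse = "/"), x$pln_to_eur))
  cat(sprintf("  %d dummy contrasts: %s\n", length(x$contrasts),
              paste(x$contrasts, collapse = ", ")))
  invisible(x)
}

#' Enumerate the full factorial of choice profiles
#'
#' Every distinct combination of form, size, color and copayment level under
#' a scheme; with the default scheme, 3 x 3 x 4 x 4 = 144 profiles.
#'
#' @param scheme An [attribute_scheme()].
#' @return A tibble with columns `form`, `size`, `color`, `copay_pln`,
#'   one row per profile.
#' @export
profile_grid <- function(scheme = attribute_scheme()) {
  stopifnot(inherits(scheme, "attribute_scheme"))
  tidyr::expand_grid(
    form      = scheme$attributes$form,
    size      = scheme$attributes$size,
    color     = scheme$attributes$color,
    copay_pln = scheme$cost_levels_pln
  )
}

#' Dummy-code choice profiles
#'
#' Adds the scheme's 7 contrast columns (0/1) and the EUR cost column to a
#' data frame of profiles. Base levels encode to all zeros; `cost_eur` is
#' `copay_pln * pln_to_eur`.
#'
#' @param data A data frame with columns `form`, `size`, `color`, `copay_pln`.
#' @param scheme An [attribute_scheme()].
#' @return `data` with the contrast columns and `cost_eur` appended.
#' @examples
#' encode_profiles(profile_grid()[1:3, ])
#' @export
encode_profiles <- function(data, scheme = attribute_scheme()) {
  stopifnot(is.data.frame(data), inherits(scheme, "attribute_scheme"))
  need <- c("form", "size", "color", "copay_pln")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("encode_profiles(): missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  for (a in c("form", "size", "color")) {
    bad <- !(data[[a]] %in% scheme$attributes[[a]])
    if (any(bad)) {
      abort(sprintf(
        "encode_profiles(): unknown level '%s' for attribute '%s' (first at row %d)",
        as.character(data[[a]][bad][1L]), a, which(bad)[1L]))
    }
  }
  bad <- !(data$copay_pln %in% scheme$cost_levels_pln)
  if (any(bad)) {
    abort(sprintf(
      "encode_profiles(): unknown level '%s' for attribute 'copay_pln' (first at row %d)",
      as.character(data$copay_pln[bad][1L]), which(bad)[1L]))
  }
  out <- data
  codes <- scheme$coding[!is.na(scheme$coding$column), ]
  for (i in seq_len(nrow(codes))) {
    out[[codes$column[i]]] <-
      as.integer(data[[codes$attribute[i]]] == codes$level[i])
  }
  out$cost_eur <- data$copay_pln * scheme$pln_to_eur
  out
}

#' Extract the design matrix from an encoded dataset
#'
#' @param data Encoded data (see [encode_profiles()]).
#' @param scheme An [attribute_scheme()].
#' @return Numeric matrix with the scheme's 7 contrast columns.
#' @keywords internal
contrast_matrix <- function(data, scheme = attribute_scheme()) {
  as.matrix(data[, scheme$contrasts, drop = FALSE])
}
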