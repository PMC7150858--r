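# Sobol low-discrepancy sequences with random digital-shift scrambling.
#
# Direction numbers are the standard Joe-Kuo (D6) primitive-polynomial
# parameters for dimensions 2..13; dimension 1 is the van der Corput
# sequence in base 2. Integers are built at 30-bit precision so everything
# stays inside R's 32-bit signed integer arithmetic.

.sobol_bits <- 30L

# Joe-Kuo parameters: s = polynomial degree, a = interior coefficient bits,
# m = initial direction integers (odd).
.sobol_params <- list(
  list(s = 1L, a = 0L,  m = c(1L)),
  list(s = 2L, a = 1L,  m = c(1L, 3L)),
  list(s = 3L, a = 1L,  m = c(1L, 3L, 1L)),
  list(s = 3L, a = 2L,  m = c(1L, 1L, 1L)),
  list(s = 4L, a = 1L,  m = c(1L, 1L, 3L, 3L)),
  list(s = 4L, a = 4L,  m = c(1L, 3L, 5L, 13L)),
  list(s = 5L, a = 2L,  m = c(1L, 1L, 5L, 5L, 17L)),
  list(s = 5L, a = 4L,  m = c(1L, 1L, 5L, 5L, 5L)),
  list(s = 5L, a = 7L,  m = c(1L, 1L, 7L, 11L, 19L)),
  list(s = 5L, a = 11L, m = c(1L, 1L, 5L, 1L, 1L)),
  list(s = 5L, a = 13L, m = c(1L, 1L, 1L, 3L, 11L)),
  list(s = 5L, a = 14L, m = c(1L, 3L, 5L, 5L, 31L))
)

# direction integers v_1..v_bits for one dimension (already scaled by
# 2^(bits - j))
sobol_directions <- function(dim, bits = .sobol_bits) {
  if (dim == 1L) {
    return(bitwShiftL(1L, bits - seq_len(bits)))
  }
  p <- .sobol_params[[dim - 1L]]
  s <- p$s
  m <- integer(bits)
  m[seq_len(min(s, bits))] <- p$m[seq_len(min(s, bits))]
  if (bits > s) {
    a_bits <- as.integer(bitwAnd(bitwShiftR(p$a, (s - 2L):0L), 1L))
    for (j in (s + 1L):bits) {
      v <- bitwXor(m[j - s], bitwShiftL(m[j - s], s))
      if (s > 1L) {
        for (k in seq_len(s - 1L)) {
          if (a_bits[k] == 1L) v <- bitwXor(v, bitwShiftL(m[j - k], k))
        }
      }
      m[j] <- v
    }
  }
  bitwShiftL(m, bits - seq_len(bits))
}

#' Sobol quasi-Monte-Carlo points
#'
#' Generates the first `n` points of the Sobol sequence in `(0, 1)^dims`
#' (up to 13 dimensions), optionally randomized by a digital shift: each
#' dimension's integer representation is XOR-ed with a random 30-bit
#' integer keyed by `scramble_seed`, which preserves the digital-net
#' equidistribution while randomizing point locations. A half-cell offset
#' keeps all coordinates strictly inside (0, 1).
#'
#' @param n Number of points.
#' @param dims Number of dimensions (1..13).
#' @param scramble_seed Integer seed for the digital shift, or `NULL` for
#'   the unscrambled sequence.
#' @return An `n` x `dims` numeric matrix with entries in (0, 1).
#' @examples
#' head(sobol_points(8, 2))
#' @export
sobol_points <- function(n, dims, scramble_seed = NULL) {
  stopifnot(n >= 1L, dims >= 1L, dims <= length(.sobol_params) + 1L)
  if (n >= 2^.sobol_bits) abort("sobol_points(): n too large for 30-bit precision")
  idx <- seq_len(n) - 1L
  gray <- bitwXor(idx, bitwShiftR(idx, 1L))
  shifts <- if (!is.null(scramble_seed)) {
    withr::with_seed(scramble_seed, {
      # assemble 30 random bits per dimension
      vapply(seq_len(dims), function(d) {
        bits <- sample(c(0L, 1L), .sobol_bits, replace = TRUE)
        sum(bits * bitwShiftL(1L, seq_len(.sobol_bits) - 1L))
      }, integer(1))
    })
  } else {
    integer(dims)
  }
  out <- matrix(0, nrow = n, ncol = dims)
  denom <- 2^.sobol_bits
  nbit <- max(1L, ceiling(log2(max(2, n))))
  for (d in seq_len(dims)) {
    v <- sobol_directions(d)
    x <- integer(n)
    for (b in seq_len(min(nbit, .sobol_bits))) {
      on <- bitwAnd(gray, bitwShiftL(1L, b - 1L)) != 0L
      if (any(on)) x[on] <- bitwXor(x[on], v[b])
    }
    x <- bitwXor(x, shifts[d])
    out[, d] <- (x + 0.5) / denom
  }
  out
}

#' Mixed logit simulation specification
#'
#' Settings for the maximum simulated likelihood estimator: which attribute
#' contrasts carry random (normally distributed) WTP coefficients, the number
#' of draws per respondent, and the draw scheme -- scrambled Sobol
#' (quasi-Monte-Carlo, the default) or plain pseudo-random normals (mainly
#' useful as an independent cross-check).
#'
#' @param n_draws Draws per respondent (default 10000; desk-scale fits
#'   typically use 500).
#' @param draw_scheme `"scrambled_sobol"` or `"pseudo_random"`.
#' @param scramble_seed Integer seed for draw generation.
#' @param random_attrs Character vector of contrast names with random
#'   coefficients; default all 7.
#' @param maxit,reltol Optimizer settings passed to [stats::optim()] (BFGS).
#' @param start Optional named start-value list
#'   (`wtp_mean`, `wtp_sd`, `scale_mu`, `scale_sigma`).
#' @return An object of class `mxl_spec`.
#' @export
mxl_spec <- function(n_draws = 10000L,
                     draw_scheme = c("scrambled_sobol", "pseudo_random"),
                     scramble_seed = 1L,
                     random_attrs = attribute_scheme()$contrasts,
                     maxit = 400L, reltol = 1e-9, start = NULL) {
  draw_scheme <- match.arg(draw_scheme)
  stopifnot(n_draws >= 1L)
  random_attrs <- match.arg(random_attrs, attribute_scheme()$contrasts,
                            several.ok = TRUE)
  structure(
    list(n_draws = as.integer(n_draws), draw_scheme = draw_scheme,
         scramble_seed = as.integer(scramble_seed),
         random_attrs = random_attrs,
         maxit = as.integer(maxit), reltol = reltol, start = start),
    class = "mxl_spec"
  )
}

#' Generate per-respondent draw blocks
#'
#' Standard-normal deviates used to simulate the mixing distribution: one
#' `n_draws` x (`length(random_attrs)` + 1) block per respondent (the last
#' column drives the lognormal scale). Under the Sobol scheme, respondent i
#' receives the i-th contiguous block of the scrambled sequence mapped
#' through the standard-normal inverse CDF, so blocks are distinct across
#' respondents and identical across calls with the same spec.
#'
#' @param spec An [mxl_spec()].
#' @param n_respondents Number of respondents.
#' @return A list of `n_respondents` matrices.
#' @export
make_draws <- function(spec, n_respondents) {
  stopifnot(inherits(spec, "mxl_spec"), n_respondents >= 1L)
  dims <- length(spec$random_attrs) + 1L
  D <- spec$n_draws
  total <- n_respondents * D
  U <- switch(spec$draw_scheme,
    scrambled_sobol = sobol_points(total, dims, scramble_seed = spec$scramble_seed),
    pseudo_random = withr::with_seed(spec$scramble_seed,
                                     matrix(runif(total * dims), nrow = total))
  )
  Z <- qnorm(U)
  lapply(seq_len(n_respondents), function(i) {
    Z[((i - 1L) * D + 1L):(i * D), , drop = FALSE]
  })
}
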