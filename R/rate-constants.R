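#' Rate constants of the aggregation model
#'
#' Bundles the oligomer size `n` and the five kinetic constants of the
#' cross-linking reaction scheme. Time is dimensionless throughout; the
#' free-particle pools are assumed abundant, so binding of a free
#' cross-linker and of a free oligomer enter as the pseudo-first-order
#' constants `kappa1 = kappa1' * [Ubi]` and `kappa2 = kappa2' * [p62_n]`.
#'
#' The symbol for the compactification constant is level-dependent: the
#' continuum ODE system uses `kappa3 = kappa3' * k0`, where `k0` is the
#' typical aggregate size of the scaling, while the discrete reaction
#' scheme uses the second-order constant `kappa3'` itself. A
#' `rate_constants` object stores a single `kappa3` field whose meaning is
#' fixed by which functions consume it; [continuum_params()] and
#' [discrete_params()] convert explicitly, never implicitly.
#'
#' @param n Integer oligomer size (ubiquitin-binding sites per p62
#'   oligomer), at least 3.
#' @param kappa1 Rate of adding a free cross-linker per free binding site
#'   (per time).
#' @param kappa2 Rate of adding a free oligomer per one-hand bound
#'   cross-linker (per time).
#' @param kappa3 Compactification constant; continuum-scaled (per time) for
#'   the ODE system, second-order for the discrete scheme.
#' @param kappa_m1 Unbinding rate of a one-hand bound cross-linker (per
#'   time).
#' @param kappa_m Cross-link breaking rate per both-hand bound cross-linker
#'   (per time).
#' @param k0 Optional typical-size scale relating the discrete and
#'   continuum levels.
#'
#' @return An object of class `rate_constants` (a named list).
#' @examples
#' rate_constants(n = 5, kappa1 = 1, kappa2 = 1, kappa3 = 1,
#'                kappa_m1 = 1, kappa_m = 0.6)
#' @export
rate_constants <- function(n, kappa1, kappa2, kappa3, kappa_m1, kappa_m,
                           k0 = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 3 || n != round(n)) {
    stop("`n` must be a single integer >= 3", call. = FALSE)
  }
  kappas <- c(kappa1 = kappa1, kappa2 = kappa2, kappa3 = kappa3,
              kappa_m1 = kappa_m1, kappa_m = kappa_m)
  if (!is.numeric(kappas) || length(kappas) != 5L || anyNA(kappas) ||
      any(kappas < 0)) {
    stop("all five rate constants must be finite and >= 0", call. = FALSE)
  }
  if (!is.null(k0)) {
    stopifnot(is.numeric(k0), length(k0) == 1L, k0 > 0)
  }
  structure(
    list(n = as.integer(n), kappa1 = kappa1, kappa2 = kappa2,
         kappa3 = kappa3, kappa_m1 = kappa_m1, kappa_m = kappa_m, k0 = k0),
    class = "rate_constants"
  )
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("<rate_constants>  n =", x$n, "\n")
  cat(sprintf("  kappa1 = %g  kappa2 = %g  kappa3 = %g\n",
              x$kappa1, x$kappa2, x$kappa3))
  cat(sprintf("  kappa_m1 = %g  kappa_m = %g", x$kappa_m1, x$kappa_m))
  if (!is.null(x$k0)) cat(sprintf("  (k0 = %g)", x$k0))
  cat("\n")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.rate_constants <- function(x, ...) {
  tibble::tibble(n = x$n, kappa1 = x$kappa1, kappa2 = x$kappa2,
                 kappa3 = x$kappa3, kappa_m1 = x$kappa_m1,
                 kappa_m = x$kappa_m,
                 k0 = if (is.null(x$k0)) NA_real_ else x$k0)
}

#' Convert between discrete and continuum compactification constants
#'
#' In the large-aggregate scaling the state is divided by a typical size
#' `k0` and the second-order compactification constant `kappa3'` is
#' replaced by `kappa3 = kappa3' * k0`. These helpers perform that
#' conversion explicitly and record `k0` on the result.
#'
#' @param params A [rate_constants()] object whose `kappa3` is on the other
#'   level (discrete for `continuum_params()`, continuum for
#'   `discrete_params()`).
#' @param k0 Positive typical-size scale.
#' @return A `rate_constants` object on the requested level.
#' @export
continuum_params <- function(params, k0) {
  stopifnot(inherits(params, "rate_constants"), is.numeric(k0), k0 > 0)
  rate_constants(params$n, params$kappa1, params$kappa2,
                 params$kappa3 * k0, params$kappa_m1, params$kappa_m,
                 k0 = k0)
}

#' @rdname continuum_params
#' @export
discrete_params <- function(params, k0) {
  stopifnot(inherits(params, "rate_constants"), is.numeric(k0), k0 > 0)
  rate_constants(params$n, params$kappa1, params$kappa2,
                 params$kappa3 / k0, params$kappa_m1, params$kappa_m,
                 k0 = k0)
}
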