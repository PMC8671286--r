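#' Reference parameter sets spanning the three regimes
#'
#' The simulation conditions used throughout the package's examples and
#' tests: unit rate constants except the cross-link breaking rate
#' `kappa_m`, oligomer size `n = 5`, initial state `(p, q, r) = (2, 4, 3)`.
#' `kappa_m = 0.6` gives a finite limiting size, `0.93` dissolution,
#' `0.2` unbounded growth; `kappa_m = 0` is the cross-link-conserving
#' case. Each entry carries its closed-form expected outputs (regime
#' parameter, steady state, growth coefficients or limits), regenerated
#' from the formulas at call time.
#'
#' @return A named list of fixtures; each element has `params`, `init`,
#'   and an `expected` list.
#' @examples
#' regime_fixtures()$finite_size$expected$alpha_bar
#' @export
regime_fixtures <- function() {
  init <- c(p = 2, q = 4, r = 3)
  mk <- function(km) rate_constants(5, 1, 1, 1, 1, km)
  fin <- mk(0.6); ext <- mk(0.93); gro <- mk(0.2); kz <- mk(0)
  list(
    finite_size = list(
      name = "finite_size", params = fin, init = init,
      expected = list(alpha_bar = alpha_bar(fin), regime = "finite_size",
                      steady_state = steady_state(fin))
    ),
    extinction = list(
      name = "extinction", params = ext, init = init,
      expected = list(alpha_bar = alpha_bar(ext), regime = "extinction",
                      steady_state = NULL)
    ),
    unbounded_growth = list(
      name = "unbounded_growth", params = gro, init = init,
      expected = list(alpha_bar = alpha_bar(gro),
                      regime = "unbounded_growth",
                      coefficients = asymptotic_coefficients(gro))
    ),
    kappa_zero = list(
      name = "kappa_zero", params = kz, init = init,
      expected = list(limits = kappa_zero_limits(kz))
    )
  )
}

#' Random admissible discrete aggregate states
#'
#' Uniform rejection sampling of admissible `(i, j, k)` triplets with
#' `k` between 2 and `k_max`, used to seed stochastic-simulation tests.
#'
#' @param n_states Number of states to draw.
#' @param n Oligomer size.
#' @param k_max Largest oligomer count.
#' @param seed Integer seed.
#' @return A tibble with columns `i, j, k`.
#' @export
random_admissible_states <- function(n_states, n, k_max = 10L, seed = 1L) {
  set.seed(as.integer(seed))
  out <- matrix(NA_integer_, nrow = 0L, ncol = 3L)
  while (nrow(out) < n_states) {
    k <- sample(2:k_max, 1L)
    j <- sample((k - 1):floor(n * k / 2), 1L)
    imax <- n * k - 2L * j
    i <- if (imax > 0L) sample(0:imax, 1L) else 0L
    if (is_admissible(i, j, k, n)) out <- rbind(out, c(i, j, k))
  }
  tibble::tibble(i = out[, 1L], j = out[, 2L], k = out[, 3L])
}

#' Enumerate all admissible discrete states up to a size cap
#'
#' Brute-force enumeration of every admissible `(i, j, k)` with
#' `2 <= k <= k_max`, the reference set for exhaustive property checks on
#' propensities and detachment counts.
#'
#' @param n Oligomer size.
#' @param k_max Largest oligomer count.
#' @return A tibble with columns `i, j, k`.
#' @export
enumerate_admissible <- function(n, k_max) {
  grid <- tidyr::expand_grid(
    k = 2:k_max,
    j = 0:floor(n * k_max / 2),
    i = 0:(n * k_max)
  )
  grid <- grid[is_admissible(grid$i, grid$j, grid$k, n), c("i", "j", "k")]
  tibble::as_tibble(grid)
}

#' Write the reference fixtures to disk
#'
#' Emits the [regime_fixtures()] parameter sets with their closed-form
#' expected values as JSON, plus seeded random admissible discrete states
#' as CSV.
#'
#' @param out_dir Writable directory (created if absent).
#' @param seed Seed for the random discrete states.
#' @return `out_dir`, invisibly.
#' @export
generate_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fx <- regime_fixtures()
  ser <- purrr::map(fx, function(f) {
    list(params = unclass(f$params)[c("n", "kappa1", "kappa2", "kappa3",
                                      "kappa_m1", "kappa_m")],
         init = as.list(f$init),
         expected = purrr::map(f$expected, function(e) {
           if (inherits(e, "kappa_zero_limits")) unclass(e)
           else if (is.data.frame(e)) as.list(e)
           else e
         }))
  })
  jsonlite::write_json(ser, file.path(out_dir, "regime_fixtures.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  states <- random_admissible_states(10L, n = 5L, k_max = 8L, seed = seed)
  readr::write_csv(states, file.path(out_dir, "ssa_states.csv"))
  invisible(out_dir)
}
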