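#' Rate constants from concentrations and a dissociation constant
#'
#' Under the symmetry assumptions used for comparison with aggregation
#' experiments — equal binding constants (`kappa1' = kappa2'`) and equal
#' unbinding constants (`kappa_m1 = kappa_m`) — the model is parametrised
#' by the free-particle concentrations and one dissociation constant
#' `K_d = kappa_m1 / kappa1'` (in concentration units):
#' `kappa1 = kappa1' [Ubi]`, `kappa2 = kappa1' [p62_n]`,
#' `kappa_m1 = kappa_m = kappa1' K_d`. The regime parameter is invariant
#' under rescaling `kappa1'`, which only sets the time unit.
#'
#' @param ubi Free cross-linker concentration (uM).
#' @param p62n Free oligomer concentration (uM); note
#'   `[p62_n] = [p62] / n` when the monomer concentration is measured.
#' @param kd Dissociation constant (uM).
#' @param n Oligomer size.
#' @param kappa1_prime Binding rate constant (per uM per time); sets the
#'   time unit only.
#' @param kappa3 Compactification constant (continuum level).
#' @return A [rate_constants()] object.
#' @export
params_from_concentrations <- function(ubi, p62n, kd, n,
                                       kappa1_prime = 1, kappa3 = 1) {
  stopifnot(ubi >= 0, p62n >= 0, kd >= 0, kappa1_prime > 0, kappa3 > 0)
  rate_constants(n,
                 kappa1 = kappa1_prime * ubi,
                 kappa2 = kappa1_prime * p62n,
                 kappa3 = kappa3,
                 kappa_m1 = kappa1_prime * kd,
                 kappa_m = kappa1_prime * kd)
}

# quadratic coefficients (a K^2 + b K - c = 0) of the onset relations
onset_quadratic <- function(ubi, n, branch) {
  if (branch == "alpha1") {
    list(a = (2 * n - 3) / (n - 2)^2, b = ubi / (n - 2))
  } else {
    list(a = n * (n^2 + n - 4) / (4 * (n - 2)^2),
         b = n * ubi / (2 * (n - 2)))
  }
}

#' Oligomer concentration on a regime boundary
#'
#' The onset relations in concentration space, solved for `[p62_n]`:
#' stability onset (`alpha_bar = 1`)
#' \deqn{[p62_n][Ubi] = \frac{K_d}{n-2}\left([Ubi] +
#'   \frac{(2n-3)K_d}{n-2}\right),}
#' growth onset (`alpha_bar = 0`)
#' \deqn{[p62_n][Ubi] = \frac{n K_d}{2(n-2)}\left([Ubi] +
#'   \frac{(n^2+n-4)K_d}{2(n-2)}\right).}
#' As `[Ubi] -> Inf` the branches flatten to the horizontal asymptotes
#' `K_d/(n-2)` and `n K_d/(2(n-2))`: below those oligomer concentrations
#' aggregates are unstable (respectively never grow) no matter how much
#' cross-linker is present.
#'
#' @param ubi Cross-linker concentration (uM); vectorised.
#' @param kd Dissociation constant (uM).
#' @param n Oligomer size.
#' @param branch `"alpha1"` (stability onset) or `"alpha0"` (growth
#'   onset).
#' @return `[p62_n]` on the selected boundary (uM).
#' @export
boundary_p62 <- function(ubi, kd, n, branch = c("alpha1", "alpha0")) {
  branch <- match.arg(branch)
  stopifnot(all(ubi > 0), kd > 0)
  if (branch == "alpha1") {
    kd / ((n - 2) * ubi) * (ubi + (2 * n - 3) * kd / (n - 2))
  } else {
    n * kd / (2 * (n - 2) * ubi) *
      (ubi + (n^2 + n - 4) * kd / (2 * (n - 2)))
  }
}

#' Dissociation constant from aggregation-onset concentrations
#'
#' Treats the given `([Ubi], [p62_n])` as a point on the selected regime
#' boundary and solves the onset relation for `K_d`: the unique positive
#' root of the implied quadratic, evaluated in the cancellation-free form
#' `K = 2c / (b + sqrt(b^2 + 4 a c))`.
#'
#' @param ubi Cross-linker concentration at onset (uM).
#' @param p62n Oligomer concentration (uM).
#' @param n Oligomer size.
#' @param branch `"alpha1"` if the onset marks the appearance of stable
#'   finite aggregates, `"alpha0"` if it marks unbounded growth.
#' @return `K_d` in uM (0 when `p62n = 0`).
#' @examples
#' estimate_kd(ubi = 0.6, p62n = 0.4, n = 5, branch = "alpha1")  # ~0.44
#' @export
estimate_kd <- function(ubi, p62n, n, branch = c("alpha1", "alpha0")) {
  branch <- match.arg(branch)
  stopifnot(ubi > 0, p62n >= 0)
  if (p62n == 0) return(0)
  co <- onset_quadratic(ubi, n, branch)
  cc <- p62n * ubi
  disc <- co$b^2 + 4 * co$a * cc
  stopifnot(disc > 0)
  2 * cc / (co$b + sqrt(disc))
}

#' Dissociation-constant scan over oligomer sizes
#'
#' Repeats [estimate_kd()] on both onset branches for a range of oligomer
#' sizes at fixed concentrations. For large `n` the stability-onset
#' estimate grows like `n^(1/2)` while the growth-onset estimate decays
#' like `n^(-1/2)`.
#'
#' @param ubi,p62n Onset concentrations (uM).
#' @param n_range Integer vector of oligomer sizes (within 3..4096).
#' @return A tibble with columns `n`, `branch`, `kd`.
#' @export
kd_vs_n_scan <- function(ubi, p62n, n_range) {
  stopifnot(all(n_range >= 3), all(n_range <= 4096))
  tidyr::expand_grid(n = as.integer(n_range),
                     branch = c("alpha1", "alpha0")) |>
    dplyr::mutate(kd = purrr::map2_dbl(.data$n, .data$branch,
                                       ~ estimate_kd(ubi, p62n, .x, .y)))
}

#' Regime phase diagram in concentration space
#'
#' Labels each `([Ubi], [p62_n])` grid cell with its predicted long-time
#' regime under the symmetric-rate-constant parametrisation at fixed
#' `K_d`, together with the two analytic boundary branches. Moving up any
#' vertical line (more oligomer at fixed cross-linker) the regimes are
#' ordered extinction, finite size, unbounded growth.
#'
#' @param kd Dissociation constant (uM).
#' @param n Oligomer size.
#' @param ubi_grid,p62_grid Positive concentration grids (uM).
#' @return A list of class `p62_phase_diagram` with elements `grid` (a
#'   tibble `ubi, p62n, alpha_bar, regime, boundary`) and `boundaries` (a
#'   tibble `ubi, p62n_alpha1, p62n_alpha0`).
#' @export
phase_diagram <- function(kd, n, ubi_grid, p62_grid) {
  stopifnot(kd > 0, all(ubi_grid > 0), all(p62_grid > 0))
  grid <- tidyr::expand_grid(ubi = ubi_grid, p62n = p62_grid) |>
    dplyr::mutate(
      report = purrr::map2(.data$ubi, .data$p62n, function(u, p) {
        glance(classify_regime(params_from_concentrations(u, p, kd, n)))
      })
    ) |>
    tidyr::unnest("report")
  boundaries <- tibble::tibble(
    ubi = ubi_grid,
    p62n_alpha1 = boundary_p62(ubi_grid, kd, n, "alpha1"),
    p62n_alpha0 = boundary_p62(ubi_grid, kd, n, "alpha0")
  )
  structure(list(grid = grid, boundaries = boundaries,
                 kd = kd, n = n),
            class = "p62_phase_diagram")
}

#' @export
print.p62_phase_diagram <- function(x, ...) {
  cat(sprintf("<p62_phase_diagram>  n = %d, K_d = %g uM, %d cells\n",
              x$n, x$kd, nrow(x$grid)))
  print(table(x$grid$regime))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.p62_phase_diagram <- function(object, ...) {
  long <- tidyr::pivot_longer(object$boundaries,
                              cols = c("p62n_alpha1", "p62n_alpha0"),
                              names_to = "branch", values_to = "p62n")
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$ubi, y = .data$p62n)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$regime)) +
    ggplot2::geom_line(data = long,
                       ggplot2::aes(linetype = .data$branch),
                       colour = "black") +
    ggplot2::labs(x = "[Ubi] (uM)", y = "[p62_n] (uM)",
                  fill = "regime", linetype = NULL) +
    ggplot2::theme_minimal()
}
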