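#' Detachment probability in the continuum limit
#'
#' Conditional probability that breaking a cross-link detaches a whole
#' oligomer from the aggregate, as a function of the scaled both-hand
#' bound count `q` and oligomer count `r`:
#' `alpha(q, r) = (n r - 2 q) / ((n - 2) r)`.
#' It is 1 for a chain-like aggregate (`q = r`) and 0 for a fully packed
#' one (`2 q = n r`); admissibility keeps it in `[0, 1]`.
#'
#' @param q Scaled count of both-hand bound cross-linkers (>= r).
#' @param r Scaled count of p62 oligomers (> 0).
#' @param n Oligomer size.
#' @return `alpha` in `[0, 1]`, vectorised over `q` and `r`.
#' @examples
#' alpha_continuum(q = 1, r = 1, n = 5)    # chain: 1
#' alpha_continuum(q = 2.5, r = 1, n = 5)  # fully packed: 0
#' @export
alpha_continuum <- function(q, r, n) {
  if (any(r <= 0)) stop("`r` must be positive", call. = FALSE)
  bad <- 2 * q > n * r + 1e-12 * pmax(1, n * r) | q < r - 1e-12 * pmax(1, r)
  if (any(bad)) {
    stop("inadmissible (q, r): need r <= q <= n r / 2", call. = FALSE)
  }
  pmin(1, pmax(0, (n * r - 2 * q) / ((n - 2) * r)))
}

check_admissible_continuum <- function(p, q, r, n, tol = 1e-9) {
  scale <- max(1, p, q, r)
  if (anyNA(c(p, q, r))) stop("state contains NA", call. = FALSE)
  if (p < -tol * scale || q < -tol * scale || r < -tol * scale) {
    stop("inadmissible state: negative component", call. = FALSE)
  }
  if (r <= 0 && (p > tol * scale || q > tol * scale)) {
    stop("inadmissible state: r = 0 with (p, q) != (0, 0)", call. = FALSE)
  }
  s <- n * r - p - 2 * q
  if (s < -tol * scale) {
    stop("inadmissible state: free-site count n r - p - 2 q < 0",
         call. = FALSE)
  }
  if (q < r - tol * scale) {
    stop("inadmissible state: connectivity requires q >= r", call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct an admissible continuum state
#'
#' Validates the continuum admissibility conditions
#' `s = n r - p - 2 q >= 0` and `q >= r` strictly (no silent repair) and
#' returns a one-row tibble with the derived free-site count `s` and
#' connectivity surplus `gap = q - r`.
#'
#' @param p,q,r Scaled counts of one-hand bound cross-linkers, both-hand
#'   bound cross-linkers and oligomers.
#' @param n Oligomer size.
#' @return A one-row tibble with columns `p, q, r, s, gap`.
#' @export
continuum_state <- function(p, q, r, n) {
  check_admissible_continuum(p, q, r, n, tol = 0)
  tibble::tibble(p = p, q = q, r = r, s = n * r - p - 2 * q, gap = q - r)
}

#' Auxiliary propagated quantities
#'
#' The free-site count `s = n r - p - 2 q` and the connectivity surplus
#' `gap = q - r`. Both are nonnegative on admissible states and stay so
#' along solutions (their evolution equations have nonnegative inflow at
#' the boundary).
#'
#' @inheritParams continuum_state
#' @return A tibble with columns `s` and `gap`, vectorised over the state.
#' @export
auxiliary_quantities <- function(p, q, r, n) {
  tibble::tibble(s = n * r - p - 2 * q, gap = q - r)
}

#' Right-hand side of the continuum aggregation ODE system
#'
#' Mass-action rates of change of `(p, q, r)`:
#' \deqn{\dot p = (\kappa_1 - \kappa_3 p) s
#'   + \kappa_- q (1 - (n-1) p / ((n-2) r)) - (\kappa_2 + \kappa_{-1}) p}
#' \deqn{\dot q = \kappa_2 p + \kappa_3 p s - \kappa_- q}
#' \deqn{\dot r = \kappa_2 p - \kappa_- q \alpha(q, r)}
#' with `s = n r - p - 2 q`. The right-hand side is undefined at `r = 0`
#' but tends to `(0, 0, 0)` along admissible states approaching the
#' origin, which is therefore treated as a steady state.
#'
#' @param p,q,r Admissible continuum state with `r > 0` (or the origin).
#' @param params A [rate_constants()] object (continuum-level `kappa3`).
#' @return Named numeric vector `c(dp, dq, dr)`.
#' @examples
#' pars <- rate_constants(5, 1, 1, 1, 1, 1)
#' aggregate_rhs(0, 1, 1, pars)  # c(4, -1, -1)
#' @export
aggregate_rhs <- function(p, q, r, params) {
  stopifnot(inherits(params, "rate_constants"))
  n <- params$n
  if (r <= 0) {
    if (p == 0 && q == 0) return(c(dp = 0, dq = 0, dr = 0))
    stop("r = 0 with (p, q) != (0, 0) is inadmissible", call. = FALSE)
  }
  check_admissible_continuum(p, q, r, n)
  s <- n * r - p - 2 * q
  # clip only round-off excursions outside [0, 1]
  a <- min(1, max(0, (n * r - 2 * q) / ((n - 2) * r)))
  dp <- (params$kappa1 - params$kappa3 * p) * s +
    params$kappa_m * q * (1 - (n - 1) * p / ((n - 2) * r)) -
    (params$kappa2 + params$kappa_m1) * p
  dq <- params$kappa2 * p + params$kappa3 * p * s - params$kappa_m * q
  dr <- params$kappa2 * p - params$kappa_m * q * a
  c(dp = dp, dq = dq, dr = dr)
}

rhs_desolve <- function(t, y, parms) {
  n <- parms$n
  p <- y[[1L]]; q <- y[[2L]]; r <- y[[3L]]
  s <- n * r - p - 2 * q
  a <- min(1, max(0, (n * r - 2 * q) / ((n - 2) * r)))
  dp <- (parms$kappa1 - parms$kappa3 * p) * s +
    parms$kappa_m * q * (1 - (n - 1) * p / ((n - 2) * r)) -
    (parms$kappa2 + parms$kappa_m1) * p
  dq <- parms$kappa2 * p + parms$kappa3 * p * s - parms$kappa_m * q
  dr <- parms$kappa2 * p - parms$kappa_m * q * a
  list(c(dp, dq, dr))
}

#' Integrate the continuum aggregation model
#'
#' Solves the initial value problem for `(p, q, r)` with an adaptive
#' stiff-capable integrator (`deSolve`'s `lsodar`). Solutions exist
#' globally and remain admissible; integration stops early only when the
#' trajectory enters a small neighbourhood of the origin (complete
#' dissolution), where the vector field degenerates.
#'
#' @param params A [rate_constants()] object (continuum-level `kappa3`).
#' @param init Named numeric `c(p = , q = , r = )`, admissible with
#'   `r > 0`.
#' @param t_end Final time (> 0).
#' @param times Optional output grid (strictly increasing, starting at 0);
#'   defaults to 401 equispaced points.
#' @param rtol,atol Relative and absolute integration tolerances.
#' @param origin_eps Radius of the extinction neighbourhood: the run stops,
#'   flagged `terminated_at_origin`, once `r < origin_eps` (admissibility
#'   then forces `p` and `q` to the same scale).
#' @return A tibble of class `p62_trajectory` with columns
#'   `t, p, q, r, s, gap`, and attributes `params`,
#'   `terminated_at_origin` (logical) and `extinction_time` (or `NA`).
#' @examples
#' pars <- rate_constants(5, 1, 1, 1, 1, 0.6)
#' traj <- integrate_aggregate(pars, c(p = 2, q = 4, r = 3), t_end = 50)
#' tail(traj)
#' @export
integrate_aggregate <- function(params, init, t_end, times = NULL,
                                rtol = 1e-8, atol = 1e-10,
                                origin_eps = 1e-10) {
  stopifnot(inherits(params, "rate_constants"), t_end > 0)
  init <- c(p = unname(init[["p"]]), q = unname(init[["q"]]),
            r = unname(init[["r"]]))
  if (init[["r"]] <= 0) stop("initial state must have r > 0", call. = FALSE)
  check_admissible_continuum(init[["p"]], init[["q"]], init[["r"]],
                             params$n, tol = 0)
  if (is.null(times)) times <- seq(0, t_end, length.out = 401L)
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing and start at 0",
         call. = FALSE)
  }
  rootfun <- function(t, y, parms) y[[3L]] - origin_eps
  sol <- deSolve::lsodar(
    y = init, times = times, func = rhs_desolve, parms = params,
    rtol = rtol, atol = atol, rootfunc = rootfun, maxsteps = 100000L
  )
  troot <- attr(sol, "troot")
  terminated <- !is.null(troot) && length(troot) > 0
  out <- tibble::as_tibble(as.data.frame(unclass(sol)))
  names(out) <- c("t", "p", "q", "r")
  # clip round-off-scale boundary violations; larger ones are an error
  for (col in c("p", "q", "r")) {
    v <- out[[col]]
    if (any(v < -1e-8, na.rm = TRUE)) {
      stop("integrator produced a state well outside the admissible cone",
           call. = FALSE)
    }
    out[[col]] <- pmax(v, 0)
  }
  out$s <- pmax(params$n * out$r - out$p - 2 * out$q, 0)
  out$gap <- out$q - out$r
  out <- out[stats::complete.cases(out), , drop = FALSE]
  structure(out,
            class = c("p62_trajectory", class(out)),
            params = params,
            terminated_at_origin = terminated,
            extinction_time = if (terminated) troot[1] else NA_real_)
}

#' Write a trajectory to CSV
#'
#' Plain CSV with header `t,p,q,r,s,gap`, full double precision.
#'
#' @param traj A trajectory tibble from [integrate_aggregate()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)[, c("t", "p", "q", "r", "s", "gap")]
  for (col in names(df)) df[[col]] <- format(df[[col]], digits = 17,
                                             scientific = FALSE, trim = TRUE)
  readr::write_csv(df, path)
  invisible(path)
}

#' @exportS3Method ggplot2::autoplot
autoplot.p62_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as.data.frame(object)[, c("t", "p", "q", "r")],
    cols = c("p", "q", "r"), names_to = "component", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "scaled count", colour = NULL) +
    ggplot2::theme_minimal()
}
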