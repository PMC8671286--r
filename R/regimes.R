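#' Closed-form regime parameter
#'
#' The long-time fate of the continuum model is governed by
#' \deqn{\bar\alpha = \frac{n}{n-2} + \frac{\kappa_{-1} + \kappa_1 -
#'   \sqrt{(\kappa_1+\kappa_{-1})^2 + 4\kappa_1\kappa_2(n-1)}}
#'   {\kappa_-(n-1)}.}
#' Aggregates dissolve for `alpha_bar >= 1`, reach a finite limiting size
#' for `0 < alpha_bar < 1`, and grow without bound (quadratically in time)
#' for `alpha_bar <= 0`.
#'
#' @param params A [rate_constants()] object with all five constants
#'   positive; for `kappa_m = 0` see [kappa_zero_limits()].
#' @return The scalar regime parameter.
#' @examples
#' alpha_bar(rate_constants(5, 1, 1, 1, 1, 0.6))  # ~0.637
#' @export
alpha_bar <- function(params) {
  stopifnot(inherits(params, "rate_constants"))
  if (params$kappa_m == 0) {
    stop("kappa_m = 0: the regime parameter is undefined; ",
         "use kappa_zero_limits()", call. = FALSE)
  }
  if (any(c(params$kappa1, params$kappa2, params$kappa3,
            params$kappa_m1) <= 0)) {
    stop("all rate constants must be positive", call. = FALSE)
  }
  n <- params$n
  disc <- sqrt((params$kappa1 + params$kappa_m1)^2 +
                 4 * params$kappa1 * params$kappa2 * (n - 1))
  n / (n - 2) + (params$kappa_m1 + params$kappa1 - disc) /
    (params$kappa_m * (n - 1))
}

#' Explicit non-trivial steady state
#'
#' When `0 < alpha_bar < 1` the system has exactly one steady state beside
#' the origin, given in closed form via the per-oligomer ratio
#' `q_hat = (n - (n-2) alpha_bar) / 2 in (1, n/2)`:
#' \deqn{\bar p = \frac{\kappa_1\kappa_2 (n-2)}
#'   {\kappa_3(\kappa_- \hat q (n-1) + \kappa_{-1}(n-2))}
#'   \frac{1-\bar\alpha}{\bar\alpha}, \quad
#'   \bar q = \frac{\kappa_2}{\kappa_- \bar\alpha}\,\bar p, \quad
#'   \bar r = \bar q / \hat q.}
#'
#' @inheritParams alpha_bar
#' @return A one-row tibble `p, q, r` or `NULL` when no non-trivial steady
#'   state exists (`alpha_bar` outside `(0, 1)`).
#' @examples
#' steady_state(rate_constants(5, 1, 1, 1, 1, 0.6))
#' @export
steady_state <- function(params) {
  ab <- alpha_bar(params)
  if (ab <= 0 || ab >= 1) return(NULL)
  n <- params$n
  q_hat <- (n - (n - 2) * ab) / 2
  denom <- params$kappa3 *
    (params$kappa_m * q_hat * (n - 1) + params$kappa_m1 * (n - 2))
  p_bar <- params$kappa1 * params$kappa2 * (n - 2) / denom * (1 - ab) / ab
  q_bar <- params$kappa2 / (params$kappa_m * ab) * p_bar
  r_bar <- q_bar / q_hat
  tibble::tibble(p = p_bar, q = q_bar, r = r_bar)
}

#' Classify the long-time regime of a parameter set
#'
#' Buckets `alpha_bar` into the three conjectured fates — `extinction`
#' (`alpha_bar >= 1`), `finite_size` (`0 < alpha_bar < 1`, with the
#' explicit steady state attached) and `unbounded_growth`
#' (`alpha_bar <= 0`, with the quadratic-growth coefficients attached) —
#' and flags exact boundary values. The equivalent product inequalities on
#' `kappa1 kappa2` are evaluated independently as a cross-check.
#'
#' @inheritParams alpha_bar
#' @param boundary_tol Width below which `alpha_bar` counts as exactly on
#'   a boundary (flag only; the bucket is unchanged).
#' @return An object of class `regime_report`: a list with elements
#'   `alpha_bar`, `q_hat`, `p_hat`, `regime`, `boundary`, `steady_state`
#'   (tibble or `NULL`), `asymptotics` (tibble or `NULL`) and `params`.
#' @examples
#' classify_regime(rate_constants(5, 1, 1, 1, 1, 0.93))
#' @export
classify_regime <- function(params, boundary_tol = 1e-9) {
  ab <- alpha_bar(params)
  n <- params$n
  q_hat <- (n - (n - 2) * ab) / 2
  # product-inequality cross-check (stability and growth onsets)
  km <- params$kappa_m
  lhs <- params$kappa1 * params$kappa2
  stable_ok <- lhs > km / (n - 2) *
    (params$kappa1 + (n - 1) / (n - 2) * km + params$kappa_m1)
  finite_ok <- lhs < km * n / (2 * (n - 2)) *
    (params$kappa1 + n * (n - 1) / (2 * (n - 2)) * km + params$kappa_m1)
  if (abs(ab) > boundary_tol && abs(ab - 1) > boundary_tol) {
    if (xor(stable_ok, ab < 1) || xor(finite_ok, ab > 0)) {
      stop("internal inconsistency between alpha_bar and the product ",
           "inequalities", call. = FALSE)
    }
  }
  regime <- if (ab >= 1) "extinction"
            else if (ab > 0) "finite_size"
            else "unbounded_growth"
  boundary <- abs(ab) <= boundary_tol || abs(ab - 1) <= boundary_tol
  ss <- if (regime == "finite_size") steady_state(params) else NULL
  p_hat <- if (!is.null(ss)) ss$p / ss$r else NA_real_
  asym <- if (ab < 0) asymptotic_coefficients(params) else NULL
  structure(list(alpha_bar = ab, q_hat = q_hat, p_hat = p_hat,
                 regime = regime, boundary = boundary,
                 steady_state = ss, asymptotics = asym, params = params),
            class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  cat("<regime_report>\n")
  cat(sprintf("  alpha_bar = %.6g   q_hat = %.6g   regime = %s%s\n",
              x$alpha_bar, x$q_hat, x$regime,
              if (x$boundary) " (boundary)" else ""))
  if (!is.null(x$steady_state)) {
    cat(sprintf("  steady state (p, q, r) = (%.6g, %.6g, %.6g)\n",
                x$steady_state$p, x$steady_state$q, x$steady_state$r))
  }
  if (!is.null(x$asymptotics)) {
    cat(sprintf("  growth coefficients p1 = %.6g, q2 = %.6g, r2 = %.6g\n",
                x$asymptotics$p1, x$asymptotics$q2, x$asymptotics$r2))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.regime_report <- function(x, ...) {
  out <- tibble::tibble(
    alpha_bar = x$alpha_bar, q_hat = x$q_hat, p_hat = x$p_hat,
    regime = x$regime, boundary = x$boundary,
    p = NA_real_, q = NA_real_, r = NA_real_,
    p1 = NA_real_, q2 = NA_real_, r2 = NA_real_
  )
  if (!is.null(x$steady_state)) {
    out$p <- x$steady_state$p; out$q <- x$steady_state$q
    out$r <- x$steady_state$r
  }
  if (!is.null(x$asymptotics)) {
    out$p1 <- x$asymptotics$p1; out$q2 <- x$asymptotics$q2
    out$r2 <- x$asymptotics$r2
  }
  out
}

#' @exportS3Method generics::glance
glance.regime_report <- function(x, ...) {
  tibble::tibble(alpha_bar = x$alpha_bar, regime = x$regime,
                 boundary = x$boundary)
}

#' Critical cross-link breaking rate at a regime boundary
#'
#' Solves the stability-onset (`alpha_bar = 1`) or growth-onset
#' (`alpha_bar = 0`) relation for `kappa_m`, the positive root of the
#' implied quadratic.
#'
#' @param params A [rate_constants()] object; its `kappa_m` is ignored.
#' @param boundary `"alpha1"` (stability onset) or `"alpha0"` (growth
#'   onset).
#' @return The unique positive critical `kappa_m`.
#' @examples
#' pars <- rate_constants(5, 1, 1, 1, 1, 1)
#' critical_kappa_minus(pars, "alpha1")  # ~0.927
#' @export
critical_kappa_minus <- function(params, boundary = c("alpha1", "alpha0")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(params, "rate_constants"))
  n <- params$n
  k1 <- params$kappa1; k2 <- params$kappa2; km1 <- params$kappa_m1
  if (any(c(k1, k2, km1) <= 0)) {
    stop("kappa1, kappa2, kappa_m1 must be positive", call. = FALSE)
  }
  if (boundary == "alpha1") {
    # k1 k2 = km/(n-2) (k1 + (n-1)/(n-2) km + km1)
    a <- (n - 1) / (n - 2)^2
    b <- (k1 + km1) / (n - 2)
  } else {
    # k1 k2 = km n/(2(n-2)) (k1 + n(n-1)/(2(n-2)) km + km1)
    a <- n^2 * (n - 1) / (4 * (n - 2)^2)
    b <- n * (k1 + km1) / (2 * (n - 2))
  }
  cc <- k1 * k2
  root <- 2 * cc / (b + sqrt(b^2 + 4 * a * cc))
  if (!is.finite(root) || root <= 0) {
    stop("no positive critical kappa_m", call. = FALSE)
  }
  root
}

#' Quadratic-growth coefficients in the unbounded regime
#'
#' For `alpha_bar < 0` the solution grows like
#' `p ~ p1 t`, `q ~ q2 t^2`, `r ~ r2 t^2` (and `s ~ s1 t`), with
#' coefficients determined uniquely by formal asymptotics:
#' \deqn{p_1 = \frac{\kappa_- n}{\kappa_3(2n\kappa_2 + \kappa_- n +
#'   4\kappa_{-1})}\left(\kappa_1\kappa_2 - \frac{\kappa_- n}{2(n-2)}
#'   \left(\kappa_1 + \kappa_{-1} + \frac{\kappa_- n(n-1)}{2(n-2)}\right)
#'   \right) > 0,}
#' \deqn{q_2 = \frac{n}{2} r_2 = \frac{\kappa_3 (n-2)(2n\kappa_2 +
#'   \kappa_- n + 4\kappa_{-1})}{\kappa_-(4\kappa_1(n-2) + \kappa_- n^2)}
#'   \, p_1^2.}
#' Asymptotically the aggregate is tightly packed (`2 q2 = n r2`).
#'
#' @inheritParams alpha_bar
#' @return A one-row tibble with columns `p1, q2, r2, s1`.
#' @examples
#' asymptotic_coefficients(rate_constants(5, 1, 1, 1, 1, 0.2))
#' @export
asymptotic_coefficients <- function(params) {
  ab <- alpha_bar(params)
  if (ab >= 0) {
    stop("quadratic growth requires alpha_bar < 0 (got ",
         signif(ab, 4), ")", call. = FALSE)
  }
  n <- params$n
  k1 <- params$kappa1; k2 <- params$kappa2; k3 <- params$kappa3
  km1 <- params$kappa_m1; km <- params$kappa_m
  margin <- k1 * k2 - km * n / (2 * (n - 2)) *
    (k1 + km1 + km * n * (n - 1) / (2 * (n - 2)))
  p1 <- km * n / (k3 * (2 * n * k2 + km * n + 4 * km1)) * margin
  q2 <- k3 * (n - 2) * (2 * n * k2 + km * n + 4 * km1) /
    (km * (4 * k1 * (n - 2) + km * n^2)) * p1^2
  r2 <- 2 * q2 / n
  s1 <- km * q2 / (k3 * p1)
  tibble::tibble(p1 = p1, q2 = q2, r2 = r2, s1 = s1)
}

#' Limits of the model without cross-link breaking
#'
#' With `kappa_m = 0` the pair `(p, s)` solves the closed planar system
#' \deqn{\dot p = \kappa_1 s - (\kappa_2 + \kappa_{-1} + \kappa_3 s) p,
#'   \qquad
#'   \dot s = ((n-1)\kappa_2 + \kappa_{-1}) p - (\kappa_1 + \kappa_3 p) s,}
#' whose unique non-trivial equilibrium
#' \deqn{p_\infty = \frac{(n-2)\kappa_1\kappa_2}
#'   {\kappa_3(n\kappa_2 + 2\kappa_{-1})}, \qquad
#'   s_\infty = \frac{(n-2)\kappa_2}{2\kappa_3}}
#' is globally attracting (box-type Lyapunov function, see
#' [lyapunov_value()]), so the aggregate always grows linearly in time,
#' with asymptotic slopes `dr/dt -> kappa2 p_inf` and
#' `dq/dt -> p_inf (kappa2 + kappa3 s_inf)`.
#'
#' @param params A [rate_constants()] object with `kappa_m = 0` and the
#'   remaining constants positive.
#' @return An object of class `kappa_zero_limits`: a list with elements
#'   `p_inf`, `s_inf`, `slope_q`, `slope_r`.
#' @examples
#' kappa_zero_limits(rate_constants(5, 1, 1, 1, 1, 0))
#' @export
kappa_zero_limits <- function(params) {
  stopifnot(inherits(params, "rate_constants"))
  if (params$kappa_m != 0) {
    stop("kappa_zero_limits() requires kappa_m = 0", call. = FALSE)
  }
  if (any(c(params$kappa1, params$kappa2, params$kappa3,
            params$kappa_m1) <= 0)) {
    stop("kappa1, kappa2, kappa3, kappa_m1 must be positive", call. = FALSE)
  }
  n <- params$n
  p_inf <- (n - 2) * params$kappa1 * params$kappa2 /
    (params$kappa3 * (n * params$kappa2 + 2 * params$kappa_m1))
  s_inf <- (n - 2) * params$kappa2 / (2 * params$kappa3)
  structure(list(p_inf = p_inf, s_inf = s_inf,
                 slope_q = p_inf * (params$kappa2 + params$kappa3 * s_inf),
                 slope_r = params$kappa2 * p_inf),
            class = "kappa_zero_limits")
}

#' @export
print.kappa_zero_limits <- function(x, ...) {
  cat(sprintf("<kappa_zero_limits>  p_inf = %.6g  s_inf = %.6g\n",
              x$p_inf, x$s_inf))
  cat(sprintf("  asymptotic slopes: dq/dt -> %.6g, dr/dt -> %.6g\n",
              x$slope_q, x$slope_r))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.kappa_zero_limits <- function(x, ...) {
  tibble::tibble(p_inf = x$p_inf, s_inf = x$s_inf,
                 slope_q = x$slope_q, slope_r = x$slope_r)
}

#' Lyapunov diagnostic for the cross-link-conserving system
#'
#' For `kappa_m = 0` the planar `(p, s)` flow admits the Lyapunov function
#' `L(p, s) = a - 1`, where `a >= 1` is the unique scale with `(p, s)` on
#' the boundary of the box `[p_inf/a, a p_inf] x [s_inf/a, a s_inf]`. It
#' vanishes only at the equilibrium and decreases strictly along
#' solutions.
#'
#' @param p,s Positive coordinates; vectorised.
#' @param limits A [kappa_zero_limits()] object.
#' @return Nonnegative Lyapunov value(s).
#' @export
lyapunov_value <- function(p, s, limits) {
  stopifnot(inherits(limits, "kappa_zero_limits"))
  if (any(p <= 0) || any(s <= 0)) {
    stop("`p` and `s` must be positive", call. = FALSE)
  }
  a <- pmax(p / limits$p_inf, limits$p_inf / p,
            s / limits$s_inf, limits$s_inf / s)
  a - 1
}

#' Log-log growth exponent of a trajectory component
#'
#' Least-squares slope of `log(component)` against `log(t)` over a time
#' window, the standard diagnostic for power-law growth: in the unbounded
#' regime the slope approaches 1 for `p` and 2 for `q` and `r` as the
#' window moves to later times.
#'
#' @param traj A trajectory tibble from [integrate_aggregate()].
#' @param component One of `"p"`, `"q"`, `"r"`.
#' @param window Length-2 numeric, the time interval used for the fit;
#'   its start must be >= 10 to exclude the transient.
#' @return The fitted slope.
#' @export
exponent_estimate <- function(traj, component = c("p", "q", "r"),
                              window) {
  component <- match.arg(component)
  stopifnot(length(window) == 2L, window[1] < window[2])
  if (window[1] < 10) {
    stop("`window` must start at t >= 10 (transient excluded)",
         call. = FALSE)
  }
  sub <- traj[traj$t >= window[1] & traj$t <= window[2], ]
  if (nrow(sub) < 3L) stop("window contains fewer than 3 points",
                           call. = FALSE)
  y <- sub[[component]]
  if (any(y <= 0)) {
    stop("component is not strictly positive on the window", call. = FALSE)
  }
  unname(stats::coef(stats::lm(log(y) ~ log(sub$t)))[2L])
}
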