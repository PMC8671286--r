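test_that("alpha_bar evaluates the regime parameter in all three regimes", {
  expect_equal(alpha_bar(pars_finite), 0.63661, tolerance = 1e-4)
  expect_gt(alpha_bar(pars_extinct), 1)
  expect_lt(alpha_bar(pars_growth), 0)
  expect_error(alpha_bar(pars_kzero), "kappa_zero_limits")
})

test_that("classification matches the three reference regimes", {
  rep_f <- classify_regime(pars_finite)
  expect_identical(rep_f$regime, "finite_size")
  expect_false(rep_f$boundary)
  expect_false(is.null(rep_f$steady_state))
  expect_identical(classify_regime(pars_extinct)$regime, "extinction")
  rep_g <- classify_regime(pars_growth)
  expect_identical(rep_g$regime, "unbounded_growth")
  expect_false(is.null(rep_g$asymptotics))
  expect_null(classify_regime(pars_extinct)$steady_state)
  # q_hat relation to alpha_bar
  expect_equal(rep_f$alpha_bar,
               5 / 3 - 2 * rep_f$q_hat / 3, tolerance = 1e-12)
})

test_that("tidiers return one-row summaries", {
  td <- tidy(classify_regime(pars_finite))
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 1L)
  expect_identical(td$regime, "finite_size")
  expect_false(is.na(td$p))
  gl <- glance(classify_regime(pars_growth))
  expect_named(gl, c("alpha_bar", "regime", "boundary"))
})

test_that("steady state matches the reference values and solves rhs = 0", {
  ss <- steady_state(pars_finite)
  expect_equal(c(ss$p, ss$q, ss$r), c(0.2553, 0.6684, 0.4326),
               tolerance = 1e-3)
  expect_lt(max(abs(aggregate_rhs(ss$p, ss$q, ss$r, pars_finite))), 1e-8)
  expect_null(steady_state(pars_extinct))
  expect_equal(alpha_continuum(ss$q, ss$r, 5), alpha_bar(pars_finite),
               tolerance = 1e-10)
})

test_that("random finite-size parameter sets give exact steady states", {
  found <- 0L
  for (pars in random_params(400, seed = 202)) {
    ab <- tryCatch(alpha_bar(pars), error = function(e) NA_real_)
    if (is.na(ab) || ab <= 0 || ab >= 1) next
    found <- found + 1L
    ss <- steady_state(pars)
    scale <- max(1, ss$p, ss$q, ss$r)
    expect_lt(max(abs(aggregate_rhs(ss$p, ss$q, ss$r, pars))) / scale,
              1e-8)
    q_hat <- ss$q / ss$r
    expect_gt(q_hat, 1)
    expect_lt(q_hat, pars$n / 2)
    expect_gt(pars$n * ss$r - ss$p - 2 * ss$q, 0)  # s_hat > 0
    if (found >= 50L) break
  }
  expect_gte(found, 50L)
})

test_that("critical kappa_m agrees with a bisection oracle", {
  base <- rate_constants(5, 1, 1, 1, 1, 1)
  expect_equal(critical_kappa_minus(base, "alpha1"), 0.9271,
               tolerance = 1e-3)
  expect_equal(critical_kappa_minus(base, "alpha0"), 0.3708,
               tolerance = 1e-3)
  # bisection on alpha_bar(kappa_m) - target as an independent route
  for (pars in random_params(5, seed = 99)) {
    for (branch in c("alpha1", "alpha0")) {
      target <- if (branch == "alpha1") 1 else 0
      f <- function(km) {
        alpha_bar(rate_constants(pars$n, pars$kappa1, pars$kappa2,
                                 pars$kappa3, pars$kappa_m1, km)) - target
      }
      root <- stats::uniroot(f, c(1e-8, 1e4), tol = 1e-12)$root
      expect_equal(critical_kappa_minus(pars, branch), root,
                   tolerance = 1e-8)
    }
  }
  # the reference breaking rates straddle the two thresholds
  expect_true(0.2 < 0.3708 && 0.3708 < 0.6 && 0.6 < 0.9271 &&
                0.9271 < 0.93)
})

test_that("quadratic-growth coefficients match trajectory fits", {
  co <- asymptotic_coefficients(pars_growth)
  expect_equal(co$p1, 0.03704, tolerance = 1e-3)
  expect_equal(co$q2, 0.01816, tolerance = 1e-3)
  expect_equal(co$r2, 0.007264, tolerance = 1e-3)
  expect_equal(co$q2 / co$r2, 5 / 2, tolerance = 1e-12)
  expect_error(asymptotic_coefficients(pars_finite), "alpha_bar < 0")
  # three alpha_bar < 0 parameter sets: fits at t = 1e4 within 2 %
  sets <- list(pars_growth,
               rate_constants(5, 2, 1, 1, 1, 0.3),
               rate_constants(4, 1, 2, 0.5, 1, 0.25))
  for (pars in sets) {
    co <- asymptotic_coefficients(pars)
    traj <- integrate_aggregate(pars, init_ref, 1e4,
                                times = c(0, 10^seq(0, 4, length.out = 101)))
    last <- traj[nrow(traj), ]
    expect_equal(last$p / 1e4, co$p1, tolerance = 0.02)
    expect_equal(last$q / 1e8, co$q2, tolerance = 0.02)
    expect_equal(last$r / 1e8, co$r2, tolerance = 0.02)
  }
})

test_that("the growth-coefficient margin changes sign at the onset", {
  base <- rate_constants(5, 1, 1, 1, 1, 1)
  crit <- critical_kappa_minus(base, "alpha0")
  margin <- function(km) {
    n <- 5
    1 * 1 - km * n / (2 * (n - 2)) *
      (1 + 1 + km * n * (n - 1) / (2 * (n - 2)))
  }
  expect_gt(margin(crit * 0.99), 0)
  expect_lt(margin(crit * 1.01), 0)
  expect_equal(margin(crit), 0, tolerance = 1e-12)
  # p1 > 0 whenever defined
  below <- rate_constants(5, 1, 1, 1, 1, crit * 0.95)
  expect_gt(asymptotic_coefficients(below)$p1, 0)
})

test_that("alpha_bar is strictly decreasing in kappa2", {
  k2_grid <- seq(0.1, 5, length.out = 40)
  ab <- purrr::map_dbl(k2_grid, function(k2)
    alpha_bar(rate_constants(5, 1, k2, 1, 1, 0.6)))
  expect_true(all(diff(ab) < 0))
})

test_that("sign pattern of alpha_bar agrees with the product inequalities", {
  # classify_regime() recomputes both routes and stops on disagreement
  for (pars in random_params(200, seed = 77)) {
    rep <- classify_regime(pars)
    expect_true(rep$regime %in%
                  c("extinction", "finite_size", "unbounded_growth"))
  }
})

test_that("long-horizon integration fate matches the predicted regime", {
  picked <- 0L
  for (pars in random_params(120, seed = 13)) {
    ab <- alpha_bar(pars)
    if (abs(ab) < 0.05 || abs(ab - 1) < 0.05) next  # boundary excluded
    if (picked >= 12L) break
    picked <- picked + 1L
    regime <- classify_regime(pars)$regime
    init <- c(p = 0.5, q = 1.2, r = 1)  # admissible for every n >= 3
    traj <- integrate_aggregate(pars, init, t_end = 3000)
    size0 <- sum(init)
    size <- traj$p + traj$q + traj$r
    final <- traj[nrow(traj), ]
    if (regime == "extinction") {
      expect_lt(final$p + final$q + final$r, 0.05 * size0)
    } else if (regime == "unbounded_growth") {
      expect_gt(max(size), 10 * size0)
    } else {
      ss <- steady_state(pars)
      expect_equal(c(final$p, final$q, final$r), c(ss$p, ss$q, ss$r),
                   tolerance = 0.05)
    }
  }
  expect_identical(picked, 12L)
})

test_that("the cross-link-conserving limits are globally attracting", {
  lim <- kappa_zero_limits(pars_kzero)
  expect_equal(lim$p_inf, 3 / 7, tolerance = 1e-12)
  expect_equal(lim$s_inf, 1.5, tolerance = 1e-12)
  expect_equal(lim$slope_r, pars_kzero$kappa2 * lim$p_inf)
  expect_equal(lim$slope_q,
               lim$p_inf * (pars_kzero$kappa2 + pars_kzero$kappa3 * lim$s_inf))
  expect_error(kappa_zero_limits(pars_finite), "kappa_m = 0")
  # limits are independent of the initial state
  for (init in list(init_ref, c(p = 1, q = 6, r = 4))) {
    traj <- integrate_aggregate(pars_kzero, init, t_end = 200)
    final <- traj[nrow(traj), ]
    expect_equal(final$p, lim$p_inf, tolerance = 1e-4)
    expect_equal(final$s, lim$s_inf, tolerance = 1e-4)
  }
  # s_inf grows linearly in n at fixed rates
  s_inf_n <- purrr::map_dbl(c(10, 20, 40), function(n)
    kappa_zero_limits(rate_constants(n, 1, 1, 1, 1, 0))$s_inf)
  expect_equal(s_inf_n[2] / s_inf_n[1], (20 - 2) / (10 - 2) * 1,
               tolerance = 1e-12)
})

test_that("the Lyapunov value is definite and decreases along solutions", {
  lim <- kappa_zero_limits(pars_kzero)
  expect_equal(lyapunov_value(lim$p_inf, lim$s_inf, lim), 0)
  expect_equal(lyapunov_value(2 * lim$p_inf, lim$s_inf, lim), 1)
  expect_error(lyapunov_value(-1, 1, lim), "positive")
  traj <- integrate_aggregate(pars_kzero, init_ref, t_end = 100)
  L <- lyapunov_value(traj$p[-1], traj$s[-1], lim)
  expect_true(all(diff(L) <= 1e-8))
  expect_lt(L[length(L)], L[1])
})

test_that("exponent estimation recovers exact power laws and the regime", {
  fake <- tibble::tibble(t = seq(10, 1000, length.out = 200))
  fake$p <- 3.2 * fake$t^1.7
  expect_equal(exponent_estimate(fake, "p", c(10, 1000)), 1.7,
               tolerance = 1e-10)
  expect_error(exponent_estimate(fake, "p", c(1, 100)), "t >= 10")
  traj <- integrate_aggregate(pars_growth, init_ref, 1e4,
                              times = c(0, 10^seq(0, 4, length.out = 201)))
  expect_equal(exponent_estimate(traj, "p", c(1e3, 1e4)), 1,
               tolerance = 0.05)
  expect_equal(exponent_estimate(traj, "q", c(1e3, 1e4)), 2,
               tolerance = 0.05)
  expect_equal(exponent_estimate(traj, "r", c(1e3, 1e4)), 2,
               tolerance = 0.05)
})
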