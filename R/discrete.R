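#' Admissibility of a discrete aggregate state
#'
#' An aggregate of `k` p62 oligomers with `i` one-hand bound and `j`
#' both-hand bound cross-linkers is admissible when it has at least two
#' oligomers, enough both-hand bound cross-linkers to be connected, and no
#' more bound hands than binding sites:
#' `k >= 2`, `j >= k - 1`, `i + 2 j <= n k`.
#'
#' @param i,j,k Nonnegative integer counts; vectorised.
#' @param n Oligomer size.
#' @return Logical vector.
#' @examples
#' is_admissible(0, 1, 2, n = 3)  # a chain of two oligomers
#' @export
is_admissible <- function(i, j, k, n) {
  i >= 0 & j >= 0 & k >= 2 & j >= k - 1 & i + 2 * j <= n * k
}

#' Detachment probability for a discrete aggregate
#'
#' Probability that a breaking cross-link was the sole connection of an
#' oligomer, so that the oligomer falls off: the linear interpolant in `j`
#' between 1 (chain, `j = k - 1`) and 0 (tightly packed,
#' `n k - 2 j <= n - 2`):
#' `alpha = (n k - 2 j - n + 2)_+ / ((n - 2) k + 4 - n)`.
#'
#' @param j,k Counts from an admissible state; vectorised.
#' @param n Oligomer size.
#' @return Value in `[0, 1]`.
#' @examples
#' alpha_discrete(j = 3, k = 3, n = 5)  # 0.75
#' @export
alpha_discrete <- function(j, k, n) {
  pmax(n * k - 2 * j - n + 2, 0) / ((n - 2) * k + 4 - n)
}

#' Number of one-hand bound cross-linkers lost with a detaching oligomer
#'
#' When a detaching oligomer leaves, it takes `ell` one-hand bound
#' cross-linkers with it: the rounded expected share of the aggregate's
#' one-hand bound cross-linkers sitting on the lost oligomer's `n - 1`
#' remaining sites, `ell = round((n - 1) i / (n k - 2 j))` (ties half-up).
#' The result always satisfies the post-state admissibility bounds
#' `(n - 1 - n k + i + 2 j)_+ <= ell <= min(i, n - 1)`.
#'
#' @param i,j,k Admissible state with `n k - 2 j >= n - 1` (the regime
#'   where detachment is possible).
#' @param n Oligomer size.
#' @return Integer `ell`.
#' @examples
#' ell_choice(i = 1, j = 3, k = 3, n = 5)  # 0
#' @export
ell_choice <- function(i, j, k, n) {
  if (n * k - 2 * j < n - 1) {
    stop("detachment impossible: n k - 2 j < n - 1", call. = FALSE)
  }
  as.integer(floor((n - 1) * i / (n * k - 2 * j) + 0.5))
}

#' Reaction propensities of a discrete aggregate state
#'
#' Mass-action rates of the six reactions: cross-linker addition (`r1`),
#' oligomer addition (`r2`), compactification (`r3`), cross-linker loss
#' (`r_m1`), oligomer detachment (`r_m2`) and loosening (`r_m3`). The two
#' unbinding outcomes partition cross-link breakage:
#' `r_m2 + r_m3 = kappa_m * j`. Here `kappa3` is the second-order
#' compactification constant (see [discrete_params()]).
#'
#' @param i,j,k Admissible discrete state.
#' @param params A [rate_constants()] object with discrete-level `kappa3`.
#' @return Named numeric vector
#'   `c(r1, r2, r3, r_m1, r_m2, r_m3)`.
#' @examples
#' pars <- rate_constants(5, 1, 1, 1, 1, 1)
#' propensities(2, 3, 3, pars)
#' @export
propensities <- function(i, j, k, params) {
  stopifnot(inherits(params, "rate_constants"))
  n <- params$n
  if (!is_admissible(i, j, k, n)) {
    stop("inadmissible discrete state", call. = FALSE)
  }
  free <- n * k - i - 2 * j
  a <- alpha_discrete(j, k, n)
  c(r1 = params$kappa1 * free,
    r2 = params$kappa2 * i,
    r3 = params$kappa3 * i * free,
    r_m1 = params$kappa_m1 * i,
    r_m2 = params$kappa_m * a * j,
    r_m3 = params$kappa_m * (1 - a) * j)
}

#' Apply one reaction to a discrete state
#'
#' Stoichiometries: 1 adds a one-hand bound cross-linker; 2 adds an
#' oligomer (a one-hand bound cross-linker becomes the new link); 3
#' compactifies (a one-hand bound cross-linker binds its second hand);
#' -1 loses a one-hand bound cross-linker; -2 detaches an oligomer with
#' `ell` one-hand bound cross-linkers (loss of the whole aggregate when
#' `k = 2`); -3 loosens a cross-link.
#'
#' @param i,j,k Admissible discrete state at which the reaction is enabled.
#' @param reaction One of `1, 2, 3, -1, -2, -3`.
#' @param n Oligomer size.
#' @return Named integer vector `c(i, j, k)`, or the string
#'   `"aggregate_lost"` for reaction -2 at `k = 2`.
#' @examples
#' apply_reaction(2, 3, 3, reaction = 2, n = 5)  # c(1, 4, 4)
#' @export
apply_reaction <- function(i, j, k, reaction, n) {
  if (!is_admissible(i, j, k, n)) {
    stop("inadmissible discrete state", call. = FALSE)
  }
  out <- switch(as.character(reaction),
    "1" = {
      if (n * k - i - 2 * j < 1) stop("reaction 1 disabled: no free site",
                                      call. = FALSE)
      c(i + 1, j, k)
    },
    "2" = {
      if (i < 1) stop("reaction 2 disabled: i = 0", call. = FALSE)
      c(i - 1, j + 1, k + 1)
    },
    "3" = {
      if (i < 1 || n * k - i - 2 * j < 1) {
        stop("reaction 3 disabled", call. = FALSE)
      }
      c(i - 1, j + 1, k)
    },
    "-1" = {
      if (i < 1) stop("reaction -1 disabled: i = 0", call. = FALSE)
      c(i - 1, j, k)
    },
    "-2" = {
      if (alpha_discrete(j, k, n) <= 0) {
        stop("reaction -2 disabled: aggregate too tightly packed",
             call. = FALSE)
      }
      if (k == 2) return("aggregate_lost")
      ell <- ell_choice(i, j, k, n)
      c(i + 1 - ell, j - 1, k - 1)
    },
    "-3" = {
      if (j < k) stop("reaction -3 disabled: j < k", call. = FALSE)
      c(i + 1, j - 1, k)
    },
    stop("unknown reaction", call. = FALSE)
  )
  if (is.character(out)) return(out)
  if (!is_admissible(out[1], out[2], out[3], n)) {
    stop("reaction produced an inadmissible state", call. = FALSE)
  }
  stats::setNames(as.integer(out), c("i", "j", "k"))
}

reaction_codes <- c(1L, 2L, 3L, -1L, -2L, -3L)

#' Exact stochastic simulation of the discrete aggregation scheme
#'
#' Gillespie direct method on the continuous-time Markov chain defined by
#' [propensities()]: exponential waiting times from the total propensity,
#' a single uniform draw choosing the reaction. The run ends at `t_max`,
#' when the aggregate is lost (oligomer detachment at `k = 2`), or in an
#' absorbing state (total propensity zero).
#'
#' @param init Named integer vector `c(i = , j = , k = )`, admissible.
#' @param params A [rate_constants()] object with discrete-level `kappa3`.
#' @param t_max Simulation horizon.
#' @param seed Integer seed; the run is reproducible given the seed.
#' @return A tibble of class `p62_ssa` with columns
#'   `t, reaction, i, j, k` (the initial state carries `reaction = NA`),
#'   and attribute `termination` in
#'   `c("reached_t_max", "aggregate_lost", "absorbing")`.
#' @examples
#' pars <- rate_constants(5, 1, 1, 1, 1, 1)
#' ssa_run(c(i = 2, j = 3, k = 3), pars, t_max = 1, seed = 1)
#' @export
ssa_run <- function(init, params, t_max, seed) {
  stopifnot(inherits(params, "rate_constants"), t_max > 0)
  i <- as.integer(init[["i"]]); j <- as.integer(init[["j"]])
  k <- as.integer(init[["k"]])
  n <- params$n
  if (!is_admissible(i, j, k, n)) {
    stop("inadmissible initial state", call. = FALSE)
  }
  set.seed(as.integer(seed))
  k1 <- params$kappa1; k2 <- params$kappa2; k3 <- params$kappa3
  km1 <- params$kappa_m1; km <- params$kappa_m
  cap <- 1024L
  ts <- numeric(cap); rs <- integer(cap)
  is <- integer(cap); js <- integer(cap); ks <- integer(cap)
  nev <- 1L
  ts[1L] <- 0; rs[1L] <- NA_integer_; is[1L] <- i; js[1L] <- j; ks[1L] <- k
  t <- 0
  termination <- "reached_t_max"
  repeat {
    free <- n * k - i - 2 * j
    a <- max(n * k - 2 * j - n + 2, 0) / ((n - 2) * k + 4 - n)
    w <- c(k1 * free, k2 * i, k3 * i * free, km1 * i,
           km * a * j, km * (1 - a) * j)
    a0 <- sum(w)
    if (a0 <= 0) { termination <- "absorbing"; break }
    t <- t + stats::rexp(1L, a0)
    if (t > t_max) break
    u <- stats::runif(1L) * a0
    rx <- 1L
    acc <- w[1L]
    while (acc < u && rx < 6L) { rx <- rx + 1L; acc <- acc + w[rx] }
    code <- reaction_codes[rx]
    lost <- FALSE
    if (code == 1L) i <- i + 1L
    else if (code == 2L) { i <- i - 1L; j <- j + 1L; k <- k + 1L }
    else if (code == 3L) { i <- i - 1L; j <- j + 1L }
    else if (code == -1L) i <- i - 1L
    else if (code == -2L) {
      if (k == 2L) lost <- TRUE
      else {
        ell <- as.integer(floor((n - 1) * i / (n * k - 2 * j) + 0.5))
        i <- i + 1L - ell; j <- j - 1L; k <- k - 1L
      }
    } else { i <- i + 1L; j <- j - 1L }
    nev <- nev + 1L
    if (nev > cap) {
      cap <- cap * 2L
      length(ts) <- cap; length(rs) <- cap
      length(is) <- cap; length(js) <- cap; length(ks) <- cap
    }
    ts[nev] <- t; rs[nev] <- code
    if (lost) {
      is[nev] <- NA_integer_; js[nev] <- NA_integer_; ks[nev] <- NA_integer_
      termination <- "aggregate_lost"
      break
    }
    is[nev] <- i; js[nev] <- j; ks[nev] <- k
  }
  out <- tibble::tibble(t = ts[seq_len(nev)], reaction = rs[seq_len(nev)],
                        i = is[seq_len(nev)], j = js[seq_len(nev)],
                        k = ks[seq_len(nev)])
  structure(out, class = c("p62_ssa", class(out)),
            params = params, termination = termination, seed = seed)
}

#' Write an SSA event log to CSV
#'
#' Header `t,reaction,i,j,k`; reactions coded `1, 2, 3, -1, -2, -3`.
#'
#' @param run A tibble from [ssa_run()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(run, path) {
  readr::write_csv(as.data.frame(run), path)
  invisible(path)
}

# sample the state right before each grid time from one SSA path
sample_on_grid <- function(run, times) {
  idx <- findInterval(times, run$t)
  idx[idx < 1L] <- 1L
  run[idx, c("i", "j", "k")]
}

#' Ensemble of SSA runs on a fixed output grid, scaled to continuum units
#'
#' Runs `replicates` independent paths from the discrete image of a
#' continuum initial state (`(i, j, k) = round(k0 * (p, q, r))`) with
#' `kappa3' = kappa3 / k0`, samples each path at the grid times
#' (state of the last event before each time), and returns per-time
#' ensemble means and standard errors of `(i, j, k) / k0`. A path that
#' loses its aggregate contributes the origin from that time on.
#'
#' @param params Continuum-level [rate_constants()].
#' @param init Continuum initial state `c(p = , q = , r = )`.
#' @param t_max Horizon.
#' @param k0 Scaling constant (typical aggregate size).
#' @param replicates Number of independent paths.
#' @param times Output grid; defaults to 21 equispaced points.
#' @param seed Base seed; path `m` uses `seed + m`.
#' @return A tibble with columns
#'   `t, mean_p, mean_q, mean_r, se_p, se_q, se_r`.
#' @export
ssa_ensemble <- function(params, init, t_max, k0, replicates,
                         times = NULL, seed = 1L) {
  stopifnot(inherits(params, "rate_constants"))
  if (is.null(times)) times <- seq(0, t_max, length.out = 21L)
  dparams <- discrete_params(params, k0)
  dinit <- c(i = as.integer(round(k0 * init[["p"]])),
             j = as.integer(round(k0 * init[["q"]])),
             k = as.integer(round(k0 * init[["r"]])))
  if (!is_admissible(dinit[["i"]], dinit[["j"]], dinit[["k"]], params$n)) {
    stop("rounded discrete image of `init` is not admissible", call. = FALSE)
  }
  samples <- purrr::map(seq_len(replicates), function(m) {
    run <- ssa_run(dinit, dparams, t_max, seed = as.integer(seed) + m)
    st <- sample_on_grid(run, times)
    # after aggregate loss the state is the origin
    st[is.na(st$i), ] <- list(0L, 0L, 0L)
    st
  })
  acc <- function(col) {
    m <- vapply(samples, function(s) s[[col]] / k0, numeric(length(times)))
    if (is.null(dim(m))) m <- matrix(m, nrow = length(times))
    list(mean = rowMeans(m),
         se = apply(m, 1L, stats::sd) / sqrt(replicates))
  }
  pi <- acc("i"); qj <- acc("j"); rk <- acc("k")
  tibble::tibble(t = times,
                 mean_p = pi$mean, mean_q = qj$mean, mean_r = rk$mean,
                 se_p = pi$se, se_q = qj$se, se_r = rk$se)
}
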