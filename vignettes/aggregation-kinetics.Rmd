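---
title: "Modelling p62–ubiquitin aggregation kinetics with p62aggr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling p62–ubiquitin aggregation kinetics with p62aggr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p62aggr)
```

## The model and its assumptions

p62 (SQSTM1) oligomers condense ubiquitinated cargo into aggregates that
autophagy later degrades. `p62aggr` models a *single* aggregate built from
two species: p62 oligomers of fixed size $n \ge 3$, each carrying $n$
ubiquitin-binding sites, and two-handed ubiquitin cross-linkers that can be
bound by one hand or by both. The aggregate state is the triplet
$(i, j, k)$ — one-hand bound cross-linkers, both-hand bound cross-linkers,
oligomers — restricted to the *admissible* cone

$$k \ge 2, \qquad j \ge k - 1, \qquad i + 2j \le nk,$$

expressing that an aggregate has at least two oligomers, enough
cross-links to be connected, and no more bound hands than binding sites.
Three modelling assumptions matter most:

1. **Abundant free pools.** Free cross-linker and oligomer concentrations
   are fixed, so binding enters through pseudo-first-order constants
   $\kappa_1 = \kappa_1'[\mathrm{Ubi}]$ and
   $\kappa_2 = \kappa_2'[\mathrm{p62}_n]$. This describes the early growth
   stage; depletion, nucleation and coagulation of several aggregates are
   outside the model.
2. **Mean-field shape.** A triplet represents many possible aggregate
   geometries; rates are averages over them. In particular the probability
   that a breaking cross-link detaches a whole oligomer is modelled by the
   linear interpolant $\alpha_{j,k}$ between 1 (chain, $j = k-1$) and 0
   (tightly packed, $nk - 2j \le n - 2$), and a detaching oligomer carries
   away the rounded expected number
   $\ell = \lfloor (n-1)i/(nk-2j) \rceil$ of one-hand bound cross-linkers.
3. **No fragmentation.** Breaking a cross-link detaches at most one
   oligomer (the whole aggregate is lost if $k = 2$); this keeps the state
   change gradual, which is what makes a differential-equation limit
   possible, and is self-consistent because growing aggregates turn out to
   be tightly packed.

Six reactions act on the state: cross-linker addition, oligomer addition,
compactification (a one-hand bound cross-linker binds its second hand),
and their three reversals (unbinding, oligomer detachment, loosening).
`propensities()` exposes the mass-action rates, `apply_reaction()` the
stoichiometries, and `ssa_run()` simulates the continuous-time Markov
chain exactly (direct method: one exponential waiting time from the total
propensity, one uniform draw to choose the reaction, one seeded RNG stream
per run).

## The continuum limit

For large aggregates the state is scaled by a typical size $k_0$
(comparable to $\kappa_1/\kappa_3'$ and $\kappa_2/\kappa_3'$):
$p = i/k_0$, $q = j/k_0$, $r = k/k_0$, and
$\kappa_3 = \kappa_3' k_0$. Because the same symbol is conventionally used
for the compactification constant on both levels, `rate_constants()`
stores a single `kappa3` field and the explicit converters
`continuum_params()` / `discrete_params()` move between levels; nothing
converts implicitly. The scaled dynamics are

$$\dot p = (\kappa_1 - \kappa_3 p)s
  + \kappa_- q\Big(1 - \frac{(n-1)p}{(n-2)r}\Big) - (\kappa_2 + \kappa_{-1})p,
  \qquad
  \dot q = \kappa_2 p + \kappa_3 p s - \kappa_- q,
  \qquad
  \dot r = \kappa_2 p - \kappa_- q\,\alpha(q, r),$$

with $s = nr - p - 2q$ and $\alpha(q,r) = (nr-2q)/((n-2)r)$. The
admissibility conditions $s \ge 0$, $q \ge r$ are propagated by the flow,
solutions exist globally, and the total size obeys
$p+q+r \le (p_0+q_0+r_0)e^{t\max\{\kappa_1 n, \kappa_2\}}$ and
$r \ge 2q/n \ge (2q_0/n)e^{-\kappa_- t}$ — all of which the test suite
checks along computed trajectories.

## Regimes

The long-time fate is governed by the closed-form parameter returned by
`alpha_bar()`:

$$\bar\alpha = \frac{n}{n-2} + \frac{\kappa_{-1} + \kappa_1 -
  \sqrt{(\kappa_1+\kappa_{-1})^2 + 4\kappa_1\kappa_2(n-1)}}{\kappa_-(n-1)}.$$

```{r}
purrr::map_dfr(c(0.6, 0.93, 0.2), function(km)
  glance(classify_regime(rate_constants(5, 1, 1, 1, 1, km))))
```

* **Finite size** ($0 < \bar\alpha < 1$): there is exactly one non-trivial
  steady state, available in closed form through the per-oligomer ratio
  $\hat q = (n - (n-2)\bar\alpha)/2 \in (1, n/2)$; `steady_state()`
  evaluates it and the tests verify the ODE residual vanishes there
  ($\|\dot{(p,q,r)}\|_\infty < 10^{-8}$) for randomly drawn parameter
  sets.
* **Extinction** ($\bar\alpha \ge 1$): only the origin remains; numerical
  trajectories decay to it.
* **Unbounded growth** ($\bar\alpha \le 0$): formal asymptotics give
  $p \sim p_1 t$ and $q \sim q_2 t^2$, $r \sim r_2 t^2$ with explicit
  coefficients and $2q_2 = n r_2$: the growing aggregate is asymptotically
  fully packed. `asymptotic_coefficients()` evaluates them, and
  `exponent_estimate()` recovers the exponents from log–log slopes of
  integrated trajectories.

That convergence to these fates holds for *all* admissible initial states
is, strictly speaking, a conjecture supported by simulation (rigorous
proofs exist only in part); `classify_regime()` therefore reports a
*predicted* regime, and the suite cross-checks prediction against
integration fate on random parameter sets. Exact boundary values
$\bar\alpha \in \{0, 1\}$ are folded into the neighbouring buckets
(extinction and growth respectively) but flagged `boundary`, because the
bifurcation machinery needs the exact-onset case distinguished.
$\bar\alpha$ is strictly decreasing in $\kappa_2$ — more oligomer supply
never destabilises — which makes the regime bands in concentration space
simply ordered.

### The cross-link-conserving case

With $\kappa_- = 0$ (no cross-link breakage) the pair $(p, s)$ closes into
a planar system whose unique equilibrium

$$p_\infty = \frac{(n-2)\kappa_1\kappa_2}{\kappa_3(n\kappa_2 + 2\kappa_{-1})},
  \qquad s_\infty = \frac{(n-2)\kappa_2}{2\kappa_3}$$

is globally attracting; the aggregate then grows linearly,
$\dot r \to \kappa_2 p_\infty$. The attraction proof uses a box-shaped
Lyapunov function — the smallest $a \ge 1$ with $(p, s)$ inside
$[p_\infty/a,\, a p_\infty] \times [s_\infty/a,\, a s_\infty]$ — which
`lyapunov_value()` exposes as a diagnostic; tests confirm it decreases
along trajectories. (The $p_\infty$ formula is the unique solution of the
planar equilibrium equations — substituting it back makes both components
of the vector field vanish — and numerical integration from any admissible
start confirms it, e.g. $p \to 3/7$ for unit rates and $n = 5$.)

```{r}
lim <- kappa_zero_limits(rate_constants(5, 1, 1, 1, 1, 0))
tidy(lim)
```

## Concentrations and the dissociation constant

For comparison with aggregation experiments the rate constants are reduced
by symmetry assumptions — equal binding constants
($\kappa_1' = \kappa_2'$) and equal unbinding constants
($\kappa_{-1} = \kappa_-$) — leaving the oligomer size, the two
concentrations and one dissociation constant
$K_d = \kappa_{-1}/\kappa_1'$ (µM). Since $\bar\alpha$ is invariant under
rescaling $\kappa_1'$, the regime depends only on
$([\mathrm{Ubi}], [\mathrm{p62}_n], K_d, n)$. Setting $\bar\alpha = 1$ or
$\bar\alpha = 0$ yields the stability-onset and growth-onset curves in the
concentration plane (`boundary_p62()`), which are quadratics in $K_d$;
`estimate_kd()` inverts them in the cancellation-free form
$K = 2c/(b + \sqrt{b^2 + 4ac})$, with the round-trip through
`boundary_p62()` fuzz-tested to $10^{-10}$ relative.

```{r}
tidyr::expand_grid(ubi = c(0.6, 2.6), branch = c("alpha1", "alpha0")) |>
  dplyr::mutate(kd = purrr::map2_dbl(ubi, branch,
                                     ~ estimate_kd(.x, 0.4, 5, .y)))
```

Reading the onset of aggregation at a p62 monomer concentration of 2 µM
(i.e. $[\mathrm{p62}_5] = 0.4$ µM) and cross-linker concentrations between
0.6 and 2.6 µM gives $K_d$ between 0.44 and 0.73 µM if the onset marks
stability, or 0.20–0.31 µM if it marks growth — far below the isolated
UBA–ubiquitin affinity, as expected when avidity dominates.
`phase_diagram()` labels a concentration grid with the predicted regimes
(with `autoplot()` for the standard bifurcation picture), and
`kd_vs_n_scan()` repeats the estimate across oligomer sizes, where the two
branches scale as $K_d = O(n^{1/2})$ and $O(n^{-1/2})$. The onset
concentrations 0.6/1.6/2.6 µM are treated as exact inputs; no uncertainty
propagation is attempted.

## Numerical choices

* **Integrator.** `integrate_aggregate()` uses `deSolve::lsodar`
  (adaptive, stiff-capable) at `rtol = 1e-8`, `atol = 1e-10`; halving the
  tolerances changes reported values below reporting precision (tested).
  The quadratic nonlinearities plus horizons up to $t = 10^4$ for
  asymptotics motivate a stiff-capable default.
* **Origin handling.** The right-hand side is undefined at $r = 0$ but
  extends continuously by 0 on admissible states, so the origin is a
  steady state. A root function stops integration once $r < 10^{-10}$
  (admissibility then pins $p, q$ to the same scale) and flags the
  trajectory `terminated_at_origin`; this avoids 0/0 evaluations.
* **Boundary round-off.** Stored states are clipped to the admissible cone
  only at round-off magnitude ($<10^{-8}$); larger violations raise an
  error, since the conditions are analytically propagated and a real
  violation means integrator misuse. State constructors validate strictly
  — there is no silent repair.
* **Tie-breaking in $\ell$.** "Closest integer" leaves ties at .5
  unspecified; the package rounds half-up. Any tie rule keeps $\ell$
  inside its admissibility bounds (integer bounds; verified by brute-force
  enumeration over all admissible states with $k \le 6$, $n \in
  \{3,4,5\}$).
* **Exponent windows.** Power-law exponents are fitted on the final decade
  of a $t = 10^4$ run by default (window configurable, start $\ge 10$ to
  exclude the transient).
* **Degenerate inputs.** $\kappa_- = 0$ routes to `kappa_zero_limits()`
  (where $\bar\alpha$ is undefined); `estimate_kd()` returns 0 for zero
  oligomer concentration; reactions whose enabling condition fails have
  exactly zero propensity and error if forced.

## What the simulated conditions do and do not show

The reference conditions used across examples and tests
(`regime_fixtures()`) are unit rate constants with
$\kappa_- \in \{0.6, 0.93, 0.2, 0\}$, $n = 5$ and initial state
$(2, 4, 3)$ — one parameter set per regime, with all expected outputs
available in closed form. They emulate the qualitative structure of the
model (the three fates and their boundaries), not any measured time
series: real aggregates have distributed oligomer sizes, deplete their
free pools, nucleate and coagulate, none of which is modelled. Passing
tests therefore validate the mathematics and the implementation, not the
biological fidelity of any particular rate value.

Problem sizes were chosen so the whole suite runs in well under a minute
of ODE work: fate cross-checks integrate 12 random parameter sets to
$t = 3000$; steady-state residuals are checked on 50 random finite-size
sets; asymptotic coefficients are validated against $t = 10^4$ runs for
three growth-regime sets. The stochastic–deterministic consistency check
uses $k_0 = 200$ with 500 replicates on a short horizon ($t = 0.25$,
before a 200-oligomer aggregate can drift far). One caveat discovered and
documented here: the ensemble mean of the discrete chain differs from the
ODE by a systematic $O(1/k_0)$ term (mean-field closure plus the
deterministic rounding of $\ell$), so at 500 replicates the deviation of
$p$ sits near 3–4 standard errors even though it shrinks steadily with
$k_0$ (verified over $k_0 = 25$–400, and verified to vanish on the linear
sub-model $\kappa_3' = \kappa_- = 0$ where the chain mean equals the ODE
exactly). A strict 3-standard-error band at those settings is therefore
marginally exceeded by the bias, not by an implementation error.

## Limitations

* Single aggregate, infinite free pools: no nucleation, depletion,
  coagulation, or size distributions.
* The regime trichotomy is numerically corroborated, not proven, away from
  the cases covered by rigorous results.
* Concentration-space estimates inherit the symmetry assumptions
  $\kappa_1' = \kappa_2'$, $\kappa_{-1} = \kappa_-$; if binding to an
  oligomer and cross-linking differ substantially, $K_d$ estimates shift.
* Time is dimensionless throughout; only concentration units (µM) are
  physical.
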