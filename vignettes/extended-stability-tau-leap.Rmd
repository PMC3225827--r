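---
title: "Extended-stability Runge-Kutta tau-leap methods: model, design and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended-stability Runge-Kutta tau-leap methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tauleapRK)
```

## The model

We simulate well-stirred chemically reacting systems: $N$ species with
integer state $X(t)$, $m$ reaction channels characterised by
stoichiometric update vectors $\nu_j$ and propensity functions
$a_j(x)$ ($a_j(x)\,dt$ is the probability channel $j$ fires in
$[t, t+dt)$).  The exact description is the chemical master equation
(CME); the SSA samples it exactly by drawing exponential waiting times
with rate $a_0 = \sum_j a_j$ and firing one channel at a time.

The Poisson $\tau$-leap method advances by a fixed leap $\tau$, firing
every channel $K_j \sim \mathcal{P}(\tau a_j(X_n))$ times.  Writing the
compensated (zero-mean) fluctuation $L(\tau, x) = \mathcal{P}(\tau x) -
\tau x$ and the drift $f(x) = \sum_j \nu_j a_j(x)$, the leap is
$X_{n+1} = X_n + \tau f(X_n) + \sum_j \nu_j L(\tau, a_j(X_n))$ — an
Euler-type step on the drift plus one Poisson fluctuation term.  The
$s$-stage Runge–Kutta $\tau$-leap framework generalises only the drift
part:

$$d_n = \sum_j \nu_j L(\tau, a_j(X_n)), \qquad
  Y_i = X_n + \tau\sum_{j<i}\alpha_{ij} f(Y_j) + w_i d_n, \qquad
  X_{n+1} = X_n + \tau\sum_j \beta_j f(Y_j) + d_n.$$

One set of Poisson draws per step, regardless of $s$ — the extra cost
over the plain $\tau$-leap is deterministic drift evaluations only.
The framework contains the Poisson $\tau$-leap ($s=1$) and the explicit
midpoint $\tau$-leap ($s=2$, $b=(0,1)$, $\alpha_{21}=1/2$) as special
cases.  Weights must satisfy $\sum_j \beta_j = 1$ (first-order
consistency of the mean); stage abscissae enter only through
$w_i d_n$, since propensities are autonomous.

## Linear stability and stationary variance

On linear (unimolecular) kinetics $a_j(x) = c_j^T x$ the drift is $W x$
with $W = \sum_j \nu_j c_j^T$, and the ensemble mean obeys
$\mathbb{E}[X_{n+1}] = R(\tau W)\,\mathbb{E}[X_n]$, where $R$ is the
stability function of the underlying Runge–Kutta method ($R(z) = 1 +
z\,b^T(I - Az)^{-1}e$, a polynomial $1 + \sum_j r_j z^j$ with $r_j =
b^T A^{j-1} e$ for explicit methods).  `mean_propagator()` evaluates
the matrix version.

The reversible isomerisation $S_1 \rightleftharpoons S_2$ (rates $k_1,
k_2$, conserved total $T$) is the scalar test system: its stationary
CME law is Binomial$(T, k_2/(k_1+k_2))$ with variance $T k_1 k_2 /
(k_1+k_2)^2$.  A method run at leap $\tau$, i.e. at $z = -\tau(k_1 +
k_2)$, reaches a stationary variance of $\psi(z)$ times the exact one,

$$\psi(z) = \frac{2}{z}\,\frac{R(z)-1}{R(z)+1},$$

defined for $R^2(z) \ne 1$ and extended by its limit $\psi(0) = 1$
(every consistent method has $R(z) = 1 + z + O(z^2)$, so the
singularity at $0$ is removable; treating it this way removes all
special-casing from constraint and plotting code).  Only methods with
$R(z) = (1+z/2)/(1-z/2)$ — necessarily implicit, e.g. the implicit
midpoint rule — have $\psi \equiv 1$; the package supports such
tableaus in the analysis layer but deliberately rejects them in the
simulators, which are explicit-methods machinery.

## Designing variance-bounded methods

The design criterion is: fix a variance tolerance $\varepsilon \in
(0,1)$ and maximise $l$ such that $|\psi(z) - 1| < \varepsilon$ on
$(-l, 0]$.  Rearranging $\psi$, the bound is equivalent to the sandwich

$$\frac{1 + \tfrac{z}{2}(1+\varepsilon)}{1 - \tfrac{z}{2}(1+\varepsilon)}
  \;<\; R(z) \;<\;
  \frac{1 + \tfrac{z}{2}(1-\varepsilon)}{1 - \tfrac{z}{2}(1-\varepsilon)},$$

whose two bounds lie in $(-1, 1)$ for $z < 0$ — so the variance bound
*implies* $|R(z)| < 1$, and stability comes for free.

For $s = 2$ the optimum is closed-form (`two_stage_gamma()`,
`two_stage_interval()`): $R(z) = 1 + z + \gamma z^2$ with $\gamma =
(1+\varepsilon)\left[(\tfrac12+\varepsilon) -
\sqrt{\varepsilon(1+\varepsilon)}\right]$.  At the optimum the interior
maximum of $\psi$ is tangent to $1 + \varepsilon$ and the interval ends
where $\psi$ crosses $1 - \varepsilon$.  Two numerical conventions
follow from that geometry:

* the printed textbook expressions for the $\psi$-extrema of this
  family are unreliable as transcribed, so extrema are always handled
  numerically from $\psi$ itself;
* `two_stage_interval()` also covers the sub-optimal regime (notably
  $\gamma \le 1/8$, where $\psi$ grows monotonically) by taking the
  earlier of the two band crossings; a near-tangent upper crossing
  (quadratic discriminant below $10^{-4}$) is treated as the tangency
  of the optimal family rather than as a genuine violation, which is
  what makes the function stable under coefficients rounded to a few
  decimals.

For general $s$, with $r_1 = 1$ fixed, the free coefficients are $r_2,
\dots, r_s$.  The key structural observation exploited by
`optimize_polynomial()` is that $R(z)$ is *linear* in these
coefficients, so for fixed $l$ the sandwich over any grid is a
polyhedral feasibility problem.  The solver is therefore:

1. outer bisection on $l$ (tolerance $10^{-5}$), bracketed by the
   Poisson bound $2\varepsilon/(1+\varepsilon)$ and the degree-$s$
   Chebyshev bound $2s^2$;
2. at each trial $l$, an exact minimax linear program over a
   2000-point Chebyshev grid on $(-l, 0]$ (clustered at both
   endpoints, where the constraints are most active), solved by
   simplex with constraint generation — a subgrid LP plus successive
   addition of the most-violated grid points, which converges in a few
   small solves because at most $\sim 2s$ constraints are active at
   an optimum.  Coefficients are solved in the scaled basis
   $q_j = r_j l^j$ to keep the constraint matrix well conditioned;
3. a posteriori certification of $|\psi - 1| < \varepsilon$ on a dense
   grid over $(-l(1-10^{-6}), 0]$, with $l$ backed off (never widened)
   in $2\cdot10^{-4}$ relative steps until the certificate passes.

Because the inner problem is a linear program solved exactly, no
multistart heuristics are needed and the result is deterministic; up to
grid resolution the certified $l$ is the *global* optimum of the stated
design problem.  The three-stage optima ($l = 3.9457,\ 5.8960,\
8.1206$ at $\varepsilon = 0.1, 0.25, 0.5$) agree with the two-stage
closed form's pattern and with independent interval scans; the
five-stage optima ($l = 10.72,\ 15.43,\ 20.94$) carry the same dense
certificates.  Where shorter intervals for five-stage methods of this
family have circulated, they correspond to feasible but sub-optimal
coefficient sets — a local solution of the same nonlinear program —
and the certificates here verify both feasibility and the longer range
directly.

Any polynomial with $r_1 = 1$ and nonzero interior coefficients is
realized by `tableau_from_polynomial()` as the canonical *efficient*
tableau: $b = (0, \dots, 0, 1)$ and a single subdiagonal
$\alpha_{s-j+1,s-j} = r_{j+1}/r_j$, so the nested products reproduce
the $r_j$ exactly and the step collapses to a fixed-point iteration
with $s - 1$ drift evaluations.

## Simulators and their contracts

The single-step kernels (`ssa_step()`, `poisson_tau_leap_step()`,
`rk_tau_leap_step()`, `rk_tau_leap_step_efficient()`) are pure-R
reference implementations; `simulate_ensemble()` runs whole
trajectories through compiled engines with identical per-step algebra.
Two exact-equivalence contracts are maintained *bitwise*, not just to
tolerance, by fixing the floating-point grouping of the update as
$X_n + \sum_j \nu_j K_j + \left(\sum_j \beta_j g_j - g_1\right)$ with
$g_i = \tau f(Y_i)$:

* the $s = 1$ tableau reproduces the Poisson $\tau$-leap exactly under
  a shared RNG stream (the correction term is exactly zero, and states
  remain integers);
* the efficient kernel reproduces the general kernel on subdiagonal
  tableaus (the general stage loop encounters exactly one nonzero
  term, in the same operation order).

Both contracts are asserted in the test suite at the single-step level
and over whole compiled ensembles.

Other simulator conventions:

* **States.** RK states are real-valued between steps (the $\tau f$
  terms are not integer-preserving); histograms round to the nearest
  integer before comparison.  SSA and Poisson $\tau$-leap states stay
  integer.
* **No clamping.** Intermediate-stage propensities are evaluated by
  the raw formulas even at slightly negative stage excursions; only
  the Poisson means at the step start are sign-checked.
* **Failure semantics.** A replicate is *failed* when a Poisson mean
  is negative at a step start, or a coordinate becomes non-finite or
  exceeds $10^{12}$ in magnitude (configurable).  Failures are counted
  and reported as a rate — flagged above $10^{-3}$ — rather than
  raised, because how negative populations "should" be handled by
  these methods is a modelling convention, not part of the scheme.
* **Reproducibility.** Each replicate runs on its own L'Ecuyer-CMRG
  substream derived from the master seed by stream jumps
  (`parallel::nextRNGStream`), so ensembles are reproducible and
  independent of replicate execution order.

## Reference systems and the network generator

The isomerisation system supplies exact stationary moments and the
binomial stationary law; the Schlögl system (four channels on one
species; the two non-autocatalytic species buffered into the rates) is
the stiff nonlinear benchmark with a bimodal stationary density.  The
buffered counts are required configuration; the shipped default
scenario $A = 10^5$, $B = 2\cdot10^5$, $X_0 = 250$ is a reconstructed
parameterization chosen for bimodality, and is documented as such
rather than as a printed reference value.

`random_linear_network()` is the synthetic fixture generator for the
linear theory: conservative unimolecular transfer networks (each
channel moves one molecule between two species, so update vectors sum
to zero and $W$ has zero column sums) with rates uniform on $(0.5,
1.5) \times$ `rate_scale` and Poisson initial counts.  It emulates
exactly the class of systems for which the mean-propagation and
stationary-variance theory is exact; it does *not* emulate nonlinear
propensities, multi-molecule stoichiometry, or near-zero copy numbers,
so passing its property tests validates the linear machinery — the
Schlögl tests are what probe nonlinear behaviour, and only
qualitatively.

## Ensemble statistics

`relative_variance_estimate()` reports $\hat\psi$ = sample stationary
variance / analytic variance with a bootstrap standard error (200
resamples, internally seeded so reports are reproducible).
`kl_divergence()` computes $D(P_E, P_M) = \sum_x P_E(x)\log_2
(P_E(x)/P_M(x))$ in bits.  `histogram_comparison()` fixes the two
conventions the divergence needs:

* **Support.** The shared support is the union of *observed* integer
  values (after rounding RK states), with no truncation; an analytic
  reference pmf is restricted to it and renormalized.  At $10^4$
  samples this makes the exact-sampler KL floor about $0.004$ bits on
  the isomerisation law (plug-in bias $\approx (K-1)/(2N\ln 2)$ over
  $K \approx 60$ occupied bins), safely under the $0.005$-bit
  acceptance threshold used in the tests.
* **Smoothing.** If the method pmf still has empty bins on the
  reference support, add-half (Jeffreys) pseudo-counts are applied to
  the method pmf only, identically across methods, and the result is
  flagged — the divergence is simply undefined otherwise, and any
  choice here is a reporting convention.

## Problem sizes and tolerances used by the tests

The test suite runs ensembles of $10^4$ replicates for the acceptance
layer ($\hat\psi$ at $z \in \{-1, -3, -8\}$, SSA exactness, Schlögl
bimodality) and $2000$–$4000$ for unit-level property checks; Monte
Carlo assertions use 3–3.5 standard errors.  These sizes put the
statistical resolution of $\hat\psi$ near $\pm 4\%$, comfortably
inside the designed $\varepsilon$ bands, while keeping the default
suite fast.  Interval scans use a $10^4$-point pre-scan over
$(-200, 0]$ refined by bisection to $10^{-6}$ — the scan density is
configurable because $\psi$ and $|R|$ can violate constraints on thin
windows between grid points at high stage counts.  Unbounded intervals
return the explicit sentinel `Inf`, never a large float.

## Known limitations

* The variance theory is exact only for linear kinetics; on nonlinear
  systems the methods are first-order accurate in the weak sense and
  validated empirically (Schlögl), not analytically.
* No adaptive $\tau$ selection, no implicit or binomial $\tau$-leap
  simulation, no delayed reactions, and one Poisson set per step
  (multiple sets would be a different method family).
* Stability is analysed on the negative real axis only, which is where
  linear reaction spectra live; complex-plane stability regions are
  out of scope.
* The optimizer certifies the stability polynomial, not nonlinear
  order conditions; all tableaus with the same $R(z)$ are equivalent
  for linear problems, and the efficient subdiagonal realization is
  chosen among them for its cost.
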