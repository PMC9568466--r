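---
title: "Habitat-choice games coupled to predator-prey dynamics: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat-choice games coupled to predator-prey dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgame)
```

## The model

`popgame` studies a water column $X = [0, 100]$ m inhabited by two
unstructured populations: zooplankton consumers with biomass $N_c$ and
forage-fish predators with biomass $N_p$ (both g m$^{-3}$). Each individual
continuously chooses a depth distribution — a probability density $\sigma$
over $X$ with respect to the uniform measure $\mu$ — and, because migration
is fast relative to demography, the distributions are assumed to equilibrate
instantaneously to the mean-field Nash equilibrium of the habitat game at
the current biomasses. The slow dynamics are a Kolmogorov system
$\dot N_i = N_i f_i$ whose per-capita rates are built from three
depth-dependent fields:

* a light profile $\phi(x) = e^{-kx}$ setting the consumer carrying
  capacity $K\phi + K_0$ (phytoplankton grows near the surface),
* a predation-success profile $D(x) = e^{-k\kappa x^2}$ for the visual
  predator, entering its clearance rate $\beta_p = b\,m_p^{3/4} D + \beta_0$,
* a constant consumer clearance $\beta_c = b\,m_c^{3/4}$ (olfactory
  forager).

The consumer grows logistically against the local capacity averaged over its
distribution; the predator has a Type II functional response in the
encounter rate $B = N_c \langle \beta_p \bar\sigma_c, \bar\sigma_p\rangle$,
a metabolic loss $\mu_p$ and an optional quadratic intraspecific competition
loss scaled by $c$. Consumer mortality is tied to predator growth by biomass
flux: $\varepsilon N_c M_c = N_p G_p$.

Individual payoffs are the individual growth rates. The consumer's payoff is
*linear* in its own strategy, so its strategy gradient is a pointwise
fitness field and its mean payoff equals its per-capita growth rate — which
forces the consumer's equilibrium fitness level to equal $f_c$, hence zero
at any coexistence fixed point. The predator's payoff is nonlinear (its own
satiation), with gradient
$\varepsilon F_p^2 N_c \beta_p \bar\sigma_c / (F_p + B)^2
 - c N_p \beta_p \bar\sigma_p$.

## Parameters

Defaults follow Kleiber scaling with the standard table for this system:
$m_c = 0.01$ g, $m_p = 10$ g, $b = 27.5$ g$^{1/4}$m$^3$/month,
$F_p = 7$ month$^{-1}$, $\mu_p = 0.35$ month$^{-1}$, $\varepsilon = 0.1$,
$K_0 = \beta_0 = 10^{-4}$, $k = 0.05$ m$^{-1}$, $\kappa = 0.1$ m$^2$.
Two printed values disagree with their scaling formulas
($\mu_p$ vs $\gamma m_p^{3/4} \approx 1.12$; $F_p$ vs
$\alpha m_p^{3/4} \approx 7.03$): the tabulated values are the defaults and
`derive_from_scaling = TRUE` switches to the formulas. The exponent of $D$
is stated as "$k/m$" with $m$ unexplained; we read it as $k \cdot \kappa =
0.005$ m$^{-2}$ (predation success decays over the top 20–30 m, consistent
with the predator distributions this produces) and expose it as the single
override `d_coef` so an alternative reading costs one argument.

The habitat measure $\mu$ is taken *normalized* (the uniform probability
measure on $[0,100]$), so the constant density $\sigma \equiv 1$ is the
uniform strategy; the source text calls $\phi$ a probability density but
prints $\phi = e^{-kx}$, which does not integrate to 1 against $\mu$ — we
follow the printed formula.

## Discretization

Space is discretized on a uniform closed grid (default 300 nodes) with
trapezoidal quadrature normalized so the weights sum to one. All inner
products, hence all model terms, go through this quadrature; it integrates
linear functions exactly and converges at second order, which the test suite
verifies against closed-form integrals.

## Solving the instantaneous game

The first-order conditions for the symmetric mean-field equilibrium are, per
living species, stationarity $g_i - \lambda_i + \nu_i = 0$, primal
feasibility ($\sigma_i \ge 0$, $\int \sigma_i \, d\mu = 1$), dual
feasibility $\nu_i \ge 0$ and complementary slackness
$\langle \sigma_i, \nu_i\rangle = 0$. We eliminate the slacks with the
Fischer–Burmeister function $\psi(a,b) = a + b - \sqrt{a^2+b^2}$, whose
zeros are exactly the complementary pairs, giving a square semismooth system
in $(\sigma_c, \lambda_c, \sigma_p, \lambda_p)$. It is solved by damped
Newton iteration with analytic Jacobians (each block is diagonal plus a
rank-one coupling through $B$), an Armijo line search on the squared
residual, a Levenberg–Marquardt fallback when the plain step stalls, and a
smoothing homotopy ($\psi_\mu$ with $\mu \downarrow 0$) as a restart for
hard cold starts. Default tolerance is $10^{-9}$ on the residual infinity
norm; in practice converged solutions sit at $10^{-13}$–$10^{-15}$, which
matters because the predator game is genuinely ill-conditioned where
$\beta_p$ falls to $\beta_0 = 10^{-4}$ (deep water): a residual $r$ only
pins the strategy there to about $r/\beta_0$.

A species with zero biomass has no effect on the other's payoff through its
strategy, so its density is pinned to uniform by convention and excluded
from the residual accounting.

## The replicator oracle

`replicator_solve()` exists to check the Newton solver along an independent
algorithmic path. The naive simultaneous replicator iteration orbits the
equilibrium — the consumer flees the predator while the predator chases the
consumer, a rotation that no step-size schedule removes at useful speed —
and the deep-water ill-conditioning caps any first-order method far above
the 1e-6 agreement we want. The oracle therefore runs in two stages:
an extragradient-damped replicator iteration identifies the equilibrium
support, and an algebraic reduction polishes on that support: at fixed
encounter rate $B$ the two stationarity equalities are affine in
$(\sigma_c(x), \sigma_p(x))$ node by node and in
$(\lambda_c, \lambda_p)$ globally, so everything reduces to a single scalar
root-find in $B$ (log-scale scan plus bisection, no initialization). A
repair loop adds nodes with off-support fitness advantages and removes nodes
with negative eliminated densities; on grids with at most six nodes all
support pairs are enumerated outright. When the discretized game has several
equilibria (see below) the oracle returns the one nearest its own
stage-one iterate — a dynamic selection, not an enumeration-order accident.

## What the numerics revealed about uniqueness

Theory for this model asserts a unique Nash equilibrium for every biomass
pair, via strict pseudomonotonicity of the stacked operator $-dU$. Two
numerical observations qualify this on the discrete grid. First, at some
parameter combinations (e.g. $K \approx 25$, $c \approx 0.7$, $N_c \approx 3$
on a 3-node grid) the support enumeration finds two equilibria — an interior
and a corner one — each satisfying every first-order condition at
$10^{-14}$. Second, the Lemma-style differential probe finds feasible
directions of negative curvature at sampled points, while the definitional
pairwise implication test finds no violations in hundreds of samples.
Positive curvature is sufficient, not necessary, for strict
pseudomonotonicity, so the property is unrefuted pointwise but evidently
not uniform over the state space of the discretized game. Consequently the
pseudomonotonicity diagnostic gates its pass flag on the definitional test
and logs the minimal curvature in its details.

## Coupled population–Nash fixed points

`solve_coexistence_equilibrium()` finds $(N_c^*, N_p^*) > 0$ with
$f_c = f_p = 0$ under equilibrium behavior by damped Newton on
$(\log N_c, \log N_p)$ with a finite-difference Jacobian, warm-starting
every inner game solve. Because the behavioral equilibrium is attracting in
practice, a stalled Newton falls back to pseudo-time relaxation
($N_i \leftarrow N_i e^{h f_i}$, adaptive $h$) and re-enters Newton — this
combination converges from arbitrary starts across the $(K, c)$ ranges we
sweep. The search box is $[10^{-6}, 10^4]$ g m$^{-3}$ per axis; an iterate
pinned to the lower edge raises a no-coexistence error describing the
boundary behavior.

Two structural facts are worth noting. The consumer's linear payoff forces
$\lambda_c = f_c = 0$ at any coexistence equilibrium — the zero-fitness
ideal free distribution — and the tests assert this at $10^{-6}$. For the
predator, the analogous level $\lambda_p$ is the strategy-gradient height,
from which the constant $\mu_p$ has dropped out; nothing forces it to zero
and the package reports it without asserting a value. And behavior is what
enables coexistence at low enrichment: at $K = 3$ the *constant-behavior*
planar system has no positive fixed point at all (the closed-form $N_p^*$
is negative), while the behavioral system has a comfortable one.

## Transient dynamics

`simulate_population()` integrates $\dot N_i = N_i f_i$ by forward Euler
(default $h = 0.01$ month), re-solving the game each step in `optimal` mode
(warm-started; transients are smooth) or pinning strategies to uniform in
`constant` mode, which reproduces the classical planar system with averaged
coefficients. Populations are clamped at zero and the clamping recorded.
At $K = 40$, $c = 0$ the constant-mode system sits beyond its Hopf
bifurcation and sustains a limit cycle of period $\approx 23$ months;
the optimal-mode system from the same initial state collapses onto the
stable coexistence point within a few cycles. The oscillation diagnostic is
deliberately crude — peak-to-peak amplitude over quarters of the run —
because the published claims are qualitative, and the initial state
$(N_c, N_p) = (0.5, 0.03)$, step and horizon (240 months) are declared
choices: the source figures do not print theirs, so the tests check the
limit-cycle-vs-damping *contrast*, not a curve overlay.

## The synthetic world and what a green test establishes

There is no external data: grids, parameter records and sampled strategy
profiles are the package's entire world, generated in code. Random
configurations for the oracle-equivalence and gradient checks are drawn
from the model's operating regime — $K$ log-uniform on $[0.5, 40]$, $c$
uniform on $[0, 1]$, $N_c$ log-uniform on $[0.05, 2]$ and $N_p$ on
$[0.005, 0.5]$, spanning the equilibria and transient excursions the
dynamics actually visit — under fixed seeds. A green suite establishes
internal consistency (solver vs. oracle vs. closed forms vs. finite
differences) and the qualitative claims (trends, damping, ideal-free
structure) at these parameters; it does not establish anything about real
water columns, day–night light cycles, size structure, or the
infinite-dimensional problem the discretization approximates.

## Known limitations and numerical footnotes

* Grid convergence of the coexistence biomasses is second order, but the
  predator's sharp support edge makes its constant modest: $N_p^*$ differs
  by $1.9\times10^{-3}$ relative between 150 and 300 nodes (and
  $4\times10^{-4}$ between 300 and 600), while $N_c^*$ is already at
  $2\times10^{-4}$.
* The replicator stage of the oracle is a support detector, not a
  high-precision solver; all precision comes from the algebraic polish.
* The ESS check perturbs within a declared magnitude (default $10^{-3}$)
  because the underlying definition quantifies over "slight" perturbations
  without a metric; its conclusions are sampling statements.
* Sweep ranges ($K \in [0.5, 100]$ log-spaced, $c \in [0, 1]$ linear) are
  declared defaults; the published figures do not print their ranges.
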