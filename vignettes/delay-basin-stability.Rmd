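---
title: "Generalized basin stability for delayed dynamics: models, numerics, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized basin stability for delayed dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(delaybasin)
```

This vignette is the package's account of what it computes and why the
numerical choices are what they are.  It states no empirical number that
the test suite or `scripts/acceptance.R` does not itself recompute.

## 1. The estimand

For a delay differential equation
$\dot x(t) = f(x(t), x(t-\tau_1), \dots, x(t-\tau_d))$, $x \in \mathbb R^s$,
an initial condition is a continuous function on $[-\tau_{\max}, 0]$.  The
basin of attraction of an asymptotically stable state $\varphi^*$ is the
set of history functions whose solutions converge to it — a subset of an
infinite-dimensional space, with no canonical volume.

The generalized (order-$n$) basin stability replaces the function space
by a finite coordinate chart: fix a basis family $\{e_i\}$ and write a
history as $g_n(\theta) = \sum_{i=1}^n a_i e_i(\theta)$ per state
component, with every coefficient bounded, $|a_{ji}| \le \alpha$.  The
chart is the hypercube $C_{(n,\alpha)} = [-\alpha, \alpha]^{s n}$, which
carries ordinary Lebesgue measure.  The order-$n$ basin stability of
$\varphi^*$ is the fraction of $C_{(n,\alpha)}$ whose reconstructed
histories lie in the basin, i.e. the basin volume normalized by
$(2\alpha)^{sn}$ — and therefore directly comparable across $n$ and
$\alpha$.  It is estimated by Monte Carlo: $T$ i.i.d. uniform draws,
integrate, classify, $\hat p = M/T$.

Two caveats are inherent and documented rather than hidden.  First, the
number depends on the basis family and on $(n, \alpha)$; it is an
*indexed family* of basin measures, not a single invariant.  The package
therefore treats stabilization-in-$n$/-$\alpha$ and agreement of the
*trends* across three structurally different families (two orthonormal,
one not) as the acceptance condition — `convergence_scan()` and
`basis_consensus()` implement exactly that and fail explicitly when the
condition is not met.  Second, a convergence proof as $n \to \infty$ is
not available; the package's claims are empirical and scoped to the
scanned grid.

## 2. Bases and the domain map

* trigonometric: $1/\sqrt{2\pi},\ \cos k\theta/\sqrt\pi,\ \sin
  k\theta/\sqrt\pi$ on $[-\pi,\pi]$, cosine before sine at each $k$;
* Legendre: $\sqrt{(2k+1)/2}\, P_k$ on $[-1,1]$, degrees $0..n-1$;
* Bernstein: $B_{i,n-1}$ on $[0,1]$, kept non-orthogonal (it is used as a
  generating family, and its partition-of-unity structure is the point of
  including a non-orthogonal member in the cross-validation).

The exact normalization of the first two families is the standard
unit-$L^2$ choice; it matters only in that it makes one coefficient bound
$\alpha$ comparable across families.  Histories on $[-\tau, 0]$ are
obtained through the orientation-preserving affine map onto the natural
domain.  Coefficients are interpreted in the natural domain and *not*
Jacobian-rescaled under the map: the hypercube itself is the measured
object, and any fixed bijection between chart and function space is
admissible; this is the simplest.  Each of the $s$ components gets an
independent coefficient row, so the chart dimension is $s\,n$.

Projection is the quadrature inner product for the orthonormal families
(256-node Gauss–Legendre; exact to rounding for every product the
package forms) and least squares on a 512-point grid for Bernstein.

## 3. Integration: method of steps

Fixed-step classical RK4; delayed values come from the history for
$t - \tau < 0$ and from cubic Hermite interpolation of the stored
solution (values and derivatives at the grid) afterwards.  Design
choices, in decreasing order of consequence:

* **Step snapping.**  `dt` is snapped down so the smallest positive delay
  is an integer multiple; delayed lookups at whole steps then hit stored
  points exactly, removing interpolation error at the single-delay
  systems' lookups.  `dt` never exceeds the smallest positive delay, so
  all RK4 stage lookups lie in the completed past.
* **No discontinuity tracking.**  The solution of a DDE has derivative
  jumps at multiples of $\tau$; RK4 steps across them lose local order.
  The error is bounded and local, and two orders of magnitude below the
  $10^{-2}$ classification tolerance at the default steps; propagation
  tracking is not worth its complexity here.
* **Divergence is data.**  Any state leaving $[-10^6, 10^6]$ (or a
  non-finite right-hand side) flags the trajectory divergent and stops;
  divergent samples are reported in the unclassified count, never thrown
  as errors.  All attractors studied live at order 1–10.  One practical
  consequence: an explicit solver on a stiff cubic nonlinearity (the
  bistable fixture at large amplitudes) can blow up numerically; the
  fixture tests use `dt = 0.005`, at which no sampled history of the
  documented plans diverges.
* Zero-delay systems reduce exactly to classical RK4 (delayed arguments
  are the stage states), which the ODE-limit test exploits.

Trajectory order on smooth stretches is the nominal 4; the
grid-refinement test asserts a ratio $>8$ when halving `dt` against the
$e^{-t}$ closed form.

## 4. Attractors and classification

Equilibria of the DDE coincide with roots of the right-hand side with all
delayed arguments frozen at the instantaneous state; `find_equilibria()`
polishes a $41\times41$ grid of Newton seeds and flags stability by the
zero-delay Jacobian spectrum.  That flag can miss delay-induced
instability, so `revalidate_attractors()` integrates small random history
perturbations at the working delay and drops attractors that fail to
recapture them (`bs_vs_parameter(revalidate = TRUE)` re-runs this per
grid point and records destabilized attractors as $\hat p = 0$ with a
flag).  For the Hopfield defaults the delayed self-feedback gains at all
four stable equilibria are below the decay rate, so no delay
destabilization occurs at any $\tau$ — the revalidation test confirms
this empirically rather than assuming it.

A trajectory is classified to an attractor when its sup-norm distance
stays below $\delta = 10^{-2}$ throughout the final 20 time units of a
300-unit run (settle time 200).  The four Hopfield equilibria are
separated by order-1 distances; the attractor-set constructor enforces
pairwise separation $> 3\delta$, which makes double classification
impossible.  Anything else — divergent, still transient, oscillating — is
"unclassified", counted separately, and *never* assigned to the nearest
attractor; conservation $\sum_k M_k + M_{\text{uncl}} = T$ holds exactly
by construction.  The compiled sampling loop classifies a trajectory
early once it has stayed within $\delta/2$ of one attractor for a full
window; for trajectories that truly settle this provably agrees with the
final-window rule, and `early_exit = FALSE` gives the literal rule for
cross-checking (one suite test pins the two paths to identical counts).

The Hopfield labels follow the basin phenomenology: E1/E2 are the
anti-diagonal pair $\pm(u_m, -u_m)$ whose basins empty as $\tau$ grows,
E3/E4 the diagonal pair $\pm(u_d, u_d)$ that ends up dominant with equal
shares.  The coordinates are found by the census, not assumed; the suite
cross-checks them against one-dimensional bisection along the symmetry
lines $u_1 = \pm u_2$.

## 5. Sampling design

Coefficients are i.i.d. uniform on $[-\alpha, \alpha]$ (no importance
sampling; the estimand is the plain hypercube fraction).  Defaults for
the Hopfield study are $\alpha = 6$, $n = 20$: the values at which the
convergence scan stabilizes, per its own criterion.  Sample counts come
from the standard binomial planning rule
`choose_sample_size(w, level)` $= \lceil z^2 p(1-p)/w^2\rceil$ at worst
case $p = 1/2$ (385 samples for a ±5% half-width at 95%).  Confidence
intervals are Wilson score intervals, which behave sanely at the
$\hat p \in \{0, 1\}$ ends where the interesting curves live.  Identical
plan + seed gives bitwise-identical counts; every cell of a scan derives
its seed deterministically from the master seed.

The convergence scan's fluctuation statistic is the largest spread of
$\hat p$ (max over attractors) across a trailing window of 3 grid
points, with tolerance 0.02 set a priori.  Two deliberate design points:

* **Common random numbers.**  Within a basis, one $s \times n_{\max}
  \times T$ uniform draw is made and each $(n, \alpha)$ cell reuses its
  leading columns scaled by $\alpha$.  Neighbouring cells then share
  their histories except for the added terms, so the trailing-difference
  statistic measures systematic order-dependence instead of independent
  binomial noise.  With independent per-cell draws the statistic's noise
  floor ($\approx 2.2\times$ the binomial SE) would sit *above* any
  tolerance close to the standard error, making the criterion
  uninformative by construction.
* **Noise-floor warning.**  A tolerance below $\sqrt{0.25/T}$ is accepted
  but flagged; the scan records the warning in its result.

The scan still measures a real, slowly decaying $n$-sensitivity for this
model: at per-cell $T = 6000$ the statistic falls below 0.02 from
$n^\* = 16$ simultaneously for the three bases (the acceptance test runs
exactly this), while at $T = 2000$ the residual sampling noise of the
max-statistic straddles the tolerance.

For the delay sweep, $\hat p(E_1)$ curves are min–max normalized per
basis and compared by Spearman rank correlation with threshold
$\rho > 0.9$: the claim under test is consensus of *shape* (the exact
values differ across bases, as they must), and a rank correlation is the
weakest statistic faithful to that claim.  The acceptance sweep uses
$\tau \in \{1, \dots, 8\}$: the basin migration completes at different
delays for different bases — latest for Legendre, whose endpoint-heavy
members keep the anti-diagonal basins alive longest — and the grid must
span the full transition for "decays toward zero" to be observable.
Longer horizons (`t_end = 450`, settle 350) accompany the larger delays,
since transients scale with the delay span.

## 6. Delay-coupled networks

The network model is $N$ identical Rössler units,
$\dot x_i = F(x_i) - \sigma \sum_j g_{ij} E\, x_j(t-\tau)$, with
$G = D - A$ the Laplacian of a connected undirected graph and $E$ the
coupling projector ($x \to x$ coupling by default).  Zero row sums cancel
the coupling on the manifold, so the synchronous orbit obeys the plain
Rössler equations, and the transverse modes satisfy
$\dot\xi = DF(s(t))\,\xi - \varepsilon E\, \xi(t-\tau)$ with
$\varepsilon = \sigma\gamma_k$.  `msf_lambda()` estimates the largest
Lyapunov exponent of that delayed variational equation by long
integration with Benettin-style renormalization applied to the whole
discretized variational history segment — the state of a delayed system
is the segment, not a point — every 1 time unit, discarding a 200-unit
transient and averaging over 2000 units by default (3000 in the
acceptance script; the running-average fluctuation over the last half is
returned as a convergence diagnostic and flags non-converged estimates).
Defaults `dt = 0.01`; Rössler parameters $(a, b, c) = (0.2, 0.2, 7)$, the
standard choice of the non-delayed basin-stability literature for
synchronization, for which the zero-delay $x \to x$ master stability
function has its classic stable interval $\approx (0.19, 4.6)$ — the
zero-coupling limit and the linear-node characteristic-root oracle pin
the machinery in the suite.

The Methods-level description of the coupled system leaves the precise
delayed-coupling convention genuinely open (self-term delayed or
instantaneous, coupling component, orbit feedback).  The package
implements the fully delayed Laplacian convention above as the default —
it is the only single-parameter family consistent with normalizing by
$\varepsilon = \sigma\gamma_k$ alone — and exposes the alternatives
(`component = "x"/"y"/"z"/"all"`, `c_inst`, `c_orbit`) so transmission-
delay variants can be studied with the same estimator.  Under the default
convention the delayed feedback is purely destabilizing at short delays:
the stable band shrinks with $\tau$ and no re-entrant stable regime at
large $\varepsilon$ exists (for $x \to x$ coupling, quenching $\xi_x$
leaves $\dot\xi_y = \xi_x + a\xi_y$ with $a > 0$, so a large-$\varepsilon$
stable regime is structurally impossible around the chaotic orbit).  The
acceptance script reports the honestly bisected boundary of the stable
set under this convention.

Given a graph, `stable_sigma_range()` intersects
$\{\sigma : \sigma\gamma_k \in \text{stable set}\}$ over all transverse
modes; for a single stable interval this reduces to
$(\varepsilon_{\text{lo}}/\gamma_2,\ \varepsilon_{\text{hi}}/\gamma_{\max})$,
empty exactly when the synchronizability $R = \gamma_{\max}/\gamma_2$
exceeds $\varepsilon_{\text{hi}}/\varepsilon_{\text{lo}}$ — the algebra
the suite checks.  An empty range is a *result* (the network cannot
synchronize stably at this delay), reported as mean basin stability 0
with a flag.

Mean basin stability of the synchronization manifold: 10 equally spaced
$\sigma$ values across the admissible range (arc-length spacing across a
union of intervals, midpoint rule — endpoints sit at the margin of
stability and would measure the threshold, not the basin); per $\sigma$,
$T = 200$ histories, each node's history being a fixed reference point on
the Rössler attractor (a long deterministic pre-integration) plus an
independent trigonometric expansion of order 5 with coefficients uniform
on $[-\alpha, \alpha]$, $\alpha = 1$ — an order-1 perturbation relative
to the attractor's own scale, large enough to leave the basin at
unfavourable topologies without trivially killing synchrony everywhere.
The network perturbation protocol is the package's own documented choice,
not a published one.  A sample is synchronized when the largest pairwise
node distance stays below $10^{-2}$ over the final 10% of an 80-unit run
(`dt = 0.04`; the sparse-Laplacian compiled loop makes the full sweep a
few minutes).  The sweep at $N = 30$, $k = 6$, $\tau = 0.4$, 5 network
realizations per rewiring probability reproduces the qualitative
phenomenology — mean basin stability peaks at intermediate rewiring and
declines toward the random-graph end, while the synchronizability ratio
trends downward — with one scale caveat: at $N = 30$ the ring's $R$ is
only marginally above the admissible ratio, and $R(p)$ flattens (and can
tick up) near $p = 1$, so the suite tests the decreasing *trend*
(Spearman) and the endpoint ordering rather than strict per-point
monotonicity, which is a property of larger lattices.

## 7. Fixtures as oracles

The machine-checkable fixtures (`fixture_system()`) are first-class code:
a symmetric bistable scalar DDE (equal basins by oddness), a linear
globally stable DDE ($\hat p \equiv 1$ for any plan), a shifted
double-well whose basin in coefficient space is an explicit half-space
(the classifying functional is linear in the coefficients, so the
hypercube fraction is computable without integrating the DDE), the
scalar delayed variational equation whose exponent is the dominant root
of $\lambda = -1 - \varepsilon e^{-\lambda\tau}$ (solved independently by
damped complex Newton from a grid of starts), and the complete graph
($R = 1$ exactly).  Every Monte-Carlo result in the package is pinned to
at least one of these independent routes in the suite.

What the synthetic setups do *not* emulate: observational noise,
parameter uncertainty, non-identical network units, state-dependent or
distributed delays.  Passing tests certify the estimator and its
bookkeeping on clean models, not robustness of basin-stability readings
on measured systems.

## 8. Problem sizes

Suite and acceptance runs use desk-scale sizes chosen once: $T = 1000$–
$6000$ for Hopfield sampling, $\tau$ grids of 8 points, MSF averaging
2000–3000 time units, network sweeps at $N = 30$ with 5 realizations and
$T = 200$ per $\sigma$.  Full-size runs ($N = 100$, larger $T$) use the
same code paths through the exported arguments.

## 9. Known limitations

* The estimate is basis- and chart-relative by definition; the scan can
  only certify stabilization on the scanned grid.
* Explicit fixed-step integration: no stiff systems, no state-dependent,
  distributed or neutral delays (out of scope by design).
* Equilibrium attractors are fully supported; periodic attractors are
  classified by distance to reference orbit samples, but no automatic
  discovery of unknown attractors is attempted — an incomplete attractor
  set shows up as unclassified mass, which is reported, never silently
  reassigned.
* The delayed-coupling convention ambiguity above: quantitative MSF
  boundaries are convention-dependent, and only the implemented
  convention's numbers are claimed.
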