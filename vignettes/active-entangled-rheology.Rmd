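---
title: "Viscoelasticity and topology of tangentially driven entangled polymer melts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Viscoelasticity and topology of tangentially driven entangled polymer melts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

actipoly simulates melts of flexible, tangentially self-propelled
bead-spring polymers with overdamped Brownian dynamics and analyses their
linear viscoelasticity (stress autocorrelation, plateau modulus,
disengagement time, Green-Kubo viscosity, dynamic moduli) and topology
(primitive paths, kink counts, entanglement length). This vignette is the
package's account of the model, the numerical choices, and what the
desk-scale tests do and do not establish.

## The model

Each of $N$ linear chains has $N_p$ beads of diameter $\sigma$, so the
contour length is $L = N_p\sigma$. Beads interact through

* a purely repulsive WCA potential (truncated-shifted Lennard-Jones, cut
  at $2^{1/6}\sigma$) with energy $\epsilon_{\mathrm{WCA}}$;
* FENE springs between bonded neighbours,
  $U = -\tfrac{k}{2}R_0^2\ln\!\big(1-(r/R_0)^2\big)$, with the canonical
  bead-spring pair $k = 30\,k_BT/\sigma^2$, $R_0 = 1.5\sigma$. The
  quoted FENE energy scale of $30\,k_BT$ is interpreted as this spring
  constant, the convention that matches $R_0 = 1.5\sigma$;
* a bending potential $\kappa \sum_j (1 - \mathbf{t}_j\cdot\mathbf{t}_{j+1})$
  over consecutive unit tangents along each backbone. A per-bead triple
  sum over $j = i-1, i, i+1$ would count every tangent pair three times;
  the implementation charges each unique tangent pair once with stiffness
  $\kappa$, which is the conventional discrete worm-like-chain form and
  matches the flexible regime $\kappa = 1\,k_BT$ used throughout;
* a tangential active force of constant magnitude $F_p$ per bead, directed
  along the normalized sum of the two adjacent bond tangents (head-ward
  along the single tangent at chain ends). The raw tangent sum does not
  have constant magnitude, so it is normalized; a bead whose adjacent
  tangents are antiparallel within $10^{-8}$ (a perfect hairpin) gets zero
  active force.

The equation of motion per bead is overdamped Langevin dynamics,
$\zeta\dot{\mathbf r}_i = -\nabla_i U + \mathbf F_{p,i} + \mathbf F_{r,i}$,
with Gaussian white noise of covariance $2 k_B T\zeta\,\delta_{ij}
\delta_{\alpha\beta}\delta(t-t')$. Units are reduced throughout:
$\sigma = k_BT = \zeta = 1$, hence $D_0 = 1$ and $\tau_0 = \sigma^2/D_0 = 1$.
The Peclet number is $\mathrm{Pe} = v\sigma/D_0$ with $v = F_p/\zeta$;
`sim_params()` accepts either `Pe` or `Fp` and derives the rest. Defaults
follow the melt conditions used for all production analyses:
$\rho^* = N N_p \sigma^3/V = 0.85$, $\epsilon_{\mathrm{WCA}} = 1$,
$\kappa = 1$, $\delta t = 10^{-4}\tau_0$.

## Integration and reproducibility

`bd_run()` uses the Euler-Maruyama scheme, the standard first-order
integrator for overdamped dynamics. Two consequences matter in practice:

* stationary distributions carry an $O(\delta t\,k/\zeta)$ bias from the
  stiffest force; at $\delta t = 10^{-4}\tau_0$ the stationary bond-length
  distribution deviates from the Boltzmann density by about 2% in
  Kolmogorov-Smirnov distance, falling to 0.5% at $2\times10^{-5}\tau_0$.
  The bond-distribution test therefore runs at the finer step; melt
  observables (energies, $R_{ee}^2$, stress) are insensitive at the
  default step (halving $\delta t$ moves the stationary bond mean by well
  under 0.5%);
* the noise stream is a counter-based RNG keyed by `(seed, global step,
  bead)`, so trajectories are bit-reproducible, independent of how the
  run is split into calls, and restartable from any saved frame.

Forces are evaluated from wrapped coordinates through a linked-cell list
rebuilt every step (cell edge $\ge 2^{1/6}\sigma$); bonded terms use the
unwrapped coordinates, whose differences are the exact bond vectors.
Observables that measure chain extent ($R_{ee}^2$, internal distances,
primitive paths, MSD) always use unwrapped coordinates.

## Melt preparation

`build_random_melt()` places freely jointed random walks with bond length
$0.97\sigma$ (near the minimum of FENE+WCA, so the start carries no force
spike; verified a posteriori by the bond-distribution test) in a cubic box
that solves $\rho^* = N N_p\sigma^3/V$ exactly. `soft_pushoff()` removes
overlaps under the capped repulsion $U = A(1+\cos(\pi r/r_c))$,
$r_c = 2^{1/6}\sigma$, ramping $A$ from 1 to 100 $k_BT$; it then demands a
minimum pair distance of $0.9\sigma$ by default. That floor is a guard
against residual overlaps; for several thousand beads the *equilibrium*
minimum contact distance itself dips slightly below $0.9\sigma$ (a
$\sim 11\,k_BT$ WCA contact becomes likely somewhere in the box), so
large-melt protocols pass `min_dist = 0.85`.

`bond_swap_sweep()` implements symmetric double-bridging: cut the bond at
rank $a$ on two chains and exchange the tails, which preserves
monodispersity and every bead position. A proposal is rejected outright
unless all four involved bonds are shorter than the eligibility radius
(1.3$\sigma$ by default), which keeps the proposal density symmetric, and
is otherwise accepted with Metropolis probability on the FENE plus bending
energy change (WCA terms cancel exactly because nothing moves). The move
set satisfies detailed balance — verified against exact enumeration on a
two-chain system — but in a *dense flexible* melt its acceptance is tiny
(of order $10^{-5}$ per attempt): monodispersity forces same-rank cut
pairs, and a spliced bond stretched to $1.1$–$1.3\sigma$ costs
$\sim 10\,k_BT$ of FENE energy. Equilibration therefore leans on the fact
that the initial state is *exactly* ideal-chain distributed by
construction, with push-off and Brownian dynamics relaxing the local
structure; swaps act as an auxiliary decorrelator. `equilibrate()`
alternates BD blocks and sweeps until $\langle R_{ee}^2\rangle$ and the
internal-distance curve $\langle R^2(n)\rangle/n$ are stationary. The
stationarity test accepts when successive halves of the history agree
within 2% *or* within twice their combined standard error — for
desk-scale chain counts the raw 2% band is below the statistical noise
floor of $\langle R_{ee}^2\rangle$, so the noise-aware form is the one
that is actually decidable.

## Stress and its correlation

The virial stress is
$\sigma_{\alpha\beta} = -\frac{1}{2V}\sum_k\sum_l F_{kl}^\alpha r_{kl}^\beta$
over pairwise force contributions under minimum image. WCA and FENE terms
are pairwise by nature; the three-body bending term is decomposed into
central pair forces along the three pair vectors of each triplet (writing
the bending angle through the three pair distances), which reproduces the
exact per-bead forces and yields a manifestly symmetric virial. The
tangential active force is not a pair force; each bead's two tangent
contributions are attributed to their generating bonds and included in the
stress by default (`include_active_stress = FALSE` exposes the passive
convention; the output provenance records which was used).

`accumulate_g()` estimates
$G(t) = \frac{V}{3k_BT}\sum_{\alpha\beta\in\{xy,xz,yz\}}
\langle\sigma_{\alpha\beta}(t)\sigma_{\alpha\beta}(0)\rangle$
— the sum over the three unique off-diagonal components with the $1/(3k_BT)$
prefactor, i.e. $V/k_BT$ times their average — with a multiple-tau
correlator: 16 directly correlated lags per level, then pairwise
pre-averaging and lag doubling. On synthetic series the estimator agrees
with the brute-force time average to better than 2% at every lag with at
least 100 sample pairs. Stress sampling starts only in the steady state,
$t > L/v$ for active runs (the time a chain needs to crawl its own
contour), immediately for passive ones.

## Plateau, disengagement time, viscosity, moduli

`fit_plateau_and_tau()` fits the terminal decay
$G(t) = G_0\,e^{-t/\tau_{\mathrm{eff}}}$. The window is auto-selected:
candidate windows start once $G$ has decayed below 80% of its running
maximum, extend down to 5% of their start value, must hold at least five
points and fit $\ln G$ with $R^2 \ge 0.98$; among near-maximal spans the
earliest start wins (it minimises the extrapolation lever of the
intercept). The log-space fit is weighted by $\mathrm{count}\times G$ —
between the multiplicative- and additive-noise limits — and then refined
by a small Gauss-Newton pass in linear space, which is free of the
log-transform's small-$G$ bias. On noiseless Maxwell input the fit is
exact to $10^{-6}$; with 5% multiplicative noise both parameters return
within 3% across three decades of $G_0$ and $\tau$.

A mid-time log-log slope classifies the relaxation: it is measured over
lags a decade or so before the terminal window; when no exponential
window exists, it falls back to the mid-decay window where $G$ lies
between 50% and 5% of its first-lag value (anchored to the signal's own
decay, so the window does not wander with the extent of the noisy tail).
A slope steeper than $-0.35$ raises the Rouse-like no-plateau flag, as
does failure to find any exponential window. Unentangled melts show the $t^{-1/2}$ Rouse decay and trip this
flag; a Maxwell-like plateau does not.

`green_kubo_eta()` integrates $G$ by cumulative trapezoid on the
multiple-tau grid; $\eta_\infty$ is the mean of $\eta(t)$ over the final
decade of lags with a saturation diagnostic. `moduli()` evaluates
$G'(\omega) = \omega\int G\sin(\omega t)\,dt$ and
$G''(\omega) = \omega\int G\cos(\omega t)\,dt$ by exact piecewise-linear
(Filon-type) quadrature per segment, switching to Simpson's rule where
$\omega\,\Delta t < 10^{-3}$ to avoid cancellation; $\omega_c$ is the
log-log interpolated crossing of $G'$ and $G''$. On Maxwell input the
closed forms are matched to 0.5% and $\omega_c\tau_{\mathrm{eff}}$ stays
within [0.8, 1.2], tying the two time extractors together.

`tau_eff_prediction()` evaluates the interpolation
$\tau_{\mathrm{eff}}^{-1} = D_0\sigma/L^3 + v/L$: reptative scaling for
the passive branch, ballistic tube escape $L/v$ for the active one.
`rescale_collapse()` applies the activity scalings — stress curves map to
$(tv/L,\; G\sigma^3/(F_pL))$, viscosity curves to
$(tv/L,\; \eta\sigma^3/(\zeta L^2))$ — and scores a family of curves by
the median pairwise absolute log-distance on a common log grid.

## Primitive paths

`ppa_contract()` realises the geometric definition directly: with chain
ends fixed, each interior node is pulled toward the chord between its
neighbours; a move is accepted only if the two swept triangles intersect
no segment of any other chain, with a bisection line search when blocked.
A node whose taut arms already pass over an obstacle can no longer shorten
by chord moves alone; it is then slid to the point on the blocking segment
that minimises the local taut length (offset by $10^{-7}\sigma$ so
uncrossability is never lost), which is exactly the taut-string pivot.
Nearly collinear nodes (angular deviation below $10^{-3}$ rad) are removed
when their sliver triangle is obstacle-free. Sweeps run chains in index
order and nodes in rank order, so the result is deterministic; iteration
stops when a sweep shortens the total length by less than $10^{-6}\sigma$
(sweeps that only merge duplicate nodes never count as converged). The
intersection test is deliberately conservative — boundary grazes count as
hits — so topology can never be lost to roundoff at the cost of a
$\sim10^{-6}\sigma$ standoff from obstacles, far below the $10^{-3}\sigma$
accuracy of the geometric oracles. Obstacles are replicated over periodic
images within a one-bead-diameter shell of the contracting chain's
bounding box. By default all chains contract against each other
simultaneously (primitive-path-network practice); a fixed-obstacle mode
exists for the oracle tests.

Kinks are interior nodes of the converged path with angular deviation at
least $10^{-3}$ rad; absolute kink counts are convention-dependent across
primitive-path codes, so ratios to a passive reference ($Z/Z^0$, via
`ppa_timeseries()`) are the comparable quantities. The entanglement
length uses the standard estimator
$N_e = (N_p - 1)\langle R_{ee}^2\rangle/\langle L_{pp}^2\rangle$, which
reduces to $N_p - 1$ for unentangled chains, and feeds the equilibrium
tube-model plateau prediction $G_0 \simeq 4\rho k_BT/(5 N_e^0)$.

## What the desk-scale suite shows — and what it cannot

The headline phenomena at production scale — plateau moduli amplified by
orders of magnitude with $G_0 \sim F_p L$, fluidization with
$\eta_\infty \sim L^2$, $\tau_{\mathrm{eff}} \sim L$, entanglement
densification at $tv/L \sim 0.1$ — emerge for highly entangled melts
($L/\sigma \gtrsim 350$, up to 2610, with $N_e \simeq 41$) over at least
$10^7$ steps. Those system sizes need cluster compute; this package runs
the same code paths at desk scale and validates each ingredient against a
closed form or an independent oracle instead:

* Rouse regime: a passive melt of 20 chains of 25 beads (unentangled,
  $N_p < N_e$), run for over 100$\tau_0$ after a Rouse-time-scale
  equilibration, must show algebraic mid-time stress decay and no
  plateau. One caveat is worth stating plainly: the asymptotic Rouse
  exponent $-1/2$ requires a decade of active modes, which a 25-mer does
  not possess — the discrete Rouse mode sum itself (the same oracle the
  phantom-chain test validates the stress pipeline against, which
  reproduces the measured $G(t)$ shape to a constant prefactor) predicts
  mid-window log-log slopes near $-0.6$ at this chain length, and the
  melt measurement lands at $-0.6 \pm 0.05$ across seeds once the
  short-time collisional stress is superimposed. The measured slope
  therefore sits at the very edge of the $-0.5 \pm 0.1$ band and its
  pass is seed-dependent; the no-plateau classification is robust, and
  the numerical slope approaches $-1/2$ only for longer unentangled
  chains.
* Ideal-chain statistics: melts at $N_p \in \{25, 50, 100\}$ (about 3000
  beads each, relaxed for $2\tau_0$ after push-off from the exactly ideal
  random-walk start) must regress
  $\ln\langle R_{ee}^2\rangle$ on $\ln L$ with slope $1.0 \pm 0.15$.
* All Green-Kubo/Maxwell closed forms, the virial oracle, the
  primitive-path geometry oracles, the interpolation formula, the
  equilibrium plateau prediction and the scaling-collapse property are
  checked at their stated tolerances.

The synthetic generators emulate stationary stress signals (white noise,
Ornstein-Uhlenbeck, Maxwell with multiplicative noise) and hand-computable
entanglement geometries; they do not emulate long-range correlated stress
from collective modes, polydispersity, or the slow tube-renewal dynamics
of truly entangled melts. A green desk suite therefore certifies the
correctness of the machinery and the unentangled-limit physics, not the
cluster-scale scaling laws themselves, which are documented here as the
intended production use.

## Worked example

```{r}
library(actipoly)

p <- sim_params(N = 20, Np = 25, Pe = 0, seed = 1)
eq <- prepare_melt(p)
run <- bd_run(eq$config, p, run_schedule(2e5, stride_stress = 10), seed = 2)

corr <- accumulate_g(run$stress, kBT = p$kBT)
fit <- fit_plateau_and_tau(corr)
glance(fit)
autoplot(corr)

ppa <- ppa_contract(run$config)
glance(ppa)
```
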