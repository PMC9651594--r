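---
title: "Models and methods: partially privatized public goods in well-mixed consumer-resource systems"
author: "privgoods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(privgoods)
```

## The scientific problem

Costly "public goods" — secreted compounds any neighbour can exploit — are
abundant in microbial communities that lack the spatial structure usually
invoked to protect producers from free-riders. `privgoods` implements two
mechanistic consumer-resource models of this situation for *consumable*
goods (resources that are drawn down by use, such as fixed nitrogen or
siderophore-bound iron), where the producer retains a *privatized* fraction
of its own product. The models are resource-explicit: the extracellular
environment is a dynamic state variable, so competitive outcomes depend on
resource supply and on how strains modify their environment, not only on
costs and benefits.

## The single-resource model

Two strains with densities $x_1, x_2$ compete for one resource $R$:

$$\frac{dx_i}{dt} = (g_i(R) - \delta)\,x_i, \qquad
\frac{dR}{dt} = \mu - \rho R + (1-\alpha) f(R)\,x_1 - U(R)(x_1 + x_2),$$

with $g_1(R) = (\alpha - \gamma) f(R) + U(R)$ for the producer and
$g_2(R) = U(R)$ for the loss-of-function non-producer. Production $f$ is
facultative (non-increasing in $R$), uptake $U$ is increasing, a fraction
$\alpha$ of production is retained privately, and production costs $\gamma$
per unit produced. Resource units are chosen so that one unit of acquired
resource buys one unit of per-capita growth (stoichiometric coefficient 1);
no unit-conversion layer is provided.

The forms of $f$ and $U$ are pluggable. The defaults,
$f(R) = b\ell/(\ell+R)$ and $U(R) = aR/(d+R)$, mirror the colimitation
model's kinetics and satisfy all shape assumptions. Because the assumptions
($f' \le 0$, $U' > 0$, $g_1' \ge 0$) are modelling constraints rather than
consequences of any formula, `single_resource_spec()` validates them
numerically on a 1,000-point grid over $[0, R_{\max}]$ (default
$R_{\max} = 100$) and rejects violating configurations.

The central results are the $R^*$ ordering (the strain viable at the lower
resource concentration excludes the other) and the privatization criterion:
the producer wins if and only if $\alpha > \gamma$ while production is
still active at the loser's equilibrium. Sufficiently subsidized producers
($\alpha \gg \gamma$) in weakly supplied environments can grow without
bound — the population feeds itself through privatized production — and the
integrator reports this as a distinct outcome rather than an error.

## The colimitation model

The second model tracks extracellular fixed nitrogen $N$, siderophores $S$
(treated as synonymous with bioavailable iron) and $n$ strain densities.
Per-capita rates, all facultative or saturating:

* fixation $f_N(N) = \ell b_i/(\ell + N)$ and siderophore production
  $f_S(S) = m q_i/(m + S)$ (half-inhibition constants $\ell, m$),
* uptake $U_N(N) = aN/(d+N)$ and $U_S(S) = uS/(p+S)$ (half-saturation
  constants $d, p$).

Fixed nitrogen is partially privatized: the producer keeps a fraction
$\alpha$ for growth and leaks $1-\alpha$; siderophores are fully public.
Total nitrogen acquisition is $\eta_i(N) = \alpha f_{N_i}(N) + U_N(N)$.
Growth is biochemically colimited: siderophore (iron) uptake sets the
half-saturation of growth on acquired nitrogen,

$$G_i(S,N) = \frac{r\,\eta_i(N)}{\eta_i(N) + h_i(S)}, \qquad
h_i(S) = \frac{r}{c}\,\frac{U_S(S) + k_S}{U_S(S)},$$

so $h$ rises from $(r/c)(1 + k_S/u)$ at saturating siderophore supply to
twice the uptake-unlimited value $r/c$ when $U_S = k_S$, and diverges as
$U_S \to 0$ (no growth without iron). Net per-capita growth subtracts the
production costs and mortality:
$G_i - \gamma f_{N_i}(N) - \beta f_{S_i}(S) - \delta$. Resource dynamics
add external supply $\mu_N, \mu_S$, washout $\rho$, leaked production and
uptake. With no cells the environment relaxes to the supply point
$(\mu_S/\rho,\ \mu_N/\rho)$.

A note on the factor $r/c$ in $h(S)$: $c$ is a siderophore *affinity*, so
larger $c$ must lower the half-saturation (cheaper growth at a given iron
uptake). The package consistently uses the $r/c$ scaling; the alternative
$r \cdot c$ scaling was examined during development and rejected because it
inverts the meaning of $c$ and degrades the model's internal consistency
checks.

Every base parameter set defines four strains sharing all parameters except
the production maxima: Full ($b, q$), LOFN ($b=0$), LOFS ($q=0$) and LOFB
($b=q=0$). For realism, parameter sets are constrained so that total
nitrogen acquisition $\eta(N)$ never decreases with ambient nitrogen
(facultative shutdown of fixation must not overcompensate rising uptake).
The package derives the closed form $\alpha b \le a \min(d/\ell, \ell/d)$
for this condition (the worst case of $d\eta/dN$ sits at $N=0$ or
$N \to \infty$) and cross-validates it against a dense numerical grid
check; the grid check is authoritative if the two ever disagree (they have
not, in $10^5$ tested draws).

## Parameters

All quantities are in the model's nondimensional units (resource
concentrations scaled to growth units, rates per unit time).

| symbol | meaning | sampling range | default |
|---|---|---|---|
| `mu_S` | siderophore input rate | [0, 1] | 0.001 |
| `mu_N` | nitrogen input rate | [0, 1] | 0.9 |
| `rho` | resource washout rate | [0, 1] | 0.1 |
| `alpha` | fixation privatization | [0, 1] | 0.875 |
| `gamma` | fixation cost | [0, 1] | 0.4 |
| `delta` | cell death rate | [0.001, 0.5] | 0.4 |
| `b` | max fixation rate | [0, 2] | trait (no default) |
| `ell` | fixation half-inhibition | [0, 2] | 3 |
| `a` | max N uptake rate | [0.1, 2] | 3 |
| `d` | N uptake half-saturation | [0, 2] | 2 |
| `q` | max siderophore production | [0, 2] | 1.75 |
| `m` | siderophore production half-inhibition | [0, 2] | 1 |
| `u` | max siderophore uptake | [0.1, 2] | 1 |
| `p` | siderophore uptake half-saturation | [0, 2] | 1.85 |
| `beta` | siderophore production cost | [0, 1] | 0.4 |
| `r` | max growth rate | [0.1, 2] | 2 |
| `k_S` | colimitation strength | [0, 0.5] | 0.1 |
| `c` | siderophore affinity | [0.1, 2] | 1.25 |

The default column (used by the adaptive-dynamics analyses) intentionally
includes values of `a` and `ell` above their sampling ranges; defaults
describe one focal environment, the ranges describe the sensitivity
screen's sampling universe. `b` is the evolving trait in the
adaptive-dynamics analyses and has no canonical default; the constructor
uses 1 and screens sample it.

## The synthetic parameter generator

`sample_parameters()` is the package's data generator: independent uniform
draws over the ranges above, rejected against the acquisition-monotonicity
constraint (about half of raw draws are accepted), fully reproducible from
an integer seed. What it emulates is a sensitivity screen over a broad,
uncorrelated prior on kinetic parameters; what it does not emulate is any
empirical covariance structure among traits of real organisms (beyond the
correlations induced by the constraint itself), measurement error, or
environmental fluctuations. Passing screens therefore demonstrate
properties of the model over this design, not statements about any
particular organism.

## Numerical protocols

* **Equilibration.** `integrate_to_equilibrium()` uses `deSolve::lsodar`
  (rtol `1e-8`, atol `1e-12`) from initial conditions 0.3 for every state
  variable over a horizon of $10^5$ time units. A strain is viable when its
  final density is at least $10^{-8}$. Early exit triggers when scaled
  resource derivatives fall below $10^{-9}$ and every strain is either at
  per-capita equilibrium ($|g_i| < 10^{-10}$) or at effectively zero
  density; a slowly declining strain keeps integrating until it crosses the
  extinction threshold or the horizon, so early exit cannot change the
  final-density classification. Any state component reaching $10^6$
  classifies the run as unbounded; unbounded runs count as viable in the
  screens (their final density is above threshold) but carry a flag.
* **Roots.** Resource coordinates of isoclines and asymptotes are monotone
  problems and use a doubling bracket plus Brent refinement to tolerance
  $10^{-12}$; non-monotone scans (supply mapping, isocline intersections)
  use log-spaced grids with sign-change refinement.
* **Limits.** The $N \to \infty$ and $S \to \infty$ limits behind $N^*$,
  $S^*$ and the sensitivity bounds substitute the analytic limits of the
  kinetics (production $\to 0$, uptake $\to$ maximum) rather than large
  finite values.
* **Ties.** Invasion growth within $10^{-9}$ of zero counts as failed
  invasion: the boundary is measure-zero under the sampling design and the
  conservative call avoids spurious "successes" at numerical noise level.
* **Degenerate inputs.** $h(S=0) = \infty$ is represented as such, with
  growth defined as 0 there; strains with identical production traits are
  rejected by the coexistence finder as degenerate.

## Graphical competition machinery

`trace_zngi()` samples a strain's zero net growth isocline (ZNGI) — the
resource concentrations where net per-capita growth vanishes — between its
two asymptotes: $S^*$ (minimum siderophores, nitrogen unlimited) and $N^*$
(minimum nitrogen, siderophores unlimited). $N^*$ depends only on whether a
strain fixes nitrogen, $S^*$ only on whether it produces siderophores, and
producing siderophores always raises the producer's own $S^*$ — the root of
the universal advantage of siderophore loss.

`impact_vector()` gives a strain's net per-capita effect on each resource,
`map_supply_to_equilibrium()` solves the resident steady state by
root-finding along the ZNGI (cross-validated against time integration), and
`find_coexistence()` locates ZNGI intersections and classifies their
stability from the relative orientation of the two impact vectors: a point
is stable when each strain impacts most the resource limiting its own
growth (sign convention validated against perturbed integration). One
subtlety found during development: a siderophore producer introduced at
screening density can *bootstrap* its own siderophore pool and equilibrate
above the supply point, so the supply mapping never assumes that negative
growth at the supply point implies washout; it always scans for interior
equilibria.

## Privatization bounds

The marginal value of fixation is $\alpha$ times the sensitivity of growth
to nitrogen acquisition, $\mathcal{S}(S,N) = \partial G/\partial \eta =
r h(S)/(\eta(N)+h(S))^2$. Fixation pays near the nitrogen-limited end of
the ZNGI when $\alpha > \gamma/\mathcal{S}(\infty, N^*)$ and near the
siderophore-limited end when $\alpha > \gamma/\mathcal{S}(S^*, \infty)$;
the latter bound is always the stricter one, splitting parameter sets into
*net benefit*, *environment dependent* and *net cost* regimes. The bounds
are evaluated numerically through the sensitivity function; the closed form
of the $b = 0$ special case, $\alpha > \gamma r^2 (1+k_S/u)/(c (r-\delta)^2)$,
was derived independently and serves as a test oracle.

One evaluation subtlety deserves a warning. The nitrogen-limited bound
derives from $\partial N^*/\partial b$, so for the marginal benefit of a
strain that already fixes it must be evaluated at that strain's own $N^*$
(the default). The *ordering* of the two bounds, however, is guaranteed
only at the non-fixing reference (`from_absence = TRUE`), where
$\mathcal{S}(\infty, N^*_0) = (r-\delta)^2/(r\,h(\infty))$ and the ordering
reduces to $h(S^*) > h(\infty)$, which always holds. At a fixer's own
asymptote, nitrogen acquisition at $N^*$ rises with the fixation maximum
and marginal reversals of the ordering occur for a small fraction of
parameter sets; `privatization_bound()` exposes both evaluations
explicitly.

## Adaptive dynamics

`fitness_gradient()`, `compute_pip()` and `find_ess()` implement monomorphic
adaptive dynamics under separation of ecological and evolutionary
timescales: residents equilibrate, rare mutants are scored by their
invasion growth rate at the resident equilibrium, and the gradient is a
central finite difference (relative step $10^{-4}$) in the invader's trait.
Trait grids default to 101 points over $[0, 2]$ for `b` (the sampled
range); the tests and examples use coarser grids (9–21 points) plus
bisection, which resolve the same regimes at a fraction of the cost. In the
fixation-trait analyses the non-focal siderophore trait is held at the
default `q = 1.75`; this is a configurable choice — the captions of the
analyses this mirrors do not pin it — and the default is stated here
deliberately.

Three regimes emerge for fixation: *loss of trait* (gradient negative
throughout), an *interior ESS* (gradient root, uninvasible on the grid),
and *no stable equilibrium* (selection pushes the trait into values where
resident dynamics are unbounded). Siderophore production `q` always evolves
to 0 — production of a fully public consumable is never evolutionarily
stable — and can drag the population to extinction on the way down when the
environment supplies too few siderophores abiotically (evolutionary
suicide); `find_ess()` then reports the loss regime with an `NA`
uninvasibility check, since no resident environment remains. Selection on
privatization `alpha` is always upward; leakiness in nature is thus best
read as a physical constraint, not an optimum.

`zngi_envelope()` computes the geometrical envelope of a trait family's
ZNGIs (pointwise minimum nitrogen requirement across the family). Each
envelope point is an ESS for the resource environment it represents, and
the envelope's trait label switches from 0 to positive fixation moving from
siderophore-limited (high N:S) to nitrogen-limited (low N:S) environments;
`critical_ns_ratio()` locates that transition by bisection and returns the
equilibrium N:S ratio there.

## Design choices made where the design was open

* The single-resource production and uptake forms are abstract in the
  underlying theory; the package ships the saturating defaults above plus a
  plug-in interface, because those forms satisfy every stated shape
  constraint and keep the two models structurally parallel.
* The steady-state and extinction tolerances ($10^{-9}$ scaled derivative,
  $10^{-8}$ final density, $10^6$ unbounded cap) are the package's own
  choices; classifications are insensitive to them across the tested
  screens because the protocols classify by final density.
* Screens default to 2,000 accepted parameter sets. At that size binomial
  standard errors on the reported percentages are at most about one
  percentage point, while a full screen stays in the minutes range on one
  CPU; larger screens are a matter of passing a larger `n`.
* The acceptance analysis reports invasion percentages conditioned on
  resident viability only; invader monoculture viability is deliberately
  not required, since an invader scored at the resident's equilibrium needs
  no viable monoculture of its own.

## Known limitations

* Both models are deterministic and perfectly well mixed: no spatial
  structure, no demographic noise, no explicit iron chemistry (siderophore
  concentration stands in for bioavailable iron, and membrane-associated
  siderophores are out of scope).
* The screens characterize the model over its sampling design; the induced
  parameter correlations mean single-parameter summaries (bins, lattices)
  are not independent-effect estimates.
* The coexistence finder targets the two-strain analyses; it is not a
  general continuation or bifurcation toolkit, and communities of more
  than two strains are supported by the integrator but not by the
  graphical machinery.
* Interior ESSs exist only in the colimitation model; the single-resource
  model exhibits runaway selection on production whenever
  $\alpha > \gamma$, and the package reports that honestly as unbounded
  dynamics rather than forcing an equilibrium.
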