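---
title: "The g-e pseudo-spin model of TAG melting: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The g-e pseudo-spin model of TAG melting: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gephase)
```

## The model and its assumptions

Saturated triacylglycerols (TAGs) melt through a chain-disordering
transition. The package reduces each hydrocarbon chain to two effective
states: an ordered ground state *g* collecting the compact low-energy
conformers (energy 0, degeneracy 1 by convention — this only fixes the zero
of energy), and a melted excited state *e* collecting the vast family of
disordered conformers (energy `Ee`, degeneracy `De`). With the pseudo-spin
σ = ±1 labelling *g*/*e*, the effective Hamiltonian is an Ising model in a
temperature-dependent field,

$$\mathcal{H} = -\tfrac{J}{2}\sum_{\langle ij\rangle}\sigma_i\sigma_j
  - H(T)\sum_i \sigma_i,\qquad
  H(T) = H_0 - \tfrac{T}{2}\,\ln(D_e/D_g),$$

with every energy stored divided by $k_B$, i.e. in Kelvin. The
temperature-dependence of the field is entropic: the degeneracy advantage of
the melted state grows with $T$ and overturns the energetic preference for
order at

$$T^* = \frac{2H_0}{\ln(D_e/D_g)},$$

while the coupling alone sets the mean-field critical temperature
$T_c = zJ$. The order of the two temperatures fixes the character of the
transition: discontinuous for $T^* < T_c$ (with metastable branches),
critical at $T^* = T_c$, crossover for $T^* > T_c$. Assumptions worth
keeping in mind: nearest-neighbour attractive coupling only (London
dispersion between chains, plus an effective glycerol-core electrostatic
term in the chain-length map), a single transition (no α/β′/β polymorph
structure), and mean-field thermodynamics except where the Monte Carlo
module simulates the lattice directly.

## Mean-field solution, branches, spinodals

At each temperature the solver finds every fixed point of
$\sigma = \tanh\!\big((zJ\sigma + H(T))/T\big)$ by scanning σ on 2001
uniform points of $[-1,1]$ and bisecting each bracketed sign change to an
interval of $10^{-12}$; the map is bounded so the residual at the endpoints
has fixed sign and the number of fixed points is 1 or 3 (2 exactly at a
tangency). Stability comes from the map slope (|slope| < 1), and the two
extremal roots are ranked by the variational free energy per chain

$$f(\sigma) = \tfrac{zJ}{2}\sigma^2 - T\,\ln\!\Big(2\cosh\frac{zJ\sigma + H(T)}{T}\Big),$$

whose stationary points are exactly the fixed points. At $T^*$ the field
vanishes, $f$ is even, the two branches tie, and the solution is flagged as
coexistence with the positive root reported stable purely as a
deterministic convention.

The enthalpy reported per mole of molecule is the energetic part only,
$U = n_\text{chains} R\,(-\tfrac{zJ}{2}\sigma^2 - H_0\sigma)/1000$ kJ/mol:
the $-k_BT\ln D$ degeneracy term is entropy, and the temperature-dependent
half of the field comes from that entropy, so the field term enters with
$H_0$, not $H(T)$. This is a definitional choice the package documents
rather than inherits — the enthalpy jump at $T^*$ then has the closed form
$\Delta U = n_\text{chains} R\,2H_0\sigma_0/1000$ because the coexisting
roots are $\pm\sigma_0$ and the quadratic terms cancel.

Spinodals — the temperatures where a metastable extremal root merges with
the unstable root — are located by bisection on the change of the root
count, to a temperature resolution of $10^{-6}$ K. The independent check
used in the tests is the tangency condition
$1 = (zJ/T)\,\mathrm{sech}^2((zJ\sigma+H)/T)$ solved jointly with the fixed
point. A root-count bisection inherits the σ-grid resolution, so extremely
weak discontinuities (coexisting roots closer than ~$10^{-3}$) are beyond
its resolution; the calibration module therefore refuses inputs that land
within $\sigma_0 < 10^{-3}$ of the critical point rather than returning
numbers the solver cannot support.

## Chain-length scaling

The map $J = J_C + J_0 L$, $E_e = E_0 L$, $D_e = D_C\,D_{e0}(L)\,3^L$
(with the step $D_{e0}(0)=1$, $D_{e0}(L>0)=D_0$, implemented exactly as a
step, no smoothing) gives

$$\frac{T_c}{T^*} = \frac{z(J_C+J_0L)\,[L\ln 3 + \ln(D_C D_{e0})]}
  {\tfrac{z}{2}(J_C+J_0L) + E_0 L}.$$

The stored field scale is $H_0 = \tfrac{z}{4}J + \tfrac{1}{2}E_0L$, chosen
so that $T^* = 2H_0/\ln(D_e/D_g)$ reproduces the ratio above identically —
the internally consistent convention among the model's printed forms, which
disagree by a constant factor on the coupling contribution to the field;
the package standardizes on the convention whose short- and long-chain
limits close exactly ($T_c/T^* \to 0$ as $L\to 0$ with $D_C = 1$, and slope
$2zJ_0\ln 3/(zJ_0 + 2E_0)$ per carbon as $L\to\infty$). Chain length is
real-valued because the limits require it; `critical_length()` bisects
$T_c/T^* = 1$ to $10^{-9}$.

## Trilaurin calibration

`calibrate_trilaurin()` inverts the closed forms: from $T^*$ (default
319.4 K, the trilaurin β melting point — an external physical constant
supplied as an input, not derived here) and $\Delta U$ (default
86.7 kJ/mol, the model's reference value for trilaurin, within the
81–124 kJ/mol literature spread), it computes
$\ln(D_e/D_g) = 12\ln 3$ (with $D_0 = D_C = 1$), $H_0 = T^*\ln(D_e/D_g)/2$,
$\sigma_0 = 1000\,\Delta U/(3R\,2H_0) \approx 0.826$, and
$J = T^*\,\mathrm{atanh}(\sigma_0)/(z\sigma_0) \approx 75.7$ K, giving
$T_c \approx 454$ K and spinodals at 310.6 K and 326.7 K — metastable
regimes extending about 16 °C combined, comfortably above the 10 °C scale
at which memory phenomena are observed. The calibration is a bijection on
its valid domain and is verified by recomputing the enthalpy jump from the
solver branches.

## Modified VFT lifetimes and memory classification

The superheated-state lifetime is
$\tau(T) = \tau_0\,[\exp(D^* T^*/(T-T^*)) - 1]$, strictly decreasing and
convex on $(T^*,\infty)$, diverging at $T^*$ and vanishing at high
temperature; its exact inverse gives the temperature at which a given
holding time sits on the boundary. Holding below $T^*$ trivially preserves
memory; above it, memory persists while $t < \tau(T)$ (region I) and is
lost otherwise (region II), with boundary ties assigned to "lost" — the
conservative call for memory-erasure protocols. $D^*$ is treated as a
temperature-independent constant; a $D^*$ that itself vanishes at $T^*$ is
conceivable but unspecified, and is deliberately out of scope.

`fit_vft()` estimates $(T^*, D^*, \tau_0)$ from boundary lifetimes by
least squares **on log-lifetimes**. A naive least-squares criterion on the
linearized response $\ln(1+\tau/\tau_0)$ is degenerate when $\tau_0$ is
free — inflating $\tau_0$ shrinks every residual toward zero regardless of
fit quality — so the residual must be anchored on the observed lifetimes;
log-lifetime residuals also match the multiplicative (lognormal) noise
such time data carry. $T^*$ is constrained below the smallest observed
temperature via a logistic transform, $D^*$ and $\tau_0$ are fitted in log
space for positivity ($\tau_0$ can be fixed by flag: on narrow temperature
ranges $\tau_0$ and $D^*$ are weakly identified), and the Nelder-Mead
search is multistarted over the offset of $\min(T)$ above $T^*$.
Uncertainty comes from a seeded nonparametric bootstrap over points
(default 1000 resamples; bootstrap refits warm-start at the full-data
estimate).

`boundary_from_labeled()` turns labeled (temperature, time, persists/lost)
observations into fittable boundary estimates: per temperature, the
geometric mean of the longest persisting and shortest lost time —
symmetric on the log scale on which the data live.

## The synthetic-data generator

No machine-readable memory dataset ships anywhere, so the generator is the
package's test bed. Its study conditions: a generating curve with
$T^* = 317$ K, $D^* = 0.05$, $\tau_0 = 1$ min — placing lifetimes of
minutes to days within 2–35 K of the transition, the scale of fat
crystal-memory experiments; 8 holding temperatures; 6 log-spaced candidate
times per temperature across 0.2–2000 min; multiplicative lognormal noise
with σ = 0.2 on the per-temperature effective lifetime. Each candidate time
is labeled by comparison with the effective lifetime, so zero-noise
datasets are exactly separable by the generating curve and labels are
monotone in time.

What it emulates: the labeled, log-spaced, boundary-crossing structure of
holding time–temperature memory experiments. What it does not: multiple
coexisting memory types with distinct boundaries, temperature-dependent
noise, operator censoring, or drift in $T^*$ between runs — so passing
recovery tests demonstrates the estimator works under the stated error
model, not that real datasets are this clean. Under these conditions the
fitted $T^*$ covers the truth in the bootstrap 95% interval in well over
90 of 100 replicates (the intervals are honest but wide: with 8 boundary
points all three parameters are weakly identified, which is exactly why
the experiment-design advice is to span as wide a temperature range as the
material allows).

## Monte Carlo realization

The same Hamiltonian runs on periodic square (z = 4) or triangular (z = 6)
lattices — triangular is the default, matching hexagonal chain packing;
the model itself does not prescribe a geometry. Conventions: the
$-\tfrac{J}{2}\sum_{ij}$ double-counted form equals $-J$ per distinct
neighbour pair, implemented per-pair from one shared bond construction (on
side-2 periodic lattices opposite neighbour slots coincide, so bonds carry
multiplicity two — kept consistent between the exact enumerator and the
Metropolis kernel); single-site Metropolis with uniformly random site
selection, one sweep = N attempts; all randomness from R's RNG so a single
seed fixes the trajectory bit-for-bit, with per-replica seeds derived by a
fixed splitting rule.

The exact enumerator sums all $2^N$ configurations for lattices up to 20
sites and anchors the sampler: at $T^*$ the Hamiltonian is invariant under
a global spin flip, so the mean order parameter is zero exactly — a
symmetry check, not a statistical one. Sampler means are required to match
enumeration within three standard errors on 2×2 and 3×3 lattices across
five temperatures.

Protocols: `hysteresis_ramp()` heats a fully ordered lattice and cools a
fully melted one through the transition; fast ramps (a few sweeps per
temperature step) traverse the metastable window faster than its decay and
show superheating and a positive loop area, slower ramps shrink the loop,
and crossover parameter sets give areas statistically indistinguishable
from zero. `estimate_lifetime_mc()` measures first-passage times from the
ordered start to block-mean $m \le 0$ — a parameter-free decay criterion —
inside the superheated window; sweeps are the time unit, with no attempt
to map them onto laboratory minutes. For the calibrated trilaurin set the
temperature sits at $T/T_c \approx 0.7$ where interface tension is modest,
so metastable decay on a 16×16 lattice takes tens of sweeps; lifetimes
still fall monotonically across the window, mirroring the modified VFT
shape.

## Numerical choices and problem sizes

* Fixed-point residual tolerance $10^{-10}$ (bisection to $10^{-12}$);
  classification tolerance $|T^*-T_c|/T_c \le 10^{-6}$ for "critical";
  spinodal bisection resolution $10^{-6}$ K; free-energy tie tolerance
  $10^{-9}$ relative (ties broken toward the positive root).
* The test suite runs the solver-vs-scan oracle on 200 random cases
  ($10^5$-point scans), Metropolis-vs-enumeration on 2×2/3×3 × 5
  temperatures × 20 000 sweeps, the VFT recovery study on 100 synthetic
  replicates × 200 bootstrap resamples (200 resamples estimate a single
  95% interval endpoint amply for a coverage count; user-facing fits
  default to 1000), and first-passage runs on 16×16 lattices with 12
  replicas per temperature. These sizes were chosen to keep the whole
  suite in the few-minute range on one core while leaving every
  statistical margin wide.
* Degenerate inputs are refused rather than coerced: non-positive
  temperatures, lifetimes at or below $T^*$, calibrations with
  $\sigma_0 \ge 1$ or $\sigma_0 < 10^{-3}$, lattice/coordination
  mismatches, and boundary extraction without both labels at any
  temperature.

## Known limitations

Single transition only — no α/β′/β polymorphism, so distinct memory types
must be fitted as separate VFT curves; mean-field exponents (no
fluctuation corrections near the critical point, where the root-count
machinery also loses resolution); $J_C$ is an input, not derived from
partial charges; Monte Carlo lifetimes are qualitative (lattice, size and
sweep units are not mapped to material time scales).
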