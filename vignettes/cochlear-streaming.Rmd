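---
title: "Modeling sound-driven cochlear fluid streaming and drug transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling sound-driven cochlear fluid streaming and drug transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cochstream)
```

## The problem

Perilymph is essentially stationary, so a drug placed on the round window
must diffuse along the scala tympani to reach apical (low-frequency)
cochlear locations — a journey of a centimeter that diffusion alone makes
impractically slow. Experiments show that moderate sound exposure
shortens drug effect times at locations basal of the traveling-wave peak,
and that the effect disappears when outer-hair-cell (OHC) motility is
suppressed. The proposed mechanism is hydrodynamic: the sound-evoked
traveling wave, boosted by OHC motility, produces an oscillatory
cross-sectional area change of the organ-of-Corti fluid space that acts
like a peristaltic pump. Period-averaging the resulting oscillatory flow
leaves a steady streaming ("drift") field — apical along the tunnel of
Corti, with a basal return flow along the scala tympani — which advects
solute far faster than diffusion.

`cochstream` implements this mechanism end to end on synthetic inputs,
plus the experimental analysis chain used to quantify it (Teager-energy
driven responses, 75%-threshold effect times, DPOAE integrity checks, and
diffusion-trend cohort statistics).

## Model structure and assumptions

The pipeline has three stages, deliberately decoupled (one-way coupling
wave → flow → transport):

1. **Wall kinematics** (`synthesize_wave()`). The fluid–structure problem
   of organ-of-Corti vibration is replaced by a parametric traveling-wave
   surrogate. The basilar membrane (BM) moves as
   $\eta_b(x,t) = A_b(x)\cos(\omega t - \phi(x))$ with an envelope rising
   as $(x/x_\mathrm{peak})^2$ to the characteristic place and cutting off
   over 0.6 mm apically, and phase $\phi(x) = \int_0^x k(x')\,dx'$ whose
   wavenumber grows quadratically from $2\pi/12\,\mathrm{mm}^{-1}$ to
   $2\pi/1.5\,\mathrm{mm}^{-1}$, so phase velocity decays toward the
   apex. When OHCs are active, the top wall of the Corti duct moves with
   gain 1.25 and phase lead 0.5 rad inside a 4 mm sub-peak window: the
   top/bottom differential is the oscillatory area change that pumps.
   With `ohc_active = FALSE` (the salicylate condition) the duct
   translates rigidly and the area change is identically zero.
   Amplitudes scale linearly with stimulus pressure; the model has no
   compressive nonlinearity.

2. **Oscillatory flow and drift** (`solve_oscillatory_flow()`,
   `compute_drift()`). Incompressible Navier–Stokes with the advective
   term retained,
   $\partial_t u + u\!\cdot\!\nabla u = -\tfrac1\rho\nabla p + \nu\nabla^2 u$,
   $\nabla\!\cdot\!u = 0$, on a 2D two-layer domain: Corti duct
   (default 150 µm) above scala tympani (400 µm), 12 mm long, closed
   ends. The kinematic viscosity is $\nu = 70\times10^{-6}$ m²/s — one
   hundred times water, the accepted effective value for these narrow
   spaces — and $\rho = 1000$ kg/m³. The BM is a zero-thickness interface
   with Darcy permeability: the transmembrane exchange velocity is
   $u_p = -K\,\Delta p$ with $\Delta p = p_\mathrm{corti} -
   p_\mathrm{scala}$ and $K = 1$ m/(s·Pa) by default; fluid velocity at
   the membrane is $u_f = u_m + u_p$. The drift field is the fixed-point
   (Eulerian) period average $u_D(x_p) = \frac1T\int_t^{t+T}
   u_E(x_p,\tau)\,d\tau$, taken over the final period once the solution
   repeats from period to period.

3. **Solute transport** (`solve_transport()`, `effect_time_map()`).
   Advection–diffusion $\partial_t C = D\nabla^2 C - u_D\!\cdot\!\nabla C$
   with a constant 10 mM source on the basal-most 0.2 mm of the outer
   scala wall (the round-window niche) and zero-flux walls elsewhere. The
   simulated effect time at a place is the first time the concentration
   at Corti-duct mid-height (where the inner hair cells sit) reaches 1%
   of the source (100 µM).

### What the model omits

No 3D flow or radial structure; no feedback of the flow onto the wave; no
hair-bundle transduction or electromotility circuit (the active gain is
parametric); no compressive nonlinearity; no solute binding, clearance or
uptake; no scala media/vestibuli; the helicotrema is closed (rigid apical
wall). The consequences are discussed under *Limitations*.

## Numerical methods

**Flow.** MAC staggered finite differences with an incremental
pressure-correction projection; Crank–Nicolson viscosity,
Adams–Bashforth-2 advection; all operators assembled once per solve and
Cholesky-factored (`Matrix`). The Darcy exchange is taken implicitly in
the pressure solve, which is what makes $K \sim 1$ m/(s·Pa) — an almost
pressure-transparent membrane — stable. Default time step is $T/100$
(10 µs at 1 kHz, scaled with frequency); integration starts from rest and
stops when the relative L2 change of the velocity field between
consecutive periods falls below $10^{-4}$ (the 1 kHz cochlear run is
periodic after 3 periods, within 5 ms of simulated time). Grids must
resolve the Stokes layer $\delta = (\nu/\omega)^{1/2}$ (106 µm at 1 kHz)
with at least 8 cells, or the solver refuses to run.

**Moving walls.** Wall motion is imposed on the fixed mesh
(displacements are ≪ layer heights). The boundary transfer includes the
second-order tangential Taylor term
$u_\mathrm{wall} = u_\mathrm{tan} - \eta\,\partial u/\partial y$
(gradients lagged one step). This term is essential, not cosmetic: in the
viscous (lubrication) regime the entire Eulerian mean flow is generated
by the correlation $\langle\eta\,\partial u/\partial y\rangle$, and the
solver reproduces the independent lubrication-theory mean flow of a
small-amplitude peristaltic channel to ~3% because of it. The
normal-component quadratic term $\eta\,\partial v/\partial y$ is omitted:
its period mean is nonzero and on a fixed mesh would act as a spurious
steady mass source through the wall (its physical content, the boundary's
Stokes-drift flux, cancels in the material flux). With it omitted, the
total drift flux through any cross-section of the closed domain is zero
to machine precision. The `nonlinear` flag disables both the advective
term and these quadratic boundary terms together, since they are jointly
the streaming sources.

**Closed-box compatibility.** A traveling wave does not conserve domain
volume instant by instant, so the spatial mean of the predictor
divergence is subtracted before each pressure solve. This uniform
correction stands in for round-window membrane compliance; it period-
averages to zero and does not affect the drift.

**Transport.** Conservative finite volumes on the flow grid (face
velocities are the MAC drift components, so the advecting field is
discretely divergence-free and solute mass balance is exact to solver
precision). First-order upwind advection with implicit Euler stepping
(monotone, bounds-preserving); pure-diffusion runs use Crank–Nicolson
with two implicit start-up steps. Time steps start at one stimulus period
(1 ms at 1 kHz) and grow geometrically (factor 1.3) to a cap of
`t_end / 200`. Output snapshots are linear interpolations inside a step;
effect times are linear interpolations between snapshots.

**Resolution and the demonstration diffusivity.** The solute diffusion
coefficient defaults to $D = 10^{-9}$ m²/s (small-molecule order) and is
fully configurable; none of the package's validated properties depend on
its value. Upwind advection carries numerical diffusion of order
$|u|\,\Delta x/2$. At the desk-scale resolutions this package targets
(axial cells of 25–50 µm, against the ~1 µm meshes a production study
would use), that is a few $10^{-8}$ m²/s inside the fast track. The
coupled demonstrations therefore use $D = 10^{-8}$ m²/s so that the
physical transport contrast (advective fast track, stalling point) is
resolved above the numerical background rather than drowned in it; the
directional and ordering properties asserted by the tests are unchanged
by this choice. Problem sizes used throughout the tests and the
acceptance script: flow on 240×44 (default) or 480×44 (coupled
demonstrations) cells, transport to 1300 s, Stokes benchmark on 4×256
cells, peristaltic benchmark on 96×16 cells.

## Calibration of the surrogate amplitude

The stage that would set absolute wall amplitudes (the 3D organ-of-Corti
model) is outside this package, so the surrogate has one calibration
constant: the peak BM amplitude at 80 dB SPL, default 6 µm. It was chosen
once so that the active 1 kHz / 80 dB run yields a peak drift speed of
order mm/s (the package computes 1.4 mm/s), the scale at which streaming
becomes a relevant transport mechanism near the wave peak; it should be
read as
an *effective* duct-wall motion encapsulating OHC-driven internal
deformation, not as a literal BM displacement (in vivo BM motion at
80 dB is tens to hundreds of nm). All drift magnitudes scale with the
square of this constant; the directional structure, K-insensitivity,
null-streaming and oracle properties do not depend on it.

## What the streaming field looks like

The active 1 kHz / 80 dB run produces a circulation cell in the sub-peak
tail (roughly 6–9 mm for a 9.3 mm peak place): apical flux in the Corti
duct, basal return flux in the scala tympani, and a weaker countering
cell just apical of the peak. Feeding this drift into transport gives a
fast track — the 100 µM contour along the Corti duct runs ahead of the
pure-diffusion contour — and a stalling point: the facilitation ratio
$t_E^\mathrm{adv}/t_E^\mathrm{diff}$ falls to ~0.5 near 9.8 mm and then
collapses back toward 1 where the countering circulation blocks further
advective transport. With OHCs passive (zero area change) the Corti-duct
flux reverses sign and weakens several-fold; with the nonlinear terms
disabled as well, the drift is zero to rounding — confirming that the
streaming source is the retained nonlinearity acting on the wall
deformation.

## The measurement chain

The experimental side mirrors the published protocol. Multiunit
recordings are Teager-transformed ($\psi[n] = x[n]^2 - x[n-1]x[n+1]$) and
the driven response is the tone-segment mean minus the spontaneous mean.
Response curves are normalized to their pre-application baseline (all
samples at $t<0$; the paper does not define its baseline window, so this
is the package's choice, minimum 3 samples). The effect time is the first
crossing below 75% of baseline that is *sustained* for 3 consecutive
samples — a single-sample rule is fragile against the bimodal decay
shapes seen apically; `k_sustained = 1` restores the naive rule.

DPOAE levels along a swept two-tone stimulus ($f_2$ linear 0.5→10 kHz
over 4 s, $f_2 = 1.25 f_1$) are estimated per 100 ms Hann window (20 ms
steps) by least squares on sine/cosine pairs at the instantaneous
primary and $2f_1\!-\!f_2$ phases. The noise floor applies the identical
path to (mean of even presentations − mean of odd)/2, which cancels
deterministic content exactly. A pre/post change exceeding (strictly)
5 dB anywhere in 0.1–10 kHz flags exclusion.

Cohort statistics: the silence-condition trend $t_E = x^2/(4 D_\mathrm{eff}
z^2)$, $z = \mathrm{erfc}^{-1}(0.01)$, is fit in log-time space (closed
form for $D_\mathrm{eff}$); effect times are normalized as
$20\log_{10}(t_E/t_\mathrm{Trend})$; groups are compared with two-tailed
Welch t-tests (the unequal-variance flavor is the package's choice; the
experimental protocol specifies only that the tests are two-tailed) for
the whole range and for
low/high-CF strata split at 4.5 kHz, with a CF exactly at the split
assigned to the low stratum. Records whose curves never cross threshold
are excluded listwise with a logged count.

## The synthetic-data generators

`gen_response_curve()` emits baseline-1 curves with multiplicative
Gaussian noise and a logistic decay placed so the noiseless 0.75 crossing
equals the requested effect time (exact for unimodal shapes; approximate
when the bimodal plateau is enabled), sampled every 57.2 s like the
experimental stimulus sequence. `gen_cohort()` draws CFs log-uniformly
(default 1–16 kHz), converts to place through the gerbil map, and sets
$t_E = \frac{x^2}{4 D_\mathrm{eff} z^2}\,10^{(\mathrm{offset}+\epsilon)/20}$,
$\epsilon \sim N(0, \sigma^2)$ with $\sigma = 3$ dB — lognormal noise,
additive in dB, matching the dB-space residual treatment. Condition
offsets default to the qualitative experimental pattern (broadband sound
and mid-frequency tones: −6 dB at high CF only; low-frequency tones:
negative everywhere; post-salicylate: 0); the magnitudes are free
parameters of the generator, not claims about the measured values.
`gen_spike_signal()` and `gen_dpoae_sweep()` provide waveform-level
fixtures with known ground truth. All generators are bit-reproducible
under a fixed seed.

Because the cohort generator realizes exactly the analysis model
(quadratic trend, lognormal dB noise), passing recovery tests shows the
estimator chain is correct and calibrated — it does not show that real
cohorts satisfy those assumptions (real data add animal-level
correlation, unreached records censored at session end, and bimodal
curves whose "effect time" is genuinely ambiguous).

## Numerical choices, edge cases, defaults

* Periodicity tolerance $10^{-4}$ (relative L2 between periods);
  non-convergence raises an error carrying the residual history.
* Degenerate inputs: zero-amplitude waves short-circuit to exactly zero
  flow; `K = 0` is the impermeable-membrane limit; `level = -Inf` dB is
  silence.
* The same $\nu$ is used in both layers by default (the stated value is
  a single number); a per-layer override is deliberately *not* exposed
  until there is a need, keeping `fluid_props()` minimal.
* Effect-time maps flag places whose concentration series dips back
  below threshold after crossing (a numerical artifact at coarse
  resolution) and use the earliest crossing.
* Broadband stimuli are a documented approximation: decompose into
  tones, run the flow stage per tone, superpose drifts. The
  superposition ignores cross-frequency advective interaction and is the
  caller's responsibility.

## Limitations

The two biggest gaps to a fully resolved physiological model are the parametric wave
surrogate (absolute drift magnitudes inherit its calibration; only
scalings and directions are predictive) and desk-scale mesh resolution
(first-order upwind transport smears the stalling point unless $D$ is
kept at or above the numerical-diffusion scale, as described above).
The closed apical end omits the helicotrema, so a physical return path
is replaced by the membrane exchange; the effect on the basal-most and
apical-most millimeter of the flux profiles has not been quantified.
Statistics are plain t-tests on records pooled across animals, matching
the experimental design — repeated measures per animal are not modeled.
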