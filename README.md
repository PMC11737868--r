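# cochstream

Sound-driven cochlear fluid streaming and inner-ear drug transport.

Drugs applied at the round window must travel centimeters along the
perilymph to reach apical cochlear locations, and perilymph does not
flow — so transport is diffusive and slow. Moderate sound exposure
measurably speeds drug delivery at places basal of the traveling-wave
peak, and the speed-up disappears when outer-hair-cell (OHC) motility is
suppressed. `cochstream` models the proposed mechanism and implements the
analysis chain used to quantify it. It is written for auditory
biophysicists and inner-ear pharmacokinetics researchers who want a
tested, desk-scale implementation of both the model and the statistics.

## The model

Three coupled stages (one-way coupling):

1. **Traveling-wave wall kinematics.** A parametric surrogate supplies
   basilar-membrane motion `A_b(x) cos(wt − φ(x))` peaking at the
   characteristic place of the stimulus, with phase velocity decaying
   toward the apex. Active OHCs add a gain and phase lead to the top wall
   of the Corti duct over the sub-peak tail, creating an oscillatory
   cross-sectional area change — a peristaltic pump.
2. **Oscillatory flow → steady streaming.** Incompressible Navier–Stokes
   (advective term retained, ν = 70e−6 m²/s, ρ = 1000 kg/m³) on a 2D
   two-layer domain — Corti duct over scala tympani — coupled through a
   Darcy-permeable basilar membrane, `u_p = −K Δp`, K = 1 m/(s·Pa). The
   solver runs to a periodic steady state; period-averaging the Eulerian
   velocity, `u_D = (1/T) ∫ u_E dt`, leaves the steady drift field.
3. **Solute transport.** Advection–diffusion
   `∂C/∂t = D ∇²C − u_D·∇C` from a constant 10 mM round-window source;
   the simulated effect time is the first arrival of 100 µM (1% of the
   source) at Corti-duct mid-height.

The measurement chain mirrors the experimental protocol: Teager-energy
operator `ψ[n] = x[n]² − x[n−1]x[n+1]` and driven responses, effect time
as the sustained 75%-of-baseline crossing, swept-tone DPOAE level
estimation (least squares in 100 ms Hann windows) with an even/odd noise
floor and a 5 dB exclusion rule, the 1D-diffusion effect-time trend
`tE = x²/(4 D_eff z²)` with `z = erfc⁻¹(0.01)`, dB normalization
`20 log10(tE/tTrend)`, and stratified Welch t-tests split at 4.5 kHz.
Synthetic generators produce every input with known ground truth.

## Worked example

Generate a synthetic cohort (48 silence records, 34 sound records with a
−6 dB high-CF facilitation offset, 3 dB lognormal noise), fit the
diffusion trend to the silence arm, and run the stratified comparison:

```r
library(cochstream)
geom <- cochlear_geometry()
geom
#> <cochlear_geometry>
#>   length: 12 mm; Corti duct 150 um over scala tympani 400 um
#>   CF range: 62.8 kHz (base) -> 0.147 kHz (apex)
#>   grid: nx = 240, ny = 12 (Corti) + 32 (scala)

rec <- gen_cohort(cohort_spec(n = c(silence = 48, sound = 34),
                              D_eff_m2_s = 1e-9, sigma_db = 3, seed = 42),
                  geom)
trend <- fit_diffusion_trend(rec[rec$condition == "silence", ])
trend
#> <trend_model>
#>   D_eff = 1e-09 m^2/s (n = 48, residual sd 3.04 dB)
#>   free-exponent fit of tE vs x: 1.908 (diffusion predicts 2)

compare_groups(rec[rec$condition == "silence", ],
               rec[rec$condition == "sound", ], trend)
#> Stratified Welch t-tests on dB-normalized effect times
#>   stratum n_a n_b mean_a_db mean_b_db    t        p computable
#> 1   whole  48  34      0.00     -2.69 3.16 2.52e-03       TRUE
#> 2  low_cf  21  20     -0.09     -0.31 0.21 8.31e-01       TRUE
#> 3 high_cf  27  14      0.07     -6.08 6.73 2.79e-07       TRUE
```

The recovered `D_eff` is the generator's ground truth to 0.1%; the
facilitation is detected in the high-CF stratum and not in the low-CF
stratum — the qualitative signature of sound-assisted delivery.

The physical pipeline runs the same way (about 10 s for the flow stage at
the default grid):

```r
wave  <- synthesize_wave(geom, stimulus("tone", frequency_hz = 1000,
                                        level_db_spl = 80))
sol   <- solve_oscillatory_flow(geom, wave)        # periodic in 3 periods
drift <- compute_drift(sol)
drift
#> <drift_field>
#>   peak |u_D| = 0.00141 m/s (peak oscillatory speed 0.0596 m/s)

cross_section_flux(drift, 7.5e-3, "corti")         # apical (positive)
#> [1] 2.548152e-08
cross_section_flux(drift, 7.5e-3, "scala")         # basal return flow
#> [1] -2.548152e-08
```

Peak drift is of mm/s order; the Corti duct streams apically and the
scala tympani carries the return flow, with zero net flux through every
cross-section of the closed domain. Feeding `drift` into
`solve_transport()` and `effect_time_map()` yields the fast-track /
stalling-point transport pattern discussed in the vignette.

## Package layout

* `R/geometry.R`, `R/wave.R` — domain, place–frequency map, wave surrogate
* `R/flow_domain.R`, `R/flow_solver.R`, `R/drift.R` — Navier–Stokes MAC
  solver, Darcy membrane, period-averaged drift, fluxes, particle tracking
* `R/transport.R` — advection–diffusion, erfc closed forms, effect-time maps
* `R/neural.R`, `R/cohort.R` — Teager/driven-response/DPOAE chain, trend
  fit and group statistics
* `R/synthetic.R` — generators for curves, cohorts, spike signals, sweeps
* `vignettes/cochlear-streaming.Rmd` — model, numerics, calibration and
  limitations
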