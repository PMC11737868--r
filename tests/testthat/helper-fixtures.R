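# Shared, lazily computed fixtures. The flow and transport solves are the
# expensive parts of the suite; each is run once and reused across test
# files (unit tests and the acceptance properties check the same physics
# from different angles).

.fx_env <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fx_env[[name]])) .fx_env[[name]] <- fn()
  .fx_env[[name]]
}

fx_geom <- function() fixture("geom", function() cochlear_geometry())

fx_wave_active <- function() fixture("wave_active", function() {
  synthesize_wave(fx_geom(), stimulus("tone", frequency_hz = 1000,
                                      level_db_spl = 80), ohc_active = TRUE)
})

fx_wave_passive <- function() fixture("wave_passive", function() {
  synthesize_wave(fx_geom(), stimulus("tone", frequency_hz = 1000,
                                      level_db_spl = 80), ohc_active = FALSE)
})

# active 1 kHz / 80 dB two-layer flow at the default (desk-scale) grid
fx_flow_active <- function() fixture("flow_active", function() {
  solve_flow(cochlear_flow_domain(fx_geom(), fx_wave_active()),
             flow_numerics(max_periods = 30, min_periods = 3))
})

fx_drift_active <- function() fixture("drift_active", function() {
  compute_drift(fx_flow_active())
})

# oscillating-wall (Stokes second problem) benchmark solution
fx_stokes <- function() fixture("stokes", function() {
  nu <- 70e-6; f0 <- 1000; w <- 2 * pi * f0
  ds <- sqrt(2 * nu / w)
  U0 <- 1e-3
  dom <- channel_domain(length_m = 4e-4, height_m = 10 * ds, nx = 4, ny = 256,
                        omega = w, fluid = fluid_props(nu, 1000, 0),
                        periodic_x = TRUE,
                        u_bot_hat = function(x) rep(U0 + 0i, length(x)))
  sol <- solve_flow(dom, flow_numerics(dt_s = 1 / f0 / 200, max_periods = 30,
                                       min_periods = 20,
                                       periodicity_tol = 1e-6,
                                       nonlinear = FALSE, n_snapshots = 40))
  list(sol = sol, dom = dom, U0 = U0, nu = nu, omega = w, ds = ds)
})

# small-amplitude peristaltic channel benchmark
fx_perist <- function() fixture("perist", function() {
  h0 <- 100e-6; lam <- 4e-3; f0 <- 100
  w <- 2 * pi * f0; k <- 2 * pi / lam
  eps <- 0.04; a <- eps * h0
  dom <- channel_domain(length_m = lam, height_m = h0, nx = 96, ny = 16,
                        omega = w, fluid = fluid_props(70e-6, 1000, 0),
                        periodic_x = TRUE,
                        eta_top_hat = function(x) a * exp(-1i * k * x))
  sol <- solve_flow(dom, flow_numerics(dt_s = 1 / f0 / 200, max_periods = 25,
                                       min_periods = 5,
                                       periodicity_tol = 1e-7))
  list(sol = sol, dom = dom, h0 = h0, a = a, k = k, omega = w, eps = eps)
})

# coupled demonstration: drift-driven transport vs pure diffusion on a
# refined axial grid (the directional / stalling-point phenomenology needs
# the fast-track advection resolved above the upwind numerical diffusion)
fx_coupled <- function() fixture("coupled", function() {
  geom <- cochlear_geometry(grid = list(nx = 480L, ny_corti = 12L,
                                        ny_scala = 32L))
  wave <- synthesize_wave(geom, stimulus("tone", frequency_hz = 1000,
                                         level_db_spl = 80))
  sol <- solve_flow(cochlear_flow_domain(geom, wave),
                    flow_numerics(max_periods = 30, min_periods = 3))
  drift <- compute_drift(sol)
  D <- 1e-8                      # demonstration diffusivity, see vignette
  tend <- 1300
  outs <- exp(seq(log(2), log(tend), length.out = 140))
  ser_adv <- solve_transport(drift, D_m2_s = D, bc = transport_bc(),
                             t_end_s = tend, output_times_s = outs, theta = 1)
  ser_dif <- solve_transport(geom, drift = NULL, D_m2_s = D,
                             bc = transport_bc(), t_end_s = tend,
                             output_times_s = outs, theta = 1)
  list(geom = geom, wave = wave, drift = drift,
       ser_adv = ser_adv, ser_dif = ser_dif,
       prof_adv = effect_time_map(ser_adv), prof_dif = effect_time_map(ser_dif))
})

# 1D pure-diffusion run against the erfc closed form
fx_diff1d <- function() fixture("diff1d", function() {
  D <- 1e-9; C0 <- 10
  dom <- channel_domain(length_m = 0.012, height_m = 1e-4, nx = 600, ny = 1,
                        omega = 2 * pi * 1000, fluid = fluid_props(),
                        periodic_x = FALSE)
  ser <- solve_transport(dom, drift = NULL, D_m2_s = D,
                         bc = transport_bc(c_rw_mol_m3 = C0, where = "basal_end"),
                         t_end_s = 400, output_times_s = c(50, 100, 200, 400))
  list(ser = ser, dom = dom, D = D, C0 = C0)
})
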