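test_that("Darcy exchange follows u_p = -K dp with validation", {
  expect_equal(darcy_exchange(0, 1), 0)
  expect_equal(darcy_exchange(-3, 1), 3)
  expect_equal(darcy_exchange(c(-5, 2, 100), 0), c(0, 0, 0))
  expect_error(darcy_exchange(1, -0.1), "K_m_s_pa")
})

test_that("zero-amplitude forcing gives an identically zero flow", {
  geom <- cochlear_geometry(grid = list(nx = 40L, ny_corti = 12L, ny_scala = 32L))
  w0 <- synthesize_wave(geom, stimulus("tone", frequency_hz = 1000,
                                       level_db_spl = -Inf))
  sol <- solve_flow(cochlear_flow_domain(geom, w0),
                    flow_numerics(max_periods = 6, min_periods = 2))
  expect_lt(max(abs(sol$u_mean)), 1e-16)
  expect_lt(max(abs(sol$v_mean)), 1e-16)
  expect_equal(sol$peak_oscillatory_speed, 0)
})

test_that("oscillating-wall flow matches the Stokes-layer closed form", {
  fx <- fx_stokes()
  y <- fx$dom$y_p
  num <- sapply(seq_along(fx$sol$snap_times),
                function(k) fx$sol$snap_u[[k]][1, ])
  exact <- sapply(fx$sol$snap_times,
                  function(t) stokes_wall_profile(y, t, fx$U0, fx$nu, fx$omega))
  relrms <- sqrt(mean((num - exact)^2)) / sqrt(mean(exact^2))
  expect_lt(relrms, 1e-3)
  # the Eulerian period average of the linear problem is zero
  expect_lt(max(abs(fx$sol$u_mean)) / fx$U0, 1e-6)
})

test_that("paper-parameter run reaches a periodic steady state within 5 ms", {
  # nu = 70e-6 m^2/s, rho = 1000 kg/m^3, 1 kHz forcing, 10 us steps
  sol <- fx_flow_active()
  expect_true(sol$converged)
  expect_equal(sol$dt, 1e-5, tolerance = 1e-12)
  expect_lte(sol$n_periods * sol$period_s, 5e-3 + 1e-12)
})

test_that("under-resolved Stokes layer is refused before integration", {
  geom <- cochlear_geometry(grid = list(nx = 40L, ny_corti = 2L, ny_scala = 2L))
  wave <- synthesize_wave(geom, stimulus("tone", frequency_hz = 1000))
  expect_error(solve_flow(cochlear_flow_domain(geom, wave)), "Stokes layer")
})

test_that("non-convergence raises an explicit error carrying residuals", {
  fx <- fx_perist()
  err <- tryCatch(
    solve_flow(fx$dom, flow_numerics(dt_s = 1 / (fx$omega / 2 / pi) / 200,
                                     max_periods = 2, min_periods = 1,
                                     periodicity_tol = 1e-14)),
    error = function(e) e)
  expect_s3_class(err, "cochstream_flow_error")
  expect_true(length(err$residuals) > 0)
})

test_that("small-amplitude peristaltic drift matches lubrication theory", {
  fx <- fx_perist()
  drift <- compute_drift(fx$sol)
  dom <- fx$dom
  # compare the section-integrated Eulerian mean over a fixed band that
  # stays inside the fluid at all phases
  rows <- which(dom$y_p <= fx$h0 * (1 - 2 * fx$eps))
  cols <- seq(8, 88, by = 8)
  num <- mean(sapply(cols, function(i) sum(drift$u[i, rows] * dom$row_dy[rows])))
  ora <- mean(sapply(cols, function(i) {
    ys <- dom$y_p[rows]
    sum(lubrication_mean_u(rep(dom$x_u[i], length(ys)), ys,
                           fx$h0, fx$a, fx$k, fx$omega) * dom$row_dy[rows])
  }))
  expect_lt(abs(num - ora) / abs(ora), 0.10)
  # mean-profile shape: near-linear Couette with slip ~ 3 eps^2 c at the top
  slip <- 3 * fx$eps^2 * (fx$omega / fx$k)
  expect_equal(mean(drift$u[cols, max(rows)]),
               slip * dom$y_p[max(rows)] / fx$h0, tolerance = 0.12)
})

test_that("drift is insensitive to membrane permeability over 0.3-3 m/(s Pa)", {
  geom <- fx_geom()
  wave <- fx_wave_active()
  peaks <- vapply(c(0.3, 3), function(K) {
    sol <- solve_flow(cochlear_flow_domain(geom, wave,
                                           fluid_props(K_m_s_pa = K)),
                      flow_numerics(max_periods = 30, min_periods = 3))
    max(abs(compute_drift(sol)$u))
  }, numeric(1))
  peaks <- c(peaks, max(abs(fx_drift_active()$u)))   # K = 1 reference
  expect_lt(max(peaks) / min(peaks), 2)
})

test_that("membrane pressure difference stays at the few-Pa scale", {
  sol <- fx_flow_active()
  fm <- sol$domain$fm
  dp <- sol$pressure_pa[, fm] - sol$pressure_pa[, fm - 1]
  expect_lt(max(abs(dp)), 5)
})
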