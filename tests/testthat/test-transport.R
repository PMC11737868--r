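test_that("pure-diffusion run matches the erfc closed form", {
  fx <- fx_diff1d()
  ser <- fx$ser
  for (k in seq_along(ser$times_s)) {
    Cn <- ser$C[[k]][, 1]
    Ce <- diffusion_1d_closed_form(ser$x_centers_m, ser$times_s[k], fx$D, fx$C0)
    sel <- Ce >= 0.01 * fx$C0    # the concentration range used downstream
    expect_lt(max(abs(Cn[sel] - Ce[sel]) / Ce[sel]), 0.02)
  }
})

test_that("solute gain equals source influx (discrete mass balance)", {
  fx <- fx_diff1d()
  mb <- fx$ser$mass_balance
  expect_lt(max(abs(mb$mass_mol - mb$influx_mol) / mb$influx_mol), 0.005)
  # and on the advective 2D run
  mb2 <- fx_coupled()$ser_adv$mass_balance
  expect_lt(max(abs(mb2$mass_mol - mb2$influx_mol) / mb2$influx_mol), 0.005)
})

test_that("uniform source-level field is a steady state", {
  dom <- channel_domain(length_m = 2e-3, height_m = 1e-4, nx = 50, ny = 4,
                        omega = 2 * pi * 1000, fluid = fluid_props(),
                        periodic_x = FALSE)
  bc <- transport_bc(c_rw_mol_m3 = 10, where = "basal_end")
  ser <- solve_transport(dom, drift = NULL, D_m2_s = 1e-9, bc = bc,
                         t_end_s = 50, output_times_s = c(10, 50),
                         C_init = 10)
  for (M in ser$C) expect_equal(max(abs(M - 10)), 0, tolerance = 1e-9)
})

test_that("a pulse in a uniform drift translates at U t with mass preserved", {
  nx <- 400; L <- 2e-2; h <- 1e-4
  dom <- channel_domain(length_m = L, height_m = h, nx = nx, ny = 1,
                        omega = 2 * pi * 100, fluid = fluid_props(),
                        periodic_x = FALSE)
  U0 <- 1e-4
  fake_drift <- structure(
    list(u = matrix(U0, nx + 1, 1), v = matrix(0, nx, 2), up = NULL,
         domain = dom, omega = dom$omega, peak_oscillatory_speed = U0),
    class = "drift_field")
  x <- dom$x_p
  C0 <- exp(-((x - 5e-3) / 5e-4)^2)
  tend <- 60                       # pulse moves 6 mm, stays interior
  ser <- solve_transport(dom, drift = fake_drift, D_m2_s = 1e-12, bc = NULL,
                         t_end_s = tend, output_times_s = c(30, 60),
                         C_init = matrix(C0, nx, 1), dt0_s = 5e-3,
                         dt_max_s = 0.05)
  dxc <- dom$dx
  m0 <- sum(C0) * dxc * h
  for (k in seq_along(ser$times_s)) {
    Ck <- ser$C[[k]][, 1]
    mk <- sum(Ck) * dxc * h
    expect_lt(abs(mk - m0) / m0, 0.005)          # mass preserved
    cen <- sum(x * Ck) / sum(Ck)
    expect_equal(cen, 5e-3 + U0 * ser$times_s[k], tolerance = 0.02)
  }
})

test_that("diffusion closed form obeys boundary values and limits", {
  expect_equal(diffusion_1d_closed_form(0, 10, 1e-9, 7), 7)
  expect_equal(diffusion_1d_closed_form(5e-3, 1e12, 1e-9, 7), 7, tolerance = 1e-4)
  expect_error(diffusion_1d_closed_form(1e-3, 0, 1e-9), "t_s")
  expect_error(diffusion_1d_closed_form(-1e-3, 10, 1e-9), "x_m")
  # threshold inversion agrees with a brute-force time scan
  for (x in c(2e-3, 5e-3)) {
    t_cf <- diffusion_effect_time(x, 1e-9, 0.01)
    t_scan <- scan_diffusion_effect_time(x, 1e-9, 0.01)
    expect_equal(t_cf, t_scan, tolerance = 1e-3)
  }
})

test_that("effect-time map inverts the diffusion field within 3%", {
  D <- 1e-9; C0 <- 10
  dom <- channel_domain(length_m = 0.012, height_m = 1e-4, nx = 600, ny = 1,
                        omega = 2 * pi * 1000, fluid = fluid_props(),
                        periodic_x = FALSE)
  ser <- solve_transport(dom, drift = NULL, D_m2_s = D,
                         bc = transport_bc(c_rw_mol_m3 = C0, where = "basal_end"),
                         t_end_s = 3000,
                         output_times_s = exp(seq(log(0.5), log(3000),
                                                  length.out = 150)))
  prof <- effect_time_map(ser, readout = 1)
  # default threshold is 1% of the 10 mM source = 100 uM (0.1 mol/m^3)
  expect_equal(attr(prof, "threshold_mol_m3"), 0.1)
  sel <- !is.na(prof$te_s) & prof$x_m > 0.5e-3
  te_exact <- diffusion_effect_time(prof$x_m[sel], D)
  expect_lt(max(abs(prof$te_s[sel] - te_exact) / te_exact), 0.03)
  # effect time vanishes at the source and is monotone with distance
  expect_lt(prof$te_s[1], ser$times_s[1])
  expect_true(all(diff(prof$te_s[sel]) > 0))
})

test_that("concentrations respect bounds and rise monotonically in time", {
  fx <- fx_coupled()
  crw <- fx$ser_adv$bc$c_rw_mol_m3
  n <- length(fx$ser_adv$C)
  probe <- fx$ser_adv$C[[n]]
  expect_true(min(probe) >= -1e-9 * crw && max(probe) <= crw * (1 + 1e-9))
  # temporal monotonicity at a sample of interior points
  idx <- cbind(c(40, 120, 240, 360), c(10, 20, 36, 40))
  vals <- sapply(fx$ser_adv$C, function(M) M[idx])
  expect_true(all(apply(vals, 1, function(v) all(diff(v) >= -1e-12 * crw))))
})

test_that("advection stretches the threshold contour apically in the Corti duct", {
  fx <- fx_coupled()
  wave <- fx$wave
  # at matched times the 100 uM contour sits apical of the pure-diffusion
  # contour along the Corti layer: equivalently te_adv < te_dif in the
  # fast track
  x <- fx$prof_adv$x_m
  ft <- x > wave$x_peak_m - 3e-3 & x < wave$x_peak_m - 0.5e-3
  expect_true(all(fx$prof_adv$te_s[ft] < fx$prof_dif$te_s[ft]))
  # and nowhere is transport meaningfully slower than diffusion alone
  ok <- !is.na(fx$prof_adv$te_s) & !is.na(fx$prof_dif$te_s) & x > 1e-3
  expect_true(mean(fx$prof_adv$te_s[ok] <= fx$prof_dif$te_s[ok] * 1.05) > 0.95)
})

test_that("facilitation stalls apical of the circulation (local minimum)", {
  fx <- fx_coupled()
  x <- fx$prof_adv$x_m
  ratio <- fx$prof_adv$te_s / fx$prof_dif$te_s   # < 1 where facilitated
  sel <- which(x > 2e-3 & x < 11.5e-3 & !is.na(ratio))
  r <- stats::filter(ratio[sel], rep(1 / 5, 5), sides = 2)  # light smoothing
  inner <- which(!is.na(r))
  imin <- inner[which.min(r[inner])]
  # an interior minimum: facilitation collapses (ratio rises) apically of it
  expect_gt(imin, min(inner) + 3)
  expect_lt(imin, max(inner) - 3)
  apical_tail <- r[inner[inner > imin]]
  expect_gt(max(apical_tail) - r[imin], 0.02)
  # the minimum sits near the circulation boundary apical of the fast track
  expect_gt(x[sel[imin]], fx$wave$x_peak_m - 1.5e-3)
})
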