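test_that("Teager operator has the discrete-sinusoid closed form", {
  # constants and zeros map to zero
  expect_equal(teager_transform(rep(3.7, 50))$samples, rep(0, 48))
  expect_equal(teager_transform(rep(0, 10))$samples, rep(0, 8))
  expect_error(teager_transform(c(1, 2)), "3 samples")
  # A sin(W n) -> constant A^2 sin^2(W), and non-negative for |W| < pi/2
  for (W in c(0.2, 0.7, 1.4)) {
    A <- 1.5
    psi <- teager_transform(A * sin(W * (0:499)))$samples
    expect_lt(max(abs(psi - A^2 * sin(W)^2)), 1e-10)
    expect_true(all(psi >= -1e-12))
  }
})

test_that("driven response subtracts spontaneous activity with a floor", {
  expect_equal(as.numeric(driven_response(5, 2)), 3)
  r <- driven_response(2, 2)
  expect_equal(as.numeric(r), 0)
  r2 <- driven_response(1, 2)
  expect_equal(as.numeric(r2), 0)
  expect_true(attr(r2, "floored"))
  # driven response grows with injected spike rate (simulation ladder)
  rates <- c(0, 100, 300, 900)
  dr <- vapply(rates, function(rate) {
    tone <- gen_spike_signal(rate, tone_locked_fraction = 1, seed = 5)
    spont <- gen_spike_signal(0, seed = 6)
    driven_response(mean(teager_transform(tone)$samples),
                    mean(teager_transform(spont)$samples))
  }, numeric(1))
  expect_true(all(diff(dr) > 0))
  expect_lt(dr[1], 0.05)
})

test_that("normalization requires a baseline and scales it to one", {
  s <- neural_response_series(seq(-5, 30, by = 1), rep(c(4, 2), c(10, 26)))
  n <- normalize_response(s)
  expect_equal(mean(n$response[n$t_min < 0]), 1)
  s2 <- neural_response_series(c(-1, 0, 1, 2), c(1, 1, 1, 1))
  expect_error(normalize_response(s2), "baseline")
})

test_that("effect time finds the sustained 75% crossing by interpolation", {
  # analytically placed crossing recovered within one sample interval
  for (te in c(12, 54, 150)) {
    s <- gen_response_curve(te, tau_min = 4, noise_sd = 0)
    expect_equal(effect_time(s), te, tolerance = 57.2 / 60 / te)
  }
  # dense brute-force scan agrees with the interpolated crossing
  s <- gen_response_curve(54, tau_min = 4, noise_sd = 0,
                          sampling_interval_s = 0.5)
  expect_equal(effect_time(s), 54, tolerance = 1e-3)
  # flat curve never crosses
  flat <- neural_response_series(seq(-5, 60), rep(1, 66), normalized = TRUE)
  expect_true(is.na(effect_time(flat)))
  expect_true(attr(effect_time(flat), "unreached"))
  # sustained rule: a single-sample dip is ignored at k = 3, caught at k = 1
  y <- rep(1, 66); y[20] <- 0.5; y[50:66] <- 0.5
  dip <- neural_response_series(seq(-5, 60), y, normalized = TRUE)
  expect_equal(effect_time(dip, k_sustained = 3), 43.5, tolerance = 1)
  expect_equal(effect_time(dip, k_sustained = 1), 13.5, tolerance = 1)
  # delaying the decay delays the effect time (monotonicity)
  t1 <- effect_time(gen_response_curve(30, tau_min = 5, noise_sd = 0))
  t2 <- effect_time(gen_response_curve(45, tau_min = 5, noise_sd = 0))
  expect_gt(t2, t1)
})

test_that("DPOAE level track recovers an embedded distortion product", {
  sw <- gen_dpoae_sweep(dp_db_spl = 20, primaries_db_spl = 60,
                        noise_db_spl = 10, seed = 7)   # SNR 10 dB
  tr <- dpoae_level_track(sw)
  inner <- tr$t_s > 0.3 & tr$t_s < 3.7
  expect_lt(max(abs(tr$dp_db_spl[inner] - 20)), 1)
  # frequency bookkeeping: f_dp = 2 f1 - f2 = 0.6 f2 for ratio 1.25
  expect_equal(tr$fdp_hz, 2 * tr$f1_hz - tr$f2_hz, tolerance = 1e-10)
  expect_equal(tr$fdp_hz / tr$f2_hz, rep(0.6, nrow(tr)), tolerance = 1e-10)
  # no DP: track falls to the estimator's noise floor
  sw0 <- gen_dpoae_sweep(dp_db_spl = -Inf, primaries_db_spl = 60,
                         noise_db_spl = 10, seed = 8)
  tr0 <- dpoae_level_track(sw0)
  expect_lt(max(tr0$dp_db_spl[tr0$t_s > 0.3 & tr0$t_s < 3.7]), 0)
  expect_error(dpoae_level_track(sw, window_s = 10), "window longer")
})

test_that("even/odd noise floor cancels deterministic components", {
  # identical presentations -> numerical zero (deeply negative dB)
  sw <- gen_dpoae_sweep(dp_db_spl = 20, noise_db_spl = -Inf, seed = 1)
  nf <- dpoae_noise_floor(sw)
  expect_lt(max(nf$dp_db_spl), -300)
  # adding a large common tone leaves the floor unchanged
  swn <- gen_dpoae_sweep(dp_db_spl = 20, noise_db_spl = 20, seed = 2)
  nf1 <- dpoae_noise_floor(swn)
  sw_tone <- swn
  tone <- sqrt(2) * 20e-6 * 10^(80 / 20)   # 80 dB SPL peak amplitude in Pa
  add <- tone * sin(2 * pi * 3000 * (seq_along(swn$presentations[[1]]) - 1) / swn$fs_hz)
  sw_tone$presentations <- lapply(swn$presentations, function(p) p + add)
  nf2 <- dpoae_noise_floor(sw_tone)
  expect_equal(nf2$dp_db_spl, nf1$dp_db_spl, tolerance = 1e-6)
  # the floor tracks the injected noise level (Monte-Carlo check): raising
  # the microphone noise by 20 dB raises the floor by 20 dB
  floor_at <- function(level, k) {
    s <- gen_dpoae_sweep(dp_db_spl = -Inf, primaries_db_spl = -Inf,
                         noise_db_spl = level, n_presentations = 10, seed = k)
    f <- dpoae_noise_floor(s)
    mean(f$dp_db_spl[f$t_s > 0.3 & f$t_s < 3.7])
  }
  f10 <- vapply(1:6, function(k) floor_at(10, k), numeric(1))
  f30 <- vapply(1:6, function(k) floor_at(30, 100 + k), numeric(1))
  expect_lt(stats::sd(f10), 2)
  expect_equal(mean(f30) - mean(f10), 20, tolerance = 0.15)
  expect_error(dpoae_noise_floor(gen_dpoae_sweep(n_presentations = 1)),
               "2 presentations")
})

test_that("pre/post DPOAE change implements the 5 dB exclusion rule", {
  sw <- gen_dpoae_sweep(dp_db_spl = 20, noise_db_spl = -Inf, seed = 1)
  tr <- dpoae_level_track(sw)
  same <- dpoae_change(tr, tr)
  expect_equal(same$max_change_db, 0)
  expect_false(same$excluded)
  down6 <- tr; down6$dp_db_spl <- tr$dp_db_spl - 6
  d6 <- dpoae_change(tr, down6)
  expect_equal(d6$max_change_db, 6)
  expect_true(d6$excluded)
  # boundary semantics: a change of exactly 5 dB is NOT excluded
  down5 <- tr; down5$dp_db_spl <- tr$dp_db_spl - 5
  d5 <- dpoae_change(tr, down5)
  expect_equal(d5$max_change_db, 5)
  expect_false(d5$excluded)
})
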