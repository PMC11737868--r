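test_that("generators are bit-reproducible under a fixed seed", {
  a <- gen_response_curve(40, noise_sd = 0.05, seed = 13)
  b <- gen_response_curve(40, noise_sd = 0.05, seed = 13)
  expect_identical(a$response, b$response)
  ca <- gen_cohort(cohort_spec(n = c(silence = 10), seed = 13))
  cb <- gen_cohort(cohort_spec(n = c(silence = 10), seed = 13))
  expect_identical(ca, cb)
  sa <- gen_spike_signal(100, seed = 13)
  sb <- gen_spike_signal(100, seed = 13)
  expect_identical(sa$samples, sb$samples)
  da <- gen_dpoae_sweep(noise_db_spl = 10, seed = 13)
  db <- gen_dpoae_sweep(noise_db_spl = 10, seed = 13)
  expect_identical(da$presentations, db$presentations)
})

test_that("noiseless response curves cross 0.75 exactly at the set time", {
  s <- gen_response_curve(54, tau_min = 4, noise_sd = 0)
  expect_equal(effect_time(s), 54, tolerance = 57.2 / 60 / 54)
  # infinite steepness limit is a step at tE
  st <- gen_response_curve(54, tau_min = 1e-9, noise_sd = 0)
  expect_equal(effect_time(st), 54, tolerance = 57.2 / 60 / 54)
  y <- st$response[st$t_min >= 0]
  expect_true(all(y[st$t_min[st$t_min >= 0] < 53] == 1))
  expect_true(all(y[st$t_min[st$t_min >= 0] > 55] == 0))
  # bimodal curves carry a plateau between the two modes
  bi <- gen_response_curve(20, tau_min = 2, bimodal = TRUE,
                           plateau_level = 0.4, plateau_te_min = 60,
                           noise_sd = 0)
  mid <- bi$response[bi$t_min > 30 & bi$t_min < 50]
  expect_true(all(abs(mid - 0.4) < 0.05))
})

test_that("sigma = 0 cohorts lie exactly on the trend (0 dB residuals)", {
  rec <- gen_cohort(cohort_spec(n = c(silence = 15, sound = 10),
                                offsets_db = list(silence = c(0, 0),
                                                  sound = c(0, 0)),
                                sigma_db = 0, seed = 4))
  tm <- fit_diffusion_trend(rec[rec$condition == "silence", ])
  resid <- effect_time_dB(rec$te_min, tm$predict_min(rec$place_m))
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("generator-estimator loop recovers D_eff within 10%", {
  rec <- gen_cohort(cohort_spec(n = c(silence = 48), D_eff_m2_s = 1e-9,
                                sigma_db = 3, seed = 48))
  tm <- fit_diffusion_trend(rec)
  expect_lt(abs(tm$D_eff_m2_s - 1e-9) / 1e-9, 0.10)
})

test_that("injected high-CF offset is detected in the right stratum", {
  hits <- vapply(1:60, function(k) {
    rec <- gen_cohort(cohort_spec(n = c(silence = 19, sound = 13),
                                  sigma_db = 3, seed = 1000 + k))
    a <- rec[rec$condition == "silence", ]
    b <- rec[rec$condition == "sound", ]
    cmp <- compare_groups(a, b, fit_diffusion_trend(a))
    c(high = cmp$p[cmp$stratum == "high_cf"] < 0.05,
      low = cmp$p[cmp$stratum == "low_cf"] < 0.05)
  }, logical(2))
  expect_gt(mean(hits["high", ]), 0.5)    # -6 dB offset lives at high CF
  expect_lt(mean(hits["low", ]), 0.3)     # and not at low CF
})

test_that("spike generator responds to rate and silence", {
  s0 <- gen_spike_signal(0, seed = 2)
  s1 <- gen_spike_signal(500, seed = 2)
  m0 <- mean(teager_transform(s0)$samples)
  m1 <- mean(teager_transform(s1)$samples)
  expect_gt(m1, m0)
  expect_lt(as.numeric(driven_response(m0, m0)), 1e-12)
})

test_that("dpoae generator embeds the requested levels", {
  sw <- gen_dpoae_sweep(dp_db_spl = 20, primaries_db_spl = 60,
                        noise_db_spl = -Inf, n_presentations = 2, seed = 1)
  tr <- dpoae_level_track(sw)
  inner <- tr$t_s > 0.3 & tr$t_s < 3.7
  expect_lt(max(abs(tr$dp_db_spl[inner] - 20)), 1)
  expect_equal(length(sw$presentations), 2L)
})
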