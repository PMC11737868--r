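# Synthetic-data generators: every input the analysis chain needs, with
# known ground truth, so the full pipeline runs without any recordings.

#' Generate a synthetic normalized neural response curve
#'
#' A baseline of 1 with multiplicative Gaussian noise followed by a
#' logistic decay placed so that the noiseless curve crosses 0.75 exactly
#' at `te_min`; the crossing steepness is set by `tau_min` (the decay's
#' time constant; `tau_min -> 0` gives a step at `te_min`). An optional
#' second decay mode produces the bimodal shapes seen in apical-channel
#' recordings; its 0.75 crossing placement is then approximate.
#'
#' Samples are spaced by the stimulus-sequence duration (51 pips plus a
#' pause, 57.2 s).
#'
#' @param te_min ground-truth effect time (minutes)
#' @param tau_min logistic time constant (minutes)
#' @param noise_sd multiplicative noise standard deviation (fraction of
#'   the momentary level)
#' @param bimodal logical; add a second plateau/decay mode
#' @param plateau_level,plateau_te_min level and second-crossing time of
#'   the bimodal plateau (used when `bimodal = TRUE`)
#' @param sampling_interval_s sample spacing (s), default 57.2
#' @param baseline_min minutes of pre-application baseline
#' @param duration_min minutes of post-application recording
#' @param cf_hz,condition metadata carried into the series
#' @param seed RNG seed (fixed seed gives bit-identical output)
#' @return a normalized [neural_response_series()]
#' @export
gen_response_curve <- function(te_min, tau_min = 4, noise_sd = 0,
                               bimodal = FALSE, plateau_level = 0.5,
                               plateau_te_min = NULL,
                               sampling_interval_s = 57.2,
                               baseline_min = 10, duration_min = NULL,
                               cf_hz = NA, condition = NA, seed = NULL) {
  check_positive(te_min, "te_min")
  check_positive(sampling_interval_s, "sampling_interval_s")
  duration_min <- duration_min %||% max(2 * te_min, te_min + 30)
  dt <- sampling_interval_s / 60
  t <- seq(-baseline_min, duration_min, by = dt)
  shape <- function(tm) {
    if (!bimodal) {
      t0 <- te_min + tau_min * log(3)   # noiseless 0.75 crossing at te_min
      stats::plogis(-(tm - t0) / max(tau_min, 1e-9))
    } else {
      te2 <- plateau_te_min %||% (2 * te_min)
      w <- 1 - plateau_level
      t01 <- te_min + tau_min * log(3)  # approximate placement
      w * stats::plogis(-(tm - t01) / max(tau_min, 1e-9)) +
        plateau_level * stats::plogis(-(tm - te2) / max(tau_min, 1e-9))
    }
  }
  y <- shape(t)
  if (noise_sd > 0) y <- with_seed(seed, y * (1 + stats::rnorm(length(y), 0, noise_sd)))
  neural_response_series(t, y, cf_hz = cf_hz, condition = condition,
                         normalized = TRUE)
}

#' Cohort specification for synthetic effect-time records
#'
#' The generative model matches the analysis chain's assumptions: places
#' are drawn over a CF range, trend times follow the 1D-diffusion law
#' `tE = x^2 / (4 D_eff z^2)`, and each condition multiplies the trend by
#' `10^((offset + eps) / 20)` with `eps ~ N(0, sigma_db^2)` (lognormal
#' noise, additive in dB). Condition offsets are given per stratum
#' (`low`/`high` relative to `cf_split_hz`), qualitatively mirroring the
#' experimental pattern: broadband sound and mid-frequency tones
#' facilitate high-CF (basal) places, low-frequency tones facilitate
#' everywhere, salicylate-treated ears do not differ from silence.
#'
#' @param n named integer vector: records per condition, e.g.
#'   `c(silence = 48, sound = 34)`
#' @param D_eff_m2_s true effective diffusion constant of the trend
#' @param offsets_db named list of `c(low, high)` dB offsets per condition
#' @param sigma_db lognormal noise sd in dB
#' @param cf_range_hz CF sampling range (log-uniform)
#' @param cf_split_hz stratum split for the offsets
#' @param threshold_frac effect threshold fraction (trend law)
#' @param probes_per_animal records contributed by each animal
#' @param seed RNG seed
#' @return an object of class `cohort_spec`
#' @export
cohort_spec <- function(n = c(silence = 48, sound = 34),
                        D_eff_m2_s = 1e-9,
                        offsets_db = list(silence = c(0, 0),
                                          sound = c(0, -6),
                                          post_SA = c(0, 0),
                                          LF_tone = c(-8, -6),
                                          MF_tone = c(0, -6)),
                        sigma_db = 3, cf_range_hz = c(1000, 16000),
                        cf_split_hz = 4500, threshold_frac = 0.01,
                        probes_per_animal = 3L, seed = NULL) {
  if (is.null(names(n)) || any(!names(n) %in% names(offsets_db)))
    stop_validation("n", "must be named with conditions present in offsets_db")
  check_positive(n, "n"); check_positive(D_eff_m2_s, "D_eff_m2_s")
  check_nonnegative(sigma_db, "sigma_db")
  structure(list(n = n, D_eff_m2_s = D_eff_m2_s, offsets_db = offsets_db,
                 sigma_db = sigma_db, cf_range_hz = cf_range_hz,
                 cf_split_hz = cf_split_hz, threshold_frac = threshold_frac,
                 probes_per_animal = as.integer(probes_per_animal),
                 seed = seed), class = "cohort_spec")
}

#' Generate a synthetic effect-time cohort
#'
#' @param spec a [cohort_spec()]
#' @param geom a [cochlear_geometry()] supplying the place-frequency map
#' @return data frame of records: `animal_id`, `cf_hz`, `place_m`,
#'   `condition`, `te_min`
#' @export
gen_cohort <- function(spec, geom = cochlear_geometry()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    rows <- lapply(names(spec$n), function(cond) {
      m <- spec$n[[cond]]
      cf <- exp(stats::runif(m, log(spec$cf_range_hz[1]), log(spec$cf_range_hz[2])))
      x <- place_from_cf(geom, cf)
      te_trend_s <- diffusion_effect_time(x, spec$D_eff_m2_s, spec$threshold_frac)
      off <- ifelse(cf <= spec$cf_split_hz, spec$offsets_db[[cond]][1],
                    spec$offsets_db[[cond]][2])
      eps <- stats::rnorm(m, 0, spec$sigma_db)
      te_min <- te_trend_s / 60 * 10^((off + eps) / 20)
      animal <- paste0("G", cond, "_",
                       sprintf("%03d", (seq_len(m) - 1L) %/% spec$probes_per_animal + 1L))
      data.frame(animal_id = animal, cf_hz = cf, place_m = x,
                 condition = cond, te_min = te_min)
    })
    do.call(rbind, rows)
  })
}

# stereotyped extracellular spike: biphasic (first derivative of a
# Gaussian), ~1 ms footprint
spike_waveform <- function(fs_hz, width_s = 3e-4) {
  t <- seq(-3 * width_s, 3 * width_s, by = 1 / fs_hz)
  w <- -t / width_s * exp(-t^2 / (2 * width_s^2))
  w / max(abs(w))
}

#' Generate a synthetic multiunit spike signal
#'
#' Gaussian background noise plus stereotyped biphasic spike waveforms at
#' Poisson times; a configurable fraction of spikes is phase-locked to a
#' probe tone (driven activity), the rest are spontaneous. Used to
#' exercise the Teager / driven-response chain.
#'
#' @param rate_hz total spike rate
#' @param tone_locked_fraction fraction of spikes locked to the probe tone
#' @param tone_hz probe tone frequency
#' @param fs_hz sampling rate (>= 10 kHz)
#' @param duration_s signal duration
#' @param spike_amp spike amplitude relative to the unit background noise
#' @param seed RNG seed
#' @return a [sampled_signal()]
#' @export
gen_spike_signal <- function(rate_hz, tone_locked_fraction = 0.5,
                             tone_hz = 4000, fs_hz = 50000, duration_s = 1,
                             spike_amp = 4, seed = NULL) {
  if (fs_hz < 10000) stop_validation("fs_hz", "must be >= 10 kHz")
  check_nonnegative(rate_hz, "rate_hz")
  with_seed(seed, {
    n <- as.integer(round(duration_s * fs_hz))
    x <- stats::rnorm(n)
    if (rate_hz > 0) {
      n_sp <- stats::rpois(1, rate_hz * duration_s)
      n_locked <- stats::rbinom(1, n_sp, tone_locked_fraction)
      t_free <- stats::runif(n_sp - n_locked, 0, duration_s)
      # locked spikes: pick a tone cycle, fire near a fixed phase
      cyc <- sample.int(max(1L, floor(tone_hz * duration_s)), n_locked,
                        replace = TRUE)
      t_lock <- (cyc - 1 + 0.25) / tone_hz +
        stats::rnorm(n_locked, 0, 0.05 / tone_hz)
      w <- spike_waveform(fs_hz)
      half <- (length(w) - 1L) %/% 2L
      for (ts in c(t_free, t_lock)) {
        i0 <- as.integer(round(ts * fs_hz)) + 1L
        idx <- (i0 - half):(i0 + half)
        ok <- idx >= 1L & idx <= n
        x[idx[ok]] <- x[idx[ok]] + spike_amp * w[ok]
      }
    }
    sampled_signal(x, fs_hz = fs_hz, cf_hz = tone_hz)
  })
}

#' Generate synthetic swept-tone DPOAE presentations
#'
#' Two primaries sweep upward (`f2` linear from `f2_start_hz` to
#' `f2_end_hz` over `sweep_s`, `f2 = ratio * f1`) with raised-cosine
#' on/off ramps, plus a `2 f1 - f2` distortion product at `dp_db_spl` and
#' white microphone noise; `n_presentations` independent noisy copies are
#' returned (the deterministic content is identical across
#' presentations, as for a repeated stimulus).
#'
#' @param dp_db_spl distortion-product level (dB SPL); `-Inf` for none
#' @param primaries_db_spl primary level (dB SPL, each)
#' @param noise_db_spl white-noise level (dB SPL per sample sd); `-Inf`
#'   for a noiseless sweep
#' @param n_presentations number of presentations
#' @param fs_hz sampling rate
#' @param f2_start_hz,f2_end_hz,sweep_s,ratio sweep parameters
#' @param ramp_s raised-cosine ramp duration
#' @param seed RNG seed
#' @return an object of class `dpoae_sweep`
#' @export
gen_dpoae_sweep <- function(dp_db_spl = 20, primaries_db_spl = 60,
                            noise_db_spl = -Inf, n_presentations = 10,
                            fs_hz = 50000, f2_start_hz = 500,
                            f2_end_hz = 10000, sweep_s = 4, ratio = 1.25,
                            ramp_s = 0.025, seed = NULL) {
  n <- as.integer(round(sweep_s * fs_hz))
  t <- (seq_len(n) - 1L) / fs_hz
  ph2 <- dpoae_phase2(t, f2_start_hz, f2_end_hz, sweep_s)
  ph1 <- ph2 / ratio
  phd <- 2 * ph1 - ph2
  ramp <- rep(1, n)
  nr <- as.integer(round(ramp_s * fs_hz))
  ramp[seq_len(nr)] <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
  ramp[n + 1L - seq_len(nr)] <- ramp[seq_len(nr)]
  a_pr <- spl_to_pa(primaries_db_spl)
  a_dp <- if (is.finite(dp_db_spl)) spl_to_pa(dp_db_spl) else 0
  det_part <- ramp * (a_pr * sin(ph1) + a_pr * sin(ph2) + a_dp * sin(phd))
  sd_noise <- if (is.finite(noise_db_spl)) spl_to_pa(noise_db_spl) / sqrt(2) else 0
  pres <- with_seed(seed, lapply(seq_len(n_presentations), function(k) {
    det_part + if (sd_noise > 0) stats::rnorm(n, 0, sd_noise) else 0
  }))
  structure(list(presentations = pres, fs_hz = fs_hz,
                 f2_start_hz = f2_start_hz, f2_end_hz = f2_end_hz,
                 sweep_s = sweep_s, ratio = ratio,
                 dp_db_spl = dp_db_spl, primaries_db_spl = primaries_db_spl),
            class = "dpoae_sweep")
}
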