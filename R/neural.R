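#' Sampled signal container
#'
#' @param samples numeric vector (arbitrary units)
#' @param fs_hz sampling rate (Hz)
#' @param cf_hz optional characteristic frequency of the recording channel
#' @return an object of class `sampled_signal`
#' @export
sampled_signal <- function(samples, fs_hz, cf_hz = NULL) {
  check_positive(fs_hz, "fs_hz")
  if (any(!is.finite(samples))) stop_validation("samples", "must be finite")
  structure(list(samples = samples, fs_hz = fs_hz, cf_hz = cf_hz),
            class = "sampled_signal")
}

#' Teager energy transform
#'
#' Discrete Teager-Kaiser energy operator,
#' `psi[n] = x[n]^2 - x[n-1] x[n+1]`, used to emphasize multiunit spiking
#' activity in neural recordings before amplitude extraction. The output
#' has two fewer samples than the input (interior points only). For a
#' sinusoid `A sin(W n)` the operator returns the constant
#' `A^2 sin(W)^2`.
#'
#' @param sig a [sampled_signal()] or numeric vector (>= 3 samples)
#' @return a `sampled_signal` of Teager energy (length n - 2)
#' @export
teager_transform <- function(sig) {
  x <- if (inherits(sig, "sampled_signal")) sig$samples else sig
  n <- length(x)
  if (n < 3L) stop("teager_transform needs at least 3 samples", call. = FALSE)
  psi <- x[2:(n - 1L)]^2 - x[1:(n - 2L)] * x[3:n]
  fs <- if (inherits(sig, "sampled_signal")) sig$fs_hz else NA_real_
  sampled_signal(psi, fs_hz = if (is.na(fs)) 1 else fs,
                 cf_hz = if (inherits(sig, "sampled_signal")) sig$cf_hz)
}

#' Driven neural response amplitude
#'
#' The driven response is the mean Teager energy during the probe-tone
#' segment minus the mean during the preceding silence (spontaneous
#' activity), floored at zero. A `floored` attribute flags cases where the
#' spontaneous level exceeded the driven level.
#'
#' @param tone_teager_mean mean Teager energy of the tone segment (a.u.)
#' @param spontaneous_teager_mean mean Teager energy of the silent segment
#' @return driven response (a.u., >= 0) with attribute `floored`
#' @export
driven_response <- function(tone_teager_mean, spontaneous_teager_mean) {
  check_nonnegative(tone_teager_mean, "tone_teager_mean")
  check_nonnegative(spontaneous_teager_mean, "spontaneous_teager_mean")
  d <- tone_teager_mean - spontaneous_teager_mean
  out <- pmax(d, 0)
  attr(out, "floored") <- d < 0
  out
}

#' Neural response time series
#'
#' @param t_min sampling times in minutes relative to drug application
#'   (negative = baseline window); strictly increasing
#' @param response driven response amplitudes (a.u.) or already-normalized
#'   values
#' @param cf_hz channel characteristic frequency
#' @param condition experimental condition label (e.g. `"silence"`,
#'   `"sound"`, `"post_SA"`, `"LF_tone"`, `"MF_tone"`)
#' @param normalized logical; if `FALSE`, call [normalize_response()]
#'   before computing effect times
#' @return an object of class `neural_response_series`
#' @export
neural_response_series <- function(t_min, response, cf_hz = NA, condition = NA,
                                   normalized = FALSE) {
  if (length(t_min) != length(response))
    stop_validation("response", "length must match t_min")
  if (any(diff(t_min) <= 0)) stop_validation("t_min", "must be strictly increasing")
  structure(list(t_min = t_min, response = response, cf_hz = cf_hz,
                 condition = condition, normalized = normalized),
            class = "neural_response_series")
}

#' Normalize a response series to its pre-application baseline
#'
#' Baseline is the mean driven response over all samples with `t < 0`
#' (minimum 3 samples).
#'
#' @param series a [neural_response_series()]
#' @return the series with `response` divided by the baseline mean
#' @export
normalize_response <- function(series) {
  stopifnot(inherits(series, "neural_response_series"))
  base <- series$response[series$t_min < 0]
  if (length(base) < 3L)
    stop("need at least 3 baseline (t < 0) samples to normalize", call. = FALSE)
  b <- mean(base)
  if (b <= 0) stop("baseline mean is not positive", call. = FALSE)
  series$response <- series$response / b
  series$normalized <- TRUE
  series
}

#' Effect time of a normalized response curve
#'
#' The latency after drug application at which the normalized neural
#' response first drops below `threshold` (default 75% of baseline) and
#' stays below it for `k_sustained` consecutive samples (default 3; the
#' sustained rule rejects single-sample noise dips, which matters for
#' curves with bimodal decay). Sub-interval timing is obtained by linear
#' interpolation between the bracketing samples. Curves that never cross
#' return `NA` with attribute `unreached = TRUE`.
#'
#' @param series a normalized [neural_response_series()]
#' @param threshold fraction of baseline (default 0.75)
#' @param k_sustained consecutive samples required below threshold;
#'   `1` reproduces a naive first crossing
#' @return effect time in minutes, or `NA` if unreached
#' @export
effect_time <- function(series, threshold = 0.75, k_sustained = 3L) {
  stopifnot(inherits(series, "neural_response_series"))
  if (!isTRUE(series$normalized))
    stop("series must be normalized (see normalize_response())", call. = FALSE)
  post <- series$t_min >= 0
  tt <- series$t_min[post]; yy <- series$response[post]
  n <- length(yy)
  below <- yy < threshold
  k <- min(as.integer(k_sustained), n)
  hit <- NA_integer_
  if (k >= 1L && any(below)) {
    run <- 0L
    for (i in seq_len(n)) {
      run <- if (below[i]) run + 1L else 0L
      if (run >= k) { hit <- i - k + 1L; break }
    }
  }
  if (is.na(hit)) {
    out <- NA_real_
    attr(out, "unreached") <- TRUE
    return(out)
  }
  if (hit == 1L) {
    tt[1L]
  } else {
    y0 <- yy[hit - 1L]; y1 <- yy[hit]
    tt[hit - 1L] + (tt[hit] - tt[hit - 1L]) * (y0 - threshold) /
      max(y0 - y1, .Machine$double.eps)
  }
}

# chirp phase of the f2 primary: f2 rises linearly f2_start -> f2_end
dpoae_phase2 <- function(t, f2_start, f2_end, sweep_s) {
  2 * pi * (f2_start * t + (f2_end - f2_start) / sweep_s * t^2 / 2)
}

#' DPOAE level track from a swept two-tone response
#'
#' Least-squares estimation of the `2 f1 - f2` distortion-product level
#' along a linear upward sweep of the primaries (`f2 = ratio * f1`). In
#' each Hann-weighted window (default 100 ms, shifted in 20 ms steps),
#' sine/cosine pairs at the instantaneous primary and distortion-product
#' phases are fit by least squares; the DP amplitude is reported in
#' dB SPL.
#'
#' @param sweep a `dpoae_sweep` (see [gen_dpoae_sweep()]; presentations
#'   are averaged) or a numeric waveform in Pa
#' @param fs_hz sampling rate; taken from the sweep object if present
#' @param f2_start_hz,f2_end_hz,sweep_s,ratio sweep parameters (f2 from
#'   0.5 to 10 kHz over 4 s, f2 = 1.25 f1, as defaults)
#' @param window_s Hann analysis window length (s)
#' @param step_s window step (s)
#' @return data frame: window center time, instantaneous `f1`, `f2` and
#'   DP frequency (Hz), and `dp_db_spl`
#' @export
dpoae_level_track <- function(sweep, fs_hz = NULL, f2_start_hz = 500,
                              f2_end_hz = 10000, sweep_s = 4, ratio = 1.25,
                              window_s = 0.1, step_s = 0.02) {
  if (inherits(sweep, "dpoae_sweep")) {
    x <- Reduce(`+`, sweep$presentations) / length(sweep$presentations)
    fs_hz <- sweep$fs_hz
    f2_start_hz <- sweep$f2_start_hz; f2_end_hz <- sweep$f2_end_hz
    sweep_s <- sweep$sweep_s; ratio <- sweep$ratio
  } else x <- as.numeric(sweep)
  check_positive(fs_hz, "fs_hz")
  n <- length(x)
  if (window_s * fs_hz > n)
    stop("analysis window longer than the sweep", call. = FALSE)
  wlen <- as.integer(round(window_s * fs_hz))
  step <- max(1L, as.integer(round(step_s * fs_hz)))
  hann <- 0.5 * (1 - cos(2 * pi * seq_len(wlen) / (wlen + 1)))
  starts <- seq(1L, n - wlen + 1L, by = step)
  t_all <- (seq_len(n) - 1L) / fs_hz
  res <- lapply(starts, function(s0) {
    idx <- s0:(s0 + wlen - 1L)
    tw <- t_all[idx]
    ph2 <- dpoae_phase2(tw, f2_start_hz, f2_end_hz, sweep_s)
    ph1 <- ph2 / ratio
    phd <- 2 * ph1 - ph2
    X <- cbind(1, cos(ph1), sin(ph1), cos(ph2), sin(ph2), cos(phd), sin(phd))
    w <- sqrt(hann)
    fit <- stats::lm.fit(X * w, x[idx] * w)
    amp_dp <- sqrt(sum(fit$coefficients[6:7]^2))
    tc <- mean(tw)
    f2c <- f2_start_hz + (f2_end_hz - f2_start_hz) * tc / sweep_s
    c(t_s = tc, f1_hz = f2c / ratio, f2_hz = f2c,
      fdp_hz = (2 / ratio - 1) * f2c, dp_db_spl = pa_to_spl(amp_dp))
  })
  as.data.frame(do.call(rbind, res))
}

#' DPOAE noise floor from repeated presentations
#'
#' The level track of the "null" waveform, `(mean of even-numbered
#' presentations - mean of odd-numbered presentations) / 2`, processed
#' identically to the signal path. Deterministic (repeatable) components
#' cancel, leaving the incoherent noise.
#'
#' @param sweep a `dpoae_sweep` with at least 2 presentations
#' @param ... passed to [dpoae_level_track()]
#' @return data frame as from [dpoae_level_track()]
#' @export
dpoae_noise_floor <- function(sweep, ...) {
  stopifnot(inherits(sweep, "dpoae_sweep"))
  m <- length(sweep$presentations)
  if (m < 2L) stop("need at least 2 presentations", call. = FALSE)
  ev <- seq(2L, m, by = 2L); od <- seq(1L, m, by = 2L)
  null_wave <- (Reduce(`+`, sweep$presentations[ev]) / length(ev) -
                  Reduce(`+`, sweep$presentations[od]) / length(od)) / 2
  dpoae_level_track(null_wave, fs_hz = sweep$fs_hz,
                    f2_start_hz = sweep$f2_start_hz,
                    f2_end_hz = sweep$f2_end_hz,
                    sweep_s = sweep$sweep_s, ratio = sweep$ratio, ...)
}

#' Pre/post DPOAE change and exclusion rule
#'
#' Maximum absolute level difference between two DP tracks over a
#' frequency band, with the exclusion flag raised when the change exceeds
#' (strictly) `threshold_db`. Tracks are compared on the `f2` grid of the
#' pre track (linear interpolation of the post track).
#'
#' @param pre_track,post_track data frames from [dpoae_level_track()]
#' @param band_hz length-2 frequency band (Hz), default 0.1-10 kHz
#' @param threshold_db exclusion threshold (dB), default 5
#' @return list with `max_change_db` and logical `excluded`
#' @export
dpoae_change <- function(pre_track, post_track, band_hz = c(100, 10000),
                         threshold_db = 5) {
  f <- pre_track$f2_hz
  rng <- range(post_track$f2_hz)
  sel <- f >= band_hz[1] & f <= band_hz[2] & f >= rng[1] & f <= rng[2]
  if (!any(sel)) stop("tracks do not overlap the requested band", call. = FALSE)
  post_i <- stats::approx(post_track$f2_hz, post_track$dp_db_spl,
                          xout = f[sel], rule = 1)$y
  d <- abs(pre_track$dp_db_spl[sel] - post_i)
  mx <- max(d, na.rm = TRUE)
  list(max_change_db = mx, excluded = mx > threshold_db)
}
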