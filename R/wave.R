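#' Traveling-wave surrogate parameters
#'
#' The full fluid-structure model of organ-of-Corti vibration is out of
#' scope; its output is emulated by a parametric traveling wave. The
#' basilar-membrane (bottom) wall displacement is
#' `A_b(x) cos(wt - phi(x))` with a smooth envelope rising to the
#' characteristic place `x_peak` and cutting off apically, and an
#' accumulated phase `phi(x) = integral of k(x')` whose wavenumber grows
#' toward the peak (so phase velocity w/k decays toward the apex). When
#' outer hair cells are active, the top (reticular-lamina side) wall moves
#' with gain `active_gain` and phase lead `active_phase_rad` inside a
#' sub-peak tail window, creating the oscillatory cross-sectional area
#' change that acts as a peristaltic pump. With `ohc_active = FALSE`
#' (salicylate condition) top and bottom motion are identical and the area
#' change is exactly zero.
#'
#' Amplitudes scale linearly with stimulus pressure (no compressive
#' nonlinearity). `amp_peak_m_at_80db` is the calibration constant of the
#' surrogate: the peak bottom-wall amplitude for an 80 dB SPL tone. Its
#' default is chosen so the active 1 kHz / 80 dB drift field peaks at the
#' mm/s order of magnitude; see the package vignette for the rationale.
#'
#' @param amp_peak_m_at_80db peak bottom-wall displacement amplitude (m) at
#'   80 dB SPL
#' @param rise_exponent envelope rise `(x/x_peak)^q` basal of the peak
#' @param rolloff_m apical cutoff length scale (m); the envelope decays as
#'   a Gaussian of this width beyond `x_peak`
#' @param k_base_rad_m,k_peak_rad_m wavenumber (rad/m) at the base and at
#'   the peak; `k` interpolates as `(x/x_peak)^k_exponent` between them
#' @param k_exponent exponent of the wavenumber law
#' @param active_gain top-wall amplitude gain inside the active tail window
#' @param active_phase_rad top-wall phase lead inside the active tail window
#' @param tail_length_m length of the sub-peak active window (m)
#' @return an object of class `wave_params`
#' @export
wave_params <- function(amp_peak_m_at_80db = 6e-6,
                        rise_exponent = 2,
                        rolloff_m = 0.6e-3,
                        k_base_rad_m = 2 * pi / 0.012,
                        k_peak_rad_m = 2 * pi / 1.5e-3,
                        k_exponent = 2,
                        active_gain = 1.25,
                        active_phase_rad = 0.5,
                        tail_length_m = 4e-3) {
  check_nonnegative(amp_peak_m_at_80db, "amp_peak_m_at_80db")
  check_positive(rise_exponent, "rise_exponent")
  check_positive(rolloff_m, "rolloff_m")
  check_positive(k_base_rad_m, "k_base_rad_m")
  check_positive(k_peak_rad_m, "k_peak_rad_m")
  check_positive(tail_length_m, "tail_length_m")
  structure(list(amp_peak_m_at_80db = amp_peak_m_at_80db,
                 rise_exponent = rise_exponent, rolloff_m = rolloff_m,
                 k_base_rad_m = k_base_rad_m, k_peak_rad_m = k_peak_rad_m,
                 k_exponent = k_exponent, active_gain = active_gain,
                 active_phase_rad = active_phase_rad,
                 tail_length_m = tail_length_m),
            class = "wave_params")
}

#' Synthesize the traveling-wave wall kinematics for a tone
#'
#' Produces the `traveling_wave` object consumed by the flow solver: complex
#' displacement amplitude fields for the top wall of the Corti duct and for
#' the basilar membrane (the bottom wall of the duct, shared with the scala
#' tympani). Real displacement is `Re(eta_hat(x) exp(i w t))`, positive
#' upward. Broadband stimuli are handled by the caller as a sum of tones.
#'
#' @param geom a [cochlear_geometry()]
#' @param stim a [stimulus()]; must be a tone (or silence, which yields a
#'   zero-amplitude wave at the map midpoint frequency)
#' @param ohc_active logical; `FALSE` forces identical top/bottom motion
#'   (zero cross-sectional area change, the salicylate condition)
#' @param params a [wave_params()]
#' @return an object of class `traveling_wave` with amplitude/phase
#'   accessor functions, `omega`, and `x_peak_m`
#' @export
synthesize_wave <- function(geom, stim, ohc_active = TRUE, params = wave_params()) {
  stopifnot(inherits(geom, "cochlear_geometry"), inherits(stim, "stimulus"))
  if (stim$kind == "broadband")
    stop("broadband stimuli must be decomposed into tones by the caller",
         call. = FALSE)
  f <- if (stim$kind == "silence") {
    sqrt(cf_from_place(geom, 0) * cf_from_place(geom, geom$length_m))
  } else stim$frequency_hz
  x_peak <- place_from_cf(geom, f)  # errors if outside map range
  omega <- 2 * pi * f
  level <- if (stim$kind == "silence") -Inf else stim$level_db_spl
  amp_peak <- params$amp_peak_m_at_80db * 10^((level - 80) / 20)

  envelope <- function(x) {
    e <- (pmin(x, x_peak) / x_peak)^params$rise_exponent
    apical <- pmax(x - x_peak, 0) / params$rolloff_m
    e * exp(-apical^2)
  }
  # accumulated phase: phi(x) = int_0^x k, with k frozen at its peak value
  # apically of x_peak
  kfun <- function(x) {
    s <- (pmin(x, x_peak) / x_peak)^params$k_exponent
    params$k_base_rad_m + (params$k_peak_rad_m - params$k_base_rad_m) * s
  }
  phase <- function(x) {
    kb <- params$k_base_rad_m; kp <- params$k_peak_rad_m; q <- params$k_exponent
    xc <- pmin(x, x_peak)
    ph <- kb * xc + (kp - kb) * xc * (xc / x_peak)^q / (q + 1)
    ph + kp * pmax(x - x_peak, 0)
  }
  # active-gain window: raised-sine bump over the sub-peak tail
  tail_win <- function(x) {
    x0 <- max(x_peak - params$tail_length_m, 0)
    w <- (x - x0) / (x_peak - x0)
    ifelse(w > 0 & w < 1, sin(pi * w)^2, 0)
  }
  g_fun <- if (ohc_active) {
    function(x) 1 + (params$active_gain - 1) * tail_win(x)
  } else function(x) rep(1, length(x))
  psi_fun <- if (ohc_active) {
    function(x) params$active_phase_rad * tail_win(x)
  } else function(x) rep(0, length(x))

  eta_b_hat <- function(x) amp_peak * envelope(x) * exp(-1i * phase(x))
  eta_t_hat <- function(x) {
    amp_peak * envelope(x) * g_fun(x) * exp(-1i * (phase(x) - psi_fun(x)))
  }

  structure(list(omega = omega, frequency_hz = f, level_db_spl = level,
                 x_peak_m = x_peak, ohc_active = ohc_active, params = params,
                 eta_b_hat = eta_b_hat, eta_t_hat = eta_t_hat,
                 amplitude_b = function(x) abs(eta_b_hat(x)),
                 amplitude_t = function(x) abs(eta_t_hat(x)),
                 phase_b = phase, geom_length_m = geom$length_m),
            class = "traveling_wave")
}

#' @export
print.traveling_wave <- function(x, ...) {
  cat("<traveling_wave>\n")
  cat(sprintf("  %.3g kHz at %s dB SPL; peak place %.2f mm; OHC %s\n",
              x$frequency_hz / 1e3,
              format(x$level_db_spl), x$x_peak_m * 1e3,
              if (x$ohc_active) "active" else "passive"))
  cat(sprintf("  peak amplitude %.3g nm\n", max(x$amplitude_b(x$x_peak_m)) * 1e9))
  invisible(x)
}

#' Wall displacement and velocity
#'
#' Evaluates the surrogate wall kinematics at places `x` and time `t`.
#' Velocity is the exact time derivative of displacement and both are
#' periodic with period `2*pi/omega`.
#'
#' @param wave a [synthesize_wave()] result
#' @param surface `"top"` (top wall of the Corti duct) or `"bottom"`
#'   (basilar membrane)
#' @param x places (m); vectorized
#' @param t time (s), scalar or same length as `x`
#' @return list with `displacement_m` and `velocity_m_s`
#' @export
wall_kinematics <- function(wave, surface = c("top", "bottom"), x, t) {
  stopifnot(inherits(wave, "traveling_wave"))
  surface <- match.arg(surface)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  eta <- switch(surface, top = wave$eta_t_hat(x), bottom = wave$eta_b_hat(x))
  ph <- exp(1i * wave$omega * t)
  list(displacement_m = Re(eta * ph),
       velocity_m_s = Re(1i * wave$omega * eta * ph))
}
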