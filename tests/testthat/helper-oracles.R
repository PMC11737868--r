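# Independent analytic/numerical oracles used to validate the solvers.
# These are implemented from the governing equations directly and share no
# code with the solver paths they check.

# Stokes' oscillating-wall solution: u(y, t) = U0 exp(-y/ds) cos(wt - y/ds),
# ds = sqrt(2 nu / w), for a wall at y = 0 oscillating tangentially.
stokes_wall_profile <- function(y, t, U0, nu, omega) {
  ds <- sqrt(2 * nu / omega)
  U0 * exp(-y / ds) * cos(omega * t - y / ds)
}

# Lubrication-theory Eulerian mean velocity for a plane channel whose top
# wall carries the traveling wave h(x,t) = h0 + a cos(kx - wt) (bottom wall
# rigid, both walls no-slip, periodic in x, zero net pressure rise per
# wavelength). At each instant the flow is quasi-static Poiseuille:
#   q(x,t) = Q0(t) + (a w / k) (cos(kx - wt) - cos(wt)),
# with Q0 fixed by  integral of q / h^3 dx = 0 over a wavelength; the
# velocity profile is u = 6 q/h (Y - Y^2), Y = y/h. The Eulerian mean is
# the time average at a fixed point.
lubrication_mean_u <- function(x, y, h0, a, k, omega, nt = 2000, nxq = 512) {
  w <- omega
  tg <- (seq_len(nt) - 0.5) / nt * (2 * pi / w)
  xq <- (seq_len(nxq) - 0.5) / nxq * (2 * pi / k)
  vapply(seq_along(x), function(m) {
    ph <- k * x[m] - w * tg
    h <- h0 + a * cos(ph)
    Qx <- outer(-w * tg, k * xq, function(wt, kx) (a * w / k) * (cos(kx + wt) - cos(wt)))
    h3 <- (h0 + a * cos(outer(-w * tg, k * xq, `+`)))^-3
    Q0 <- -rowSums(Qx * h3) / rowSums(h3)
    Q <- Q0 + (a * w / k) * (cos(ph) - cos(w * tg))
    Y <- y[m] / h
    mean(6 * Q / h * (Y - Y^2))
  }, numeric(1))
}

# brute-force threshold-crossing time of the 1D diffusion solution by a
# dense time scan (validates the closed-form inversion)
scan_diffusion_effect_time <- function(x, D, frac = 0.01, c0 = 10,
                                       t_max = NULL, n = 200000) {
  t_max <- t_max %||% (x^2 / D)
  tt <- seq(t_max / n, t_max, length.out = n)
  cc <- diffusion_1d_closed_form(x, tt, D, c0)
  k <- which(cc >= frac * c0)[1]
  if (is.na(k)) return(NA_real_)
  tt[k]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
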