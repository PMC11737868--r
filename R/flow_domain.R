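#' Fluid properties
#'
#' @param nu_m2_s kinematic viscosity (m^2/s). The cochlear default is
#'   70e-6, one hundred times that of water, reflecting the effective
#'   viscosity of the narrow perilymphatic spaces.
#' @param rho_kg_m3 density (kg/m^3)
#' @param K_m_s_pa basilar-membrane permeability coefficient in m/(s Pa);
#'   the transmembrane exchange velocity is `u_p = -K * dp` (Darcy's law).
#'   `0` makes the membrane impermeable.
#' @return an object of class `fluid_props`
#' @export
fluid_props <- function(nu_m2_s = 70e-6, rho_kg_m3 = 1000, K_m_s_pa = 1) {
  check_positive(nu_m2_s, "nu_m2_s")
  check_positive(rho_kg_m3, "rho_kg_m3")
  check_nonnegative(K_m_s_pa, "K_m_s_pa")
  structure(list(nu_m2_s = nu_m2_s, rho_kg_m3 = rho_kg_m3,
                 K_m_s_pa = K_m_s_pa), class = "fluid_props")
}

#' Darcy transmembrane exchange velocity
#'
#' `u_p = -K * dp` with `dp = p_corti - p_scala`; positive `u_p` is
#' directed from the scala tympani into the Corti duct (upward).
#'
#' @param dp_pa transmembrane pressure difference (Pa), Corti minus scala
#' @param K_m_s_pa permeability coefficient, m/(s Pa)
#' @return exchange velocity in m/s
#' @export
darcy_exchange <- function(dp_pa, K_m_s_pa) {
  check_nonnegative(K_m_s_pa, "K_m_s_pa")
  -K_m_s_pa * dp_pa
}

# ---- internal flow-domain representation -------------------------------
#
# A stack of 1 or 2 uniform-dy channel layers over a shared x grid.
# Wall/membrane motion is monochromatic: real displacement is
# Re(eta_hat(x) exp(i w t)), positive upward; prescribed tangential wall
# velocity likewise Re(u_hat(x) exp(i w t)).
new_flow_domain <- function(nx, dx, layers, periodic_x, omega, fluid,
                            eta_bot_hat = NULL, eta_top_hat = NULL,
                            eta_mem_hat = NULL,
                            u_bot_hat = NULL, u_top_hat = NULL) {
  nlay <- length(layers)
  stopifnot(nlay %in% c(1L, 2L))
  row_dy <- unlist(lapply(layers, function(l) rep(l$dy, l$ny)))
  ny <- length(row_dy)
  fm <- if (nlay == 2L) layers[[1]]$ny + 1L else NA_integer_  # membrane v-face
  nux <- if (periodic_x) nx else nx + 1L
  x_p <- (seq_len(nx) - 0.5) * dx
  x_u <- (seq_len(nux) - 1) * dx
  zfun <- function(x) rep(0 + 0i, length(x))
  dom <- list(
    nx = nx, dx = dx, ny = ny, row_dy = row_dy, fm = fm,
    layer_rows = split(seq_len(ny), rep(seq_len(nlay),
                                        vapply(layers, `[[`, 1L, "ny"))),
    periodic_x = periodic_x, omega = omega, fluid = fluid,
    x_p = x_p, x_u = x_u,
    y_face = cumsum(c(0, row_dy)),
    eta_bot_hat = eta_bot_hat %||% zfun, eta_top_hat = eta_top_hat %||% zfun,
    eta_mem_hat = eta_mem_hat %||% zfun,
    u_bot_hat = u_bot_hat %||% zfun, u_top_hat = u_top_hat %||% zfun)
  dom$y_p <- dom$y_face[-length(dom$y_face)] + row_dy / 2
  class(dom) <- "flow_domain"
  dom
}

#' Single-layer channel domain (oracle configurations)
#'
#' A rectangular channel with optionally periodic ends, used for the
#' analytic benchmark problems (oscillating-wall Stokes layer, peristaltic
#' pumping). Wall motion is given as complex amplitude functions of x.
#'
#' @param length_m,height_m channel dimensions
#' @param nx,ny grid cells
#' @param omega angular frequency of the forcing (rad/s)
#' @param fluid a [fluid_props()]
#' @param periodic_x logical; `TRUE` for a periodic channel, `FALSE` for
#'   rigid closed ends
#' @param eta_bot_hat,eta_top_hat complex displacement amplitude of the
#'   bottom/top wall as a function of x (m, positive up)
#' @param u_bot_hat,u_top_hat complex tangential wall velocity amplitude
#'   as a function of x (m/s)
#' @return a `flow_domain`
#' @export
channel_domain <- function(length_m, height_m, nx, ny, omega, fluid,
                           periodic_x = TRUE,
                           eta_bot_hat = NULL, eta_top_hat = NULL,
                           u_bot_hat = NULL, u_top_hat = NULL) {
  check_positive(length_m, "length_m"); check_positive(height_m, "height_m")
  new_flow_domain(nx = as.integer(nx), dx = length_m / nx,
                  layers = list(list(ny = as.integer(ny), dy = height_m / ny)),
                  periodic_x = periodic_x, omega = omega, fluid = fluid,
                  eta_bot_hat = eta_bot_hat, eta_top_hat = eta_top_hat,
                  u_bot_hat = u_bot_hat, u_top_hat = u_top_hat)
}

#' Two-layer cochlear flow domain
#'
#' Assembles the flow domain for a cochlear run: scala tympani below,
#' Corti duct above, separated by the Darcy-permeable basilar membrane
#' which moves with the bottom-wall traveling wave; the top wall of the
#' Corti duct carries the (possibly OHC-boosted) top-wall wave. The outer
#' walls and the basal/apical ends are rigid no-slip.
#'
#' @param geom a [cochlear_geometry()]
#' @param wave a [synthesize_wave()] result
#' @param fluid a [fluid_props()]
#' @return a `flow_domain`
#' @export
cochlear_flow_domain <- function(geom, wave, fluid = fluid_props()) {
  stopifnot(inherits(geom, "cochlear_geometry"), inherits(wave, "traveling_wave"))
  g <- geom$grid
  new_flow_domain(
    nx = g$nx, dx = geom$length_m / g$nx,
    layers = list(list(ny = g$ny_scala, dy = geom$scala_height_m / g$ny_scala),
                  list(ny = g$ny_corti, dy = geom$corti_height_m / g$ny_corti)),
    periodic_x = FALSE, omega = wave$omega, fluid = fluid,
    eta_bot_hat = NULL,               # rigid outer scala wall
    eta_mem_hat = wave$eta_b_hat,     # basilar membrane
    eta_top_hat = wave$eta_t_hat)     # top of the Corti duct
}

#' Flow solver numerics
#'
#' @param dt_s time step (s); default is 1/100 of the forcing period
#'   (10 us at 1 kHz), scaled with frequency
#' @param max_periods,min_periods bounds on the number of forcing periods
#'   integrated while seeking the periodic steady state
#' @param periodicity_tol relative L2 change of the velocity field between
#'   consecutive periods accepted as "periodic"
#' @param nonlinear retain the advective term and the quadratic wall
#'   boundary-transfer terms (the streaming sources); `FALSE` gives the
#'   purely linear oscillatory problem
#' @param n_snapshots velocity snapshots stored per period (for drift
#'   verification and particle tracking)
#' @param min_stokes_cells required number of grid cells per Stokes-layer
#'   thickness `(nu/omega)^0.5`; violating grids are refused
#' @return an object of class `flow_numerics`
#' @export
flow_numerics <- function(dt_s = NULL, max_periods = 40L, min_periods = 4L,
                          periodicity_tol = 1e-4, nonlinear = TRUE,
                          n_snapshots = 32L, min_stokes_cells = 8) {
  if (!is.null(dt_s)) check_positive(dt_s, "dt_s")
  check_positive(max_periods, "max_periods")
  check_positive(periodicity_tol, "periodicity_tol")
  structure(list(dt_s = dt_s, max_periods = as.integer(max_periods),
                 min_periods = as.integer(min_periods),
                 periodicity_tol = periodicity_tol, nonlinear = nonlinear,
                 n_snapshots = as.integer(n_snapshots),
                 min_stokes_cells = min_stokes_cells),
            class = "flow_numerics")
}
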