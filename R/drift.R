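#' Period-averaged drift field
#'
#' Averages the Eulerian velocity of a periodic flow solution over its
#' final forcing period at fixed positions: `u_D(x) = (1/T) int u_E dt`.
#' The oscillatory component cancels, leaving the steady streaming field
#' that drives solute advection.
#'
#' @param sol a `periodic_flow_solution` from [solve_flow()]
#' @return an object of class `drift_field` with `u` (axial, on u-faces),
#'   `v` (vertical, on v-faces), the membrane exchange mean `up`, and the
#'   originating domain
#' @export
compute_drift <- function(sol) {
  if (!inherits(sol, "periodic_flow_solution"))
    stop("`sol` must be a periodic_flow_solution", call. = FALSE)
  if (!isTRUE(sol$converged))
    stop("flow solution is not periodic; drift is undefined", call. = FALSE)
  structure(list(u = sol$u_mean, v = sol$v_mean, up = sol$up_mean,
                 domain = sol$domain, omega = sol$domain$omega,
                 peak_oscillatory_speed = sol$peak_oscillatory_speed),
            class = "drift_field")
}

#' @export
print.drift_field <- function(x, ...) {
  cat("<drift_field>\n")
  cat(sprintf("  peak |u_D| = %.3g m/s (peak oscillatory speed %.3g m/s)\n",
              max(abs(x$u)), x$peak_oscillatory_speed))
  invisible(x)
}

layer_rows_for <- function(dom, layer) {
  if (is.na(dom$fm)) {
    if (layer != "both")
      stop("single-layer domain has no '", layer, "' layer", call. = FALSE)
    return(seq_len(dom$ny))
  }
  switch(layer,
         scala = dom$layer_rows[[1L]],
         corti = dom$layer_rows[[2L]],
         both = seq_len(dom$ny))
}

#' Axial volume flux of the drift field through a cross-section
#'
#' Line integral of the axial drift velocity over the chosen layer height
#' at place `x`; positive toward the apex. For the closed two-layer domain
#' the flux over `"both"` layers vanishes at every section (mass
#' conservation), so opposite-signed `"corti"` and `"scala"` fluxes
#' measure the longitudinal circulation.
#'
#' @param drift a [compute_drift()] result
#' @param x_m place in meters, strictly inside the domain
#' @param layer `"corti"`, `"scala"`, or `"both"`
#' @return flux in m^2/s (per unit radial width)
#' @export
cross_section_flux <- function(drift, x_m, layer = c("both", "corti", "scala")) {
  stopifnot(inherits(drift, "drift_field"))
  layer <- match.arg(layer)
  dom <- drift$domain
  L <- dom$nx * dom$dx
  if (any(x_m <= 0 | x_m >= L)) stop("x_m outside (0, L)", call. = FALSE)
  rows <- layer_rows_for(dom, layer)
  vapply(x_m, function(x) {
    # interpolate u between the two nearest u-faces
    s <- x / dom$dx
    i0 <- floor(s) + 1L
    i0 <- min(max(i0, 1L), length(dom$x_u) - 1L)
    w <- (x - dom$x_u[i0]) / dom$dx
    ux <- (1 - w) * drift$u[i0, rows] + w * drift$u[i0 + 1L, rows]
    sum(ux * dom$row_dy[rows])
  }, numeric(1))
}

# bilinear interpolation on the staggered grids (clamped at edges)
interp_grid <- function(xs, ys, Z, x, y) {
  nxp <- length(xs); nyp <- length(ys)
  i <- findInterval(x, xs, all.inside = TRUE)
  j <- findInterval(y, ys, all.inside = TRUE)
  wx <- pmin(pmax((x - xs[i]) / (xs[i + 1L] - xs[i]), 0), 1)
  wy <- pmin(pmax((y - ys[j]) / (ys[j + 1L] - ys[j]), 0), 1)
  (1 - wx) * ((1 - wy) * Z[cbind(i, j)] + wy * Z[cbind(i, j + 1L)]) +
    wx * ((1 - wy) * Z[cbind(i + 1L, j)] + wy * Z[cbind(i + 1L, j + 1L)])
}

#' Trace passive particles through the time-periodic flow
#'
#' RK4 advection of tracers through the stored final-period velocity
#' snapshots (linear interpolation in time, bilinear in space). This is
#' the Lagrangian check on the Eulerian drift: the mean displacement per
#' period of an interior particle should agree in sign/direction with the
#' local period-averaged velocity.
#'
#' @param sol a `periodic_flow_solution`
#' @param seeds two-column matrix (x, y) of seed positions (m)
#' @param n_periods number of forcing periods to integrate
#' @param substeps RK4 steps per snapshot interval
#' @return data frame with final positions, mean drift velocity per
#'   particle, and an `exited` flag for trajectories that left the domain
#' @export
trace_particles <- function(sol, seeds, n_periods = 5L, substeps = 2L) {
  stopifnot(inherits(sol, "periodic_flow_solution"))
  seeds <- as.matrix(seeds)
  if (ncol(seeds) != 2L) stop("seeds must be a 2-column (x, y) matrix", call. = FALSE)
  dom <- sol$domain
  Tper <- sol$period_s
  L <- dom$nx * dom$dx; H <- sum(dom$row_dy) * 1  # total height via faces
  H <- dom$y_face[length(dom$y_face)]
  ts <- sol$snap_times
  nsn <- length(ts)
  # periodic extension: prepend last snapshot at t = ts[nsn] - T
  t_ext <- c(ts[nsn] - Tper, ts)
  u_ext <- c(sol$snap_u[nsn], sol$snap_u)
  v_ext <- c(sol$snap_v[nsn], sol$snap_v)
  vel <- function(x, y, t) {
    tm <- t %% Tper
    k <- findInterval(tm, t_ext, all.inside = TRUE)
    a <- (tm - t_ext[k]) / (t_ext[k + 1L] - t_ext[k])
    u1 <- interp_grid(dom$x_u, dom$y_p, u_ext[[k]], x, y)
    u2 <- interp_grid(dom$x_u, dom$y_p, u_ext[[k + 1L]], x, y)
    v1 <- interp_grid(dom$x_p, dom$y_face, v_ext[[k]], x, y)
    v2 <- interp_grid(dom$x_p, dom$y_face, v_ext[[k + 1L]], x, y)
    cbind((1 - a) * u1 + a * u2, (1 - a) * v1 + a * v2)
  }
  np <- nrow(seeds)
  pos <- seeds
  exited <- rep(FALSE, np)
  dt <- Tper / (nsn * substeps)
  nsteps <- as.integer(round(n_periods * Tper / dt))
  t <- 0
  for (s in seq_len(nsteps)) {
    act <- !exited
    if (!any(act)) break
    p <- pos[act, , drop = FALSE]
    k1 <- vel(p[, 1], p[, 2], t)
    k2 <- vel(p[, 1] + dt / 2 * k1[, 1], p[, 2] + dt / 2 * k1[, 2], t + dt / 2)
    k3 <- vel(p[, 1] + dt / 2 * k2[, 1], p[, 2] + dt / 2 * k2[, 2], t + dt / 2)
    k4 <- vel(p[, 1] + dt * k3[, 1], p[, 2] + dt * k3[, 2], t + dt)
    p <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out <- p[, 1] < 0 | p[, 1] > L | p[, 2] < 0 | p[, 2] > H
    if (dom$periodic_x) {
      p[, 1] <- p[, 1] %% L
      out <- p[, 2] < 0 | p[, 2] > H
    }
    pos[act, ] <- p
    exited[act][out] <- TRUE
    t <- t + dt
  }
  data.frame(x0 = seeds[, 1], y0 = seeds[, 2],
             x = pos[, 1], y = pos[, 2],
             mean_u = (pos[, 1] - seeds[, 1]) / (n_periods * Tper),
             mean_v = (pos[, 2] - seeds[, 2]) / (n_periods * Tper),
             exited = exited)
}
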