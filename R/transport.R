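#' Transport boundary conditions
#'
#' A constant-concentration source on the round-window patch of the basal
#' scala-tympani boundary; every other boundary is zero-flux. The default
#' source is 10 mM (10 mol/m^3) over the basal-most 0.2 mm of the outer
#' scala wall. `where = "basal_end"` instead applies the source on the
#' basal end face (used for 1D-reduced diffusion benchmarks).
#'
#' @param c_rw_mol_m3 source concentration (mol/m^3); 10 = 10 mM
#' @param patch_length_m axial extent of the source patch (m)
#' @param where `"bottom"` (outer scala wall) or `"basal_end"` (x = 0 face)
#' @param membrane_solute `"open"` lets solute cross the basilar membrane
#'   by diffusive contact plus the Darcy exchange flow; `"impermeable"`
#'   blocks it
#' @return an object of class `transport_bc`
#' @export
transport_bc <- function(c_rw_mol_m3 = 10, patch_length_m = 0.2e-3,
                         where = c("bottom", "basal_end"),
                         membrane_solute = c("open", "impermeable")) {
  check_positive(c_rw_mol_m3, "c_rw_mol_m3")
  check_positive(patch_length_m, "patch_length_m")
  structure(list(c_rw_mol_m3 = c_rw_mol_m3, patch_length_m = patch_length_m,
                 where = match.arg(where),
                 membrane_solute = match.arg(membrane_solute)),
            class = "transport_bc")
}

# grid-only flow domain from a geometry (no wall motion; used when solving
# pure diffusion without a flow stage)
transport_grid_from_geometry <- function(geom) {
  g <- geom$grid
  new_flow_domain(
    nx = g$nx, dx = geom$length_m / g$nx,
    layers = list(list(ny = g$ny_scala, dy = geom$scala_height_m / g$ny_scala),
                  list(ny = g$ny_corti, dy = geom$corti_height_m / g$ny_corti)),
    periodic_x = FALSE, omega = 2 * pi, fluid = fluid_props())
}

#' Solve advection-diffusion transport of a round-window solute
#'
#' Integrates `dC/dt = D lap(C) - u_D . grad(C)` (conservative
#' finite-volume form, first-order upwind advection) over the two-layer
#' domain, with a constant-concentration round-window source and zero-flux
#' walls. Time stepping starts at one stimulus period and grows
#' geometrically (an adaptive schedule); diffusion-only runs
#' use Crank-Nicolson with Rannacher start-up, advective runs implicit
#' Euler (monotone, bounds-preserving).
#'
#' @param domain a `drift_field` (transport through its streaming field),
#'   a `flow_domain`, or a [cochlear_geometry()] (pure diffusion)
#' @param drift optional `drift_field` when `domain` is not one
#' @param D_m2_s solute diffusion coefficient (m^2/s)
#' @param bc a [transport_bc()]
#' @param t_end_s final time (s)
#' @param output_times_s times at which concentration snapshots are kept
#'   (linearly interpolated between steps); defaults to 40 log-spaced times
#' @param dt0_s initial step (s); default one forcing period when a drift
#'   field is supplied, else 1e-3
#' @param growth geometric step-growth factor
#' @param dt_max_s step-size cap; default `t_end_s / 200`
#' @param theta time-integration weight; default 0.5 (Crank-Nicolson) for
#'   pure diffusion, 1 (implicit Euler) when advecting
#' @param C_init optional initial concentration: a scalar or an `nx x ny`
#'   matrix (default 0 everywhere)
#' @return an object of class `concentration_series`
#' @export
solve_transport <- function(domain, drift = NULL, D_m2_s = 1e-9,
                            bc = transport_bc(), t_end_s,
                            output_times_s = NULL, dt0_s = NULL,
                            growth = 1.3, dt_max_s = NULL, theta = NULL,
                            C_init = 0) {
  check_positive(D_m2_s, "D_m2_s")
  check_positive(t_end_s, "t_end_s")
  no_source <- is.null(bc)
  if (no_source) bc <- transport_bc()  # placeholder carrying defaults only
  if (inherits(domain, "drift_field")) { drift <- domain; dom <- drift$domain }
  else if (inherits(domain, "flow_domain")) dom <- domain
  else if (inherits(domain, "cochlear_geometry")) dom <- transport_grid_from_geometry(domain)
  else stop("domain must be a drift_field, flow_domain or cochlear_geometry",
            call. = FALSE)
  if (dom$periodic_x) stop("transport requires a closed domain", call. = FALSE)
  nx <- dom$nx; ny <- dom$ny; dx <- dom$dx
  row_dy <- dom$row_dy; fm <- dom$fm
  advective <- !is.null(drift) && (max(abs(drift$u)) + max(abs(drift$v))) > 0
  theta <- theta %||% (if (advective) 1 else 0.5)
  dt0 <- dt0_s %||% (if (!is.null(drift)) 2 * pi / drift$omega else 1e-3)
  dt_max <- dt_max_s %||% (t_end_s / 200)
  out_t <- sort(output_times_s %||% exp(seq(log(t_end_s / 100), log(t_end_s),
                                            length.out = 40)))
  out_t <- out_t[out_t <= t_end_s + 1e-12]

  U <- if (!is.null(drift)) drift$u else matrix(0, if (dom$periodic_x) nx else nx + 1L, ny)
  V <- if (!is.null(drift)) drift$v else matrix(0, nx, ny + 1L)
  if (!is.na(fm) && bc$membrane_solute == "impermeable") V[, fm] <- 0

  vol <- as.numeric(dx * matrix(row_dy, nx, ny, byrow = TRUE))
  idx <- function(i, j) i + (j - 1L) * nx

  # assemble dC/dt operator A (triplets) and Dirichlet source vector b
  ii <- jj <- integer(0); vv <- numeric(0)
  bvec <- numeric(nx * ny)
  src_g <- numeric(0); src_cells <- integer(0)   # source conductances
  add_face <- function(p, e, g, q) {
    # flux from cell p to cell e: g (Cp - Ce) + q+ Cp - q- Ce
    qp <- max(q, 0); qm <- max(-q, 0)
    ii <<- c(ii, p, p, e, e); jj <<- c(jj, p, e, p, e)
    vv <<- c(vv, -(g + qp) / vol[p], (g + qm) / vol[p],
             (g + qp) / vol[e], -(g + qm) / vol[e])
  }
  for (j in seq_len(ny)) {              # x faces (interior)
    area <- row_dy[j]
    for (i in seq_len(nx - 1L)) {
      uf <- U[i + 1L, j]
      add_face(idx(i, j), idx(i + 1L, j), D_m2_s * area / dx, uf * area)
    }
  }
  for (j in seq_len(ny - 1L)) {         # y faces
    f <- j + 1L
    open_mem <- is.na(fm) || f != fm || bc$membrane_solute == "open"
    if (!open_mem) next
    dist <- (row_dy[j] + row_dy[j + 1L]) / 2
    for (i in seq_len(nx)) {
      vf <- V[i, f]
      add_face(idx(i, j), idx(i, j + 1L), D_m2_s * dx / dist, vf * dx)
    }
  }
  # round-window Dirichlet source (skipped when bc was NULL)
  if (no_source) {
  } else if (bc$where == "bottom") {
    cells <- which(dom$x_p <= bc$patch_length_m)
    if (length(cells) == 0L)
      stop("source patch shorter than one grid cell", call. = FALSE)
    for (i in cells) {
      p <- idx(i, 1L)
      g <- D_m2_s * dx / (row_dy[1L] / 2)
      ii <- c(ii, p); jj <- c(jj, p); vv <- c(vv, -g / vol[p])
      bvec[p] <- bvec[p] + g * bc$c_rw_mol_m3 / vol[p]
      src_g <- c(src_g, g); src_cells <- c(src_cells, p)
    }
  } else {                              # basal end face, all rows
    for (j in seq_len(ny)) {
      p <- idx(1L, j)
      g <- D_m2_s * row_dy[j] / (dx / 2)
      ii <- c(ii, p); jj <- c(jj, p); vv <- c(vv, -g / vol[p])
      bvec[p] <- bvec[p] + g * bc$c_rw_mol_m3 / vol[p]
      src_g <- c(src_g, g); src_cells <- c(src_cells, p)
    }
  }
  n <- nx * ny
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))

  src_flux <- function(C) {
    if (length(src_cells) == 0L) 0
    else sum(src_g * (bc$c_rw_mol_m3 - C[src_cells]))
  }

  C <- if (is.matrix(C_init)) as.numeric(C_init) else rep(C_init, n)
  mass0 <- sum(C * vol)
  t <- 0; dt <- min(dt0, dt_max)
  fac <- NULL; fac_dt <- -1; fac_th <- -1
  snaps <- vector("list", length(out_t))
  names(snaps) <- format(out_t)
  oi <- 1L
  influx_int <- 0
  mass_rec <- data.frame(t_s = numeric(0), mass_mol = numeric(0),
                         influx_mol = numeric(0))
  n_startup <- if (theta < 1) 2L else 0L  # Rannacher start-up
  step_no <- 0L
  while (t < t_end_s - 1e-12 && oi <= length(out_t)) {
    step_no <- step_no + 1L
    th <- if (step_no <= n_startup) 1 else theta
    if (is.null(fac) || abs(dt - fac_dt) > 1e-14 * dt || th != fac_th) {
      M <- Matrix::Diagonal(n, 1 / dt) - th * A
      fac <- Matrix::lu(M); fac_dt <- dt; fac_th <- th
    }
    rhs <- C / dt + (1 - th) * as.numeric(A %*% C) + bvec
    Cn <- as.numeric(Matrix::solve(fac, rhs))
    influx_int <- influx_int + dt * (th * src_flux(Cn) + (1 - th) * src_flux(C))
    tn <- t + dt
    # record outputs by linear interpolation inside the step
    while (oi <= length(out_t) && out_t[oi] <= tn + 1e-12) {
      a <- if (tn > t) (out_t[oi] - t) / dt else 1
      Cs <- (1 - a) * C + a * Cn
      snaps[[oi]] <- matrix(Cs, nx, ny)
      mass_rec <- rbind(mass_rec,
                        data.frame(t_s = out_t[oi],
                                   mass_mol = sum(Cs * vol),
                                   influx_mol = mass0 + influx_int -
                                     dt * (1 - a) * (th * src_flux(Cn) + (1 - th) * src_flux(C))))
      oi <- oi + 1L
    }
    C <- Cn; t <- tn
    dt <- min(dt * growth, dt_max, max(t_end_s - t, 1e-12))
  }
  # bounds diagnostics
  over <- max(C) - bc$c_rw_mol_m3; under <- -min(C)
  if (max(over, under) > 1e-6 * bc$c_rw_mol_m3 && theta == 1)
    warning(sprintf("concentration bounds violated by %.3g", max(over, under)))
  structure(list(domain = dom, drift = drift, D_m2_s = D_m2_s, bc = bc,
                 times_s = out_t, C = snaps,
                 x_centers_m = dom$x_p, y_centers_m = dom$y_p,
                 mass_balance = mass_rec, theta = theta,
                 advective = advective), class = "concentration_series")
}

#' @export
print.concentration_series <- function(x, ...) {
  cat("<concentration_series>\n")
  cat(sprintf("  %d snapshots to t = %.4g s; D = %.3g m^2/s; %s\n",
              length(x$times_s), max(x$times_s), x$D_m2_s,
              if (x$advective) "advective" else "pure diffusion"))
  invisible(x)
}

#' One-dimensional diffusion from a constant source (closed form)
#'
#' Concentration at distance `x` and time `t` from a constant source `C0`
#' in a semi-infinite 1D domain: `C = C0 erfc(x / (2 sqrt(D t)))`. This is
#' the generative model of the silence-condition effect-time trend.
#'
#' @param x_m distance from the source (m), >= 0
#' @param t_s time (s), > 0
#' @param D_m2_s diffusion coefficient (m^2/s)
#' @param c0_mol_m3 source concentration
#' @return concentration in the same units as `c0_mol_m3`
#' @export
diffusion_1d_closed_form <- function(x_m, t_s, D_m2_s, c0_mol_m3 = 10) {
  if (any(t_s <= 0)) stop("t_s must be > 0", call. = FALSE)
  if (any(x_m < 0)) stop("x_m must be >= 0", call. = FALSE)
  check_positive(D_m2_s, "D_m2_s")
  c0_mol_m3 * erfc(x_m / (2 * sqrt(D_m2_s * t_s)))
}

#' Diffusion effect time (closed-form threshold inversion)
#'
#' Time for the 1D diffusion solution to first reach the fraction
#' `threshold_frac` of the source concentration at distance `x`:
#' `t = x^2 / (4 D z^2)` with `z = erfc^-1(threshold_frac)`.
#'
#' @inheritParams diffusion_1d_closed_form
#' @param threshold_frac threshold as a fraction of the source (default
#'   0.01, i.e. 100 uM for a 10 mM source)
#' @return time in seconds
#' @export
diffusion_effect_time <- function(x_m, D_m2_s, threshold_frac = 0.01) {
  check_positive(D_m2_s, "D_m2_s")
  if (any(threshold_frac <= 0 | threshold_frac >= 1))
    stop("threshold_frac must be in (0, 1)", call. = FALSE)
  x_m^2 / (4 * D_m2_s * erfc_inv(threshold_frac)^2)
}

#' Effect-time map from a concentration series
#'
#' First time each place reaches the threshold concentration (default 1%
#' of the round-window source, i.e. 100 uM for 10 mM) at the chosen
#' readout depth, by linear interpolation between stored snapshots.
#' Places that never cross within the simulated span are `NA` (unreached).
#'
#' @param series a [solve_transport()] result
#' @param threshold_mol_m3 threshold concentration; default
#'   `0.01 * c_rw`
#' @param readout `"corti_mid"` (mid-height of the Corti duct, where the
#'   inner hair cells sit), `"scala_mid"`, or a row index
#' @return an object of class `effect_time_profile`: data frame with
#'   `x_m`, `te_s`, and attribute `n_nonmonotone` counting places where
#'   the series dipped back below threshold after crossing
#' @export
effect_time_map <- function(series, threshold_mol_m3 = NULL,
                            readout = c("corti_mid", "scala_mid")) {
  stopifnot(inherits(series, "concentration_series"))
  thr <- threshold_mol_m3 %||% (0.01 * series$bc$c_rw_mol_m3)
  dom <- series$domain
  row <- if (is.numeric(readout)) as.integer(readout) else {
    readout <- match.arg(readout)
    if (readout == "corti_mid") {
      if (is.na(dom$fm)) stop("no Corti layer in this domain", call. = FALSE)
      rows <- dom$layer_rows[[2L]]
      rows[ceiling(length(rows) / 2)]
    } else {
      rows <- dom$layer_rows[[1L]]
      rows[ceiling(length(rows) / 2)]
    }
  }
  tt <- series$times_s
  nonmono <- 0L
  te <- vapply(seq_along(series$x_centers_m), function(i) {
    cc <- vapply(series$C, function(M) M[i, row], numeric(1))
    above <- cc >= thr
    if (!any(above)) return(NA_real_)
    k <- which(above)[1L]
    if (any(!above[seq_along(above) > k])) nonmono <<- nonmono + 1L
    if (k == 1L) {
      # already above at the first snapshot: interpolate from C = 0 at t = 0
      return(tt[1L] * thr / max(cc[1L], thr))
    }
    tt[k - 1L] + (tt[k] - tt[k - 1L]) * (thr - cc[k - 1L]) / (cc[k] - cc[k - 1L])
  }, numeric(1))
  out <- data.frame(x_m = series$x_centers_m, te_s = te)
  attr(out, "n_nonmonotone") <- nonmono
  attr(out, "threshold_mol_m3") <- thr
  attr(out, "readout_row") <- row
  class(out) <- c("effect_time_profile", "data.frame")
  out
}
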