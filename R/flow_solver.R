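# Incompressible Navier-Stokes on a MAC staggered grid with deforming-wall
# boundary transfer and a Darcy-permeable internal membrane.
#
# Scheme: incremental pressure-correction projection; Crank-Nicolson
# viscosity, Adams-Bashforth-2 advection; the membrane exchange velocity
# u_p = -K dp is taken implicitly in the pressure solve. Wall motion is
# imposed on the fixed mesh by boundary-velocity transfer; with
# `nonlinear = TRUE` the transfer includes the quadratic Taylor terms
# (u_wall = u_tan - eta du/dy, v_wall = eta_dot - eta dv/dy), which
# together with the advective term are the sources of steady streaming.
# All operators are assembled once per solve and Cholesky-factored.

wrap_idx <- function(i, n) ((i - 1L) %% n) + 1L

# 1D second-derivative operator in y over rows, Dirichlet walls at
# half-spacing at layer boundaries; returns matrix + closure weights.
build_dyy_rows <- function(row_dy, fm) {
  ny <- length(row_dy)
  ii <- jj <- integer(0); vv <- numeric(0)
  closures <- list()  # each: list(row, w, bc)
  diagv <- numeric(ny)
  bc_below <- function(j) {
    if (j == 1L) "bot" else if (!is.na(fm) && j == fm) "mem_up" else NA_character_
  }
  bc_above <- function(j) {
    if (j == ny) "top" else if (!is.na(fm) && j + 1L == fm) "mem_low" else NA_character_
  }
  for (j in seq_len(ny)) {
    dy <- row_dy[j]
    b <- bc_below(j); a <- bc_above(j)
    if (is.na(b)) {
      c1 <- 1 / ((row_dy[j - 1L] + dy) / 2 * dy)
      ii <- c(ii, j); jj <- c(jj, j - 1L); vv <- c(vv, c1)
      diagv[j] <- diagv[j] - c1
    } else {
      w <- 2 / dy^2
      closures[[length(closures) + 1L]] <- list(row = j, w = w, bc = b)
      diagv[j] <- diagv[j] - w
    }
    if (is.na(a)) {
      c1 <- 1 / ((row_dy[j + 1L] + dy) / 2 * dy)
      ii <- c(ii, j); jj <- c(jj, j + 1L); vv <- c(vv, c1)
      diagv[j] <- diagv[j] - c1
    } else {
      w <- 2 / dy^2
      closures[[length(closures) + 1L]] <- list(row = j, w = w, bc = a)
      diagv[j] <- diagv[j] - w
    }
  }
  D <- Matrix::sparseMatrix(i = c(ii, seq_len(ny)), j = c(jj, seq_len(ny)),
                            x = c(vv, diagv), dims = c(ny, ny))
  list(D = D, closures = closures)
}

# 1D second derivative over v faces (excluding walls and membrane)
build_dyy_vfaces <- function(row_dy, fm, fv) {
  ny <- length(row_dy)
  nfv <- length(fv)
  pos <- match(seq_len(ny + 1L), fv)  # face index -> unknown slot (NA if prescribed)
  ii <- jj <- integer(0); vv <- numeric(0)
  diagv <- numeric(nfv)
  closures <- list()
  for (s in seq_len(nfv)) {
    f <- fv[s]
    dyf <- (row_dy[f - 1L] + row_dy[f]) / 2
    for (nb in c(f - 1L, f + 1L)) {
      dyb <- row_dy[min(f, nb)]       # row between face f and nb
      co <- 1 / (dyb * dyf)
      if (!is.na(pos[nb])) {
        ii <- c(ii, s); jj <- c(jj, pos[nb]); vv <- c(vv, co)
      } else {
        bc <- if (nb == 1L) "vbot" else if (nb == ny + 1L) "vtop" else "vmem"
        closures[[length(closures) + 1L]] <- list(row = s, w = co, bc = bc)
      }
      diagv[s] <- diagv[s] - co
    }
  }
  D <- Matrix::sparseMatrix(i = c(ii, seq_len(nfv)), j = c(jj, seq_len(nfv)),
                            x = c(vv, diagv), dims = c(nfv, nfv))
  list(D = D, closures = closures)
}

build_dxx <- function(n, dx, periodic, half_space_walls = FALSE) {
  # half_space_walls: Dirichlet value at dx/2 beyond the first/last point
  # (used for v at closed side walls); otherwise Dirichlet at full spacing
  # beyond the range (u faces adjacent to fixed end faces).
  if (periodic) {
    ii <- rep(seq_len(n), 3L)
    jj <- c(wrap_idx(seq_len(n) - 1L, n), seq_len(n), wrap_idx(seq_len(n) + 1L, n))
    vv <- c(rep(1, n), rep(-2, n), rep(1, n)) / dx^2
    return(Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n)))
  }
  D <- Matrix::bandSparse(n, k = c(-1L, 0L, 1L),
                          diagonals = list(rep(1, n - 1L), rep(-2, n),
                                           rep(1, n - 1L))) / dx^2
  if (half_space_walls) {
    D[1L, 1L] <- -3 / dx^2
    D[n, n] <- -3 / dx^2
  }
  D
}

build_flow_operators <- function(dom, dt) {
  nu <- dom$fluid$nu_m2_s
  nx <- dom$nx; ny <- dom$ny; dx <- dom$dx
  row_dy <- dom$row_dy; fm <- dom$fm
  per <- dom$periodic_x
  u_cols <- if (per) seq_len(nx) else 2:nx      # unknown u-face columns
  nui <- length(u_cols)
  fv <- setdiff(2:ny, fm)                        # unknown v faces
  nfv <- length(fv)

  dxx_u <- build_dxx(nui, dx, per)
  dyy_u <- build_dyy_rows(row_dy, fm)
  L_u <- Matrix::kronecker(Matrix::Diagonal(ny), dxx_u) +
    Matrix::kronecker(dyy_u$D, Matrix::Diagonal(nui))
  A_u <- Matrix::Diagonal(nui * ny, 1 / dt) - (nu / 2) * L_u

  dxx_v <- build_dxx(nx, dx, per, half_space_walls = TRUE)
  dyy_v <- build_dyy_vfaces(row_dy, fm, fv)
  L_v <- Matrix::kronecker(Matrix::Diagonal(nfv), dxx_v) +
    Matrix::kronecker(dyy_v$D, Matrix::Diagonal(nx))
  A_v <- Matrix::Diagonal(nx * nfv, 1 / dt) - (nu / 2) * L_v

  # pressure Poisson (FV, volume-weighted, SPD) with Darcy coupling
  idx <- function(i, j) i + (j - 1L) * nx
  Krho <- dom$fluid$K_m_s_pa * dom$fluid$rho_kg_m3
  ii <- jj <- integer(0); vv <- numeric(0)
  add <- function(a, b, co) {
    ii <<- c(ii, a, b, a, b); jj <<- c(jj, a, b, b, a)
    vv <<- c(vv, co, co, -co, -co)
  }
  for (j in seq_len(ny)) {                       # x-direction faces
    co <- dt * row_dy[j] / dx
    i1 <- seq_len(nx - 1L)
    for (i in i1) add(idx(i, j), idx(i + 1L, j), co)
    if (per) add(idx(nx, j), idx(1L, j), co)
  }
  for (j in seq_len(ny - 1L)) {                  # y-direction faces
    f <- j + 1L
    co <- if (!is.na(fm) && f == fm) Krho * dx
          else dt * dx / ((row_dy[j] + row_dy[j + 1L]) / 2)
    for (i in seq_len(nx)) add(idx(i, j), idx(i, j + 1L), co)
  }
  A_p <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(nx * ny, nx * ny))
  A_p_red <- A_p[-1L, -1L]

  list(u_cols = u_cols, nui = nui, fv = fv, nfv = nfv,
       L_u = L_u, L_v = L_v,
       ch_u = Matrix::Cholesky(Matrix::forceSymmetric(A_u), perm = TRUE),
       ch_v = Matrix::Cholesky(Matrix::forceSymmetric(A_v), perm = TRUE),
       ch_p = Matrix::Cholesky(Matrix::forceSymmetric(A_p_red), perm = TRUE),
       clo_u = dyy_u$closures, clo_v = dyy_v$closures,
       Krho = Krho, dt = dt)
}

# closure contribution of tangential-wall Dirichlet values to (nu/2)*Lap(u)
closure_u <- function(ops, ny, bc) {
  M <- matrix(0, ops$nui, ny)
  for (cl in ops$clo_u) {
    val <- switch(cl$bc, bot = bc$u_bot, top = bc$u_top,
                  mem_low = bc$u_mem_low, mem_up = bc$u_mem_up)
    M[, cl$row] <- M[, cl$row] + cl$w * val
  }
  M
}

closure_v <- function(ops, nx, bc) {
  M <- matrix(0, nx, ops$nfv)
  for (cl in ops$clo_v) {
    val <- switch(cl$bc, vbot = bc$v_bot, vtop = bc$v_top, vmem = bc$v_mem)
    M[, cl$row] <- M[, cl$row] + cl$w * val
  }
  M
}

# advection terms (divergence form) at interior u and v faces
flow_advection <- function(dom, ops, U, V, bc) {
  nx <- dom$nx; ny <- dom$ny; dx <- dom$dx; per <- dom$periodic_x
  row_dy <- dom$row_dy; fm <- dom$fm
  nux <- nrow(U)
  # cell-center u and uu
  uc <- if (per) 0.5 * (U + U[wrap_idx(seq_len(nx) + 1L, nx), , drop = FALSE])
        else 0.5 * (U[seq_len(nx), , drop = FALSE] + U[2:(nx + 1L), , drop = FALSE])
  uu <- uc * uc
  # corner arrays (u-face x positions x y faces)
  ubar <- matrix(0, nux, ny + 1L)
  for (f in 2:ny) {
    if (!is.na(fm) && f == fm) { ubar[, f] <- bc$u_mem_full } else {
      ubar[, f] <- 0.5 * (U[, f - 1L] + U[, f])
    }
  }
  ubar[, 1L] <- bc$u_bot_full
  ubar[, ny + 1L] <- bc$u_top_full
  vbar <- matrix(0, nux, ny + 1L)
  if (per) {
    vbar <- 0.5 * (V[wrap_idx(seq_len(nx) - 1L, nx), , drop = FALSE] + V)
  } else {
    vbar[2:nx, ] <- 0.5 * (V[1:(nx - 1L), , drop = FALSE] + V[2:nx, , drop = FALSE])
    # side walls: no-slip, corner uv = 0
  }
  uv <- ubar * vbar
  # adv_u at interior u faces
  ui <- ops$u_cols
  if (per) {
    duu <- (uu[ui, , drop = FALSE] - uu[wrap_idx(ui - 1L, nx), , drop = FALSE]) / dx
  } else {
    duu <- (uu[ui, , drop = FALSE] - uu[ui - 1L, , drop = FALSE]) / dx
  }
  duv <- (uv[ui, 2:(ny + 1L), drop = FALSE] - uv[ui, 1:ny, drop = FALSE]) /
    matrix(row_dy, length(ui), ny, byrow = TRUE)
  adv_u <- duu + duv
  # adv_v at interior v faces
  fvv <- ops$fv
  vc <- 0.5 * (V[, 1:ny, drop = FALSE] + V[, 2:(ny + 1L), drop = FALSE])  # centers
  vv2 <- vc * vc
  dyf <- (row_dy[fvv - 1L] + row_dy[fvv]) / 2
  dvv <- (vv2[, fvv, drop = FALSE] - vv2[, fvv - 1L, drop = FALSE]) /
    matrix(dyf, nx, length(fvv), byrow = TRUE)
  if (per) {
    duvx <- (uv[wrap_idx(seq_len(nx) + 1L, nx), fvv, drop = FALSE] -
               uv[seq_len(nx), fvv, drop = FALSE]) / dx
  } else {
    duvx <- (uv[2:(nx + 1L), fvv, drop = FALSE] - uv[1:nx, fvv, drop = FALSE]) / dx
  }
  list(adv_u = adv_u, adv_v = dvv + duvx)
}

# boundary values at time t, including lagged Taylor transfer terms
flow_bc_values <- function(dom, ops, t, state, nonlinear) {
  w <- dom$omega
  et <- exp(1i * w * t)
  nx <- dom$nx; ny <- dom$ny; fm <- dom$fm
  row_dy <- dom$row_dy
  xi <- dom$x_u[ops$u_cols]; xu <- dom$x_u; xp <- dom$x_p
  U <- state$U; V <- state$V
  re <- function(z) Re(z * et)
  vdot <- function(hat) Re(1i * w * hat * et)

  v_bot <- vdot(dom$eta_bot_hat(xp))
  v_top <- vdot(dom$eta_top_hat(xp))
  v_mem_wall <- if (!is.na(fm)) vdot(dom$eta_mem_hat(xp)) else NULL
  u_bot_full <- re(dom$u_bot_hat(xu))
  u_top_full <- re(dom$u_top_hat(xu))
  u_mem_full <- if (!is.na(fm)) numeric(length(xu)) else NULL

  if (nonlinear) {
    eb_u <- Re(dom$eta_bot_hat(xu) * et)
    et_u <- Re(dom$eta_top_hat(xu) * et)
    dy1 <- row_dy[1L]; dyn <- row_dy[ny]
    # one-sided wall-normal gradients, lagged one step
    dudy_bot <- (U[, 1L] - state$bc_prev$u_bot_full) / (dy1 / 2)
    dudy_top <- (state$bc_prev$u_top_full - U[, ny]) / (dyn / 2)
    u_bot_full <- u_bot_full - eb_u * dudy_bot
    u_top_full <- u_top_full - et_u * dudy_top
    # note: only the tangential transfer term is applied. The normal-component
    # quadratic term eta * dv/dy has a nonzero period mean which, on a fixed
    # mesh, acts as a steady mass source through the wall; its physical
    # content (the boundary's Stokes-drift flux) cancels in the material
    # flux, so it is omitted to keep the mean flow mass-consistent.
    if (!is.na(fm)) {
      em_u <- Re(dom$eta_mem_hat(xu) * et)
      dylo <- row_dy[fm - 1L]; dyhi <- row_dy[fm]
      dudy_mem_lo <- (state$bc_prev$u_mem_low_full - U[, fm - 1L]) / (dylo / 2)
      dudy_mem_hi <- (U[, fm] - state$bc_prev$u_mem_up_full) / (dyhi / 2)
      u_mem_low_full <- -em_u * dudy_mem_lo
      u_mem_up_full <- -em_u * dudy_mem_hi
      u_mem_full <- 0.5 * (u_mem_low_full + u_mem_up_full)
    }
  } else if (!is.na(fm)) {
    u_mem_low_full <- u_mem_up_full <- u_mem_full <- numeric(length(xu))
  }
  if (is.na(fm)) u_mem_low_full <- u_mem_up_full <- NULL

  list(u_bot = u_bot_full[ops$u_cols], u_top = u_top_full[ops$u_cols],
       u_mem_low = if (!is.na(fm)) u_mem_low_full[ops$u_cols],
       u_mem_up = if (!is.na(fm)) u_mem_up_full[ops$u_cols],
       u_bot_full = u_bot_full, u_top_full = u_top_full,
       u_mem_low_full = u_mem_low_full, u_mem_up_full = u_mem_up_full,
       u_mem_full = if (!is.na(fm)) u_mem_full,
       v_bot = v_bot, v_top = v_top, v_mem_wall = v_mem_wall)
}

#' Solve the oscillatory flow on a flow domain to a periodic steady state
#'
#' Integrates the incompressible Navier-Stokes equations from rest under
#' monochromatic wall forcing until the velocity field repeats from one
#' forcing period to the next within `periodicity_tol`, then returns the
#' final period (snapshots, period-averaged fields, membrane exchange
#' velocity and diagnostics).
#'
#' @param dom a `flow_domain` (from [cochlear_flow_domain()] or
#'   [channel_domain()])
#' @param num a [flow_numerics()]
#' @return an object of class `periodic_flow_solution`
#' @export
solve_flow <- function(dom, num = flow_numerics()) {
  stopifnot(inherits(dom, "flow_domain"))
  w <- dom$omega
  Tper <- 2 * pi / w
  nu <- dom$fluid$nu_m2_s
  dt0 <- num$dt_s %||% (Tper / 100)
  spp <- max(16L, as.integer(round(Tper / dt0)))
  dt <- Tper / spp
  # resolution check: Stokes layer must be resolved before integrating
  delta <- sqrt(nu / w)
  if (delta / max(dom$row_dy) < num$min_stokes_cells)
    stop(sprintf(paste0("grid does not resolve the Stokes layer: ",
                        "delta = %.3g m needs dy <= %.3g m (>= %g cells), ",
                        "coarsest dy = %.3g m"),
                 delta, delta / num$min_stokes_cells, num$min_stokes_cells,
                 max(dom$row_dy)), call. = FALSE)
  # advective CFL pre-check from the wall forcing amplitude
  umax_bc <- max(abs(1i * w * dom$eta_bot_hat(dom$x_p)),
                 abs(1i * w * dom$eta_top_hat(dom$x_p)),
                 if (!is.na(dom$fm)) abs(1i * w * dom$eta_mem_hat(dom$x_p)) else 0,
                 abs(dom$u_bot_hat(dom$x_u)), abs(dom$u_top_hat(dom$x_u)), 0)
  if (umax_bc * dt / min(dom$dx, dom$row_dy) > 0.9)
    stop("advective CFL violated by wall forcing; reduce dt_s", call. = FALSE)

  ops <- build_flow_operators(dom, dt)
  nx <- dom$nx; ny <- dom$ny; fm <- dom$fm
  nux <- if (dom$periodic_x) nx else nx + 1L
  row_dy <- dom$row_dy
  dyf_all <- (row_dy[-ny] + row_dy[-1L]) / 2   # spacing at interior faces 2..ny
  vol <- dom$dx * matrix(row_dy, nx, ny, byrow = TRUE)

  U <- matrix(0, nux, ny); V <- matrix(0, nx, ny + 1L); P <- matrix(0, nx, ny)
  zero_bc <- flow_bc_values(dom, ops,
                            t = 0,
                            state = list(U = U, V = V,
                                         bc_prev = list(u_bot_full = numeric(nux),
                                                        u_top_full = numeric(nux),
                                                        u_mem_low_full = numeric(nux),
                                                        u_mem_up_full = numeric(nux))),
                            nonlinear = FALSE)
  bc_n <- zero_bc
  adv_prev <- NULL
  snap_steps <- unique(as.integer(round(seq_len(num$n_snapshots) * spp / num$n_snapshots)))
  n_snap <- length(snap_steps)
  snap_u <- vector("list", n_snap); snap_v <- vector("list", n_snap)
  snap_up <- vector("list", n_snap)
  residuals <- numeric(0)
  U_prev_end <- U; V_prev_end <- V
  converged <- FALSE
  peak_speed <- 0

  ui <- ops$u_cols; fvv <- ops$fv
  t <- 0
  for (p in seq_len(num$max_periods)) {
    Usum <- matrix(0, nux, ny); Vsum <- matrix(0, nx, ny + 1L)
    UPsum <- if (!is.na(fm)) numeric(nx)
    si <- 0L
    for (s in seq_len(spp)) {
      tn1 <- t + dt
      state <- list(U = U, V = V, bc_prev = bc_n)
      bc_n1 <- flow_bc_values(dom, ops, tn1, state, num$nonlinear)
      # membrane star value: wall velocity + Darcy exchange from current P
      if (!is.na(fm)) {
        dP_n <- P[, fm] - P[, fm - 1L]
        v_mem_star <- bc_n1$v_mem_wall - ops$Krho * dP_n
        bc_n1$v_mem <- v_mem_star
        bc_n$v_mem <- V[, fm]
      }
      # advection (AB2)
      if (num$nonlinear) {
        adv <- flow_advection(dom, ops, U, V, bc_n)
        adv_u <- if (is.null(adv_prev)) adv$adv_u
                 else 1.5 * adv$adv_u - 0.5 * adv_prev$adv_u
        adv_v <- if (is.null(adv_prev)) adv$adv_v
                 else 1.5 * adv$adv_v - 0.5 * adv_prev$adv_v
        adv_prev <- adv
      } else adv_u <- adv_v <- 0
      # u predictor
      Uint <- U[ui, , drop = FALSE]
      lap_n_u <- matrix(as.numeric(ops$L_u %*% as.numeric(Uint)), ops$nui, ny) +
        closure_u(ops, ny, bc_n)
      if (dom$periodic_x) {
        gpx <- (P[ui, , drop = FALSE] -
                  P[wrap_idx(ui - 1L, nx), , drop = FALSE]) / dom$dx
      } else {
        gpx <- (P[ui, , drop = FALSE] - P[ui - 1L, , drop = FALSE]) / dom$dx
      }
      rhs_u <- Uint / dt - adv_u - gpx + (nu / 2) * lap_n_u +
        (nu / 2) * closure_u(ops, ny, bc_n1)
      Ustar_int <- matrix(as.numeric(Matrix::solve(ops$ch_u, as.numeric(rhs_u))),
                          ops$nui, ny)
      # v predictor
      Vint <- V[, fvv, drop = FALSE]
      lap_n_v <- matrix(as.numeric(ops$L_v %*% as.numeric(Vint)), nx, ops$nfv) +
        closure_v(ops, nx, bc_n)
      dyf <- matrix((row_dy[fvv - 1L] + row_dy[fvv]) / 2, nx, ops$nfv, byrow = TRUE)
      gpy <- (P[, fvv, drop = FALSE] - P[, fvv - 1L, drop = FALSE]) / dyf
      rhs_v <- Vint / dt - adv_v - gpy + (nu / 2) * lap_n_v +
        (nu / 2) * closure_v(ops, nx, bc_n1)
      Vstar_int <- matrix(as.numeric(Matrix::solve(ops$ch_v, as.numeric(rhs_v))),
                          nx, ops$nfv)
      # assemble starred fields with boundary values at t(n+1)
      Ustar <- matrix(0, nux, ny); Ustar[ui, ] <- Ustar_int
      Vstar <- matrix(0, nx, ny + 1L)
      Vstar[, fvv] <- Vstar_int
      Vstar[, 1L] <- bc_n1$v_bot
      Vstar[, ny + 1L] <- bc_n1$v_top
      if (!is.na(fm)) Vstar[, fm] <- v_mem_star
      # divergence and compatibility correction
      if (dom$periodic_x) {
        du <- (Ustar[wrap_idx(seq_len(nx) + 1L, nx), , drop = FALSE] - Ustar) / dom$dx
      } else {
        du <- (Ustar[2:(nx + 1L), , drop = FALSE] - Ustar[1:nx, , drop = FALSE]) / dom$dx
      }
      dv <- (Vstar[, 2:(ny + 1L), drop = FALSE] - Vstar[, 1:ny, drop = FALSE]) /
        matrix(row_dy, nx, ny, byrow = TRUE)
      divs <- du + dv
      divs <- divs - sum(divs * vol) / sum(vol)
      b <- -as.numeric(divs * vol)
      phi <- numeric(nx * ny)
      phi[-1L] <- as.numeric(Matrix::solve(ops$ch_p, b[-1L]))
      Phi <- matrix(phi, nx, ny)
      # correct
      if (dom$periodic_x) {
        gphix <- (Phi[ui, , drop = FALSE] -
                    Phi[wrap_idx(ui - 1L, nx), , drop = FALSE]) / dom$dx
      } else {
        gphix <- (Phi[ui, , drop = FALSE] - Phi[ui - 1L, , drop = FALSE]) / dom$dx
      }
      U <- Ustar; U[ui, ] <- Ustar_int - dt * gphix
      gphiy <- (Phi[, fvv, drop = FALSE] - Phi[, fvv - 1L, drop = FALSE]) / dyf
      V <- Vstar; V[, fvv] <- Vstar_int - dt * gphiy
      if (!is.na(fm)) V[, fm] <- v_mem_star - ops$Krho * (Phi[, fm] - Phi[, fm - 1L])
      P <- P + Phi
      bc_n <- bc_n1
      t <- tn1
      Usum <- Usum + U; Vsum <- Vsum + V
      if (!is.na(fm)) UPsum <- UPsum + (V[, fm] - bc_n1$v_mem_wall)
      if (s %in% snap_steps) {
        si <- si + 1L
        snap_u[[si]] <- U; snap_v[[si]] <- V
        if (!is.na(fm)) snap_up[[si]] <- V[, fm] - bc_n1$v_mem_wall
      }
    }
    speed <- sqrt(max(U^2) + max(V^2))
    peak_speed <- max(peak_speed, speed)
    nrm <- sqrt(sum(U^2) + sum(V^2))
    res <- sqrt(sum((U - U_prev_end)^2) + sum((V - V_prev_end)^2)) /
      max(nrm, .Machine$double.eps)
    residuals <- c(residuals, res)
    U_prev_end <- U; V_prev_end <- V
    if (p >= num$min_periods && res < num$periodicity_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop(errorCondition(
      sprintf("flow did not reach a periodic steady state in %d periods (last residual %.3g)",
              num$max_periods, utils::tail(residuals, 1)),
      residuals = residuals, class = c("cochstream_flow_error", "error")))

  structure(list(
    domain = dom, numerics = num, dt = dt, steps_per_period = spp,
    period_s = Tper,
    snap_times = snap_steps * dt, snap_u = snap_u, snap_v = snap_v,
    snap_up = if (!is.na(fm)) snap_up,
    u_mean = Usum / spp, v_mean = Vsum / spp,
    up_mean = if (!is.na(fm)) UPsum / spp,
    pressure_pa = P * dom$fluid$rho_kg_m3,
    peak_oscillatory_speed = peak_speed,
    residuals = residuals, n_periods = length(residuals),
    converged = converged), class = "periodic_flow_solution")
}

#' @export
print.periodic_flow_solution <- function(x, ...) {
  cat("<periodic_flow_solution>\n")
  cat(sprintf("  %d x %d grid, %d periods to periodicity (residual %.2g)\n",
              x$domain$nx, x$domain$ny, x$n_periods, utils::tail(x$residuals, 1)))
  cat(sprintf("  peak oscillatory speed %.3g m/s\n", x$peak_oscillatory_speed))
  invisible(x)
}

#' Solve the cochlear two-layer oscillatory flow
#'
#' Convenience wrapper: builds the two-layer domain from geometry + wave
#' and runs [solve_flow()].
#'
#' @inheritParams cochlear_flow_domain
#' @param num a [flow_numerics()]
#' @return a `periodic_flow_solution`
#' @export
solve_oscillatory_flow <- function(geom, wave, fluid = fluid_props(),
                                   num = flow_numerics()) {
  solve_flow(cochlear_flow_domain(geom, wave, fluid), num)
}
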