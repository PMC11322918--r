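# Advection-diffusion transport of the morphogen proxy across the chamber.
#
# Equation (depth-averaged, porosity phi, Darcy flux v):
#   phi dc/dt + v . grad c = phi D lap c
# i.e. dc/dt + (v/phi) . grad c = D lap c with the seepage velocity v/phi.
# Dirichlet concentrations are held on the two fluidic-line interfaces
# (source_concentration on the dosed/top line, 0 on the plain/bottom line);
# chamber end walls are no-flux. Discretization: finite volume, explicit
# first-order upwind advection + implicit (backward Euler) diffusion; the
# step is auto-capped at 0.4x the explicit advective CFL bound.

#' Solve morphogen transport over the solved flow field
#'
#' @param flow A `flow_field` from [solve_darcy()] (may carry zero velocity
#'   for the pure-diffusion gradient experiment).
#' @param params A [transport_params()].
#' @param times Output times (s), strictly increasing, starting at >= 0.
#'   Defaults to 25 snapshots spanning `total_time`.
#' @param initial Initial concentration: a scalar or an `nx x ny` matrix.
#' @return A `concentration_field`: array `concentration` (`nx x ny x
#'   n_times`), `times`, boundary values and grid metadata.
#' @examples
#' geom <- device_preset("aligned", grid_spacing = 25e-6)
#' flow <- solve_darcy(geom, porous_medium(), pressure_boundary(0, 0))
#' conc <- solve_transport(flow, transport_params(total_time = 3600))
#' @export
solve_transport <- function(flow, params = transport_params(),
                            times = NULL, initial = 0) {
  stopifnot(inherits(flow, "flow_field"), inherits(params, "transport_params"))
  geom <- flow$geom
  h <- flow$grid_spacing
  nx <- flow$nx; ny <- flow$ny
  phi <- flow$props$porosity
  D <- params$diffusivity
  c_top <- params$source_concentration
  c_bot <- 0

  if (is.null(times)) {
    times <- seq(0, params$total_time, length.out = 25L)
  }
  if (is.unsorted(times, strictly = TRUE) || times[1] < 0) {
    stop_fm("`times` must be strictly increasing and non-negative")
  }

  # Seepage velocities on faces.
  uf <- flow$u_face / phi
  vf <- flow$v_face / phi

  # Advective CFL bound for the explicit upwind step.
  vmax <- max(abs(uf), abs(vf))
  dt_cfl <- if (vmax > 0) h / vmax else Inf
  if (params$time_step > dt_cfl) {
    stop_fm(sprintf(
      "unstable time step: %.4g s exceeds the explicit advective CFL bound %.4g s",
      params$time_step, dt_cfl
    ))
  }
  dt_max <- min(params$time_step, 0.4 * dt_cfl)

  C <- if (is.matrix(initial)) {
    stopifnot(all(dim(initial) == c(nx, ny)))
    initial
  } else {
    matrix(initial, nx, ny)
  }

  out <- array(NA_real_, dim = c(nx, ny, length(times)))
  t_now <- 0
  k_out <- 1L
  if (times[1] == 0) {
    out[, , 1L] <- C
    k_out <- 2L
  }

  # Implicit diffusion operator (I + dt D L); factor once per step size.
  lap <- transport_diffusion_operator(nx, ny, h)
  fact_dt <- NA_real_
  fact <- NULL
  bnd_idx_bot <- seq_len(nx)                      # (i, j = 1)
  bnd_idx_top <- (ny - 1L) * nx + seq_len(nx)     # (i, j = ny)

  while (k_out <= length(times)) {
    t_target <- times[k_out]
    while (t_now < t_target - 1e-12) {
      dt <- min(dt_max, t_target - t_now)
      # -- explicit upwind advection ------------------------------------
      if (vmax > 0) {
        C <- C + dt * upwind_advection(C, uf, vf, h, c_bot, c_top)
      }
      # -- implicit diffusion (backward Euler) --------------------------
      if (!identical(dt, fact_dt)) {
        A <- Matrix::Diagonal(nx * ny) + dt * D * lap
        fact <- Matrix::Cholesky(Matrix::forceSymmetric(A))
        fact_dt <- dt
      }
      rhs <- as.vector(C)
      # Dirichlet lines enter through the half-cell ghost flux 2D/h^2 * c_line
      rhs[bnd_idx_bot] <- rhs[bnd_idx_bot] + dt * D * 2 / h^2 * c_bot
      rhs[bnd_idx_top] <- rhs[bnd_idx_top] + dt * D * 2 / h^2 * c_top
      C <- matrix(as.numeric(Matrix::solve(fact, rhs)), nx, ny)
      t_now <- t_now + dt
    }
    out[, , k_out] <- C
    k_out <- k_out + 1L
  }

  structure(
    list(
      concentration = out, times = times,
      c_top = c_top, c_bot = c_bot,
      grid_spacing = h, nx = nx, ny = ny,
      geom = geom, params = params, flow = flow
    ),
    class = "concentration_field"
  )
}

# Upwind advective tendency dc/dt (1/s) from seepage face velocities.
upwind_advection <- function(C, uf, vf, h, c_bot, c_top) {
  nx <- nrow(C); ny <- ncol(C)
  # x faces: uf is (nx+1) x ny, walls already zero.
  cu_x <- matrix(0, nx + 1L, ny)
  inner <- 2:nx
  up_pos <- uf[inner, , drop = FALSE] >= 0
  c_w <- C[inner - 1L, , drop = FALSE]; c_e <- C[inner, , drop = FALSE]
  cu_x[inner, ] <- ifelse(up_pos, c_w, c_e)
  Fx <- uf * cu_x
  # y faces: vf is nx x (ny+1); boundary inflow carries the line value.
  cu_y <- matrix(0, nx, ny + 1L)
  if (ny > 1L) {
    innj <- 2:ny
    vp <- vf[, innj, drop = FALSE] >= 0
    c_s <- C[, innj - 1L, drop = FALSE]; c_n <- C[, innj, drop = FALSE]
    cu_y[, innj] <- ifelse(vp, c_s, c_n)
  }
  cu_y[, 1L] <- ifelse(vf[, 1L] >= 0, c_bot, C[, 1L])
  cu_y[, ny + 1L] <- ifelse(vf[, ny + 1L] >= 0, C[, ny], c_top)
  Fy <- vf * cu_y
  -((Fx[2:(nx + 1L), , drop = FALSE] - Fx[seq_len(nx), , drop = FALSE]) / h +
      (Fy[, 2:(ny + 1L), drop = FALSE] - Fy[, seq_len(ny), drop = FALSE]) / h)
}

# Sparse diffusion operator L so that lap c = -L c (dimensionless / h^2),
# with Dirichlet half-cell coupling at the two line interfaces and no-flux
# at the x walls. Returns L (positive semi-definite).
transport_diffusion_operator <- function(nx, ny, h) {
  n <- nx * ny
  idx <- function(i, j) (j - 1L) * nx + i
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  diag_acc <- numeric(n)
  w <- 1 / h^2
  add_pair <- function(a, b, val) {
    ii <<- c(ii, a, b); jj <<- c(jj, b, a); vv <<- c(vv, rep(-val, 2 * length(a)))
    diag_acc[a] <<- diag_acc[a] + val
    diag_acc[b] <<- diag_acc[b] + val
  }
  if (nx > 1L) {
    for (i in seq_len(nx - 1L)) {
      add_pair(idx(i, seq_len(ny)), idx(i + 1L, seq_len(ny)), w)
    }
  }
  if (ny > 1L) {
    for (j in seq_len(ny - 1L)) {
      add_pair(idx(seq_len(nx), j), idx(seq_len(nx), j + 1L), w)
    }
  }
  # Dirichlet lines: ghost value at distance h/2 -> conductance 2/h^2.
  diag_acc[idx(seq_len(nx), 1L)] <- diag_acc[idx(seq_len(nx), 1L)] + 2 * w
  diag_acc[idx(seq_len(nx), ny)] <- diag_acc[idx(seq_len(nx), ny)] + 2 * w
  Matrix::sparseMatrix(
    i = c(ii, seq_len(n)), j = c(jj, seq_len(n)), x = c(vv, diag_acc),
    dims = c(n, n)
  )
}

#' Transient diffusion profile between two held concentrations (series oracle)
#'
#' Closed-form eigenfunction-series solution of 1-D diffusion across a slab
#' of width `L` with `c(0) = 0`, `c(L) = c_top` and `c(y, 0) = 0`:
#' `c(y,t) = c_top * ( y/L + sum_n 2 (-1)^n / (n pi) sin(n pi y / L)
#' exp(-n^2 pi^2 D t / L^2) )`. Used as the independent oracle for the
#' transport solver and for the gradient-formation criterion.
#'
#' @param y Positions across the slab (m), 0 at the plain line.
#' @param t Time (s), scalar.
#' @param L Slab width (m).
#' @param D Diffusivity (m^2/s).
#' @param c_top Held concentration at `y = L`.
#' @param n_terms Number of series terms.
#' @return Concentrations at `y`.
#' @export
diffusion_series_profile <- function(y, t, L, D, c_top = 1, n_terms = 200L) {
  steady <- y / L
  if (t <= 0) {
    return(c_top * (steady * 0))
  }
  acc <- steady
  for (n in seq_len(n_terms)) {
    decay <- exp(-n^2 * pi^2 * D * t / L^2)
    if (decay < 1e-16) break
    acc <- acc + 2 * (-1)^n / (n * pi) * sin(n * pi * y / L) * decay
  }
  c_top * acc
}

#' Gradient profile, formation time, and 24 h maintenance
#'
#' The cross-chamber profile is the concentration averaged along the chamber
#' length at each output time. The gradient counts as "formed" at the first
#' output time at which the profile is everywhere within `tolerance` (as a
#' fraction of the boundary concentration difference) of the steady profile;
#' it is "maintained" through `maintain_hours` if it stays within tolerance
#' from formation to that horizon.
#'
#' @param conc A `concentration_field`.
#' @param tolerance Fraction of the boundary difference (default 0.1).
#' @param maintain_hours Maintenance horizon in hours (default 24).
#' @return A list: `profile` (tibble: time, y, concentration, deviation),
#'   `steady_profile` (tibble y, concentration), `formation_time` (s; `NA`
#'   if never reached in the simulated window), `maintained` (logical, `NA`
#'   if the stack does not span the horizon), `degenerate_zero_gradient`.
#' @export
gradient_metrics <- function(conc, tolerance = 0.1, maintain_hours = 24) {
  stopifnot(inherits(conc, "concentration_field"))
  check_number(tolerance, "tolerance", 0, strict = TRUE)
  ny <- conc$ny
  y <- (seq_len(ny) - 0.5) * conc$grid_spacing
  prof <- t(apply(conc$concentration, 3L, colMeans)) # n_times x ny
  if (is.null(dim(prof))) prof <- matrix(prof, nrow = length(conc$times))

  steady <- steady_profile(conc)
  scale <- abs(conc$c_top - conc$c_bot)
  degenerate <- scale < .Machine$double.eps
  denom <- if (degenerate) 1 else scale

  dev <- abs(sweep(prof, 2L, steady)) / denom
  within <- apply(dev, 1L, max) <= tolerance
  formation_time <- if (any(within)) conc$times[which(within)[1]] else NA_real_

  horizon <- maintain_hours * 3600
  maintained <- if (max(conc$times) + 1e-9 < horizon) {
    NA
  } else if (is.na(formation_time)) {
    FALSE
  } else {
    keep <- conc$times >= formation_time & conc$times <= horizon
    all(within[keep])
  }

  profile_tbl <- tibble(
    time = rep(conc$times, each = ny),
    y = rep(y, times = length(conc$times)),
    concentration = as.vector(t(prof)),
    deviation_from_steady = as.vector(t(dev))
  )
  list(
    profile = profile_tbl,
    steady_profile = tibble(y = y, concentration = steady),
    formation_time = formation_time,
    maintained = maintained,
    degenerate_zero_gradient = degenerate,
    tolerance = tolerance
  )
}

# Steady cross-chamber profile for the (possibly advective) transport
# problem: solves the steady 1-D advection-diffusion equation with the mean
# cross-velocity; reduces to the linear profile at zero flow.
steady_profile <- function(conc) {
  ny <- conc$ny
  h <- conc$grid_spacing
  W <- ny * h
  y <- (seq_len(ny) - 0.5) * h
  phi <- conc$flow$props$porosity
  v_mean <- mean(conc$flow$v_face) / phi
  D <- conc$params$diffusivity
  pe <- v_mean * W / D
  if (abs(pe) < 1e-10) {
    conc$c_bot + (conc$c_top - conc$c_bot) * y / W
  } else {
    conc$c_bot + (conc$c_top - conc$c_bot) *
      (exp(pe * y / W) - 1) / (exp(pe) - 1)
  }
}

#' @export
print.concentration_field <- function(x, ...) {
  cat("<concentration_field>", x$nx, "x", x$ny, "cells,",
      length(x$times), "snapshots\n")
  cat(sprintf("  t in [%.4g, %.4g] s; c in [%.4g, %.4g]\n",
              min(x$times), max(x$times),
              min(x$concentration), max(x$concentration)))
  invisible(x)
}

#' @method tidy concentration_field
#' @export
tidy.concentration_field <- function(x, ...) {
  grid <- expand.grid(i = seq_len(x$nx), j = seq_len(x$ny),
                      k = seq_along(x$times))
  h <- x$grid_spacing
  conc <- as.vector(x$concentration)
  tibble(
    time = x$times[grid$k],
    x = (grid$i - 0.5) * h,
    y = (grid$j - 0.5) * h,
    concentration = conc
  )
}
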