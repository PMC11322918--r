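# Finite-volume Darcy solver on the homogenized 2-D chamber.
#
# Grid convention for field matrices: p[i, j] with i = 1..nx the along-length
# (x) index and j = 1..ny the across-width (y) index; j = 1 touches the plain
# (bottom, outlet) fluidic line, j = ny the dosed (top, inlet) line. Walls at
# the two chamber ends (x faces) are no-flux. Face fluxes live on a staggered
# grid so discrete mass conservation holds cell by cell.

#' Solve hydrostatic-head-driven Darcy flow in the tissue chamber
#'
#' Solves `div( (k/mu) grad p ) = 0` by finite volumes on a uniform grid.
#' The fluidic-line pressures (from the boundary heads) couple to the chamber
#' through the homogenized pore conductance of the geometry; chamber end
#' walls are no-flux. Velocity is the Darcy flux `v = -(k/mu) grad p`.
#'
#' Because the problem is linear, velocities scale exactly linearly with the
#' applied pressure difference.
#'
#' @param geom A [device_geometry()].
#' @param props A [porous_medium()].
#' @param bc A [pressure_boundary()]; `inlet_head` is applied to the dosed
#'   (top) line, `outlet_head` to the plain (bottom) line.
#' @return A `flow_field`: cell-centre `pressure`, `velocity_x`,
#'   `velocity_y` matrices (m/s), staggered face fluxes `u_face`/`v_face`,
#'   grid metadata, and the applied pressure difference `delta_p` (Pa).
#' @examples
#' geom <- device_preset("aligned", grid_spacing = 25e-6)
#' flow <- solve_darcy(geom, porous_medium(), pressure_boundary(2))
#' max(abs(flow$velocity_y)) # cross-chamber Darcy speed, m/s
#' @export
solve_darcy <- function(geom, props = porous_medium(), bc) {
  stopifnot(inherits(geom, "device_geometry"), inherits(props, "porous_medium"),
            inherits(bc, "pressure_boundary"))
  h <- geom$grid_spacing
  nx <- max(2L, round(geom$chamber_length / h))
  ny <- max(10L, round(geom$chamber_width / h))
  mob <- props$permeability / props$viscosity   # Darcy mobility k/mu

  p_top <- props$density * bc$gravitational_acceleration * bc$inlet_head * 1e-3
  p_bot <- props$density * bc$gravitational_acceleration * bc$outlet_head * 1e-3

  # Effective boundary-face conductance: pore interface in series with the
  # half cell between face and cell centre (velocity per Pa).
  G <- geom$pore_conductance
  if (!is.finite(G) && G <= 0) stop_fm("pore_conductance must be > 0")
  c_bnd <- 1 / (1 / G + (h / 2) / mob)
  if (!is.finite(c_bnd) || c_bnd <= 0) {
    stop_fm("under-constrained boundary: no finite pressure coupling to ",
            "either fluidic line (pore_conductance = ", format(G), ")")
  }

  n <- nx * ny
  idx <- function(i, j) (j - 1L) * nx + i

  # Assemble -div(mob grad p) = boundary sources; transmissibilities are
  # per-unit-depth volumetric flux per Pa (uniform grid: dx/dy cancel).
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  add <- function(a, b, val) {
    ii <<- c(ii, a); jj <<- c(jj, b); vv <<- c(vv, val)
  }
  t_in <- mob # interior face transmissibility (times Dp, per unit depth)
  diag_acc <- numeric(n)
  rhs <- numeric(n)

  # x-direction interior faces
  for (i in seq_len(nx - 1L)) {
    a <- idx(i, seq_len(ny)); b <- idx(i + 1L, seq_len(ny))
    for (k in seq_along(a)) add(a[k], b[k], -t_in)
    for (k in seq_along(a)) add(b[k], a[k], -t_in)
    diag_acc[a] <- diag_acc[a] + t_in
    diag_acc[b] <- diag_acc[b] + t_in
  }
  # y-direction interior faces
  for (j in seq_len(ny - 1L)) {
    a <- idx(seq_len(nx), j); b <- idx(seq_len(nx), j + 1L)
    for (k in seq_along(a)) add(a[k], b[k], -t_in)
    for (k in seq_along(a)) add(b[k], a[k], -t_in)
    diag_acc[a] <- diag_acc[a] + t_in
    diag_acc[b] <- diag_acc[b] + t_in
  }
  # boundary faces to the two fluidic lines (face length h, conductance c_bnd)
  t_bnd <- c_bnd * h
  bot <- idx(seq_len(nx), 1L)
  top <- idx(seq_len(nx), ny)
  diag_acc[bot] <- diag_acc[bot] + t_bnd
  diag_acc[top] <- diag_acc[top] + t_bnd
  rhs[bot] <- rhs[bot] + t_bnd * p_bot
  rhs[top] <- rhs[top] + t_bnd * p_top

  A <- Matrix::sparseMatrix(
    i = c(ii, seq_len(n)), j = c(jj, seq_len(n)), x = c(vv, diag_acc),
    dims = c(n, n)
  )
  p <- tryCatch(
    as.numeric(Matrix::solve(A, rhs)),
    error = function(e) {
      stop_fm("under-constrained boundary: the pressure system is singular (",
              conditionMessage(e), ")")
    }
  )
  P <- matrix(p, nrow = nx, ncol = ny)

  # Staggered face fluxes (m/s). u_face: (nx+1) x ny; v_face: nx x (ny+1),
  # positive toward +x / +y (+y points from the plain to the dosed line).
  u_face <- matrix(0, nx + 1L, ny)
  u_face[2:nx, ] <- -mob * (P[2:nx, , drop = FALSE] -
                              P[seq_len(nx - 1L), , drop = FALSE]) / h
  v_face <- matrix(0, nx, ny + 1L)
  if (ny > 1L) {
    v_face[, 2:ny] <- -mob * (P[, 2:ny, drop = FALSE] -
                                P[, seq_len(ny - 1L), drop = FALSE]) / h
  }
  v_face[, 1L] <- c_bnd * (p_bot - P[, 1L])
  v_face[, ny + 1L] <- c_bnd * (P[, ny] - p_top)

  vx <- (u_face[seq_len(nx), ] + u_face[2:(nx + 1L), ]) / 2
  vy <- (v_face[, seq_len(ny)] + v_face[, 2:(ny + 1L)]) / 2

  structure(
    list(
      pressure = P, velocity_x = vx, velocity_y = vy,
      u_face = u_face, v_face = v_face,
      grid_spacing = h, nx = nx, ny = ny,
      geom = geom, props = props,
      delta_p = p_top - p_bot
    ),
    class = "flow_field"
  )
}

#' Discrete divergence of a solved flow field
#'
#' Mass-conservation diagnostic: the finite-volume divergence computed from
#' the staggered face fluxes, cell by cell. For a converged solve this is
#' zero to linear-solver precision.
#'
#' @param flow A `flow_field`.
#' @return Matrix of `div v` (1/s), dimensions `nx x ny`.
#' @export
flow_divergence <- function(flow) {
  stopifnot(inherits(flow, "flow_field"))
  h <- flow$grid_spacing
  nx <- flow$nx; ny <- flow$ny
  (flow$u_face[2:(nx + 1L), , drop = FALSE] -
     flow$u_face[seq_len(nx), , drop = FALSE]) / h +
    (flow$v_face[, 2:(ny + 1L), drop = FALSE] -
       flow$v_face[, seq_len(ny), drop = FALSE]) / h
}

#' Reynolds and Peclet numbers of a solved flow
#'
#' `Re = rho * |v| * W / mu` and `Pe = |v| * W / D` with `W` the chamber
#' width. The scalars use the maximum Darcy speed in the chamber; the
#' per-node maps use the local speed.
#'
#' @param flow A `flow_field`.
#' @param params A [transport_params()] (supplies the diffusivity).
#' @return A list: `Re_max`, `Pe_max` (scalars), `Re_map`, `Pe_map`
#'   (matrices), `speed_max`, `speed_mean` (m/s).
#' @export
reynolds_peclet <- function(flow, params = transport_params()) {
  stopifnot(inherits(flow, "flow_field"))
  speed <- sqrt(flow$velocity_x^2 + flow$velocity_y^2)
  W <- flow$geom$chamber_width
  props <- flow$props
  re_map <- props$density * speed * W / props$viscosity
  pe_map <- speed * W / params$diffusivity
  list(
    Re_max = max(re_map), Pe_max = max(pe_map),
    Re_map = re_map, Pe_map = pe_map,
    speed_max = max(speed), speed_mean = mean(speed)
  )
}

#' Calibrate the pore conductance to a target cross-chamber velocity
#'
#' The micropore row is homogenized into a single interface conductance. In
#' uniform cross-flow the chamber behaves as three hydraulic resistances in
#' series (interface, matrix, interface), so the conductance that produces a
#' target Darcy speed `v*` at a reference pressure difference `dP` is
#' `G = 2 / (dP / v* - W mu / k)`. The target must lie below the
#' open-interface limit `k dP / (mu W)`.
#'
#' @param geom A [device_geometry()].
#' @param props A [porous_medium()].
#' @param target_velocity Target cross-chamber Darcy speed (m/s).
#' @param reference_head Reference head difference (mm H2O).
#' @return The calibrated pore conductance (m^2 s / kg).
#' @export
calibrate_pore_conductance <- function(geom, props, target_velocity,
                                       reference_head) {
  check_number(target_velocity, "target_velocity", 0, strict = TRUE)
  dP <- head_to_pressure(reference_head, props)
  v_open <- props$permeability * dP / (props$viscosity * geom$chamber_width)
  if (target_velocity >= v_open) {
    stop_fm("target velocity ", format(target_velocity),
            " m/s exceeds the open-interface limit ", format(v_open),
            " m/s at ", reference_head, " mm H2O")
  }
  2 / (dP / target_velocity -
         geom$chamber_width * props$viscosity / props$permeability)
}

#' @describeIn solve_darcy Tidy a flow field into one row per grid cell
#'   (`x`, `y` in m; `pressure` Pa; `vx`, `vy`, `speed` m/s).
#' @param x A `flow_field`.
#' @param ... Unused.
#' @method tidy flow_field
#' @export
tidy.flow_field <- function(x, ...) {
  h <- x$grid_spacing
  grid <- expand.grid(i = seq_len(x$nx), j = seq_len(x$ny))
  press <- as.vector(x$pressure)
  vx <- as.vector(x$velocity_x)
  vy <- as.vector(x$velocity_y)
  tibble(
    x = (grid$i - 0.5) * h,
    y = (grid$j - 0.5) * h,
    pressure = press, vx = vx, vy = vy,
    speed = sqrt(vx^2 + vy^2)
  )
}

#' @method glance flow_field
#' @export
glance.flow_field <- function(x, ...) {
  spd <- sqrt(x$velocity_x^2 + x$velocity_y^2)
  div <- flow_divergence(x)
  tibble(
    delta_p = x$delta_p,
    speed_max = max(spd),
    speed_mean = mean(spd),
    max_divergence_rel = if (max(spd) > 0) {
      max(abs(div)) * x$grid_spacing / max(spd)
    } else {
      0
    },
    nx = x$nx, ny = x$ny
  )
}

#' @export
print.flow_field <- function(x, ...) {
  g <- glance(x)
  cat("<flow_field>", x$nx, "x", x$ny, "cells\n")
  cat(sprintf("  delta P: %.4g Pa; max speed %.4g um/s; mean %.4g um/s\n",
              g$delta_p, g$speed_max * 1e6, g$speed_mean * 1e6))
  invisible(x)
}
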