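# Advection-diffusion transport: trivial limits, the eigenfunction-series
# oracle, the maximum principle, and gradient formation metrics.

slab_geom <- function(width = 250e-6, n_across = 50) {
  device_geometry(1e-4, width, grid_spacing = width / n_across)
}

zero_flow <- function(geom) {
  solve_darcy(geom, porous_medium(), pressure_boundary(0, 0))
}

test_that("zero boundary concentrations stay identically zero", {
  flow <- zero_flow(slab_geom(n_across = 20))
  conc <- solve_transport(
    flow, transport_params(time_step = 50, total_time = 2000,
                           source_concentration = 0),
    times = c(0, 1000, 2000)
  )
  expect_true(all(conc$concentration == 0))
})

test_that("pure diffusion relaxes to the linear profile with midpoint 1/2", {
  geom <- slab_geom(n_across = 40)
  flow <- zero_flow(geom)
  L <- geom$chamber_width; D <- 7e-11
  t_long <- 5 * L^2 / D
  conc <- solve_transport(flow, transport_params(time_step = 50,
                                                 total_time = t_long),
                          times = c(0, t_long))
  prof <- colMeans(conc$concentration[, , 2])
  y <- (seq_len(conc$ny) - 0.5) * conc$grid_spacing
  expect_equal(prof, y / L, tolerance = 1e-3)
  mid <- approx(y, prof, xout = L / 2)$y
  expect_equal(mid, 0.5, tolerance = 1e-3)
})

test_that("transient solution matches the eigenfunction series to < 1% L2", {
  geom <- slab_geom(n_across = 50)
  flow <- zero_flow(geom)
  L <- geom$chamber_width; D <- 7e-11
  tt <- seq(0, 3 * L^2 / D, length.out = 13)[-1]
  conc <- solve_transport(flow, transport_params(diffusivity = D,
                                                 time_step = 2,
                                                 total_time = max(tt)),
                          times = tt)
  y <- (seq_len(conc$ny) - 0.5) * conc$grid_spacing
  for (k in seq_along(tt)) {
    num <- colMeans(conc$concentration[, , k])
    ora <- diffusion_series_profile(y, tt[k], L, D)
    rel_l2 <- sqrt(mean((num - ora)^2)) / sqrt(mean(ora^2))
    expect_lt(rel_l2, 0.01)
  }
})

test_that("concentrations never leave the boundary-value interval", {
  geom <- slab_geom(n_across = 30)
  flow <- zero_flow(geom)
  conc <- solve_transport(flow, transport_params(time_step = 20,
                                                 total_time = 2000))
  expect_gte(min(conc$concentration), -1e-9)
  expect_lte(max(conc$concentration), 1 + 1e-9)
})

test_that("advective steady state matches the analytic exponential profile", {
  # uniform cross-flow at Pe ~ 2: c(y) = (exp(Pe y/L) - 1) / (exp(Pe) - 1)
  geom <- slab_geom(n_across = 50)
  props <- porous_medium()
  D <- 7e-11; L <- geom$chamber_width
  pe <- 2
  v_seep <- pe * D / L
  dP <- v_seep * props$porosity * props$viscosity * L / props$permeability
  head_mm <- dP / (props$density * 9.80665) * 1e3
  # drive the flow upward (toward the dosed line) so v and Pe are positive
  flow <- solve_darcy(geom, props, pressure_boundary(0, head_mm))
  t_long <- 6 * L^2 / D
  conc <- solve_transport(flow, transport_params(diffusivity = D,
                                                 time_step = 2,
                                                 total_time = t_long),
                          times = c(0, t_long))
  y <- (seq_len(conc$ny) - 0.5) * conc$grid_spacing
  num <- colMeans(conc$concentration[, , 2])
  ana <- (exp(pe * y / L) - 1) / (exp(pe) - 1)
  expect_lt(sqrt(mean((num - ana)^2)), 0.02)
})

test_that("an unstable advective time step is refused with the bound", {
  geom <- slab_geom(n_across = 20)
  flow <- solve_darcy(geom, porous_medium(), pressure_boundary(20, 0))
  expect_error(
    solve_transport(flow, transport_params(time_step = 1e5,
                                           total_time = 2e5)),
    "CFL bound"
  )
})

test_that("gradient metrics: trivial cases and the series-oracle time", {
  geom <- slab_geom(n_across = 40)
  flow <- zero_flow(geom)
  L <- geom$chamber_width; D <- 7e-11
  ny <- flow$ny
  y <- (seq_len(ny) - 0.5) * geom$grid_spacing

  # steady linear initial condition -> formed at t = 0
  lin <- matrix(rep(y / L, each = flow$nx), flow$nx, ny)
  conc_lin <- solve_transport(flow, transport_params(time_step = 20,
                                                     total_time = 400),
                              times = c(0, 200, 400), initial = lin)
  gm_lin <- gradient_metrics(conc_lin)
  expect_identical(gm_lin$formation_time, 0)

  # all-zero degenerate case
  conc0 <- solve_transport(
    flow, transport_params(time_step = 20, total_time = 400,
                           source_concentration = 0),
    times = c(0, 400)
  )
  gm0 <- gradient_metrics(conc0)
  expect_identical(gm0$formation_time, 0)
  expect_true(gm0$degenerate_zero_gradient)

  # formation time within one output interval of the series oracle
  dt_out <- 10
  times <- seq(0, 900, by = dt_out)
  conc <- solve_transport(flow, transport_params(diffusivity = D,
                                                 time_step = 2,
                                                 total_time = max(times)),
                          times = times)
  tol <- 0.05
  gm <- gradient_metrics(conc, tolerance = tol)
  dev_oracle <- vapply(times, function(t) {
    max(abs(diffusion_series_profile(y, t, L, D) - y / L))
  }, numeric(1))
  t_oracle <- times[which(dev_oracle <= tol)[1]]
  expect_lte(abs(gm$formation_time - t_oracle), dt_out)

  # never-reached case reported as NA, not an error
  conc_short <- solve_transport(flow, transport_params(diffusivity = D,
                                                       time_step = 2,
                                                       total_time = 30),
                                times = c(0, 15, 30))
  gm_short <- gradient_metrics(conc_short, tolerance = 0.01)
  expect_true(is.na(gm_short$formation_time))
  expect_false(isTRUE(gm_short$maintained))
})

test_that("halving the grid changes formation time by < 2%", {
  L <- 250e-6; D <- 7e-11
  form_time <- function(n_across) {
    geom <- slab_geom(n_across = n_across)
    flow <- zero_flow(geom)
    times <- seq(0, 800, by = 4)
    conc <- solve_transport(flow, transport_params(diffusivity = D,
                                                   time_step = 2,
                                                   total_time = max(times)),
                            times = times)
    gradient_metrics(conc, tolerance = 0.1)$formation_time
  }
  t_coarse <- form_time(25)
  t_fine <- form_time(50)
  expect_lt(abs(t_fine - t_coarse) / t_fine, 0.02)
})
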