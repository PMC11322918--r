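# Darcy flow in the homogenized chamber: unit conversions, the analytic
# slab limit, linearity, and mass conservation.

test_that("hydrostatic head converts to pressure as rho*g*h", {
  expect_identical(head_to_pressure(0), 0)
  expect_equal(head_to_pressure(2), 19.6133, tolerance = 1e-9)
  expect_equal(head_to_pressure(20), 196.133, tolerance = 1e-9)
  # linear in head
  h <- c(1, 3, 7.5)
  expect_equal(head_to_pressure(h), h * head_to_pressure(1))
  expect_error(head_to_pressure(c(2, -1)), "line\\(s\\) 2")
})

test_that("geometry constructors enforce their invariants", {
  expect_error(device_geometry(5e-3, 250e-6, grid_spacing = 50e-6),
               "grid_spacing")
  expect_error(pressure_boundary(-1), "head")
  expect_error(porous_medium(porosity = 1.2), "porosity")
  al <- device_preset("aligned")
  expect_equal(al$chamber_length / al$chamber_width, 20)
  rd <- device_preset("random")
  expect_equal(rd$chamber_length / rd$chamber_width, 1)
  rd2 <- device_preset("random", side = 2e-3)
  expect_equal(rd2$chamber_length, 2e-3)
})

test_that("equal heads on both lines give zero flow", {
  geom <- device_geometry(4e-4, 2e-4, grid_spacing = 2e-5)
  flow <- solve_darcy(geom, porous_medium(), pressure_boundary(5, 5))
  # zero up to linear-solver roundoff (driven flows are ~1e-6 m/s)
  expect_lt(max(abs(flow$velocity_x)), 1e-16)
  expect_lt(max(abs(flow$velocity_y)), 1e-16)
  rp <- reynolds_peclet(flow)
  expect_lt(rp$Re_max, 1e-12)
  expect_lt(rp$Pe_max, 1e-8)
})

test_that("1-D slab limit matches v = k dP / (mu L) to 1e-6 relative", {
  # open interface (pore_conductance = Inf), width 1 mm, dP = 1 mm H2O
  geom <- device_geometry(2e-4, 1e-3, grid_spacing = 5e-5)
  flow <- solve_darcy(geom, porous_medium(), pressure_boundary(1, 0))
  v_true <- 2e-13 * 9.80665 / (1e-3 * 1e-3)  # 1.96133e-6 m/s
  expect_equal(max(abs(flow$v_face)), v_true, tolerance = 1e-6)
  expect_equal(min(abs(flow$v_face)), v_true, tolerance = 1e-6)
  # flow is purely cross-chamber
  expect_lt(max(abs(flow$velocity_x)), 1e-12 * v_true)
})

test_that("velocities are exactly linear in the applied pressure", {
  geom <- device_preset("aligned", grid_spacing = 25e-6,
                        pore_conductance = 1e-7)
  f1 <- solve_darcy(geom, porous_medium(), pressure_boundary(2, 0))
  f2 <- solve_darcy(geom, porous_medium(), pressure_boundary(4, 0))
  expect_equal(f2$v_face, 2 * f1$v_face, tolerance = 1e-12)
  expect_equal(f2$u_face, 2 * f1$u_face, tolerance = 1e-12)
})

test_that("solved fields conserve mass cell by cell", {
  geom <- device_preset("aligned", grid_spacing = 25e-6,
                        pore_conductance = 5e-8)
  flow <- solve_darcy(geom, porous_medium(), pressure_boundary(10, 0))
  spd <- sqrt(flow$velocity_x^2 + flow$velocity_y^2)
  rel <- max(abs(flow_divergence(flow))) * flow$grid_spacing / max(spd)
  expect_lt(rel, 1e-6)
})

test_that("velocity equals the Darcy flux of the pressure field", {
  geom <- device_geometry(4e-4, 2.5e-4, grid_spacing = 12.5e-6,
                          pore_conductance = 1e-7)
  props <- porous_medium()
  flow <- solve_darcy(geom, props, pressure_boundary(3, 1))
  mob <- props$permeability / props$viscosity
  h <- flow$grid_spacing
  # interior central differences of pressure vs cell-centre velocities
  P <- flow$pressure
  nx <- flow$nx; ny <- flow$ny
  vx_c <- -mob * (P[3:nx, 2:(ny - 1)] - P[1:(nx - 2), 2:(ny - 1)]) / (2 * h)
  expect_equal(flow$velocity_x[2:(nx - 1), 2:(ny - 1)], vx_c,
               tolerance = 1e-10)
  vy_c <- -mob * (P[2:(nx - 1), 3:ny] - P[2:(nx - 1), 1:(ny - 2)]) / (2 * h)
  expect_equal(flow$velocity_y[2:(nx - 1), 2:(ny - 1)], vy_c,
               tolerance = 1e-10)
})

test_that("a zero pore conductance is reported as under-constrained", {
  geom <- device_geometry(4e-4, 2e-4, grid_spacing = 2e-5)
  geom$pore_conductance <- 0
  expect_error(solve_darcy(geom, porous_medium(), pressure_boundary(1, 0)),
               "under-constrained")
})

test_that("Reynolds and Peclet numbers match their closed forms", {
  # Re = rho v W / mu and Pe = v W / D at |v| = 10 um/s, W = 250 um
  geom <- device_geometry(2e-4, 250e-6, grid_spacing = 12.5e-6)
  props <- porous_medium()
  # pick the head that produces exactly 10 um/s in the open slab
  v_target <- 10e-6
  dP <- v_target * props$viscosity * geom$chamber_width / props$permeability
  head_mm <- dP / (props$density * 9.80665) * 1e3
  flow <- solve_darcy(geom, props, pressure_boundary(head_mm, 0))
  rp <- reynolds_peclet(flow, transport_params(diffusivity = 7e-11))
  expect_equal(rp$Re_max, 2.5e-3, tolerance = 1e-6)
  expect_equal(rp$Pe_max, 10e-6 * 250e-6 / 7e-11, tolerance = 1e-6)
  expect_equal(dim(rp$Re_map), c(flow$nx, flow$ny))
})

test_that("pore-conductance calibration hits its target velocity", {
  geom <- device_preset("aligned", grid_spacing = 25e-6)
  props <- porous_medium()
  G <- calibrate_pore_conductance(geom, props, 5e-6, reference_head = 10)
  geom$pore_conductance <- G
  flow <- solve_darcy(geom, props, pressure_boundary(10, 0))
  expect_equal(max(abs(flow$v_face)), 5e-6, tolerance = 1e-3)
  expect_error(
    calibrate_pore_conductance(geom, props, 1, reference_head = 10),
    "open-interface limit"
  )
})
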