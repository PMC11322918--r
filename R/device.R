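#' Device geometry for the homogenized 2-D tissue chamber
#'
#' Describes the rectangular tissue chamber in plan view, with fluidic lines
#' running along the two long sides. The row of micropores connecting each
#' fluidic line to the chamber is homogenized into a hydraulic conductance
#' per unit interface length (`pore_conductance`): the Darcy flux through the
#' interface is `pore_conductance * (p_line - p_chamber)` in m/s.
#'
#' Flow and gradients cross the chamber along its *width* (the 250 um
#' dimension in the high-aspect-ratio preset); the chamber *length* runs
#' parallel to the fluidic lines.
#'
#' @param chamber_length Chamber length (m), parallel to the fluidic lines.
#' @param chamber_width Chamber width (m), the cross-gradient dimension.
#' @param chamber_height Chamber height (m); the model is depth-averaged, so
#'   height only enters reporting, not the 2-D solve.
#' @param line_width Fluidic line width (m), metadata for reporting.
#' @param pore_conductance Homogenized interface conductance (m^2 s / kg):
#'   interface Darcy flux per unit pressure difference. `Inf` means the line
#'   pressure is imposed directly on the chamber boundary (open interface).
#' @param grid_spacing Finite-volume cell size (m); must resolve the width
#'   with at least 10 cells.
#' @return A `device_geometry` object.
#' @examples
#' device_geometry(5e-3, 250e-6)
#' @export
device_geometry <- function(chamber_length,
                            chamber_width,
                            chamber_height = 100e-6,
                            line_width = 250e-6,
                            pore_conductance = Inf,
                            grid_spacing = chamber_width / 25) {
  check_number(chamber_length, "chamber_length", 0, strict = TRUE)
  check_number(chamber_width, "chamber_width", 0, strict = TRUE)
  check_number(chamber_height, "chamber_height", 0, strict = TRUE)
  check_number(line_width, "line_width", 0, strict = TRUE)
  check_number(pore_conductance, "pore_conductance", 0, strict = TRUE,
               finite = FALSE)
  check_number(grid_spacing, "grid_spacing", 0, strict = TRUE)
  if (grid_spacing > chamber_width / 10 + 1e-15) {
    stop_fm("`grid_spacing` must be <= chamber_width / 10 (got ",
            format(grid_spacing), " vs limit ", format(chamber_width / 10), ")")
  }
  structure(
    list(
      chamber_length = chamber_length,
      chamber_width = chamber_width,
      chamber_height = chamber_height,
      line_width = line_width,
      pore_conductance = pore_conductance,
      grid_spacing = grid_spacing
    ),
    class = "device_geometry"
  )
}

#' Named device presets
#'
#' `"aligned"`: the fiber-aligning chamber, 5 mm x 250 um (20:1
#' length-to-width ratio). `"random"`: the control chamber with a 1:1
#' length-to-width ratio, default side 1 mm (the side length is a parameter,
#' not a constant of the device family).
#'
#' @param name `"aligned"` or `"random"`.
#' @param side Side length (m) of the square random chamber.
#' @param ... Passed on to [device_geometry()] (e.g. `grid_spacing`,
#'   `pore_conductance`).
#' @return A `device_geometry`.
#' @examples
#' device_preset("aligned")
#' device_preset("random", side = 2e-3)
#' @export
device_preset <- function(name = c("aligned", "random"), side = 1e-3, ...) {
  name <- match.arg(name)
  if (name == "aligned") {
    device_geometry(chamber_length = 5e-3, chamber_width = 250e-6, ...)
  } else {
    device_geometry(chamber_length = side, chamber_width = side, ...)
  }
}

#' Porous medium properties
#'
#' Defaults are the collagen-I hydrogel values used throughout: porosity
#' 0.99, hydraulic permeability 2e-13 m^2, water viscosity 1 cP, water
#' density 1000 kg/m^3.
#'
#' @param porosity Void fraction in (0, 1].
#' @param permeability Hydraulic permeability (m^2).
#' @param viscosity Dynamic viscosity (Pa s).
#' @param density Fluid density (kg/m^3).
#' @return A `porous_medium` object.
#' @export
porous_medium <- function(porosity = 0.99,
                          permeability = 2e-13,
                          viscosity = 1e-3,
                          density = 1000) {
  check_number(porosity, "porosity", 0, strict = TRUE)
  if (porosity > 1) stop_fm("`porosity` must be <= 1")
  check_number(permeability, "permeability", 0, strict = TRUE)
  check_number(viscosity, "viscosity", 0, strict = TRUE)
  check_number(density, "density", 0, strict = TRUE)
  structure(
    list(porosity = porosity, permeability = permeability,
         viscosity = viscosity, density = density),
    class = "porous_medium"
  )
}

#' Hydrostatic pressure boundary conditions
#'
#' Heads are liquid-column heights in mm H2O on the dosed (top) and plain
#' (bottom) fluidic lines; the cross-chamber driving pressure is their
#' difference converted via rho * g * h.
#'
#' @param inlet_head Head on the dosed line (mm H2O).
#' @param outlet_head Head on the plain line (mm H2O).
#' @param gravitational_acceleration g (m/s^2), standard gravity by default.
#' @return A `pressure_boundary` object.
#' @export
pressure_boundary <- function(inlet_head,
                              outlet_head = 0,
                              gravitational_acceleration = STANDARD_GRAVITY) {
  for (nm in c("inlet_head", "outlet_head")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || is.na(val) || val < 0) {
      stop_fm("negative or invalid head on `", nm,
              "`: heads are liquid-column heights and must be >= 0")
    }
  }
  check_number(gravitational_acceleration, "gravitational_acceleration", 0,
               strict = TRUE)
  structure(
    list(inlet_head = inlet_head, outlet_head = outlet_head,
         gravitational_acceleration = gravitational_acceleration),
    class = "pressure_boundary"
  )
}

#' Solute transport parameters
#'
#' Defaults describe 70 kDa dextran (the morphogen proxy): diffusivity
#' 7e-11 m^2/s. Concentrations are normalized: 1 on the dosed line, 0 on the
#' plain line.
#'
#' @param diffusivity Solute diffusivity (m^2/s).
#' @param time_step Requested time step (s); the solver additionally caps it
#'   at 0.4x the explicit advective CFL bound and refuses steps above it.
#' @param total_time Simulated time (s).
#' @param source_concentration Normalized concentration held on the dosed
#'   line (the plain line is held at 0).
#' @return A `transport_params` object.
#' @export
transport_params <- function(diffusivity = 7e-11,
                             time_step = 5,
                             total_time = 24 * 3600,
                             source_concentration = 1) {
  check_number(diffusivity, "diffusivity", 0, strict = TRUE)
  check_number(time_step, "time_step", 0, strict = TRUE)
  check_number(total_time, "total_time", 0, strict = TRUE)
  check_number(source_concentration, "source_concentration", 0)
  structure(
    list(diffusivity = diffusivity, time_step = time_step,
         total_time = total_time, source_concentration = source_concentration),
    class = "transport_params"
  )
}

#' Convert a hydrostatic head to pressure
#'
#' `p = rho * g * h` with the head in metres (input in mm H2O). Linear in
#' head; 1 mm H2O of water at standard gravity is 9.80665 Pa.
#'
#' @param head_mm Head in mm H2O (scalar or vector).
#' @param props A [porous_medium()] (supplies the fluid density).
#' @param g Gravitational acceleration (m/s^2).
#' @return Pressure(s) in Pa.
#' @examples
#' head_to_pressure(2) # 19.6133 Pa
#' @export
head_to_pressure <- function(head_mm, props = porous_medium(),
                             g = STANDARD_GRAVITY) {
  if (!is.numeric(head_mm) || any(is.na(head_mm))) {
    stop_fm("`head_mm` must be numeric with no missing values")
  }
  if (any(head_mm < 0)) {
    bad <- which(head_mm < 0)
    stop_fm("negative head on line(s) ", paste(bad, collapse = ", "),
            ": heads are liquid-column heights and must be >= 0")
  }
  props$density * g * head_mm * 1e-3
}

#' @export
print.device_geometry <- function(x, ...) {
  cat("<device_geometry>\n")
  cat(sprintf("  chamber: %.3g x %.3g mm (L x W), height %.3g um\n",
              x$chamber_length * 1e3, x$chamber_width * 1e3,
              x$chamber_height * 1e6))
  cat(sprintf("  grid spacing: %.3g um, pore conductance: %s m^2 s/kg\n",
              x$grid_spacing * 1e6, format(x$pore_conductance)))
  invisible(x)
}
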