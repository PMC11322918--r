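# Seeded synthetic-data generators with serialized ground truth.
#
# Every generator is a pure function of (seed, parameters): identical calls
# give bit-identical output, and the generating truth is returned alongside
# the data so each analysis stage can be scored against it. The noise model
# everywhere is Poisson shot noise (photon budget `poisson_scale` counts at
# unit intensity) plus additive Gaussian read noise.

# Apply the shared noise model. poisson_scale = 0 disables shot noise,
# gaussian_sd = 0 disables read noise.
apply_imaging_noise <- function(image, poisson_scale = 0, gaussian_sd = 0) {
  out <- image
  if (poisson_scale > 0) {
    out <- matrix(
      stats::rpois(length(out), lambda = pmax(out, 0) * poisson_scale),
      nrow(out), ncol(out)
    ) / poisson_scale
  }
  if (gaussian_sd > 0) {
    out <- out + matrix(stats::rnorm(length(out), sd = gaussian_sd),
                        nrow(out), ncol(out))
  }
  out
}

#' Generate a synthetic fiber image with known orientations
#'
#' Renders anti-aliased line segments whose orientations are drawn from the
#' axial (doubled-angle) von Mises distribution, on a constant background
#' with Poisson + Gaussian noise. The true angle list is returned for
#' recovery scoring.
#'
#' @param seed Integer seed; the generator is bit-reproducible.
#' @param image_size Image side (px, square).
#' @param n_fibers Number of segments; the default emulates a dense
#'   2 mg/mL collagen field at confocal-reflectance resolution.
#' @param mean_angle Mean orientation (degrees, axial, math convention).
#' @param concentration von Mises concentration `kappa` on doubled angles;
#'   0 = uniform, `Inf` = all fibers at `mean_angle`.
#' @param fiber_length Range (px) of segment lengths.
#' @param fiber_width Gaussian cross-profile sigma (px).
#' @param intensity Peak added intensity per fiber.
#' @param background Background level.
#' @param poisson_scale,gaussian_sd Noise model (see package vignette).
#' @return A list: `image` (matrix), `truth` (tibble: angle, cx, cy,
#'   length), and the generating parameters.
#' @export
gen_fiber_image <- function(seed, image_size = 384, n_fibers = 700,
                            mean_angle = 90, concentration = 4,
                            fiber_length = c(30, 80), fiber_width = 1.2,
                            intensity = 0.6, background = 0.1,
                            poisson_scale = 200, gaussian_sd = 0.01) {
  stopifnot(n_fibers >= 1)
  with_seed(seed, {
    angles <- sample_axial_angles(n_fibers, mean_angle, concentration)
    cx <- stats::runif(n_fibers, 1, image_size)
    cy <- stats::runif(n_fibers, 1, image_size)
    len <- stats::runif(n_fibers, fiber_length[1], fiber_length[2])
    img <- matrix(background, image_size, image_size)
    for (f in seq_len(n_fibers)) {
      seg <- segment_contribution(image_size, image_size, cx[f], cy[f],
                                  angles[f], len[f], fiber_width, intensity)
      if (length(seg$idx)) img[seg$idx] <- img[seg$idx] + seg$add
    }
    img <- apply_imaging_noise(img, poisson_scale, gaussian_sd)
    list(
      image = img,
      truth = tibble(angle = angles, cx = cx, cy = cy, length = len),
      params = list(seed = seed, image_size = image_size,
                    n_fibers = n_fibers, mean_angle = mean_angle,
                    concentration = concentration)
    )
  })
}

# One anti-aliased segment (Gaussian cross-profile) as linear-index
# contributions to an nr x nc image. (cx, cy) in pixel units, math
# convention (y up); angle in degrees. Returned as (idx, add) so the caller
# can accumulate in place without copying the image per fiber.
segment_contribution <- function(nr, nc, cx, cy, angle, len, width, intensity) {
  th <- angle * pi / 180
  dx <- cos(th); dy <- sin(th)
  half <- len / 2
  pad <- ceiling(3 * width)
  xs <- cx + c(-1, 1) * (abs(dx) * half + pad)
  ys <- cy + c(-1, 1) * (abs(dy) * half + pad)
  cols <- max(1, floor(xs[1])):min(nc, ceiling(xs[2]))
  rows_math <- max(1, floor(ys[1])):min(nr, ceiling(ys[2]))
  if (length(cols) == 0 || length(rows_math) == 0) {
    return(list(idx = integer(0), add = numeric(0)))
  }
  px <- outer(rep(1, length(rows_math)), cols) - cx
  py <- outer(rows_math, rep(1, length(cols))) - cy
  # distance to the segment: project onto the axis, clamp, measure residual
  tproj <- pmin(pmax(px * dx + py * dy, -half), half)
  d2 <- (px - tproj * dx)^2 + (py - tproj * dy)^2
  add <- intensity * exp(-d2 / (2 * width^2))
  rows_img <- nr - rows_math + 1L  # math y -> image row
  idx <- outer(rows_img, (cols - 1L) * nr, `+`)
  list(idx = as.vector(idx), add = as.vector(add))
}

#' Generate a synthetic FRAP sequence with known velocity
#'
#' A Gaussian-profile bleached spot on a uniform fluorophore field, advected
#' at the true velocity and recovering by diffusion: the closed-form
#' evolution of an initial Gaussian bleach of depth `bleach_depth` and
#' variance `sigma0^2` under 2-D diffusion is a Gaussian of variance
#' `sigma0^2 + 2 D t` and depth `bleach_depth * sigma0^2 / (sigma0^2 + 2 D t)`,
#' centred on the advected position.
#'
#' @param seed Integer seed.
#' @param velocity True `(vx, vy)` in um/s, math convention.
#' @param dye_diffusivity Recovery diffusivity (um^2/s); 0 freezes recovery.
#' @param bleach_depth Fractional depth of the bleach (0..1).
#' @param bleach_diameter Spot diameter (um); the Gaussian sigma is
#'   `diameter / 4` so the visibly dark disk matches the nominal diameter.
#' @param frame_interval s between frames.
#' @param n_frames Number of frames.
#' @param pixel_size um/px.
#' @param image_size `c(rows, cols)` in px.
#' @param start Spot centre at t = 0 (um, math convention); default places
#'   the spot so the full drift stays in frame.
#' @param poisson_scale,gaussian_sd Noise model.
#' @return A list: `sequence` (a [frap_sequence()]), `truth` (tibble:
#'   time, x, y per frame plus `vx`, `vy`, `speed`, `direction` attrs).
#' @export
gen_frap_sequence <- function(seed, velocity = c(10, 0),
                              dye_diffusivity = 20, bleach_depth = 0.8,
                              bleach_diameter = 30, frame_interval = 0.5,
                              n_frames = 31, pixel_size = 2,
                              image_size = c(96, 224), start = NULL,
                              poisson_scale = 500, gaussian_sd = 0.005) {
  stopifnot(all(is.finite(velocity)), length(velocity) == 2)
  with_seed(seed, {
    nr <- image_size[1]; nc <- image_size[2]
    wx <- nc * pixel_size; wy <- nr * pixel_size
    times <- (seq_len(n_frames) - 1) * frame_interval
    drift <- velocity * max(times)
    if (is.null(start)) {
      # keep the whole track at least one spot-diameter inside the frame
      margin <- bleach_diameter
      start <- c(
        if (velocity[1] >= 0) margin else wx - margin,
        wy / 2 - drift[2] / 2
      )
      start[1] <- min(max(start[1], margin), wx - margin)
    }
    sigma0 <- bleach_diameter / 4
    xs <- (seq_len(nc) - 0.5) * pixel_size
    ys <- (nr - seq_len(nr) + 0.5) * pixel_size  # math y per image row
    frames <- vector("list", n_frames)
    cx <- start[1] + velocity[1] * times
    cy <- start[2] + velocity[2] * times
    for (k in seq_len(n_frames)) {
      s2 <- sigma0^2 + 2 * dye_diffusivity * times[k]
      depth_k <- bleach_depth * sigma0^2 / s2
      gx <- exp(-(xs - cx[k])^2 / (2 * s2))
      gy <- exp(-(ys - cy[k])^2 / (2 * s2))
      frame <- 1 - depth_k * outer(gy, gx)
      frames[[k]] <- apply_imaging_noise(frame, poisson_scale, gaussian_sd)
    }
    truth <- tibble(time = times, x = cx, y = cy)
    attr(truth, "vx") <- velocity[1]
    attr(truth, "vy") <- velocity[2]
    attr(truth, "speed") <- sqrt(sum(velocity^2))
    attr(truth, "direction") <- wrap_direction(atan2(velocity[2], velocity[1]) *
                                                 180 / pi)
    list(
      sequence = frap_sequence(frames, frame_interval, pixel_size,
                               bleach_diameter),
      truth = truth
    )
  })
}

#' Generate a synthetic cyst mask with known protrusions and ruffling
#'
#' The boundary is a polar curve around the centre:
#' ellipse radius + Gaussian bumps at the protrusion angles + band-limited
#' random ruffles whose amplitude differs between the top (y > centre) and
#' bottom half. Rasterized to a binary row-down mask; all generating truth
#' is returned.
#'
#' @param seed Integer seed.
#' @param image_size Image side (px, square).
#' @param pixel_size um/px.
#' @param semi_major,semi_minor Ellipse semi-axes (um).
#' @param orientation Ellipse major-axis angle (degrees, math convention).
#' @param protrusions Tibble/data.frame with columns `angle` (deg, measured
#'   counter-clockwise from +x at the centroid), `prominence` (um),
#'   `width` (deg); or NULL.
#' @param ruffle_amplitude_top,ruffle_amplitude_bottom RMS ruffle amplitude
#'   (um) on each half.
#' @param ruffle_harmonics Integer range of angular harmonics carrying the
#'   ruffles.
#' @return A list: `mask` (logical matrix, row-down), `pixel_size`,
#'   `truth` (centre, axes, protrusion table, ruffle settings).
#' @export
gen_cyst_mask <- function(seed, image_size = 256, pixel_size = 1,
                          semi_major = 60, semi_minor = 45, orientation = 0,
                          protrusions = NULL,
                          ruffle_amplitude_top = 0,
                          ruffle_amplitude_bottom = 0,
                          ruffle_harmonics = c(8, 16)) {
  if (!is.null(protrusions)) {
    protrusions <- as_tibble(protrusions)
    stopifnot(all(c("angle", "prominence") %in% names(protrusions)))
    if (!"width" %in% names(protrusions)) protrusions$width <- 12
    if (any(protrusions$prominence >= semi_minor)) {
      stop_fm("protrusion prominences must stay below the minor semi-axis")
    }
  }
  with_seed(seed, {
    centre <- c(image_size, image_size) * pixel_size / 2
    n_phi <- 2048L
    phi <- (seq_len(n_phi) - 1) * 2 * pi / n_phi
    alpha <- orientation * pi / 180
    r <- semi_major * semi_minor /
      sqrt((semi_minor * cos(phi - alpha))^2 + (semi_major * sin(phi - alpha))^2)
    if (!is.null(protrusions) && nrow(protrusions) > 0) {
      for (p in seq_len(nrow(protrusions))) {
        dphi <- (phi - protrusions$angle[p] * pi / 180 + pi) %% (2 * pi) - pi
        w <- protrusions$width[p] * pi / 180
        r <- r + protrusions$prominence[p] * exp(-dphi^2 / (2 * w^2))
      }
    }
    ruffle <- ruffle_profile(phi, ruffle_amplitude_top,
                             ruffle_amplitude_bottom, ruffle_harmonics)
    r <- r + ruffle
    # rasterize: pixel inside iff its radius is below r(phi)
    xs <- (seq_len(image_size) - 0.5) * pixel_size - centre[1]
    ys <- (image_size - seq_len(image_size) + 0.5) * pixel_size - centre[2]
    X <- outer(rep(1, image_size), xs)   # [row, col]
    Y <- outer(ys, rep(1, image_size))
    rho <- sqrt(X^2 + Y^2)
    ang <- atan2(Y, X) %% (2 * pi)
    r_at <- approx(x = c(phi, 2 * pi), y = c(r, r[1]), xout = ang)$y
    mask <- rho <= r_at
    list(
      mask = mask, pixel_size = pixel_size,
      truth = list(
        centre = centre, semi_major = semi_major, semi_minor = semi_minor,
        orientation = wrap_axial(orientation),
        protrusions = protrusions %||% tibble(angle = numeric(0),
                                              prominence = numeric(0),
                                              width = numeric(0)),
        ruffle_amplitude_top = ruffle_amplitude_top,
        ruffle_amplitude_bottom = ruffle_amplitude_bottom,
        ruffle_harmonics = ruffle_harmonics
      )
    )
  })
}

# Band-limited random radial perturbation with side-dependent RMS amplitude:
# harmonics in `harmonics` with random phases, scaled to unit RMS, then
# modulated by a smooth top/bottom envelope.
ruffle_profile <- function(phi, amp_top, amp_bottom, harmonics) {
  if (amp_top <= 0 && amp_bottom <= 0) return(numeric(length(phi)))
  ms <- seq(harmonics[1], harmonics[2])
  base <- numeric(length(phi))
  for (m in ms) {
    base <- base + cos(m * phi + stats::runif(1, 0, 2 * pi))
  }
  base <- base / sqrt(length(ms) / 2)  # unit RMS
  envelope <- amp_bottom + (amp_top - amp_bottom) /
    (1 + exp(-sin(phi) / 0.15))       # smooth switch at the horizontal
  base * envelope
}

#' Render a concentration field into a noisy synthetic dextran image series
#'
#' Turns solver output into fluorescence-like images (intensity proportional
#' to concentration) at the requested times, with the shared noise model.
#' Used to test profile extraction end to end against the solver as oracle.
#'
#' @param seed Integer seed.
#' @param conc A `concentration_field` from [solve_transport()].
#' @param times Times to render (defaults to all snapshots).
#' @param px_per_cell Pixels rendered per solver cell.
#' @param poisson_scale,gaussian_sd Noise model.
#' @return A list: `frames` (list of row-down matrices), `times`, `truth`
#'   (the sampled concentration profiles).
#' @export
gen_gradient_scene <- function(seed, conc, times = NULL, px_per_cell = 2,
                               poisson_scale = 300, gaussian_sd = 0.005) {
  stopifnot(inherits(conc, "concentration_field"))
  times <- times %||% conc$times
  idx <- vapply(times, function(t) which.min(abs(conc$times - t)), integer(1))
  with_seed(seed, {
    frames <- lapply(idx, function(k) {
      C <- conc$concentration[, , k]  # [nx, ny], j = 1 at the bottom line
      # upsample to pixels: x -> columns, y -> rows (row 1 = top = dosed line)
      big <- C[rep(seq_len(nrow(C)), each = px_per_cell),
               rep(seq_len(ncol(C)), each = px_per_cell), drop = FALSE]
      img <- t(big)[rev(seq_len(ncol(big))), , drop = FALSE]
      apply_imaging_noise(img, poisson_scale, gaussian_sd)
    })
    list(
      frames = frames, times = conc$times[idx],
      truth = lapply(idx, function(k) colMeans(conc$concentration[, , k])),
      pixel_size = conc$grid_spacing * 1e6 / px_per_cell
    )
  })
}

#' Extract a cross-chamber intensity profile from a rendered gradient image
#'
#' Averages the image along the chamber length, returning intensity against
#' the cross-chamber coordinate with y = 0 at the plain (bottom) line.
#'
#' @param frame Row-down image matrix.
#' @param pixel_size um/px.
#' @return Tibble: `y` (um), `intensity`.
#' @export
extract_gradient_profile <- function(frame, pixel_size = 1) {
  stopifnot(is.matrix(frame))
  prof <- rowMeans(frame)
  tibble(
    y = (nrow(frame) - seq_len(nrow(frame)) + 0.5) * pixel_size,
    intensity = prof
  )
}
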