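# FRAP centroid-tracking velocimetry.
#
# A circular region is photobleached in a dextran-flooded chamber; under
# convection the dark spot drifts with the interstitial fluid while it
# refills by diffusion. The velocity estimate is the slope of the spot
# centroid against time, not a first/last displacement, so frame-level
# segmentation noise averages out.

#' Construct a FRAP image sequence
#'
#' @param frames A list of numeric matrices (row-down images) or a 3-D array
#'   `rows x cols x frames`, all frames the same size.
#' @param frame_interval Time between frames (s).
#' @param pixel_size Pixel size (um/pixel).
#' @param bleach_diameter Nominal bleached-spot diameter (um); used as the
#'   plausible-area gate in segmentation.
#' @return A `frap_sequence`.
#' @export
frap_sequence <- function(frames, frame_interval = 0.5, pixel_size = 1,
                          bleach_diameter = 30) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  }
  if (!is.list(frames) || length(frames) < 3L) {
    stop_fm("`frames` must hold at least 3 frames")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_fm("all frames must have identical dimensions")
  }
  check_number(frame_interval, "frame_interval", 0, strict = TRUE)
  check_number(pixel_size, "pixel_size", 0, strict = TRUE)
  check_number(bleach_diameter, "bleach_diameter", 0, strict = TRUE)
  structure(
    list(frames = frames, frame_interval = frame_interval,
         pixel_size = pixel_size, bleach_diameter = bleach_diameter),
    class = "frap_sequence"
  )
}

#' Segment the bleached spot in one frame
#'
#' Mirrors the crop/threshold/despeckle recipe: the frame is inverted (the
#' spot is dark), lightly Gaussian-smoothed against shot noise, cropped to a
#' window around the darkest point, thresholded with Otsu's method within
#' the crop (or a supplied threshold), despeckled with a 3x3 median filter,
#' and the largest connected component is kept. Cropping keeps the spot a
#' sizeable fraction of the thresholded region, which Otsu needs once
#' diffusive recovery has shrunk the contrast. A component whose area falls
#' outside `area_gate` times the nominal bleach-spot area marks the frame
#' invalid rather than raising an error.
#'
#' @param frame Numeric matrix (row-down image).
#' @param pixel_size um/pixel.
#' @param bleach_diameter Nominal spot diameter (um).
#' @param threshold Optional manual threshold on the inverted, rescaled
#'   frame (overrides Otsu).
#' @param area_gate Acceptable component area as multiples of the nominal
#'   spot area, default `c(0.25, 4)`.
#' @param smoothing_sigma Gaussian pre-smoothing (px); default one
#'   fifteenth of the nominal spot diameter (at least 1 px).
#' @param crop_factor Half-width of the analysis window as a multiple of
#'   the nominal spot diameter.
#' @return A list: `mask` (logical matrix), `valid`, `reason`.
#' @export
segment_bleach_spot <- function(frame, pixel_size = 1, bleach_diameter = 30,
                                threshold = NULL, area_gate = c(0.25, 4),
                                smoothing_sigma = NULL, crop_factor = 2) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  rng <- range(frame)
  empty <- matrix(FALSE, nrow(frame), ncol(frame))
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) {
    return(list(mask = empty, valid = FALSE, reason = "constant frame"))
  }
  inv <- (rng[2] - frame) / diff(rng)  # bright spot on dark background, [0,1]
  sig <- smoothing_sigma %||% max(1, bleach_diameter / 15 / pixel_size)
  inv_s <- gauss_blur_sep(inv, sig)
  # crop a window centred on the brightest (deepest-bleached) smoothed pixel
  peak <- which(inv_s == max(inv_s), arr.ind = TRUE)[1, ]
  half <- ceiling(crop_factor * bleach_diameter / pixel_size)
  rsel <- max(1, peak[1] - half):min(nrow(inv), peak[1] + half)
  csel <- max(1, peak[2] - half):min(ncol(inv), peak[2] + half)
  crop <- inv_s[rsel, csel, drop = FALSE]
  thr <- threshold %||% EBImage::otsu(as_ebimage(crop), range = c(0, 1))
  bin_crop <- despeckle3(crop > thr)
  if (!any(bin_crop)) {
    return(list(mask = empty, valid = FALSE, reason = "no foreground"))
  }
  comp <- empty
  comp[rsel, csel] <- largest_component(bin_crop)
  area_px <- sum(comp)
  nominal_px <- pi * (bleach_diameter / 2 / pixel_size)^2
  if (area_px < area_gate[1] * nominal_px || area_px > area_gate[2] * nominal_px) {
    return(list(
      mask = empty, valid = FALSE,
      reason = sprintf("component area %.0f px outside [%.0f, %.0f] px gate",
                       area_px, area_gate[1] * nominal_px,
                       area_gate[2] * nominal_px)
    ))
  }
  list(mask = comp, valid = TRUE, reason = NA_character_)
}

#' Track the bleached-spot centroid over a FRAP sequence
#'
#' Each frame is segmented with [segment_bleach_spot()]; the spot position
#' is the bleach-depth-weighted centroid of the masked pixels (weight =
#' local intensity deficit), or the plain binary centroid when
#' `weighted = FALSE`. Positions are reported in um, mathematical
#' convention (y up); invalid frames are kept in the table with
#' `valid = FALSE` and `NA` positions.
#'
#' @param seq A [frap_sequence()].
#' @param weighted Intensity-weighted centroid (default) or binary.
#' @param ... Passed to [segment_bleach_spot()].
#' @return A `frap_track` tibble: `frame`, `time`, `x`, `y`, `valid`.
#' @export
track_centroid <- function(seq, weighted = TRUE, ...) {
  stopifnot(inherits(seq, "frap_sequence"))
  n <- length(seq$frames)
  nr <- nrow(seq$frames[[1]])
  rows <- purrr::map(seq_len(n), function(k) {
    frame <- seq$frames[[k]]
    seg <- segment_bleach_spot(frame, pixel_size = seq$pixel_size,
                               bleach_diameter = seq$bleach_diameter, ...)
    t_k <- (k - 1) * seq$frame_interval
    if (!seg$valid) {
      return(tibble(frame = k, time = t_k, x = NA_real_, y = NA_real_,
                    valid = FALSE, reason = seg$reason))
    }
    idx <- which(seg$mask, arr.ind = TRUE)
    w <- if (weighted) {
      # intensity deficit relative to the frame maximum: deeper bleach,
      # larger weight
      pmax(max(frame) - frame[seg$mask], 0)
    } else {
      rep(1, nrow(idx))
    }
    if (sum(w) <= 0) w <- rep(1, nrow(idx))
    pos <- px_to_um(idx[, 1], idx[, 2], nr, seq$pixel_size)
    tibble(frame = k, time = t_k,
           x = sum(pos$x * w) / sum(w), y = sum(pos$y * w) / sum(w),
           valid = TRUE, reason = NA_character_)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("frap_track", class(out))
  out
}

#' Estimate the convective velocity from a centroid track
#'
#' Least-squares slopes of `x(t)` and `y(t)` over the valid frames give the
#' velocity components; the pooled coefficient of determination of the two
#' fits is the quality score. Directions use the mathematical convention
#' (degrees counter-clockwise from +x, in `[0, 360)`).
#'
#' @param track A `frap_track` from [track_centroid()].
#' @return A `velocity_estimate`: `speed` (um/s), `direction` (deg),
#'   `vx`, `vy`, `fit_r2`, `n_frames_used`.
#' @export
estimate_velocity <- function(track) {
  stopifnot(inherits(track, "frap_track") || is.data.frame(track))
  ok <- track[track$valid & is.finite(track$x) & is.finite(track$y), ]
  if (nrow(ok) < 3L) {
    stop_fm("velocity estimation needs >= 3 valid samples, got ", nrow(ok))
  }
  fx <- lm(x ~ time, data = ok)
  fy <- lm(y ~ time, data = ok)
  vx <- unname(coef(fx)[2])
  vy <- unname(coef(fy)[2])
  ssr <- sum(residuals(fx)^2) + sum(residuals(fy)^2)
  sst <- sum((ok$x - mean(ok$x))^2) + sum((ok$y - mean(ok$y))^2)
  r2 <- if (sst < .Machine$double.eps) 1 else max(0, min(1, 1 - ssr / sst))
  structure(
    list(
      speed = sqrt(vx^2 + vy^2),
      direction = wrap_direction(atan2(vy, vx) * 180 / pi),
      vx = vx, vy = vy, fit_r2 = r2, n_frames_used = nrow(ok)
    ),
    class = "velocity_estimate"
  )
}

#' @method tidy velocity_estimate
#' @export
tidy.velocity_estimate <- function(x, ...) {
  tibble(
    speed = x$speed, direction = x$direction, vx = x$vx, vy = x$vy,
    fit_r2 = x$fit_r2, n_frames_used = x$n_frames_used
  )
}

#' @method glance velocity_estimate
#' @export
glance.velocity_estimate <- function(x, ...) tidy(x)

#' @export
print.velocity_estimate <- function(x, ...) {
  cat(sprintf(
    "<velocity_estimate> %.3g um/s at %.1f deg (vx %.3g, vy %.3g), R2 %.3f, %d frames\n",
    x$speed, x$direction, x$vx, x$vy, x$fit_r2, x$n_frames_used))
  invisible(x)
}

#' @importFrom stats residuals
NULL
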