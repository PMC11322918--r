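# Protrusion detection and angle statistics.
#
# Automated mode: the outer radial envelope r(phi) around the centroid is
# compared against the best-fit ellipse radius; peaks of the residual with
# prominence above threshold, separated by a minimum angle, are protrusions.
# Manual mode: user-supplied tip coordinates are passed through verbatim,
# preserving the interactive click-the-tip workflow.

#' Protrusion angle from centroid to tip
#'
#' Angle of `tip - centroid` against the horizontal axis in mathematical
#' convention, folded into `[0, 180]` (an angle and its opposite direction
#' report the same value, matching the 0-180 convention of protrusion
#' histograms).
#'
#' @param centroid `(x, y)` in um.
#' @param tip `(x, y)` in um.
#' @return Angle in degrees, `[0, 180]`.
#' @examples
#' protrusion_angle(c(0, 0), c(-10, 10)) # 135
#' @export
protrusion_angle <- function(centroid, tip) {
  d <- as.numeric(tip) - as.numeric(centroid)
  if (sqrt(sum(d^2)) <= .Machine$double.eps) {
    stop_fm("tip coincides with the centroid: angle undefined")
  }
  ang <- wrap_direction(atan2(d[2], d[1]) * 180 / pi)
  if (ang > 180) ang <- ang - 180
  ang
}

#' Detect protrusions on a cyst boundary
#'
#' See the file header for the algorithm. When the contour is not
#' star-shaped around the centroid (the radial profile is multivalued), the
#' outer envelope (maximum radius per angular bin) is used and the result
#' is flagged via the `fallback` attribute.
#'
#' @param shape A [cyst_shape()].
#' @param prominence Minimum residual height above the fitted ellipse (um).
#' @param min_separation Minimum angular separation between detected
#'   protrusions (degrees).
#' @param tips Optional manual mode: an n x 2 matrix / data.frame of tip
#'   coordinates (um, math convention); detection is skipped and each tip
#'   is converted to an angle verbatim.
#' @param n_bins Angular resolution of the radial profile.
#' @param residual_smoothing Gaussian smoothing of the radial residual
#'   (degrees) before peak finding; acts as the low-pass separating
#'   protrusion-scale features from finer ruffle texture.
#' @return A tibble: `angle` (deg, `[0,180]`), `direction` (deg,
#'   `[0,360)`), `tip_x`, `tip_y` (um), `prominence` (um; `NA` in manual
#'   mode). Attribute `fallback` marks non-star-shaped contours.
#' @export
detect_protrusions <- function(shape, prominence = 5, min_separation = 20,
                               tips = NULL, n_bins = 720,
                               residual_smoothing = 4) {
  stopifnot(inherits(shape, "cyst_shape"))
  ctr <- shape$centroid
  if (!is.null(tips)) {
    tips <- as.matrix(tips)
    out <- purrr::map_dfr(seq_len(nrow(tips)), function(i) {
      tibble(
        angle = protrusion_angle(ctr, tips[i, ]),
        direction = wrap_direction(
          atan2(tips[i, 2] - ctr["y"], tips[i, 1] - ctr["x"]) * 180 / pi),
        tip_x = tips[i, 1], tip_y = tips[i, 2],
        prominence = NA_real_
      )
    })
    attr(out, "fallback") <- FALSE
    return(out)
  }

  dx <- shape$contour[, 1] - ctr["x"]
  dy <- shape$contour[, 2] - ctr["y"]
  phi <- atan2(dy, dx) %% (2 * pi)
  r <- sqrt(dx^2 + dy^2)
  bin <- pmin(floor(phi / (2 * pi) * n_bins), n_bins - 1) + 1L
  r_env <- rep(NA_real_, n_bins)
  multi <- FALSE
  for (k in seq_along(bin)) {
    b <- bin[k]
    if (is.na(r_env[b])) {
      r_env[b] <- r[k]
    } else {
      if (abs(r_env[b] - r[k]) > 0.1 * r_env[b]) multi <- TRUE
      r_env[b] <- max(r_env[b], r[k])
    }
  }
  # fill empty bins by periodic interpolation
  if (anyNA(r_env)) {
    good <- which(!is.na(r_env))
    if (length(good) < 8) stop_fm("radial profile too sparse")
    xg <- c(good - n_bins, good, good + n_bins)
    yg <- rep(r_env[good], 3)
    r_env <- approx(xg, yg, xout = seq_len(n_bins))$y
    multi <- multi || (n_bins - length(good)) > 0.1 * n_bins
  }

  # baseline: robust low-order Fourier fit of the radial profile
  # (harmonics 0-2 describe an off-centre ellipse); iterative trimming of
  # high outliers keeps the bumps themselves from inflating the baseline
  phi_bin <- (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
  X <- cbind(1, cos(phi_bin), sin(phi_bin),
             cos(2 * phi_bin), sin(2 * phi_bin))
  keep_fit <- rep(TRUE, n_bins)
  beta <- NULL
  for (it in 1:3) {
    beta <- stats::lm.fit(X[keep_fit, , drop = FALSE],
                          r_env[keep_fit])$coefficients
    res <- r_env - as.vector(X %*% beta)
    cut <- 2.5 * stats::mad(res[keep_fit], center = 0)
    keep_fit <- res <= max(cut, 1e-6)
  }
  r_base <- as.vector(X %*% beta)
  resid <- smooth_periodic(r_env - r_base,
                           sigma = n_bins / 360 * residual_smoothing)

  # periodic local maxima above the prominence threshold
  rp <- c(resid[n_bins], resid[-n_bins])
  rn <- c(resid[-1], resid[1])
  cand <- which(resid >= prominence & resid >= rp & resid >= rn)
  if (length(cand) == 0) {
    out <- tibble(angle = numeric(0), direction = numeric(0),
                  tip_x = numeric(0), tip_y = numeric(0),
                  prominence = numeric(0))
    attr(out, "fallback") <- multi
    return(out)
  }
  # greedy minimum angular separation, strongest first
  cand <- cand[order(resid[cand], decreasing = TRUE)]
  sep <- min_separation / 360 * n_bins
  keep <- integer(0)
  for (cc in cand) {
    if (all(circ_bin_dist(cc, keep, n_bins) >= sep)) keep <- c(keep, cc)
  }
  keep <- sort(keep)
  out <- purrr::map_dfr(keep, function(b) {
    ph <- phi_bin[b]
    tip <- c(ctr["x"] + r_env[b] * cos(ph), ctr["y"] + r_env[b] * sin(ph))
    tibble(
      angle = protrusion_angle(ctr, tip),
      direction = wrap_direction(ph * 180 / pi),
      tip_x = tip[1], tip_y = tip[2],
      prominence = resid[b]
    )
  })
  attr(out, "fallback") <- multi
  out
}

circ_bin_dist <- function(b, others, n_bins) {
  if (length(others) == 0) return(Inf)
  d <- abs(b - others)
  pmin(d, n_bins - d)
}

#' Histogram of protrusion angles
#'
#' Shares the binning contract of [angle_histogram()] (half-open 10-degree
#' bins over `[0, 180)`, an exact 180 wrapping to 0), and reports the
#' fraction of protrusions oriented with the fiber axis (default range
#' 70-110 degrees).
#'
#' @param angles Numeric vector of protrusion angles (deg) or the tibble
#'   from [detect_protrusions()].
#' @param bin_width Bin width (deg), divisor of 180.
#' @param range_lo,range_hi Range for the directional fraction.
#' @return A list: `histogram` (tibble as [angle_histogram()]),
#'   `fraction_in_range`, `n`, `zero_count` flag.
#' @export
protrusion_histogram <- function(angles, bin_width = 10,
                                 range_lo = 70, range_hi = 110) {
  if (is.data.frame(angles)) angles <- angles$angle
  smp <- orientation_sample(angles)
  list(
    histogram = angle_histogram(smp, bin_width = bin_width),
    fraction_in_range = fraction_in_range(smp, range_lo, range_hi),
    n = length(angles),
    zero_count = length(angles) == 0
  )
}

#' Percentage of protrusions in the top and bottom halves
#'
#' Classifies each protrusion tip against the horizontal line through the
#' cyst centroid; a tip exactly on the line counts as top (deterministic
#' tie rule). Percentages sum to 100.
#'
#' @param protrusions Tibble from [detect_protrusions()] (needs `tip_y`).
#' @param shape The [cyst_shape()] the protrusions came from.
#' @return A one-row tibble: `top_pct`, `bottom_pct`, `n_top`, `n_bottom`.
#' @export
percent_protrusions_top <- function(protrusions, shape) {
  stopifnot(inherits(shape, "cyst_shape"))
  if (nrow(protrusions) == 0) {
    stop_fm("no protrusions to classify")
  }
  top <- protrusions$tip_y >= shape$centroid["y"]
  tibble(
    top_pct = 100 * mean(top), bottom_pct = 100 * mean(!top),
    n_top = sum(top), n_bottom = sum(!top)
  )
}
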