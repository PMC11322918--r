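# Collagen fiber-orientation quantification.
#
# Local orientation comes from the image structure tensor: at fiber pixels
# the intensity gradient is perpendicular to the fiber, so the fiber angle
# is the minor-eigenvector direction of the smoothed tensor. Pixels are
# weighted by tensor coherence, the standard confidence measure for local
# anisotropy. Angle convention: degrees in [0, 180), 0 = horizontal,
# increasing counter-clockwise in mathematical coordinates.

#' Construct an orientation sample
#'
#' @param angles Angles in degrees; wrapped into `[0, 180)` (axial data).
#' @param weights Nonnegative weights (coherence, fiber length, ...).
#' @return An `orientation_sample` tibble with columns `angle`, `weight`.
#' @export
orientation_sample <- function(angles, weights = NULL) {
  if (length(angles) == 0) {
    out <- tibble(angle = numeric(0), weight = numeric(0))
  } else {
    weights <- weights %||% rep(1, length(angles))
    stopifnot(length(weights) == length(angles))
    if (any(!is.finite(angles)) || any(!is.finite(weights))) {
      stop_fm("angles and weights must be finite")
    }
    if (any(weights < 0)) stop_fm("weights must be nonnegative")
    if (sum(weights) <= 0) stop_fm("weights must not all be zero")
    out <- tibble(angle = wrap_axial(angles), weight = weights)
  }
  class(out) <- c("orientation_sample", class(out))
  out
}

#' Estimate local fiber orientations from an intensity image
#'
#' Structure-tensor orientation at fiber-containing pixels. The image is
#' pre-smoothed (`sigma_gradient`), central-difference gradients form the
#' tensor `J = [gx^2, gx*gy; gx*gy, gy^2]`, which is smoothed at the fiber
#' scale (`sigma_tensor`). Pixels whose gradient energy exceeds
#' `energy_threshold` times the mean energy contribute one angle (the minor
#' eigenvector direction, i.e. along the fiber) weighted by the tensor
#' coherence `(l1 - l2) / (l1 + l2)`.
#'
#' A featureless (constant) image yields an empty sample with a message
#' attribute rather than an error.
#'
#' @param image Numeric matrix (row-down image).
#' @param sigma_gradient Gaussian pre-smoothing scale (px).
#' @param sigma_tensor Tensor smoothing scale (px).
#' @param energy_threshold Keep pixels with gradient energy above this
#'   multiple of the image mean energy.
#' @param min_coherence Drop pixels with coherence below this value.
#' @return An [orientation_sample()]; attribute `flagged` is `TRUE` when no
#'   pixel passed the energy threshold.
#' @export
estimate_orientations <- function(image, sigma_gradient = 1.5,
                                  sigma_tensor = 4,
                                  energy_threshold = 1,
                                  min_coherence = 0.2) {
  stopifnot(is.matrix(image), is.numeric(image))
  margin <- ceiling(2 * (sigma_gradient + sigma_tensor)) + 1L
  if (nrow(image) <= 2 * margin || ncol(image) <= 2 * margin) {
    stop_fm("image smaller than the analysis window (needs > ",
            2 * margin, " px per side)")
  }
  sm <- ebi_to_matrix(EBImage::gblur(as_ebimage(image), sigma = sigma_gradient))
  nr <- nrow(sm); nc <- ncol(sm)
  gx <- matrix(0, nr, nc)  # d/dx = d/dcol
  gy <- matrix(0, nr, nc)  # d/dy in math convention = -d/drow
  gx[, 2:(nc - 1)] <- (sm[, 3:nc] - sm[, 1:(nc - 2)]) / 2
  gy[2:(nr - 1), ] <- -(sm[3:nr, ] - sm[1:(nr - 2), ]) / 2
  j11 <- ebi_to_matrix(EBImage::gblur(as_ebimage(gx * gx), sigma = sigma_tensor))
  j22 <- ebi_to_matrix(EBImage::gblur(as_ebimage(gy * gy), sigma = sigma_tensor))
  j12 <- ebi_to_matrix(EBImage::gblur(as_ebimage(gx * gy), sigma = sigma_tensor))

  energy <- j11 + j22
  keep <- matrix(FALSE, nr, nc)
  keep[(margin + 1):(nr - margin), (margin + 1):(nc - margin)] <- TRUE
  mean_energy <- mean(energy[keep])
  if (!is.finite(mean_energy) || mean_energy <= .Machine$double.eps) {
    out <- orientation_sample(numeric(0))
    attr(out, "flagged") <- TRUE
    return(out)
  }
  keep <- keep & energy > energy_threshold * mean_energy

  # Dominant eigenvector of J is the gradient direction; the fiber runs
  # perpendicular to it. 2*theta_grad = atan2(2 J12, J11 - J22).
  theta_grad <- 0.5 * atan2(2 * j12[keep], (j11 - j22)[keep])
  fiber_angle <- wrap_axial(theta_grad * 180 / pi + 90)
  coherence <- sqrt((j11 - j22)[keep]^2 + 4 * j12[keep]^2) /
    pmax(energy[keep], .Machine$double.eps)
  ok <- coherence >= min_coherence
  out <- orientation_sample(fiber_angle[ok], coherence[ok])
  attr(out, "flagged") <- !any(ok)
  out
}

#' Alignment coefficient of an axial angle sample
#'
#' The resultant length of the doubled angles:
#' `coefficient = | sum w exp(2 i theta) | / sum w`, a scalar in `[0, 1]`
#' that is 1 iff all weighted angles are equal (mod 180 deg) and 0 for a
#' balanced (e.g. uniform) orientation distribution. The mean orientation
#' is half the argument of the same resultant, wrapped to `[0, 180)`.
#'
#' @param sample An [orientation_sample()] (or anything coercible: a numeric
#'   vector of degrees).
#' @return An `alignment_result`: `coefficient`, `mean_angle`, `n`.
#' @export
alignment_coefficient <- function(sample) {
  if (!inherits(sample, "orientation_sample")) {
    sample <- orientation_sample(sample)
  }
  if (nrow(sample) == 0) {
    stop_fm("alignment coefficient of an empty orientation sample is undefined")
  }
  th2 <- 2 * sample$angle * pi / 180
  w <- sample$weight
  zr <- sum(w * cos(th2)) / sum(w)
  zi <- sum(w * sin(th2)) / sum(w)
  structure(
    list(
      coefficient = min(1, sqrt(zr^2 + zi^2)),
      mean_angle = wrap_axial(atan2(zi, zr) * 90 / pi),
      n = nrow(sample)
    ),
    class = "alignment_result"
  )
}

#' @method tidy alignment_result
#' @export
tidy.alignment_result <- function(x, ...) {
  tibble(coefficient = x$coefficient, mean_angle = x$mean_angle, n = x$n)
}

#' @method glance alignment_result
#' @export
glance.alignment_result <- function(x, ...) tidy(x)

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> coefficient %.3f, mean angle %.1f deg, n = %d\n",
              x$coefficient, x$mean_angle, x$n))
  invisible(x)
}

#' Binned histogram of axial angles
#'
#' Weight sums per half-open bin `[k*w, (k+1)*w)` over `[0, 180)`; an input
#' of exactly 180 deg wraps to 0. The bin width must divide 180.
#'
#' @param sample An [orientation_sample()] or numeric vector of degrees.
#' @param bin_width Bin width in degrees (divisor of 180).
#' @return A tibble: `bin_start`, `bin_mid`, `bin_end`, `count` (weight
#'   sum), `frequency` (normalized; 0 for an empty sample).
#' @export
angle_histogram <- function(sample, bin_width = 10) {
  if (!inherits(sample, "orientation_sample")) {
    sample <- orientation_sample(sample)
  }
  check_number(bin_width, "bin_width", 0, strict = TRUE)
  if (abs(180 / bin_width - round(180 / bin_width)) > 1e-9) {
    stop_fm("`bin_width` must divide 180 (got ", bin_width, ")")
  }
  n_bins <- as.integer(round(180 / bin_width))
  starts <- (seq_len(n_bins) - 1) * bin_width
  counts <- numeric(n_bins)
  if (nrow(sample) > 0) {
    bin <- pmin(floor(sample$angle / bin_width), n_bins - 1) + 1L
    for (k in seq_along(bin)) counts[bin[k]] <- counts[bin[k]] + sample$weight[k]
  }
  total <- sum(counts)
  tibble(
    bin_start = starts, bin_mid = starts + bin_width / 2,
    bin_end = starts + bin_width,
    count = counts,
    frequency = if (total > 0) counts / total else counts
  )
}

#' Weighted fraction of angles in an axial range
#'
#' @param sample An [orientation_sample()] or numeric vector of degrees.
#' @param lo,hi Range bounds in degrees, `0 <= lo < hi <= 180`; the range is
#'   half-open `[lo, hi)`.
#' @return Fraction in `[0, 1]` (0 for an empty sample).
#' @export
fraction_in_range <- function(sample, lo = 70, hi = 110) {
  if (!inherits(sample, "orientation_sample")) {
    sample <- orientation_sample(sample)
  }
  if (!(lo >= 0 && lo < hi && hi <= 180)) {
    stop_fm("need 0 <= lo < hi <= 180 (got ", lo, ", ", hi, ")")
  }
  if (nrow(sample) == 0) return(0)
  inside <- sample$angle >= lo & sample$angle < hi
  sum(sample$weight[inside]) / sum(sample$weight)
}
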