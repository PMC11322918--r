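# Cyst/organoid shape: mask -> contour -> ellipse-fit metrics.
#
# Masks are row-down binary matrices; contours, centroids and every
# reported angle are converted once to mathematical coordinates (um, y up,
# angles counter-clockwise from +x).

#' Build a cyst shape from a binary mask
#'
#' Keeps the largest connected component, fills holes (a cyst projection is
#' a filled blob even when the lumen images dark), traces the boundary, and
#' converts everything to um in mathematical coordinates.
#'
#' @param mask Logical or 0/1 matrix (row-down image).
#' @param pixel_size um/pixel.
#' @return A `cyst_shape`: `mask`, `pixel_size`, `contour` (n x 2 matrix of
#'   x, y in um, ordered along the boundary), `centroid` (x, y um),
#'   `area_px`.
#' @export
cyst_shape <- function(mask, pixel_size = 1) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  if (!any(mask)) stop_fm("empty mask: no foreground pixels")
  check_number(pixel_size, "pixel_size", 0, strict = TRUE)
  lab <- EBImage::bwlabel(as_ebimage(mask * 1))
  filled <- EBImage::fillHull(lab)
  labm <- ebi_to_matrix(filled)
  sizes <- tabulate(labm[labm > 0])
  keep <- which.max(sizes)
  comp <- labm == keep
  oc <- EBImage::ocontour(EBImage::bwlabel(as_ebimage(comp * 1)))[[1]]
  nr <- nrow(mask)
  # ocontour is 0-based in (x = col - 1, y = row - 1)
  contour <- cbind(
    x = (oc[, 1] + 0.5) * pixel_size,
    y = (nr - oc[, 2] - 0.5) * pixel_size
  )
  idx <- which(comp, arr.ind = TRUE)
  pos <- px_to_um(idx[, 1], idx[, 2], nr, pixel_size)
  structure(
    list(
      mask = comp, pixel_size = pixel_size, contour = contour,
      centroid = c(x = mean(pos$x), y = mean(pos$y)),
      area_px = sum(comp)
    ),
    class = "cyst_shape"
  )
}

#' Binarize a fluorescence z-projection into a cyst shape
#'
#' Otsu threshold on the rescaled intensity image, hole fill, largest
#' component, boundary extraction.
#'
#' @param image Numeric matrix (row-down intensity image).
#' @param pixel_size um/pixel.
#' @param threshold Optional manual threshold on the rescaled image.
#' @return A [cyst_shape()].
#' @export
binarize_projection <- function(image, pixel_size = 1, threshold = NULL) {
  stopifnot(is.matrix(image), is.numeric(image))
  rng <- range(image)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) {
    stop_fm("constant image: nothing to segment")
  }
  sc <- (image - rng[1]) / diff(rng)
  thr <- threshold %||% EBImage::otsu(as_ebimage(sc), range = c(0, 1))
  mask <- sc > thr
  if (!any(mask)) stop_fm("no foreground after thresholding")
  cyst_shape(mask, pixel_size)
}

#' Shape metrics of a cyst
#'
#' Standard ellipse-fit morphometrics: the best-fit ellipse comes from the
#' second central moments of the mask (semi-axes `a = 2 sqrt(l1)`,
#' `b = 2 sqrt(l2)` from the covariance eigenvalues, exact for a true
#' ellipse). Then `aspect_ratio = major/minor`, `roundness = 4 A / (pi *
#' major_axis^2)` (the inverse aspect ratio for an ellipse),
#' `shape_factor = 4 pi A / P^2` (circularity: 1 for a circle, lower for a
#' ruffled boundary), and `orientation_angle` is the major-axis angle in
#' `[0, 180)`.
#'
#' @param shape A [cyst_shape()].
#' @param smoothing Contour smoothing (um) for the perimeter measurement;
#'   suppresses pixel staircase overestimation.
#' @return A one-row tibble: `area` (um^2), `perimeter` (um),
#'   `aspect_ratio`, `roundness`, `shape_factor`, `orientation_angle`
#'   (deg), `major_axis`, `minor_axis` (um), `centroid_x`, `centroid_y`.
#' @export
shape_metrics <- function(shape, smoothing = 2) {
  stopifnot(inherits(shape, "cyst_shape"))
  px <- shape$pixel_size
  area <- shape$area_px * px^2

  idx <- which(shape$mask, arr.ind = TRUE)
  pos <- px_to_um(idx[, 1], idx[, 2], nrow(shape$mask), px)
  xc <- pos$x - mean(pos$x); yc <- pos$y - mean(pos$y)
  # add the pixel's own second moment (px^2/12) so a 1-px-wide shape has
  # nonzero width
  cov <- matrix(c(mean(xc^2) + px^2 / 12, mean(xc * yc),
                  mean(xc * yc), mean(yc^2) + px^2 / 12), 2, 2)
  eig <- eigen(cov, symmetric = TRUE)
  a <- 2 * sqrt(eig$values[1])   # semi-major
  b <- 2 * sqrt(eig$values[2])   # semi-minor
  orient <- wrap_axial(atan2(eig$vectors[2, 1], eig$vectors[1, 1]) * 180 / pi)

  per <- contour_perimeter(shape$contour, smoothing = smoothing)

  tibble(
    area = area, perimeter = per,
    aspect_ratio = a / b,
    roundness = 4 * area / (pi * (2 * a)^2),
    shape_factor = 4 * pi * area / per^2,
    orientation_angle = orient,
    major_axis = 2 * a, minor_axis = 2 * b,
    centroid_x = unname(shape$centroid["x"]),
    centroid_y = unname(shape$centroid["y"])
  )
}

# Perimeter of a closed pixel contour: resample + Gaussian smoothing to
# remove the staircase bias of the 8-connected boundary chain.
contour_perimeter <- function(contour, smoothing = 2, n_samples = 512) {
  rs <- resample_closed(contour, n_samples)
  sm <- cbind(
    smooth_periodic(rs[, 1], smoothing / attr(rs, "ds")),
    smooth_periodic(rs[, 2], smoothing / attr(rs, "ds"))
  )
  d <- sqrt(diff(c(sm[, 1], sm[1, 1]))^2 + diff(c(sm[, 2], sm[1, 2]))^2)
  sum(d)
}

#' @export
print.cyst_shape <- function(x, ...) {
  cat(sprintf("<cyst_shape> %d px foreground, centroid (%.1f, %.1f) um, %d contour points\n",
              x$area_px, x$centroid["x"], x$centroid["y"], nrow(x$contour)))
  invisible(x)
}

#' @method tidy cyst_shape
#' @export
tidy.cyst_shape <- function(x, ...) {
  ct <- x$contour
  tibble(x = ct[, 1], y = ct[, 2])
}
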