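# Cyst morphometrics: binarization, ellipse-fit metrics, protrusions,
# contour splitting, and curvature.

test_that("binarization recovers a bright ellipse with high overlap", {
  g <- gen_cyst_mask(seed = 3, semi_major = 60, semi_minor = 40)
  img <- 0.1 + 0.8 * g$mask +
    fluidmorph:::with_seed(9, matrix(rnorm(length(g$mask), sd = 0.05),
                                     nrow(g$mask)))
  shape <- binarize_projection(img, pixel_size = 1)
  jac <- sum(shape$mask & g$mask) / sum(shape$mask | g$mask)
  expect_gt(jac, 0.97)
  expect_error(binarize_projection(matrix(0, 64, 64)), "constant")
})

test_that("with two blobs the larger is retained", {
  m <- disk_mask(200, 200, 60, 60, 40) | disk_mask(200, 200, 150, 150, 12)
  shape <- cyst_shape(m, 1)
  expect_true(abs(shape$area_px - sum(disk_mask(200, 200, 60, 60, 40))) < 5)
  expect_lt(abs(shape$centroid["x"] - 59.5), 1)
})

test_that("circle closed forms: AR = roundness = shape factor = 1", {
  g <- gen_cyst_mask(seed = 1, semi_major = 50, semi_minor = 50)
  m <- shape_metrics(cyst_shape(g$mask, 1))
  expect_equal(m$aspect_ratio, 1, tolerance = 0.02)
  expect_equal(m$roundness, 1, tolerance = 0.02)
  expect_equal(m$shape_factor, 1, tolerance = 0.02)
  expect_equal(m$area, pi * 50^2, tolerance = 0.02)
  expect_equal(m$perimeter, 2 * pi * 50, tolerance = 0.02)
})

test_that("2:1 ellipse: AR = 2, roundness = 0.5, orientation follows the axis", {
  g <- gen_cyst_mask(seed = 2, semi_major = 100, semi_minor = 50,
                     image_size = 300)
  m <- shape_metrics(cyst_shape(g$mask, 1))
  expect_equal(m$aspect_ratio, 2, tolerance = 0.02)
  expect_equal(m$roundness, 0.5, tolerance = 0.02)
  expect_lt(ang_diff(m$orientation_angle, 0, period = 180), 1)
  g90 <- gen_cyst_mask(seed = 2, semi_major = 80, semi_minor = 40,
                       orientation = 90, image_size = 300)
  m90 <- shape_metrics(cyst_shape(g90$mask, 1))
  expect_lt(ang_diff(m90$orientation_angle, 90, period = 180), 1)
})

test_that("metrics are scale-equivariant", {
  g1 <- gen_cyst_mask(seed = 5, semi_major = 40, semi_minor = 30,
                      image_size = 128)
  g2 <- gen_cyst_mask(seed = 5, semi_major = 80, semi_minor = 60,
                      image_size = 256)
  m1 <- shape_metrics(cyst_shape(g1$mask, 1))
  m2 <- shape_metrics(cyst_shape(g2$mask, 1))
  expect_equal(m2$area / m1$area, 4, tolerance = 0.02)
  expect_equal(m2$perimeter / m1$perimeter, 2, tolerance = 0.02)
  expect_equal(m2$aspect_ratio, m1$aspect_ratio, tolerance = 0.02)
  expect_equal(m2$roundness, m1$roundness, tolerance = 0.02)
  expect_equal(m2$shape_factor, m1$shape_factor, tolerance = 0.02)
  k1 <- mean_curvature(contour_curvature(cyst_shape(g1$mask, 1)))
  k2 <- mean_curvature(contour_curvature(cyst_shape(g2$mask, 1)))
  expect_equal(k1 / k2, 2, tolerance = 0.03)
})

test_that("rotating a shape shifts orientation and protrusion angles by the same delta", {
  measure <- function(rot) {
    g <- gen_cyst_mask(seed = 6, semi_major = 70, semi_minor = 45,
                       orientation = 20 + rot, image_size = 256,
                       protrusions = data.frame(angle = 35 + rot,
                                                prominence = 14, width = 12))
    sh <- cyst_shape(g$mask, 1)
    pr <- detect_protrusions(sh, prominence = 6)
    expect_gte(nrow(pr), 1)
    list(orient = shape_metrics(sh)$orientation_angle,
         dir = pr$direction[which.max(pr$prominence)])
  }
  ref <- measure(0)
  for (delta in c(30, 60)) {
    m <- measure(delta)
    expect_lt(ang_diff(m$orient, ref$orient + delta, period = 180), 2)
    expect_lt(ang_diff(m$dir, ref$dir + delta), 2)
  }
})

test_that("protrusion angle geometry follows atan2 with 0-180 folding", {
  expect_equal(protrusion_angle(c(0, 0), c(10, 0)), 0)
  expect_equal(protrusion_angle(c(0, 0), c(0, 10)), 90)
  expect_equal(protrusion_angle(c(0, 0), c(-10, 10)), 135)
  # folding: pointing down-right reports the axial angle
  expect_equal(protrusion_angle(c(0, 0), c(0, -10)), 90)
  expect_error(protrusion_angle(c(1, 1), c(1, 1)), "centroid")
})

test_that("protrusion detection finds planted bumps and nothing on ellipses", {
  g0 <- gen_cyst_mask(seed = 7, semi_major = 60, semi_minor = 45)
  pr0 <- detect_protrusions(cyst_shape(g0$mask, 1), prominence = 5)
  expect_identical(nrow(pr0), 0L)

  g2 <- gen_cyst_mask(seed = 8, semi_major = 50, semi_minor = 50,
                      protrusions = data.frame(angle = c(30, 120),
                                               prominence = 15, width = 12))
  pr2 <- detect_protrusions(cyst_shape(g2$mask, 1), prominence = 5)
  expect_identical(nrow(pr2), 2L)
  expect_lt(ang_diff(sort(pr2$direction)[1], 30), 5)
  expect_lt(ang_diff(sort(pr2$direction)[2], 120), 5)
})

test_that("manual tips pass through to exact protrusion angles", {
  g <- gen_cyst_mask(seed = 9, semi_major = 50, semi_minor = 50)
  sh <- cyst_shape(g$mask, 1)
  tips <- rbind(sh$centroid + c(40, 0), sh$centroid + c(0, 45),
                sh$centroid + c(-30, 30))
  pr <- detect_protrusions(sh, tips = tips)
  expect_equal(pr$angle, c(0, 90, 135), tolerance = 1e-9)
  expect_true(all(is.na(pr$prominence)))
})

test_that("protrusion histogram shares the axial binning contract", {
  ph <- protrusion_histogram(c(75, 85, 175))
  expect_equal(ph$histogram$count[ph$histogram$bin_start == 70], 1)
  expect_equal(ph$histogram$count[ph$histogram$bin_start == 80], 1)
  expect_equal(ph$histogram$count[ph$histogram$bin_start == 170], 1)
  ph0 <- protrusion_histogram(numeric(0))
  expect_true(ph0$zero_count)
  expect_identical(ph0$fraction_in_range, 0)
  set.seed(3)
  phu <- protrusion_histogram(runif(1000, 0, 180))
  expect_lt(abs(phu$fraction_in_range - 40 / 180), 0.03)
})

test_that("percent-protrusions-top classifies tips with the top tie rule", {
  g <- gen_cyst_mask(seed = 10, semi_major = 50, semi_minor = 50)
  sh <- cyst_shape(g$mask, 1)
  cy <- sh$centroid["y"]
  pr <- tibble::tibble(
    angle = c(10, 20, 30, 40), direction = c(10, 20, 30, 220),
    tip_x = sh$centroid["x"] + c(10, 10, -10, -10),
    tip_y = c(cy + 5, cy + 3, cy + 8, cy - 5), prominence = 1
  )
  pct <- percent_protrusions_top(pr, sh)
  expect_equal(pct$top_pct, 75)
  expect_equal(pct$bottom_pct, 25)
  # a tip exactly on the line counts as top
  pr$tip_y[4] <- cy
  expect_equal(percent_protrusions_top(pr, sh)$top_pct, 100)
  expect_error(percent_protrusions_top(pr[0, ], sh), "no protrusions")
})

test_that("splitting a circle gives equal-arc halves; translation invariance", {
  g <- gen_cyst_mask(seed = 11, semi_major = 50, semi_minor = 50)
  sh <- cyst_shape(g$mask, 1)
  halves <- split_top_bottom(sh)
  expect_lt(abs(halves$top$arc_length - halves$bottom$arc_length) /
              halves$bottom$arc_length, 0.01)
  # translate the mask down 20 px: identical halves after translation
  m2 <- rbind(matrix(FALSE, 20, ncol(g$mask)),
              g$mask[seq_len(nrow(g$mask) - 20), ])
  h2 <- split_top_bottom(cyst_shape(m2, 1))
  expect_equal(h2$top$arc_length, halves$top$arc_length, tolerance = 1e-6)
})

test_that("top-only ruffling lengthens the top arc", {
  g <- gen_cyst_mask(seed = 12, semi_major = 55, semi_minor = 45,
                     ruffle_amplitude_top = 8, ruffle_amplitude_bottom = 0)
  halves <- split_top_bottom(cyst_shape(g$mask, 1))
  expect_gt(halves$top$arc_length, halves$bottom$arc_length)
})

test_that("curvature closed forms: circle 1/r, straight line zero", {
  g <- gen_cyst_mask(seed = 13, semi_major = 50, semi_minor = 50)
  prof <- contour_curvature(cyst_shape(g$mask, 1))
  expect_equal(mean_curvature(prof), 0.02, tolerance = 0.03)
  expect_equal(abs(attr(prof, "total_turning")), 2 * pi, tolerance = 0.01)
  # nearly-straight open segment -> zero curvature, flagged
  seg <- cbind(seq(0, 100, length.out = 50), rep(1, 50))
  pseg <- contour_curvature(seg, closed = FALSE)
  expect_true(attr(pseg, "degenerate"))
  expect_equal(mean_curvature(pseg), 0)
  expect_error(contour_curvature(seg[1:5, ]), "7 points")
})

test_that("sine-perturbed circle matches the dense polar-curve oracle", {
  R <- 50; a <- 5; m <- 7
  n <- 3000
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- R + a * sin(m * phi)
  curve <- cbind(r * cos(phi), r * sin(phi))
  prof <- contour_curvature(curve, closed = TRUE, smoothing = 1)
  oracle <- polar_curve_mean_curvature(function(p) R + a * sin(m * p))
  expect_equal(mean_curvature(prof), oracle, tolerance = 0.05)
})

test_that("curvature ratio: circle near 1, swap gives the reciprocal", {
  g <- gen_cyst_mask(seed = 14, semi_major = 50, semi_minor = 50)
  sh <- cyst_shape(g$mask, 1)
  halves <- split_top_bottom(sh)
  cr <- curvature_ratio(halves$top, halves$bottom)
  expect_equal(cr$ratio, 1, tolerance = 0.05)
  cr_swap <- curvature_ratio(halves$bottom, halves$top)
  expect_equal(cr_swap$ratio, 1 / cr$ratio, tolerance = 1e-9)
})

test_that("a degenerate bottom reports an undefined ratio", {
  seg <- cbind(seq(0, 100, length.out = 60), rep(0, 60))
  flat <- contour_curvature(seg, closed = FALSE)
  g <- gen_cyst_mask(seed = 15, semi_major = 50, semi_minor = 50)
  round_prof <- contour_curvature(cyst_shape(g$mask, 1))
  cr <- curvature_ratio(round_prof, flat)
  expect_true(cr$undefined)
  expect_true(is.na(cr$ratio))
})
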