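# Shared internal helpers: argument checking, angle arithmetic, and the
# image coordinate convention.
#
# Images are stored as base matrices m[row, col], row 1 = top of the image.
# All *reported* angles and positions use mathematical convention: x to the
# right, y up, angles counter-clockwise from +x. The conversion happens in
# exactly one place (px_to_um / angle_image_to_math) so the row-down origin
# never leaks into user-facing numbers.

stop_fm <- function(..., class = "fluidmorph_error") {
  rlang::abort(paste0(...), class = class)
}

check_number <- function(x, name, min = -Inf, strict = FALSE, finite = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (!finite || is.finite(x)) && (if (strict) x > min else x >= min)
  if (!ok) {
    stop_fm(sprintf(
      "`%s` must be a single %s number %s %s (got: %s)",
      name, if (finite) "finite" else "", if (strict) ">" else ">=", min,
      paste(format(x), collapse = ", ")
    ))
  }
  invisible(x)
}

# Wrap angles (degrees) into [0, 180) -- axial data identify theta and theta+180.
wrap_axial <- function(deg) {
  out <- deg %% 180
  out[out < 0] <- out[out < 0] + 180
  out
}

# Wrap directional angles (degrees) into [0, 360).
wrap_direction <- function(deg) {
  out <- deg %% 360
  out[out < 0] <- out[out < 0] + 360
  out
}

# Convert a pixel (row, col) centre to physical (x, y) in um, math convention.
px_to_um <- function(row, col, nrow_img, pixel_size) {
  list(
    x = (col - 0.5) * pixel_size,
    y = (nrow_img - row + 0.5) * pixel_size
  )
}

# EBImage wants dim 1 = x (columns); our matrices are [row, col].
as_ebimage <- function(m) EBImage::Image(t(m))

ebi_to_matrix <- function(img) t(EBImage::imageData(img))

# Separable Gaussian blur with edge replication, FFT-based down the
# columns of the (padded) matrix via mvfft; two passes + transposes give
# the 2-D blur. Much lighter than an EBImage round trip for small frames
# in tight loops.
gauss_blur_sep <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  blur_cols <- function(mm) {
    nr <- nrow(mm)
    ext <- rbind(mm[half:1L, , drop = FALSE], mm,
                 mm[nr:(nr - half + 1L), , drop = FALSE])
    n2 <- nrow(ext)
    kvec <- numeric(n2)
    kvec[1:(half + 1L)] <- kern[(half + 1L):(2L * half + 1L)]
    kvec[(n2 - half + 1L):n2] <- kern[1:half]
    out <- Re(stats::mvfft(stats::mvfft(ext) * stats::fft(kvec),
                           inverse = TRUE)) / n2
    out[(half + 1L):(half + nr), , drop = FALSE]
  }
  t(blur_cols(t(blur_cols(m))))
}

# 3x3 median despeckle of a binary mask = majority vote over the
# neighbourhood (edge-padded with zeros), vectorized via shifted sums.
despeckle3 <- function(mask) {
  m <- mask * 1
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  acc <- matrix(0, nr, nc)
  for (dr in 0:2) {
    for (dc in 0:2) {
      acc <- acc + p[(1L + dr):(nr + dr), (1L + dc):(nc + dc)]
    }
  }
  acc >= 5
}

# Largest connected foreground component of a logical matrix.
largest_component <- function(mask) {
  lab <- EBImage::bwlabel(as_ebimage(mask * 1))
  labm <- ebi_to_matrix(lab)
  if (max(labm) < 1) {
    return(matrix(FALSE, nrow(mask), ncol(mask)))
  }
  sizes <- tabulate(labm[labm > 0])
  labm == which.max(sizes)
}

# Seeded evaluation that restores the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
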