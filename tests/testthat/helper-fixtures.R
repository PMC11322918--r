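# Shared fixtures and small independent oracles, all built in code.

# A frame with a dark disk on a bright background (row-down matrix).
make_disk_frame <- function(nr = 128, nc = 128, row = nr / 2, col = nc / 2,
                            radius = 15, bg = 1, depth = 0.8) {
  rr <- outer(seq_len(nr), rep(1, nc))
  cc <- outer(rep(1, nr), seq_len(nc))
  d2 <- (rr - row)^2 + (cc - col)^2
  bg - depth * (d2 <= radius^2)
}

disk_mask <- function(nr, nc, row, col, radius) {
  rr <- outer(seq_len(nr), rep(1, nc))
  cc <- outer(rep(1, nr), seq_len(nc))
  (rr - row)^2 + (cc - col)^2 <= radius^2
}

# Smallest absolute difference between two directions (degrees, mod `period`).
ang_diff <- function(a, b, period = 360) {
  d <- (a - b) %% period
  pmin(d, period - d)
}

# Independent curvature oracle for a polar curve r(phi), densely sampled:
# kappa = (r^2 + 2 r'^2 - r r'') / (r^2 + r'^2)^(3/2), derivatives by
# spectral differentiation would be overkill -- use dense finite differences.
polar_curve_mean_curvature <- function(r_fun, n = 200000L) {
  phi <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- r_fun(phi)
  dphi <- 2 * pi / n
  ip <- c(2:n, 1L); im <- c(n, 1:(n - 1L))
  rp <- (r[ip] - r[im]) / (2 * dphi)
  rpp <- (r[ip] - 2 * r + r[im]) / dphi^2
  kap <- (r^2 + 2 * rp^2 - r * rpp) / (r^2 + rp^2)^1.5
  # mean over arc length (uniform-phi samples weighted by ds = sqrt(r^2+r'^2))
  w <- sqrt(r^2 + rp^2)
  sum(abs(kap) * w) / sum(w)
}

# Rotate a row-down image 90 degrees (content rotation; dims swap).
rot90_img <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# Greedy protrusion matching against truth directions (degrees, mod 360).
match_protrusions <- function(true_dirs, est_dirs, tol = 20) {
  used <- rep(FALSE, length(est_dirs))
  err <- numeric(0)
  tp <- 0L
  for (td in true_dirs) {
    if (!any(!used)) break
    cand <- which(!used)
    d <- ang_diff(est_dirs[cand], td)
    j <- cand[which.min(d)]
    if (min(d) <= tol) {
      used[j] <- TRUE
      tp <- tp + 1L
      err <- c(err, min(d))
    }
  }
  list(tp = tp, fp = sum(!used), fn = length(true_dirs) - tp, err = err)
}

# Random protrusion directions with a minimum pairwise circular separation.
sample_separated_dirs <- function(n, min_sep = 40) {
  out <- numeric(0)
  while (length(out) < n) {
    cand <- stats::runif(1, 0, 360)
    if (all(ang_diff(cand, out) >= min_sep)) out <- c(out, cand)
  }
  out
}
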