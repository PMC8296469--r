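# grid fixtures built in code

iso_header <- function(n = 16, spacing = 2.5) {
  grid_header(c(n, n, n), origin = c(0, 0, 0), spacing = rep(spacing, 3))
}

# smooth random dose field: white noise blurred to a clinically plausible
# correlation length, scaled to a 70-Gy-ish range
random_smooth_dose <- function(header, seed, sigma_mm = 6, max_gy = 70) {
  set.seed(seed)
  arr <- array(stats::runif(prod(header$dims)), dim = header$dims)
  sm <- doseQA:::gauss_smooth3(arr, sigma_mm, header$spacing)
  vals <- as.vector(sm)
  vals <- vals / max(vals) * max_gy
  dose_grid(header, vals)
}

random_mask <- function(header, seed, p = 0.3) {
  set.seed(seed)
  voxel_mask(header, stats::runif(prod(header$dims)) < p)
}

# slow, direct even-odd point-in-polygon check (one point at a time)
pip_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-edge check
    dx <- xj - xi; dy <- yj - yi
    L2 <- dx * dx + dy * dy
    if (L2 > 0) {
      t <- ((px - xi) * dx + (py - yi) * dy) / L2
      t <- min(max(t, 0), 1)
      if ((xi + t * dx - px)^2 + (yi + t * dy - py)^2 < 1e-18) return(TRUE)
    }
    if ((yi > py) != (yj > py)) {
      xin <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xin) inside <- !inside
    }
    j <- i
  }
  inside
}

# naive sort-based DVH oracle
dvh_oracle <- function(doses, vox_cc, v_levels, d_levels) {
  n <- length(doses)
  sorted <- sort(doses, decreasing = TRUE)
  list(d_max = max(doses),
       d_mean = sum(doses) / n,
       v_cc = vapply(v_levels, function(x) sum(doses >= x) * vox_cc, numeric(1)),
       v_pct = vapply(v_levels, function(x) 100 * sum(doses >= x) / n, numeric(1)),
       d_gy = vapply(d_levels, function(p) sorted[min(max(ceiling(p / 100 * n), 1), n)],
                     numeric(1)))
}
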