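test_that("identical dose pairs give gamma 0 and 100% passing", {
  h <- iso_header(10)
  ref <- random_smooth_dose(h, 1)
  g <- compute_gamma(ref, ref)
  expect_equal(g$passing_rate_pct, 100)
  expect_equal(max(g$gamma_map, na.rm = TRUE), 0)
})

test_that("a uniform scaling at exactly the dose criterion passes on the boundary", {
  h <- iso_header(10)
  ref <- random_smooth_dose(h, 2)
  ev <- dose_grid(h, ref$values * 1.03)
  g <- compute_gamma(ref, ev, gamma_criteria(3, 2))
  expect_equal(g$passing_rate_pct, 100)
})

test_that("a flat field 5% high has gamma 5/3 everywhere and 0% passing", {
  h <- iso_header(8)
  ref <- dose_grid(h, rep(50, 512))
  ev <- dose_grid(h, rep(52.5, 512))
  g <- compute_gamma(ref, ev, gamma_criteria(3, 2, 10))
  expect_equal(g$passing_rate_pct, 0)
  expect_equal(unique(round(g$gamma_map, 12)), round(5 / 3, 12))
  expect_equal(g$analyzed_count, 512)
})

test_that("pruned engine and exhaustive oracle agree bitwise", {
  h <- iso_header(12)
  for (seed in 1:4) {
    ref <- random_smooth_dose(h, seed)
    set.seed(seed + 100)
    ev <- dose_grid(h, pmax(ref$values * (1 + rnorm(1728, 0, 0.03)), 0))
    crit <- gamma_criteria(3, 2, 10, search_cap_mm = 3)
    gf <- compute_gamma(ref, ev, crit)
    gb <- gamma_bruteforce(ref, ev, crit)
    expect_lte(max(abs(gf$gamma_map - gb$gamma_map), na.rm = TRUE), 1e-9)
    expect_equal(gf$passing_rate_pct, gb$passing_rate_pct)
  }
})

test_that("a dose ramp shifted by exactly one DTA passes everywhere", {
  # ref(x) linear in x; eval shifted +2 mm along x => matching dose at 2 mm
  h <- grid_header(c(20, 6, 6), origin = c(0, 0, 0), spacing = c(2, 2.5, 2.5))
  x <- h$origin[1] + (0:19) * 2
  ramp <- function(xv) 40 + 0.8 * xv
  ref_vals <- as.vector(array(rep(ramp(x), 36), dim = c(20, 6, 6)))
  ev_vals <- as.vector(array(rep(ramp(x - 2), 36), dim = c(20, 6, 6)))
  ref <- dose_grid(h, ref_vals)
  ev <- dose_grid(h, ev_vals)
  crit <- gamma_criteria(3, 2, 10)
  gf <- compute_gamma(ref, ev, crit)
  gb <- gamma_bruteforce(ref, ev, crit)
  expect_true(all(gf$gamma_map <= 1 + 1e-9, na.rm = TRUE))
  expect_lte(max(abs(gf$gamma_map - gb$gamma_map), na.rm = TRUE), 1e-9)
})

test_that("gamma is invariant under a common dose rescaling", {
  h <- iso_header(10)
  ref <- random_smooth_dose(h, 5)
  set.seed(55)
  ev <- dose_grid(h, pmax(ref$values * (1 + rnorm(1000, 0, 0.03)), 0))
  g1 <- compute_gamma(ref, ev)
  for (k in c(0.25, 3.7)) {
    g2 <- compute_gamma(dose_grid(h, k * ref$values), dose_grid(h, k * ev$values))
    expect_equal(g2$gamma_map, g1$gamma_map, tolerance = 1e-9)
    expect_equal(g2$passing_rate_pct, g1$passing_rate_pct)
    expect_equal(g2$analyzed_count, g1$analyzed_count)
  }
})

test_that("loosening either criterion never lowers the passing rate", {
  h <- iso_header(12)
  for (seed in 6:8) {
    ref <- random_smooth_dose(h, seed)
    set.seed(seed + 200)
    ev <- dose_grid(h, pmax(ref$values * (1 + rnorm(1728, 0, 0.04)), 0))
    p22 <- compute_gamma(ref, ev, gamma_criteria(2, 2))$passing_rate_pct
    p32 <- compute_gamma(ref, ev, gamma_criteria(3, 2))$passing_rate_pct
    p33 <- compute_gamma(ref, ev, gamma_criteria(3, 3))$passing_rate_pct
    expect_lte(p22, p32)
    expect_lte(p32, p33)
  }
})

test_that("disjoint ROI analysis decomposes the whole-grid result", {
  h <- iso_header(10)
  ref <- random_smooth_dose(h, 9)
  set.seed(99)
  ev <- dose_grid(h, pmax(ref$values * (1 + rnorm(1000, 0, 0.03)), 0))
  a <- random_mask(h, 10, 0.4)
  b <- combine_masks(voxel_mask(h, !a$flags), random_mask(h, 11, 0.6), "intersect")
  ga <- compute_gamma(ref, ev, roi = a)
  gb <- compute_gamma(ref, ev, roi = b)
  gu <- compute_gamma(ref, ev, roi = combine_masks(a, b, "union"))
  expect_equal(ga$analyzed_count + gb$analyzed_count, gu$analyzed_count)
  expect_equal((ga$passing_rate_pct * ga$analyzed_count +
                  gb$passing_rate_pct * gb$analyzed_count) / gu$analyzed_count,
               gu$passing_rate_pct)
  # re-scoring an existing map equals a direct ROI evaluation
  g_all <- compute_gamma(ref, ev)
  expect_equal(gamma_rate_in_mask(g_all, a)$passing_rate_pct, ga$passing_rate_pct)
})

test_that("gamma is not symmetric in reference and evaluated", {
  h <- iso_header(8)
  set.seed(13)
  base <- random_smooth_dose(h, 13)
  ev <- dose_grid(h, base$values * 1.05)
  fwd <- compute_gamma(base, ev)
  rev <- compute_gamma(ev, base)
  # normalization and suppression follow the reference, so rates differ
  expect_false(isTRUE(all.equal(fwd$gamma_map, rev$gamma_map)))
})

test_that("suppression removes voxels from the denominator and can empty the ROI", {
  h <- grid_header(c(4, 4, 2), spacing = c(2.5, 2.5, 2.5))
  vals <- c(rep(100, 16), rep(1, 16))  # second slice below 10% of max
  ref <- dose_grid(h, vals)
  g <- compute_gamma(ref, ref)
  expect_equal(g$analyzed_count, 16)
  low_roi <- voxel_mask(h, rep(c(FALSE, TRUE), each = 16))
  expect_error(compute_gamma(ref, ref, roi = low_roi), "suppression")
})

test_that("geometry and size guards reject invalid input", {
  h <- iso_header(8)
  h2 <- grid_header(c(8, 8, 8), origin = c(0, 0, 1))
  ref <- random_smooth_dose(h, 20)
  expect_error(compute_gamma(ref, dose_grid(h2, ref$values)), "geometry error")
  big <- grid_header(c(33, 33, 33))
  expect_error(gamma_bruteforce(dose_grid(big, rep(1, 33^3)),
                                dose_grid(big, rep(1, 33^3))), "size error")
  expect_error(gamma_criteria(dose_diff_pct = -1), "> 0")
  expect_error(gamma_criteria(search_cap_mm = 1), "at least")
})

test_that("gamma maps export as DGRID with -1 marking unscored voxels", {
  h <- grid_header(c(4, 4, 1), spacing = c(2.5, 2.5, 2.5))
  vals <- c(rep(50, 8), rep(0.1, 8))
  g <- compute_gamma(dose_grid(h, vals), dose_grid(h, vals))
  path <- withr::local_tempfile(fileext = ".dgrid")
  write_gamma_map(g, path)
  txt <- readLines(path)
  payload <- as.numeric(unlist(strsplit(paste(txt[-(1:5)], collapse = " "), " +")))
  expect_equal(sum(payload == -1), 8)
  expect_equal(sum(payload == 0), 8)
})
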