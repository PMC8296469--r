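test_that("rasterization sets exactly the voxel centres inside the polygon", {
  # centres at 1.25, 3.75, 6.25, 8.75 (+margins) against a (0,0)-(10,10) square
  h <- grid_header(c(6, 6, 1), origin = c(-1.25, -1.25, 0), spacing = c(2.5, 2.5, 2.5))
  sq <- contour_set(list(PGTVnx = list(list(z = 0, xy = rbind(c(0, 0), c(10, 0),
                                                              c(10, 10), c(0, 10))))))
  m <- rasterize_contours(sq, "PGTVnx", h)
  expect_equal(sum(m$flags), 16)

  tiny <- contour_set(list(dot = list(list(z = 0, xy = rbind(c(5, 5), c(5.5, 5),
                                                             c(5.25, 5.6))))))
  expect_equal(sum(rasterize_contours(tiny, "dot", h)$flags), 0)
})

test_that("rasterization matches a brute-force even-odd oracle on a concave polygon", {
  h <- grid_header(c(12, 12, 1), origin = c(0, 0, 0), spacing = c(2.5, 2.5, 2.5))
  set.seed(11)
  # star-like concave polygon
  theta <- seq(0, 2 * pi, length.out = 13)[-13]
  r <- ifelse(seq_along(theta) %% 2 == 0, 13, 6) + runif(12, -1, 1)
  poly <- cbind(14 + r * cos(theta), 14 + r * sin(theta))
  cs <- contour_set(list(star = list(list(z = 0, xy = poly))))
  m <- rasterize_contours(cs, "star", h)
  xc <- h$origin[1] + (0:11) * 2.5
  expected <- outer(seq_along(xc), seq_along(xc),
                    Vectorize(function(i, j) pip_oracle(xc[i], xc[j], poly)))
  expect_identical(array(m$flags, dim = h$dims)[, , 1], expected)
})

test_that("polygons outside the grid z-extent are ignored with a warning", {
  h <- grid_header(c(4, 4, 2), origin = c(0, 0, 0), spacing = c(2.5, 2.5, 2.5))
  cs <- contour_set(list(s = list(list(z = 50, xy = rbind(c(0, 0), c(10, 0), c(10, 10))))))
  expect_warning(m <- rasterize_contours(cs, "s", h), "outside the grid")
  expect_equal(sum(m$flags), 0)
})

test_that("volume_cc is the voxel count times the voxel volume", {
  h <- grid_header(c(4, 4, 4), spacing = c(2.5, 2.5, 2.5))
  expect_equal(volume_cc(voxel_mask(h, rep(TRUE, 64))), 1.0)
  expect_equal(volume_cc(voxel_mask(h, rep(FALSE, 64))), 0)
  h1 <- grid_header(c(10, 10, 10), spacing = c(1, 1, 1))
  expect_equal(volume_cc(voxel_mask(h1, rep(TRUE, 1000))), 1.0)
})

test_that("volume_cc is additive over disjoint masks", {
  h <- iso_header(8)
  a <- random_mask(h, 1, 0.3)
  b <- combine_masks(random_mask(h, 2, 0.3), a, "subtract")  # force disjoint
  expect_equal(volume_cc(a) + volume_cc(b),
               volume_cc(combine_masks(a, b, "union")))
})

test_that("mask algebra follows boolean identities and inclusion-exclusion", {
  h <- iso_header(8)
  a <- random_mask(h, 5, 0.4)
  b <- random_mask(h, 6, 0.4)
  expect_identical(combine_masks(a, a, "intersect")$flags, a$flags)
  expect_identical(combine_masks(a, a, "union")$flags, a$flags)
  expect_equal(sum(combine_masks(a, a, "subtract")$flags), 0)
  expect_equal(sum(combine_masks(a, b, "union")$flags) +
                 sum(combine_masks(a, b, "intersect")$flags),
               sum(a$flags) + sum(b$flags))
  h2 <- grid_header(c(8, 8, 8), origin = c(1, 0, 0))
  expect_error(combine_masks(a, voxel_mask(h2, rep(TRUE, 512)), "union"), "geometry error")
})

test_that("interface_shell peels the documented erosion layers", {
  h <- grid_header(c(5, 5, 5), spacing = c(2.5, 2.5, 2.5))
  cube <- array(FALSE, dim = c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- TRUE
  m <- voxel_mask(h, as.vector(cube))
  shell <- interface_shell(m, 2.5)  # one erosion of a 3^3 cube leaves the centre
  expect_equal(sum(shell$flags), 26)
  expect_true(all(m$flags[shell$flags]))  # shell is a subset of the mask

  single <- voxel_mask(h, seq_len(125) == 63)
  expect_identical(interface_shell(single, 2.5)$flags, single$flags)

  expect_warning(empty <- interface_shell(m, 0.5), "empty shell")
  expect_equal(sum(empty$flags), 0)
})

test_that("erosion shell equals the city-block boundary-distance rule on a sphere", {
  n <- 24
  h <- grid_header(c(n, n, n), spacing = c(1, 1, 1))
  cc <- (n - 1) / 2
  idx <- as.matrix(expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1)))
  inside <- sqrt(rowSums((idx - cc)^2)) <= 8
  m <- voxel_mask(h, inside)
  shell <- interface_shell(m, 2)  # k = 2 erosions

  # oracle: propagate city-block distance from background in k sweeps
  dist <- array(ifelse(inside, Inf, 0), dim = c(n, n, n))
  for (step in 1:2) {
    prev <- dist
    for (ax in 1:3) {
      lo <- array(Inf, dim = dim(prev)); hi <- lo
      if (ax == 1) { lo[2:n, , ] <- prev[1:(n - 1), , ]; hi[1:(n - 1), , ] <- prev[2:n, , ] }
      if (ax == 2) { lo[, 2:n, ] <- prev[, 1:(n - 1), ]; hi[, 1:(n - 1), ] <- prev[, 2:n, ] }
      if (ax == 3) { lo[, , 2:n] <- prev[, , 1:(n - 1)]; hi[, , 1:(n - 1)] <- prev[, , 2:n] }
      dist <- pmin(dist, lo + 1, hi + 1)
    }
  }
  oracle_shell <- inside & as.vector(dist) <= 2
  expect_identical(shell$flags, oracle_shell)
})

test_that("doubling the rasterization resolution changes a convex volume by at most a boundary shell", {
  circle <- function(z) list(z = z, xy = cbind(20 + 15 * cos(seq(0, 2 * pi, length.out = 65)[-65]),
                                               20 + 15 * sin(seq(0, 2 * pi, length.out = 65)[-65])))
  cs <- contour_set(list(disk = list(circle(1.25), circle(3.75))))
  # refine in-plane only: the nearest-plane rule ties the z claim of each
  # polygon to the grid's slice spacing, so z stays at the contour spacing
  h1 <- grid_header(c(16, 16, 2), origin = c(1.25, 1.25, 1.25), spacing = c(2.5, 2.5, 2.5))
  h2 <- grid_header(c(32, 32, 2), origin = c(0.625, 0.625, 1.25), spacing = c(1.25, 1.25, 2.5))
  v1 <- volume_cc(rasterize_contours(cs, "disk", h1))
  v2 <- volume_cc(rasterize_contours(cs, "disk", h2))
  # boundary shell estimate: perimeter x voxel size x slab thickness
  shell_cc <- 2 * pi * 15 * 2.5 * 5 / 1000
  expect_lt(abs(v1 - v2), shell_cc)
})
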