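test_that("rasterization matches polygon-area counting", {
  geom <- dose_grid(array(0, dim = c(30, 30, 3)), c(1, 1, 5),
                    origin = c(-14.5, -14.5, -5))
  sq <- contour_set("sq", lapply(c(-5, 0, 5), function(z)
    list(z = z, polygons = list(square_polygon(0, 0, 10)))))
  m <- rasterize(sq, geom)
  # 10 mm square on a 1 mm grid: 100 voxel centres per slice
  expect_equal(apply(m$mask, 3, sum), c(100, 100, 100))

  expect_equal(sum(rasterize(contour_set("empty"), geom)$mask), 0)

  # circle radius 10 mm on a 0.5 mm grid: area within 1% of pi * 100
  geom2 <- dose_grid(array(0, dim = c(60, 60, 1)), c(0.5, 0.5, 1),
                     origin = c(-14.75, -14.75, 0))
  th <- seq(0, 2 * pi, length.out = 200)[-200]
  circ <- contour_set("c", list(list(z = 0, polygons =
    list(cbind(10 * cos(th), 10 * sin(th))))))
  mc <- rasterize(circ, geom2)
  expect_equal(sum(mc$mask) * 0.25, pi * 100, tolerance = 0.01)

  out <- contour_set("out", list(list(z = 0, polygons =
    list(square_polygon(20, 0, 10)))))
  expect_error(rasterize(out, geom2), "outside the grid")
})

test_that("even-odd rule carves holes", {
  geom <- dose_grid(array(0, dim = c(30, 30, 1)), c(1, 1, 1),
                    origin = c(-14.5, -14.5, 0))
  ring <- contour_set("ring", list(list(z = 0, polygons = list(
    square_polygon(0, 0, 20), square_polygon(0, 0, 10)))))
  m <- rasterize(ring, geom)
  expect_equal(sum(m$mask), 400 - 100)
})

test_that("margin expansion is a Euclidean dilation: identity, ball, extensivity, monotonicity", {
  m <- array(FALSE, dim = c(13, 13, 13))
  m[7, 7, 7] <- TRUE
  sm <- structure_mask(m, c(1, 1, 1), c(-6, -6, -6))
  expect_identical(expand_margin(sm, 0)$mask, sm$mask)

  ball <- expand_margin(sm, 5)
  ca <- coord_arrays(13, 1)
  expect_identical(ball$mask, ca$x^2 + ca$y^2 + ca$z^2 <= 25 + 1e-9)

  sph <- sphere_mask(8, spacing = 1, pad = 8)
  d3 <- expand_margin(sph, 3)
  d5 <- expand_margin(sph, 5)
  expect_true(all(d3$mask[sph$mask]))       # extensive
  expect_true(all(d5$mask[d3$mask]))        # monotone in margin
})

test_that("anisotropic margins dilate each axis by its own distance", {
  m <- array(FALSE, dim = c(11, 11, 11))
  m[6, 6, 6] <- TRUE
  sm <- structure_mask(m, c(1, 1, 1), c(-5, -5, -5))
  ell <- expand_margin(sm, c(2, 3, 4))
  ca <- coord_arrays(11, 1)
  expect_identical(ell$mask,
                   (ca$x / 2)^2 + (ca$y / 3)^2 + (ca$z / 4)^2 <= 1 + 1e-9)
})

test_that("dilated sphere volume approaches the analytic enlarged sphere", {
  sph <- sphere_mask(20, spacing = 0.5, pad = 7)
  vol <- mask_volume_cm3(expand_margin(sph, 5))
  expect_equal(vol, 4 / 3 * pi * 25^3 / 1000, tolerance = 0.02)
})

test_that("surface area and volume match analytic values for spheres and cubes", {
  sph <- sphere_mask(20, spacing = 1)
  sv <- surface_and_volume(sph)
  expect_equal(sv$V, 4 / 3 * pi * 8, tolerance = 0.01)
  expect_equal(sv$A, 4 * pi * 4, tolerance = 0.03)

  # 10 mm cube aligned to a 1 mm grid: exactly 1 cm^3
  ca <- coord_arrays(16, 1)
  cube <- structure_mask(abs(ca$x) <= 4.5 & abs(ca$y) <= 4.5 &
                           abs(ca$z) <= 4.5, c(1, 1, 1), ca$origin)
  expect_equal(surface_and_volume(cube)$V, 1)

  # additivity over two disjoint spheres
  ca2 <- coord_arrays(51, 1)  # odd n keeps voxel centres on integers
  two <- structure_mask(
    (ca2$x + 14)^2 + ca2$y^2 + ca2$z^2 <= 64 |
      (ca2$x - 14)^2 + ca2$y^2 + ca2$z^2 <= 36,
    c(1, 1, 1), ca2$origin)
  one_a <- surface_and_volume(sphere_mask(8, 1))
  one_b <- surface_and_volume(sphere_mask(6, 1))
  both <- surface_and_volume(two)
  expect_equal(both$V, one_a$V + one_b$V, tolerance = 1e-9)
  expect_equal(both$A, one_a$A + one_b$A, tolerance = 0.01)

  expect_error(surface_and_volume(
    structure_mask(array(FALSE, c(2, 2, 2)), c(1, 1, 1))), "empty")
})

test_that("sphericity closed forms", {
  r <- runif(1, 0.5, 5)  # any radius, exact sphere: psi = 1
  expect_equal(sphericity(4 * pi * r^2, 4 / 3 * pi * r^3), 1,
               tolerance = 1e-12)
  expect_equal(sphericity(6, 1), (pi / 6)^(1 / 3), tolerance = 1e-12)
  # halving A at fixed V doubles psi
  expect_equal(sphericity(3, 1), 2 * sphericity(6, 1))
  expect_error(sphericity(-1, 1), "positive")
  expect_error(sphericity(1, 0), "positive")
})

test_that("shell sphericity surrogate: concentric-sphere value, d->0 limit, linearity in d", {
  v20 <- 4 / 3 * pi * 2^3      # cm^3, r = 20 mm
  v25 <- 4 / 3 * pi * 2.5^3
  psi_t <- sphericity_like(v20, v25, 5)
  expect_gt(psi_t, 1)           # exceeds the true-sphericity ceiling
  expect_equal(psi_t, 1.0203, tolerance = 1e-4)

  # d -> 0: tends to the mid-shell sphere's sphericity (= 1)
  r <- 20
  d <- 0.1
  vc <- 4 / 3 * pi * (r / 10)^3
  vp <- 4 / 3 * pi * ((r + d) / 10)^3
  expect_lt(abs(sphericity_like(vc, vp, d) - 1), 0.001)

  # linear in d at fixed volumes
  expect_equal(sphericity_like(v20, v25, 10), 2 * sphericity_like(v20, v25, 5))
  expect_error(sphericity_like(v25, v20, 5), "degenerate")
})

test_that("min distance matches brute-force all-pairs search and geometric cases", {
  a <- sphere_mask(10, spacing = 2, pad = 4, centre = c(-15, 0, 0), n = 24)
  b <- sphere_mask(10, spacing = 2, pad = 4, centre = c(15, 0, 0), n = 24)
  d <- min_distance(a, b)
  expect_equal(d, 10, tolerance = 2 * sqrt(3))  # within one voxel diagonal
  expect_equal(min_distance(a, b), min_distance(b, a))

  # overlapping masks: 0
  c1 <- sphere_mask(10, spacing = 2, pad = 4, centre = c(-5, 0, 0), n = 24)
  c2 <- sphere_mask(10, spacing = 2, pad = 4, centre = c(5, 0, 0), n = 24)
  expect_equal(min_distance(c1, c2), 0)

  # exhaustive all-pairs oracle on small random masks
  for (seed in 1:5) {
    set.seed(seed)
    m1 <- array(runif(12^3) < 0.02, dim = c(12, 12, 12))
    m2 <- array(runif(12^3) < 0.02, dim = c(12, 12, 12))
    if (!any(m1) || !any(m2)) next
    s1 <- structure_mask(m1, c(1.5, 2, 2.5))
    s2 <- structure_mask(m2, c(1.5, 2, 2.5))
    p1 <- which(m1, arr.ind = TRUE)
    p2 <- which(m2, arr.ind = TRUE)
    dd <- outer(seq_len(nrow(p1)), seq_len(nrow(p2)), function(i, j)
      sqrt(((p1[i, 1] - p2[j, 1]) * 1.5)^2 + ((p1[i, 2] - p2[j, 2]) * 2)^2 +
             ((p1[i, 3] - p2[j, 3]) * 2.5)^2))
    expect_equal(min_distance(s1, s2), min(dd), tolerance = 1e-9)
    expect_true(min_distance(s1, s2) <=
                  min_distance(s1, s2, per_slice = TRUE) + 1e-9)
  }
  expect_error(min_distance(a, structure_mask(array(FALSE, dim(b$mask)),
                                              b$spacing, b$origin)),
               "empty")
})

test_that("isocentre displacement uses the squared components", {
  expect_equal(isocentre_displacement(0, 0), 0)
  expect_equal(isocentre_displacement(3, 4), 5)
  expect_equal(isocentre_displacement(-3, 4), 5)
})

test_that("overlap volumes and percentages", {
  a <- sphere_mask(10, spacing = 1, pad = 3)
  expect_equal(overlap(a, a)$pct, 100)
  expect_equal(overlap(a, a)$cm3, mask_volume_cm3(a))

  b <- structure_mask(array(FALSE, dim(a$mask)), a$spacing, a$origin)
  expect_equal(overlap(a, b)$cm3, 0)
  expect_equal(overlap(a, b)$pct, 0)
  expect_error(overlap(b, a), "empty")

  # half-embedded cube: 50% within one voxel layer
  ca <- coord_arrays(20, 1)
  cube <- structure_mask(abs(ca$x) <= 4.5 & abs(ca$y) <= 4.5 &
                           abs(ca$z) <= 4.5, rep(1, 3), ca$origin)
  half <- structure_mask(ca$x > 0, rep(1, 3), ca$origin)
  expect_equal(overlap(cube, half)$pct, 50, tolerance = 10 * 10 / 1000 + 0.06)
})

test_that("distance to skin measures to the external-contour boundary", {
  ca <- coord_arrays(30, 2)
  body <- structure_mask(ca$x^2 + ca$y^2 <= 25^2, rep(2, 3), ca$origin,
                         role = "external")
  ctv <- sphere_mask(6, spacing = 2, centre = c(10, 0, 0), n = 30)
  d <- distance_to_skin(ctv, body)
  # nearest outside voxel sits just past the 25 mm rim from the CTV rim
  expect_equal(d, 25 - 16, tolerance = 2 * sqrt(2) + 0.6)
})

test_that("shape_metrics assembles a coherent row for concentric spheres", {
  ctv <- sphere_mask(15, spacing = 2, pad = 10)
  ptv <- expand_margin(ctv, 5, name = "PTV", role = "PTV")
  row <- shape_metrics(ctv, ptv, 5)
  expect_equal(row$V_CTV_cm3, mask_volume_cm3(ctv))
  expect_gt(row$psi, 0.95)
  expect_gt(row$psi_tilde, 0.9)
  expect_lt(row$R_mm, 1.5)
  expect_true(is.na(row$d_CTV_cord_mm))
})
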