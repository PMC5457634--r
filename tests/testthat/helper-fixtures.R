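# shared fixture builders: everything is generated in code at test time

# voxel-centre coordinate arrays for a cube grid centred on the origin
coord_arrays <- function(n, spacing) {
  cc <- (seq_len(n) - (n + 1) / 2) * spacing
  list(
    x = array(rep(cc, times = n * n), dim = c(n, n, n)),
    y = array(rep(rep(cc, each = n), times = n), dim = c(n, n, n)),
    z = array(rep(cc, each = n * n), dim = c(n, n, n)),
    origin = rep(cc[1], 3))
}

# digitized sphere mask on a cube grid centred on the origin
sphere_mask <- function(radius, spacing = 1, pad = 5, centre = c(0, 0, 0),
                        n = NULL) {
  if (is.null(n)) n <- 2 * ceiling((radius + pad) / spacing) + 1
  ca <- coord_arrays(n, spacing)
  m <- (ca$x - centre[1])^2 + (ca$y - centre[2])^2 +
    (ca$z - centre[3])^2 <= radius^2
  structure_mask(m, rep(spacing, 3), ca$origin, name = "sphere")
}

# smooth random planar field: a handful of Gaussian blobs
smooth_plane <- function(n, seed, spacing = 2, dmax = 10) {
  set.seed(seed)
  f <- matrix(0, n, n)
  xs <- seq_len(n)
  for (b in 1:6) {
    cx <- runif(1, 5, n - 5)
    cy <- runif(1, 5, n - 5)
    s <- runif(1, 4, 10)
    a <- runif(1, 0.3, 1)
    f <- f + a * outer(exp(-(xs - cx)^2 / (2 * s^2)),
                       exp(-(xs - cy)^2 / (2 * s^2)))
  }
  planar_dose(f * dmax / max(f), rep(spacing, 2))
}

# small random dose grid plus a structure mask covering part of it
random_dose_and_mask <- function(seed, n = 16, spacing = 2, dmax = 60) {
  set.seed(seed)
  vals <- array(runif(n^3, 0, dmax), dim = c(n, n, n))
  ca <- coord_arrays(n, spacing)
  mask <- ca$x^2 + ca$y^2 + ca$z^2 <= (n * spacing / 3)^2
  list(dose = dose_grid(vals, rep(spacing, 3), ca$origin),
       mask = structure_mask(mask, rep(spacing, 3), ca$origin, "s"))
}

# square contour (counter-clockwise) centred at (cx, cy) with side `side`
square_polygon <- function(cx, cy, side) {
  h <- side / 2
  matrix(c(cx - h, cy - h, cx + h, cy - h, cx + h, cy + h, cx - h, cy + h),
         ncol = 2, byrow = TRUE)
}
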