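# uniform-dose and slab fixtures shared across blocks
uniform_fixture <- function(dose_gy = 10, n = 10) {
  ca <- coord_arrays(n, 2)
  list(dose = dose_grid(array(dose_gy, dim = rep(n, 3)), rep(2, 3),
                        ca$origin),
       mask = structure_mask(array(TRUE, dim = rep(n, 3)), rep(2, 3),
                             ca$origin))
}

# 10 equal-volume slabs at 5, 15, ..., 95 Gy
slab_fixture <- function() {
  vals <- array(0, dim = c(10, 4, 4))
  for (i in 1:10) vals[i, , ] <- 10 * i - 5
  list(dose = dose_grid(vals, c(1, 1, 1)),
       mask = structure_mask(array(TRUE, dim = c(10, 4, 4)), c(1, 1, 1)))
}

test_that("DVH of a uniform dose is a step function", {
  f <- uniform_fixture(10)
  dvh <- compute_dvh(f$dose, f$mask, 0.5)
  expect_equal(dvh$fraction[dvh$dose <= 10], rep(1, sum(dvh$dose <= 10)))
  expect_equal(dvh$fraction[dvh$dose > 10], rep(0, sum(dvh$dose > 10)))
  expect_equal(dose_at_volume(dvh, 2), 10, tolerance = 0.5)
  expect_equal(dose_at_volume(dvh, 98), 10, tolerance = 0.5)
  expect_equal(volume_at_dose(dvh, 5), 100)
  expect_equal(volume_at_dose(dvh, 20), 0)
  expect_equal(volume_at_dose(dvh, 0), 100)
})

test_that("slab phantom reproduces the counting oracle", {
  f <- slab_fixture()
  dvh <- compute_dvh(f$dose, f$mask, 0.1)
  expect_equal(100 * dvh$fraction[which.min(abs(dvh$dose - 50))], 50,
               tolerance = 1)
  expect_equal(volume_at_dose(dvh, 20), 80, tolerance = 1)
  expect_equal(dose_at_volume(dvh, 98), 5, tolerance = 0.1)
  expect_equal(dose_at_volume(dvh, 2), 95, tolerance = 0.1)
})

test_that("DVH curves are non-increasing and match the sorted-values oracle", {
  for (seed in 1:8) {
    rd <- random_dose_and_mask(seed)
    bw <- 0.25
    dvh <- compute_dvh(rd$dose, rd$mask, bw)
    expect_true(all(diff(dvh$fraction) <= 0))
    expect_equal(dvh$fraction[1], 1)
    # oracle: direct counting at every edge
    d <- rd$dose$values[rd$mask$mask]
    frac <- vapply(dvh$dose, function(t) mean(d >= t), numeric(1))
    expect_equal(dvh$fraction, frac, tolerance = 1e-12)
  }
})

test_that("dose_at_volume inverts volume_at_dose on strictly monotone curves", {
  set.seed(42)
  ca <- coord_arrays(12, 1)
  vals <- array(sort(runif(12^3, 1, 60)), dim = rep(12, 3))
  dose <- dose_grid(vals, rep(1, 3), ca$origin)
  mask <- structure_mask(array(TRUE, rep(12, 3)), rep(1, 3), ca$origin)
  dvh <- compute_dvh(dose, mask, 0.05)
  for (t in c(10, 25, 47)) {
    v <- volume_at_dose(dvh, t)
    expect_equal(dose_at_volume(dvh, v), t, tolerance = 0.1)
  }
})

test_that("hottest-volume dose (D1cc-style) follows the counting oracle", {
  f <- uniform_fixture(12)
  expect_equal(dose_at_absolute_volume(f$dose, f$mask, 1), 12)
  expect_equal(dose_at_absolute_volume(f$dose, f$mask, 3.7), 12)

  # 2 cm^3 at 30 Gy, the rest at 10 Gy, ask for the hottest 1 cm^3
  vals <- array(10, dim = c(8, 4, 4))
  vals[1:16] <- 30                     # 16 voxels * 0.125 cm^3 = 2 cm^3
  dose <- dose_grid(vals, rep(5, 3))
  mask <- structure_mask(array(TRUE, dim = c(8, 4, 4)), rep(5, 3))
  expect_equal(dose_at_absolute_volume(dose, mask, 1), 30)
  # full volume: the structure minimum
  expect_equal(dose_at_absolute_volume(dose, mask, mask_volume_cm3(mask)),
               10)
  expect_error(dose_at_absolute_volume(dose, mask, 1e6), "exceeds")
})

test_that("conformation number follows its defining ratios", {
  ca <- coord_arrays(12, 5)
  target <- structure_mask(ca$x^2 + ca$y^2 + ca$z^2 <= 20^2, rep(5, 3),
                           ca$origin)
  # dose >= RI exactly on the target
  vals <- array(0, dim = rep(12, 3))
  vals[target$mask] <- 40
  dose <- dose_grid(vals, rep(5, 3), ca$origin)
  expect_equal(conformation_number(dose, target, 38), 1)

  # constructed ratios: TV = n voxels, TV_RI = 95%, V_RI = 150%
  n <- sum(target$mask)
  idx <- which(target$mask)
  out_idx <- which(!target$mask)
  vals2 <- array(0, dim = rep(12, 3))
  k_in <- round(0.95 * n)
  vals2[idx[seq_len(k_in)]] <- 40
  vals2[out_idx[seq_len(round(1.5 * n) - k_in)]] <- 40
  dose2 <- dose_grid(vals2, rep(5, 3), ca$origin)
  tv_ri <- k_in
  v_ri <- round(1.5 * n)
  expect_equal(conformation_number(dose2, target, 38),
               (tv_ri / n) * (tv_ri / v_ri), tolerance = 1e-12)

  expect_message(cn0 <- conformation_number(dose, target, 100),
                 "CN = 0")
  expect_equal(cn0, 0)
})

test_that("homogeneity indices: closed forms and scale invariance", {
  expect_equal(homogeneity_index(55, 45, 50), 0.2)
  expect_equal(homogeneity_index(10, 10, 10), 0)
  expect_equal(homogeneity_index(55, 45, 50),
               homogeneity_index(110, 90, 100))

  f <- uniform_fixture(10)
  expect_equal(dhd(f$dose, f$mask), 0)

  # doses {9, 11}: sd = sqrt(2), mean 10
  vals <- array(c(9, 11), dim = c(2, 1, 1))
  dose <- dose_grid(vals, c(1, 1, 1))
  mask <- structure_mask(array(TRUE, c(2, 1, 1)), c(1, 1, 1))
  expect_equal(dhd(dose, mask), sqrt(2) / 10, tolerance = 1e-12)

  # scale invariance of DHD, linear scaling of the mean dose
  rd <- random_dose_and_mask(3)
  scaled <- dose_grid(rd$dose$values * 2.7, rd$dose$spacing, rd$dose$origin)
  expect_equal(dhd(scaled, rd$mask), dhd(rd$dose, rd$mask))
  expect_equal(mean(scaled$values[rd$mask$mask]),
               2.7 * mean(rd$dose$values[rd$mask$mask]))
})

test_that("planning constraints use strict inequalities", {
  base <- data.frame(V20Gy_pct = 23.9, V5Gy_pct = 63.3, MLD_cGy = 1500,
                     D1cc_cord_cGy = 2900, oeso_mean_cGy = 1700)
  ch <- check_constraints(base)
  expect_true(ch$pass[ch$constraint == "lung V20Gy < 35%"])
  expect_false(ch$pass[ch$constraint == "lung V5Gy < 60%"])
  expect_false(ch$pass[ch$constraint == "MLD < 15 Gy"])  # boundary fails
  expect_true(ch$pass[ch$constraint == "cord D1cc < 50 Gy"])
  # missing metric -> not evaluated
  ch2 <- check_constraints(data.frame(V20Gy_pct = 10))
  expect_true(is.na(ch2$pass[ch2$constraint == "MLD < 15 Gy"]))
})

test_that("plan_metrics wires the individual metrics together", {
  f <- uniform_fixture(36, n = 8)
  pm <- plan_metrics(f$dose, f$mask, 36, lungs = f$mask, cord = f$mask,
                     oesophagus = f$mask, mu = 250)
  expect_equal(pm$HI, 0, tolerance = 0.01)
  expect_equal(pm$DHD, 0)
  expect_equal(pm$CN, 1)        # everything is target and covered
  expect_equal(pm$MLD_cGy, 3600)
  expect_equal(pm$V20Gy_pct, 100)
  expect_equal(pm$D1cc_cord_cGy, 3600)
  expect_equal(pm$MU, 250)
})
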