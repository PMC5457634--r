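test_that("the default phantom partitions the body into the four media", {
  ph <- make_phantom()
  expect_setequal(unique(as.vector(ph$media$labels)), 0:3)
  # lung fraction of the body in a plausible thoracic range
  body <- sum(ph$media$labels > 0)
  lung <- sum(ph$media$labels == 1L)
  expect_gt(lung / body, 0.10)
  expect_lt(lung / body, 0.50)
  # identical spec -> identical map
  expect_identical(make_phantom()$media$labels, ph$media$labels)
  # cord and oesophagus are soft tissue inside the body
  expect_true(all(ph$media$labels[ph$cord$mask] == 2L))
  expect_true(all(ph$media$labels[ph$oesophagus$mask] == 2L))
})

test_that("a phantom with lungs running into the spine is rejected", {
  expect_error(make_phantom(phantom_spec(lung_centre_mm = c(10, 40),
                                         lung_axes_mm = c(40, 40, 80))),
               "overlap")
})

test_that("spherical targets are near-spherical and lobes push sphericity down", {
  ph <- make_phantom(phantom_spec(dim = c(60L, 60L, 60L),
                                  spacing = c(2, 2, 2),
                                  body_mm = c(200, 200)))
  psi_of <- function(lobes) {
    tg <- make_target(target_spec(centre_mm = c(0, 0, 0), radius_mm = 22,
                                  lobes = lobes, margin_mm = 5, seed = 4),
                      ph)
    sv <- surface_and_volume(tg$ctv)
    sphericity(sv$A, sv$V)
  }
  psi1 <- psi_of(1)
  psi2 <- psi_of(2)
  psi4 <- psi_of(4)
  expect_gt(psi1, 0.95)
  expect_lt(psi2, psi1)
  expect_lt(psi4, psi2)
})

test_that("the PTV always contains the CTV and respects the margin", {
  ph <- make_phantom()
  tg <- make_target(target_spec(centre_mm = c(55, -5, 0), radius_mm = 30,
                                lobes = 3, margin_mm = 8, seed = 2), ph)
  expect_true(all(tg$ptv$mask[tg$ctv$mask]))
  expect_gt(mask_volume_cm3(tg$ptv), mask_volume_cm3(tg$ctv))
  # margin expansion consistency: dilating the CTV reproduces the PTV
  expect_identical(tg$ptv$mask, expand_margin(tg$ctv, 8)$mask)
})

test_that("a single field falls off monotonically with depth in homogeneous medium", {
  ph <- make_phantom(phantom_spec(dim = c(40L, 40L, 20L),
                                  spacing = c(5, 5, 5),
                                  body_mm = c(500, 500),
                                  lung_axes_mm = c(1e-3, 1e-3, 1e-3),
                                  spine_radius_mm = 1e-3,
                                  cord_radius_mm = 1e-3))
  tg <- make_target(target_spec(centre_mm = c(0, 0, 0), radius_mm = 20,
                                margin_mm = 5), ph)
  bs <- beam_spec("static", n_fields = 3, gantry_deg = 0,
                  penumbra_sigma_mm = 3)
  d <- simulate_dose(ph, tg$ptv, bs)
  # gantry 0: beam travels towards +y; central-axis dose decreases in depth
  axis <- d$values[20, , 10]
  expect_true(all(diff(axis) < 0))
})

test_that("an arc on a centred spherical target is nearly azimuthally symmetric", {
  ph <- make_phantom(phantom_spec(dim = c(45L, 45L, 25L),
                                  spacing = c(5, 5, 5),
                                  body_mm = c(100, 100),
                                  lung_axes_mm = c(1e-3, 1e-3, 1e-3),
                                  spine_radius_mm = 1e-3,
                                  cord_radius_mm = 1e-3,
                                  oeso_radius_mm = 1e-3))
  tg <- make_target(target_spec(centre_mm = c(0, 0, 0), radius_mm = 15,
                                margin_mm = 5), ph)
  d <- simulate_dose(ph, tg$ptv, beam_spec("arc"))
  # bilinear samples on a ring of radius 40 mm in the central slice
  # (lattice rounding would alias the sampled radius by up to half a voxel)
  th <- seq(0, 2 * pi, length.out = 145)[-145]
  ring <- vapply(th, function(a) {
    gx <- (40 * cos(a) + 110) / 5
    gy <- (40 * sin(a) + 110) / 5
    i0 <- floor(gx); j0 <- floor(gy); tx <- gx - i0; ty <- gy - j0
    v <- d$values
    (1 - tx) * (1 - ty) * v[i0 + 1, j0 + 1, 13] +
      tx * (1 - ty) * v[i0 + 2, j0 + 1, 13] +
      (1 - tx) * ty * v[i0 + 1, j0 + 2, 13] +
      tx * ty * v[i0 + 2, j0 + 2, 13]
  }, numeric(1))
  expect_lt((max(ring) - min(ring)) / max(ring), 0.05)
})

test_that("the arc trades a larger low-dose lung bath for conformity", {
  ph <- make_phantom()
  tg <- make_target(target_spec(centre_mm = c(55, -5, 0), radius_mm = 32,
                                margin_mm = 5, seed = 3), ph)
  st <- simulate_dose(ph, tg$ptv, beam_spec("static", n_fields = 3))
  arc <- simulate_dose(ph, tg$ptv, beam_spec("arc"))
  pm_s <- plan_metrics(st, tg$ptv, 36, lungs = ph$lungs,
                       external = ph$external)
  pm_a <- plan_metrics(arc, tg$ptv, 36, lungs = ph$lungs,
                       external = ph$external)
  expect_gte(pm_a$V5Gy_pct, pm_s$V5Gy_pct)
  expect_gte(pm_a$CN, pm_s$CN)
})

test_that("measured planes: identity without perturbations, closed-form offset, determinism", {
  ph <- make_phantom()
  tg <- make_target(target_spec(radius_mm = 30, margin_mm = 5), ph)
  d <- simulate_dose(ph, tg$ptv, beam_spec("arc"))
  clean <- beam_spec("arc", noise_sd_pct = 0,
                     medium_offset_pct = c(lung = 0, soft = 0, bone = 0),
                     shift_mm = c(0, 0))
  film0 <- make_measured_plane(d, -26, clean, ph$media)
  expect_equal(film0$values, extract_plane(d, -26)$values)

  # a uniform +3% calculated-vs-measured offset sits at gamma ~ 1 (3%, 3mm)
  # in flat high-dose regions
  offs <- beam_spec("arc", noise_sd_pct = 0,
                    medium_offset_pct = c(lung = 3, soft = 3, bone = 3),
                    shift_mm = c(0, 0))
  film3 <- make_measured_plane(d, -26, offs, ph$media)
  g <- gamma_map(film3, extract_plane(d, -26), gamma_params(3, 3, 50))
  flat <- g$gamma[abs(film3$values / max(film3$values) - 1) < 0.02]
  expect_gt(stats::median(flat, na.rm = TRUE), 0.9)

  noisy <- beam_spec("arc", noise_sd_pct = 2, seed = 99)
  f1 <- make_measured_plane(d, -26, noisy, ph$media)
  f2 <- make_measured_plane(d, -26, noisy, ph$media)
  expect_identical(f1$values, f2$values)
  expect_error(extract_plane(d, 1e4), "outside")
})

test_that("small cohorts build deterministically with PTV volumes in the study range", {
  c1 <- make_cohort(2, master_seed = 11)
  c2 <- make_cohort(2, master_seed = 11)
  expect_identical(c1$table, c2$table)
  expect_equal(nrow(c1$table), 2 * 5)
  expect_true(all(c1$table$V_PTV_cm3 >= 145.2 &
                    c1$table$V_PTV_cm3 <= 2686.5))
  expect_true(all(c1$table$MU[c1$table$variant != "3DCRT"] <
                    c1$table$MU[c1$table$variant == "3DCRT"][
                      c1$table$patient[c1$table$variant != "3DCRT"]] + 60))
  expect_setequal(unique(c1$table$variant),
                  c("3DCRT", "DCAT_00", "DCAT_30", "DCAT_45", "DCAT_90"))
})

test_that("cohort artifacts on disk feed the downstream error pipeline", {
  tmp <- withr::local_tempdir()
  co <- make_cohort(2, master_seed = 5, out_dir = tmp)
  expect_true(file.exists(file.path(tmp, "manifest.json")))
  expect_true(file.exists(file.path(tmp, "cohort.csv")))
  # film vs exported plane pairs recover a sensible per-medium decomposition
  stats_list <- lapply(1:2, function(p) {
    pdir <- file.path(tmp, sprintf("patient%02d", p))
    calc <- read_portable(file.path(pdir, "plane_DCAT_45"))
    film <- read_portable(file.path(pdir, "film_DCAT_45"))
    media <- read_portable(file.path(pdir, "media_plane"))
    per_plan_region_stats(relative_difference(calc, film), media)
  })
  dec <- decompose_errors(stats_list)
  expect_true(all(c("soft") %in% dec$medium))
  expect_true(all(is.finite(dec$M)))
})
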