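# Synthetic thorax phantoms, targets, plans and "film" planes.  The beam
# engine is intentionally crude -- parallel-beam exponential attenuation
# through the medium map plus a Gaussian-penumbra aperture conforming to
# the target projection -- because the analysis pipeline, not the dose
# physics, is what the package exercises.

#' Thorax phantom specification
#'
#' @param dim grid shape (voxels, x/y/z).
#' @param spacing mm per axis.
#' @param body_mm semi-axes (mm) of the elliptic body cylinder (x, y).
#' @param lung_centre_mm,lung_axes_mm centre offset (x, y) and semi-axes
#'   (x, y, z) of each lung ellipsoid (mirrored in x).
#' @param spine_centre_y_mm,spine_radius_mm posterior vertebral column
#'   (bone) cylinder.
#' @param cord_radius_mm spinal-cord cylinder radius (soft tissue, inside
#'   the vertebral canal).
#' @param oeso_centre_y_mm,oeso_radius_mm oesophagus tube.
#' @param seed integer seed recorded with the spec.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(64L, 48L, 40L), spacing = c(5, 5, 5),
                         body_mm = c(150, 100),
                         lung_centre_mm = c(58, -8),
                         lung_axes_mm = c(46, 64, 82),
                         spine_centre_y_mm = 62, spine_radius_mm = 14,
                         cord_radius_mm = 5,
                         oeso_centre_y_mm = 34, oeso_radius_mm = 6,
                         seed = 1L) {
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(dim = as.integer(dim), spacing = spacing,
                 body_mm = body_mm, lung_centre_mm = lung_centre_mm,
                 lung_axes_mm = lung_axes_mm,
                 spine_centre_y_mm = spine_centre_y_mm,
                 spine_radius_mm = spine_radius_mm,
                 cord_radius_mm = cord_radius_mm,
                 oeso_centre_y_mm = oeso_centre_y_mm,
                 oeso_radius_mm = oeso_radius_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

grid_coords <- function(dim, spacing, origin) {
  list(x = origin[1] + (seq_len(dim[1]) - 1) * spacing[1],
       y = origin[2] + (seq_len(dim[2]) - 1) * spacing[2],
       z = origin[3] + (seq_len(dim[3]) - 1) * spacing[3])
}

#' Build a thorax-like phantom
#'
#' Deterministic for a fixed spec.  The grid is centred on the body axis
#' (patient origin at x = y = 0, z centred on the grid).  Media partition
#' the grid into outside / lung / soft tissue / bone; the spinal cord and
#' oesophagus are soft-tissue structures returned as separate masks.
#'
#' @param spec a [phantom_spec()].
#' @return list with `media` ([medium_map()]), `external`, `lungs`,
#'   `cord`, `oesophagus` ([structure_mask()]s) and the `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  dm <- spec$dim
  sp <- spec$spacing
  origin <- -(dm - 1) * sp / 2
  cc <- grid_coords(dm, sp, origin)
  X <- array(rep(cc$x, times = dm[2] * dm[3]), dim = dm)
  Y <- array(rep(rep(cc$y, each = dm[1]), times = dm[3]), dim = dm)
  Z <- array(rep(cc$z, each = dm[1] * dm[2]), dim = dm)

  body <- (X / spec$body_mm[1])^2 + (Y / spec$body_mm[2])^2 <= 1
  lungs <- ((X - spec$lung_centre_mm[1]) / spec$lung_axes_mm[1])^2 +
    ((Y - spec$lung_centre_mm[2]) / spec$lung_axes_mm[2])^2 +
    (Z / spec$lung_axes_mm[3])^2 <= 1
  lungs <- lungs | (((X + spec$lung_centre_mm[1]) / spec$lung_axes_mm[1])^2 +
    ((Y - spec$lung_centre_mm[2]) / spec$lung_axes_mm[2])^2 +
    (Z / spec$lung_axes_mm[3])^2 <= 1)
  lungs <- lungs & body
  spine <- X^2 + (Y - spec$spine_centre_y_mm)^2 <= spec$spine_radius_mm^2
  spine <- spine & body
  if (any(lungs & spine))
    stop("invalid phantom spec: lungs overlap the vertebral column")
  cord <- (X^2 + (Y - spec$spine_centre_y_mm)^2 <= spec$cord_radius_mm^2) &
    body
  oeso <- (X^2 + (Y - spec$oeso_centre_y_mm)^2 <= spec$oeso_radius_mm^2) &
    body & !lungs & !spine

  labels <- array(0L, dim = dm)
  labels[body] <- 2L          # soft tissue
  labels[lungs] <- 1L
  labels[spine] <- 3L
  labels[cord] <- 2L          # cord runs inside the canal, soft tissue

  list(media = medium_map(labels, sp, origin),
       external = structure_mask(body, sp, origin, "external", "external"),
       lungs = structure_mask(lungs, sp, origin, "lungs", "lung"),
       cord = structure_mask(cord, sp, origin, "cord", "cord"),
       oesophagus = structure_mask(oeso, sp, origin, "oesophagus",
                                   "oesophagus"),
       spec = spec)
}

#' Target specification
#'
#' A clinical target built as a union of spherical lobes: one lobe gives a
#' near-spherical CTV, more lobes push the mask-derived sphericity down.
#'
#' @param centre_mm CTV centre (x, y, z) in mm.
#' @param radius_mm principal lobe radius in mm.
#' @param lobes number of lobes (`>= 1`).
#' @param lobe_radius_frac,lobe_offset_frac satellite-lobe radius and
#'   centre offset as fractions of `radius_mm`.
#' @param margin_mm isotropic CTV-to-PTV margin (mm), `> 0`; clinically
#'   5-10 mm depending on target location.
#' @param seed seed for the satellite-lobe directions.
#' @return list of class `target_spec`.
#' @export
target_spec <- function(centre_mm = c(55, -5, 0), radius_mm = 30,
                        lobes = 1L, lobe_radius_frac = 0.6,
                        lobe_offset_frac = 0.85, margin_mm = 5,
                        seed = 1L) {
  if (margin_mm <= 0) stop("margin must be positive")
  if (lobes < 1) stop("need at least one lobe")
  structure(list(centre_mm = centre_mm, radius_mm = radius_mm,
                 lobes = as.integer(lobes),
                 lobe_radius_frac = lobe_radius_frac,
                 lobe_offset_frac = lobe_offset_frac,
                 margin_mm = margin_mm, seed = as.integer(seed)),
            class = "target_spec")
}

#' Build CTV and PTV masks from a target specification
#'
#' The PTV is the Euclidean margin expansion of the CTV.  A PTV escaping
#' the body is clipped to the grid with a warning (never an error).
#'
#' @param spec a [target_spec()].
#' @param phantom a phantom from [make_phantom()].
#' @return list with `ctv` and `ptv` [structure_mask()]s.
#' @export
make_target <- function(spec, phantom) {
  media <- phantom$media
  dm <- dim(media$labels)
  sp <- media$spacing
  cc <- grid_coords(dm, sp, media$origin)
  X <- array(rep(cc$x, times = dm[2] * dm[3]), dim = dm)
  Y <- array(rep(rep(cc$y, each = dm[1]), times = dm[3]), dim = dm)
  Z <- array(rep(cc$z, each = dm[1] * dm[2]), dim = dm)

  set.seed(spec$seed)
  centres <- matrix(spec$centre_mm, nrow = 1)
  radii <- spec$radius_mm
  if (spec$lobes > 1) {
    for (l in seq_len(spec$lobes - 1L)) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      centres <- rbind(centres, spec$centre_mm +
                         u * spec$lobe_offset_frac * spec$radius_mm)
      radii <- c(radii, spec$lobe_radius_frac * spec$radius_mm)
    }
  }
  ctv <- array(FALSE, dim = dm)
  for (l in seq_len(nrow(centres))) {
    ctv <- ctv | ((X - centres[l, 1])^2 + (Y - centres[l, 2])^2 +
                    (Z - centres[l, 3])^2 <= radii[l]^2)
  }
  if (!any(ctv)) stop("target does not cover any voxel")
  if (any(ctv & !phantom$external$mask)) {
    warning("CTV extends outside the body; clipped")
    ctv <- ctv & phantom$external$mask
  }
  ctv_mask <- structure_mask(ctv, sp, media$origin, "CTV", "CTV")
  ptv <- expand_margin(ctv_mask, spec$margin_mm, name = "PTV", role = "PTV")
  if (any(ptv$mask & !phantom$external$mask))
    warning("PTV escapes the body; kept (clipped to the grid only)")
  list(ctv = ctv_mask, ptv = ptv)
}

#' Beam specification for the synthetic dose engine
#'
#' @param technique `"static"` (3D CRT-like principal fields) or `"arc"`
#'   (single conformal arc).
#' @param n_fields static technique: number of principal fields (3, 4
#'   or 5).
#' @param gantry_deg static gantry angles; defaults depend on `n_fields`.
#' @param arc_start_deg,arc_span_deg,cp_spacing_deg arc geometry: start
#'   gantry angle, clockwise span and control-point spacing (defaults
#'   182 degrees, 356 degrees, 4 degrees giving 89 control points).
#' @param collimator_deg collimator angle (degrees); in this engine it
#'   only perturbs the penumbra width and the MU proxy (documented
#'   synthetic stand-in -- a parallel-beam model has no physical
#'   collimator).
#' @param margin_mm field margin around the PTV projection:
#'   `c(transversal, craniocaudal)` in mm.  Static defaults to
#'   `c(5, 8)`, arc to `c(5, 5)`.
#' @param penumbra_sigma_mm Gaussian penumbra sigma (mm).
#' @param mu_water attenuation coefficient of soft tissue (1/mm).
#' @param attenuation relative attenuation per medium
#'   (outside, lung, soft, bone).
#' @param prescription_gy prescription dose (Gy); the PTV median is
#'   normalized to it.
#' @param noise_sd_pct film noise SD, % of the plane maximum.
#' @param shift_mm rigid registration shift (x, y) applied to measured
#'   planes.
#' @param medium_offset_pct named per-medium systematic offsets (%)
#'   applied to measured planes.
#' @param mu recorded monitor-unit proxy for the plan.
#' @param seed seed for the measured-plane noise.
#' @return list of class `beam_spec`.
#' @export
beam_spec <- function(technique = c("arc", "static"), n_fields = 3L,
                      gantry_deg = NULL, arc_start_deg = 182,
                      arc_span_deg = 356, cp_spacing_deg = 4,
                      collimator_deg = 45, margin_mm = NULL,
                      penumbra_sigma_mm = 5, mu_water = 0.0055,
                      attenuation = c(outside = 0, lung = 0.25,
                                      soft = 1, bone = 1.6),
                      prescription_gy = 36,
                      noise_sd_pct = 1.5, shift_mm = c(0, 0),
                      medium_offset_pct = c(lung = 0, soft = 0, bone = 0),
                      mu = NA_real_, seed = 1L) {
  technique <- match.arg(technique)
  if (cp_spacing_deg <= 0) stop("control-point spacing must be positive")
  if (noise_sd_pct < 0) stop("noise sd must be >= 0")
  if (is.null(margin_mm))
    margin_mm <- if (technique == "static") c(5, 8) else c(5, 5)
  if (is.null(gantry_deg) && technique == "static") {
    gantry_deg <- switch(as.character(n_fields),
                         "3" = c(0, 140, 220),
                         "4" = c(0, 90, 180, 270),
                         "5" = c(0, 72, 144, 216, 288),
                         stop("static plans use 3, 4 or 5 fields"))
  }
  structure(list(technique = technique, n_fields = as.integer(n_fields),
                 gantry_deg = gantry_deg, arc_start_deg = arc_start_deg,
                 arc_span_deg = arc_span_deg,
                 cp_spacing_deg = cp_spacing_deg,
                 collimator_deg = collimator_deg, margin_mm = margin_mm,
                 penumbra_sigma_mm = penumbra_sigma_mm,
                 mu_water = mu_water, attenuation = attenuation,
                 prescription_gy = prescription_gy,
                 noise_sd_pct = noise_sd_pct, shift_mm = shift_mm,
                 medium_offset_pct = medium_offset_pct, mu = mu,
                 seed = as.integer(seed)),
            class = "beam_spec")
}

beam_angles <- function(beams) {
  if (beams$technique == "static") {
    beams$gantry_deg
  } else {
    n_cp <- floor(beams$arc_span_deg / beams$cp_spacing_deg)
    (beams$arc_start_deg + (seq_len(n_cp) - 1) * beams$cp_spacing_deg) %% 360
  }
}

# collimator angle has no physical meaning in a parallel-beam engine; it
# perturbs the penumbra slightly (largest at 45 degrees, mirroring wider
# jaw openings) so the variant axis is exercised end to end
collimator_sigma <- function(beams, collimator_deg = beams$collimator_deg) {
  beams$penumbra_sigma_mm * (1 + 0.06 * sin(2 * collimator_deg * pi / 180)^2)
}

mu_field <- function(phantom, beams) {
  att <- beams$attenuation[c("outside", "lung", "soft", "bone")]
  array(beams$mu_water * att[phantom$media$labels + 1L],
        dim = dim(phantom$media$labels))
}

#' Simulate the dose of a plan on a phantom
#'
#' Sums, over static fields or arc control points, a parallel beam whose
#' aperture conforms to the PTV beam's-eye-view projection expanded by the
#' field margins and blurred with a Gaussian penumbra, attenuated
#' exponentially along the ray through the medium map.  The result is
#' normalized so the PTV median dose equals the prescription.
#'
#' @param phantom from [make_phantom()].
#' @param ptv the PTV [structure_mask()] (nonempty).
#' @param beams a [beam_spec()].
#' @return a [dose_grid()].
#' @export
simulate_dose <- function(phantom, ptv, beams) {
  simulate_plan_doses(phantom, ptv, beams, beams$collimator_deg)[[1]]
}

#' Simulate one plan at several collimator-angle variants
#'
#' The ray-traced attenuation is shared across variants (only the
#' penumbra-blurred apertures differ), so this is much cheaper than
#' separate [simulate_dose()] calls.
#'
#' @inheritParams simulate_dose
#' @param collimator_degs vector of collimator angles.
#' @return named list of [dose_grid()]s, one per collimator angle.
#' @export
simulate_plan_doses <- function(phantom, ptv, beams, collimator_degs) {
  if (!any(ptv$mask)) stop("empty PTV")
  media <- phantom$media
  dm <- dim(media$labels)
  sp <- media$spacing
  mu <- mu_field(phantom, beams)
  angles <- beam_angles(beams)
  weights <- rep(1 / length(angles), length(angles))

  idx <- which(ptv$mask, arr.ind = TRUE)
  pts <- sweep(sweep(idx - 1, 2, sp, "*"), 2, media$origin, "+")
  iso <- colMeans(pts)
  sigmas <- vapply(collimator_degs, function(cd)
    collimator_sigma(beams, cd), numeric(1))

  # one aperture grid for all angles/variants
  rmax <- sqrt(max((pts[, 1] - iso[1])^2 + (pts[, 2] - iso[2])^2))
  wmax <- max(abs(pts[, 3] - iso[3]))
  dv <- 2.5
  pad <- max(beams$margin_mm) + 3 * max(sigmas) + 2 * dv
  v0 <- -(rmax + pad); w0 <- -(wmax + pad)
  nv <- ceiling(2 * (rmax + pad) / dv) + 1L
  nw <- ceiling(2 * (wmax + pad) / dv) + 1L

  nang <- length(angles)
  nvar <- length(collimator_degs)
  ap <- array(0, dim = c(nv, nw, nang, nvar))
  for (a in seq_len(nang)) {
    g <- angles[a] * pi / 180
    lv <- c(cos(g), sin(g))
    v <- (pts[, 1] - iso[1]) * lv[1] + (pts[, 2] - iso[2]) * lv[2]
    w <- pts[, 3] - iso[3]
    iv <- pmin(pmax(round((v - v0) / dv) + 1L, 1L), nv)
    jw <- pmin(pmax(round((w - w0) / dv) + 1L, 1L), nw)
    occ <- matrix(0, nv, nw)
    occ[cbind(iv, jw)] <- 1
    # margin dilation (transversal in v, craniocaudal in w)
    d2 <- edt3d_cpp(occ, c(nv, nw, 1L),
                    c(dv / max(beams$margin_mm[1], 1e-9),
                      dv / max(beams$margin_mm[2], 1e-9), 1))
    open_field <- matrix(as.numeric(d2 <= 1 + 1e-12), nv, nw)
    for (vi in seq_len(nvar)) {
      ap[, , a, vi] <- gauss_smooth_cpp(open_field, c(nv, nw, 1L),
                                        rep(sigmas[vi] / dv, 3))
    }
  }

  raw <- beam_dose_cpp(mu, dm, sp, media$origin, iso, angles, weights,
                       ap, c(nv, nw, nang, nvar), v0, w0, dv, dv,
                       min(sp))
  nvox <- prod(dm)
  out <- list()
  for (vi in seq_len(nvar)) {
    d <- array(raw[(vi - 1) * nvox + seq_len(nvox)], dim = dm)
    med <- stats::median(d[ptv$mask])
    if (med <= 0) stop("degenerate plan: zero median PTV dose")
    out[[sprintf("%02d", round(collimator_degs[vi]))]] <-
      dose_grid(d * beams$prescription_gy / med, sp, media$origin)
  }
  out
}

#' Extract an axial plane from a dose grid
#'
#' @param dose a [dose_grid()].
#' @param z plane position (mm); the nearest grid slice is used.
#' @param label plane label.
#' @return a [planar_dose()].
#' @export
extract_plane <- function(dose, z, label = sprintf("z = %.1f mm", z)) {
  zs <- axis_coords(dose, 3)
  if (z < min(zs) - dose$spacing[3] / 2 || z > max(zs) + dose$spacing[3] / 2)
    stop("plane z = ", z, " mm lies outside the dose grid")
  k <- which.min(abs(zs - z))
  planar_dose(dose$values[, , k], dose$spacing[1:2], dose$origin[1:2],
              label = label)
}

#' Extract an axial plane of a 3D medium map
#'
#' @param media a 3D [medium_map()].
#' @param z plane position (mm).
#' @return a 2D [medium_map()].
#' @export
medium_plane <- function(media, z) {
  zs <- media$origin[3] + (seq_len(dim(media$labels)[3]) - 1) * media$spacing[3]
  k <- which.min(abs(zs - z))
  medium_map(media$labels[, , k], media$spacing[1:2], media$origin[1:2])
}

bilinear_shift <- function(values, spacing, shift_mm) {
  if (all(shift_mm == 0)) return(values)
  nx <- nrow(values); ny <- ncol(values)
  gx <- rep(seq_len(nx), times = ny) - 1 - shift_mm[1] / spacing[1]
  gy <- rep(seq_len(ny), each = nx) - 1 - shift_mm[2] / spacing[2]
  ok <- gx >= 0 & gy >= 0 & gx <= nx - 1 & gy <= ny - 1
  i0 <- pmin(pmax(floor(gx), 0), nx - 2)
  j0 <- pmin(pmax(floor(gy), 0), ny - 2)
  tx <- gx - i0; ty <- gy - j0
  id <- function(i, j) i + j * nx + 1
  v <- (1 - tx) * (1 - ty) * values[id(i0, j0)] +
    tx * (1 - ty) * values[id(i0 + 1, j0)] +
    (1 - tx) * ty * values[id(i0, j0 + 1)] +
    tx * ty * values[id(i0 + 1, j0 + 1)]
  v[!ok] <- 0
  matrix(v, nx, ny)
}

#' Simulate a measured ("film") dose plane
#'
#' Extracts an axial plane from the calculated dose, applies the per-
#' medium systematic offsets, adds Gaussian noise (as % of the plane
#' maximum) and applies the rigid registration shift -- emulating a
#' radiochromic film measurement in a phantom gap.  With zero offsets,
#' noise and shift the extracted plane is returned unchanged.
#'
#' @param dose a [dose_grid()] (or a [planar_dose()], in which case
#'   `plane_z` and `media` slicing are skipped).
#' @param plane_z axial position of the film plane (mm).
#' @param beams a [beam_spec()] supplying `medium_offset_pct`,
#'   `noise_sd_pct`, `shift_mm` and `seed`.
#' @param media the phantom [medium_map()] (3D, sliced at `plane_z`; or
#'   2D used as is).
#' @return a [planar_dose()].
#' @export
make_measured_plane <- function(dose, plane_z = NULL, beams, media = NULL) {
  if (inherits(dose, "dose_grid")) {
    if (is.null(plane_z)) stop("plane_z required for a 3D dose grid")
    plane <- extract_plane(dose, plane_z,
                           label = sprintf("film at z = %.1f mm", plane_z))
    if (!is.null(media) && length(dim(media$labels)) == 3L)
      media <- medium_plane(media, plane_z)
  } else {
    plane <- dose
  }
  vals <- plane$values
  if (!is.null(media)) {
    off <- beams$medium_offset_pct
    for (mn in names(off)) {
      code <- match(mn, media$levels) - 1L
      sel <- media$labels == code
      # offsets are quoted as (calculated - measured)/measured, so the
      # measured plane divides them out
      vals[sel] <- vals[sel] / (1 + off[[mn]] / 100)
    }
  }
  if (beams$noise_sd_pct > 0) {
    set.seed(beams$seed)
    vals <- vals + stats::rnorm(length(vals),
                                sd = beams$noise_sd_pct / 100 * max(vals))
  }
  vals <- bilinear_shift(vals, plane$spacing, beams$shift_mm)
  vals[vals < 0] <- 0
  planar_dose(vals, plane$spacing, plane$origin, label = plane$label)
}

# prescription-dose distribution: the palliative 36 Gy scheme dominates,
# with a tail of other fractionations
sample_prescription <- function() {
  doses <- c(36, 50, 30, 55, 59.4, 48, 45, 39, 35, 20)
  probs <- c(21, 3, 3, 2, 1, 1, 1, 1, 1, 1) / 35
  sample(doses, 1, prob = probs)
}

#' Generate a synthetic patient cohort with paired plans
#'
#' For each patient: a slightly jittered thorax phantom; a lobed target
#' sampled so PTV volumes are log-uniform within 145.2-2686.5 cm^3; a
#' static plan (3, 4 or 5 fields with probabilities 25/35, 9/35, 1/35)
#' and a single-arc plan at four collimator-angle variants (0, 30, 45,
#' 90 degrees); all geometric and DVH plan metrics computed through the
#' package's other modules.  Fully deterministic for a fixed master seed.
#'
#' @param n_patients number of patients (`>= 2`).
#' @param master_seed integer master seed.
#' @param phantom_dim,phantom_spacing cohort grid settings.
#' @param out_dir optional directory; when given, portable doses, masks,
#'   media, measured film planes and a JSON manifest are written per
#'   patient.
#' @param film_z_offset_mm film plane position relative to the isocentre
#'   (default 26 mm caudal).
#' @return list of class `cohort` with `table` (one row per patient per
#'   variant: metrics plus per-patient covariates) and `manifest`.
#' @export
make_cohort <- function(n_patients, master_seed = 1L,
                        phantom_dim = c(64L, 48L, 40L),
                        phantom_spacing = c(5, 5, 5),
                        out_dir = NULL, film_z_offset_mm = -26) {
  if (n_patients < 2) stop("need at least 2 patients")
  set.seed(master_seed)
  patient_seeds <- sample.int(.Machine$integer.max - 1L, n_patients)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  variants <- c("3DCRT", "DCAT_00", "DCAT_30", "DCAT_45", "DCAT_90")
  colli <- c(0, 30, 45, 90)
  rows <- list()
  manifest <- list()

  for (p in seq_len(n_patients)) {
    set.seed(patient_seeds[p])
    jit <- function(x, f = 0.05) x * stats::runif(length(x), 1 - f, 1 + f)
    ph_spec <- phantom_spec(dim = phantom_dim, spacing = phantom_spacing,
                            body_mm = jit(c(150, 100)),
                            lung_axes_mm = jit(c(46, 64, 82)),
                            seed = patient_seeds[p])
    phantom <- make_phantom(ph_spec)

    prescription <- sample_prescription()
    v_ptv_target <- exp(stats::runif(1, log(170), log(2400)))
    lobes <- sample(1:4, 1, prob = c(0.4, 0.3, 0.2, 0.1))
    margin <- sample(5:10, 1)
    # place small targets in a lung, large ones centrally
    big <- v_ptv_target > 900
    centre <- if (big) c(stats::runif(1, -25, 25), stats::runif(1, -30, 10),
                         stats::runif(1, -20, 20))
      else c(sample(c(-1, 1), 1) * stats::runif(1, 40, 75),
             stats::runif(1, -45, 20), stats::runif(1, -35, 35))

    r <- (3 * v_ptv_target * 1000 / (4 * pi))^(1 / 3) - margin
    target <- NULL
    for (iter in 1:3) {
      tsp <- target_spec(centre_mm = centre, radius_mm = r, lobes = lobes,
                         margin_mm = margin, seed = patient_seeds[p])
      target <- suppressWarnings(make_target(tsp, phantom))
      v_now <- mask_volume_cm3(target$ptv)
      if (abs(v_now - v_ptv_target) / v_ptv_target < 0.05) break
      r <- r * (v_ptv_target / v_now)^(1 / 3)
    }

    n_fields <- sample(c(3L, 4L, 5L), 1, prob = c(25, 9, 1) / 35)
    mu_static <- round(stats::rnorm(1, 270, 35))
    mu_arc <- round(mu_static - stats::rnorm(1, 50, 12))
    film_seed <- (patient_seeds[p] %% 1000000L) + 17L

    static_beams <- beam_spec("static", n_fields = n_fields,
                              prescription_gy = prescription,
                              mu = mu_static,
                              medium_offset_pct = c(lung = 1.0, soft = 1.6,
                                                    bone = -4.3),
                              shift_mm = c(1.5, -1.0),
                              seed = film_seed)
    arc_beams <- beam_spec("arc", prescription_gy = prescription,
                           mu = mu_arc,
                           medium_offset_pct = c(lung = 0.2, soft = 1.2,
                                                 bone = -2.4),
                           shift_mm = c(0.8, 0.5),
                           seed = film_seed + 1L)

    static_dose <- simulate_dose(phantom, target$ptv, static_beams)
    arc_doses <- simulate_plan_doses(phantom, target$ptv, arc_beams, colli)

    geo <- shape_metrics(target$ctv, target$ptv, margin,
                         cord = phantom$cord, lungs = phantom$lungs,
                         external = phantom$external)
    geo$V_lung_cm3 <- mask_volume_cm3(phantom$lungs)
    geo$stage <- cut(geo$V_PTV_cm3, c(0, 400, 1000, Inf),
                     labels = c("II", "III", "IV"))

    doses <- c(list(static_dose), unname(arc_doses))
    mus <- c(mu_static, round(mu_arc * (1 + c(0, 0.5, 1, 2) / 100)))
    for (vi in seq_along(variants)) {
      pm <- plan_metrics(doses[[vi]], target$ptv, prescription,
                         lungs = phantom$lungs, cord = phantom$cord,
                         oesophagus = phantom$oesophagus,
                         external = phantom$external, mu = mus[vi])
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(patient = p, variant = variants[vi]), pm, geo)
    }

    if (!is.null(out_dir)) {
      pdir <- file.path(out_dir, sprintf("patient%02d", p))
      dir.create(pdir, showWarnings = FALSE)
      write_portable(phantom$media, file.path(pdir, "media"))
      for (nm in c("external", "lungs", "cord", "oesophagus"))
        write_portable(phantom[[nm]], file.path(pdir, nm))
      write_portable(target$ctv, file.path(pdir, "ctv"))
      write_portable(target$ptv, file.path(pdir, "ptv"))
      write_portable(static_dose, file.path(pdir, "dose_3DCRT"))
      for (vi in seq_along(colli))
        write_portable(arc_doses[[vi]],
                       file.path(pdir, sprintf("dose_DCAT_%02d", colli[vi])))
      film_z <- film_z_offset_mm
      for (tech in c("3DCRT", "DCAT_45")) {
        dz <- if (tech == "3DCRT") static_dose else arc_doses[["45"]]
        bs <- if (tech == "3DCRT") static_beams else arc_beams
        film <- make_measured_plane(dz, film_z, bs, phantom$media)
        write_portable(film, file.path(pdir, paste0("film_", tech)))
        write_portable(extract_plane(dz, film_z),
                       file.path(pdir, paste0("plane_", tech)))
      }
      write_portable(medium_plane(phantom$media, film_z),
                     file.path(pdir, "media_plane"))
      manifest[[length(manifest) + 1L]] <-
        list(patient = p, dir = basename(pdir), margin_mm = margin,
             prescription_gy = prescription, n_fields = n_fields,
             film_z_mm = film_z)
    }
  }

  table <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    utils::write.csv(table, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(n_patients = n_patients,
                              master_seed = master_seed,
                              patients = manifest),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(list(table = table, manifest = manifest,
                 master_seed = master_seed), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients x %d variants (seed %d)\n",
              length(unique(x$table$patient)),
              length(unique(x$table$variant)), x$master_seed))
  invisible(x)
}
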