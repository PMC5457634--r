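#' Cumulative dose-volume histogram
#'
#' The fraction at dose t is the volume of structure voxels receiving at
#' least t, divided by the structure volume, evaluated on uniform dose-bin
#' edges from 0 to just past the structure maximum.
#'
#' @param dose a [dose_grid()].
#' @param mask a nonempty [structure_mask()] on the same geometry.
#' @param bin_width dose bin width in Gy (default 0.01).
#' @return object of class `dvh_curve`: list with `dose` (bin edges, Gy),
#'   `fraction` (non-increasing, starts at 1), `structure`, `volume_cm3`.
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.01) {
  stop_unless_same_geometry(dose, mask, "dose and mask")
  if (!any(mask$mask)) stop("empty mask")
  if (!is.finite(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  d <- sort(dose$values[mask$mask])
  n <- length(d)
  edges <- seq(0, max(d) + bin_width, by = bin_width)
  # voxels with dose >= t  ==  n - #(dose < t)
  frac <- (n - findInterval(edges, d, left.open = TRUE)) / n
  structure(list(dose = edges, fraction = frac, structure = mask$name,
                 volume_cm3 = mask_volume_cm3(mask)),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> '%s': %.2f cm^3, %d bins up to %.2f Gy\n",
              x$structure, x$volume_cm3, length(x$dose), max(x$dose)))
  invisible(x)
}

#' Dose covering a volume percentage (Dv)
#'
#' Smallest dose t at which the cumulative volume fraction drops to
#' `v`/100, linearly interpolated between bin edges.  `dose_at_volume(dvh,
#' 2)` is D2 (near-maximum dose), `dose_at_volume(dvh, 98)` is D98
#' (near-minimum dose).
#'
#' @param dvh a `dvh_curve`.
#' @param v volume percentage in (0, 100).
#' @return dose in Gy.
#' @export
dose_at_volume <- function(dvh, v) {
  if (!is.finite(v) || v <= 0 || v >= 100) stop("v must be in (0, 100)")
  f <- v / 100
  frac <- dvh$fraction
  i <- which(frac <= f)[1]
  if (is.na(i)) return(dvh$dose[length(dvh$dose)])
  if (i == 1L) return(dvh$dose[1])
  # interpolate between the bracketing edges
  f0 <- frac[i - 1L]; f1 <- frac[i]
  d0 <- dvh$dose[i - 1L]; d1 <- dvh$dose[i]
  if (f0 == f1) return(d1)
  d0 + (f0 - f) / (f0 - f1) * (d1 - d0)
}

#' Volume percentage receiving at least a dose (VxGy)
#'
#' @param dvh a `dvh_curve`.
#' @param t dose in Gy, `>= 0`.
#' @return percentage of the structure volume receiving `>= t`, linearly
#'   interpolated between bin edges.
#' @export
volume_at_dose <- function(dvh, t) {
  if (!is.finite(t) || t < 0) stop("t must be >= 0")
  if (t >= max(dvh$dose)) return(0)
  100 * stats::approx(dvh$dose, dvh$fraction, xout = t, rule = 2)$y
}

#' Dose to the hottest absolute volume (e.g. D1cc)
#'
#' Maximum dose t such that at least `vol` cm^3 of the structure receives
#' `>= t` (the "hottest `vol`" dose), interpolated between the sorted
#' voxel doses.
#'
#' @param dose a [dose_grid()].
#' @param mask a nonempty [structure_mask()] on the same geometry.
#' @param vol absolute volume in cm^3, `0 < vol <=` structure volume.
#' @return dose in Gy.
#' @export
dose_at_absolute_volume <- function(dose, mask, vol) {
  stop_unless_same_geometry(dose, mask, "dose and mask")
  if (!any(mask$mask)) stop("empty mask")
  vtot <- mask_volume_cm3(mask)
  if (!is.finite(vol) || vol <= 0) stop("vol must be > 0")
  if (vol > vtot + 1e-9)
    stop(sprintf("vol (%.3f cm^3) exceeds structure volume (%.3f cm^3)",
                 vol, vtot))
  d <- sort(dose$values[mask$mask], decreasing = TRUE)
  vv <- voxel_volume_cm3(mask)
  j <- vol / vv  # voxel count covering vol (possibly fractional)
  if (j <= 1) return(d[1])
  j <- min(j, length(d))
  lo <- floor(j)
  if (lo == j || lo == length(d)) return(d[j])
  d[lo] + (j - lo) * (d[lo + 1L] - d[lo])
}

#' Conformation number
#'
#' \deqn{CN = (TV_{RI}/TV) \cdot (TV_{RI}/V_{RI})}
#' where `TV_RI` is the target volume covered by the reference isodose,
#' `TV` the target volume and `V_RI` the total volume covered by the
#' reference isodose (restricted to the external contour when supplied).
#' CN is 1 exactly when the reference-isodose region coincides with the
#' target; if no voxel reaches the reference isodose, CN is 0 by
#' convention.
#'
#' @param dose a [dose_grid()].
#' @param target nonempty target [structure_mask()].
#' @param reference_isodose reference isodose in Gy (commonly 95% of the
#'   prescription), `> 0`.
#' @param external optional external-contour mask restricting `V_RI`.
#' @return CN in `[0, 1]`.
#' @export
conformation_number <- function(dose, target, reference_isodose,
                                external = NULL) {
  stop_unless_same_geometry(dose, target, "dose and target")
  if (!any(target$mask)) stop("empty target")
  if (!is.finite(reference_isodose) || reference_isodose <= 0)
    stop("reference_isodose must be > 0")
  hot <- dose$values >= reference_isodose
  if (!is.null(external)) {
    stop_unless_same_geometry(dose, external, "dose and external")
    hot <- hot & external$mask
  }
  tv <- sum(target$mask)
  tv_ri <- sum(hot & target$mask)
  v_ri <- sum(hot)
  if (v_ri == 0) {
    message("no voxel reaches the reference isodose; CN = 0 by convention")
    return(0)
  }
  (tv_ri / tv) * (tv_ri / v_ri)
}

#' Homogeneity index
#'
#' \deqn{HI = (D_2 - D_{98}) / D_{nom}};  0 for a perfectly homogeneous
#' target dose.
#'
#' @param D2,D98 near-maximum and near-minimum doses (Gy).
#' @param D_nom nominal prescribed dose (Gy), `> 0`.
#' @return dimensionless HI.
#' @export
homogeneity_index <- function(D2, D98, D_nom) {
  if (!is.finite(D_nom) || D_nom <= 0) stop("D_nom must be > 0")
  (D2 - D98) / D_nom
}

#' Dose homogeneity dispersion
#'
#' Sample standard deviation of the dose over the structure, divided by
#' its mean; scale-invariant, 0 for a uniform dose.
#'
#' @param dose a [dose_grid()].
#' @param mask a nonempty [structure_mask()] on the same geometry.
#' @return dimensionless DHD.
#' @export
dhd <- function(dose, mask) {
  stop_unless_same_geometry(dose, mask, "dose and mask")
  if (!any(mask$mask)) stop("empty mask")
  d <- dose$values[mask$mask]
  m <- mean(d)
  if (m <= 0) stop("mean structure dose is zero; DHD undefined")
  stats::sd(d) / m
}

#' Scalar plan metrics from a dose grid and structure masks
#'
#' Computes every DVH-derived plan metric of the comparison report in one
#' call.  Doses to organs at risk are reported in cGy, matching clinical
#' convention; target indices are dimensionless.
#'
#' @param dose a [dose_grid()].
#' @param ptv target [structure_mask()].
#' @param prescription_gy nominal prescribed dose (Gy).
#' @param lungs,cord,oesophagus,external optional [structure_mask()]s;
#'   metrics needing an absent structure are `NA`.
#' @param mu recorded monitor units for the plan (integer attribute of the
#'   plan, never computed here); `NA` when unknown.
#' @param reference_isodose_pct reference isodose as % of prescription
#'   (default 95).
#' @param bin_width DVH bin width in Gy.
#' @return a one-row `data.frame` with CN, HI, DHD, D2/D98 (Gy),
#'   MLD (cGy), V20Gy/V5Gy (%), D1cc_cord (cGy), mean oesophagus dose
#'   (cGy), MU, prescription and reference isodose level.
#' @export
plan_metrics <- function(dose, ptv, prescription_gy, lungs = NULL,
                         cord = NULL, oesophagus = NULL, external = NULL,
                         mu = NA_real_, reference_isodose_pct = 95,
                         bin_width = 0.01) {
  ri <- prescription_gy * reference_isodose_pct / 100
  dv <- compute_dvh(dose, ptv, bin_width)
  D2 <- dose_at_volume(dv, 2)
  D98 <- dose_at_volume(dv, 98)
  lung_dvh <- if (!is.null(lungs)) compute_dvh(dose, lungs, bin_width)
  data.frame(
    CN = conformation_number(dose, ptv, ri, external),
    HI = homogeneity_index(D2, D98, prescription_gy),
    DHD = dhd(dose, ptv),
    D2_Gy = D2,
    D98_Gy = D98,
    MLD_cGy = if (is.null(lungs)) NA_real_ else
      100 * mean(dose$values[lungs$mask]),
    V20Gy_pct = if (is.null(lungs)) NA_real_ else volume_at_dose(lung_dvh, 20),
    V5Gy_pct = if (is.null(lungs)) NA_real_ else volume_at_dose(lung_dvh, 5),
    D1cc_cord_cGy = if (is.null(cord)) NA_real_ else
      100 * dose_at_absolute_volume(dose, cord,
                                    min(1, mask_volume_cm3(cord))),
    oeso_mean_cGy = if (is.null(oesophagus)) NA_real_ else
      100 * mean(dose$values[oesophagus$mask]),
    MU = mu,
    prescription_Gy = prescription_gy,
    reference_isodose_pct = reference_isodose_pct)
}

#' Planning-constraint check
#'
#' Evaluates the departmental planning constraints with strict
#' inequalities (a value exactly on the limit fails): lung V20Gy < 35%,
#' V5Gy < 60%, MLD < 15 Gy; spinal-cord maximum dose < 50 Gy with D1cc as
#' the maximum-dose surrogate; mean oesophagus dose < 34 Gy.  Constraints
#' whose metric is missing are reported as not evaluated (`NA`).
#'
#' @param metrics a one-row `data.frame` from [plan_metrics()] (or a list
#'   with the same fields).
#' @return `data.frame` with columns `constraint`, `value`, `limit`,
#'   `pass`.
#' @export
check_constraints <- function(metrics) {
  get <- function(f) if (is.null(metrics[[f]])) NA_real_ else
    as.numeric(metrics[[f]])
  tab <- data.frame(
    constraint = c("lung V20Gy < 35%", "lung V5Gy < 60%", "MLD < 15 Gy",
                   "cord D1cc < 50 Gy", "oesophagus mean < 34 Gy"),
    value = c(get("V20Gy_pct"), get("V5Gy_pct"), get("MLD_cGy") / 100,
              get("D1cc_cord_cGy") / 100, get("oeso_mean_cGy") / 100),
    limit = c(35, 60, 15, 50, 34))
  tab$pass <- ifelse(is.na(tab$value), NA, tab$value < tab$limit)
  tab
}
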