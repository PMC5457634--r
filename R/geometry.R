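#' Rasterize planar contours onto a grid geometry
#'
#' A voxel is included iff its centre lies inside any polygon (even-odd
#' rule) of the contour slice nearest in z; each contour slice covers the
#' slab of half the contour slice gap on either side (a single-slice
#' contour covers one grid slice spacing).  No partial-volume weighting is
#' applied.
#'
#' @param contours a [contour_set()].
#' @param geometry a `dose_grid`, `structure_mask` or `medium_map`
#'   supplying shape, spacing and origin.
#' @param name,role forwarded to [structure_mask()]; `name` defaults to the
#'   contour set's name.
#' @return a [structure_mask()].
#' @export
rasterize <- function(contours, geometry, name = contours$name,
                      role = "other") {
  dims <- dim(if (!is.null(geometry$values)) geometry$values else
              if (!is.null(geometry$mask)) geometry$mask else geometry$labels)
  mask <- array(FALSE, dim = dims)
  if (!length(contours$slices))
    return(structure_mask(mask, geometry$spacing, geometry$origin,
                          name = name, role = role))
  xs <- geometry$origin[1] + (seq_len(dims[1]) - 1) * geometry$spacing[1]
  ys <- geometry$origin[2] + (seq_len(dims[2]) - 1) * geometry$spacing[2]
  zs <- geometry$origin[3] + (seq_len(dims[3]) - 1) * geometry$spacing[3]
  cz <- vapply(contours$slices, function(s) s$z, numeric(1))
  half <- if (length(cz) > 1) stats::median(diff(cz)) / 2 else
    geometry$spacing[3] / 2
  # contour extent check
  for (s in contours$slices) {
    for (p in s$polygons) {
      p <- as.matrix(p)
      if (min(p[, 1]) < min(xs) - 1e-9 || max(p[, 1]) > max(xs) + 1e-9 ||
          min(p[, 2]) < min(ys) - 1e-9 || max(p[, 2]) > max(ys) + 1e-9)
        stop("contour at z = ", s$z, " mm extends outside the grid")
    }
  }
  pts <- expand.grid(x = xs, y = ys)
  for (k in seq_along(zs)) {
    d <- abs(cz - zs[k])
    i <- which.min(d)
    if (d[i] > half + 1e-9) next
    sl <- contours$slices[[i]]
    inside <- rep(FALSE, nrow(pts))
    for (p in sl$polygons) {
      p <- as.matrix(p)
      inside <- xor(inside,
                    points_in_polygon_cpp(pts$x, pts$y, p[, 1], p[, 2]))
    }
    mask[, , k] <- inside
  }
  structure_mask(mask, geometry$spacing, geometry$origin,
                 name = name, role = role)
}

#' Euclidean margin expansion of a structure mask
#'
#' Dilates the mask so a voxel is included iff its centre lies within the
#' (possibly anisotropic) margin of the input set, computed with an exact
#' Euclidean distance transform.  Extensive (output contains input) and
#' monotone in the margin.
#'
#' @param mask a [structure_mask()].
#' @param margin mm; scalar (isotropic) or length-3 per-axis margin,
#'   all `>= 0`.
#' @param name optional new structure name.
#' @param role optional new role tag.
#' @return the dilated [structure_mask()].
#' @export
expand_margin <- function(mask, margin, name = mask$name, role = mask$role) {
  if (length(margin) == 1L) margin <- rep(margin, 3L)
  if (length(margin) != 3L || any(margin < 0))
    stop("margin must be a scalar or length-3 vector of non-negative mm")
  if (all(margin == 0) || !any(mask$mask))
    return(structure_mask(mask$mask, mask$spacing, mask$origin, name, role))
  # scale each axis by 1/margin so the margin ellipsoid becomes a unit ball
  eff <- pmax(margin, 1e-9)
  d2 <- edt3d_cpp(as.numeric(mask$mask), dim(mask$mask),
                  mask$spacing / eff)
  out <- array(d2 <= 1 + 1e-12, dim = dim(mask$mask))
  structure_mask(out, mask$spacing, mask$origin, name, role)
}

#' Surface area and volume of a structure mask
#'
#' Volume is voxel count times voxel volume.  Surface area comes from a
#' marching-tetrahedra triangulation of the 0.5 level set of the binary
#' field after smoothing with a 1.25-voxel-sigma Gaussian (plain face
#' counting overestimates smooth surfaces by a constant factor; the
#' smoothing bandwidth makes the level-set curvature bias dominate the
#' lattice faceting bias, so the estimate converges monotonically on
#' smooth shapes as the grid is refined).
#'
#' @param mask a nonempty [structure_mask()].
#' @return list with `A` (cm^2) and `V` (cm^3).
#' @export
surface_and_volume <- function(mask) {
  if (!any(mask$mask)) stop("empty mask")
  V <- mask_volume_cm3(mask)
  dims <- dim(mask$mask)
  # zero-pad so smoothing and the isosurface close at the borders
  pad <- 6L
  big <- array(0, dims + 2L * pad)
  big[pad + seq_len(dims[1]), pad + seq_len(dims[2]),
      pad + seq_len(dims[3])] <- as.numeric(mask$mask)
  sm <- gauss_smooth_cpp(big, dim(big), c(1.25, 1.25, 1.25))
  A_mm2 <- isosurface_area_cpp(sm, dim(big), mask$spacing, 0.5)
  list(A = A_mm2 / 100, V = V)
}

#' Sphericity of a shape
#'
#' \deqn{\Psi = \pi^{1/3} (6V)^{2/3} / A}
#'
#' equals 1 for a perfect sphere and decreases towards 0 as the shape
#' departs from it.
#'
#' @param A surface area (cm^2), `> 0`.
#' @param V volume (cm^3), `> 0`.
#' @return dimensionless sphericity.
#' @export
sphericity <- function(A, V) {
  if (!is.finite(A) || !is.finite(V) || A <= 0 || V <= 0)
    stop("A and V must be positive")
  pi^(1 / 3) * (6 * V)^(2 / 3) / A
}

#' Shell-based sphericity surrogate from CTV and PTV volumes
#'
#' Uses the onion-like CTV-inside-PTV construction: the shell volume over
#' the margin approximates the surface area of the mid-shell structure,
#' giving
#' \deqn{\tilde\Psi = \pi^{1/3} d \, (3 (V_{CTV}+V_{PTV}))^{2/3} /
#'   (V_{PTV}-V_{CTV}).}
#' Behaves like sphericity but can exceed 1 (concentric spheres give
#' about 1.02 at a 5 mm margin on a 20 mm CTV radius) and tends to the
#' mid-shell sphericity as `d` tends to 0.
#'
#' @param V_CTV,V_PTV volumes in cm^3 with `V_PTV > V_CTV > 0`.
#' @param d CTV-to-PTV margin in mm, `> 0`.
#' @return dimensionless sphericity surrogate.
#' @export
sphericity_like <- function(V_CTV, V_PTV, d) {
  if (!is.finite(d) || d <= 0) stop("d must be positive")
  if (!is.finite(V_CTV) || V_CTV <= 0) stop("V_CTV must be positive")
  if (!(V_PTV > V_CTV)) stop("degenerate shell: V_PTV must exceed V_CTV")
  vc <- V_CTV * 1000  # cm^3 -> mm^3
  vp <- V_PTV * 1000
  pi^(1 / 3) * d * (3 * (vc + vp))^(2 / 3) / (vp - vc)
}

#' Minimum Euclidean distance between two structures
#'
#' Minimum over voxel-centre pairs, computed in full 3D with an exact
#' distance transform; 0 if the structures intersect.  The `per_slice`
#' variant restricts the search to within-slice (2D) distances and takes
#' the minimum over slices, mirroring scripts that scan structure files
#' slice by slice; the 3D result is never larger.
#'
#' @param maskA,maskB nonempty [structure_mask()]s on the same geometry.
#' @param per_slice logical; compute the per-slice 2D variant.
#' @return distance in mm.
#' @export
min_distance <- function(maskA, maskB, per_slice = FALSE) {
  stop_unless_same_geometry(maskA, maskB, "masks")
  if (!any(maskA$mask) || !any(maskB$mask)) stop("empty mask")
  if (per_slice) {
    nz <- dim(maskA$mask)[3]
    best <- Inf
    for (k in seq_len(nz)) {
      a <- maskA$mask[, , k]
      b <- maskB$mask[, , k]
      if (!any(a) || !any(b)) next
      d2 <- edt3d_cpp(as.numeric(b), c(dim(a), 1L), c(maskA$spacing[1:2], 1))
      best <- min(best, min(d2[as.logical(a)]))
    }
    if (!is.finite(best)) stop("no slice contains both structures")
    return(sqrt(best))
  }
  d2 <- edt3d_cpp(as.numeric(maskB$mask), dim(maskB$mask), maskB$spacing)
  sqrt(min(d2[maskA$mask]))
}

#' Minimum distance from a structure to the skin surface
#'
#' Distance from `mask` to the complement of the external (body) contour.
#'
#' @param mask a nonempty [structure_mask()] (e.g. the CTV).
#' @param external the external/body [structure_mask()].
#' @return distance in mm.
#' @export
distance_to_skin <- function(mask, external) {
  stop_unless_same_geometry(mask, external, "masks")
  if (!any(mask$mask)) stop("empty mask")
  outside <- !external$mask
  if (!any(outside)) stop("external mask covers the whole grid")
  d2 <- edt3d_cpp(as.numeric(outside), dim(outside), external$spacing)
  sqrt(min(d2[mask$mask]))
}

#' Isocentre displacement in the transversal plane
#'
#' \deqn{R = \sqrt{x_{ml}^2 + x_{ap}^2}}
#'
#' @param x_ml,x_ap displacements (mm) in the medio-lateral and
#'   antero-posterior directions.
#' @return displacement magnitude in mm.
#' @export
isocentre_displacement <- function(x_ml, x_ap) sqrt(x_ml^2 + x_ap^2)

#' Overlap between two structures
#'
#' @param maskA,maskB [structure_mask()]s on the same geometry; `maskA`
#'   must be nonempty (the percentage is relative to it).
#' @return list with `cm3` (intersection volume) and `pct` (fraction of
#'   `maskA`, in percent).
#' @export
overlap <- function(maskA, maskB) {
  stop_unless_same_geometry(maskA, maskB, "masks")
  nA <- sum(maskA$mask)
  if (nA == 0) stop("empty maskA: overlap percentage undefined")
  nI <- sum(maskA$mask & maskB$mask)
  list(cm3 = nI * voxel_volume_cm3(maskA), pct = 100 * nI / nA)
}

#' Geometric target metrics for a CTV/PTV pair
#'
#' One row of the geometric-metrics report: volumes, mask-derived surface
#' area and sphericity of the PTV, the shell-based surrogate, distances to
#' cord and skin, isocentre displacement, and PTV-lung overlap.
#'
#' @param ctv,ptv CTV and PTV [structure_mask()]s.
#' @param margin_mm CTV-to-PTV margin used for the surrogate (mm).
#' @param cord,lungs,external optional [structure_mask()]s; metrics needing
#'   an absent structure come back `NA`.
#' @param origin_xy patient origin (mm, length 2) for the isocentre
#'   displacement; defaults to `c(0, 0)`.
#' @return a one-row `data.frame`.
#' @export
shape_metrics <- function(ctv, ptv, margin_mm, cord = NULL, lungs = NULL,
                          external = NULL, origin_xy = c(0, 0)) {
  sv <- surface_and_volume(ptv)
  v_ctv <- mask_volume_cm3(ctv)
  v_ptv <- mask_volume_cm3(ptv)
  idx <- which(ptv$mask, arr.ind = TRUE)
  centre <- ptv$origin + (colMeans(idx) - 1) * ptv$spacing
  data.frame(
    V_CTV_cm3 = v_ctv,
    V_PTV_cm3 = v_ptv,
    A_PTV_cm2 = sv$A,
    psi = sphericity(sv$A, sv$V),
    psi_tilde = sphericity_like(v_ctv, v_ptv, margin_mm),
    margin_mm = margin_mm,
    R_mm = isocentre_displacement(centre[1] - origin_xy[1],
                                  centre[2] - origin_xy[2]),
    d_CTV_cord_mm = if (is.null(cord)) NA_real_ else min_distance(ctv, cord),
    d_PTV_cord_mm = if (is.null(cord)) NA_real_ else min_distance(ptv, cord),
    d_CTV_skin_mm = if (is.null(external)) NA_real_ else
      distance_to_skin(ctv, external),
    overlap_lung_cm3 = if (is.null(lungs)) NA_real_ else
      overlap(ptv, lungs)$cm3,
    overlap_lung_pct = if (is.null(lungs)) NA_real_ else
      overlap(ptv, lungs)$pct)
}
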