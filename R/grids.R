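#' Regular 3D dose grid
#'
#' A scalar dose field (Gy) on a regular grid in patient-style mm
#' coordinates.  `values[i, j, k]` sits at
#' `origin + (i-1, j-1, k-1) * spacing`; axis order is x (medio-lateral),
#' y (antero-posterior), z (cranio-caudal) with voxel values located at
#' voxel centres.
#'
#' @param values numeric 3D array of doses in Gy (all `>= 0`).
#' @param spacing numeric length-3, mm per axis (all `> 0`).
#' @param origin numeric length-3, mm position of the first voxel centre.
#' @param flipped_z logical; `TRUE` when the source file stored frames in
#'   descending z and they were re-sorted ascending on read.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, spacing, origin = c(0, 0, 0),
                      flipped_z = FALSE) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  if (any(dim(values) < 1L)) stop("zero-sized grid")
  check_grid_fields(values, spacing, origin, 3L)
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), axis_order = "xyz",
                 flipped_z = isTRUE(flipped_z)),
            class = "dose_grid")
}

#' Planar (2D) dose distribution
#'
#' Represents one dose plane, e.g. a film measurement or a plane exported
#' from a treatment planning system.
#'
#' @param values numeric matrix of doses in Gy; rows index x, columns y.
#' @param spacing numeric length-2, mm per axis.
#' @param origin numeric length-2, mm position of the first pixel centre.
#' @param label free-text plane label (e.g. "26 mm caudal to isocentre").
#' @return An object of class `planar_dose`.
#' @export
planar_dose <- function(values, spacing, origin = c(0, 0), label = "") {
  values <- as.matrix(values)
  if (any(dim(values) < 1L)) stop("zero-sized grid")
  check_grid_fields(values, spacing, origin, 2L)
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), label = as.character(label)),
            class = "planar_dose")
}

check_grid_fields <- function(values, spacing, origin, ndim) {
  if (length(spacing) != ndim || length(origin) != ndim)
    stop("spacing and origin must have length ", ndim)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be positive")
  if (any(!is.finite(origin))) stop("origin must be finite")
  if (anyNA(values)) stop("values must not contain NA")
  if (any(values < 0)) stop("doses must be >= 0")
  invisible(TRUE)
}

#' Binary structure mask on a grid geometry
#'
#' @param mask logical (or 0/1) 3D array aligned to a reference grid.
#' @param spacing,origin grid geometry in mm (as in [dose_grid()]).
#' @param name structure name.
#' @param role one of `"CTV"`, `"PTV"`, `"lung"`, `"cord"`, `"oesophagus"`,
#'   `"external"`, `"other"`.
#' @return An object of class `structure_mask`; its voxel volume (cm^3) is
#'   the product of the spacings.
#' @export
structure_mask <- function(mask, spacing, origin = c(0, 0, 0),
                           name = "structure", role = "other") {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3D array")
  if (any(dim(mask) < 1L)) stop("zero-sized grid")
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop("mask must not contain NA")
  role <- match.arg(role, c("CTV", "PTV", "lung", "cord", "oesophagus",
                            "external", "other"))
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive numbers")
  structure(list(mask = mask, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), name = as.character(name),
                 role = role),
            class = "structure_mask")
}

#' Per-voxel medium labels
#'
#' Labels every voxel as one of `outside`, `lung`, `soft`, `bone`; the
#' media partition the grid (each voxel carries exactly one label).
#'
#' @param labels integer 3D array with values 0 (outside), 1 (lung),
#'   2 (soft tissue), 3 (bone) -- or a 2D matrix for planar label maps.
#' @param spacing,origin grid geometry in mm.
#' @return An object of class `medium_map`.
#' @export
medium_map <- function(labels, spacing, origin = NULL) {
  labels <- as.array(labels)
  nd <- length(dim(labels))
  if (!nd %in% c(2L, 3L)) stop("`labels` must be a 2D or 3D array")
  storage.mode(labels) <- "integer"
  if (!all(labels %in% 0:3))
    stop("labels must be 0 (outside), 1 (lung), 2 (soft), 3 (bone)")
  if (is.null(origin)) origin <- rep(0, nd)
  if (length(spacing) != nd || length(origin) != nd)
    stop("spacing/origin must match label dimensionality")
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 levels = c("outside", "lung", "soft", "bone")),
            class = "medium_map")
}

#' Planar contours of one structure
#'
#' @param name structure name.
#' @param slices list of slices, each a list with elements `z` (mm) and
#'   `polygons` (list of closed planar polygons, each an n x 2 matrix of
#'   mm vertices, n >= 3, last vertex implicitly joined to the first).
#' @return An object of class `contour_set`.  Slices are sorted by
#'   strictly increasing z.
#' @export
contour_set <- function(name, slices = list()) {
  for (s in slices) {
    if (is.null(s$z) || !is.finite(s$z)) stop("every slice needs a z (mm)")
    for (p in s$polygons) {
      p <- as.matrix(p)
      if (ncol(p) != 2L || nrow(p) < 3L)
        stop("polygons must be n x 2 matrices with n >= 3")
    }
  }
  if (length(slices)) {
    z <- vapply(slices, function(s) s$z, numeric(1))
    if (anyDuplicated(z)) stop("slice z positions must be distinct")
    slices <- slices[order(z)]
  }
  structure(list(name = as.character(name), slices = slices),
            class = "contour_set")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s voxels, spacing %s mm, origin %s mm, max %.3f Gy\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", "),
              max(x$values)))
  invisible(x)
}

#' @export
print.planar_dose <- function(x, ...) {
  cat(sprintf("<planar_dose> %s px, spacing %s mm, max %.3f Gy%s\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              max(x$values),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s' (%s): %d voxels, %.2f cm^3\n",
              x$name, x$role, sum(x$mask), mask_volume_cm3(x)))
  invisible(x)
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set> '%s': %d slice(s)\n", x$name, length(x$slices)))
  invisible(x)
}

#' Voxel volume of a grid geometry in cm^3
#' @param x a `structure_mask` or `dose_grid`.
#' @return voxel volume in cm^3.
#' @export
voxel_volume_cm3 <- function(x) prod(x$spacing) / 1000

#' Total volume of a structure mask in cm^3
#' @param x a `structure_mask`.
#' @return volume in cm^3.
#' @export
mask_volume_cm3 <- function(x) sum(x$mask) * voxel_volume_cm3(x)

# geometry (shape, spacing, origin) equality check shared by every module
# that pairs a dose with a mask
same_geometry <- function(a, b, tol = 1e-6) {
  da <- dim(if (!is.null(a$values)) a$values else if (!is.null(a$mask)) a$mask else a$labels)
  db <- dim(if (!is.null(b$values)) b$values else if (!is.null(b$mask)) b$mask else b$labels)
  identical(da, db) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

stop_unless_same_geometry <- function(a, b, what = "inputs") {
  if (!same_geometry(a, b))
    stop(what, " must share grid geometry (shape, spacing, origin)")
  invisible(TRUE)
}

# voxel-centre coordinates along one axis
axis_coords <- function(x, axis) {
  n <- dim(if (!is.null(x$values)) x$values else if (!is.null(x$mask)) x$mask else x$labels)[axis]
  x$origin[axis] + (seq_len(n) - 1) * x$spacing[axis]
}
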