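#' Write a grid object to the portable on-disk format
#'
#' The portable format is a raw little-endian array (`<stem>.bin`) plus a
#' JSON sidecar (`<stem>.json`) recording type, shape, spacing, origin,
#' names and free-form provenance.  Doses are stored as float64, masks and
#' medium labels as uint8.  The round trip is lossless.
#'
#' @param x a `dose_grid`, `planar_dose`, `structure_mask` or `medium_map`.
#' @param stem path stem; `.json` and `.bin` are appended.
#' @param provenance optional named list recorded verbatim in the sidecar
#'   (e.g. generator parameters).
#' @return `stem`, invisibly.
#' @export
write_portable <- function(x, stem, provenance = NULL) {
  UseMethod("write_portable")
}

portable_write_files <- function(stem, meta, raw_bytes) {
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  con <- file(paste0(stem, ".bin"), "wb")
  on.exit(close(con))
  writeBin(raw_bytes, con)
  invisible(stem)
}

#' @export
write_portable.dose_grid <- function(x, stem, provenance = NULL) {
  meta <- list(type = "dose_grid", shape = dim(x$values),
               spacing = x$spacing, origin = x$origin,
               dtype = "float64", units = "Gy",
               flipped_z = x$flipped_z, provenance = provenance)
  portable_write_files(stem, meta,
                       writeBin(as.numeric(x$values), raw(), size = 8,
                                endian = "little"))
}

#' @export
write_portable.planar_dose <- function(x, stem, provenance = NULL) {
  meta <- list(type = "planar_dose", shape = dim(x$values),
               spacing = x$spacing, origin = x$origin,
               dtype = "float64", units = "Gy", label = x$label,
               provenance = provenance)
  portable_write_files(stem, meta,
                       writeBin(as.numeric(x$values), raw(), size = 8,
                                endian = "little"))
}

#' @export
write_portable.structure_mask <- function(x, stem, provenance = NULL) {
  meta <- list(type = "structure_mask", shape = dim(x$mask),
               spacing = x$spacing, origin = x$origin, dtype = "uint8",
               name = x$name, role = x$role, provenance = provenance)
  portable_write_files(stem, meta, as.raw(as.integer(x$mask)))
}

#' @export
write_portable.medium_map <- function(x, stem, provenance = NULL) {
  meta <- list(type = "medium_map", shape = dim(x$labels),
               spacing = x$spacing, origin = x$origin, dtype = "uint8",
               levels = x$levels, provenance = provenance)
  portable_write_files(stem, meta, as.raw(as.integer(x$labels)))
}

#' Read a portable grid object written by [write_portable()]
#'
#' @param stem path stem used at write time.
#' @return the stored object, with an attribute `provenance` carrying the
#'   sidecar's provenance list (if any).
#' @export
read_portable <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  n <- prod(shape)
  con <- file(paste0(stem, ".bin"), "rb")
  on.exit(close(con))
  vals <- if (identical(meta$dtype, "uint8")) {
    as.integer(readBin(con, raw(), n = n + 1L))
  } else {
    readBin(con, numeric(), n = n + 1L, size = 8, endian = "little")
  }
  if (length(vals) != n)
    stop("portable format error: array length ", length(vals),
         " does not match sidecar shape ", paste(shape, collapse = "x"))
  arr <- array(vals, dim = shape)
  out <- switch(meta$type,
    dose_grid = dose_grid(arr, meta$spacing, meta$origin,
                          flipped_z = isTRUE(meta$flipped_z)),
    planar_dose = planar_dose(arr, meta$spacing, meta$origin,
                              label = if (is.null(meta$label)) "" else meta$label),
    structure_mask = structure_mask(arr, meta$spacing, meta$origin,
                                    name = meta$name, role = meta$role),
    medium_map = medium_map(arr, meta$spacing, meta$origin),
    stop("unknown portable type: ", meta$type))
  attr(out, "provenance") <- meta$provenance
  out
}
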