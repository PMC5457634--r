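# Minimal DICOM support: explicit-VR little-endian, enough for RT Dose and
# RT Structure Set objects.  The writer exists to produce small synthetic
# fixtures; the reader handles files written by it and by mainstream TPS
# exports using the same transfer syntax.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_RT_DOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
UID_RT_STRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"

# ---- low-level encoding --------------------------------------------------

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_string_raw <- function(s, pad = as.raw(0x20)) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, pad)
  r
}

dcm_ds <- function(x) paste(vapply(x, function(v)
  formatC(v, digits = 10, format = "g", width = 1), character(1)),
  collapse = "\\")

# one data element, explicit VR little endian
dcm_elem <- function(group, elem, vr, value) {
  body <- if (is.raw(value)) value else switch(vr,
    UI = dcm_string_raw(value, pad = as.raw(0x00)),
    DS = , IS = , CS = , LO = , SH = , ST = , PN = , DA = , TM =
      dcm_string_raw(value),
    US = u16(value),
    UL = u32(value),
    stop("unsupported VR for auto-encoding: ", vr))
  len <- length(body)
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(u16(group), u16(elem), charToRaw(vr), as.raw(c(0, 0)), u32(len), body)
  } else {
    c(u16(group), u16(elem), charToRaw(vr), u16(len), body)
  }
}

dcm_item <- function(body) c(u16(0xFFFE), u16(0xE000), u32(length(body)), body)

dcm_file <- function(dataset, sop_class_uid, sop_instance_uid) {
  meta <- c(
    dcm_elem(0x0002, 0x0002, "UI", sop_class_uid),
    dcm_elem(0x0002, 0x0003, "UI", sop_instance_uid),
    dcm_elem(0x0002, 0x0010, "UI", UID_EXPLICIT_LE))
  meta <- c(dcm_elem(0x0002, 0x0000, "UL", length(meta)), meta)
  c(raw(128), charToRaw("DICM"), meta, dataset)
}

# ---- low-level decoding --------------------------------------------------

r_u16 <- function(raw, pos)
  readBin(raw[pos:(pos + 1L)], "integer", size = 2, endian = "little",
          signed = FALSE)

r_u32 <- function(raw, pos) {
  v <- readBin(raw[pos:(pos + 3L)], "integer", size = 4, endian = "little")
  if (v < 0) v + 2^32 else as.numeric(v)
}

VR_LONG <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Parse one explicit-VR dataset between pos and end (1-based, inclusive
# start, exclusive end).  Returns list(elements = named list, pos).
# SQ values are lists of item datasets.  Stops early at `stop_tag`
# (item/sequence delimiters handled by callers via that mechanism).
dcm_parse <- function(raw, pos, end) {
  out <- list()
  while (pos + 7L <= end) {
    group <- r_u16(raw, pos)
    elem <- r_u16(raw, pos + 2L)
    if (group == 0xFFFE) {  # delimiter item; caller-level bookkeeping
      len <- r_u32(raw, pos + 4L)
      return(list(elements = out, pos = pos, delimiter = c(group, elem)))
    }
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% VR_LONG) {
      len <- r_u32(raw, pos + 8L)
      pos <- pos + 12L
    } else {
      len <- r_u16(raw, pos + 6L)
      pos <- pos + 8L
    }
    tag <- sprintf("%04X,%04X", group, elem)
    if (vr == "SQ") {
      parsed <- dcm_parse_sq(raw, pos, len, end)
      out[[tag]] <- structure(parsed$items, vr = "SQ")
      pos <- parsed$pos
    } else {
      if (len == 4294967295) stop("undefined length outside SQ unsupported")
      val <- if (len > 0) raw[pos:(pos + len - 1L)] else raw(0)
      out[[tag]] <- structure(list(bytes = val), vr = vr)
      pos <- pos + len
    }
  }
  list(elements = out, pos = pos, delimiter = NULL)
}

dcm_parse_sq <- function(raw, pos, len, end) {
  sq_end <- if (len == 4294967295) end else pos + len
  items <- list()
  while (pos + 7L <= sq_end) {
    group <- r_u16(raw, pos)
    elem <- r_u16(raw, pos + 2L)
    ilen <- r_u32(raw, pos + 4L)
    pos <- pos + 8L
    if (group == 0xFFFE && elem == 0xE0DD) break  # sequence delimiter
    if (!(group == 0xFFFE && elem == 0xE000))
      stop("malformed sequence: expected item tag")
    item_end <- if (ilen == 4294967295) sq_end else pos + ilen
    parsed <- dcm_parse(raw, pos, item_end)
    items[[length(items) + 1L]] <- parsed$elements
    pos <- parsed$pos
    if (!is.null(parsed$delimiter) &&
        all(parsed$delimiter == c(0xFFFE, 0xE00D))) pos <- pos + 8L
  }
  list(items = items, pos = max(pos, if (len != 4294967295) sq_end else pos))
}

dcm_val_string <- function(el) {
  if (is.null(el)) return(NULL)
  b <- el$bytes
  b <- b[b != as.raw(0)]  # UI padding
  trimws(rawToChar(b))
}

dcm_val_numeric <- function(el) {
  s <- dcm_val_string(el)
  if (is.null(s) || !nzchar(s)) return(numeric(0))
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_val_u16 <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$bytes, "integer", n = length(el$bytes) / 2, size = 2,
          endian = "little", signed = FALSE)
}

read_dicom_file <- function(path) {
  raw <- readBin(path, raw(), n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  # file meta group is always explicit LE; its group length delimits it
  meta_len <- r_u32(raw, pos + 8L)
  meta <- dcm_parse(raw, pos, pos + 12L + meta_len)
  ts <- dcm_val_string(meta$elements[["0002,0010"]])
  if (!is.null(ts) && ts != UID_EXPLICIT_LE)
    stop("unsupported transfer syntax: ", ts,
         " (only explicit VR little endian is supported)")
  dcm_parse(raw, pos + 12L + meta_len, length(raw) + 1L)$elements
}

# ---- RT Dose -------------------------------------------------------------

#' Read a DICOM RT Dose object
#'
#' Applies the dose-grid scaling, so values come back in Gy.  Multi-frame
#' objects return a [dose_grid()]; single-frame objects return a
#' [planar_dose()].  Frames stored in descending z are re-sorted ascending
#' and the flip recorded in the `flipped_z` field.
#'
#' @param path path to an RT Dose file (explicit VR little endian).
#' @return a `dose_grid` or `planar_dose`.
#' @export
read_rt_dose <- function(path) {
  ds <- read_dicom_file(path)
  rows <- dcm_val_u16(ds[["0028,0010"]])
  cols <- dcm_val_u16(ds[["0028,0011"]])
  if (is.null(rows) || is.null(cols)) stop("RT Dose without Rows/Columns")
  nfr <- dcm_val_numeric(ds[["0028,0008"]])
  nfr <- if (length(nfr)) as.integer(nfr) else 1L
  ps <- dcm_val_numeric(ds[["0028,0030"]])  # row spacing \ col spacing
  ipp <- dcm_val_numeric(ds[["0020,0032"]])
  scaling <- dcm_val_numeric(ds[["3004,000E"]])
  if (!length(scaling)) stop("RT Dose without DoseGridScaling")
  bits <- dcm_val_u16(ds[["0028,0100"]])
  px <- ds[["7FE0,0010"]]
  if (is.null(px)) stop("RT Dose without PixelData")
  n <- as.numeric(rows) * cols * nfr
  stored <- if (bits == 32) {
    readBin(px$bytes, "integer", n = n, size = 4, endian = "little")
  } else if (bits == 16) {
    readBin(px$bytes, "integer", n = n, size = 2, endian = "little",
            signed = FALSE)
  } else stop("unsupported BitsAllocated: ", bits)
  if (length(stored) != n) stop("PixelData shorter than Rows*Columns*Frames")
  doses <- stored * scaling
  sx <- ps[2]; sy <- ps[1]

  if (nfr == 1L) {
    return(planar_dose(array(doses, dim = c(cols, rows)),
                       spacing = c(sx, sy), origin = ipp[1:2],
                       label = "RT Dose frame"))
  }
  gfov <- dcm_val_numeric(ds[["3004,000C"]])
  if (length(gfov) != nfr)
    stop("format error: multi-frame RT Dose without a full GridFrameOffsetVector")
  dz <- diff(gfov)
  if (max(abs(dz - dz[1])) > 1e-3)
    stop("non-uniform slice spacing in GridFrameOffsetVector (tolerance 1e-3 mm)")
  arr <- array(doses, dim = c(cols, rows, nfr))
  flipped <- dz[1] < 0
  z0 <- ipp[3] + gfov[1]
  if (flipped) {
    arr <- arr[, , rev(seq_len(nfr)), drop = FALSE]
    z0 <- ipp[3] + gfov[nfr]
  }
  dose_grid(arr, spacing = c(sx, sy, abs(dz[1])),
            origin = c(ipp[1], ipp[2], z0), flipped_z = flipped)
}

#' Write a synthetic DICOM RT Dose fixture
#'
#' Stores doses as 32-bit unsigned integers with the given grid scaling;
#' doses should be (near-)multiples of `scaling` for a lossless round trip.
#'
#' @param x a `dose_grid` or `planar_dose`.
#' @param path destination file.
#' @param scaling dose-grid scaling in Gy per stored unit.
#' @param descending_z store frames with a descending grid-frame offset
#'   vector (to exercise the reader's re-sorting).
#' @return `path`, invisibly.
#' @export
write_rt_dose <- function(x, path, scaling = 1e-4, descending_z = FALSE) {
  if (inherits(x, "planar_dose")) {
    arr <- array(x$values, dim = c(dim(x$values), 1L))
    spacing <- c(x$spacing, 1)
    origin <- c(x$origin, 0)
  } else {
    arr <- x$values
    spacing <- x$spacing
    origin <- x$origin
  }
  d <- dim(arr)
  nfr <- d[3]
  gfov <- (seq_len(nfr) - 1) * spacing[3]
  if (descending_z && nfr > 1) {
    arr <- arr[, , rev(seq_len(nfr)), drop = FALSE]
    origin[3] <- origin[3] + (nfr - 1) * spacing[3]
    gfov <- -gfov
  }
  stored <- as.integer(round(as.numeric(arr) / scaling))
  body <- c(
    dcm_elem(0x0008, 0x0016, "UI", UID_RT_DOSE),
    dcm_elem(0x0008, 0x0060, "CS", "RTDOSE"),
    dcm_elem(0x0020, 0x0032, "DS", dcm_ds(origin)),
    dcm_elem(0x0020, 0x0037, "DS", dcm_ds(c(1, 0, 0, 0, 1, 0))),
    dcm_elem(0x0028, 0x0002, "US", 1),
    dcm_elem(0x0028, 0x0008, "IS", as.character(nfr)),
    dcm_elem(0x0028, 0x0010, "US", d[2]),          # rows (y)
    dcm_elem(0x0028, 0x0011, "US", d[1]),          # columns (x)
    dcm_elem(0x0028, 0x0030, "DS", dcm_ds(c(spacing[2], spacing[1]))),
    dcm_elem(0x0028, 0x0100, "US", 32),
    dcm_elem(0x0028, 0x0101, "US", 32),
    dcm_elem(0x0028, 0x0102, "US", 31),
    dcm_elem(0x0028, 0x0103, "US", 0),
    dcm_elem(0x3004, 0x0002, "CS", "GY"),
    dcm_elem(0x3004, 0x0004, "CS", "PHYSICAL"),
    if (nfr > 1) dcm_elem(0x3004, 0x000C, "DS", dcm_ds(gfov)),
    dcm_elem(0x3004, 0x000E, "DS", dcm_ds(scaling)),
    dcm_elem(0x7FE0, 0x0010, "OW",
             writeBin(stored, raw(), size = 4, endian = "little")))
  writeBin(dcm_file(body, UID_RT_DOSE, paste0("2.25.", 1e9)), path)
  invisible(path)
}

# ---- RT Structure Set ----------------------------------------------------

#' Read a DICOM RT Structure Set
#'
#' @param path path to an RT Structure Set file.
#' @return a list of [contour_set()] objects, one per ROI, in file order.
#'   ROIs without contour data are returned empty, with a warning.
#' @export
read_rt_struct <- function(path) {
  ds <- read_dicom_file(path)
  roi_seq <- ds[["3006,0020"]]
  if (is.null(roi_seq)) stop("RT Structure Set without StructureSetROISequence")
  roi_names <- list()
  for (item in roi_seq) {
    num <- dcm_val_numeric(item[["3006,0022"]])
    roi_names[[as.character(num)]] <- dcm_val_string(item[["3006,0026"]])
  }
  contour_seq <- ds[["3006,0039"]]
  out <- list()
  for (item in if (is.null(contour_seq)) list() else contour_seq) {
    num <- dcm_val_numeric(item[["3006,0084"]])
    name <- roi_names[[as.character(num)]]
    if (is.null(name)) name <- paste0("ROI-", num)
    contours <- item[["3006,0040"]]
    if (is.null(contours) || !length(contours)) {
      warning("ROI '", name, "' has no contour data; returned empty")
      out[[length(out) + 1L]] <- contour_set(name)
      next
    }
    by_z <- list()
    for (ct in contours) {
      xyz <- dcm_val_numeric(ct[["3006,0050"]])
      pts <- matrix(xyz, ncol = 3, byrow = TRUE)
      z <- pts[1, 3]
      key <- sprintf("%.6f", z)
      if (is.null(by_z[[key]])) by_z[[key]] <- list(z = z, polygons = list())
      by_z[[key]]$polygons <- c(by_z[[key]]$polygons, list(pts[, 1:2, drop = FALSE]))
    }
    out[[length(out) + 1L]] <- contour_set(name, unname(by_z))
  }
  out
}

#' Write a synthetic DICOM RT Structure Set fixture
#'
#' @param contour_sets list of [contour_set()] objects.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_rt_struct <- function(contour_sets, path) {
  roi_items <- raw(0)
  contour_items <- raw(0)
  for (i in seq_along(contour_sets)) {
    cs <- contour_sets[[i]]
    roi_items <- c(roi_items, dcm_item(c(
      dcm_elem(0x3006, 0x0022, "IS", as.character(i)),
      dcm_elem(0x3006, 0x0026, "LO", cs$name))))
    polys <- raw(0)
    for (sl in cs$slices) {
      for (p in sl$polygons) {
        p <- as.matrix(p)
        xyz <- as.numeric(t(cbind(p, sl$z)))
        polys <- c(polys, dcm_item(c(
          dcm_elem(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
          dcm_elem(0x3006, 0x0046, "IS", as.character(nrow(p))),
          dcm_elem(0x3006, 0x0050, "DS", dcm_ds(xyz)))))
      }
    }
    item_body <- dcm_elem(0x3006, 0x0084, "IS", as.character(i))
    if (length(polys)) {
      sq <- c(u16(0x3006), u16(0x0040), charToRaw("SQ"), as.raw(c(0, 0)),
              u32(length(polys)), polys)
      item_body <- c(sq, item_body)
    }
    contour_items <- c(contour_items, dcm_item(item_body))
  }
  body <- c(
    dcm_elem(0x0008, 0x0016, "UI", UID_RT_STRUCT),
    dcm_elem(0x0008, 0x0060, "CS", "RTSTRUCT"),
    c(u16(0x3006), u16(0x0020), charToRaw("SQ"), as.raw(c(0, 0)),
      u32(length(roi_items)), roi_items),
    c(u16(0x3006), u16(0x0039), charToRaw("SQ"), as.raw(c(0, 0)),
      u32(length(contour_items)), contour_items))
  writeBin(dcm_file(body, UID_RT_STRUCT, paste0("2.25.", 2e9)), path)
  invisible(path)
}
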