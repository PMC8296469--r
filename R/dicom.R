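# Minimal DICOM parser: explicit-VR little-endian part-10 files, which is
# how RT Dose / RT Structure Set objects are exported by treatment planning
# systems. Only the element types needed for those two IODs are decoded;
# sequences (defined and undefined length) are parsed recursively.

DICOM_STRING_VRS <- c("AE", "AS", "CS", "DA", "DT", "LO", "LT", "PN",
                      "SH", "ST", "TM", "UC", "UI", "UR", "UT")

uint32_of <- function(raw4) {
  v <- as.numeric(readBin(raw4, "integer", n = 1L, size = 4L, endian = "little"))
  if (v < 0) v <- v + 2^32
  v
}

dicom_parse_elements <- function(bytes, pos, end) {
  out <- list()
  while (pos < end) {
    if (end - pos < 8) stop("format error: truncated DICOM element", call. = FALSE)
    group   <- readBin(bytes[pos + 1:2], "integer", size = 2L, signed = FALSE, endian = "little")
    element <- readBin(bytes[pos + 3:4], "integer", size = 2L, signed = FALSE, endian = "little")
    pos <- pos + 4L

    if (group == 0xFFFE) {
      # item delimiters only appear inside sequences; handled by caller
      stop("format error: unexpected item tag outside a sequence", call. = FALSE)
    }
    vr <- rawToChar(bytes[pos + 1:2])
    pos <- pos + 2L
    if (vr %in% c("OB", "OW", "OF", "OD", "OL", "SQ", "UN", "UT", "UC", "UR")) {
      pos <- pos + 2L  # reserved
      len <- uint32_of(bytes[pos + 1:4])
      pos <- pos + 4L
    } else {
      len <- readBin(bytes[pos + 1:2], "integer", size = 2L, signed = FALSE, endian = "little")
      pos <- pos + 2L
    }

    key <- sprintf("%04X,%04X", group, element)
    if (vr == "SQ") {
      parsed <- dicom_parse_sequence(bytes, pos, len)
      out[[key]] <- parsed$items
      pos <- parsed$pos
    } else {
      if (len == 4294967295) stop("format error: undefined length outside SQ unsupported", call. = FALSE)
      raw_val <- if (len > 0) bytes[pos + seq_len(len)] else raw(0)
      pos <- pos + len
      out[[key]] <- dicom_decode_value(vr, raw_val)
    }
  }
  list(data = out, pos = pos)
}

dicom_parse_sequence <- function(bytes, pos, len) {
  items <- list()
  undefined <- (len == 4294967295)
  end <- if (undefined) length(bytes) else pos + len
  while (pos < end) {
    g <- readBin(bytes[pos + 1:2], "integer", size = 2L, signed = FALSE, endian = "little")
    e <- readBin(bytes[pos + 3:4], "integer", size = 2L, signed = FALSE, endian = "little")
    ilen <- uint32_of(bytes[pos + 5:8])
    pos <- pos + 8L
    if (g == 0xFFFE && e == 0xE0DD) break            # sequence delimitation
    if (!(g == 0xFFFE && e == 0xE000))
      stop("format error: malformed sequence item tag", call. = FALSE)
    if (ilen == 4294967295) {
      # undefined-length item: scan until item delimitation tag (FFFE,E00D)
      item_end <- pos
      depth <- 0L
      repeat {
        gg <- readBin(bytes[item_end + 1:2], "integer", size = 2L, signed = FALSE, endian = "little")
        ee <- readBin(bytes[item_end + 3:4], "integer", size = 2L, signed = FALSE, endian = "little")
        if (gg == 0xFFFE && ee == 0xE00D && depth == 0L) break
        # skip one element conservatively by re-parsing
        parsed <- dicom_parse_elements(bytes, item_end, item_end + 1L)
        item_end <- parsed$pos
      }
      parsed <- dicom_parse_elements(bytes, pos, item_end)
      items[[length(items) + 1L]] <- parsed$data
      pos <- item_end + 8L
    } else {
      parsed <- dicom_parse_elements(bytes, pos, pos + ilen)
      items[[length(items) + 1L]] <- parsed$data
      pos <- pos + ilen
    }
  }
  list(items = items, pos = pos)
}

dicom_decode_value <- function(vr, raw_val) {
  if (vr %in% DICOM_STRING_VRS) {
    s <- trimws(rawToChar(raw_val[raw_val != as.raw(0)]))
    return(s)
  }
  switch(vr,
    DS = {
      s <- trimws(rawToChar(raw_val))
      if (nchar(s) == 0) numeric(0) else as.numeric(strsplit(s, "\\\\")[[1]])
    },
    IS = {
      s <- trimws(rawToChar(raw_val))
      if (nchar(s) == 0) integer(0) else as.integer(strsplit(s, "\\\\")[[1]])
    },
    US = readBin(raw_val, "integer", n = length(raw_val) %/% 2L, size = 2L,
                 signed = FALSE, endian = "little"),
    SS = readBin(raw_val, "integer", n = length(raw_val) %/% 2L, size = 2L,
                 signed = TRUE, endian = "little"),
    UL = {
      v <- as.numeric(readBin(raw_val, "integer", n = length(raw_val) %/% 4L,
                              size = 4L, endian = "little"))
      v[v < 0] <- v[v < 0] + 2^32
      v
    },
    SL = readBin(raw_val, "integer", n = length(raw_val) %/% 4L, size = 4L, endian = "little"),
    FL = readBin(raw_val, "double", n = length(raw_val) %/% 4L, size = 4L, endian = "little"),
    FD = readBin(raw_val, "double", n = length(raw_val) %/% 8L, size = 8L, endian = "little"),
    raw_val  # OB / OW / OF / UN: keep raw, decoded by the caller
  )
}

dicom_read_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop(sprintf("format error: %s is not a DICOM part-10 file (missing DICM magic)", path),
         call. = FALSE)
  # file meta group (0002,xxxx) is always explicit VR little endian
  pos <- 132L
  meta_len_parsed <- dicom_parse_elements(bytes, pos, pos + 12L)
  meta_group_len <- meta_len_parsed$data[["0002,0000"]]
  if (is.null(meta_group_len))
    stop("format error: missing file meta group length", call. = FALSE)
  meta_end <- meta_len_parsed$pos + meta_group_len
  meta <- dicom_parse_elements(bytes, meta_len_parsed$pos, meta_end)
  ts <- meta$data[["0002,0010"]]
  if (!is.null(ts) && !identical(ts, "1.2.840.10008.1.2.1"))
    stop(sprintf("unsupported transfer syntax '%s' (only explicit VR little endian is supported)", ts),
         call. = FALSE)
  dicom_parse_elements(bytes, meta_end, length(bytes))$data
}

dicom_required <- function(ds, key, what) {
  v <- ds[[key]]
  if (is.null(v))
    stop(sprintf("format error: missing DICOM element (%s) %s", key, what), call. = FALSE)
  v
}

#' Read a DICOM RT Dose file into a dose grid
#'
#' Supports axis-aligned (identity orientation), uniformly spaced dose grids
#' stored as unsigned 16- or 32-bit pixel data with a dose-grid scaling
#' factor, the standard export layout for treatment planning systems. Dose
#' must be reported in Gy. Anything else (rotated orientation, non-uniform
#' frame offsets, other units) is a hard error: the package never resamples
#' or rescales geometry silently.
#'
#' @param path path to an RT Dose DICOM file (explicit VR little endian).
#' @return A [dose_grid()] in Gy.
#' @export
read_dicom_rtdose <- function(path) {
  ds <- dicom_read_file(path)
  modality <- ds[["0008,0060"]]
  if (!is.null(modality) && !identical(modality, "RTDOSE"))
    stop(sprintf("format error: modality '%s' is not RTDOSE", modality), call. = FALSE)

  rows <- dicom_required(ds, "0028,0010", "Rows")
  cols <- dicom_required(ds, "0028,0011", "Columns")
  nframes <- as.integer(dicom_required(ds, "0028,0008", "NumberOfFrames"))
  pixel_spacing <- dicom_required(ds, "0028,0030", "PixelSpacing")   # row (y), col (x)
  ipp <- dicom_required(ds, "0020,0032", "ImagePositionPatient")
  iop <- dicom_required(ds, "0020,0037", "ImageOrientationPatient")
  gfov <- dicom_required(ds, "3004,000C", "GridFrameOffsetVector")
  scaling <- dicom_required(ds, "3004,000E", "DoseGridScaling")
  units <- dicom_required(ds, "3004,0002", "DoseUnits")
  bits <- dicom_required(ds, "0028,0100", "BitsAllocated")
  pixrep <- ds[["0028,0103"]]
  pixel_data <- dicom_required(ds, "7FE0,0010", "PixelData")

  if (!identical(toupper(units), "GY"))
    stop(sprintf("unit error: dose units '%s' are not Gy", units), call. = FALSE)
  if (max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-6)
    stop("unsupported-geometry error: ImageOrientationPatient is not axis-aligned identity",
         call. = FALSE)
  if (length(gfov) != nframes)
    stop("format error: GridFrameOffsetVector length does not match NumberOfFrames",
         call. = FALSE)
  dz <- if (nframes > 1) diff(gfov) else 1
  if (nframes > 1 && (any(dz <= 0) || max(abs(dz - dz[1])) > 1e-6))
    stop("unsupported-geometry error: non-uniform grid frame offsets", call. = FALSE)
  if (!is.null(pixrep) && pixrep != 0)
    stop("format error: signed dose pixel data unsupported", call. = FALSE)

  n <- as.integer(rows) * as.integer(cols) * nframes
  if (bits == 32) {
    vals <- as.numeric(readBin(pixel_data, "integer", n = n, size = 4L, endian = "little"))
    vals[vals < 0] <- vals[vals < 0] + 2^32
  } else if (bits == 16) {
    vals <- as.numeric(readBin(pixel_data, "integer", n = n, size = 2L,
                               signed = FALSE, endian = "little"))
  } else {
    stop(sprintf("format error: BitsAllocated = %d unsupported (16 or 32)", bits), call. = FALSE)
  }
  if (length(vals) < n)
    stop("size error: pixel data shorter than Rows x Columns x NumberOfFrames", call. = FALSE)

  header <- grid_header(dims = c(cols, rows, nframes),
                        origin = c(ipp[1], ipp[2], ipp[3] + gfov[1]),
                        spacing = c(pixel_spacing[2], pixel_spacing[1],
                                    if (nframes > 1) dz[1] else 1))
  # frame-major pixel order (col fastest, then row, then frame) is exactly
  # the package's x-fastest storage order
  dose_grid(header, vals[seq_len(n)] * scaling)
}

#' Read a DICOM RT Structure Set into a contour set
#'
#' Every ROI in the structure set becomes a named structure whose closed
#' planar contours are grouped into polygons (a z coordinate plus an ordered
#' (x, y) vertex list, all in mm). Degenerate contours with fewer than 3
#' points are dropped with a warning rather than failing the whole file.
#'
#' @param path path to an RT Structure Set DICOM file (explicit VR little
#'   endian).
#' @return A [contour_set()].
#' @export
read_dicom_rtstruct <- function(path) {
  ds <- dicom_read_file(path)
  roi_seq <- ds[["3006,0020"]]
  contour_roi_seq <- ds[["3006,0039"]]
  if (is.null(roi_seq) || is.null(contour_roi_seq))
    stop("format error: missing StructureSetROISequence or ROIContourSequence", call. = FALSE)

  roi_names <- list()
  for (item in roi_seq) {
    num <- item[["3006,0022"]]
    nm <- item[["3006,0026"]]
    if (!is.null(num) && !is.null(nm)) roi_names[[as.character(num)]] <- nm
  }

  structures <- list()
  for (item in contour_roi_seq) {
    ref <- item[["3006,0084"]]
    nm <- roi_names[[as.character(ref)]]
    if (is.null(nm)) nm <- sprintf("ROI_%s", ref)
    polys <- list()
    for (cs in item[["3006,0040"]]) {
      cdata <- cs[["3006,0050"]]
      if (is.null(cdata)) next
      npts <- length(cdata) %/% 3L
      if (npts < 3L) {
        warning(sprintf("dropping degenerate contour with %d point(s) in structure '%s'",
                        npts, nm), call. = FALSE)
        next
      }
      m <- matrix(cdata[seq_len(npts * 3L)], ncol = 3L, byrow = TRUE)
      polys[[length(polys) + 1L]] <- list(z = m[1, 3], xy = m[, 1:2, drop = FALSE])
    }
    structures[[nm]] <- polys
  }
  contour_set(structures)
}

#' Contour set: named structures of closed planar polygons
#'
#' @param structures named list; each element is a list of polygons, each
#'   polygon a list with `z` (plane coordinate, mm) and `xy` (n x 2 vertex
#'   matrix, mm, at least 3 vertices).
#' @return An object of class `contour_set`.
#' @export
contour_set <- function(structures) {
  if (is.null(names(structures)) || anyDuplicated(names(structures)))
    stop("structure names must be unique and non-empty", call. = FALSE)
  for (nm in names(structures)) {
    for (p in structures[[nm]]) {
      if (!is.list(p) || is.null(p$z) || is.null(p$xy) || nrow(p$xy) < 3L ||
          !all(is.finite(p$xy)) || !is.finite(p$z))
        stop(sprintf("structure '%s' contains an invalid polygon (need z and >= 3 finite vertices)", nm),
             call. = FALSE)
    }
  }
  structure(list(structures = structures), class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set> %d structure(s)\n", length(x$structures)))
  for (nm in names(x$structures))
    cat(sprintf("  %s: %d polygon(s)\n", nm, length(x$structures[[nm]])))
  invisible(x)
}
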