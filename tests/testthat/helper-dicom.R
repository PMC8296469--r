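# Minimal conformant DICOM fixture builders (explicit VR little endian).
# These exist only to test the readers; the package itself never writes DICOM.

dcm_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_uint32 <- function(x) {
  x <- as.numeric(x)
  lo <- x %% 65536; hi <- (x - lo) / 65536
  c(dcm_uint16(lo), dcm_uint16(hi))
}

dcm_pad <- function(r, pad = as.raw(0x20)) if (length(r) %% 2 == 1) c(r, pad) else r

dcm_element <- function(group, element, vr, data) {
  if (is.character(data)) {
    data <- charToRaw(data)
    data <- dcm_pad(data, if (vr == "UI") as.raw(0) else as.raw(0x20))
  }
  tag <- c(dcm_uint16(group), dcm_uint16(element))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UN", "UT")) {
    c(tag, charToRaw(vr), as.raw(c(0, 0)), dcm_uint32(length(data)), data)
  } else {
    c(tag, charToRaw(vr), dcm_uint16(length(data)), data)
  }
}

dcm_item <- function(data) c(dcm_uint16(0xFFFE), dcm_uint16(0xE000), dcm_uint32(length(data)), data)

dcm_file <- function(body, sop_class = "1.2.840.10008.5.1.4.1.1.481.2") {
  meta <- c(dcm_element(0x0002, 0x0002, "UI", sop_class),
            dcm_element(0x0002, 0x0003, "UI", "1.2.3.4.5.6.7.8.9"),
            dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
  c(raw(128), charToRaw("DICM"),
    dcm_element(0x0002, 0x0000, "UL", dcm_uint32(length(meta))),
    meta, body)
}

ds_str <- function(x) paste(sprintf("%.8g", x), collapse = "\\")

write_rtdose_fixture <- function(grid, path, scaling = 1e-6,
                                 orientation = c(1, 0, 0, 0, 1, 0),
                                 units = "GY", offsets = NULL) {
  h <- grid$header
  pixels <- as.integer(round(grid$values / scaling))
  if (is.null(offsets)) offsets <- (seq_len(h$dims[3]) - 1) * h$spacing[3]
  body <- c(
    dcm_element(0x0008, 0x0060, "CS", "RTDOSE"),
    dcm_element(0x0020, 0x0032, "DS", ds_str(h$origin)),
    dcm_element(0x0020, 0x0037, "DS", ds_str(orientation)),
    dcm_element(0x0028, 0x0008, "IS", as.character(h$dims[3])),
    dcm_element(0x0028, 0x0010, "US", dcm_uint16(h$dims[2])),
    dcm_element(0x0028, 0x0011, "US", dcm_uint16(h$dims[1])),
    dcm_element(0x0028, 0x0030, "DS", ds_str(c(h$spacing[2], h$spacing[1]))),
    dcm_element(0x0028, 0x0100, "US", dcm_uint16(32)),
    dcm_element(0x0028, 0x0103, "US", dcm_uint16(0)),
    dcm_element(0x3004, 0x0002, "CS", units),
    dcm_element(0x3004, 0x000C, "DS", ds_str(offsets)),
    dcm_element(0x3004, 0x000E, "DS", sprintf("%.10g", scaling)),
    dcm_element(0x7FE0, 0x0010, "OW",
                writeBin(pixels, raw(), size = 4, endian = "little"))
  )
  writeBin(dcm_file(body), path)
  invisible(path)
}

# structures: named list; each a list of polygons list(z=, xy=matrix)
write_rtstruct_fixture <- function(structures, path) {
  roi_items <- raw(0)
  contour_items <- raw(0)
  num <- 0L
  for (nm in names(structures)) {
    num <- num + 1L
    roi_items <- c(roi_items, dcm_item(c(
      dcm_element(0x3006, 0x0022, "IS", as.character(num)),
      dcm_element(0x3006, 0x0026, "LO", nm))))
    cseq <- raw(0)
    for (p in structures[[nm]]) {
      npts <- nrow(p$xy)
      triplets <- as.vector(t(cbind(p$xy, rep(p$z, npts))))
      cseq <- c(cseq, dcm_item(c(
        dcm_element(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        dcm_element(0x3006, 0x0046, "IS", as.character(npts)),
        dcm_element(0x3006, 0x0050, "DS", ds_str(triplets)))))
    }
    contour_items <- c(contour_items, dcm_item(c(
      dcm_element(0x3006, 0x0040, "SQ", cseq),
      dcm_element(0x3006, 0x0084, "IS", as.character(num)))))
  }
  body <- c(dcm_element(0x0008, 0x0060, "CS", "RTSTRUCT"),
            dcm_element(0x3006, 0x0020, "SQ", roi_items),
            dcm_element(0x3006, 0x0039, "SQ", contour_items))
  writeBin(dcm_file(body, sop_class = "1.2.840.10008.5.1.4.1.1.481.3"), path)
  invisible(path)
}
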