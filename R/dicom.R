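# Minimal single-frame CT DICOM reading.
#
# Scope: uncompressed little-endian transfer syntaxes (explicit and implicit
# VR), single-frame files, the tags a CT series stack needs. This is
# deliberately small: enough to assemble an axial series into a ct_volume with
# the per-file linear rescale to Hounsfield units applied.

DICOM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_IMPLICIT_LE <- "1.2.840.10008.1.2"

uint16le <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
uint32le <- function(raw4) {
  as.numeric(raw4[1]) + 256 * as.numeric(raw4[2]) +
    65536 * as.numeric(raw4[3]) + 16777216 * as.numeric(raw4[4])
}

tag_key <- function(group, element) sprintf("%04X,%04X", group, element)

# VRs carrying a 2-byte reserved field and 4-byte length in explicit VR
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# parse one dataset (sequence of elements) from raw vector starting at pos
parse_dicom_elements <- function(bytes, pos, explicit, stop_at = Inf) {
  out <- list()
  n <- length(bytes)
  while (pos + 7 <= n) {
    group <- uint16le(bytes[pos:(pos + 1)])
    element <- uint16le(bytes[(pos + 2):(pos + 3)])
    if (group > stop_at) break
    pos <- pos + 4
    if (explicit) {
      vr <- rawToChar(bytes[pos:(pos + 1)])
      if (vr %in% LONG_VRS) {
        len <- uint32le(bytes[(pos + 4):(pos + 7)])
        pos <- pos + 8
      } else {
        len <- uint16le(bytes[(pos + 2):(pos + 3)])
        pos <- pos + 4
      }
    } else {
      vr <- NA_character_
      len <- uint32le(bytes[pos:(pos + 3)])
      pos <- pos + 4
    }
    if (!is.finite(len) || len == 4294967295)
      stop_nc("unsupported DICOM element with undefined length at tag ", tag_key(group, element))
    value <- if (len > 0) bytes[pos:(pos + len - 1)] else raw(0)
    pos <- pos + len
    out[[tag_key(group, element)]] <- list(vr = vr, value = value)
  }
  list(elements = out, pos = pos)
}

dicom_string <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$value[el$value != as.raw(0)]))
}

dicom_numeric <- function(el) {
  s <- dicom_string(el)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dicom_uint16 <- function(el) {
  if (is.null(el)) return(NULL)
  uint16le(el$value[1:2])
}

read_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 200 || rawToChar(bytes[129:132]) != "DICM")
    stop_nc("not a DICOM file (missing DICM marker): ", path)
  # file meta group (0002) is always explicit VR little endian
  meta <- parse_dicom_elements(bytes, 133, explicit = TRUE, stop_at = 2L)
  ts <- dicom_string(meta$elements[["0002,0010"]]) %||% DICOM_EXPLICIT_LE
  if (!ts %in% c(DICOM_EXPLICIT_LE, DICOM_IMPLICIT_LE))
    stop_nc("unsupported DICOM transfer syntax ", ts, " in ", path)
  ds <- parse_dicom_elements(bytes, meta$pos, explicit = ts == DICOM_EXPLICIT_LE)
  el <- ds$elements

  need <- function(key, name) {
    if (is.null(el[[key]]))
      stop_nc("missing DICOM tag ", name, " (", key, ") in ", path)
    el[[key]]
  }
  rows <- dicom_uint16(need("0028,0010", "Rows"))
  cols <- dicom_uint16(need("0028,0011", "Columns"))
  pix_spacing <- dicom_numeric(need("0028,0030", "PixelSpacing"))
  ipp <- dicom_numeric(need("0020,0032", "ImagePositionPatient"))
  slope <- (dicom_numeric(el[["0028,1053"]]) %||% 1)[1]
  intercept <- (dicom_numeric(el[["0028,1052"]]) %||% 0)[1]
  bits <- dicom_uint16(el[["0028,0100"]]) %||% 16L
  signed <- (dicom_uint16(el[["0028,0103"]]) %||% 0L) == 1L
  if (bits != 16L) stop_nc("only 16-bit DICOM pixel data supported, got ", bits)
  pd <- need("7FE0,0010", "PixelData")
  stored <- readBin(pd$value, "integer", n = rows * cols, size = 2,
                    signed = signed, endian = "little")
  if (length(stored) != rows * cols)
    stop_nc("PixelData size does not match Rows x Columns in ", path)
  # DICOM pixel data is row-major: first row left to right
  px <- matrix(stored, nrow = rows, ncol = cols, byrow = TRUE)
  list(
    series_uid = dicom_string(el[["0020,000E"]]),
    rows = rows, cols = cols,
    pixel_spacing = pix_spacing,       # (row spacing dy, column spacing dx)
    ipp = ipp,                         # (x, y, z) mm
    slice_thickness = (dicom_numeric(el[["0018,0050"]]) %||% NA_real_)[1],
    hu = slope * px + intercept
  )
}

#' Read a DICOM series into a CT volume
#'
#' Reads all single-frame CT DICOM files of one series from a directory,
#' sorts slices by position along the slice axis, and applies each file's
#' linear rescale (slope, intercept) to obtain Hounsfield units. In-plane
#' spacing comes from PixelSpacing; slice spacing from consecutive
#' ImagePositionPatient z increments (SliceThickness for a single slice).
#' Only uncompressed little-endian transfer syntaxes are supported.
#'
#' @param directory path containing the `.dcm` files of exactly one series.
#' @return A [ct_volume()] in Hounsfield units.
#' @export
read_dicom_series <- function(directory) {
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 1) stop_nc("no files found in ", directory)
  slices <- lapply(files, read_dicom_file)

  uids <- unique(vapply(slices, function(s) s$series_uid %||% "", ""))
  if (length(uids) != 1)
    stop_nc("directory contains multiple DICOM series (SeriesInstanceUID values: ",
            paste(uids, collapse = ", "), ")")
  if (length(unique(lapply(slices, function(s) c(s$rows, s$cols)))) != 1)
    stop_nc("slices disagree on Rows x Columns")

  z <- vapply(slices, function(s) s$ipp[3], 0)
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]

  sp <- slices[[1]]$pixel_spacing
  dz <- if (length(slices) > 1) {
    stats::median(diff(z))
  } else {
    if (is.na(slices[[1]]$slice_thickness))
      stop_nc("missing DICOM tag SliceThickness (0018,0050) needed for single-slice spacing")
    slices[[1]]$slice_thickness
  }
  if (!isTRUE(dz > 0)) stop_nc("non-positive slice spacing derived from ImagePositionPatient")

  arr <- array(0, dim = c(length(slices), slices[[1]]$rows, slices[[1]]$cols))
  for (i in seq_along(slices)) arr[i, , ] <- slices[[i]]$hu
  ipp1 <- slices[[1]]$ipp
  ct_volume(arr, spacing_mm = c(dz, sp[1], sp[2]),
            origin_mm = c(ipp1[3], ipp1[2], ipp1[1]), intensity_scale = "HU")
}

# --- internal writer, used to build synthetic test fixtures only ------------

dicom_element_raw <- function(group, element, vr, value_raw) {
  if (length(value_raw) %% 2 == 1) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
  }
  head_ <- writeBin(c(group, element), raw(), size = 2, endian = "little")
  if (vr %in% LONG_VRS) {
    c(head_, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4, endian = "little"), value_raw)
  } else {
    c(head_, charToRaw(vr),
      writeBin(length(value_raw), raw(), size = 2, endian = "little"), value_raw)
  }
}

dicom_element_str <- function(group, element, vr, s) {
  dicom_element_raw(group, element, vr, charToRaw(s))
}

dicom_element_us <- function(group, element, x) {
  dicom_element_raw(group, element, "US",
                    writeBin(as.integer(x), raw(), size = 2, endian = "little"))
}

# write one synthetic single-frame CT slice (explicit VR little endian)
write_synthetic_dicom_slice <- function(path, stored, ipp, pixel_spacing,
                                        series_uid, slope = 1, intercept = -1024,
                                        slice_thickness = NULL) {
  stopifnot(is.matrix(stored))
  slice_thickness <- slice_thickness %||% 1
  pd <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")
  body <- c(
    dicom_element_str(0x0002L, 0x0010L, "UI", DICOM_EXPLICIT_LE),
    dicom_element_str(0x0018L, 0x0050L, "DS", format(slice_thickness)),
    dicom_element_str(0x0020L, 0x000EL, "UI", series_uid),
    dicom_element_str(0x0020L, 0x0032L, "DS",
                      paste(format(ipp, trim = TRUE), collapse = "\\")),
    dicom_element_us(0x0028L, 0x0010L, nrow(stored)),
    dicom_element_us(0x0028L, 0x0011L, ncol(stored)),
    if (!is.null(pixel_spacing))
      dicom_element_str(0x0028L, 0x0030L, "DS",
                        paste(format(pixel_spacing, trim = TRUE), collapse = "\\")),
    dicom_element_us(0x0028L, 0x0100L, 16L),
    dicom_element_us(0x0028L, 0x0103L, 1L),
    dicom_element_str(0x0028L, 0x1052L, "DS", format(intercept)),
    dicom_element_str(0x0028L, 0x1053L, "DS", format(slope)),
    dicom_element_raw(0x7FE0L, 0x0010L, "OW", pd)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(body, con)
  invisible(path)
}
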