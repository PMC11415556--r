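# Minimal DICOM reader: single-frame grayscale images in the implicit- or
# explicit-VR little-endian transfer syntaxes (the uncompressed syntaxes
# produced by radiography modalities). Pixel data are windowed to 8-bit with
# the stored window when present, else min-max, and MONOCHROME1 images are
# inverted so bone is bright. This covers the preprocessing contract only;
# compressed transfer syntaxes, color and multi-frame objects are out of
# scope.

u16 <- function(raw) sum(as.integer(raw) * c(1L, 256L))
u32 <- function(raw) sum(as.numeric(raw) * c(1, 256, 65536, 16777216))

# VRs that use the 12-byte explicit header (2 reserved + 4-byte length)
LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# Walks one dataset level, returning a named list tag -> raw value.
# Tags are "GGGGEEEE" uppercase hex. Sequences with defined length are
# skipped wholesale; undefined-length sequences are not supported.
parse_elements <- function(bytes, pos, end, explicit) {
  out <- list()
  while (pos + 8L <= end + 1L) {
    grp <- u16(bytes[pos:(pos + 1L)])
    ele <- u16(bytes[(pos + 2L):(pos + 3L)])
    tag <- sprintf("%04X%04X", grp, ele)
    if (explicit) {
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (vr %in% LONG_VRS) {
        len <- u32(bytes[(pos + 8L):(pos + 11L)])
        hdr <- 12L
      } else {
        len <- u16(bytes[(pos + 6L):(pos + 7L)])
        hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- u32(bytes[(pos + 4L):(pos + 7L)])
      hdr <- 8L
    }
    if (len == 4294967295)
      stop("format error: undefined-length element ", tag,
           " is not supported", call. = FALSE)
    vstart <- pos + hdr
    if (vstart + len - 1L > end)
      stop("format error: element ", tag, " overruns the file", call. = FALSE)
    if (!identical(vr, "SQ")) {
      out[[tag]] <- if (len > 0) bytes[vstart:(vstart + len - 1L)] else raw(0)
    }
    pos <- vstart + len
  }
  out
}

dicom_str <- function(el, tag) {
  v <- el[[tag]]
  if (is.null(v)) return(NULL)
  trimws(rawToChar(v[v != as.raw(0)]))
}

dicom_num <- function(el, tag) {
  s <- dicom_str(el, tag)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1L]])[1L]
}

dicom_us <- function(el, tag) {
  v <- el[[tag]]
  if (is.null(v)) return(NULL)
  u16(v[1:2])
}

#' Read a DICOM radiograph to an 8-bit image record
#'
#' Supports single-frame grayscale objects in the implicit- and explicit-VR
#' little-endian transfer syntaxes. Stored intensities are rescaled
#' (RescaleSlope/Intercept), windowed with the stored WindowCenter/Width if
#' present (else min-max), mapped to 0..255, and inverted for MONOCHROME1 so
#' that bone appears bright. A constant-intensity image (degenerate window)
#' maps to all zeros.
#'
#' @param path Path to a DICOM file.
#' @return An [image_record()] at the original pixel size.
#' @export
read_dicom <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 140L)
    stop("format error: file too short to be DICOM", call. = FALSE)
  if (rawToChar(bytes[129:132]) != "DICM")
    stop("format error: missing DICM magic (raw datasets without a preamble ",
         "are not supported)", call. = FALSE)

  # File-meta group (always explicit VR); its length is in (0002,0000)
  meta_len_el <- parse_elements(bytes, 133L, 144L, explicit = TRUE)
  meta_len <- u32(meta_len_el[["00020000"]])
  meta_end <- 144L + meta_len
  meta <- parse_elements(bytes, 133L, meta_end, explicit = TRUE)
  ts <- dicom_str(meta, "00020010")
  explicit <- if (is.null(ts) || ts == "1.2.840.10008.1.2.1") TRUE
              else if (ts == "1.2.840.10008.1.2") FALSE
              else stop("format error: unsupported transfer syntax ", ts, call. = FALSE)

  el <- parse_elements(bytes, meta_end + 1L, length(bytes), explicit = explicit)

  rows <- dicom_us(el, "00280010")
  cols <- dicom_us(el, "00280011")
  if (is.null(rows) || is.null(cols))
    stop("format error: missing Rows/Columns", call. = FALSE)
  pix <- el[["7FE00010"]]
  if (is.null(pix) || length(pix) == 0L)
    stop("format error: missing pixel data", call. = FALSE)

  photometric <- dicom_str(el, "00280004")
  if (is.null(photometric)) photometric <- "MONOCHROME2"
  if (!photometric %in% c("MONOCHROME1", "MONOCHROME2"))
    stop("format error: unsupported photometric interpretation ", photometric,
         call. = FALSE)

  bits <- dicom_us(el, "00280100")
  if (is.null(bits)) bits <- 16L
  signed <- identical(dicom_us(el, "00280103"), 1L) ||
            identical(dicom_us(el, "00280103"), 1)
  if (!bits %in% c(8L, 16L))
    stop("format error: unsupported BitsAllocated ", bits, call. = FALSE)

  n <- rows * cols
  vals <- if (bits == 8L) {
    as.numeric(pix[seq_len(n)])
  } else {
    lo <- as.numeric(pix[seq(1L, 2L * n, by = 2L)])
    hi <- as.numeric(pix[seq(2L, 2L * n, by = 2L)])
    v <- lo + 256 * hi
    if (signed) v <- ifelse(v >= 32768, v - 65536, v)
    v
  }
  slope <- dicom_num(el, "00281053"); if (is.null(slope)) slope <- 1
  intercept <- dicom_num(el, "00281052"); if (is.null(intercept)) intercept <- 0
  vals <- vals * slope + intercept

  wc <- dicom_num(el, "00281050")
  ww <- dicom_num(el, "00281051")
  m <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  out <- window_to_8bit(m, center = wc, width = ww)
  if (photometric == "MONOCHROME1") out <- 255L - out
  image_record(out, original_size = c(cols, rows))
}

#' Window an intensity matrix to 8-bit
#'
#' Applies the standard linear DICOM value-of-interest transform: intensities
#' within `width` of `center` are mapped linearly onto 0..255 and clamped
#' outside. With `center`/`width` `NULL` the stored min-max range is used; a
#' constant image (zero-width window) maps to all zeros.
#'
#' @param m Numeric matrix of intensities (rows = image rows).
#' @param center,width Window center and width, or `NULL` for min-max.
#' @return Integer matrix with values in 0..255.
#' @export
window_to_8bit <- function(m, center = NULL, width = NULL) {
  if (is.null(center) || is.null(width)) {
    lo <- min(m); hi <- max(m)
    if (hi <= lo) return(matrix(0L, nrow(m), ncol(m)))
    y <- (m - lo) / (hi - lo)
  } else {
    if (width <= 1) {
      lo <- min(m); hi <- max(m)
      if (hi <= lo) return(matrix(0L, nrow(m), ncol(m)))
      y <- (m - lo) / (hi - lo)
    } else {
      y <- (m - (center - 0.5)) / (width - 1) + 0.5
      y <- pmin(pmax(y, 0), 1)
    }
  }
  matrix(as.integer(round(y * 255)), nrow(m), ncol(m))
}
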