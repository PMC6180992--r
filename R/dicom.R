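## Minimal single-frame CT DICOM reader.
##
## Scope: uncompressed little-endian transfer syntaxes (implicit
## 1.2.840.10008.1.2 and explicit 1.2.840.10008.1.2.1), one frame per
## file, 16-bit pixel data, no undefined-length sequences. This covers the
## axial CT exports the quantification pipeline consumes; no installed R
## package provides DICOM parsing, so the subset is implemented here.

.DICOM_KEEP <- c(
  transfer_syntax = "00020010", sop_instance = "00080018",
  slice_location = "00201041", rows = "00280010", cols = "00280011",
  pixel_spacing = "00280030", bits_allocated = "00280100",
  pixel_representation = "00280103", rescale_intercept = "00281052",
  rescale_slope = "00281053", pixel_data = "7fe00010")

#' Read a single-frame CT DICOM file into HU space
#'
#' Parses the data set, applies the modality rescale
#' `HU = stored * RescaleSlope + RescaleIntercept`, and extracts pixel
#' spacing and slice location. Missing rescale or spacing attributes raise
#' a metadata error; unreadable or unsupported files raise a format error.
#'
#' @param path DICOM file path.
#' @return A [ct_slice].
#' @export
read_dicom_slice <- function(path) {
  n_bytes <- file.size(path)
  if (is.na(n_bytes) || n_bytes < 140)
    adq_error(paste("unreadable DICOM file:", path), "adipoquant_format_error")
  raw <- readBin(path, "raw", n_bytes)
  if (rawToChar(raw[129:132]) != "DICM")
    adq_error(paste("missing DICM magic in", path), "adipoquant_format_error")
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  u32 <- function(i) as.numeric(u16(i)) + 65536 * as.numeric(u16(i + 2L))

  elems <- list()
  pos <- 133L
  explicit <- TRUE
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= length(raw)) {
    grp <- u16(pos); el <- u16(pos + 2L)
    in_meta <- grp == 2L
    if (in_meta || explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) { len <- u32(pos + 8L); hdr <- 12L }
      else { len <- u16(pos + 6L); hdr <- 8L }
    } else {
      len <- u32(pos + 4L); hdr <- 8L
    }
    if (len == 4294967295)
      adq_error("undefined-length DICOM elements are not supported",
                "adipoquant_format_error")
    tag <- sprintf("%04x%04x", grp, el)
    if (tag %in% .DICOM_KEEP && len > 0)
      elems[[tag]] <- raw[(pos + hdr):(pos + hdr + len - 1L)]
    if (tag == .DICOM_KEEP[["transfer_syntax"]]) {
      ts <- trimws(rawToChar(elems[[tag]][elems[[tag]] != as.raw(0)]))
      if (!ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
        adq_error(paste("unsupported DICOM transfer syntax:", ts),
                  "adipoquant_format_error")
      explicit <- ts == "1.2.840.10008.1.2.1"
    }
    pos <- pos + hdr + len
  }

  get <- function(name) elems[[.DICOM_KEEP[[name]]]]
  need <- function(name, label) {
    v <- get(name)
    if (is.null(v))
      adq_error(sprintf("%s lacks %s", path, label), "adipoquant_metadata_error")
    v
  }
  str_val <- function(v) trimws(rawToChar(v[v != as.raw(0)]))
  ds_val <- function(v) as.numeric(strsplit(str_val(v), "\\\\")[[1]])
  us_val <- function(v) readBin(v, "integer", n = 1, size = 2,
                                endian = "little", signed = FALSE)

  rows <- us_val(need("rows", "Rows"))
  cols <- us_val(need("cols", "Columns"))
  spacing <- ds_val(need("pixel_spacing", "PixelSpacing"))
  if (length(spacing) != 2L || any(!is.finite(spacing)))
    adq_error(paste(path, "has ambiguous PixelSpacing"),
              "adipoquant_metadata_error")
  slope <- ds_val(need("rescale_slope", "RescaleSlope"))
  intercept <- ds_val(need("rescale_intercept", "RescaleIntercept"))
  bits <- if (is.null(get("bits_allocated"))) 16L
          else us_val(get("bits_allocated"))
  if (bits != 16L)
    adq_error(paste(path, ": only 16-bit pixel data is supported"),
              "adipoquant_format_error")
  signed <- !is.null(get("pixel_representation")) &&
    us_val(get("pixel_representation")) == 1L
  pix <- need("pixel_data", "PixelData")
  stored <- readBin(pix, "integer", n = rows * cols, size = 2,
                    endian = "little", signed = signed)
  if (length(stored) < rows * cols)
    adq_error(paste(path, "has truncated PixelData"),
              "adipoquant_format_error")
  hu <- matrix(stored * slope + intercept, nrow = rows, byrow = TRUE)
  loc <- if (!is.null(get("slice_location"))) ds_val(get("slice_location"))[1]
         else 0
  src <- if (!is.null(get("sop_instance"))) str_val(get("sop_instance"))
         else basename(path)
  ct_slice(hu, spacing_mm = spacing, slice_location = loc, source_id = src)
}
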