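#' CT slice container
#'
#' Bundles a matrix of Hounsfield-unit (HU) values with its physical pixel
#' size and position. All image operations in the package consume this
#' container. Coordinates throughout the package are `(row, col)`, 1-based,
#' with pixel centers at integer positions.
#'
#' @param hu Numeric matrix of HU values (rows x cols), finite everywhere.
#' @param spacing_mm Pixel size in mm as `(row, col)`; a single value is
#'   recycled to both. Must be positive.
#' @param slice_location Scalar slice position (mm or index; only ordering
#'   is used).
#' @param source_id Opaque identifier carried through to output tables.
#' @return An object of class `ct_slice`.
#' @export
ct_slice <- function(hu, spacing_mm = c(1, 1), slice_location = 0,
                     source_id = "slice") {
  hu <- as.matrix(hu)
  storage.mode(hu) <- "double"
  if (length(dim(hu)) != 2L || nrow(hu) < 1L || ncol(hu) < 1L)
    adq_error("hu must be a non-empty matrix", "adipoquant_invalid_slice")
  if (!all(is.finite(hu)))
    adq_error("hu must be finite everywhere", "adipoquant_invalid_slice")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  if (length(spacing_mm) != 2L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    adq_error("spacing_mm must be two positive values",
              "adipoquant_invalid_slice")
  structure(
    list(hu = hu, spacing_mm = spacing_mm,
         slice_location = as.numeric(slice_location)[1L],
         source_id = as.character(source_id)[1L]),
    class = "ct_slice")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %s: %d x %d px, %.3g x %.3g mm/px, location %g\n",
              x$source_id, nrow(x$hu), ncol(x$hu),
              x$spacing_mm[1], x$spacing_mm[2], x$slice_location))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$hu), max(x$hu)))
  invisible(x)
}

#' CT series container
#'
#' An ordered stack of [ct_slice] objects from one study. Slices must share
#' pixel spacing and be sorted by non-decreasing `slice_location`.
#'
#' @param slices List of `ct_slice` objects.
#' @return An object of class `ct_series`.
#' @export
ct_series <- function(slices) {
  if (!is.list(slices) || length(slices) < 1L)
    adq_error("a series needs at least one slice", "adipoquant_invalid_series")
  if (!all(vapply(slices, inherits, logical(1), "ct_slice")))
    adq_error("all elements must be ct_slice objects",
              "adipoquant_invalid_series")
  sp <- t(vapply(slices, function(s) s$spacing_mm, numeric(2)))
  if (nrow(unique(sp)) != 1L)
    adq_error("slices have inconsistent pixel spacing",
              "adipoquant_series_consistency")
  loc <- vapply(slices, function(s) s$slice_location, numeric(1))
  if (is.unsorted(loc))
    adq_error("slices must be ordered by slice_location",
              "adipoquant_invalid_series")
  structure(list(slices = slices), class = "ct_series")
}

#' @export
print.ct_series <- function(x, ...) {
  cat(sprintf("<ct_series> %d slice(s), locations %s\n", length(x$slices),
              paste(vapply(x$slices, function(s) format(s$slice_location),
                           character(1)), collapse = ", ")))
  invisible(x)
}

#' @export
length.ct_series <- function(x) length(x$slices)
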