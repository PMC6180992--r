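#' Fat-window parameters
#'
#' Hounsfield window used to classify adipose pixels. Bounds are inclusive:
#' pixel HU values are effectively integers in clinical CT, so the window
#' `(-190, -30)` is applied as `-190 <= HU <= -30`.
#'
#' @param hu_fat_lo,hu_fat_hi Window bounds in HU, `hu_fat_lo < hu_fat_hi`.
#' @return An object of class `quantify_params`.
#' @export
quantify_params <- function(hu_fat_lo = -190, hu_fat_hi = -30) {
  if (!(hu_fat_lo < hu_fat_hi))
    adq_error("hu_fat_lo must be < hu_fat_hi", "adipoquant_invalid_params")
  structure(list(hu_fat_lo = hu_fat_lo, hu_fat_hi = hu_fat_hi),
            class = "quantify_params")
}

#' Classify adipose pixels by Hounsfield window
#'
#' @param ct A [ct_slice].
#' @param params A [quantify_params].
#' @return 0/1 matrix: 1 where `hu_fat_lo <= HU <= hu_fat_hi`.
#' @export
adipose_mask <- function(ct, params = quantify_params()) {
  stopifnot(inherits(ct, "ct_slice"))
  as_mask(ct$hu >= params$hu_fat_lo & ct$hu <= params$hu_fat_hi)
}

#' Partition the slice into total/visceral/subcutaneous regions
#'
#' The total region is the filled body polygon (boundary pixels included),
#' the visceral region the filled cavity polygon, and the subcutaneous
#' region their set difference, so the three regions form an exact
#' partition: `vat | sat == tat`, `vat & sat == 0`.
#'
#' @param shape `(rows, cols)` of the slice.
#' @param body Body [ct_contour].
#' @param cavity Cavity [ct_contour]; must lie inside the body region.
#' @return `list(tat_region, vat_region, sat_region)` of 0/1 matrices.
#' @export
partition_regions <- function(shape, body, cavity) {
  tat <- fill_contour_mask(body, shape)
  vat <- fill_contour_mask(cavity, shape)
  if (any(vat & !tat))
    adq_error("cavity contour is not contained in the body contour",
              "adipoquant_nesting_error")
  sat <- as_mask(tat & !vat)
  list(tat_region = tat, vat_region = vat, sat_region = sat)
}

#' Waist circumference from the body contour
#'
#' Physical closed-polyline perimeter of the traced body contour, with
#' anisotropic pixel spacing applied per segment.
#'
#' @param body Body [ct_contour] with >= 3 points.
#' @param spacing_mm `(row, col)` pixel size in mm.
#' @return Length in cm.
#' @export
waist_circumference <- function(body, spacing_mm) {
  if (!inherits(body, "ct_contour")) body <- ct_contour(body)
  if (nrow(body$points) < 3L)
    adq_error("waist circumference needs a closed contour of >= 3 points",
              "adipoquant_degenerate_contour")
  contour_perimeter(body, spacing_mm) / 10
}

#' Per-slice adipose measures
#'
#' Intersects the fat window mask with the region partition and converts
#' pixel counts to areas. `tat_cm2 = vat_cm2 + sat_cm2` holds exactly by
#' construction. Ratios are `NA` when their denominator is zero.
#'
#' @param ct A [ct_slice].
#' @param body Body [ct_contour].
#' @param cavity Cavity [ct_contour] nested inside `body`.
#' @param qparams A [quantify_params].
#' @return An object of class `adipose_measures` with fields `tat_cm2`,
#'   `vat_cm2`, `sat_cm2`, `vsr` (VAT/SAT), `vtr` (VAT/TAT), `wc_cm`,
#'   pixel counts (`tat_px`, `vat_px`, `sat_px`), `source_id`, and
#'   `slice_location`.
#' @export
measure_slice <- function(ct, body, cavity, qparams = quantify_params()) {
  stopifnot(inherits(ct, "ct_slice"))
  fat <- adipose_mask(ct, qparams)
  reg <- partition_regions(dim(ct$hu), body, cavity)
  vat_px <- sum(fat & reg$vat_region)
  sat_px <- sum(fat & reg$sat_region)
  tat_px <- sum(fat & reg$tat_region)
  stopifnot(tat_px == vat_px + sat_px)   # exact partition
  px_cm2 <- prod(ct$spacing_mm) / 100
  structure(list(
    source_id = ct$source_id, slice_location = ct$slice_location,
    tat_cm2 = tat_px * px_cm2, vat_cm2 = vat_px * px_cm2,
    sat_cm2 = sat_px * px_cm2,
    vsr = if (sat_px > 0) vat_px / sat_px else NA_real_,
    vtr = if (tat_px > 0) vat_px / tat_px else NA_real_,
    wc_cm = waist_circumference(body, ct$spacing_mm),
    tat_px = tat_px, vat_px = vat_px, sat_px = sat_px),
    class = "adipose_measures")
}

#' @export
print.adipose_measures <- function(x, ...) {
  cat(sprintf("<adipose_measures> %s @ %g\n", x$source_id, x$slice_location))
  cat(sprintf("  TAT %.2f cm^2 = VAT %.2f + SAT %.2f; VSR %s, VTR %s; WC %.1f cm\n",
              x$tat_cm2, x$vat_cm2, x$sat_cm2,
              ifelse(is.na(x$vsr), "NA", sprintf("%.3f", x$vsr)),
              ifelse(is.na(x$vtr), "NA", sprintf("%.3f", x$vtr)), x$wc_cm))
  invisible(x)
}

#' Select the analysis slice from per-slice measures
#'
#' @param measures List of [measure_slice] results (or a data frame with
#'   `tat_cm2` / `wc_cm` columns).
#' @param criterion `"max_tat"` (largest total adipose area) or `"max_wc"`
#'   (largest waist circumference).
#' @return 1-based index of the selected slice; ties go to the smallest
#'   index.
#' @export
select_slice <- function(measures, criterion = c("max_tat", "max_wc")) {
  criterion <- match.arg(criterion)
  if (length(measures) == 0L)
    adq_error("no measures to select from", "adipoquant_invalid_params")
  field <- if (criterion == "max_tat") "tat_cm2" else "wc_cm"
  vals <- if (is.data.frame(measures)) measures[[field]]
          else vapply(measures, function(m) m[[field]], numeric(1))
  which.max(vals)   # which.max returns the first maximum
}

#' Run the full segmentation pipeline on one slice
#'
#' Body mask, Moore trace + greedy-snake body contour, pressure-snake
#' cavity contour, and adipose quantification.
#'
#' @param ct A [ct_slice].
#' @param body_params A [body_extraction_params].
#' @param snake_body [snake_params] for the body refinement stage.
#' @param snake_cavity [snake_params] for the cavity contraction stage.
#' @param qparams A [quantify_params].
#' @param skin_band_px Skin suppression band for the cavity stage.
#' @return `list(measures, body_contour, cavity_contour, body_mask)`.
#' @export
segment_slice <- function(ct, body_params = body_extraction_params(),
                          snake_body = snake_params(),
                          snake_cavity = snake_params(delta = 0.3),
                          qparams = quantify_params(), skin_band_px = 4L) {
  mask <- compute_body_mask(ct, body_params)
  body <- find_body_contour(ct, mask, snake_body)
  cavity <- find_cavity_contour(ct, body, mask, snake_cavity, skin_band_px)
  list(measures = measure_slice(ct, body, cavity, qparams),
       body_contour = body, cavity_contour = cavity, body_mask = mask)
}

#' Segmentation accuracy over a suite of seeded phantoms
#'
#' Generates `n` phantoms with consecutive seeds, runs the full pipeline
#' on each, and reports per-phantom true and estimated areas with relative
#' errors. This is the evaluation harness behind the package's accuracy
#' claims.
#'
#' @param n Number of phantoms.
#' @param seed Seed of the first phantom; phantom `i` uses `seed + i - 1`.
#' @param params Base [phantom_params] (the seed field is overridden).
#' @param ... Passed to [segment_slice].
#' @return Data frame with one row per phantom: true/estimated TAT, VAT,
#'   SAT areas (cm^2) and absolute relative errors `tat_rel_err`,
#'   `vat_rel_err`, `sat_rel_err`, plus true and estimated cavity area.
#' @export
evaluate_phantom_suite <- function(n = 50L, seed = 1L,
                                   params = phantom_params(), ...) {
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- params
    p$seed <- as.integer(seed + i - 1L)
    ph <- generate_phantom(p)
    seg <- segment_slice(ph$ct, ...)
    m <- seg$measures
    tr <- ph$truth
    rel <- function(est, true) if (true > 0) abs(est - true) / true else NA_real_
    rows[[i]] <- data.frame(
      seed = p$seed,
      tat_true = tr$tat_area_cm2, tat_est = m$tat_cm2,
      vat_true = tr$vat_area_cm2, vat_est = m$vat_cm2,
      sat_true = tr$sat_area_cm2, sat_est = m$sat_cm2,
      cavity_true = tr$cavity_area_cm2,
      cavity_est = contour_area(seg$cavity_contour) *
        prod(ph$ct$spacing_mm) / 100,
      tat_rel_err = rel(m$tat_cm2, tr$tat_area_cm2),
      vat_rel_err = rel(m$vat_cm2, tr$vat_area_cm2),
      sat_rel_err = rel(m$sat_cm2, tr$sat_area_cm2))
  }
  do.call(rbind, rows)
}
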