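#' Parameters for the synthetic abdominal CT phantom
#'
#' The phantom emulates the anatomy the segmentation pipeline assumes on an
#' axial abdominal slice: air background, an elliptical body with a thin
#' skin shell, a subcutaneous fat ring, an abdominal muscle wall, an inner
#' cavity filled with organ-density tissue carrying discrete visceral fat
#' blobs, and an optional detached scanner-table strip. Default tissue HU
#' values follow textbook ranges (air -1000, fat -100, muscle/organ 40,
#' skin 20, table -300) with the fat mean centered in the (-190, -30)
#' adipose window.
#'
#' @param image_size `(rows, cols)` in pixels.
#' @param spacing_mm `(row, col)` pixel size in mm.
#' @param body_axes_px Semi-axes `(row, col)` of the outer body ellipse.
#' @param skin_thickness_px Thickness of the skin shell.
#' @param sat_thickness_px Thickness of the subcutaneous fat ring.
#' @param wall_thickness_px Thickness of the abdominal muscle wall.
#' @param n_visceral_blobs Number of visceral fat blobs.
#' @param blob_radius_px_range `(min, max)` blob radius in pixels.
#' @param hu_means,hu_sds Named vectors (air, fat, muscle, organ, skin,
#'   table) of per-tissue HU means and texture standard deviations.
#' @param table_artifact Draw a detached table strip below the body.
#' @param noise_sd_hu Additional global Gaussian acquisition noise (HU).
#' @param seed RNG seed; identical seeds give bit-identical phantoms.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(image_size = c(192L, 192L), spacing_mm = c(2, 2),
                           body_axes_px = c(60, 75), skin_thickness_px = 2,
                           sat_thickness_px = 12, wall_thickness_px = 5,
                           n_visceral_blobs = 8L,
                           blob_radius_px_range = c(5, 10),
                           hu_means = c(air = -1000, fat = -100, muscle = 40,
                                        organ = 40, skin = 20, table = -300),
                           hu_sds = c(air = 3, fat = 15, muscle = 10,
                                      organ = 12, skin = 5, table = 5),
                           table_artifact = TRUE, noise_sd_hu = 5, seed = 1L) {
  need <- c("air", "fat", "muscle", "organ", "skin", "table")
  if (!all(need %in% names(hu_means)) || !all(need %in% names(hu_sds)))
    adq_error("hu_means and hu_sds need entries for air, fat, muscle, organ, skin, table",
              "adipoquant_invalid_params")
  if (any(hu_sds < 0) || noise_sd_hu < 0)
    adq_error("standard deviations must be >= 0", "adipoquant_invalid_params")
  if (hu_means[["fat"]] <= -190 || hu_means[["fat"]] >= -30)
    adq_error("fat HU mean must lie inside (-190, -30)",
              "adipoquant_invalid_params")
  shell <- skin_thickness_px + sat_thickness_px + wall_thickness_px
  if (any(body_axes_px <= shell + 2))
    adq_error("body axes must exceed skin + SAT + wall thickness + 2 (empty cavity)",
              "adipoquant_invalid_params")
  structure(list(image_size = as.integer(image_size), spacing_mm = spacing_mm,
                 body_axes_px = body_axes_px,
                 skin_thickness_px = skin_thickness_px,
                 sat_thickness_px = sat_thickness_px,
                 wall_thickness_px = wall_thickness_px,
                 n_visceral_blobs = as.integer(n_visceral_blobs),
                 blob_radius_px_range = blob_radius_px_range,
                 hu_means = hu_means, hu_sds = hu_sds,
                 table_artifact = isTRUE(table_artifact),
                 noise_sd_hu = noise_sd_hu, seed = as.integer(seed)),
            class = "phantom_params")
}

## center-of-pixel ellipse rasterization: pixel (r, c) belongs iff its
## center satisfies the ellipse inequality, so truth areas are exact pixel
## counts.
.ellipse_mask <- function(shape, center, axes) {
  if (any(axes <= 0)) return(matrix(0L, shape[1], shape[2]))
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  as_mask(((rr - center[1]) / axes[1])^2 + ((cc - center[2]) / axes[2])^2 <= 1)
}

.disc_mask <- function(shape, center, radius) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  as_mask((rr - center[1])^2 + (cc - center[2])^2 <= radius^2)
}

## Ramanujan's ellipse perimeter approximation (for ground-truth waist
## circumference; exact to ~1e-5 for the aspect ratios used here).
.ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Generate one synthetic abdominal CT slice with exact ground truth
#'
#' Rasterizes the concentric phantom geometry, fills each tissue with
#' Gaussian-textured HU values, optionally adds a detached table strip and
#' global acquisition noise. Ground-truth masks record the drawn fat
#' compartments: `sat_mask` is the subcutaneous ring, `vat_mask` the union
#' of visceral blobs, `tat_mask` their union, and `cavity_mask` the
#' abdominal region enclosed by the outer margin of the muscle wall (the
#' fat-muscle interface the cavity snake converges to).
#'
#' @param params A [phantom_params].
#' @return `list(ct = ct_slice, truth = phantom_truth)` where the truth
#'   holds the masks, areas in cm^2, and the body perimeter in cm.
#' @export
generate_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  with_seed(params$seed, .generate_phantom_impl(params))
}

.generate_phantom_impl <- function(params) {
  shape <- params$image_size
  ctr <- (shape + 1) / 2
  ax <- params$body_axes_px
  mu <- params$hu_means; sdv <- params$hu_sds

  body <- .ellipse_mask(shape, ctr, ax)
  skin_in <- .ellipse_mask(shape, ctr, ax - params$skin_thickness_px)
  sat_in <- .ellipse_mask(shape, ctr,
                          ax - params$skin_thickness_px - params$sat_thickness_px)
  organ <- .ellipse_mask(shape, ctr,
                         ax - params$skin_thickness_px - params$sat_thickness_px -
                           params$wall_thickness_px)
  if (sum(organ) == 0L)
    adq_error("phantom geometry leaves an empty cavity", "adipoquant_invalid_params")
  cavity <- sat_in                      # wall + organ region
  sat_ring <- as_mask(skin_in & !sat_in)
  wall <- as_mask(sat_in & !organ)
  skin <- as_mask(body & !skin_in)

  ## visceral fat blobs: rejection-sampled to sit >= 2 px inside the organ
  ## region and pairwise non-overlapping
  vat <- matrix(0L, shape[1], shape[2])
  o_ax <- ax - params$skin_thickness_px - params$sat_thickness_px -
    params$wall_thickness_px
  blobs <- matrix(numeric(0), 0, 3)     # row, col, radius
  n_blobs <- params$n_visceral_blobs
  if (n_blobs > 0L) {
    tries <- 0L
    while (nrow(blobs) < n_blobs && tries < 5000L) {
      tries <- tries + 1L
      rad <- runif(1, params$blob_radius_px_range[1],
                   params$blob_radius_px_range[2])
      eff <- o_ax - (rad + 2)
      if (any(eff <= 0)) next
      p <- c(runif(1, ctr[1] - o_ax[1], ctr[1] + o_ax[1]),
             runif(1, ctr[2] - o_ax[2], ctr[2] + o_ax[2]))
      if (((p[1] - ctr[1]) / eff[1])^2 + ((p[2] - ctr[2]) / eff[2])^2 > 1) next
      if (nrow(blobs) > 0 &&
          any(sqrt((blobs[, 1] - p[1])^2 + (blobs[, 2] - p[2])^2) <
              blobs[, 3] + rad + 1)) next
      blobs <- rbind(blobs, c(p, rad))
      vat <- as_mask(vat | .disc_mask(shape, p, rad))
    }
    if (nrow(blobs) < n_blobs)
      adq_error("could not place visceral blobs inside the cavity",
                "adipoquant_invalid_params")
  }

  fill <- function(tissue) rnorm(shape[1] * shape[2], mu[[tissue]], sdv[[tissue]])
  hu <- matrix(fill("air"), shape[1], shape[2])
  draw <- function(hu, mask, tissue) {
    idx <- mask == 1L
    hu[idx] <- rnorm(sum(idx), mu[[tissue]], sdv[[tissue]])
    hu
  }
  hu <- draw(hu, skin, "skin")
  hu <- draw(hu, sat_ring, "fat")
  hu <- draw(hu, wall, "muscle")
  hu <- draw(hu, organ, "organ")
  hu <- draw(hu, vat, "fat")

  if (params$table_artifact) {
    bottom <- max(which(rowSums(body) > 0))
    r0 <- bottom + 6L
    if (r0 + 3L <= shape[1]) {
      cols <- seq.int(floor(shape[2] * 0.2), ceiling(shape[2] * 0.8))
      strip <- matrix(0L, shape[1], shape[2])
      strip[r0:(r0 + 3L), cols] <- 1L
      hu <- draw(hu, strip, "table")
    }
  }
  if (params$noise_sd_hu > 0)
    hu <- hu + rnorm(length(hu), 0, params$noise_sd_hu)

  px_cm2 <- prod(params$spacing_mm) / 100
  tat <- as_mask(sat_ring | vat)
  truth <- structure(list(
    body_mask = body, cavity_mask = cavity, tat_mask = tat,
    vat_mask = vat, sat_mask = sat_ring,
    tat_area_cm2 = sum(tat) * px_cm2,
    vat_area_cm2 = sum(vat) * px_cm2,
    sat_area_cm2 = sum(sat_ring) * px_cm2,
    cavity_area_cm2 = sum(cavity) * px_cm2,
    body_perimeter_cm = .ellipse_perimeter(ax[1] * params$spacing_mm[1],
                                           ax[2] * params$spacing_mm[2]) / 10,
    blobs = blobs), class = "phantom_truth")
  list(ct = ct_slice(hu, params$spacing_mm, slice_location = 0,
                     source_id = sprintf("phantom-seed%d", params$seed)),
       truth = truth)
}

#' Generate a phantom series with known argmax slices
#'
#' Produces a stack of phantoms whose body axes and visceral blob counts
#' vary smoothly across slices, so the indices of maximal total adipose
#' and maximal body perimeter are computable from the ground truth (and
#' generally differ).
#'
#' @param params Base [phantom_params].
#' @param n_slices Number of slices (>= 1).
#' @param seed Series seed; per-slice seeds are derived from it.
#' @param axes_scale Numeric vector (length `n_slices`) scaling the body
#'   axes per slice; default ramps 0.92 to 1.
#' @param blob_counts Integer vector of visceral blob counts per slice;
#'   default peaks at the middle slice.
#' @return `list(series = ct_series, truths = list of phantom_truth)`.
#' @export
generate_series <- function(params = phantom_params(), n_slices = 5L,
                            seed = params$seed, axes_scale = NULL,
                            blob_counts = NULL) {
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L)
    adq_error("n_slices must be >= 1", "adipoquant_invalid_params")
  if (is.null(axes_scale))
    axes_scale <- if (n_slices == 1L) 1 else seq(0.92, 1, length.out = n_slices)
  if (is.null(blob_counts)) {
    mid <- (n_slices + 1) / 2
    blob_counts <- params$n_visceral_blobs +
      pmax(0L, round(2 * (1 - abs(seq_len(n_slices) - mid) / max(1, mid - 1))))
  }
  stopifnot(length(axes_scale) == n_slices, length(blob_counts) == n_slices)
  slices <- vector("list", n_slices)
  truths <- vector("list", n_slices)
  for (i in seq_len(n_slices)) {
    p <- params
    p$body_axes_px <- params$body_axes_px * axes_scale[i]
    p$n_visceral_blobs <- as.integer(blob_counts[i])
    p$seed <- as.integer(seed + 1000L * i)
    ph <- phantom_params(image_size = p$image_size, spacing_mm = p$spacing_mm,
                         body_axes_px = p$body_axes_px,
                         skin_thickness_px = p$skin_thickness_px,
                         sat_thickness_px = p$sat_thickness_px,
                         wall_thickness_px = p$wall_thickness_px,
                         n_visceral_blobs = p$n_visceral_blobs,
                         blob_radius_px_range = p$blob_radius_px_range,
                         hu_means = p$hu_means, hu_sds = p$hu_sds,
                         table_artifact = p$table_artifact,
                         noise_sd_hu = p$noise_sd_hu, seed = p$seed)
    out <- generate_phantom(ph)
    out$ct$slice_location <- (i - 1) * 5
    out$ct$source_id <- sprintf("phantom-series-%02d", i)
    slices[[i]] <- out$ct
    truths[[i]] <- out$truth
  }
  list(series = ct_series(slices), truths = truths)
}
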