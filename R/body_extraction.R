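#' Body-extraction parameters
#'
#' Controls the preprocessing stage that separates the patient's body from
#' air background and scanner hardware before any contouring.
#'
#' @param body_hu_min HU threshold separating tissue from air. -500 HU sits
#'   between air (-1000) and the lower edge of the adipose window (-190),
#'   so the full fat compartment is retained.
#' @param opening_radius_px Radius of the disc structuring element for the
#'   morphological opening that removes thin material artifacts (scanner
#'   table, trays).
#' @param fill_holes Fill interior holes (e.g. bowel gas) in the body mask.
#' @return An object of class `body_extraction_params`.
#' @export
body_extraction_params <- function(body_hu_min = -500, opening_radius_px = 3L,
                                   fill_holes = TRUE) {
  if (opening_radius_px < 0)
    adq_error("opening_radius_px must be >= 0", "adipoquant_invalid_params")
  structure(list(body_hu_min = body_hu_min,
                 opening_radius_px = as.integer(opening_radius_px),
                 fill_holes = isTRUE(fill_holes)),
            class = "body_extraction_params")
}

#' Segment the body from a CT slice
#'
#' Thresholds at `body_hu_min`, applies a morphological opening to detach
#' and delete thin material artifacts, keeps the largest 8-connected
#' component, and (optionally) fills interior holes. The result is a single
#' connected 0/1 mask of the body cross-section.
#'
#' @param ct A [ct_slice].
#' @param params A [body_extraction_params].
#' @return A 0/1 integer matrix the shape of `ct$hu`.
#' @export
compute_body_mask <- function(ct, params = body_extraction_params()) {
  stopifnot(inherits(ct, "ct_slice"))
  m <- as_mask(ct$hu >= params$body_hu_min)
  m <- mask_open(m, params$opening_radius_px)
  if (sum(m) == 0L)
    adq_error("no foreground pixels after thresholding and opening",
              "adipoquant_no_body")
  m <- largest_component(m, 8L)
  if (params$fill_holes) m <- fill_holes(m)
  m
}

#' Trace the outer boundary of a mask (Moore-neighbor tracing)
#'
#' Walks the 8-neighborhood around the single foreground component of
#' `mask`, clockwise, starting from the top-most then left-most foreground
#' pixel. Termination uses Jacob's stopping criterion: the walk ends when
#' the start pixel is re-entered from its original entry direction. Every
#' visited pixel is a foreground pixel with at least one background
#' 8-neighbor (pixels outside the image count as background).
#'
#' @param mask 0/1 matrix with exactly one 8-connected foreground component.
#' @return A [ct_contour] of boundary pixels in clockwise order. A
#'   single-pixel mask yields a 1-point contour.
#' @export
moore_trace <- function(mask) {
  mask <- as_mask(mask)
  lab <- label_components(mask, 8L)
  ncomp <- max(lab)
  if (ncomp == 0L)
    adq_error("mask has no foreground pixels", "adipoquant_empty_mask")
  if (ncomp > 1L)
    adq_error("mask has multiple 8-connected components",
              "adipoquant_multiple_components")
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c] == 1L

  ## start: top-most, then left-most foreground pixel
  rows <- which(rowSums(mask) > 0)
  r0 <- rows[1]
  c0 <- which(mask[r0, ] == 1L)[1]

  ## clockwise Moore neighborhood (row grows downward): N, NE, E, SE, S, SW, W, NW
  off <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))

  if (sum(mask) == 1L)
    return(ct_contour(matrix(c(r0, c0), 1, 2), validate = FALSE))

  ## Deterministic walk on (pixel, backtrack-direction) states; the walk
  ## enters a cycle (Jacob's stopping criterion: the start state of the
  ## cycle is re-entered from the same direction) whose pixel sequence is
  ## the clockwise boundary. Cycle detection on the state space is robust
  ## to spur pixels that the walk legitimately visits twice.
  max_states <- 8L * (nr * nc)
  seen <- integer(max_states)            # state key -> path index
  cap <- 4L * sum(mask) + 16L
  path <- matrix(0L, cap, 2L)
  cur <- c(r0, c0)
  dir <- 1L                              # entered from the north (background)
  npts <- 0L
  cycle <- NULL
  repeat {
    key <- ((cur[1] - 1L) * nc + (cur[2] - 1L)) * 8L + dir
    if (seen[key] > 0L) { cycle <- seen[key]:npts; break }
    npts <- npts + 1L
    if (npts > cap) adq_error("boundary trace failed to close",
                              "adipoquant_trace_error")
    path[npts, ] <- cur
    seen[key] <- npts
    ## scan clockwise starting at the backtrack direction
    found <- FALSE
    for (k in 0:7) {
      j <- ((dir - 1L + k) %% 8L) + 1L
      cand <- cur + off[j, ]
      if (fg(cand[1], cand[2])) {
        prevj <- ((j - 2L) %% 8L) + 1L   # last background neighbor scanned
        back <- cur + off[prevj, ]
        dir <- which(off[, 1] == back[1] - cand[1] &
                     off[, 2] == back[2] - cand[2])
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break                    # unreachable: single pixel handled
  }
  pts <- path[cycle, , drop = FALSE]
  ## rotate so the contour starts at the top-most then left-most pixel
  at_start <- which(pts[, 1] == r0 & pts[, 2] == c0)
  if (length(at_start) > 0L && at_start[1] > 1L) {
    i <- at_start[1]
    pts <- pts[c(i:nrow(pts), 1:(i - 1L)), , drop = FALSE]
  }
  ct_contour(pts, validate = FALSE)
}
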