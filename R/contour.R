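#' Closed pixel contour
#'
#' An ordered, closed sequence of `(row, col)` pixel coordinates describing
#' a boundary (outer body or abdominal cavity). The closing segment from the
#' last point back to the first is implicit. Consecutive duplicate points
#' are collapsed.
#'
#' @param points Two-column numeric matrix of `(row, col)` coordinates.
#' @param validate Require at least 3 distinct points (the minimum for a
#'   polygon with area). Boundary traces of degenerate 1-2 pixel masks may
#'   switch this off.
#' @return An object of class `ct_contour`.
#' @export
ct_contour <- function(points, validate = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 1L || !all(is.finite(points)))
    adq_error("points must be a finite n x 2 matrix", "adipoquant_invalid_contour")
  colnames(points) <- c("row", "col")
  ## drop consecutive duplicates (including wrap-around)
  if (nrow(points) > 1L) {
    keep <- c(TRUE, rowSums(abs(points[-1, , drop = FALSE] -
                                points[-nrow(points), , drop = FALSE])) > 0)
    points <- points[keep, , drop = FALSE]
    if (nrow(points) > 1L &&
        all(points[nrow(points), ] == points[1, ]))
      points <- points[-nrow(points), , drop = FALSE]
  }
  if (validate && nrow(points) < 3L)
    adq_error("a closed contour needs at least 3 distinct points",
              "adipoquant_invalid_contour")
  structure(list(points = points, closed = TRUE), class = "ct_contour")
}

#' @export
print.ct_contour <- function(x, ...) {
  cat(sprintf("<ct_contour> %d points, perimeter %.1f px, area %.1f px^2\n",
              nrow(x$points), contour_perimeter(x), contour_area(x)))
  invisible(x)
}

#' Closed-polyline perimeter of a contour, in pixels (or mm with spacing)
#'
#' @param contour A [ct_contour].
#' @param spacing_mm Optional `(row, col)` pixel size; when given, each
#'   segment length is measured anisotropically and the result is in mm.
#' @return Scalar perimeter.
#' @export
contour_perimeter <- function(contour, spacing_mm = c(1, 1)) {
  p <- contour$points
  n <- nrow(p)
  if (n < 2L) return(0)
  nxt <- p[c(2:n, 1), , drop = FALSE]
  sum(sqrt(((nxt[, 1] - p[, 1]) * spacing_mm[1])^2 +
           ((nxt[, 2] - p[, 2]) * spacing_mm[2])^2))
}

#' Enclosed (shoelace) area of a contour in squared pixels
#'
#' @param contour A [ct_contour].
#' @return Scalar area (>= 0).
#' @export
contour_area <- function(contour) {
  p <- contour$points
  n <- nrow(p)
  if (n < 3L) return(0)
  nxt <- p[c(2:n, 1), , drop = FALSE]
  abs(sum(p[, 1] * nxt[, 2] - nxt[, 1] * p[, 2])) / 2
}

#' Resample a closed contour to uniform arc-length spacing
#'
#' Places `round(perimeter / spacing_px)` points (minimum 8) at equal arc
#' length along the closed polyline. Resampled positions are real-valued;
#' the snake moves them in whole-pixel steps and samples the image energy
#' at the nearest pixel. Keeping the arc-length positions exact avoids the
#' rounding jitter that otherwise makes the discrete curvature term
#' restless on smooth contours.
#'
#' @param contour A [ct_contour] with at least 3 points.
#' @param spacing_px Target spacing between consecutive points, in pixels.
#' @return A resampled [ct_contour].
#' @export
resample_contour <- function(contour, spacing_px) {
  if (!inherits(contour, "ct_contour")) contour <- ct_contour(contour)
  p <- contour$points
  if (nrow(p) < 3L)
    adq_error("resampling needs at least 3 points", "adipoquant_invalid_contour")
  if (spacing_px <= 0)
    adq_error("spacing_px must be positive", "adipoquant_invalid_contour")
  per <- contour_perimeter(contour)
  if (per <= 0)
    adq_error("degenerate zero-perimeter contour", "adipoquant_degenerate_contour")
  n <- nrow(p)
  closed <- rbind(p, p[1, , drop = FALSE])
  seg <- sqrt(rowSums((closed[-1, , drop = FALSE] -
                       closed[-(n + 1), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  k <- max(8L, as.integer(round(per / spacing_px)))
  s <- (seq_len(k) - 1) * per / k
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, n)
  t <- (s - cum[idx]) / pmax(seg[idx], .Machine$double.eps)
  pts <- closed[idx, , drop = FALSE] +
    (closed[idx + 1L, , drop = FALSE] - closed[idx, , drop = FALSE]) * t
  ct_contour(pts, validate = FALSE)
}

## Integer pixels on the segment p0 -> p1 (Bresenham-style supercover via
## dense sampling; endpoints are integer pixels).
segment_pixels <- function(p0, p1) {
  n <- max(abs(p1 - p0)) + 1L
  if (n <= 1L) return(matrix(p0, 1L, 2L))
  t <- seq(0, 1, length.out = n)
  cbind(round(p0[1] + t * (p1[1] - p0[1])),
        round(p0[2] + t * (p1[2] - p0[2])))
}

## 0/1 mask of the pixels on a closed contour polyline.
draw_contour_mask <- function(contour, shape) {
  p <- round(contour$points)
  n <- nrow(p)
  mask <- matrix(0L, shape[1], shape[2])
  for (i in seq_len(n)) {
    px <- segment_pixels(p[i, ], p[if (i == n) 1L else i + 1L, ])
    ok <- px[, 1] >= 1 & px[, 1] <= shape[1] & px[, 2] >= 1 & px[, 2] <= shape[2]
    mask[px[ok, , drop = FALSE]] <- 1L
  }
  mask
}

## 0/1 mask of the filled contour polygon; pixels on the boundary polyline
## are included. Interior membership is point-in-polygon on pixel centers.
fill_contour_mask <- function(contour, shape) {
  p <- contour$points
  mask <- draw_contour_mask(contour, shape)
  rmin <- max(1L, floor(min(p[, 1]))); rmax <- min(shape[1], ceiling(max(p[, 1])))
  cmin <- max(1L, floor(min(p[, 2]))); cmax <- min(shape[2], ceiling(max(p[, 2])))
  if (rmax >= rmin && cmax >= cmin) {
    grid <- as.matrix(expand.grid(row = rmin:rmax, col = cmin:cmax))
    bnd <- rbind(p, p[1, , drop = FALSE])
    inside <- mgcv::in.out(bnd, grid)
    mask[grid[inside, , drop = FALSE]] <- 1L
  }
  mask
}
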