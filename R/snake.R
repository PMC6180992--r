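#' Greedy-snake parameters
#'
#' Weights and controls for the discrete greedy active contour. Each
#' contour point is moved, in sequence, to the minimum of a weighted sum of
#' continuity (elasticity), curvature, image, and optional inward-pressure
#' energies over an `m x m` candidate window. The geometric terms are
#' min-max normalized within each candidate window; the image energy is
#' normalized globally so edge strength stays comparable across the image.
#'
#' @param alpha Continuity (elasticity) weight; penalizes deviation of the
#'   segment length to the previous point from the current mean spacing.
#' @param beta Curvature weight; penalizes `|v_prev - 2 v + v_next|^2`.
#' @param gamma Image-energy weight; pulls points onto strong edges.
#' @param delta Inward-pressure (balloon) weight. 0 for edge refinement
#'   (body stage); positive values drive contraction through featureless
#'   tissue (cavity stage).
#' @param neighborhood_px Odd side length of the candidate window.
#' @param max_iter Maximum number of full passes over the contour.
#' @param move_tol_frac Stop when fewer than this fraction of points moved
#'   in a full pass.
#' @param resample_spacing_px Target inter-point spacing for contour
#'   resampling before and after the iteration.
#' @param smooth_sigma_px Gaussian sigma for the smoothed gradient image.
#' @return An object of class `snake_params`.
#' @export
snake_params <- function(alpha = 1.0, beta = 1.0, gamma = 1.5, delta = 0,
                         neighborhood_px = 3L, max_iter = 500L,
                         move_tol_frac = 0.02, resample_spacing_px = 5,
                         smooth_sigma_px = 2.0) {
  if (any(c(alpha, beta, gamma, delta) < 0))
    adq_error("energy weights must be >= 0", "adipoquant_invalid_params")
  neighborhood_px <- as.integer(neighborhood_px)
  if (neighborhood_px < 1L || neighborhood_px %% 2L == 0L)
    adq_error("neighborhood_px must be odd and >= 1", "adipoquant_invalid_params")
  if (move_tol_frac <= 0 || move_tol_frac >= 1)
    adq_error("move_tol_frac must be in (0, 1)", "adipoquant_invalid_params")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
                 neighborhood_px = neighborhood_px,
                 max_iter = as.integer(max_iter),
                 move_tol_frac = move_tol_frac,
                 resample_spacing_px = resample_spacing_px,
                 smooth_sigma_px = smooth_sigma_px),
            class = "snake_params")
}

#' Image (edge) energy for the greedy snake
#'
#' HU values are clipped to the soft-tissue display window `[-200, 200]`,
#' Gaussian-smoothed, and the gradient magnitude `g` is computed. The
#' energy is `1 - g / max(g)`, so strong edges have low energy. Gradients
#' inside `suppress_band` are zeroed before normalization, making those
#' edges invisible to the snake (used to hide the skin edge during the
#' cavity stage) and scaling the remaining edges to the full [0, 1] range.
#'
#' @param ct A [ct_slice].
#' @param params A [snake_params] (only `smooth_sigma_px` is used).
#' @param suppress_band Optional 0/1 mask; gradient is suppressed where 1.
#' @return Matrix in `[0, 1]`, same shape as `ct$hu`; 1 everywhere for a
#'   constant image.
#' @export
compute_image_energy <- function(ct, params = snake_params(),
                                 suppress_band = NULL) {
  stopifnot(inherits(ct, "ct_slice"))
  h <- pmin(pmax(ct$hu, -200), 200)
  g <- gradient_magnitude(gaussian_smooth(h, params$smooth_sigma_px))
  if (!is.null(suppress_band)) g[suppress_band != 0] <- 0
  mx <- max(g)
  if (mx <= 0) return(matrix(1, nrow(g), ncol(g)))
  e <- 1 - g / mx
  if (!is.null(suppress_band)) e[suppress_band != 0] <- 1
  e
}

## Move points not inside `mask` to the nearest mask pixel (Chebyshev
## rings, deterministic row-then-col tie-break).
.snap_into_mask <- function(pts, mask, max_radius = 10L) {
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in seq_len(nrow(pts))) {
    r <- pts[i, 1]; c <- pts[i, 2]
    if (r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c] != 0) next
    done <- FALSE
    for (rad in 1:max_radius) {
      rs <- max(1, r - rad):min(nr, r + rad)
      cs <- max(1, c - rad):min(nc, c + rad)
      sub <- mask[rs, cs, drop = FALSE]
      hit <- which(sub != 0, arr.ind = TRUE)
      if (nrow(hit)) {
        hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
        pts[i, ] <- c(rs[hit[1, 1]], cs[hit[1, 2]])
        done <- TRUE
        break
      }
    }
    if (!done)
      adq_error("contour point too far outside the clamp mask",
                "adipoquant_clamp_error")
  }
  pts
}

## Outward unit normal at a contour point, from the neighbor chord rotated
## 90 degrees and oriented away from the contour centroid.
.outward_normal <- function(v_prev, v_next, v_cur, centroid) {
  tang <- v_next - v_prev
  nrm <- c(tang[2], -tang[1])
  if (sum(nrm^2) == 0) nrm <- v_cur - centroid
  if (sum((v_cur - centroid) * nrm) < 0) nrm <- -nrm
  len <- sqrt(sum(nrm^2))
  if (len > 0) nrm / len else c(0, 0)
}

.minmax01 <- function(x) {
  rng <- max(x) - min(x)
  if (rng <= 0) rep(0, length(x)) else (x - min(x)) / rng
}

#' One sequential greedy pass over all contour points
#'
#' Points are visited in order; each is moved to the candidate position of
#' minimal total energy within its window. Candidate energy is
#' `alpha * E_cont + beta * E_curv + gamma * e_img + delta * E_pres` with
#' `E_cont = (d_bar - |v - v_prev|)^2`, `E_curv = |v_prev - 2v + v_next|^2`,
#' and `E_pres` the signed outward displacement along the local outward
#' normal (inward candidates score lower). `E_cont`, `E_curv`, and `E_pres`
#' are min-max normalized over the candidate window (a term with zero range
#' contributes 0); `e_img` enters globally normalized. Neighbor positions
#' (`v_prev`, `v_next`), the mean spacing `d_bar`, and the centroid are
#' taken from the pass-start snapshot, so each update is greedy-optimal
#' against the contour the pass began with. Ties keep the current position
#' if it attains the minimum, otherwise the smallest row then column wins.
#' Candidates outside the image or outside `clamp` are excluded.
#'
#' @param contour A [ct_contour] with >= 3 points.
#' @param energy Matrix from [compute_image_energy], same shape as image.
#' @param params A [snake_params].
#' @param clamp Optional 0/1 mask restricting candidate positions.
#' @return `list(contour = updated contour, n_moved = number of points that
#'   changed position)`.
#' @export
snake_pass <- function(contour, energy, params = snake_params(), clamp = NULL) {
  pts <- contour$points
  n <- nrow(pts)
  if (n < 3L)
    adq_error("snake needs at least 3 points", "adipoquant_invalid_contour")
  k <- (params$neighborhood_px - 1L) %/% 2L
  off <- as.matrix(expand.grid(dr = -k:k, dc = -k:k))
  off <- off[order(off[, 1], off[, 2]), , drop = FALSE]
  nr <- nrow(energy); nc <- ncol(energy)
  nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
  seg <- pts[nxt, , drop = FALSE] - pts
  dbar <- mean(sqrt(rowSums(seg^2)))
  centroid <- colMeans(pts)
  ## neighbor positions are taken from the pass-start snapshot: evaluating
  ## against already-updated neighbors turns the geometric terms into a
  ## self-sustaining contraction wave on featureless images (each inward
  ## move drags the next point's curvature optimum inward)
  pts0 <- pts
  n_moved <- 0L
  for (i in seq_len(n)) {
    vc <- pts0[i, ]
    vp <- pts0[prv[i], ]
    vn <- pts0[nxt[i], ]
    cand <- cbind(off[, 1] + vc[1], off[, 2] + vc[2])
    ## positions may be fractional; the raster (bounds, clamp, energy) is
    ## consulted at the nearest pixel
    px <- cbind(round(cand[, 1]), round(cand[, 2]))
    ok <- px[, 1] >= 1 & px[, 1] <= nr & px[, 2] >= 1 & px[, 2] <= nc
    if (!is.null(clamp) && any(ok))
      ok[ok] <- clamp[px[ok, , drop = FALSE]] != 0
    if (!any(ok))
      adq_error(sprintf("all candidate positions excluded for point %d", i),
                "adipoquant_clamp_error")
    cand <- cand[ok, , drop = FALSE]
    px <- px[ok, , drop = FALSE]
    e_cont <- (dbar - sqrt((cand[, 1] - vp[1])^2 + (cand[, 2] - vp[2])^2))^2
    e_curv <- (vp[1] - 2 * cand[, 1] + vn[1])^2 +
              (vp[2] - 2 * cand[, 2] + vn[2])^2
    nrm <- .outward_normal(vp, vn, vc, centroid)
    e_pres <- (cand[, 1] - vc[1]) * nrm[1] + (cand[, 2] - vc[2]) * nrm[2]
    E <- params$alpha * .minmax01(e_cont) + params$beta * .minmax01(e_curv) +
         params$gamma * energy[px] + params$delta * .minmax01(e_pres)
    cur_idx <- which(cand[, 1] == vc[1] & cand[, 2] == vc[2])
    emin <- min(E)
    if (length(cur_idx) == 1L && E[cur_idx] <= emin + 1e-12) {
      next  # current position is (tied-)optimal: stay
    }
    tie <- which(E == emin)
    best <- tie[order(cand[tie, 1], cand[tie, 2])[1]]
    pts[i, ] <- cand[best, ]
    n_moved <- n_moved + 1L
  }
  ## transient coincident neighbors are legitimate mid-iteration; the final
  ## resampling in run_snake restores the no-duplicate invariant
  out <- structure(list(points = pts, closed = TRUE), class = "ct_contour")
  list(contour = out, n_moved = n_moved)
}

#' Run the greedy snake to convergence
#'
#' Resamples the initial contour to `resample_spacing_px`, repeats
#' [snake_pass] until fewer than `move_tol_frac` of the points move in a
#' full pass (or `max_iter` passes), and resamples once more. Fully
#' deterministic.
#'
#' @inheritParams snake_pass
#' @param initial Initial [ct_contour].
#' @return The final [ct_contour].
#' @export
run_snake <- function(initial, energy, params = snake_params(), clamp = NULL) {
  cur <- resample_contour(initial, params$resample_spacing_px)
  if (params$max_iter > 0L) {
    for (it in seq_len(params$max_iter)) {
      res <- snake_pass(cur, energy, params, clamp)
      cur <- res$contour
      if (res$n_moved / nrow(cur$points) < params$move_tol_frac) break
    }
  }
  ## a fully collapsed contour cannot be resampled; return it as-is and let
  ## callers apply their area checks
  tryCatch(resample_contour(cur, params$resample_spacing_px),
           adipoquant_degenerate_contour = function(e) cur,
           adipoquant_invalid_contour = function(e) cur)
}

#' Refine the outer body contour
#'
#' Traces the boundary of the body mask (Moore-neighbor tracing) and
#' refines it with a pure three-term greedy snake (no pressure, no clamp)
#' against the image energy of the slice.
#'
#' @param ct A [ct_slice].
#' @param mask Body mask from [compute_body_mask].
#' @param params A [snake_params]; `delta` is forced to 0.
#' @return The refined body [ct_contour].
#' @export
find_body_contour <- function(ct, mask, params = snake_params()) {
  params$delta <- 0
  trace <- moore_trace(mask)
  energy <- compute_image_energy(ct, params)
  run_snake(trace, energy, params)
}

#' Find the abdominal cavity contour by pressure-driven contraction
#'
#' Recomputes the image energy with the skin edge suppressed (all pixels
#' within `skin_band_px` of the body contour), then contracts a snake
#' initialized at the body contour inward under pressure (`delta > 0`).
#' The contraction traverses the featureless subcutaneous fat ring and
#' stalls on the gradient ridge of the abdominal muscle wall. Candidates
#' are clamped to the body mask eroded by one pixel, so the result is
#' always inside the body.
#'
#' @param ct A [ct_slice].
#' @param body Body [ct_contour] from [find_body_contour].
#' @param body_mask Body mask from [compute_body_mask].
#' @param params A [snake_params]; defaults to
#'   `snake_params(delta = 0.3)`, the cavity-stage
#'   calibration (see the package vignette).
#' @param skin_band_px Half-width of the suppression band around the body
#'   contour.
#' @return The cavity [ct_contour], strictly inside the body.
#' @export
find_cavity_contour <- function(ct, body, body_mask,
                                params = snake_params(delta = 0.3),
                                skin_band_px = 4L) {
  if (params$delta <= 0)
    adq_error("cavity stage requires delta > 0", "adipoquant_invalid_params")
  shape <- dim(ct$hu)
  band <- mask_dilate(draw_contour_mask(body, shape), skin_band_px)
  energy <- compute_image_energy(ct, params, suppress_band = band)
  clamp <- mask_erode1(body_mask)
  ## the refined body contour may ride the skin edge just outside the
  ## eroded mask; snap such points to the nearest clamped pixel so every
  ## point starts with a non-empty candidate set
  init <- ct_contour(.snap_into_mask(round(body$points), clamp),
                     validate = FALSE)
  res <- run_snake(init, energy, params, clamp)
  if (contour_area(res) < 25)
    adq_error("cavity contour collapsed (no internal edge found)",
              "adipoquant_cavity_not_found")
  res
}
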