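## Shared fixtures and independent oracles for the test suite.

## A small, fast phantom used where full-size accuracy is not the point.
small_phantom_params <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(image_size = c(96L, 96L), body_axes_px = c(28, 36),
         sat_thickness_px = 7, wall_thickness_px = 4,
         n_visceral_blobs = 4L, blob_radius_px_range = c(3, 5),
         seed = seed),
    list(...))
  do.call(phantom_params, args)
}

## Axis-aligned square contour through pixel corners (r0,c0)-(r1,c1).
square_contour <- function(r0, c0, r1, c1) {
  ct_contour(rbind(c(r0, c0), c(r0, c1), c(r1, c1), c(r1, c0)))
}

## Brute-force boundary pixel set: foreground pixels with at least one
## background 8-neighbor (outside the image counts as background).
brute_boundary_set <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, 0L, 2L)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (mask[r, c] == 0) next
    bdry <- FALSE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || mask[rr, cc] == 0)
        bdry <- TRUE
    }
    if (bdry) out <- rbind(out, c(r, c))
  }
  out
}

## Random single-component hole-free mask (thresholded noise). Such masks
## typically contain pixels whose only background contact is diagonal;
## the Moore walk canonically bypasses those, so these masks are used for
## subset/closure properties and the EBImage cross-check, not for the
## exact brute-force set equality.
random_blob_mask <- function(seed, size = 12L, p = 0.55) {
  set.seed(seed)
  repeat {
    m <- matrix(as.integer(runif(size * size) < p), size, size)
    lab <- adipoquant:::label_components(m, 8L)
    if (max(lab) == 0L) next
    sizes <- tabulate(lab[lab > 0])
    m <- adipoquant:::fill_holes((lab == which.max(sizes)) * 1L)
    return(m)
  }
}

## TRUE when some foreground pixel touches background only diagonally.
has_diag_only_contact <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  for (r in 2:(nr + 1)) for (c in 2:(nc + 1)) {
    if (pad[r, c] == 0) next
    n4 <- c(pad[r - 1, c], pad[r + 1, c], pad[r, c - 1], pad[r, c + 1])
    n8 <- c(n4, pad[r - 1, c - 1], pad[r - 1, c + 1],
            pad[r + 1, c - 1], pad[r + 1, c + 1])
    if (any(n8 == 0) && all(n4 == 1)) return(TRUE)
  }
  FALSE
}

## Random single-component mask built from overlapping discs/rectangles,
## resampled until every boundary pixel has a 4-adjacent background
## neighbor — the precondition under which the Moore walk covers the
## 8-neighbor boundary set exactly.
random_shape_mask <- function(seed, size = 16L) {
  set.seed(seed)
  repeat {
    m <- matrix(0L, size, size)
    n_shapes <- sample(1:3, 1)
    ctr0 <- c(sample(5:(size - 4), 1), sample(5:(size - 4), 1))
    for (k in seq_len(n_shapes)) {
      ctr <- if (k == 1) ctr0
             else pmin(pmax(ctr0 + sample(-4:4, 2, TRUE), 3), size - 2)
      if (runif(1) < 0.5) {
        rad <- runif(1, 2, 4.5)
        rr <- matrix(seq_len(size), size, size); cc <- t(rr)
        m <- m | ((rr - ctr[1])^2 + (cc - ctr[2])^2 <= rad^2)
      } else {
        h <- sample(2:5, 2, TRUE)
        m[max(1, ctr[1] - h[1]):min(size, ctr[1] + h[1]),
          max(1, ctr[2] - h[2]):min(size, ctr[2] + h[2])] <- 1L
      }
    }
    m <- adipoquant:::as_mask(m)
    lab <- adipoquant:::label_components(m, 8L)
    if (max(lab) < 1L) next
    m <- adipoquant:::fill_holes((lab == which.max(tabulate(lab[lab > 0]))) * 1L)
    if (!has_diag_only_contact(m)) return(m)
  }
}

## Independent scalar re-implementation of one sequential greedy pass,
## also asserting that each chosen position is the window minimum.
oracle_snake_pass <- function(pts, energy, alpha, beta, gamma, delta,
                              clamp = NULL) {
  n <- nrow(pts)
  nr <- nrow(energy); nc <- ncol(energy)
  seg_len <- function(a, b) sqrt(sum((a - b)^2))
  dbar <- mean(vapply(seq_len(n), function(i)
    seg_len(pts[i, ], pts[if (i == n) 1 else i + 1, ]), numeric(1)))
  centroid <- colMeans(pts)
  pts0 <- pts                # neighbors from the pass-start snapshot
  n_moved <- 0L
  for (i in seq_len(n)) {
    vc <- pts0[i, ]
    vp <- pts0[if (i == 1) n else i - 1, ]
    vn <- pts0[if (i == n) 1 else i + 1, ]
    cand <- list(); econt <- ecurv <- epres <- eimg <- numeric(0)
    tang <- vn - vp
    nrm <- c(tang[2], -tang[1])
    if (sum(nrm^2) == 0) nrm <- vc - centroid
    if (sum((vc - centroid) * nrm) < 0) nrm <- -nrm
    len <- sqrt(sum(nrm^2)); if (len > 0) nrm <- nrm / len else nrm <- c(0, 0)
    for (dr in -1:1) for (dc in -1:1) {
      v <- vc + c(dr, dc)
      pxv <- round(v)   # raster consulted at the nearest pixel
      if (pxv[1] < 1 || pxv[1] > nr || pxv[2] < 1 || pxv[2] > nc) next
      if (!is.null(clamp) && clamp[pxv[1], pxv[2]] == 0) next
      cand[[length(cand) + 1]] <- v
      econt <- c(econt, (dbar - seg_len(v, vp))^2)
      ecurv <- c(ecurv, sum((vp - 2 * v + vn)^2))
      epres <- c(epres, sum((v - vc) * nrm))
      eimg <- c(eimg, energy[pxv[1], pxv[2]])
    }
    mm <- function(x) {
      rng <- max(x) - min(x)
      if (rng <= 0) rep(0, length(x)) else (x - min(x)) / rng
    }
    E <- alpha * mm(econt) + beta * mm(ecurv) + gamma * eimg + delta * mm(epres)
    cur <- which(vapply(cand, function(v) all(v == vc), logical(1)))
    emin <- min(E)
    if (length(cur) == 1 && E[cur] <= emin + 1e-12) {
      chosen <- cur
    } else {
      tie <- which(E == emin)
      rows <- vapply(cand[tie], `[`, numeric(1), 1)
      cols <- vapply(cand[tie], `[`, numeric(1), 2)
      chosen <- tie[order(rows, cols)[1]]
      pts[i, ] <- cand[[chosen]]
      n_moved <- n_moved + 1L
    }
    ## greedy optimality: the occupied position attains the window minimum
    stopifnot(E[chosen] <= emin + 1e-12)
  }
  list(points = pts, n_moved = n_moved)
}

## Random simple closed contour of integer points inside a square image.
random_test_contour <- function(seed, size = 32L) {
  set.seed(seed)
  m <- sample(8:14, 1)
  th <- sort(runif(m, 0, 2 * pi))
  rad <- runif(m, 4, (size / 2) - 3)
  ctr <- size / 2 + runif(2, -2, 2)
  pts <- round(cbind(ctr[1] + rad * sin(th), ctr[2] + rad * cos(th)))
  pts <- pmin(pmax(pts, 2), size - 1)
  ct_contour(pts, validate = FALSE)
}
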