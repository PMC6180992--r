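## Low-level raster helpers shared by the segmentation modules.
## Masks are plain 0/1 integer matrices.

as_mask <- function(m) {
  m <- (as.matrix(m) != 0) * 1L
  storage.mode(m) <- "integer"
  m
}

## Connected-component labeling. EBImage::bwlabel is 4-connected; for the
## 8-connected case its labels are merged across diagonal adjacencies with
## a small union-find over label ids.
label_components <- function(mask, connectivity = 8L) {
  mask <- as_mask(mask)
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow(mask))
  nlab <- max(lab)
  if (connectivity == 4L || nlab <= 1L) return(lab)

  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  ## diagonal neighbor pairs: down-right and down-left shifts
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

largest_component <- function(mask, connectivity = 8L) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(as_mask(mask * 0L))
  sizes <- tabulate(lab[lab > 0])
  as_mask(lab == which.max(sizes))
}

## Fill interior holes: background regions (4-connected) not touching the
## image border become foreground.
fill_holes <- function(mask) {
  mask <- as_mask(mask)
  bg <- 1L - mask
  lab <- label_components(bg, 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  hole <- bg == 1L & !(lab %in% border)
  mask[hole] <- 1L
  mask
}

mask_open <- function(mask, radius_px) {
  if (radius_px <= 0) return(as_mask(mask))
  brush <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
  as_mask(EBImage::opening(as_mask(mask), brush))
}

mask_dilate <- function(mask, radius_px) {
  if (radius_px <= 0) return(as_mask(mask))
  brush <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
  as_mask(EBImage::dilate(as_mask(mask), brush))
}

## Erosion by one pixel in the Chebyshev (8-neighbor) sense.
mask_erode1 <- function(mask) {
  brush <- matrix(1L, 3L, 3L)
  as_mask(EBImage::erode(as_mask(mask), brush))
}

## Separable Gaussian smoothing with edge replication; safe on images
## smaller than the kernel (unlike EBImage::gblur).
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- exp(-(seq(-k, k))^2 / (2 * sigma^2))
  w <- w / sum(w)
  conv1 <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    out <- m * 0
    for (j in seq(-k, k)) {
      idx <- pmin(pmax(seq_len(n) + j, 1L), n)
      shifted <- if (along_rows) m[idx, , drop = FALSE]
                 else m[, idx, drop = FALSE]
      out <- out + w[j + k + 1L] * shifted
    }
    out
  }
  conv1(conv1(x, TRUE), FALSE)
}

## Central-difference gradient magnitude (replicated edges).
gradient_magnitude <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  up <- x[pmax(seq_len(nr) - 1L, 1L), , drop = FALSE]
  dn <- x[pmin(seq_len(nr) + 1L, nr), , drop = FALSE]
  lf <- x[, pmax(seq_len(nc) - 1L, 1L), drop = FALSE]
  rt <- x[, pmin(seq_len(nc) + 1L, nc), drop = FALSE]
  sqrt(((dn - up) / 2)^2 + ((rt - lf) / 2)^2)
}
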