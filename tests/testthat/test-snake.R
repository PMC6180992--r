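test_that("image energy is 1 on constant images and lowest on edges", {
  expect_true(all(compute_image_energy(ct_slice(matrix(0, 16, 16))) == 1))

  ## vertical step edge: minimal energy in the step columns
  hu <- matrix(-150, 32, 32); hu[, 17:32] <- 100
  e <- compute_image_energy(ct_slice(hu), snake_params(smooth_sigma_px = 1))
  col_means <- colMeans(e[8:24, ])
  expect_true(which.min(col_means) %in% 16:17)

  ## phantom: the cavity wall edge is darker than organ interior
  ph <- generate_phantom(phantom_params(seed = 3))
  e <- compute_image_energy(ct_slice(ph$ct$hu, ph$ct$spacing_mm))
  wall_edge <- adipoquant:::as_mask(
    ph$truth$cavity_mask &
      !adipoquant:::mask_erode1(ph$truth$cavity_mask)) == 1L
  organ_interior <- (ph$truth$cavity_mask == 1L) &
    (adipoquant:::mask_dilate(ph$truth$tat_mask, 3) == 0L) &
    (adipoquant:::mask_dilate(wall_edge * 1L, 4) == 0L)
  expect_lt(mean(e[wall_edge]), mean(e[organ_interior]))
})

test_that("a 1x1 neighborhood leaves the contour unchanged", {
  ct <- random_test_contour(1)
  e <- matrix(runif(32 * 32), 32, 32)
  res <- snake_pass(ct, e, snake_params(neighborhood_px = 1L))
  expect_equal(res$n_moved, 0L)
  expect_equal(res$contour$points, ct$points)
})

test_that("with only image energy each update is a window argmin of e_img", {
  ## the scalar oracle asserts window-optimality after every single update
  ## and must agree with the implementation point for point
  for (rep in 1:20) {
    ct <- random_test_contour(rep + 100)
    e <- matrix(runif(32 * 32), 32, 32)
    p <- snake_params(alpha = 0, beta = 0, gamma = 1, delta = 0)
    res <- snake_pass(ct, e, p)
    ora <- oracle_snake_pass(ct$points, e, 0, 0, 1, 0)
    expect_equal(unname(res$contour$points), unname(ora$points))
    expect_equal(res$n_moved, ora$n_moved)
  }
})

test_that("one pass pulls an offset contour toward a high-contrast square edge", {
  hu <- matrix(-150, 32, 32)
  hu[10:23, 10:23] <- 100                       # bright square, edge at 10/23
  ct <- ct_slice(hu)
  p <- snake_params(smooth_sigma_px = 1)
  e <- compute_image_energy(ct, p)
  init <- resample_contour(square_contour(8, 8, 25, 25), 3)
  res <- snake_pass(init, e, p)
  before <- e[init$points]
  after <- e[res$contour$points]
  expect_gte(sum(after < before), nrow(init$points) / 2)
})

test_that("run_snake terminates and respects max_iter = 0", {
  ## no edges: continuity + curvature keep a circle in place (the circle
  ## radius must be large relative to the resampling spacing, else the
  ## discrete curvature minimum sits a pixel inside the arc)
  th <- seq(0, 2 * pi, length.out = 61)[-61]
  circ <- ct_contour(cbind(48 + 30 * sin(th), 48 + 30 * cos(th)))
  e1 <- matrix(1, 96, 96)
  out <- run_snake(circ, e1, snake_params(delta = 0))
  ## curve-to-curve Hausdorff via dense arc-length sampling of both
  ## closed polylines
  a <- resample_contour(out, 0.5)$points
  b <- resample_contour(circ, 0.5)$points
  d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  haus <- max(max(apply(d, 1, min)), max(apply(d, 2, min)))
  expect_lte(haus, 2)

  init <- square_contour(4, 4, 88, 88)
  out0 <- run_snake(init, e1, snake_params(max_iter = 0L))
  expect_equal(out0$points,
               resample_contour(resample_contour(init, 5), 5)$points)
})

test_that("the snake locks onto a known square edge", {
  hu <- matrix(-150, 32, 32)
  hu[9:24, 9:24] <- 100
  ct <- ct_slice(hu)
  ## point spacing ~ feature size / 5: a 16 px square needs a finer
  ## resampling than an abdominal contour for its corners to be tracked
  p <- snake_params(smooth_sigma_px = 1, resample_spacing_px = 3)
  e <- compute_image_energy(ct, p)
  init <- square_contour(6, 6, 27, 27)          # 3 px outside the edge
  fin <- run_snake(init, e, p)
  ## distance of each final point to the square boundary (edge pixels 9/24)
  dist_to_edge <- apply(fin$points, 1, function(v) {
    dr <- min(abs(v[1] - 9), abs(v[1] - 24))
    dc <- min(abs(v[2] - 9), abs(v[2] - 24))
    inside_r <- v[1] >= 9 && v[1] <= 24
    inside_c <- v[2] >= 9 && v[2] <= 24
    if (inside_r && inside_c) min(dr, dc) else max(dr * !inside_r, dc * !inside_c)
  })
  expect_gte(mean(dist_to_edge <= 1), 0.95)
})

test_that("snake runs are deterministic", {
  ph <- generate_phantom(small_phantom_params(seed = 10))
  mask <- compute_body_mask(ph$ct)
  b1 <- find_body_contour(ph$ct, mask)
  b2 <- find_body_contour(ph$ct, mask)
  expect_identical(b1$points, b2$points)
  c1 <- find_cavity_contour(ph$ct, b1, mask)
  c2 <- find_cavity_contour(ph$ct, b2, mask)
  expect_identical(c1$points, c2$points)
})

test_that("body contour recovers the phantom body area", {
  p0 <- phantom_params(
    seed = 12, noise_sd_hu = 0,
    hu_sds = c(air = 0, fat = 0, muscle = 0, organ = 0, skin = 0, table = 0))
  ph <- generate_phantom(p0)
  mask <- compute_body_mask(ph$ct)
  body <- find_body_contour(ph$ct, mask)
  expect_lt(abs(contour_area(body) - sum(ph$truth$body_mask)) /
              sum(ph$truth$body_mask), 0.01)
  expect_error(find_body_contour(ph$ct, matrix(0L, 192, 192)),
               class = "adipoquant_empty_mask")
})

test_that("cavity contour finds the abdominal wall and stays nested", {
  for (seed in 1:5) {
    ph <- generate_phantom(phantom_params(seed = seed))
    mask <- compute_body_mask(ph$ct)
    body <- find_body_contour(ph$ct, mask)
    cav <- find_cavity_contour(ph$ct, body, mask)
    expect_lt(abs(contour_area(cav) - sum(ph$truth$cavity_mask)) /
                sum(ph$truth$cavity_mask), 0.05)
    ## nesting: every cavity pixel lies inside the body region
    reg <- partition_regions(dim(ph$ct$hu), body, cav)
    expect_true(all(reg$vat_region <= reg$tat_region))
  }
})

test_that("a phantom without a SAT ring still yields a nested, conserving result", {
  ## With no subcutaneous ring the skin-suppression band also hides the
  ## abdominal wall margin (which then coincides with the body surface), so
  ## the contraction can only stall on visceral-fat edges further in; the
  ## contour stays nested and the pixel partition stays exact.
  p <- phantom_params(seed = 21, sat_thickness_px = 0)
  ph <- generate_phantom(p)
  mask <- compute_body_mask(ph$ct)
  body <- find_body_contour(ph$ct, mask)
  cav <- find_cavity_contour(ph$ct, body, mask)
  expect_gt(contour_area(cav), 25)
  m <- measure_slice(ph$ct, body, cav)
  expect_identical(m$tat_px, m$vat_px + m$sat_px)
  ## the full fat content is recovered: no subcutaneous ring was drawn, so
  ## total fat equals the visceral truth
  expect_lt(abs(m$tat_cm2 - ph$truth$vat_area_cm2) / ph$truth$vat_area_cm2,
            0.05)
})

test_that("a featureless slice collapses the cavity snake", {
  hu <- matrix(40, 96, 96)
  rr <- matrix(seq_len(96), 96, 96)
  cc <- t(rr)
  body_mask <- adipoquant:::as_mask((rr - 48)^2 + (cc - 48)^2 <= 40^2)
  hu[body_mask == 0L] <- -1000
  ct <- ct_slice(hu)
  mask <- compute_body_mask(ct)
  body <- find_body_contour(ct, mask)
  expect_error(
    find_cavity_contour(ct, body, mask,
                        params = snake_params(delta = 0.3), skin_band_px = 6L),
    class = "adipoquant_cavity_not_found")
})

test_that("contour resampling spaces points evenly and is count-idempotent", {
  sq <- square_contour(1, 1, 26, 26)            # perimeter 100 px
  r <- resample_contour(sq, 5)
  expect_equal(nrow(r$points), 20L)
  expect_equal(nrow(resample_contour(r, 5)$points), 20L)
  expect_error(resample_contour(ct_contour(rbind(c(1, 1), c(2, 2)),
                                           validate = FALSE), 5),
               class = "adipoquant_invalid_contour")
})
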