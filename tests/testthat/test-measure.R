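test_that("segmentation centers on a rendered disc and rejects uniform tiles", {
  tile <- render_tile(circle_traits(d = 6), seed = 3, noise = FALSE)
  mask <- segment_lesion(tile)
  side <- dim(tile$pixels)[1]
  ctr <- mask_centroid <- colMeans(which(unclass(mask), arr.ind = TRUE))
  expect_lt(max(abs(ctr - (side + 1) / 2)), 1)
  expect_false(attr(mask, "touches_border"))

  uni <- tile_image(array(0.7, c(64, 64, 3)), 15 / 64)
  expect_null(segment_lesion(uni))
  m <- measure_tile(uni)
  expect_true(attr(m, "no_lesion"))
  expect_true(all(is.na(unlist(m))))
})

test_that("segmented blob area matches the analytic generator area within 5%", {
  set.seed(20)
  for (i in 1:5) {
    tr <- circle_traits(d = runif(1, 5, 9), irr = runif(1, 0, 0.6),
                        asym = runif(1, 0, 0.7))
    tile <- render_tile(tr, seed = 200 + i, noise = FALSE)
    mask <- segment_lesion(tile)
    seg_area <- sum(mask) * tile$mm_per_px^2
    expect_lt(abs(seg_area - oracle_blob_area_mm2(tile)) /
                oracle_blob_area_mm2(tile), 0.05)
  }
})

test_that("disc shape measures hit their closed forms", {
  sh <- shape_measures(disc_mask(20), mm_per_px = 0.1)
  expect_equal(sh$area_mm2, pi * 2^2, tolerance = 0.05)
  expect_equal(sh$border_jaggedness, 1, tolerance = 0.03)
  expect_lte(sh$shape_asymmetry, 0.02)
  expect_equal(sh$minor_axis_mm, 4, tolerance = 0.03)
})

test_that("rectangle minor axis and asymmetry angle match closed forms", {
  m <- matrix(FALSE, 96, 96)
  m[30:49, 20:59] <- TRUE  # 20 rows x 40 cols
  sh <- shape_measures(structure(m, class = "lesion_mask"), mm_per_px = 0.1)
  expect_equal(sh$minor_axis_mm, 2, tolerance = 0.03)
  expect_true(min(abs(sh$asymmetry_angle_deg - c(0, 90, 180))) <= 1)
  expect_error(shape_measures(structure(matrix(FALSE, 8, 8),
                                        class = "lesion_mask"),
                              mm_per_px = 0.1), "empty")
})

test_that("random blob measures equal independent pixel/contour oracles", {
  set.seed(30)
  for (i in 1:4) {
    tr <- circle_traits(d = runif(1, 5, 8), irr = runif(1, 0.2, 0.7),
                        asym = runif(1, 0, 0.8))
    tile <- render_tile(tr, seed = 300 + i, noise = FALSE)
    mask <- segment_lesion(tile)
    m <- unclass(mask) > 0
    sh <- shape_measures(mask)
    mm <- tile$mm_per_px
    # area: plain pixel counting
    expect_equal(sh$area_mm2, sum(m) * mm^2, tolerance = 1e-12)
    # perimeter: independent Moore-neighbour boundary tracer
    expect_equal(sh$perimeter_mm, oracle_perimeter_px(m) * mm,
                 tolerance = 0.02)
    # minor axis: brute-force projection widths on the 1-degree grid
    pts <- which(m, arr.ind = TRUE)
    w <- sapply(0:179, function(a) {
      th <- a * pi / 180
      pr <- pts[, 2] * cos(th) + pts[, 1] * sin(th)
      max(pr) - min(pr) + 1
    })
    expect_equal(sh$minor_axis_mm, min(w) * mm, tolerance = 1e-12)
    # asymmetry: explicit reflected-mask XOR count at the reported angle
    cy <- mean(pts[, 1]); cx <- mean(pts[, 2])
    th <- sh$asymmetry_angle_deg * pi / 180
    c2 <- cos(2 * th); s2 <- sin(2 * th)
    rx <- round(cx + c2 * (pts[, 2] - cx) + s2 * (pts[, 1] - cy))
    ry <- round(cy + s2 * (pts[, 2] - cx) - c2 * (pts[, 1] - cy))
    ok <- rx >= 1 & rx <= ncol(m) & ry >= 1 & ry <= nrow(m)
    ov <- sum(m[cbind(ry[ok], rx[ok])])
    expect_equal(sh$shape_asymmetry, 1 - ov / nrow(pts), tolerance = 1e-12)
  }
})

test_that("scale equivariance: area ~ s^2, lengths ~ s, ratios invariant", {
  mask <- segment_lesion(render_tile(circle_traits(d = 6, irr = 0.5),
                                     seed = 4, noise = FALSE))
  a <- shape_measures(mask, mm_per_px = 0.1)
  b <- shape_measures(mask, mm_per_px = 0.2)
  expect_equal(b$area_mm2, 4 * a$area_mm2)
  expect_equal(b$perimeter_mm, 2 * a$perimeter_mm)
  expect_equal(b$minor_axis_mm, 2 * a$minor_axis_mm)
  expect_equal(b$border_jaggedness, a$border_jaggedness)
  expect_equal(b$shape_asymmetry, a$shape_asymmetry)
})

test_that("measurements are invariant to 90-degree tile rotation", {
  tr <- circle_traits(d = 6, irr = 0.5, asym = 0.6)
  tile <- render_tile(tr, seed = 8, noise = FALSE)
  rot <- tile
  for (ch in 1:3) rot$pixels[, , ch] <- t(tile$pixels[dim(tile$pixels)[1]:1, , ch])
  m1 <- measure_tile(tile)
  m2 <- measure_tile(rot)
  for (f in c("area_mm2", "perimeter_mm", "minor_axis_mm",
              "border_jaggedness", "shape_asymmetry",
              "lightness_contrast", "overall_color_contrast")) {
    expect_equal(m2[[f]], m1[[f]], tolerance = 0.02)
  }
  expect_true(min(abs(m2$asymmetry_angle_deg - m1$asymmetry_angle_deg +
                        c(-90, 0, 90, 180))) <= 2)
})

test_that("color measures match the textbook CIELAB oracle on two-tone tiles", {
  les <- c(0.45, 0.30, 0.22)
  bg <- c(0.85, 0.70, 0.60)
  side <- 64
  px <- array(rep(bg, each = side * side), c(side, side, 3))
  m <- unclass(disc_mask(15, side))
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[m] <- les[ch]
    px[, , ch] <- plane
  }
  tile <- tile_image(px, 15 / side)
  mask <- structure(m, class = "lesion_mask", mm_per_px = 15 / side)
  co <- color_measures(tile, mask, axis_angle_deg = 0)
  ol <- oracle_srgb_to_lab(rbind(les, bg))
  expect_equal(co$lightness_contrast, ol[1, 1] - ol[2, 1], tolerance = 0.5)
  expect_equal(co$redgreen_contrast, ol[1, 2] - ol[2, 2], tolerance = 0.5)
  expect_equal(co$blueyellow_contrast, ol[1, 3] - ol[2, 3], tolerance = 0.5)
  expect_equal(co$overall_color_contrast,
               sqrt(sum((ol[1, ] - ol[2, ])^2)), tolerance = 0.5)
  # uniform two-tone regions: no internal variance, no color asymmetry
  expect_lt(co$color_variance_inside, 1e-6)
  expect_lt(co$color_asymmetry, 1e-6)
  expect_lt(co$background_lightness_variance, 1e-6)
})

test_that("identical lesion and background colors give zero contrasts", {
  side <- 64
  px <- array(0.6, c(side, side, 3))
  tile <- tile_image(px, 15 / side)
  mask <- structure(unclass(disc_mask(12, side)), class = "lesion_mask",
                    mm_per_px = 15 / side)
  co <- color_measures(tile, mask, axis_angle_deg = 0)
  expect_equal(co$lightness_contrast, 0, tolerance = 1e-9)
  expect_equal(co$overall_color_contrast, 0, tolerance = 1e-9)
})

test_that("achromatic regions report hue as absent, not zero", {
  side <- 64
  px <- array(0.3, c(side, side, 3))  # grey lesion on grey background
  px[, , 1][unclass(disc_mask(12, side))] <- 0.1
  px[, , 2][unclass(disc_mask(12, side))] <- 0.1
  px[, , 3][unclass(disc_mask(12, side))] <- 0.1
  tile <- tile_image(px, 15 / side)
  mask <- structure(unclass(disc_mask(12, side)), class = "lesion_mask",
                    mm_per_px = 15 / side)
  co <- color_measures(tile, mask, axis_angle_deg = 0)
  expect_true(is.na(co$hue_inside_deg))
  expect_true(is.na(co$hue_outside_deg))
})

test_that("measured jaggedness tracks the irregularity trait monotonically", {
  set.seed(40)
  n <- 60
  irr <- runif(n, 0, 0.9)
  jag <- vapply(seq_len(n), function(i) {
    tile <- render_tile(circle_traits(d = 6, irr = irr[i]),
                        seed = 400 + i, noise = FALSE)
    measure_tile(tile)$border_jaggedness
  }, numeric(1))
  expect_gte(cor(irr, jag, method = "spearman"), 0.9)
})
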