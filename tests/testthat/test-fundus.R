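test_that("HSI intensity plane is the channel mean", {
  px <- array(0, c(64, 64, 3))
  px[, , 1] <- 0.3; px[, , 2] <- 0.6; px[, , 3] <- 0.9
  I <- rgb_to_intensity(rgb_image(px))
  expect_equal(I$pixels[1, 1], 0.6)
  # gray input: identity
  g <- matrix(runif(64 * 64), 64)
  px2 <- array(rep(g, 3), c(64, 64, 3))
  expect_equal(rgb_to_intensity(rgb_image(px2))$pixels, g)
  # black input: zero plane
  expect_equal(rgb_to_intensity(rgb_image(array(0, c(64, 64, 3))))$pixels,
               matrix(0, 64, 64))
})

test_that("optic-disc threshold sits 0.02 below the smoothed maximum", {
  px <- array(0.4, c(100, 100, 3))
  pr <- rep(1:100, 100); pc <- rep(1:100, each = 100)
  disc_px <- matrix((pr - 40)^2 + (pc - 60)^2 <= 15^2, 100, 100)
  for (ch in 1:3) { p <- px[, , ch]; p[disc_px] <- 0.95; px[, , ch] <- p }
  d <- detect_optic_disc(rgb_image(px), sigma = 1)
  # a wide plateau survives sigma = 1 smoothing, so Imax ~ 0.95
  expect_equal(d$threshold, 0.95 - 0.02, tolerance = 1e-3)
  expect_lt(sqrt(sum((d$center_rc - c(40, 60))^2)), 3)
  expect_gt(d$odd_px, 20)
  expect_true(d$mask[round(d$center_rc[1]), round(d$center_rc[2])])
})

test_that("disc detection is invariant to a constant brightness shift", {
  px <- array(0.3, c(100, 100, 3))
  pr <- rep(1:100, 100); pc <- rep(1:100, each = 100)
  disc_px <- matrix((pr - 50)^2 + (pc - 50)^2 <= 12^2, 100, 100)
  for (ch in 1:3) { p <- px[, , ch]; p[disc_px] <- 0.8; px[, , ch] <- p }
  d1 <- detect_optic_disc(rgb_image(px), sigma = 1)
  d2 <- detect_optic_disc(rgb_image(px + 0.15), sigma = 1)
  expect_equal(d1$center_rc, d2$center_rc, tolerance = 1e-9)
  expect_equal(d1$odd_px, d2$odd_px, tolerance = 1e-9)
})

test_that("maximum-area criterion rejects smaller bright artifacts", {
  px <- array(0.3, c(120, 120, 3))
  pr <- rep(1:120, 120); pc <- rep(1:120, each = 120)
  big <- matrix((pr - 60)^2 + (pc - 40)^2 <= 14^2, 120, 120)
  small <- matrix((pr - 30)^2 + (pc - 95)^2 <= 5^2, 120, 120)
  for (ch in 1:3) {
    p <- px[, , ch]; p[big | small] <- 0.9; px[, , ch] <- p
  }
  d <- detect_optic_disc(rgb_image(px), sigma = 1)
  expect_lt(sqrt(sum((d$center_rc - c(60, 40))^2)), 4)
})

test_that("pathologically flat images raise a typed no-disc error", {
  expect_error(detect_optic_disc(rgb_image(array(0.5, c(64, 64, 3)))),
               class = "retinodiag_no_disc")
})

test_that("vessel extraction contracts hold", {
  expect_error(morph_scales(9, 3), class = "retinodiag_bad_param")
  expect_error(morph_scales(3, 9, 30, 13), class = "retinodiag_bad_param")
  # constant image -> identical closings -> empty mask
  img <- rgb_image(array(0.5, c(64, 64, 3)))
  v <- extract_vessels(img, morph_scales())
  expect_equal(sum(v$mask), 0L)
  expect_equal(nrow(v$components), 0L)
  # a single dark pixel is below any area filter
  px <- array(0.6, c(64, 64, 3)); px[30, 30, 2] <- 0.1
  v2 <- extract_vessels(rgb_image(px), morph_scales(), min_area_px = 5)
  expect_equal(sum(v2$mask), 0L)
})

test_that("exudate detection requires a disc and applies its removal", {
  img <- rgb_image(array(0.5, c(64, 64, 3)))
  expect_error(detect_exudates(img, morph_scales()),
               class = "retinodiag_bad_input")
  disc <- synthetic_disc(c(64, 64), c(32, 32), 16)
  ex <- detect_exudates(img, morph_scales(), disc)
  expect_equal(sum(ex$mask), 0L)   # constant image -> empty
  # a bright blob fully inside the disc never appears
  px <- array(0.45, c(128, 128, 3))
  pr <- rep(1:128, 128); pc <- rep(1:128, each = 128)
  blob_in <- matrix((pr - 40)^2 + (pc - 40)^2 <= 4^2, 128, 128)
  blob_out <- matrix((pr - 95)^2 + (pc - 90)^2 <= 4^2, 128, 128)
  for (ch in 1:3) {
    p <- px[, , ch]; p[blob_in | blob_out] <- 0.95; px[, , ch] <- p
  }
  disc2 <- synthetic_disc(c(128, 128), c(40, 40), 30)
  ex2 <- detect_exudates(rgb_image(px), morph_scales(3, 5, 7, 11), disc2,
                         min_area_px = 3)
  expect_false(any(ex2$mask & disc2$mask))
  expect_true(any(ex2$mask[blob_out]))
})

test_that("MAHM detection: hole-free image is empty, vessels are removed", {
  # monotone ramp has no holes: fill(G) == G
  px <- array(rep(matrix(rep(seq(0.2, 0.8, length.out = 64), each = 64), 64),
                  3), c(64, 64, 3))
  vz <- lesion_mask(matrix(FALSE, 64, 64))
  m <- detect_mahm(rgb_image(px), vz)
  expect_equal(sum(m$mask), 0L)
  # a dark blob on a vessel is removed, one off-vessel stays
  px2 <- array(0.6, c(128, 128, 3))
  px2[, , 1] <- 0.5
  vessel <- matrix(FALSE, 128, 128); vessel[60:64, ] <- TRUE
  g <- px2[, , 2]
  g[vessel] <- 0.3
  pr <- rep(1:128, 128); pc <- rep(1:128, each = 128)
  on_v <- matrix((pr - 62)^2 + (pc - 40)^2 <= 3^2, 128, 128)
  off_v <- matrix((pr - 100)^2 + (pc - 90)^2 <= 3^2, 128, 128)
  g[on_v | off_v] <- 0.02
  px2[, , 2] <- g
  m2 <- detect_mahm(rgb_image(px2), lesion_mask(vessel), min_area_px = 3)
  expect_false(any(m2$mask[on_v]))
  expect_equal(max(label_components(m2$mask)), 1L)
})

test_that("fovea geometry contracts hold on a phantom", {
  ph <- make_fundus_phantom(small_fundus_spec(seed = 5))
  pre <- fundus_preprocess(ph$image)
  disc <- detect_optic_disc(pre)
  v <- extract_vessels(pre)
  fo <- detect_fovea(pre, v, disc)
  expect_equal(fo$radius_px, disc$odd_px)   # region radius is 1 ODD
  err <- sqrt(sum((fo$center_rc - ph$truth$fovea_center_rc)^2))
  expect_lt(err, 0.5 * ph$truth$odd_px)
  # an empty vessel mask is a typed failure
  vz <- lesion_mask(matrix(FALSE, 400, 400))
  expect_error(detect_fovea(pre, vz, disc),
               class = "retinodiag_no_main_vessel")
})

test_that("the fovea search never selects candidates nearer than 2 ODD", {
  # a very dark pixel at 1 ODD from the vertex must not win
  ph <- make_fundus_phantom(small_fundus_spec(seed = 6))
  img <- ph$image
  dcc <- ph$truth$disc_center_rc; odd <- ph$truth$odd_px
  near <- round(c(dcc[1], dcc[2] - 1.0 * odd))
  px <- img$pixels
  px[near[1] + (-2:2), near[2] + (-2:2), ] <- 0
  img2 <- rgb_image(px)
  pre <- fundus_preprocess(img2)
  disc <- detect_optic_disc(pre)
  v <- extract_vessels(pre)
  fo <- detect_fovea(pre, v, disc)
  dist_near <- sqrt(sum((fo$center_rc - near)^2))
  expect_gt(dist_near, 0.5 * odd)   # did not lock onto the 1-ODD dark spot
})
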