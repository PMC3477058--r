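make_partition <- function(shape = c(200, 200), fovea = c(100, 80),
                           disc = c(100, 160), odd = 20) {
  fundus_coordinates(synthetic_disc(shape, disc, odd),
                     synthetic_fovea(fovea, odd), shape)
}

test_that("the ten-region partition is a deterministic disjoint cover", {
  p <- make_partition()
  expect_true(all(p$label_map %in% 1:10))
  expect_equal(sort(unique(as.vector(p$label_map))), 1:10)
  # fovea center pixel is region 1
  expect_equal(p$label_map[100, 80], 1L)
  # determinism
  p2 <- make_partition()
  expect_identical(p$label_map, p2$label_map)
  # radii honor the ODD geometry: just inside 1 ODD vs just outside
  expect_equal(p$label_map[100, 80 + 19], 1L)
  expect_true(p$label_map[100, 80 + 21] %in% 2:5)
  expect_true(p$label_map[100, 80 - 45] %in% 6:9)
  expect_equal(p$label_map[100, 5], 10L)
  # errors
  expect_error(fundus_coordinates(synthetic_disc(c(200, 200), c(100, 160), 20),
                                  synthetic_fovea(c(300, 80), 20),
                                  c(200, 200)),
               class = "retinodiag_bad_input")
})

mask_with_n_px <- function(shape, region_map, region, n) {
  m <- matrix(FALSE, shape[1], shape[2])
  idx <- which(region_map == region)
  m[idx[seq_len(n)]] <- TRUE
  m
}

test_that("the worked moderate example grades as moderate", {
  p <- make_partition(shape = c(300, 300), fovea = c(150, 110),
                      disc = c(150, 230), odd = 24)
  # 5196 exudate px and 3991 MAHM px, none inside the fovea region
  ex <- mask_with_n_px(c(300, 300), p$label_map, 10, 5196)
  ma <- mask_with_n_px(c(300, 300), p$label_map, 6, 2000) |
    mask_with_n_px(c(300, 300), p$label_map, 7, 1991)
  rep <- grade_severity(lesion_mask(ex), lesion_mask(ma), p)
  expect_equal(rep$exudate_area_px, 5196)
  expect_equal(rep$mahm_area_px, 3991)
  expect_equal(rep$exudate_fovea_px + rep$mahm_fovea_px, 0)
  expect_equal(rep$grade, "moderate")
})

test_that("empty masks grade none; fovea involvement grades severe", {
  p <- make_partition()
  z <- lesion_mask(matrix(FALSE, 200, 200))
  expect_equal(grade_severity(z, z, p)$grade, "none")
  fov <- mask_with_n_px(c(200, 200), p$label_map, 1, 10)
  expect_equal(grade_severity(lesion_mask(fov), z, p)$grade, "severe")
  # small peripheral-only lesion load is mild
  periph <- mask_with_n_px(c(200, 200), p$label_map, 10, 100)
  expect_equal(grade_severity(lesion_mask(periph), z, p)$grade, "mild")
  # proliferative only via the explicit flag
  expect_equal(grade_severity(lesion_mask(periph), z, p,
                              neovascularization = TRUE)$grade,
               "proliferative")
  # shape mismatch is an error
  expect_error(grade_severity(lesion_mask(matrix(FALSE, 10, 10)), z, p),
               class = "retinodiag_bad_input")
})

test_that("per-region tallies conserve totals exactly", {
  set.seed(41)
  p <- make_partition()
  for (i in 1:5) {
    ex <- matrix(runif(200 * 200) < 0.05, 200)
    ma <- matrix(runif(200 * 200) < 0.03, 200)
    rep <- grade_severity(lesion_mask(ex), lesion_mask(ma), p)
    expect_identical(sum(rep$per_region_areas[, 1]), rep$exudate_area_px)
    expect_identical(sum(rep$per_region_areas[, 2]), rep$mahm_area_px)
    expect_identical(rep$per_region_areas[1, 1], rep$exudate_fovea_px)
  }
})

test_that("the grade is monotone nondecreasing in every area argument", {
  # exhaustive check of the rule table over a grid of configurations
  rule <- retinodiag:::grade_from_areas
  thresholds <- grading_thresholds()
  lvl <- function(g) match(g, c("none", "mild", "moderate", "severe",
                                "proliferative"))
  totals <- c(0, 1, 100, 499, 500, 501, 9999, 10000, 10001, 50000)
  fovs <- c(0, 1, 50)
  cases <- expand.grid(total = totals, fov = fovs, r10 = c(TRUE, FALSE))
  cases <- cases[cases$fov <= cases$total, ]
  cases$grade <- mapply(function(t, f, r)
    rule(t, f, r && f == 0, thresholds), cases$total, cases$fov, cases$r10)
  for (i in seq_len(nrow(cases))) for (j in seq_len(nrow(cases))) {
    # j dominates i componentwise with the same/shrinking r10 confinement
    if (cases$total[j] >= cases$total[i] && cases$fov[j] >= cases$fov[i] &&
        (!cases$r10[j] || cases$r10[i])) {
      expect_gte(lvl(cases$grade[j]), lvl(cases$grade[i]))
    }
  }
  # and through the full interface: adding fovea pixels never lowers a grade
  p <- make_partition()
  z <- lesion_mask(matrix(FALSE, 200, 200))
  base <- mask_with_n_px(c(200, 200), p$label_map, 4, 600)
  g1 <- grade_severity(lesion_mask(base), z, p)$grade
  more <- base | mask_with_n_px(c(200, 200), p$label_map, 1, 5)
  g2 <- grade_severity(lesion_mask(more), z, p)$grade
  expect_gte(lvl(g2), lvl(g1))
})
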