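test_that("widefield projection uses only the trailing planes", {
  set.seed(31)
  v <- array(rnorm(10 * 8 * 8), c(10, 8, 8))
  v[9, , ] <- 100  # dominates everywhere
  expect_true(all(widefield_projection(v, 5) == 100))
  expect_equal(widefield_projection(v, 10), max_project(v))
  # brute-force oracle over planes 21..25
  v2 <- array(rnorm(25 * 6 * 6), c(25, 6, 6))
  oracle <- matrix(0, 6, 6)
  for (y in 1:6) for (x in 1:6) oracle[y, x] <- max(v2[21:25, y, x])
  expect_equal(widefield_projection(v2, 5), oracle)
  expect_error(widefield_projection(v, 11), "n_last")
  expect_error(widefield_projection(v, 0), "n_last")
})

test_that("disk background subtraction removes flat fields and keeps peaks", {
  expect_true(all(subtract_background(matrix(7, 40, 40), 5) == 0))
  img <- matrix(0, 64, 64); img[32, 32] <- 100
  out <- subtract_background(img, 15)
  # isolated pixel on zero background: peak nearly unchanged (disk mean tiny)
  expect_gt(out[32, 32], 95)
  # linear ramp with a small radius: near-zero residual away from edges
  ramp <- matrix(rep(seq(0, 10, length.out = 64), each = 64), 64, 64)
  res <- subtract_background(ramp, 3)
  expect_lt(max(res[10:54, 10:54]), 0.2)
  expect_error(subtract_background(img, 0.5), "disk_radius")
})

test_that("seeded watershed grows cells around their nuclei and splits at ridges", {
  # two touching bright discs with a dim ridge between them
  n <- 64
  img <- matrix(0, n, n)
  d1 <- outer(1:n, 1:n, function(y, x) (y - 32)^2 + (x - 22)^2 <= 144)
  d2 <- outer(1:n, 1:n, function(y, x) (y - 32)^2 + (x - 44)^2 <= 144)
  img[d1] <- img[d1] + 10
  img[d2] <- img[d2] + 10
  img[d1 & d2] <- 6  # intensity valley along the contact
  seeds <- matrix(0L, n, n); seeds[32, 22] <- 1L; seeds[32, 44] <- 2L
  cm <- segment_cells(img, seeds, mask_threshold = 2)
  expect_s3_class(cm, "cell_map2d")
  expect_setequal(unique(cm$labels[cm$labels > 0]), 1:2)
  expect_equal(cm$labels[32, 22], 1L)
  expect_equal(cm$labels[32, 44], 2L)
  # both survive with substantial area
  expect_gt(sum(cm$labels == 1), 100)
  expect_gt(sum(cm$labels == 2), 100)
  # single seed, uniform contrast: one bounded basin covering the mask
  uni <- matrix(5, 32, 32)
  seeds1 <- matrix(0L, 32, 32); seeds1[16, 16] <- 1L
  cm1 <- segment_cells(uni, seeds1, mask_threshold = 1)
  expect_setequal(unique(as.integer(cm1$labels)), 1L)
  expect_warning(cm0 <- segment_cells(uni, matrix(0L, 32, 32)), "no nuclei")
  expect_equal(max(cm0$labels), 0L)
})

test_that("cell filtering removes border/size outliers and keeps labels in lockstep", {
  fld <- generate_field(small_scene(seed = 6, n_cells = 8, n_border_cells = 2))
  cfg <- small_config()
  proj <- max_project(fld$stack$channels$DAPI)
  lab2d <- detect_nuclei(proj, min_area = 15, max_area = 800)
  nm <- segment_nuclei_3d(fld$stack$channels$DAPI, lab2d)
  wf <- widefield_projection(fld$stack$channels$WIDEFIELD)
  cm <- segment_cells(subtract_background(wf, 15), lab2d)
  filt <- filter_cells(cm, area_bounds = c(150, 4000), border_margin = 20,
                       nuclei = nm)
  # exactly the 8 interior cells survive; the 2 planted border cells are gone
  survivors <- sort(unique(filt$labels[filt$labels > 0]))
  expect_equal(survivors, seq_len(8))
  expect_equal(max(filt$labels[c(1:20, 237:256), ]), 0L)
  expect_equal(max(filt$labels[, c(1:20, 237:256)]), 0L)
  # cell <-> nucleus bijection on survivors
  nuc <- attr(filt, "nuclei")
  nuc_labels <- sort(unique(nuc$labels[nuc$labels > 0]))
  expect_equal(nuc_labels, survivors)
  for (k in survivors) {
    idx <- which(nuc$labels == k, arr.ind = TRUE)
    expect_true(all(filt$labels[idx[, 2:3, drop = FALSE]] == k))
  }
  # idempotence
  again <- filter_cells(filt, area_bounds = c(150, 4000), border_margin = 20)
  expect_identical(again$labels, filt$labels)
})

test_that("segmentation is invariant to a constant widefield offset", {
  fld <- generate_field(small_scene(seed = 13, n_cells = 6))
  lab2d <- detect_nuclei(max_project(fld$stack$channels$DAPI),
                         min_area = 15, max_area = 800)
  wf <- widefield_projection(fld$stack$channels$WIDEFIELD)
  c1 <- segment_cells(subtract_background(wf, 15), lab2d)
  c2 <- segment_cells(subtract_background(wf + 500, 15), lab2d)
  expect_identical(c1$labels, c2$labels)
})

test_that("region moments give area, centroid and ellipse axes", {
  # 10x10 filled square at rows 11..20, cols 31..40 (0-based centroid 15, 35)
  lab <- matrix(0L, 64, 64)
  lab[12:21, 32:41] <- 1L
  cm <- structure(list(labels = lab, border_margin = NA,
                       area_bounds = c(NA, NA)), class = "cell_map2d")
  rec <- measure_cells(cm)
  expect_equal(rec$area, 100)
  expect_equal(rec$centroid_y, 15.5)
  expect_equal(rec$centroid_x, 35.5)
  expect_equal(rec$major_axis, rec$minor_axis)
  # analytic: variance of 10 unit pixels = (10^2-1)/12 + 1/12 = 100/12
  expect_equal(rec$major_axis, 4 * sqrt(100 / 12))
  # filled disk: major ~ minor within 2%
  lab2 <- matrix(0L, 64, 64)
  lab2[outer(1:64, 1:64, function(y, x) (y - 30)^2 + (x - 30)^2 <= 15^2)] <- 1L
  rec2 <- measure_cells(structure(list(labels = lab2), class = "cell_map2d"))
  expect_lt(rec2$major_axis / rec2$minor_axis, 1.02)
  # single pixel: area 1, centroid at the pixel, positive axes
  lab3 <- matrix(0L, 8, 8); lab3[3, 5] <- 1L
  rec3 <- measure_cells(structure(list(labels = lab3), class = "cell_map2d"))
  expect_equal(rec3$area, 1)
  expect_equal(c(rec3$centroid_x, rec3$centroid_y), c(4, 2))
  expect_gt(rec3$minor_axis, 0)
  expect_gte(rec3$major_axis, rec3$minor_axis)
})

test_that("moment axes agree with an independent implementation", {
  # random blob, cross-checked against EBImage::computeFeatures.moment
  set.seed(44)
  img <- matrix(0, 48, 48)
  img[outer(1:48, 1:48, function(y, x) ((y - 22) / 13)^2 + ((x - 26) / 7)^2 <= 1)] <- 1
  rec <- measure_cells(structure(list(labels = img), class = "cell_map2d"))
  ft <- EBImage::computeFeatures.moment(img)
  expect_equal(rec$major_axis, unname(ft[1, "m.majoraxis"]), tolerance = 0.02)
  ecc <- unname(ft[1, "m.eccentricity"])
  expect_equal(rec$minor_axis, unname(ft[1, "m.majoraxis"]) * sqrt(1 - ecc^2),
               tolerance = 0.02)
})
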