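# helpers to paint simple shapes
disk_mask <- function(n, cy, cx, r) {
  outer(seq_len(n) - 1, seq_len(n) - 1,
        function(y, x) (y - cy)^2 + (x - cx)^2 <= r^2)
}

test_that("maximum projection equals the per-pixel max over z", {
  one <- array(runif(64), c(1, 8, 8))
  expect_equal(max_project(one), matrix(one[1, , ], 8, 8))
  two <- array(0, c(2, 4, 4)); two[1, , ] <- 3; two[2, , ] <- 7
  expect_true(all(max_project(two) == 7))
  set.seed(21)
  v <- array(rnorm(5 * 8 * 8), c(5, 8, 8))
  oracle <- matrix(0, 8, 8)
  for (y in 1:8) for (x in 1:8) oracle[y, x] <- max(v[, y, x])
  expect_equal(max_project(v), oracle)
  expect_error(max_project(array(0, c(0, 2, 2))), "non-empty")
})

test_that("nucleus detection thresholds, size-filters and renumbers", {
  expect_equal(max(detect_nuclei(matrix(0, 32, 32), global_threshold = 1,
                                 min_area = 5, max_area = 100)), 0L)
  img <- matrix(0, 64, 64)
  img[disk_mask(64, 10, 10, 4)] <- 50
  img[disk_mask(64, 30, 40, 5)] <- 80
  img[disk_mask(64, 50, 15, 4)] <- 60
  lab <- detect_nuclei(img, global_threshold = 10, min_area = 10, max_area = 200)
  expect_equal(sort(unique(lab[lab > 0])), 1:3)
  # a disk below min_area disappears
  lab2 <- detect_nuclei(img, global_threshold = 10, min_area = 100, max_area = 200)
  expect_equal(max(lab2), 0L)
  # threshold above the image max: zero nuclei, not an error
  expect_equal(max(detect_nuclei(img, global_threshold = 1e6,
                                 min_area = 10, max_area = 200)), 0L)
  expect_error(detect_nuclei(img, 10, min_area = -1, max_area = 5), "negative")
  expect_error(detect_nuclei(img, 10, min_area = 50, max_area = 10), "min_area")
})

test_that("the cell-specific threshold is half the range above background", {
  expect_equal(per_nucleus_threshold(1000, 200), 600)
  expect_equal(per_nucleus_threshold(50, 50), 50)
  expect_equal(per_nucleus_threshold(7, 0), 3.5)
  expect_error(per_nucleus_threshold(10, 20), "below background")
})

test_that("3D nucleus segmentation applies per-label thresholds around each seed", {
  # two Gaussian-ish blobs with different peaks in one volume
  nz <- 9; n <- 48
  vol <- array(0, c(nz, n, n))
  blob <- function(vol, cz, cy, cx, r, amp) {
    for (z in seq_len(nz)) for (y in seq_len(n)) for (x in seq_len(n)) {
      d2 <- ((z - cz) / (r / 2))^2 + ((y - cy) / r)^2 + ((x - cx) / r)^2
      vol[z, y, x] <- vol[z, y, x] + amp * 2^(-d2)
    }
    vol
  }
  vol <- blob(vol, 5, 15, 15, 5, 1000)
  vol <- blob(vol, 5, 34, 34, 5, 300)   # much dimmer nucleus
  proj <- max_project(vol)
  lab2d <- detect_nuclei(proj, global_threshold = 120, min_area = 10, max_area = 500)
  expect_equal(max(lab2d), 2L)
  nm <- segment_nuclei_3d(vol, lab2d, background = 0)
  # each nucleus present in 3D and contains its brightest voxel
  for (k in 1:2) {
    reg <- which(nm$labels == k, arr.ind = TRUE)
    expect_gt(nrow(reg), 0)
    pk <- which(vol == max(vol[nm$labels == k]), arr.ind = TRUE)[1, ]
    expect_equal(unname(nm$labels[pk[1], pk[2], pk[3]]), k)
  }
  # per-label thresholds follow the 50%-of-range formula with their own maxima
  mx <- vapply(1:2, function(k) max(vol[nm$labels == k]), numeric(1))
  expect_equal(unname(nm$per_label_threshold),
               per_nucleus_threshold(mx, 0), tolerance = 0.1)
  expect_gt(nm$per_label_threshold[["1"]], nm$per_label_threshold[["2"]])
  # every labeled voxel is at or above its own label threshold
  for (k in 1:2)
    expect_true(all(vol[nm$labels == k] >= nm$per_label_threshold[[as.character(k)]]))
  # labels are disjoint by construction of a single integer array; footprint
  # of the 3D labels projects inside the 2D seeds
  proj_lab <- max_project(nm$labels)
  expect_true(all(lab2d[proj_lab == 1] %in% c(0, 1)))
})

test_that("a spurious 2D label on an empty volume yields a warning, not labels", {
  vol <- array(0, c(4, 16, 16))
  lab2d <- matrix(0L, 16, 16); lab2d[5:7, 5:7] <- 1L
  expect_warning(nm <- segment_nuclei_3d(vol, lab2d, background = 0),
                 "skipped")
  expect_equal(max(nm$labels), 0L)
})

test_that("segmentation is equivariant under joint intensity scaling", {
  fld <- generate_field(small_scene(seed = 9, n_cells = 6))
  dapi <- fld$stack$channels$DAPI
  proj <- max_project(dapi)
  lab <- detect_nuclei(proj, global_threshold = 160, min_area = 15, max_area = 800)
  bg <- estimate_background(proj, lab)
  a <- segment_nuclei_3d(dapi, lab, background = bg)
  b <- segment_nuclei_3d(dapi * 3.5, lab, background = bg * 3.5)
  expect_identical(a$labels, b$labels)
  expect_equal(b$per_label_threshold, a$per_label_threshold * 3.5)
})

test_that("all planted nuclei are recovered on synthetic fields", {
  for (seed in c(2, 4)) {
    fld <- generate_field(small_scene(seed = seed, n_cells = 10))
    proj <- max_project(fld$stack$channels$DAPI)
    lab <- detect_nuclei(proj, min_area = 15, max_area = 800)  # Otsu default
    expect_equal(max(lab), 10L)
    nm <- segment_nuclei_3d(fld$stack$channels$DAPI, lab)
    expect_equal(sum(!is.na(nm$per_label_threshold)), 10L)
    # labels disjoint: each voxel has one label by construction; every label
    # non-empty in 3D
    expect_setequal(unique(as.integer(nm$labels[nm$labels > 0])), 1:10)
  }
})
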