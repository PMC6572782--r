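test_that("interleaved stacks round-trip voxel-for-voxel with metadata", {
  set.seed(11)
  mk <- function(nz) {
    chans <- lapply(CHANNEL_ROLES, function(ch)
      array(sample(0:4095, nz * 16 * 16, replace = TRUE), c(nz, 16, 16)))
    names(chans) <- CHANNEL_ROLES
    image_stack(chans, z_step_nm = 200, source_id = sprintf("rt%d", nz))
  }
  for (nz in c(3L, 25L, 26L)) {
    s <- mk(nz)
    path <- withr::local_tempfile(fileext = ".tif")
    write_stack(s, path)
    pages <- tiff::readTIFF(path, all = TRUE)
    expect_length(pages, nz * 4L)
    r <- read_stack(path)
    expect_identical(r$n_z, nz)
    expect_equal(r$z_step_nm, 200)
    expect_equal(r$source_id, s$source_id)
    for (ch in CHANNEL_ROLES) expect_equal(r$channels[[ch]], s$channels[[ch]])
  }
})

test_that("page layout maps to (channel, z) and bad layouts are refused", {
  nz <- 4L
  chans <- lapply(seq_len(4), function(i) array(i * 10, c(nz, 8, 8)))
  names(chans) <- CHANNEL_ROLES
  s <- image_stack(chans)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(s, path)
  r <- read_stack(path)
  # plane i on disk -> channel i mod 4, z = i div 4: constant per channel here
  expect_true(all(r$channels$TMR == 10))
  expect_true(all(r$channels$WIDEFIELD == 40))
  # custom channel order permutes the roles
  r2 <- read_stack(path, channel_order = rev(CHANNEL_ROLES))
  expect_true(all(r2$channels$WIDEFIELD == 10))
  # 101 pages: not divisible by 4
  bad <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(rep(list(matrix(0, 4, 4)), 101L), bad)
  expect_error(read_stack(bad), "layout")
  expect_error(read_stack(file.path(tempdir(), "absent.tif")), "no such file")
})

test_that("image_stack enforces its invariants", {
  ok <- array(1, c(2, 4, 4))
  expect_error(image_stack(list(TMR = ok, DAPI = array(1, c(2, 4, 5)))),
               "share one")
  expect_error(image_stack(list(TMR = array(-1, c(2, 4, 4)))), "non-negative")
  expect_error(image_stack(list(TMR = ok), z_step_nm = -5), "positive")
  expect_error(image_stack(list(matrix(1, 4, 4))), "3D")
})

test_that("packaged probe table parses to 2 genes x 48 probes x 20 nt", {
  path <- system.file("extdata", "probes_stl1_ctt1.csv", package = "smfishq")
  sets <- read_probe_table(path)
  expect_length(sets, 2L)
  expect_setequal(vapply(sets, `[[`, "", "gene"), c("STL1", "CTT1"))
  for (ps in sets) {
    expect_length(ps$probes, 48L)
    expect_identical(ps$probe_length, 20L)
    expect_false(any(grepl("[^ACGT]", ps$probes)))
  }
  expect_equal(sets[[1]]$dye, "TMR")
  expect_equal(sets[[2]]$dye, "CY5")
})

test_that("probe parsing handles minimal input and rejects bad sequences", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("G1", "ACGT", "ACGT"), f)
  ps <- read_probe_table(f)
  expect_length(ps, 1L)
  expect_length(ps[[1]]$probes, 2L)
  expect_identical(ps[[1]]$probe_length, 4L)
  writeLines(c("G1", "ACGT", "ACXT"), f)
  expect_error(read_probe_table(f), "non-ACGT")
  writeLines(c("G1", "ACGT", "ACGTA"), f)
  expect_error(read_probe_table(f), "ragged")
})

test_that("experiment manifest parses designs and records both stack totals", {
  man <- read_manifest(system.file("extdata", "experiments.tsv",
                                   package = "smfishq"))
  expect_equal(nrow(man), 5L)
  m02 <- man[man$condition == "0.2 M NaCl step" & man$replicate == 1L, ]
  expect_length(m02$timepoints_min[[1]], 16L)
  expect_true(all(diff(m02$timepoints_min[[1]]) > 0))
  # per-row stack counts and the stated prose total are both preserved
  expect_equal(sum(man$n_stacks), 337L)
  expect_equal(attr(man, "stated_total_stacks"), 331)
  # non-increasing timepoints are refused
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("experiment\tcondition\treplicate\ttimepoints_min\tn_stacks",
               "E\tx\t1\t0,5,5\t3"), f)
  expect_error(read_manifest(f), "strictly increasing")
})

test_that("CellInfo export writes exactly the 5 morphology columns", {
  rec <- data.frame(label = c(2L, 1L), centroid_x = c(10, 3), centroid_y = c(12, 4),
                    major_axis = c(8, 2), minor_axis = c(6, 2), area = c(40, 4))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cell_info(rec, f)
  back <- read.csv(f)
  expect_identical(names(back),
                   c("centroid_x", "centroid_y", "major_axis", "minor_axis", "area"))
  expect_equal(nrow(back), 2L)
  # ordered by label: row 1 is label 1
  expect_equal(back$centroid_x[1], 3)
  expect_equal(unlist(back[2, ], use.names = FALSE), c(10, 12, 8, 6, 40))
  # empty record list -> header-only file, no error
  write_cell_info(rec[0, ], f)
  expect_equal(nrow(read.csv(f)), 0L)
  expect_error(write_cell_info(data.frame(label = 1L, area = 3), f), "export error")
})

test_that("count export enforces total = cytoplasm + nucleus row-wise", {
  cnt <- data.frame(cell = c(1L, 2L), channel = "TMR",
                    nuclear = c(3L, 0L), cytoplasmic = c(5L, 0L),
                    total = c(8L, 0L))
  f <- withr::local_tempfile(fileext = ".csv")
  write_counts(cnt, "TMR", f)
  back <- read.csv(f)
  expect_identical(names(back), c("total", "cytoplasm", "nucleus"))
  expect_equal(back$total, back$cytoplasm + back$nucleus)
  expect_equal(back[1, ], data.frame(total = 8L, cytoplasm = 5L, nucleus = 3L))
  expect_equal(unlist(back[2, ], use.names = FALSE), c(0L, 0L, 0L))
  cnt$total[1] <- 9L
  expect_error(write_counts(cnt, "TMR", f), "refused")
})

test_that("count export of a synthetic field satisfies additivity against truth", {
  fld <- generate_field(small_scene(seed = 5, n_cells = 10))
  truth <- fld$truth$counts
  f <- withr::local_tempfile(fileext = ".csv")
  for (ch in c("TMR", "CY5")) {
    write_counts(structure(truth, class = "data.frame"), ch, f)
    back <- read.csv(f)
    expect_equal(nrow(back), 10L)
    # brute-force sums over the ground-truth spot table
    sp <- fld$truth$spots[fld$truth$spots$channel == ch, ]
    expect_equal(sum(back$total), nrow(sp))
    expect_equal(sum(back$nucleus),
                 sum(sp$compartment == "nuclear"))
    expect_true(all(back$total == back$cytoplasm + back$nucleus))
  }
})
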