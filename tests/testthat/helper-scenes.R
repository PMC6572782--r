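# Shared fixtures and oracles for the suite. Scenes are generated in code at
# test time; nothing is read from disk except the packaged extdata tables.

# downscaled test scene: 12 z-planes, 256 x 256, yeast-like proportions
small_scene <- function(seed = 1L, n_cells = 12L, snr = 8,
                        spot_model = list(
                          TMR = list(type = "poisson", lambda = 6),
                          CY5 = list(type = "poisson", lambda = 4)),
                        min_separation = 6, n_border_cells = 0L,
                        field_shape = c(12, 256, 256)) {
  scene_spec(field_shape = field_shape, n_cells = n_cells,
             n_border_cells = n_border_cells,
             cell_radius_range = c(12, 16), nucleus_radius_range = c(4, 6),
             spot_model = spot_model, f_nuc = 0.2,
             snr = snr, min_separation = min_separation,
             border_margin_px = 24, seed = seed)
}

small_config <- function(...) {
  default_config(nucleus_area_bounds = c(15, 800),
                 cell_area_bounds = c(150, 4000),
                 border_margin = 20, ...)
}

# greedy one-to-one spot matching within a tolerance radius; returns the
# number of true positives
match_spots <- function(detected, truth, radius = 2) {
  used <- rep(FALSE, nrow(detected))
  tp <- 0L
  for (i in seq_len(nrow(truth))) {
    dd <- sqrt((detected$x - truth$x[i])^2 + (detected$y - truth$y[i])^2 +
                 (detected$z - truth$z[i])^2)
    j <- which(!used & dd <= radius)
    if (length(j)) {
      used[j[which.min(dd[j])]] <- TRUE
      tp <- tp + 1L
    }
  }
  tp
}

# align pipeline per-cell counts with ground truth via centroid matching
truth_aligned_counts <- function(result, truth) {
  map <- match_to_truth(result$records, truth$cells)
  cnt <- merge(result$counts, map, by.x = "cell", by.y = "label")
  merge(cnt, truth$counts,
        by.x = c("truth_label", "channel"), by.y = c("cell", "channel"),
        suffixes = c("", "_true"))
}

# brute-force oracle for the basal ON threshold: smallest T with
# cumulative fraction of counts <= T at or above coverage
oracle_basal_threshold <- function(counts, coverage = 0.95) {
  for (t in 0:max(counts)) {
    if (sum(counts <= t) / length(counts) >= coverage) return(t)
  }
  max(counts)
}
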