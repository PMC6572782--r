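# End-to-end experiment driver shared by the recovery tests: a two-replica,
# multi-timepoint osmotic-stress-style design with a two-state switching
# model whose ON probability steps up over time. Fields are 512 x 512 x 12
# with 125 cells each, so `fields_per_timepoint` fields give
# 125 * fields_per_timepoint cells per replicate and timepoint.

e2e_scene <- function(p_on, seed) {
  scene_spec(field_shape = c(12, 512, 512), n_cells = 125,
             cell_radius_range = c(11, 15), nucleus_radius_range = c(4, 6),
             spot_model = list(TMR = list(type = "two_state", p_on = p_on,
                                          lambda_off = 0.2, lambda_on = 12)),
             f_nuc = 0.2, snr = 8, min_separation = 5,
             border_margin_px = 22, seed = seed)
}

e2e_config <- function(spot_threshold_tmr = "auto") {
  default_config(nucleus_area_bounds = c(15, 400),
                 cell_area_bounds = c(150, 2000), border_margin = 20,
                 spot_threshold = list(TMR = spot_threshold_tmr))
}

# run the experiment and return per-cell pipeline and truth counts
run_e2e_experiment <- function(p_by_tp, n_replicas = 2L,
                               fields_per_timepoint = 16L, base_seed = 1L) {
  counts <- list()
  truth_tot <- list()
  for (rep_id in seq_len(n_replicas)) {
    # per-dye sample threshold: mean of per-image automated thresholds from
    # the first fields of the replica, then applied to every stack
    thr_fields <- lapply(1:3, function(f) {
      sp <- e2e_scene(p_by_tp[[1L]],
                      seed = (base_seed * 7919L + rep_id * 977L + f) %% 2147483647L)
      fld <- generate_field(sp)
      filt <- log_filter(fld$stack$channels$TMR, 1, 1.5)
      auto_threshold(matrix(filt[6, , ], 512, 512))
    })
    thr <- aggregate_threshold(unlist(thr_fields), "TMR")
    cfg <- e2e_config(spot_threshold_tmr = thr$mean_value)
    for (ti in seq_along(p_by_tp)) {
      tp <- as.numeric(names(p_by_tp)[ti])
      for (f in seq_len(fields_per_timepoint)) {
        seed <- (base_seed * 104729L + rep_id * 10007L + ti * 389L + f) %%
          2147483647L
        fld <- generate_field(e2e_scene(p_by_tp[[ti]], seed = seed))
        r <- process_stack(fld$stack, cfg, spot_channels = "TMR")
        cnt <- r$counts
        counts[[length(counts) + 1L]] <- data.frame(
          total = cnt$total, nuclear = cnt$nuclear,
          cytoplasmic = cnt$cytoplasmic, timepoint = tp, replicate = rep_id)
        truth_tot[[length(truth_tot) + 1L]] <- data.frame(
          total = fld$truth$counts$total, timepoint = tp, replicate = rep_id)
      }
    }
  }
  list(pipeline = do.call(rbind, counts), truth = do.call(rbind, truth_tot))
}
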