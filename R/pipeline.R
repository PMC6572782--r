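# Pipeline orchestration: a run configuration with serializable defaults,
# an in-memory per-stack driver, and directory-level batch stages
# (segment -> count -> stats) with per-run provenance logging.

#' Default run configuration
#'
#' Every tunable of the pipeline with its default, as a plain serializable
#' list: channel order, segmentation thresholds and filters, spot-detection
#' scales and thresholds (`"auto"` or a number; a manual number always
#' overrides the automation), the ON-coverage fraction, naming templates and
#' the seed. A run's effective configuration is written alongside its
#' outputs.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list (class `run_config`).
#' @export
default_config <- function(...) {
  cfg <- list(
    channel_order = CHANNEL_ROLES,
    n_channels = 4L,
    z_step_nm = 200,
    # nuclei
    dapi_threshold = "auto",          # global detection threshold or "auto" (Otsu)
    nucleus_area_bounds = c(20, 2000),
    # cells
    widefield_n_last = 5L,
    disk_radius = 15,
    cell_area_bounds = c(200, 20000),
    border_margin = 20,
    # spots
    sigma_smooth = 1,
    sigma_log = 1.5,
    spot_threshold = list(TMR = "auto", CY5 = "auto"),
    spot_min_distance = 3,            # ~2 x sigma_log: merge shoulder maxima
    auto_threshold_plane = "mid",     # representative z-plane: "mid" or index
    # statistics
    on_coverage = 0.95,
    var_convention = "population",
    # bookkeeping
    naming_template = "SD_mRNA_%s_CELLmaxRNA%s_mid.csv",
    seed = 1L,
    log_level = "info")
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = c("run_config", "list"))
}

#' Read / write a run configuration
#'
#' @param path YAML file path.
#' @return `read_config()` returns a `run_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Process one stack in memory
#'
#' Runs the full per-stack pipeline: DAPI projection and nucleus detection,
#' 3D nuclear segmentation with cell-specific thresholds, widefield cell
#' segmentation and filtering (nucleus labels remapped in lockstep), cell
#' morphology, then per spot channel LoG filtering, thresholding (manual or
#' automated) and regional-maximum spot detection, and finally per-cell
#' compartment counts.
#'
#' @param stack An [image_stack()] with DAPI, WIDEFIELD and spot channels.
#' @param config A [default_config()] list.
#' @param spot_channels Channels to detect spots in (default: the spot
#'   channels present).
#' @param keep_filtered Keep the LoG-filtered volumes in the result (for
#'   image exports); off by default to bound memory.
#' @return List: `nuclei_2d`, `nuclei` (`nucleus_map3d`), `cells`
#'   (`cell_map2d`), `records` (morphology), `counts` (`count_table`),
#'   `spots`, `thresholds` (per channel, with provenance `"manual"` /
#'   `"auto"`), `log` (character vector of decisions), and `filtered` (per
#'   channel) when `keep_filtered` is set.
#' @export
process_stack <- function(stack, config = default_config(),
                          spot_channels = NULL, keep_filtered = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  log <- character(0)
  say <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
  spot_channels <- spot_channels %||%
    intersect(names(stack$channels), c("TMR", "CY5"))
  ## nuclei
  proj <- max_project(stack$channels$DAPI)
  thr <- config$dapi_threshold
  nuclei_2d <- detect_nuclei(proj,
    global_threshold = if (identical(thr, "auto")) NULL else thr,
    min_area = config$nucleus_area_bounds[1L],
    max_area = config$nucleus_area_bounds[2L])
  say("dapi threshold %s = %.4g; %d nuclei detected",
      if (identical(thr, "auto")) "auto(otsu)" else "manual",
      attr(nuclei_2d, "global_threshold"), max(nuclei_2d))
  nuclei <- segment_nuclei_3d(stack$channels$DAPI, nuclei_2d)
  ## cells
  wf <- widefield_projection(stack$channels$WIDEFIELD, config$widefield_n_last)
  contrast <- subtract_background(wf, config$disk_radius)
  cells <- segment_cells(contrast, nuclei_2d)
  n_before <- length(unique(cells$labels[cells$labels > 0L]))
  cells <- filter_cells(cells, area_bounds = config$cell_area_bounds,
                        border_margin = config$border_margin, nuclei = nuclei)
  nuclei <- attr(cells, "nuclei")
  n_after <- length(unique(cells$labels[cells$labels > 0L]))
  say("cells: %d segmented, %d removed by size/border filter, %d kept",
      n_before, n_before - n_after, n_after)
  records <- measure_cells(cells)
  ## spots
  spots <- list()
  thresholds <- list()
  filtered <- if (keep_filtered) list() else NULL
  for (ch in spot_channels) {
    filt <- log_filter(stack$channels[[ch]], config$sigma_smooth,
                       config$sigma_log)
    tch <- config$spot_threshold[[ch]] %||% "auto"
    if (identical(tch, "auto")) {
      zi <- if (identical(config$auto_threshold_plane, "mid"))
        (dim(filt)[1L] + 1L) %/% 2L else as.integer(config$auto_threshold_plane)
      tval <- auto_threshold(matrix(filt[zi, , ], dim(filt)[2L], dim(filt)[3L]))
      say("%s threshold auto = %.4g (plane %d)", ch, tval, zi)
    } else {
      tval <- as.numeric(tch)
      say("%s threshold manual = %.4g", ch, tval)
    }
    thresholds[[ch]] <- list(value = tval,
                             provenance = if (identical(tch, "auto")) "auto" else "manual")
    sp <- detect_spots(filt, tval, channel = ch,
                       min_distance = config$spot_min_distance)
    say("%s: %d spots detected", ch, nrow(sp))
    spots[[ch]] <- sp
    if (keep_filtered) filtered[[ch]] <- filt
  }
  spots <- if (length(spots)) do.call(rbind, spots) else
    data.frame(channel = character(0), x = integer(0), y = integer(0),
               z = integer(0), intensity = numeric(0))
  rownames(spots) <- NULL
  counts <- count_cells(spots, cells, nuclei, channels = spot_channels,
                        source_id = stack$source_id)
  out <- list(nuclei_2d = nuclei_2d, nuclei = nuclei, cells = cells,
              records = records, counts = counts, spots = spots,
              thresholds = thresholds, log = log)
  if (keep_filtered) out$filtered <- filtered
  out
}

stack_tag <- function(path) tools::file_path_sans_ext(basename(path))

#' Batch segmentation over a directory of stacks
#'
#' Reads every `*.tif` stack under `input_dir`, segments nuclei and cells,
#' and writes per-stack label TIFFs (`<tag>_nuclei3D.tif`, 2D nucleus
#' centroid image `<tag>_nuclei.tif`, `<tag>_Cells.tif`, processed widefield
#' `<tag>_trans_plane.tif`), a CellInfo CSV (`<tag>_CellInfo.csv`), a
#' per-stack log, and the effective config snapshot (`run_config.yaml`).
#'
#' @param input_dir Directory of input stacks.
#' @param output_dir Output directory (created).
#' @param config A [default_config()].
#' @return Invisibly, per-stack result list; unreadable stacks are skipped
#'   with a logged error, and the call errors if every stack fails.
#' @export
run_segment <- function(input_dir, output_dir, config = default_config()) {
  paths <- list.files(input_dir, pattern = "\\.tif$", full.names = TRUE)
  if (length(paths) == 0L) stop("no .tif stacks found in ", input_dir)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(output_dir, "run_config.yaml"))
  results <- list()
  failures <- 0L
  for (p in paths) {
    tag <- stack_tag(p)
    res <- tryCatch({
      stack <- read_stack(p, config$n_channels, config$channel_order,
                          config$z_step_nm)
      r <- process_stack(stack, config)
      ## exports
      lab3 <- r$nuclei$labels
      write_label_volume(lab3, file.path(output_dir, paste0(tag, "_nuclei3D.tif")))
      cen <- centroid_image(r$nuclei_2d)
      write_label_volume(array(cen, c(1L, dim(cen))),
                         file.path(output_dir, paste0(tag, "_nuclei.tif")))
      write_label_volume(array(r$cells$labels, c(1L, dim(r$cells$labels))),
                         file.path(output_dir, paste0(tag, "_Cells.tif")))
      wf <- subtract_background(
        widefield_projection(stack$channels$WIDEFIELD, config$widefield_n_last),
        config$disk_radius)
      write_label_volume(array(round(wf), c(1L, dim(wf))),
                         file.path(output_dir, paste0(tag, "_trans_plane.tif")))
      write_cell_info(r$records, file.path(output_dir, paste0(tag, "_CellInfo.csv")))
      writeLines(r$log, file.path(output_dir, paste0(tag, "_segment.log")))
      r
    }, error = function(e) {
      message("skipping '", p, "': ", conditionMessage(e))
      e
    })
    if (inherits(res, "error")) failures <- failures + 1L else results[[tag]] <- res
  }
  if (failures == length(paths)) stop("all stacks failed to process")
  invisible(results)
}

# 16-bit label/intensity volume export (values must fit 0..65535)
write_label_volume <- function(vol, path) {
  pages <- lapply(seq_len(dim(vol)[1L]),
                  function(z) pmin(pmax(vol[z, , ], 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

# centroid image: one marked pixel per 2D label
centroid_image <- function(lab) {
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (k in unique(lab[lab > 0L])) {
    idx <- which(lab == k, arr.ind = TRUE)
    out[round(mean(idx[, 1L])), round(mean(idx[, 2L]))] <- k
  }
  out
}

#' Batch counting over segmented stacks
#'
#' Re-runs detection + assignment per stack (via [process_stack()]) and
#' writes the per-stack 3-column count CSVs plus per-experiment combined
#' files `Results_<exp>_RNA_<dye>_{total,nuclear,cytoplasm}.csv`. With
#' `export_images` it also emits, per stack and dye, the LoG-filtered stack
#' (`<tag>_<CH>3Dfilter.tif`), the detected-spot stack
#' (`<tag>_<CH>3D3immax.tif`), and max projections of the raw channel, the
#' filtered channel, and the detected-spot stack (`<tag>_<CH>max.tif`,
#' `..maxF.tif`, `..maxFimmax.tif`). Filtered intensities are stored
#' min-max scaled to the 16-bit range (inspection artifacts, not inputs).
#'
#' @param input_dir Directory of input stacks.
#' @param output_dir Output directory.
#' @param config A [default_config()].
#' @param experiment Experiment tag used in combined-file names.
#' @param export_images Also write the per-dye image artifacts.
#' @return Invisibly, the combined `count_table` across stacks.
#' @export
run_count <- function(input_dir, output_dir, config = default_config(),
                      experiment = "Exp", export_images = TRUE) {
  paths <- list.files(input_dir, pattern = "\\.tif$", full.names = TRUE)
  if (length(paths) == 0L) stop("no .tif stacks found in ", input_dir)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(output_dir, "run_config.yaml"))
  combined <- list()
  for (p in paths) {
    tag <- stack_tag(p)
    stack <- read_stack(p, config$n_channels, config$channel_order,
                        config$z_step_nm)
    r <- process_stack(stack, config, keep_filtered = export_images)
    for (ch in unique(r$counts$channel)) {
      dye <- tolower(ch)
      write_counts(r$counts, ch,
                   file.path(output_dir,
                             sprintf(config$naming_template, tag, dye)))
      if (export_images) {
        filt <- r$filtered[[ch]]
        rng <- range(filt)
        scaled <- (filt - rng[1L]) / max(rng[2L] - rng[1L], 1e-12) * 65535
        write_label_volume(scaled,
          file.path(output_dir, sprintf("%s_%s3Dfilter.tif", tag, ch)))
        sp <- r$spots[r$spots$channel == ch, , drop = FALSE]
        immax <- array(0, dim(filt))
        if (nrow(sp) > 0)
          immax[cbind(sp$z + 1L, sp$y + 1L, sp$x + 1L)] <- 65535
        write_label_volume(immax,
          file.path(output_dir, sprintf("%s_%s3D3immax.tif", tag, ch)))
        d2 <- function(m) array(m, c(1L, dim(m)))
        write_label_volume(d2(max_project(stack$channels[[ch]])),
          file.path(output_dir, sprintf("%s_%smax.tif", tag, ch)))
        write_label_volume(d2(max_project(scaled)),
          file.path(output_dir, sprintf("%s_%smaxF.tif", tag, ch)))
        write_label_volume(d2(max_project(immax)),
          file.path(output_dir, sprintf("%s_%smaxFimmax.tif", tag, ch)))
      }
    }
    combined[[tag]] <- r$counts
  }
  all <- do.call(rbind, combined)
  rownames(all) <- NULL
  for (ch in unique(all$channel)) {
    rows <- all[all$channel == ch, ]
    base <- sprintf("Results_%s_RNA_%s_%%s.csv", experiment, ch)
    utils::write.csv(data.frame(count = rows$total),
                     file.path(output_dir, sprintf(base, "total")), row.names = FALSE)
    utils::write.csv(data.frame(count = rows$nuclear),
                     file.path(output_dir, sprintf(base, "nuclear")), row.names = FALSE)
    utils::write.csv(data.frame(count = rows$cytoplasmic),
                     file.path(output_dir, sprintf(base, "cytoplasm")), row.names = FALSE)
  }
  invisible(all)
}

#' Summary statistics over combined counts
#'
#' Computes per-timepoint expression summaries for each replica and
#' aggregates them across replicas. The ON threshold is derived from the
#' pooled t = 0 (basal) sample per gene unless given explicitly.
#'
#' @param counts Data frame with columns `total`, `nuclear`, `cytoplasmic`,
#'   `timepoint`, `replicate` (and optionally `channel`/`gene`).
#' @param config A [default_config()] (uses `on_coverage`,
#'   `var_convention`).
#' @param on_threshold Explicit ON threshold; `NULL` derives it from the
#'   t = 0 rows.
#' @param condition,gene Labels carried into the summaries.
#' @return List: `on_threshold`, `per_replica` (list of
#'   [summarize_expression()] results), `aggregated` (data frame from
#'   [aggregate_replicates()]).
#' @export
run_stats <- function(counts, config = default_config(), on_threshold = NULL,
                      condition = "", gene = "") {
  if (is.null(on_threshold)) {
    basal <- counts$total[counts$timepoint == 0]
    if (length(basal) == 0L)
      stop("no t = 0 sample to derive the basal ON threshold; ",
           "pass `on_threshold` explicitly")
    on_threshold <- basal_on_threshold(basal, config$on_coverage)
  }
  per <- list()
  for (rep_id in sort(unique(counts$replicate))) {
    series <- list()
    for (tp in sort(unique(counts$timepoint))) {
      sel <- counts[counts$replicate == rep_id & counts$timepoint == tp, ]
      if (nrow(sel) == 0L) next
      series[[length(series) + 1L]] <- summarize_expression(
        total = sel$total, nuclear = sel$nuclear,
        cytoplasmic = sel$cytoplasmic, on_threshold = on_threshold,
        condition = condition, gene = gene, timepoint = tp,
        var_convention = config$var_convention)
    }
    per[[length(per) + 1L]] <- series
  }
  list(on_threshold = on_threshold, per_replica = per,
       aggregated = aggregate_replicates(per))
}
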