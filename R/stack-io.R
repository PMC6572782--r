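#' Channel roles of an interleaved acquisition
#'
#' The default acquisition interleaves four images per z-position: the TMR
#' spot channel (STL1 probes), the CY5 spot channel (CTT1 probes), the DAPI
#' nuclear stain, and a widefield (transmitted light) image.
#'
#' @export
CHANNEL_ROLES <- c("TMR", "CY5", "DAPI", "WIDEFIELD")

#' Construct an image stack
#'
#' An `image_stack` bundles one field of view: a 3D intensity array per
#' channel in `(z, y, x)` order plus acquisition metadata. All channel arrays
#' must share one shape and hold non-negative intensities.
#'
#' @param channels Named list of 3D numeric arrays `(z, y, x)`, names drawn
#'   from [CHANNEL_ROLES] (other role names are allowed).
#' @param z_step_nm Axial spacing between consecutive z-planes, nanometres.
#' @param source_id Identifier string (experiment/replicate/timepoint/field).
#' @return An object of class `image_stack` with fields `channels`,
#'   `z_step_nm`, `pixel_shape` (height, width), `n_z`, `source_id`.
#' @export
image_stack <- function(channels, z_step_nm = 200, source_id = "field") {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)))
    stop("`channels` must be a non-empty named list of 3D arrays")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, integer(1)) != 3L))
    stop("every channel must be a 3D (z, y, x) array")
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop("all channels must share one (z, y, x) shape")
  if (any(vapply(channels, function(a) any(a < 0), logical(1))))
    stop("intensities must be non-negative")
  if (!is.numeric(z_step_nm) || z_step_nm <= 0)
    stop("`z_step_nm` must be a positive number")
  d <- dims[[1L]]
  structure(
    list(channels = channels, z_step_nm = as.numeric(z_step_nm),
         pixel_shape = c(height = d[2L], width = d[3L]),
         n_z = d[1L], source_id = source_id),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack '%s': %d channel(s) [%s], %d z-planes of %dx%d px, z-step %g nm\n",
              x$source_id, length(x$channels),
              paste(names(x$channels), collapse = ", "),
              x$n_z, x$pixel_shape[1L], x$pixel_shape[2L], x$z_step_nm))
  invisible(x)
}

meta_path <- function(path) paste0(path, ".meta.json")

#' Read an interleaved multi-channel TIFF z-stack
#'
#' Stacks are stored as one multi-page TIFF per field of view with the
#' channels interleaved within each z-position: page `i` (0-based) holds
#' channel `channel_order[i mod n_channels]` at z-index `floor(i /
#' n_channels)`. A 25 z-position, 4-channel acquisition therefore has 100
#' pages; 26 z-positions give 104.
#'
#' Acquisition metadata (z-step, source id, intensity scaling) is carried in
#' a JSON sidecar `<path>.meta.json` written by [write_stack()]; absent a
#' sidecar, `z_step_nm` defaults to 200.
#'
#' @param path TIFF file path.
#' @param n_channels Number of interleaved channels per z-position.
#' @param channel_order Channel roles in on-disk page order.
#' @param z_step_nm Fallback z-step when no sidecar is present.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, n_channels = 4L,
                       channel_order = CHANNEL_ROLES,
                       z_step_nm = 200) {
  if (!file.exists(path)) stop("cannot read stack: no such file: ", path)
  if (length(channel_order) != n_channels)
    stop("`channel_order` must name exactly `n_channels` roles")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("I/O error reading '", path, "': ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  n <- length(pages)
  if (n %% n_channels != 0L)
    stop(sprintf("layout error: %d pages not divisible by %d channels", n, n_channels))
  shapes <- unique(lapply(pages, dim))
  if (length(shapes) != 1L)
    stop("format error: pages of '", path, "' have inconsistent shapes")
  n_z <- n %/% n_channels
  ny <- shapes[[1L]][1L]; nx <- shapes[[1L]][2L]
  scale <- 1
  src <- tools::file_path_sans_ext(basename(path))
  mp <- meta_path(path)
  if (file.exists(mp)) {
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
    z_step_nm <- meta$z_step_nm %||% z_step_nm
    scale <- meta$intensity_scale %||% 1
    src <- meta$source_id %||% src
  }
  channels <- lapply(seq_len(n_channels), function(ci) {
    a <- array(0, c(n_z, ny, nx))
    for (z in seq_len(n_z)) a[z, , ] <- pages[[(z - 1L) * n_channels + ci]]
    a * scale
  })
  names(channels) <- channel_order
  image_stack(channels, z_step_nm = z_step_nm, source_id = src)
}

#' Write an image stack as an interleaved multi-page TIFF
#'
#' Pages are interleaved exactly as [read_stack()] expects. Voxels are stored
#' as 16-bit unsigned samples, the native depth of the CMOS cameras this
#' layout models; stacks whose maximum exceeds 65535 are stored rescaled with
#' the scale factor recorded in the JSON sidecar (a power of two, so integer
#' data up to 2^24 round-trips exactly). Non-integer intensities are rounded.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  n_z <- stack$n_z
  roles <- names(stack$channels)
  mx <- max(vapply(stack$channels, max, numeric(1)), 0)
  scale <- if (mx > 65535) 2^ceiling(log2(mx / 65535)) else 1
  pages <- vector("list", n_z * length(roles))
  for (z in seq_len(n_z)) {
    for (ci in seq_along(roles)) {
      m <- round(stack$channels[[ci]][z, , ] / scale)
      pages[[(z - 1L) * length(roles) + ci]] <-
        pmin(pmax(m, 0), 65535) / 65535
    }
  }
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L),
                 error = function(e) stop("I/O error writing '", path, "': ",
                                          conditionMessage(e)))
  jsonlite::write_json(
    list(z_step_nm = stack$z_step_nm, channel_order = roles,
         intensity_scale = scale, source_id = stack$source_id),
    meta_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Parse a probe table
#'
#' The probe table is delimited text with one column per gene; each column
#' holds that gene's tiling oligonucleotide sequences (one probe per row).
#' The packaged table (`system.file("extdata", "probes_stl1_ctt1.csv",
#' package = "smfishq")`) carries the STL1 and CTT1 sets: 48 probes each,
#' all 20 nt.
#'
#' @param path Delimited text file, header row of gene names.
#' @param dyes Named character vector mapping gene to dye; genes absent from
#'   the map get dye `NA`.
#' @param sep Field separator.
#' @return List of `probe_set` objects (fields `gene`, `probes`, `dye`,
#'   `probe_length`), one per gene column.
#' @export
read_probe_table <- function(path, dyes = c(STL1 = "TMR", CTT1 = "CY5"),
                             sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE)
  if (ncol(tab) == 0L) stop("parse error: probe table has no columns")
  lapply(names(tab), function(gene) {
    probes <- toupper(tab[[gene]])
    probes <- probes[nzchar(probes)]
    bad <- grepl("[^ACGT]", probes)
    if (any(bad))
      stop("parse error: non-ACGT characters in probes for gene ", gene,
           " (rows ", paste(which(bad), collapse = ", "), ")")
    lens <- unique(nchar(probes))
    if (length(lens) != 1L)
      stop("invariant violation: ragged probe lengths for gene ", gene,
           ": ", paste(lens, collapse = ", "))
    structure(list(gene = gene, probes = probes,
                   dye = unname(dyes[gene]), probe_length = lens),
              class = "probe_set")
  })
}

#' Parse an experiment manifest
#'
#' One row per experimental design (condition x replicate): the osmotic-stress
#' condition, replicate number, comma-separated fixation timepoints in
#' minutes, and the number of image stacks acquired. The packaged manifest
#' (`system.file("extdata", "experiments.tsv", package = "smfishq")`)
#' transcribes the deposited designs; its `stated_total_stacks` attribute
#' records the prose total alongside the per-row stack counts, which need not
#' agree.
#'
#' @param path Tab-separated manifest file.
#' @return Data frame with columns `experiment`, `condition`, `replicate`,
#'   `timepoints_min` (list column of numeric vectors), `n_stacks`; attribute
#'   `stated_total_stacks` when the file declares one in a `# total_stacks:`
#'   comment line.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  stated <- NA_real_
  hdr <- grep("^#\\s*total_stacks:", lines, value = TRUE)
  if (length(hdr))
    stated <- as.numeric(sub("^#\\s*total_stacks:\\s*", "", hdr[1L]))
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t",
                           colClasses = "character", strip.white = TRUE)
  tp <- lapply(strsplit(tab$timepoints_min, ","), as.numeric)
  for (i in seq_along(tp)) {
    if (any(diff(tp[[i]]) <= 0) || any(tp[[i]] < 0))
      stop("manifest error: timepoints not strictly increasing in row ", i)
  }
  out <- data.frame(experiment = tab$experiment, condition = tab$condition,
                    replicate = as.integer(tab$replicate),
                    n_stacks = as.integer(tab$n_stacks))
  out$timepoints_min <- tp
  attr(out, "stated_total_stacks") <- stated
  out
}

#' Write per-cell morphology (CellInfo schema)
#'
#' Emits exactly five columns per cell — centroid x, centroid y, major axis,
#' minor axis, area — one row per cell ordered by cell label. Coordinates are
#' 0-based pixels (x = column, y = row); axes and area are in pixels.
#'
#' @param records Data frame from [measure_cells()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_info <- function(records, path) {
  cols <- c("centroid_x", "centroid_y", "major_axis", "minor_axis", "area")
  if (nrow(records) > 0 && !all(cols %in% names(records)))
    stop("export error: missing morphology field(s): ",
         paste(setdiff(cols, names(records)), collapse = ", "))
  out <- if (nrow(records) == 0) {
    as.data.frame(setNames(rep(list(numeric(0)), 5L), cols))
  } else {
    records[order(records$label), cols]
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write per-cell counts for one channel (3-column schema)
#'
#' Column 1 is the total RNA count in the cell, column 2 the cytoplasmic
#' count, column 3 the nuclear count; `total = cytoplasm + nucleus` holds
#' row-wise or the export is refused.
#'
#' @param counts Count table from [count_cells()].
#' @param channel Channel role to export (e.g. `"TMR"`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, channel, path) {
  rows <- counts[counts$channel == channel, , drop = FALSE]
  if (nrow(rows) > 0 &&
      any(rows$total != rows$cytoplasmic + rows$nuclear))
    stop("export refused: total != cytoplasmic + nuclear for channel ", channel)
  out <- data.frame(total = rows$total, cytoplasm = rows$cytoplasmic,
                    nucleus = rows$nuclear)
  if (nrow(out) > 0) out <- out[order(rows$cell), ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
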