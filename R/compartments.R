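# Spot-to-compartment assignment: the 3D nuclear mask takes precedence at
# the spot's voxel; otherwise the 2D cell footprint decides the cell and the
# spot is cytoplasmic; spots outside every footprint stay unassigned.

#' Assign spots to cells and compartments
#'
#' A spot whose voxel lies inside nucleus k is nuclear in cell k; otherwise,
#' if its (x, y) falls in cell k's footprint it is cytoplasmic in cell k;
#' otherwise it is unassigned (and excluded from all counts). Nuclear
#' membership is evaluated in 3D, cytoplasmic membership in 2D, mirroring
#' the 3D nuclear / 2D cell masks the pipeline produces.
#'
#' @param spots Spot data frame from [detect_spots()].
#' @param cells A `cell_map2d` (after [filter_cells()]).
#' @param nuclei A `nucleus_map3d` with labels matched to `cells`.
#' @return `spots` with added columns `cell` (integer, `NA` if unassigned)
#'   and `compartment` (`"nuclear"`, `"cytoplasmic"`, or `NA`).
#' @export
assign_spots <- function(spots, cells, nuclei) {
  lab2 <- if (inherits(cells, "cell_map2d")) cells$labels else cells
  lab3 <- if (inherits(nuclei, "nucleus_map3d")) nuclei$labels else nuclei
  d <- dim(lab3)
  if (nrow(spots) == 0L) {
    spots$cell <- integer(0); spots$compartment <- character(0)
    return(spots)
  }
  if (any(spots$x < 0 | spots$x >= d[3L] | spots$y < 0 | spots$y >= d[2L] |
            spots$z < 0 | spots$z >= d[1L]))
    stop("spot out of image bounds")
  nuc <- lab3[cbind(spots$z + 1L, spots$y + 1L, spots$x + 1L)]
  cyt <- lab2[cbind(spots$y + 1L, spots$x + 1L)]
  cell <- ifelse(nuc > 0L, nuc, ifelse(cyt > 0L, cyt, NA_integer_))
  spots$cell <- as.integer(cell)
  spots$compartment <- ifelse(nuc > 0L, "nuclear",
                              ifelse(cyt > 0L, "cytoplasmic", NA_character_))
  spots
}

#' Per-cell nuclear/cytoplasmic counts
#'
#' Aggregates spot assignments into one row per surviving cell and channel;
#' cells without spots get explicit zero rows. The sum over cells of
#' (nuclear + cytoplasmic) plus the unassigned count equals the number of
#' detected spots for each channel (conservation), and `total = nuclear +
#' cytoplasmic` holds by construction.
#'
#' @param spots Spot data frame ([detect_spots()] output, one or more
#'   channels row-bound).
#' @param cells A `cell_map2d`.
#' @param nuclei A `nucleus_map3d`.
#' @param channels Channel roles to tabulate (default: those present in
#'   `spots`, or `"TMR"` if none).
#' @param source_id Provenance string stored on the result.
#' @return Data frame (class `count_table`): `cell`, `channel`, `nuclear`,
#'   `cytoplasmic`, `total`, `source_id`; attribute `unassigned` is a named
#'   per-channel count of background spots.
#' @export
count_cells <- function(spots, cells, nuclei, channels = NULL,
                        source_id = "field") {
  lab2 <- if (inherits(cells, "cell_map2d")) cells$labels else cells
  ks <- sort(unique(lab2[lab2 > 0L]))
  channels <- channels %||%
    (if (nrow(spots) > 0L) unique(spots$channel) else "TMR")
  asg <- assign_spots(spots, cells, nuclei)
  grid <- expand.grid(cell = ks, channel = channels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  hit <- asg[!is.na(asg$cell), , drop = FALSE]
  tab <- function(comp) {
    sel <- hit[hit$compartment == comp, , drop = FALSE]
    t3 <- table(factor(sel$cell, levels = ks),
                factor(sel$channel, levels = channels))
    as.integer(t3[cbind(match(grid$cell, ks), match(grid$channel, channels))])
  }
  if (nrow(grid) > 0L) {
    grid$nuclear <- tab("nuclear")
    grid$cytoplasmic <- tab("cytoplasmic")
  } else {
    grid$nuclear <- integer(0); grid$cytoplasmic <- integer(0)
  }
  grid$total <- grid$nuclear + grid$cytoplasmic
  grid$source_id <- rep_len(source_id, nrow(grid))
  unas <- vapply(channels, function(ch)
    sum(is.na(asg$cell) & asg$channel == ch), integer(1))
  structure(grid, unassigned = setNames(unas, channels),
            class = c("count_table", "data.frame"))
}
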