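# Whole-cell segmentation from the widefield (transmitted light) channel:
# project the last planes of the stack, flatten illumination with a disk
# smoothing filter, then grow cell regions from the nuclear seeds with a
# seeded watershed and filter out mis-segmented or border-touching cells.

#' Maximum projection over the last planes of a widefield stack
#'
#' Cell outlines are sharpest just below the coverslip, so the projection
#' uses only the final `n_last` z-planes (default 5).
#'
#' @param widefield_volume 3D array `(z, y, x)`.
#' @param n_last Number of trailing planes to project.
#' @return 2D matrix `(y, x)`.
#' @export
widefield_projection <- function(widefield_volume, n_last = 5L) {
  d <- dim(widefield_volume)
  stopifnot(length(d) == 3L)
  if (n_last < 1L || n_last > d[1L])
    stop("parameter error: n_last must be in 1..n_z")
  max_project(widefield_volume[(d[1L] - n_last + 1L):d[1L], , , drop = FALSE])
}

#' Disk-filter background subtraction
#'
#' A background image is generated by running a disk smoothing filter (mean
#' over a disk neighbourhood) over the image; subtracting it enhances local
#' contrast and removes illumination offsets. Output is clipped at zero.
#'
#' @param image 2D matrix.
#' @param disk_radius Disk radius in pixels (>= 1).
#' @return 2D matrix of the same shape, non-negative.
#' @export
subtract_background <- function(image, disk_radius = 15) {
  if (disk_radius < 1) stop("parameter error: disk_radius must be >= 1")
  size <- 2L * as.integer(disk_radius) + 1L
  # filter2 requires the kernel to fit inside the image
  size <- min(size, 2L * ((min(dim(image)) - 1L) %/% 2L) + 1L)
  brush <- EBImage::makeBrush(size, shape = "disc")
  bg <- matrix(as.numeric(EBImage::filter2(image, brush / sum(brush))),
               nrow(image), ncol(image))
  out <- pmax(image - bg, 0)
  # flatten numerical dust so a flat field maps to exact zeros
  out[out < 1e-8 * max(1, max(abs(image)))] <- 0
  out
}

#' Seeded watershed segmentation of cells
#'
#' Cell regions are grown from the nucleus labels over the
#' background-subtracted widefield projection: the nuclear seeds are imposed
#' on the contrast image and each catchment basin inherits its seed's label
#' (EBImage's `propagate`, the seeded-watershed operator of the R image
#' stack). Pixels outside the foreground mask — contrast below its Otsu
#' cutoff and not part of a seed — stay background.
#'
#' @param contrast_image Background-subtracted widefield projection.
#' @param nuclei_2d Nucleus label matrix ([detect_nuclei()]); labels are the
#'   seeds and are propagated unchanged.
#' @param mask_threshold Foreground cutoff on `contrast_image`, or `NULL`
#'   for Otsu.
#' @return A `cell_map2d`: list with `labels` (2D integer matrix),
#'   `border_margin`, `area_bounds` (both `NA` until [filter_cells()]).
#' @export
segment_cells <- function(contrast_image, nuclei_2d, mask_threshold = NULL) {
  if (max(nuclei_2d) == 0L) {
    warning("no nuclei to seed cell segmentation; empty cell map")
    return(structure(list(labels = matrix(0L, nrow(contrast_image), ncol(contrast_image)),
                          border_margin = NA_real_, area_bounds = c(NA_real_, NA_real_)),
                     class = "cell_map2d"))
  }
  thr <- mask_threshold %||% otsu_threshold(contrast_image)
  fg <- contrast_image > thr | nuclei_2d > 0L
  # close small gaps so a cell interior forms one basin with its seed
  fg <- EBImage::closing(fg, EBImage::makeBrush(5L, shape = "disc")) > 0
  lab <- EBImage::propagate(contrast_image, seeds = nuclei_2d, mask = fg)
  lab <- matrix(as.integer(lab), nrow(contrast_image), ncol(contrast_image))
  structure(list(labels = lab, border_margin = NA_real_,
                 area_bounds = c(NA_real_, NA_real_)),
            class = "cell_map2d")
}

#' @export
print.cell_map2d <- function(x, ...) {
  cat(sprintf("cell_map2d: %d cells, area bounds [%s, %s], border margin %s px\n",
              length(unique(x$labels[x$labels > 0L])),
              format(x$area_bounds[1L]), format(x$area_bounds[2L]),
              format(x$border_margin)))
  invisible(x)
}

#' Remove mis-segmented and border cells
#'
#' Drops labels whose area is outside `area_bounds` or that touch the image
#' border strip of width `border_margin`; survivors are renumbered
#' consecutively. When a nucleus map is supplied its labels are remapped in
#' lockstep so cell k and nucleus k keep referring to the same cell.
#'
#' @param cells A `cell_map2d` from [segment_cells()].
#' @param area_bounds Numeric `(min, max)` area in pixels, inclusive.
#' @param border_margin Width in pixels of the excluded border strip.
#' @param nuclei Optional `nucleus_map3d` (or 2D label matrix) remapped in
#'   lockstep.
#' @return Filtered `cell_map2d`; attributes `label_map` (old -> new, 0 for
#'   removed) and, when `nuclei` was given, `nuclei` (remapped).
#' @export
filter_cells <- function(cells, area_bounds = c(200, 20000),
                         border_margin = 20, nuclei = NULL) {
  stopifnot(inherits(cells, "cell_map2d"))
  lab <- cells$labels
  n <- max(lab)
  keep <- integer(0)
  if (n > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = n)
    m <- as.integer(border_margin)
    border <- matrix(FALSE, nrow(lab), ncol(lab))
    if (m > 0L) {
      border[c(seq_len(min(m, nrow(lab))), nrow(lab) - seq_len(min(m, nrow(lab))) + 1L), ] <- TRUE
      border[, c(seq_len(min(m, ncol(lab))), ncol(lab) - seq_len(min(m, ncol(lab))) + 1L)] <- TRUE
    }
    touches <- unique(lab[border & lab > 0L])
    keep <- setdiff(which(areas >= area_bounds[1L] & areas <= area_bounds[2L]),
                    touches)
  }
  map <- integer(n)
  map[sort(keep)] <- seq_along(keep)
  out <- lab
  out[lab > 0L] <- map[lab[lab > 0L]]
  res <- structure(list(labels = out, border_margin = border_margin,
                        area_bounds = as.numeric(area_bounds)),
                   class = "cell_map2d")
  attr(res, "label_map") <- map
  if (!is.null(nuclei)) {
    if (inherits(nuclei, "nucleus_map3d")) {
      nl <- nuclei$labels
      nl[nl > 0L] <- map[nl[nl > 0L]]
      nuclei$labels <- nl
      old <- as.integer(names(nuclei$per_label_threshold))
      keep_thr <- old %in% which(map > 0L)
      thr <- nuclei$per_label_threshold[keep_thr]
      names(thr) <- map[old[keep_thr]]
      nuclei$per_label_threshold <- thr[order(as.integer(names(thr)))]
    } else {
      nuclei[nuclei > 0L] <- map[nuclei[nuclei > 0L]]
    }
    attr(res, "nuclei") <- nuclei
  }
  res
}

#' Per-cell morphology (CellInfo)
#'
#' Area is the pixel count, the centroid the mean pixel position (0-based,
#' x = column, y = row), and major/minor axes come from the ellipse whose
#' second-order central moments match the region's (each pixel treated as a
#' unit square, adding 1/12 to the variances, so even a single-pixel region
#' has positive axes).
#'
#' @param cells A `cell_map2d`.
#' @return Data frame with columns `label`, `centroid_x`, `centroid_y`,
#'   `major_axis`, `minor_axis`, `area`, one row per label.
#' @export
measure_cells <- function(cells) {
  lab <- if (inherits(cells, "cell_map2d")) cells$labels else cells
  ks <- sort(unique(lab[lab > 0L]))
  rows <- lapply(ks, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    y <- idx[, 1L] - 1; x <- idx[, 2L] - 1
    n <- length(x)
    vxx <- mean((x - mean(x))^2) + 1 / 12
    vyy <- mean((y - mean(y))^2) + 1 / 12
    vxy <- mean((x - mean(x)) * (y - mean(y)))
    tr <- vxx + vyy
    det <- sqrt(pmax((vxx - vyy)^2 + 4 * vxy^2, 0))
    data.frame(label = k, centroid_x = mean(x), centroid_y = mean(y),
               major_axis = 4 * sqrt((tr + det) / 2),
               minor_axis = 4 * sqrt(pmax((tr - det) / 2, 0)),
               area = n)
  })
  if (length(rows) == 0L)
    return(data.frame(label = integer(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), major_axis = numeric(0),
                      minor_axis = numeric(0), area = numeric(0)))
  do.call(rbind, rows)
}
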