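# Nuclear segmentation from the DAPI channel: a global detection threshold on
# the maximum-intensity projection finds nuclei in 2D, then each nucleus is
# re-thresholded in 3D at 50% of its own dynamic range above background, so
# cell-to-cell differences in DNA content and staining do not bias the mask.

#' Maximum-intensity projection of a z-stack
#'
#' @param volume 3D numeric array `(z, y, x)`.
#' @return 2D matrix `(y, x)` with `out[y, x] = max_z volume[z, y, x]`.
#' @export
max_project <- function(volume) {
  d <- dim(volume)
  if (is.null(d) || length(d) != 3L || any(d == 0L))
    stop("max_project() expects a non-empty 3D (z, y, x) array")
  Reduce(pmax, lapply(seq_len(d[1L]), function(z) matrix(volume[z, , ], d[2L], d[3L])))
}

#' Global Otsu threshold of an intensity image
#'
#' Used as the automated default for the global DAPI detection threshold; a
#' manual threshold always takes precedence when supplied.
#'
#' @param img 2D numeric matrix.
#' @return Threshold on the intensity scale of `img`.
#' @export
otsu_threshold <- function(img) {
  rng <- range(img)
  if (diff(rng) == 0) return(rng[1L])
  EBImage::otsu(EBImage::Image((img - rng[1L]) / diff(rng)),
                range = c(0, 1)) * diff(rng) + rng[1L]
}

#' Detect nuclei on a DAPI projection
#'
#' Thresholds the projection globally, labels connected components
#' (8-connectivity), removes components whose area falls outside
#' `[min_area, max_area]`, and renumbers survivors consecutively.
#'
#' @param dapi_projection 2D matrix, e.g. from [max_project()].
#' @param global_threshold Intensity cutoff, or `NULL` for Otsu's method via
#'   [otsu_threshold()].
#' @param min_area,max_area Area bounds in pixels (inclusive).
#' @return Integer label matrix, 0 background, 1..K nuclei; attribute
#'   `global_threshold` records the value used.
#' @export
detect_nuclei <- function(dapi_projection, global_threshold = NULL,
                          min_area = 20, max_area = 1000) {
  if (min_area < 0 || max_area < 0) stop("parameter error: negative area bound")
  if (min_area >= max_area) stop("parameter error: min_area must be < max_area")
  thr <- global_threshold %||% otsu_threshold(dapi_projection)
  lab <- label2d(dapi_projection > thr)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = max(lab))
    drop <- which(areas < min_area | areas > max_area)
    lab[lab %in% drop] <- 0L
    lab <- relabel_consecutive(lab)
  }
  attr(lab, "global_threshold") <- thr
  lab
}

#' Cell-specific DAPI threshold
#'
#' Each nucleus gets its own cutoff at 50% of the difference between the
#' maximum DAPI signal in its region and the background DAPI signal:
#' `background + 0.5 * (max - background)`.
#'
#' @param dapi_region_max Maximum DAPI intensity within the nucleus region.
#' @param background Background DAPI level (see [estimate_background()]).
#' @return The per-nucleus threshold.
#' @export
per_nucleus_threshold <- function(dapi_region_max, background) {
  if (any(background < 0)) stop("background must be non-negative")
  if (any(dapi_region_max < background))
    stop("region maximum below background")
  background + 0.5 * (dapi_region_max - background)
}

#' Background DAPI level of a projection
#'
#' The median intensity over pixels not assigned to any nucleus.
#'
#' @param dapi_projection 2D DAPI projection.
#' @param nuclei_2d Label matrix from [detect_nuclei()] (0 = background).
#' @return Scalar background level.
#' @export
estimate_background <- function(dapi_projection, nuclei_2d) {
  stats::median(dapi_projection[nuclei_2d == 0L])
}

#' Segment nuclei in 3D with cell-specific thresholds
#'
#' For each 2D nucleus label the DAPI volume is thresholded, within the
#' z-column over that nucleus's footprint, at [per_nucleus_threshold()] of
#' the column's maximum; voxels at or above the cutoff that are 26-connected
#' to the column's brightest voxel form the 3D nucleus.
#'
#' @param dapi_volume 3D DAPI array `(z, y, x)`.
#' @param nuclei_2d Label matrix from [detect_nuclei()] on the projection of
#'   `dapi_volume`.
#' @param background Background DAPI level; defaults to
#'   [estimate_background()] on the projection.
#' @return A `nucleus_map3d`: list with `labels` (3D integer array),
#'   `per_label_threshold` (named numeric), `background_level`.
#' @export
segment_nuclei_3d <- function(dapi_volume, nuclei_2d, background = NULL) {
  d <- dim(dapi_volume)
  stopifnot(length(d) == 3L, all(dim(nuclei_2d) == d[2:3]))
  background <- background %||%
    estimate_background(max_project(dapi_volume), nuclei_2d)
  labels3d <- array(0L, d)
  ks <- sort(unique(nuclei_2d[nuclei_2d > 0L]))
  thresholds <- setNames(numeric(length(ks)), ks)
  for (k in ks) {
    fp <- nuclei_2d == k
    ys <- range(which(rowSums(fp) > 0))
    xs <- range(which(colSums(fp) > 0))
    sub <- dapi_volume[, ys[1L]:ys[2L], xs[1L]:xs[2L], drop = FALSE]
    fpsub <- fp[ys[1L]:ys[2L], xs[1L]:xs[2L], drop = FALSE]
    colmask <- aperm(array(fpsub, c(dim(fpsub), d[1L])), c(3L, 1L, 2L))
    vals <- ifelse(colmask, sub, -Inf)
    mx <- max(vals)
    if (!is.finite(mx) || mx <= background) {
      warning("nucleus ", k, " has no DAPI signal above background; skipped")
      thresholds[as.character(k)] <- NA_real_
      next
    }
    thr <- per_nucleus_threshold(mx, background)
    thresholds[as.character(k)] <- thr
    mask <- colmask & sub >= thr
    if (!any(mask)) next
    comp <- label3d(mask)
    seed <- which(vals == mx, arr.ind = TRUE)[1L, , drop = FALSE]
    keep <- comp[seed]
    if (keep == 0L) next
    sel <- comp == keep
    block <- labels3d[, ys[1L]:ys[2L], xs[1L]:xs[2L], drop = FALSE]
    block[sel] <- k
    labels3d[, ys[1L]:ys[2L], xs[1L]:xs[2L]] <- block
  }
  structure(list(labels = labels3d, per_label_threshold = thresholds,
                 background_level = background),
            class = "nucleus_map3d")
}

#' @export
print.nucleus_map3d <- function(x, ...) {
  cat(sprintf("nucleus_map3d: %d nuclei, background %.3g\n",
              sum(!is.na(x$per_label_threshold)), x$background_level))
  invisible(x)
}
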