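# Single-molecule spot detection: Gaussian denoising, Laplacian-of-Gaussian
# (LoG) band-pass filtering in 3D, thresholding of the filtered stack, and
# regional-maximum localization giving one xyz position per molecule.

#' Gaussian + Laplacian-of-Gaussian filtering of a z-stack
#'
#' The volume is first smoothed with a separable Gaussian of width
#' `sigma_smooth` to suppress camera noise, then filtered with a negated,
#' scale-normalized Laplacian of Gaussian of width `sigma_log`, so
#' diffraction-limited (blob-like) spots become positive peaks whose height
#' tracks the spot amplitude. Axial anisotropy (the 200 nm z-step vs the
#' lateral pixel pitch) is handled by per-axis sigmas: each `sigma_*` may be
#' a scalar (isotropic) or a length-3 vector `(z, y, x)` in voxels.
#'
#' @param volume 3D array `(z, y, x)`.
#' @param sigma_smooth Denoising Gaussian width(s), voxels.
#' @param sigma_log LoG width(s), voxels; match to the PSF scale.
#' @return Filtered 3D array; constant input maps to (exactly) zero.
#' @export
log_filter <- function(volume, sigma_smooth = 1, sigma_log = 1.5) {
  stopifnot(length(dim(volume)) == 3L)
  if (any(sigma_smooth <= 0) || any(sigma_log <= 0))
    stop("parameter error: sigmas must be positive")
  ss <- rep_len(sigma_smooth, 3L)
  sl <- rep_len(sigma_log, 3L)
  axes <- c("z", "y", "x")
  sm <- volume
  for (i in 1:3) sm <- filter_axis(sm, gauss_kernel(ss[i]), axes[i])
  # negated LoG of the denoised volume: sum over axes of the sampled
  # second-derivative-of-Gaussian kernel on that axis with plain Gaussians on
  # the others; scale-normalized so blobs of scale ~ sigma_log give positive
  # peaks tracking their amplitude
  norm <- prod(sl)^(2 / 3)
  out <- array(0, dim(volume))
  for (i in 1:3) {
    term <- sm
    for (j in 1:3) {
      k <- if (i == j) gauss_d2_kernel(sl[j]) else gauss_kernel(sl[j])
      term <- filter_axis(term, k, axes[j])
    }
    out <- out - norm * term
  }
  out
}

#' Aggregate per-image detection thresholds
#'
#' One detection threshold is chosen per dye for each image in a sample; the
#' sample-level threshold applied to every stack is their arithmetic mean.
#'
#' @param per_image_values Positive numeric vector, one value per image.
#' @param channel Channel role the thresholds belong to.
#' @return A `detection_threshold`: list with `channel`, `per_image_values`,
#'   `mean_value`.
#' @export
aggregate_threshold <- function(per_image_values, channel = "TMR") {
  if (length(per_image_values) == 0L)
    stop("no per-image thresholds to aggregate")
  structure(list(channel = channel,
                 per_image_values = as.numeric(per_image_values),
                 mean_value = mean(per_image_values)),
            class = "detection_threshold")
}

#' Detect spots in a filtered stack
#'
#' Binarizes the LoG-filtered volume at `threshold` and reports the regional
#' maxima of the above-threshold signal: voxels at least as bright as all 26
#' neighbours. A connected plateau of equal-valued maxima collapses to a
#' single spot at its (rounded) centroid, so output is deterministic.
#'
#' @param filtered_volume 3D array from [log_filter()].
#' @param threshold Detection threshold on the filtered-intensity scale.
#' @param channel Channel role recorded per spot.
#' @param min_distance Minimum distance in voxels between reported spots; a
#'   dimmer maximum within this radius of a brighter one is treated as a
#'   shoulder of the same molecule and suppressed. 0 reports every regional
#'   maximum.
#' @return Data frame of spots: `channel`, `x`, `y`, `z` (0-based voxel
#'   indices), `intensity` (filtered value at the maximum).
#' @export
detect_spots <- function(filtered_volume, threshold, channel = "TMR",
                         min_distance = 0) {
  stopifnot(length(dim(filtered_volume)) == 3L)
  mask <- filtered_volume >= threshold
  empty <- data.frame(channel = character(0), x = integer(0), y = integer(0),
                      z = integer(0), intensity = numeric(0))
  if (!any(mask)) return(empty)
  locmax <- mask & filtered_volume == boxmax3(filtered_volume)
  if (!any(locmax)) return(empty)
  # group 26-connected plateau maxima by union-find over the (sparse) set of
  # maxima voxels rather than labeling the full volume
  d <- dim(filtered_volume)
  lin <- which(locmax)
  idx <- arrayInd(lin, d)
  lab <- seq_along(lin)
  if (length(lin) > 1L) {
    parent <- seq_along(lin)
    off <- expand.grid(dz = -1L:1L, dy = -1L:1L, dx = -1L:1L)
    off <- off[!(off$dz == 0L & off$dy == 0L & off$dx == 0L), ]
    for (s in seq_len(nrow(off))) {
      zi <- idx[, 1L] + off$dz[s]; yi <- idx[, 2L] + off$dy[s]
      xi <- idx[, 3L] + off$dx[s]
      inb <- zi >= 1L & zi <= d[1L] & yi >= 1L & yi <= d[2L] &
        xi >= 1L & xi <= d[3L]
      nb <- rep(NA_integer_, length(lin))
      nb[inb] <- match(zi[inb] + (yi[inb] - 1L) * d[1L] +
                         (xi[inb] - 1L) * d[1L] * d[2L], lin)
      hit <- which(!is.na(nb))
      for (i in hit) parent <- uf_union(parent, i, nb[i])
    }
    lab <- vapply(seq_along(lin), function(i) uf_find(parent, i), integer(1))
  }
  z <- round(tapply(idx[, 1L] - 1, lab, mean))
  y <- round(tapply(idx[, 2L] - 1, lab, mean))
  x <- round(tapply(idx[, 3L] - 1, lab, mean))
  inten <- filtered_volume[cbind(z + 1, y + 1, x + 1)]
  out <- data.frame(channel = channel, x = as.integer(x), y = as.integer(y),
                    z = as.integer(z), intensity = inten)
  if (min_distance > 0 && nrow(out) > 1L) {
    ord <- order(-out$intensity, out$z, out$y, out$x)
    out <- out[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))[-1L]) {
      prev <- which(keep[seq_len(i - 1L)])
      d2 <- (out$x[prev] - out$x[i])^2 + (out$y[prev] - out$y[i])^2 +
        (out$z[prev] - out$z[i])^2
      if (any(d2 < min_distance^2)) keep[i] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(out$z, out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Automated spot-detection threshold from one filtered plane
#'
#' Locates the elbow of the spot-count-vs-threshold curve of a
#' representative filtered z-plane: the point where the steeply decaying
#' branch of noise regional maxima ends and the shallow tail of real spot
#' counts begins. The noise branch is modelled by a Gumbel law for the
#' plane's regional-maximum values — its location and scale estimated from
#' the (noise-dominated) 50th and 75th percentiles, so sparse bright spots
#' do not bias the fit — and the threshold is placed where the expected
#' number of noise maxima above it, extrapolated to `test_multiplier` times
#' the plane's maxima (the full 3D stack), falls to `alpha`. On a pure-noise
#' plane this lands beyond the observed maxima and zero spots are detected.
#' A manually chosen threshold always wins over this automation in the
#' pipeline.
#'
#' @param filtered_plane 2D matrix: one z-plane of the LoG-filtered stack.
#' @param alpha Tolerated expected number of noise (false) spots per stack.
#' @param test_multiplier Ratio of effective tests in the full stack to
#'   regional maxima in the plane (default 30: the z-extent of a stack with
#'   margin).
#' @return Scalar threshold on the filtered-intensity scale.
#' @export
auto_threshold <- function(filtered_plane, alpha = 0.05,
                           test_multiplier = 30) {
  v <- filtered_plane[filtered_plane == boxmax3_2d(filtered_plane) &
                        filtered_plane > 0]
  if (length(v) == 0L || diff(range(filtered_plane)) == 0)
    stop("degenerate plane: no positive maxima; set the threshold manually")
  q <- stats::quantile(v, c(0.5, 0.75), names = FALSE)
  if (q[2L] <= q[1L])
    stop("degenerate plane: regional maxima have no spread; set the threshold manually")
  # Gumbel: quantile(p) = mu - beta * log(-log(p))
  beta <- (q[2L] - q[1L]) / (log(-log(0.5)) - log(-log(0.75)))
  mu <- q[1L] + beta * log(-log(0.5))
  n_tests <- length(v) * test_multiplier
  mu + beta * log(n_tests / alpha)
}
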