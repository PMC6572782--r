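# Seeded synthetic microscopy benchmark: renders four-channel yeast fields
# (TMR/CY5 spot channels, DAPI nuclei, widefield cell outlines) with full
# ground truth, so each pipeline stage can be validated against planted
# geometry and counts without any deposited data.

#' Specify a synthetic scene
#'
#' Defaults emulate the acquisition this pipeline targets: 2048 x 2048
#' planes, 25 z-positions 200 nm apart, four interleaved channels, with
#' yeast-scale cell and nucleus geometry at a 100x / 65 nm-per-pixel
#' magnification. Spot counts per cell follow either a Poisson model
#' (`list(type = "poisson", lambda)`) or a two-state mixture
#' (`list(type = "two_state", p_on, lambda_off, lambda_on)`), one model per
#' spot channel, with a fraction `f_nuc` of molecules placed in the nucleus.
#'
#' The camera model adds a constant offset, variance-matched Gaussian
#' counting noise (sd = sqrt(intensity)) and Gaussian read noise, rounded to
#' integer counts; spot peak amplitude is `snr` times the background noise
#' sd. For scenes meant to test correctness rather than resolution limits,
#' spots respect `min_separation` and nuclear (cytoplasmic) molecules stay
#' well inside (outside) the nuclear boundary.
#'
#' @param field_shape `(n_z, height, width)` in voxels.
#' @param z_step_nm Axial spacing, nanometres.
#' @param n_cells Number of cells to place (excluding border cells).
#' @param n_border_cells Cells planted deliberately overlapping the border
#'   strip, to exercise border filtering.
#' @param cell_radius_range,nucleus_radius_range Semi-axis ranges, pixels.
#' @param spot_model Named list (per spot channel) of count models.
#' @param f_nuc Fraction of molecules placed in the nucleus.
#' @param psf_sigma `(lateral, axial)` Gaussian PSF sigmas, voxels.
#' @param snr Spot peak amplitude over background noise sd.
#' @param background List: `offset` (counts), `read_sd` (counts).
#' @param min_separation Minimum pairwise spot distance per channel, voxels.
#' @param border_margin_px Clearance of valid cells from the image border.
#' @param seed Integer RNG seed; generation is deterministic given the spec.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(field_shape = c(25, 2048, 2048), z_step_nm = 200,
                       n_cells = 200, n_border_cells = 0,
                       cell_radius_range = c(25, 38),
                       nucleus_radius_range = c(10, 15),
                       spot_model = list(
                         TMR = list(type = "poisson", lambda = 5),
                         CY5 = list(type = "poisson", lambda = 5)),
                       f_nuc = 0.2,
                       psf_sigma = c(lateral = 1.5, axial = 1.3),
                       snr = 10,
                       background = list(offset = 100, read_sd = 2),
                       min_separation = 6,
                       border_margin_px = 25,
                       seed = 1L) {
  stopifnot(length(field_shape) == 3L, all(field_shape > 0), snr > 0,
            f_nuc >= 0, f_nuc <= 1, z_step_nm > 0)
  for (m in spot_model) {
    stopifnot(m$type %in% c("poisson", "two_state"))
    if (m$type == "two_state")
      stopifnot(m$p_on >= 0, m$p_on <= 1)
  }
  structure(as.list(environment()), class = "scene_spec")
}

noise_sd <- function(spec)
  sqrt(spec$background$offset + spec$background$read_sd^2)

# camera model: offset + signal + variance-matched counting noise + read
# noise, rounded to non-negative integer counts (compiled streaming pass)
render_camera <- function(signal, spec) {
  out <- cpp_render_camera(signal, spec$background$offset,
                           spec$background$read_sd^2)
  dim(out) <- dim(signal)
  out
}

draw_count <- function(model) {
  switch(model$type,
    poisson = stats::rpois(1L, model$lambda),
    two_state = {
      on <- stats::runif(1L) < model$p_on
      stats::rpois(1L, if (on) model$lambda_on else model$lambda_off)
    })
}

place_cells <- function(spec, ny, nx) {
  cells <- data.frame(cx = numeric(0), cy = numeric(0), rx = numeric(0),
                      ry = numeric(0), border = logical(0))
  tries <- 0L
  want <- spec$n_cells + spec$n_border_cells
  while (nrow(cells) < want) {
    tries <- tries + 1L
    if (tries > 200L * max(want, 1L))
      stop("infeasible packing: could not place ", want, " cells")
    rx <- stats::runif(1, spec$cell_radius_range[1L], spec$cell_radius_range[2L])
    ry <- rx * stats::runif(1, 0.85, 1)
    border_cell <- nrow(cells) >= spec$n_cells
    m <- spec$border_margin_px
    if (border_cell) {
      # centre inside the border strip so the footprint crosses it
      cx <- sample(c(stats::runif(1, 2, m / 2),
                     stats::runif(1, nx - 1 - m / 2, nx - 3)), 1L)
      cy <- stats::runif(1, ry + 2, ny - ry - 3)
    } else {
      cx <- stats::runif(1, rx + m, nx - 1 - rx - m)
      cy <- stats::runif(1, ry + m, ny - 1 - ry - m)
    }
    if (nrow(cells) > 0) {
      dd <- sqrt((cells$cx - cx)^2 + (cells$cy - cy)^2)
      if (any(dd < cells$rx + rx + 3)) next
    }
    cells <- rbind(cells, data.frame(cx = cx, cy = cy, rx = rx, ry = ry,
                                     border = border_cell))
  }
  cells$label <- seq_len(nrow(cells))
  cells
}

#' Generate one synthetic field with ground truth
#'
#' Renders the four channels of a field of view from a [scene_spec()]:
#' ellipsoidal DAPI nuclei, widefield cell interiors on the trailing
#' z-planes, and diffraction-limited spot channels with 3D Gaussian PSFs over
#' noisy background. Deterministic given `spec$seed`.
#'
#' @param spec A [scene_spec()].
#' @return List with `stack` (an [image_stack()], integer camera counts) and
#'   `truth`: data frames `cells` (ellipse parameters), `nuclei` (ellipsoid
#'   parameters), `spots` (continuous and voxel positions, channel,
#'   compartment, cell) and `counts` (per cell x channel nuclear /
#'   cytoplasmic / total).
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    nz <- spec$field_shape[1L]; ny <- spec$field_shape[2L]; nx <- spec$field_shape[3L]
    s_lat <- spec$psf_sigma[[1L]]; s_ax <- spec$psf_sigma[[2L]]
    cells <- place_cells(spec, ny, nx)
    n <- nrow(cells)
    # nuclei: ellipsoids centred on the cell (small jitter), mid-stack in z
    nuc <- data.frame(label = cells$label)
    if (n > 0) {
      rn <- stats::runif(n, spec$nucleus_radius_range[1L], spec$nucleus_radius_range[2L])
      rn <- pmin(rn, 0.55 * pmin(cells$rx, cells$ry))
      nuc$cx <- cells$cx + stats::runif(n, -2, 2)
      nuc$cy <- cells$cy + stats::runif(n, -2, 2)
      nuc$cz <- (nz - 1) / 2 + stats::runif(n, -0.5, 0.5)
      nuc$rx <- rn
      nuc$ry <- rn * stats::runif(n, 0.9, 1)
      nuc$rz <- pmax(1.5, pmin(nz / 4, rn / 2))
    } else {
      nuc$cx <- nuc$cy <- nuc$cz <- nuc$rx <- nuc$ry <- nuc$rz <- numeric(0)
    }
    # ---- spots ------------------------------------------------------------
    spot_channels <- names(spec$spot_model)
    # candidate positions are drawn in vectorized batches per cell; a short
    # greedy pass then accepts candidates respecting min_separation
    draw_candidates <- function(i, m) {
      nucf <- stats::runif(m) < spec$f_nuc
      zc <- yc <- xc <- numeric(m)
      nn <- sum(nucf)
      if (nn > 0) {
        # well inside the nuclear ellipsoid (normalized radius <= 0.55, so
        # voxel rounding cannot push a nuclear molecule over the segmented
        # half-maximum boundary)
        u <- matrix(stats::runif(3L * 4L * nn, -0.55, 0.55), ncol = 3L)
        u <- u[u[, 1L]^2 + u[, 2L]^2 + u[, 3L]^2 <= 0.55^2, , drop = FALSE]
        while (nrow(u) < nn) {
          u2 <- matrix(stats::runif(3L * 4L * nn, -0.55, 0.55), ncol = 3L)
          u <- rbind(u, u2[u2[, 1L]^2 + u2[, 2L]^2 + u2[, 3L]^2 <= 0.55^2, ,
                           drop = FALSE])
        }
        u <- u[seq_len(nn), , drop = FALSE]
        zc[nucf] <- nuc$cz[i] + u[, 1L] * nuc$rz[i]
        yc[nucf] <- nuc$cy[i] + u[, 2L] * nuc$ry[i]
        xc[nucf] <- nuc$cx[i] + u[, 3L] * nuc$rx[i]
      }
      nc <- m - nn
      if (nc > 0) {
        got <- 0L
        gz <- gy <- gx <- numeric(0)
        while (got < nc) {
          a <- stats::runif(4L * nc, 0, 2 * pi)
          r <- sqrt(stats::runif(4L * nc))
          px <- cells$cx[i] + 0.85 * r * cells$rx[i] * cos(a)
          py <- cells$cy[i] + 0.85 * r * cells$ry[i] * sin(a)
          pz <- stats::runif(4L * nc, 1.5, nz - 2.5)
          # stay clearly outside the nucleus (normalized radius >= 1.5)
          nr <- (px - nuc$cx[i])^2 / nuc$rx[i]^2 +
            (py - nuc$cy[i])^2 / nuc$ry[i]^2 +
            (pz - nuc$cz[i])^2 / nuc$rz[i]^2
          ok <- nr >= 1.5^2
          gz <- c(gz, pz[ok]); gy <- c(gy, py[ok]); gx <- c(gx, px[ok])
          got <- length(gz)
        }
        zc[!nucf] <- gz[seq_len(nc)]
        yc[!nucf] <- gy[seq_len(nc)]
        xc[!nucf] <- gx[seq_len(nc)]
      }
      list(nuclear = nucf, zc = zc, yc = yc, xc = xc)
    }
    acc <- vector("list", length(spot_channels))
    names(acc) <- spot_channels
    minsep2 <- spec$min_separation^2
    for (ch in spot_channels) {
      pz <- py <- px <- numeric(0)
      cellv <- integer(0); nucv <- logical(0)
      for (i in seq_len(n)) {
        if (cells$border[i]) next  # border cells carry no planted molecules
        cnt <- draw_count(spec$spot_model[[ch]])
        k <- 0L
        batch <- 0L
        while (k < cnt && batch < 25L) {
          batch <- batch + 1L
          cand <- draw_candidates(i, max(2L * (cnt - k), 8L))
          for (j in seq_along(cand$zc)) {
            if (k >= cnt) break
            zc <- cand$zc[j]; yc <- cand$yc[j]; xc <- cand$xc[j]
            if (length(pz) > 0 &&
                  min((pz - zc)^2 + (py - yc)^2 + (px - xc)^2) < minsep2)
              next
            pz <- c(pz, zc); py <- c(py, yc); px <- c(px, xc)
            cellv <- c(cellv, cells$label[i]); nucv <- c(nucv, cand$nuclear[j])
            k <- k + 1L
          }
        }
      }
      acc[[ch]] <- data.frame(
        channel = rep_len(ch, length(pz)), cell = cellv,
        compartment = ifelse(nucv, "nuclear", "cytoplasmic"),
        zc = pz, yc = py, xc = px)
    }
    spots <- do.call(rbind, c(acc, list(make.row.names = FALSE)))
    if (is.null(spots))
      spots <- data.frame(channel = character(0), cell = integer(0),
                          compartment = character(0), zc = numeric(0),
                          yc = numeric(0), xc = numeric(0))
    spots$z <- as.integer(round(spots$zc))
    spots$y <- as.integer(round(spots$yc))
    spots$x <- as.integer(round(spots$xc))
    # ---- rendering ---------------------------------------------------------
    amp_spot <- spec$snr * noise_sd(spec)
    channels <- list()
    for (ch in spot_channels) {
      sig <- array(0, c(nz, ny, nx))
      sel <- spots[spots$channel == ch, , drop = FALSE]
      # blob windows accumulated in-scope: subassignment stays in place;
      # amplitude is calibrated so the rounded peak voxel reaches exactly
      # snr x background-noise sd despite the sub-voxel centre offset
      for (j in seq_len(nrow(sel))) {
        zc <- sel$zc[j]; yc <- sel$yc[j]; xc <- sel$xc[j]
        zr <- max(1L, floor(zc + 1 - 3 * s_ax)):min(nz, ceiling(zc + 1 + 3 * s_ax))
        yr <- max(1L, floor(yc + 1 - 3 * s_lat)):min(ny, ceiling(yc + 1 + 3 * s_lat))
        xr <- max(1L, floor(xc + 1 - 3 * s_lat)):min(nx, ceiling(xc + 1 + 3 * s_lat))
        gz <- exp(-((zr - 1) - zc)^2 / (2 * s_ax^2))
        gy <- exp(-((yr - 1) - yc)^2 / (2 * s_lat^2))
        gx <- exp(-((xr - 1) - xc)^2 / (2 * s_lat^2))
        pk <- exp(-(round(zc) - zc)^2 / (2 * s_ax^2) -
                    (round(yc) - yc)^2 / (2 * s_lat^2) -
                    (round(xc) - xc)^2 / (2 * s_lat^2))
        sig[zr, yr, xr] <- sig[zr, yr, xr] + (amp_spot / pk) * (gz %o% gy %o% gx)
      }
      channels[[ch]] <- render_camera(sig, spec)
      rm(sig)
    }
    # DAPI: smooth ellipsoidal blobs, intensity 2^(-r^2) of the peak so the
    # half-maximum surface is the nominal nuclear boundary
    amp_dapi <- 40 * noise_sd(spec)
    sig <- array(0, c(nz, ny, nx))
    for (i in seq_len(n)) {
      zr <- max(1L, floor(nuc$cz[i] + 1 - 2.2 * nuc$rz[i])):
        min(nz, ceiling(nuc$cz[i] + 1 + 2.2 * nuc$rz[i]))
      yr <- max(1L, floor(nuc$cy[i] + 1 - 2.2 * nuc$ry[i])):
        min(ny, ceiling(nuc$cy[i] + 1 + 2.2 * nuc$ry[i]))
      xr <- max(1L, floor(nuc$cx[i] + 1 - 2.2 * nuc$rx[i])):
        min(nx, ceiling(nuc$cx[i] + 1 + 2.2 * nuc$rx[i]))
      gz <- 2^(-((zr - 1) - nuc$cz[i])^2 / nuc$rz[i]^2)
      gy <- 2^(-((yr - 1) - nuc$cy[i])^2 / nuc$ry[i]^2)
      gx <- 2^(-((xr - 1) - nuc$cx[i])^2 / nuc$rx[i]^2)
      sig[zr, yr, xr] <- sig[zr, yr, xr] + amp_dapi * (gz %o% gy %o% gx)
    }
    channels$DAPI <- render_camera(sig, spec)
    rm(sig)
    # widefield: bright cell interiors on the trailing 5 planes
    amp_wf <- 12 * noise_sd(spec)
    plane <- matrix(0, ny, nx)
    for (i in seq_len(n)) {
      yr <- max(1L, floor(cells$cy[i] + 1 - cells$ry[i])):
        min(ny, ceiling(cells$cy[i] + 1 + cells$ry[i]))
      xr <- max(1L, floor(cells$cx[i] + 1 - cells$rx[i])):
        min(nx, ceiling(cells$cx[i] + 1 + cells$rx[i]))
      yy <- ((yr - 1) - cells$cy[i]) / cells$ry[i]
      xx <- ((xr - 1) - cells$cx[i]) / cells$rx[i]
      r2 <- outer(yy^2, xx^2, `+`)
      plane[yr, xr] <- plane[yr, xr] + amp_wf * (r2 <= 1) * (1 - 0.3 * r2)
    }
    sig <- array(0, c(nz, ny, nx))
    for (z in max(1L, nz - 4L):nz) sig[z, , ] <- plane
    channels$WIDEFIELD <- render_camera(sig, spec)
    rm(sig)
    channels <- channels[intersect(CHANNEL_ROLES, names(channels))]
    stack <- image_stack(channels, z_step_nm = spec$z_step_nm,
                         source_id = sprintf("synthetic_seed%d", spec$seed))
    # ---- ground-truth counts ----------------------------------------------
    valid <- cells$label[!cells$border]
    counts <- expand.grid(cell = valid, channel = spot_channels,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cnt1 <- function(cell, channel, comp)
      sum(spots$cell == cell & spots$channel == channel &
            spots$compartment == comp)
    if (nrow(counts) > 0 && nrow(spots) > 0) {
      counts$nuclear <- mapply(cnt1, counts$cell, counts$channel, "nuclear")
      counts$cytoplasmic <- mapply(cnt1, counts$cell, counts$channel,
                                   "cytoplasmic")
    } else {
      counts$nuclear <- integer(nrow(counts))
      counts$cytoplasmic <- integer(nrow(counts))
    }
    counts$total <- counts$nuclear + counts$cytoplasmic
    list(stack = stack,
         truth = list(cells = cells, nuclei = nuc, spots = spots,
                      counts = counts))
  })
}

#' Generate a manifest-driven synthetic experiment
#'
#' One scene per (timepoint, field), with per-field seeds derived
#' deterministically from the base seed so fields are distinct but the whole
#' experiment is reproducible.
#'
#' @param manifest One row of [read_manifest()] output, or a list with
#'   `timepoints_min` (numeric vector).
#' @param spec_per_timepoint Function `(timepoint) -> scene_spec`, or a list
#'   keyed by timepoint (as character).
#' @param fields_per_timepoint Stacks per timepoint.
#' @param base_seed Base RNG seed.
#' @return List of elements `list(timepoint, field, stack, truth, seed)`.
#' @export
generate_experiment <- function(manifest, spec_per_timepoint,
                                fields_per_timepoint = 2L, base_seed = 1L) {
  tps <- if (is.data.frame(manifest)) manifest$timepoints_min[[1L]]
         else manifest$timepoints_min
  out <- list()
  for (ti in seq_along(tps)) {
    tp <- tps[ti]
    base <- if (is.function(spec_per_timepoint)) spec_per_timepoint(tp)
            else spec_per_timepoint[[as.character(tp)]]
    if (is.null(base)) stop("no scene spec for timepoint ", tp)
    for (f in seq_len(fields_per_timepoint)) {
      sp <- base
      sp$seed <- (base_seed * 1009L + ti * 131L + f) %% 2147483647L
      fld <- generate_field(sp)
      out[[length(out) + 1L]] <-
        list(timepoint = tp, field = f, seed = sp$seed,
             stack = fld$stack, truth = fld$truth)
    }
  }
  out
}

#' Match segmented cells to planted ground-truth cells
#'
#' Pairs each segmented cell label with the planted cell whose centre is
#' nearest to the segmented centroid (within `max_dist`), giving the label
#' alignment needed to compare pipeline counts against ground truth (the
#' two labelings enumerate cells in different orders).
#'
#' @param records Morphology data frame from [measure_cells()].
#' @param truth_cells `truth$cells` from [generate_field()].
#' @param max_dist Maximum centre distance in pixels for a valid match.
#' @return Data frame `label` (segmented), `truth_label`, `dist`; unmatched
#'   segmented cells get `truth_label = NA`.
#' @export
match_to_truth <- function(records, truth_cells, max_dist = 10) {
  if (nrow(records) == 0L)
    return(data.frame(label = integer(0), truth_label = integer(0),
                      dist = numeric(0)))
  out <- lapply(seq_len(nrow(records)), function(i) {
    dd <- sqrt((truth_cells$cx - records$centroid_x[i])^2 +
                 (truth_cells$cy - records$centroid_y[i])^2)
    j <- which.min(dd)
    data.frame(label = records$label[i],
               truth_label = if (dd[j] <= max_dist) truth_cells$label[j] else NA_integer_,
               dist = dd[j])
  })
  do.call(rbind, out)
}
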