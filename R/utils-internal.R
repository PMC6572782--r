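# Internal helpers shared across modules: connected-component labeling with
# full diagonal connectivity, separable axis filtering, box maximum filters,
# and scoped RNG. None of these are exported.

#' @importFrom EBImage bwlabel
NULL

## ---- union-find -----------------------------------------------------------

uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

uf_union <- function(parent, a, b) {
  ra <- uf_find(parent, a)
  rb <- uf_find(parent, b)
  if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  parent
}

# Merge label equivalences given two equally-shaped integer label arrays of
# candidate pairs (a[i], b[i]) with zeros meaning background.
uf_merge_pairs <- function(parent, a, b) {
  keep <- a > 0L & b > 0L & a != b
  if (!any(keep)) return(parent)
  n <- length(parent)
  code <- unique(as.numeric(a[keep]) * (n + 1) + as.numeric(b[keep]))
  pa <- as.integer(code %/% (n + 1))
  pb <- as.integer(code %% (n + 1))
  for (i in seq_along(code)) parent <- uf_union(parent, pa[i], pb[i])
  parent
}

## ---- connected components -------------------------------------------------

# 2D labeling with 8-connectivity. EBImage::bwlabel is 4-connected, so
# diagonal-only contacts are merged afterwards with union-find.
label2d <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n < 2L) return(lab)
  parent <- seq_len(n)
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs: (r, c) vs (r + 1, c + 1) and (r + 1, c - 1)
  parent <- uf_merge_pairs(parent, lab[-nr, -nc], lab[-1L, -1L])
  parent <- uf_merge_pairs(parent, lab[-nr, -1L], lab[-1L, -nc])
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

# 3D labeling with 26-connectivity on a (z, y, x) mask array. Each z-slice is
# labeled in 2D, then slice labels are merged across adjacent planes over the
# nine (dy, dx) in {-1, 0, 1}^2 shifts.
label3d <- function(mask) {
  d <- dim(mask)
  if (length(d) != 3L) stop("label3d() expects a 3D (z, y, x) array")
  nz <- d[1L]; ny <- d[2L]; nx <- d[3L]
  out <- array(0L, d)
  offset <- 0L
  for (z in seq_len(nz)) {
    sl <- label2d(matrix(mask[z, , ] != 0, ny, nx))
    sl[sl > 0L] <- sl[sl > 0L] + offset
    offset <- offset + max(0L, max(sl))
    out[z, , ] <- sl
  }
  n <- offset
  if (n < 2L || nz < 2L) {
    return(relabel_consecutive(out))
  }
  parent <- seq_len(n)
  shifts <- expand.grid(dy = -1L:1L, dx = -1L:1L)
  for (z in seq_len(nz - 1L)) {
    a0 <- matrix(out[z, , ], ny, nx)
    b0 <- matrix(out[z + 1L, , ], ny, nx)
    for (s in seq_len(nrow(shifts))) {
      dy <- shifts$dy[s]; dx <- shifts$dx[s]
      ya <- max(1L, 1L + dy):min(ny, ny + dy)
      xa <- max(1L, 1L + dx):min(nx, nx + dx)
      yb <- ya - dy; xb <- xa - dx
      parent <- uf_merge_pairs(parent, a0[ya, xa], b0[yb, xb])
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  relab <- match(roots, sort(unique(roots)))
  pos <- out > 0L
  out[pos] <- relab[out[pos]]
  relabel_consecutive(out)
}

# Renumber positive labels to consecutive 1..K preserving order of appearance
# by label value.
relabel_consecutive <- function(lab) {
  u <- sort(unique(lab[lab > 0L]))
  if (length(u) == 0L) return(lab)
  lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

## ---- separable filtering --------------------------------------------------

# Apply a 1D kernel along one axis of a 3D (z, y, x) array with replicate
# boundary handling (out-of-range taps clamp to the edge). Compiled kernel.
filter_axis <- function(vol, kernel, axis) {
  d <- dim(vol)
  ai <- match(axis, c("z", "y", "x")) - 1L
  array(cpp_filter_axis(as.numeric(vol), as.integer(d), kernel, ai), d)
}

gauss_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Sampled second derivative of a Gaussian, corrected to sum exactly to zero
# so a constant signal yields an exactly zero response.
gauss_d2_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- (-radius):radius
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- (x^2 - sigma^2) / sigma^4 * g
  k - mean(k)
}

## ---- box maximum ----------------------------------------------------------

# Maximum over the 3x3x3 neighbourhood (separable running max per axis).
boxmax3 <- function(vol) {
  d <- dim(vol)
  array(cpp_boxmax3(as.numeric(vol), as.integer(d)), d)
}

# 2D variant via a singleton z axis.
boxmax3_2d <- function(img) {
  v <- array(img, c(1L, nrow(img), ncol(img)))
  matrix(boxmax3(v)[1L, , ], nrow(img), ncol(img))
}

## ---- RNG scoping ----------------------------------------------------------

# Run an expression under a local seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
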