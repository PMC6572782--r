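# Population statistics over per-cell transcript counts: mean expression,
# ON-fraction against a basal cumulative cutoff, Fano factor, marginal and
# joint nuclear-cytoplasmic distributions, replicate aggregation, and
# two-sample Kolmogorov-Smirnov comparisons.

#' Basal ON/OFF threshold from the pre-stress sample
#'
#' Expression before the osmotic-stress step is taken as basal; the ON
#' threshold T is the smallest integer such that at least `coverage` of the
#' basal (t = 0) cells have counts <= T. A cell is then ON iff its count
#' exceeds T (so T = 2 means ON = "more than two molecules").
#'
#' @param basal_counts Non-negative integer counts of the t = 0 sample.
#' @param coverage Cumulative fraction of the basal distribution to enclose.
#' @return Integer threshold T.
#' @export
basal_on_threshold <- function(basal_counts, coverage = 0.95) {
  if (length(basal_counts) == 0L) stop("empty basal sample")
  stopifnot(all(basal_counts >= 0), coverage > 0, coverage <= 1)
  sup <- 0:max(basal_counts)
  cum <- vapply(sup, function(t) mean(basal_counts <= t), numeric(1))
  sup[match(TRUE, cum >= coverage)]
}

#' Fraction of ON cells
#'
#' @param counts Integer counts, one per cell.
#' @param T ON threshold: a cell is ON iff `count > T`.
#' @return Fraction in `[0, 1]`.
#' @export
on_fraction <- function(counts, T) {
  if (length(counts) == 0L) stop("empty count vector")
  stopifnot(T >= 0)
  mean(counts > T)
}

#' Fano factor of a count distribution
#'
#' Variance divided by the mean; 1 for a Poisson process, above 1 for bursty
#' transcription. The default variance convention is the population variance
#' (divide by N); set `var_convention = "sample"` for N - 1.
#'
#' @param counts Integer counts.
#' @param var_convention `"population"` (default) or `"sample"`.
#' @return Fano factor, or `NA` when the mean is zero (undefined).
#' @export
fano <- function(counts, var_convention = c("population", "sample")) {
  if (length(counts) == 0L) stop("empty count vector")
  var_convention <- match.arg(var_convention)
  m <- mean(counts)
  if (m == 0) return(NA_real_)
  n <- length(counts)
  if (n == 1L) return(0)
  v <- stats::var(counts)
  if (var_convention == "population") v <- v * (n - 1) / n
  v / m
}

#' Marginal count distribution
#'
#' Empirical probability mass over the support `0..max(counts)`.
#'
#' @param counts Non-negative integer counts.
#' @return Named probability vector (names `"0"`, `"1"`, ...), summing to 1.
#' @export
marginal_distribution <- function(counts) {
  if (length(counts) == 0L) stop("empty count vector")
  stopifnot(all(counts >= 0))
  sup <- 0:max(counts)
  p <- tabulate(counts + 1L, nbins = max(counts) + 1L) / length(counts)
  setNames(p, sup)
}

#' Joint nuclear-cytoplasmic count distribution
#'
#' Empirical joint probability mass over per-cell (nuclear, cytoplasmic)
#' count pairs. Rows index the nuclear count 0..max, columns the cytoplasmic
#' count; row and column sums reproduce the two marginal distributions
#' exactly.
#'
#' @param nuclear,cytoplasmic Paired integer vectors (same cells, same
#'   order).
#' @return Probability matrix, dimnames the integer counts.
#' @export
joint_distribution <- function(nuclear, cytoplasmic) {
  if (length(nuclear) != length(cytoplasmic))
    stop("nuclear and cytoplasmic vectors must be paired (equal length)")
  if (length(nuclear) == 0L) stop("empty count vectors")
  stopifnot(all(nuclear >= 0), all(cytoplasmic >= 0))
  tab <- table(factor(nuclear, levels = 0:max(nuclear)),
               factor(cytoplasmic, levels = 0:max(cytoplasmic)))
  m <- unclass(tab) / length(nuclear)
  dimnames(m) <- list(nuclear = 0:max(nuclear), cytoplasmic = 0:max(cytoplasmic))
  m
}

#' Summarize one condition / gene / timepoint
#'
#' Bundles the per-cell counts of one (condition, gene, timepoint) cell
#' population into the statistics reported per timepoint.
#'
#' @param total,nuclear,cytoplasmic Per-cell counts; `total` defaults to
#'   `nuclear + cytoplasmic` when both are given.
#' @param on_threshold ON threshold T (see [basal_on_threshold()]).
#' @param condition,gene,timepoint Labels carried through.
#' @param var_convention Passed to [fano()].
#' @return An `expression_summary`: list with the labels, `n_cells`, `mean`,
#'   `fano`, `on_fraction`, `on_threshold`, `marginal`, and (when nuclear and
#'   cytoplasmic counts are available) `joint`.
#' @export
summarize_expression <- function(total = NULL, nuclear = NULL,
                                 cytoplasmic = NULL, on_threshold,
                                 condition = "", gene = "", timepoint = NA,
                                 var_convention = "population") {
  if (is.null(total)) {
    if (is.null(nuclear) || is.null(cytoplasmic))
      stop("supply `total` or both `nuclear` and `cytoplasmic`")
    total <- nuclear + cytoplasmic
  }
  out <- list(condition = condition, gene = gene, timepoint = timepoint,
              n_cells = length(total), mean = mean(total),
              fano = fano(total, var_convention),
              on_fraction = on_fraction(total, on_threshold),
              on_threshold = as.integer(on_threshold),
              marginal = marginal_distribution(total))
  if (!is.null(nuclear) && !is.null(cytoplasmic))
    out$joint <- joint_distribution(nuclear, cytoplasmic)
  structure(out, class = "expression_summary")
}

#' @export
print.expression_summary <- function(x, ...) {
  cat(sprintf("expression_summary %s/%s t=%s: n=%d mean=%.3f fano=%.3f on=%.3f (T=%d)\n",
              x$condition, x$gene, format(x$timepoint), x$n_cells, x$mean,
              x$fano, x$on_fraction, x$on_threshold))
  invisible(x)
}

#' Aggregate statistics across biological replicas
#'
#' Takes one timepoint series per biological replica, aligns them by
#' timepoint, and reports, per statistic and timepoint, the across-replica
#' mean and standard deviation (sample convention, n - 1; `NA` for a single
#' replica). Replicas whose timepoint sets differ cannot be aligned and are
#' refused.
#'
#' @param replicas List with one element per biological replica; each
#'   element is a list of [summarize_expression()] results (one per
#'   timepoint), or a single summary (treated as a one-timepoint series).
#' @return Data frame with one row per timepoint: `timepoint`,
#'   `n_replicas`, and `<stat>_mean` / `<stat>_sd` for `mean`, `on_fraction`,
#'   `fano`.
#' @export
aggregate_replicates <- function(replicas) {
  if (length(replicas) == 0L) stop("no replicas supplied")
  replicas <- lapply(replicas, function(r)
    if (inherits(r, "expression_summary")) list(r) else r)
  tp_of <- function(r) sort(vapply(r, function(s) as.numeric(s$timepoint),
                                   numeric(1)))
  tps <- tp_of(replicas[[1L]])
  for (r in replicas[-1L]) {
    if (!isTRUE(all.equal(tp_of(r), tps)))
      stop("alignment error: replicas do not cover the same timepoints")
  }
  rows <- lapply(tps, function(tp) {
    g <- lapply(replicas, function(r)
      r[[which(vapply(r, function(s) as.numeric(s$timepoint), numeric(1)) == tp)[1L]]])
    one <- function(stat) vapply(g, function(s) s[[stat]], numeric(1))
    sd_or_na <- function(v) if (length(v) > 1L) stats::sd(v) else NA_real_
    data.frame(timepoint = tp, n_replicas = length(g),
               mean_mean = mean(one("mean")), mean_sd = sd_or_na(one("mean")),
               on_fraction_mean = mean(one("on_fraction")),
               on_fraction_sd = sd_or_na(one("on_fraction")),
               fano_mean = mean(one("fano")), fano_sd = sd_or_na(one("fano")))
  })
  out <- do.call(rbind, rows)
  out[order(out$timepoint), , drop = FALSE]
}

#' Two-sample Kolmogorov-Smirnov comparison of count distributions
#'
#' D = sup |ECDF_a - ECDF_b| with the asymptotic p-value (no continuity
#' correction). Counts are discrete, so ties are expected and the p-value is
#' approximate (conservative); D itself is exact.
#'
#' @param sample_a,sample_b Integer count vectors.
#' @return List with `statistic` (D) and `p_value`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop("empty sample")
  res <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}
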