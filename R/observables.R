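#' Vegetative intervals between heterocysts
#'
#' Lengths of maximal runs of vegetative cells bounded by heterocysts on
#' BOTH sides.  Runs touching a filament end are excluded: the pattern's
#' fingerprint is the between-heterocyst spacing, and end runs have no
#' second bound.
#'
#' @param filament a [Filament] object, or a logical heterocyst vector.
#' @return Integer vector of interval lengths (possibly empty).
#' @examples
#' vegetativeIntervals(c(TRUE, FALSE, FALSE, TRUE, FALSE))  # 2
#' @export
vegetativeIntervals <- function(filament) {
  het <- if (is(filament, "Filament")) filament@het else as.logical(filament)
  r <- rle(het)
  veg <- which(!r$values)
  interior <- veg[veg > 1L & veg < length(r$values)]
  as.integer(r$lengths[interior])
}

#' Heterocyst percentage of a filament
#'
#' @param filament a [Filament] object, or a logical heterocyst vector.
#' @return `100 * heterocysts / cells`.
#' @export
heterocystPercentage <- function(filament) {
  het <- if (is(filament, "Filament")) filament@het else as.logical(filament)
  if (!length(het)) stop("empty filament")
  100 * mean(het)
}

#' Sizes of contiguous-heterocyst clusters
#'
#' @param filament a [Filament] object, or a logical heterocyst vector.
#' @return A table of maximal run lengths of consecutive heterocysts
#'   (empty when there are none).
#' @examples
#' clusterSizes(c(TRUE, TRUE, FALSE, TRUE))  # one 2-cluster, one 1-cluster
#' @export
clusterSizes <- function(filament) {
  het <- if (is(filament, "Filament")) filament@het else as.logical(filament)
  r <- rle(het)
  table(factor(r$lengths[r$values]))
}

#' Contiguous heterocysts at the filament ends
#'
#' The length of the heterocyst run starting at the first cell plus the
#' length of the run ending at the last cell.  A filament that is entirely
#' heterocysts counts all its cells once.
#'
#' @param filament a [Filament] object, or a logical heterocyst vector.
#' @return Integer count.
#' @export
terminalHeterocystCount <- function(filament) {
  het <- if (is(filament, "Filament")) filament@het else as.logical(filament)
  n <- length(het)
  if (!n || !any(het)) return(0L)
  if (all(het)) return(n)
  lead <- match(FALSE, het) - 1L
  trail <- match(FALSE, rev(het)) - 1L
  as.integer(lead + trail)
}

#' Mean HetR over vegetative cells
#'
#' @param filament a [Filament] object.
#' @return Mean HetR concentration of the vegetative cells (NA if none).
#' @export
meanVegetativeHetR <- function(filament) {
  stopifnot(is(filament, "Filament"))
  veg <- !filament@het
  if (!any(veg)) return(NA_real_)
  mean(filament@conc[veg, "R"])
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' The supremum over x of the absolute difference between the two empirical
#' cumulative distribution functions, computed on the raw samples (not on
#' binned histograms, avoiding bin-edge artifacts).
#'
#' @param sampleA,sampleB nonempty numeric vectors.
#' @return The KS statistic in `[0, 1]`.
#' @examples
#' ksDistance(c(1, 2), c(1, 3))  # 0.5
#' @export
ksDistance <- function(sampleA, sampleB) {
  if (!length(sampleA) || !length(sampleB))
    stop("ksDistance: both samples must be nonempty")
  unname(suppressWarnings(stats::ks.test(sampleA, sampleB))$statistic)
}

#' Pattern statistics of one filament
#'
#' @param filament a [Filament] object.
#' @return A [PatternSummary] object.
#' @export
summarizePattern <- function(filament) {
  stopifnot(is(filament, "Filament"))
  iv <- vegetativeIntervals(filament)
  new("PatternSummary",
      intervals = as.numeric(iv),
      m = if (length(iv)) mean(iv) else NA_real_,
      p = heterocystPercentage(filament),
      cluster_histogram = clusterSizes(filament),
      terminal_count = as.numeric(terminalHeterocystCount(filament)),
      mean_R_veg = meanVegetativeHetR(filament))
}

setMethod("show", "PatternSummary", function(object) {
  cat(sprintf(
    "PatternSummary: m = %.2f, p = %.2f%%, terminal = %.0f, mean veg HetR = %.3f\n",
    object@m, object@p, object@terminal_count, object@mean_R_veg))
  invisible(object)
})

#' Batch-aggregated pattern statistics at a given time
#'
#' Filaments (the snapshots of the given trajectories nearest to `time_h`)
#' are pooled within each batch: intervals and heterocyst/cell counts are
#' aggregated, then the batch-level mean interval `m`, heterocyst
#' percentage `p`, mean terminal count and mean vegetative HetR are
#' computed.  Means and sample (n-1) standard deviations are then taken
#' across batches, mirroring replicate-based experimental error bars.
#'
#' @param trajectories list of [Trajectory] objects.
#' @param time_h filament age at which to take statistics (h).
#' @param batch integer vector assigning each trajectory to a batch
#'   (default: all in one batch).
#' @return A [BatchResult] object.
#' @export
batchStatistics <- function(trajectories, time_h,
                            batch = rep(1L, length(trajectories))) {
  stopifnot(length(trajectories) >= 1L,
            length(batch) == length(trajectories))
  ub <- sort(unique(batch))
  rows <- vector("list", length(ub))
  pooled <- vector("list", length(ub))
  for (i in seq_along(ub)) {
    fs <- lapply(trajectories[batch == ub[i]], snapshotAt, time_h = time_h)
    if (!length(fs)) stop("empty batch ", ub[i])
    iv <- unlist(lapply(fs, vegetativeIntervals))
    nhet <- sum(vapply(fs, function(f) sum(f@het), numeric(1)))
    ncell <- sum(vapply(fs, nCells, numeric(1)))
    term <- mean(vapply(fs, terminalHeterocystCount, integer(1)))
    rveg <- vapply(fs, meanVegetativeHetR, numeric(1))
    rows[[i]] <- data.frame(
      batch = ub[i],
      m = if (length(iv)) mean(iv) else NA_real_,
      p = 100 * nhet / ncell,
      terminal = term,
      mean_R_veg = mean(rveg, na.rm = TRUE),
      n_cells = ncell / sum(batch == ub[i]))
    pooled[[i]] <- as.numeric(iv)
  }
  per <- do.call(rbind, rows)
  stat_cols <- c("m", "p", "terminal", "mean_R_veg", "n_cells")
  mu <- vapply(stat_cols, function(cn) mean(per[[cn]], na.rm = TRUE),
               numeric(1))
  sdv <- vapply(stat_cols, function(cn) {
    v <- per[[cn]][!is.na(per[[cn]])]
    if (length(v) > 1) stats::sd(v) else 0
  }, numeric(1))
  new("BatchResult", per_batch = per, mean = mu, sd = sdv,
      intervals = pooled, time_h = time_h)
}

setMethod("show", "BatchResult", function(object) {
  cat(sprintf("BatchResult at t = %g h over %d batches\n",
              object@time_h, nrow(object@per_batch)))
  df <- data.frame(mean = signif(object@mean, 4), sd = signif(object@sd, 3))
  print(df)
  invisible(object)
})
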