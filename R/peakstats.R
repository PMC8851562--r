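## Ranked analysis of peak accessibility: RPKM, low-count filtering,
## replicate averaging, signed/absolute ranking, equal-sized binning and
## top-N selection.

#' RPKM normalization of a PeakSet
#'
#' `rpkm[i, s] = counts[i, s] / (width_kb_i * lib_size_s / 1e6)`.  Library
#' sizes come from the sample metadata (total mapped reads), not from the
#' in-peak counts.
#'
#' @param ps a [PeakSet-class].
#' @return Numeric matrix, peaks x samples.
#' @export
rpkm <- function(ps) {
  w <- width(rowRanges(ps))
  if (any(w <= 0)) .stopf("zero-width peak at row %d", which(w <= 0)[1])
  cnt <- assay(ps, "counts")
  denom <- outer(w / 1e3, librarySizes(ps) / 1e6)
  cnt / denom
}

#' Remove peaks with low total raw counts
#'
#' Retains peaks whose raw counts summed over all samples reach `min_total`;
#' order is preserved and attrition is logged.
#'
#' @param ps a [PeakSet-class].
#' @param min_total minimum summed raw count (default 10).
#' @return The filtered [PeakSet-class].
#' @export
filterLowCount <- function(ps, min_total = 10) {
  stopifnot(min_total >= 0)
  keep <- rowSums(assay(ps, "counts")) >= min_total
  .log("filterLowCount: kept %d of %d peaks (min_total=%g)",
       sum(keep), length(keep), min_total)
  ps[keep, ]
}

.condition_means <- function(ps, condition, value = c("rpkm", "raw")) {
  value <- match.arg(value)
  cond <- sampleConditions(ps)
  if (!condition %in% cond)
    .stopf("unknown condition label '%s' (have: %s)", condition,
           paste(unique(cond), collapse = ", "))
  m <- if (value == "rpkm") rpkm(ps) else assay(ps, "counts")
  rowMeans(m[, cond == condition, drop = FALSE])
}

#' Rank peaks by accessibility difference between two conditions
#'
#' Replicates within each condition are averaged (RPKM by default, raw mean
#' counts optionally), and peaks ordered by the difference
#' `mean(condition_b) - mean(condition_a)`.  Signed mode sorts ascending, so
#' the largest loss in `condition_b` comes first and the largest gain last;
#' absolute mode sorts by `|difference|` descending.  Ties break by peak id
#' (C-locale lexicographic), making the order fully deterministic.
#'
#' @param ps a [PeakSet-class].
#' @param condition_a reference condition (e.g. `"WT"`).
#' @param condition_b comparison condition (e.g. `"KO"`).
#' @param mode `"signed"` or `"absolute"`.
#' @param value `"rpkm"` (default) or `"raw"` average counts.
#' @return A `data.frame` with columns `peak_id`, `mean_a`, `mean_b`, `diff`
#'   in rank order; attributes `mode`, `value`, `conditions`.
#' @export
rankPeaks <- function(ps, condition_a = "WT", condition_b = "KO",
                      mode = c("signed", "absolute"),
                      value = c("rpkm", "raw")) {
  mode <- match.arg(mode); value <- match.arg(value)
  ma <- .condition_means(ps, condition_a, value)
  mb <- .condition_means(ps, condition_b, value)
  d <- mb - ma
  ids <- peakIds(ps)
  o <- if (mode == "signed") order(d, ids, method = "radix")
       else order(-abs(d), ids, method = "radix")
  rk <- data.frame(peak_id = ids[o], mean_a = unname(ma[o]),
                   mean_b = unname(mb[o]), diff = unname(d[o]),
                   stringsAsFactors = FALSE)
  attr(rk, "mode") <- mode
  attr(rk, "value") <- value
  attr(rk, "conditions") <- c(a = condition_a, b = condition_b)
  rk
}

#' Partition ranked peaks into equal-sized contiguous bins
#'
#' The number of bins is `floor(n / bin_size)` (at least 1); peaks are
#' assigned contiguously in rank order with bin sizes differing by at most
#' one (the remainder is spread over the leading bins).
#'
#' @param ranked output of [rankPeaks].
#' @param bin_size target peaks per bin.
#' @return `ranked` with added integer columns `rank` and `bin`; attribute
#'   `bin_sizes` gives the realized sizes.
#' @export
binPeaks <- function(ranked, bin_size) {
  n <- nrow(ranked)
  if (n == 0) .stopf("cannot bin an empty ranked list")
  stopifnot(bin_size >= 1)
  n_bins <- max(1L, n %/% as.integer(bin_size))
  base <- n %/% n_bins
  rem <- n %% n_bins
  sizes <- rep(base, n_bins) + rep(c(1L, 0L), c(rem, n_bins - rem))
  ranked$rank <- seq_len(n)
  ranked$bin <- rep(seq_len(n_bins), sizes)
  attr(ranked, "bin_sizes") <- sizes
  .log("binPeaks: %d peaks -> %d bins of %d-%d", n, n_bins, min(sizes), max(sizes))
  ranked
}

#' Select the top-N loss or gain peaks
#'
#' @param ranked output of [rankPeaks] (any mode; selection always uses the
#'   signed difference).
#' @param n number of peaks to select.
#' @param direction `"loss"` (most negative differences) or `"gain"`.
#' @return Character vector of peak ids, most extreme first.
#' @export
topN <- function(ranked, n, direction = c("loss", "gain")) {
  direction <- match.arg(direction)
  if (n > nrow(ranked))
    .stopf("requested top %d peaks but only %d are ranked", n, nrow(ranked))
  o <- if (direction == "loss")
    order(ranked$diff, ranked$peak_id, method = "radix")
  else
    order(-ranked$diff, ranked$peak_id, method = "radix")
  ranked$peak_id[o[seq_len(n)]]
}

## position lookup into a sparse per-base track --------------------------------

.track_index <- function(track) {
  parts <- split(track[c("pos", "count")], track$chrom)
  parts <- lapply(parts, function(p) p[order(p$pos), ])
  function(chrom, positions) {
    p <- parts[[chrom]]
    v <- numeric(length(positions))
    if (is.null(p)) return(v)
    i <- findInterval(positions, p$pos)
    hit <- i > 0
    hit[hit] <- p$pos[i[hit]] == positions[hit]
    v[hit] <- p$count[i[hit]]
    v
  }
}

#' Average signal profile around region summits
#'
#' Resamples a per-base signal track onto a fixed grid centered on each
#' region's summit (the interval midpoint), scaled to counts per million of
#' the whole track, and averages across regions.  Grid positions outside the
#' chromosome bounds are clipped to `NA` with a warning and ignored in the
#' average.
#'
#' @param track per-base track (`data.frame` chrom, pos, count) as read by
#'   [readCutTrack].
#' @param regions `GRanges` of regions (named).
#' @param flank half-width of the window around each summit (bp).
#' @param n_points number of grid points (default `2 * flank + 1`, i.e.
#'   single-base resolution).
#' @param seq_lengths optional named vector of chromosome lengths used for
#'   bounds clipping.
#' @return List with `positions` (grid offsets), `profile` (average curve)
#'   and `matrix` (regions x grid) for plotting.
#' @export
signalProfile <- function(track, regions, flank = 1000, n_points = NULL,
                          seq_lengths = NULL) {
  if (is.null(n_points)) n_points <- 2 * flank + 1
  grid <- as.integer(round(seq(-flank, flank, length.out = n_points)))
  lookup <- .track_index(track)
  scale <- 1e6 / max(1, sum(track$count))
  mids <- (start(regions) + end(regions)) %/% 2L
  chroms <- as.character(seqnames(regions))
  mat <- matrix(NA_real_, length(regions), n_points,
                dimnames = list(names(regions), grid))
  clipped <- FALSE
  for (i in seq_along(regions)) {
    pos <- mids[i] + grid
    ok <- pos >= 1
    if (!is.null(seq_lengths) && chroms[i] %in% names(seq_lengths))
      ok <- ok & pos <= seq_lengths[[chroms[i]]]
    if (!all(ok)) clipped <- TRUE
    v <- rep(NA_real_, n_points)
    v[ok] <- lookup(chroms[i], pos[ok]) * scale
    mat[i, ] <- v
  }
  if (clipped) warning("some regions extend past chromosome bounds; clipped")
  list(positions = grid, profile = colMeans(mat, na.rm = TRUE), matrix = mat)
}
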