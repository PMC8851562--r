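## Simplified TF footprinting: aggregate per-base cut counts around motif
## occurrences per condition and score the protection dip over the motif
## span relative to the outer flanks.

#' Genomic spans of motif hits inside peaks
#'
#' Converts within-peak hit offsets (from [occurrenceMatrix]) to genomic
#' motif spans using the peak intervals.
#'
#' @param hits hit table (`peak_id`, `motif_id`, `start`, `strand`).
#' @param peaks named `GRanges` of the peaks the offsets refer to.
#' @param motif_length motif width in bases.
#' @return `GRanges` of motif spans with strand and `motif_id`, `peak_id`
#'   metadata.
#' @export
occurrenceRanges <- function(hits, peaks, motif_length) {
  i <- match(hits$peak_id, names(peaks))
  if (anyNA(i))
    .stopf("hit refers to unknown peak(s): %s",
           paste(head(unique(hits$peak_id[is.na(i)]), 5), collapse = ", "))
  gstart <- start(peaks)[i] + hits$start - 1L
  GRanges(seqnames(peaks)[i],
          IRanges(gstart, gstart + motif_length - 1L),
          strand = hits$strand, motif_id = hits$motif_id,
          peak_id = hits$peak_id)
}

#' Aggregate a cut-site track around motif occurrences
#'
#' Extracts the per-base cut counts in a window of `+/- window` bp around
#' each occurrence's center, orients each vector by the hit strand (minus
#' strand vectors are reversed), sums across sites and normalizes by the
#' total cuts in all aggregated windows, so the profile sums to 1 (a uniform
#' track gives a flat profile at `1 / (2 * window + 1)`).
#'
#' @param cuts per-base track (`data.frame` chrom, pos, count), e.g. from
#'   [readCutTrack] or [simulateCutSites].
#' @param occurrences `GRanges` of motif spans (see [occurrenceRanges]).
#' @param window half-width in bp (default 100).
#' @param condition condition label stored on the profile.
#' @param motif_id motif id stored on the profile (default: from the
#'   occurrences).
#' @param seq_lengths optional chromosome lengths; occurrences whose window
#'   leaves the chromosome are an error.
#' @return A [FootprintProfile-class].
#' @export
aggregateFootprint <- function(cuts, occurrences, window = 100,
                               condition = "NA", motif_id = NULL,
                               seq_lengths = NULL) {
  if (!length(occurrences)) .stopf("no occurrences to aggregate")
  if (is.null(motif_id))
    motif_id <- as.character(mcols(occurrences)$motif_id[1])
  centers <- (start(occurrences) + end(occurrences)) %/% 2L
  chroms <- as.character(seqnames(occurrences))
  if (any(centers - window < 1))
    .stopf("occurrence window extends below position 1")
  if (!is.null(seq_lengths)) {
    lim <- seq_lengths[chroms]
    if (any(!is.na(lim) & centers + window > lim))
      .stopf("occurrence window extends past the chromosome end")
  }
  lookup <- .track_index(cuts)
  grid <- seq.int(-window, window)
  mat <- matrix(0, length(occurrences), length(grid))
  neg <- as.character(strand(occurrences)) == "-"
  for (i in seq_along(occurrences)) {
    v <- lookup(chroms[i], centers[i] + grid)
    mat[i, ] <- if (neg[i]) rev(v) else v
  }
  total <- sum(mat)
  if (total <= 0) .stopf("zero total cuts in aggregated windows; cannot normalize")
  w <- max(1L, as.integer(end(occurrences)[1] - start(occurrences)[1] + 1L))
  new("FootprintProfile", motif_id = motif_id, condition = condition,
      positions = as.integer(grid), rate = colSums(mat) / total,
      site_matrix = mat, motif_length = w)
}

.profile_depth <- function(rate, positions, motif_length, flank) {
  w <- max(positions)
  half <- (motif_length - 1L) %/% 2L
  in_motif <- abs(positions) <= half
  in_flank <- abs(positions) > w - flank
  fl <- mean(rate[in_flank])
  if (fl <= 0) return(NA_real_)
  1 - mean(rate[in_motif]) / fl
}

#' Protection depth per condition and condition difference
#'
#' Depth is `1 - mean in-motif rate / mean flank rate`, where the in-motif
#' span is `+/- floor((motif_length - 1) / 2)` around the center (always
#' inside the occupied span on either strand) and the flank is
#' the outer `flank` bp per side (default: outer 25% of the window).  The
#' difference is `depth(a) - depth(b)`; a bootstrap CI over sites is
#' attached.
#'
#' @param profile_a,profile_b [FootprintProfile-class] objects for the same
#'   motif on the same grid.
#' @param flank flank width per side (default `0.25 * window`).
#' @param n_boot bootstrap replicates (default 200; 0 disables).
#' @return List with `motif_id`, `depth_a`, `depth_b`, `difference`,
#'   `ci_lo`, `ci_hi`, `conditions`.
#' @export
protectionScore <- function(profile_a, profile_b, flank = NULL, n_boot = 200) {
  if (!identical(profile_a@positions, profile_b@positions))
    .stopf("footprint profiles are on different grids")
  if (!identical(profile_a@motif_id, profile_b@motif_id))
    .stopf("footprint profiles are for different motifs")
  w <- max(profile_a@positions)
  if (is.null(flank)) flank <- max(1L, as.integer(round(0.25 * w)))
  len <- profile_a@motif_length
  da <- .profile_depth(profile_a@rate, profile_a@positions, len, flank)
  db <- .profile_depth(profile_b@rate, profile_b@positions, len, flank)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boot_depth <- function(pr) {
      m <- pr@site_matrix
      idx <- sample.int(nrow(m), nrow(m), replace = TRUE)
      r <- colSums(m[idx, , drop = FALSE])
      tot <- sum(r)
      if (tot <= 0) return(NA_real_)
      .profile_depth(r / tot, pr@positions, len, flank)
    }
    bs <- vapply(seq_len(n_boot),
                 function(i) boot_depth(profile_a) - boot_depth(profile_b), 0)
    ci <- quantile(bs, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  }
  list(motif_id = profile_a@motif_id, depth_a = da, depth_b = db,
       difference = da - db, ci_lo = ci[1], ci_hi = ci[2],
       conditions = c(a = profile_a@condition, b = profile_b@condition))
}
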