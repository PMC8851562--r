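## PWM scanning and the ranked-bin enrichment landscape.  Scores are log2
## odds against the motif background; a position is a hit when its score on
## either strand reaches `score_fraction` of the motif's maximum achievable
## score.  Enrichment per bin is the one-sided hypergeometric upper tail of
## the motif-bearing peak count, with all binned peaks as background.

.BASE_CODE <- local({
  tab <- rep(NA_integer_, 127)
  tab[utf8ToInt("A")] <- 1L; tab[utf8ToInt("C")] <- 2L
  tab[utf8ToInt("G")] <- 3L; tab[utf8ToInt("T")] <- 4L
  tab[utf8ToInt("N")] <- 5L
  tab[utf8ToInt("a")] <- 1L; tab[utf8ToInt("c")] <- 2L
  tab[utf8ToInt("g")] <- 3L; tab[utf8ToInt("t")] <- 4L
  tab[utf8ToInt("n")] <- 5L
  tab
})

.encode_seq <- function(seq) {
  codes <- .BASE_CODE[utf8ToInt(as.character(seq))]
  if (anyNA(codes)) .stopf("sequence contains characters outside {A,C,G,T,N}")
  codes
}

## log-odds with an extra all -Inf row so that N kills any window
.log_odds5 <- function(pwm) {
  lo <- log2(pwmMatrix(pwm) / pwmBackground(pwm))
  rbind(lo, N = rep(-Inf, ncol(lo)))
}

.rc_matrix <- function(m) m[4:1, rev(seq_len(ncol(m))), drop = FALSE]

.scan_codes <- function(codes, lo5, threshold) {
  w <- ncol(lo5)
  L <- length(codes)
  if (L < w) return(integer(0))
  n_off <- L - w + 1L
  s <- numeric(n_off)
  for (j in seq_len(w))
    s <- s + lo5[cbind(codes[j:(j + n_off - 1L)], j)]
  which(s >= threshold & is.finite(s))
}

.scan_scores <- function(codes, lo5) {
  w <- ncol(lo5); L <- length(codes)
  if (L < w) return(numeric(0))
  n_off <- L - w + 1L
  s <- numeric(n_off)
  for (j in seq_len(w))
    s <- s + lo5[cbind(codes[j:(j + n_off - 1L)], j)]
  s
}

#' Scan one sequence with a PWM
#'
#' Computes the log2-odds score of the PWM at every offset on both strands
#' and reports positions scoring at least `score_fraction` of the maximum
#' achievable score.  `N` bases score `-Inf`.  A sequence shorter than the
#' motif yields an empty hit list.
#'
#' @param sequence a `DNAString`, `DNAStringSet` element or character scalar.
#' @param pwm a [PWMotif-class].
#' @param score_fraction fraction of the maximum log-odds score required
#'   (default 0.8).
#' @return `data.frame` with `start` (1-based offset of the match on the
#'   forward sequence), `strand`, `score`, sorted by position.
#' @export
scanPWM <- function(sequence, pwm, score_fraction = 0.8) {
  codes <- .encode_seq(sequence)
  lo5 <- .log_odds5(pwm)
  max_score <- sum(apply(lo5[1:4, , drop = FALSE], 2, max))
  if (max_score <= 0) .stopf("degenerate PWM: maximum log-odds score <= 0")
  thr <- score_fraction * max_score
  fwd <- .scan_scores(codes, lo5)
  rev_lo <- .rc_matrix(lo5[1:4, , drop = FALSE])
  rev_lo <- rbind(rev_lo, rep(-Inf, ncol(rev_lo)))
  rev <- .scan_scores(codes, rev_lo)
  hit_f <- which(fwd >= thr & is.finite(fwd))
  hit_r <- which(rev >= thr & is.finite(rev))
  out <- data.frame(
    start = c(hit_f, hit_r),
    strand = rep(c("+", "-"), c(length(hit_f), length(hit_r))),
    score = c(fwd[hit_f], rev[hit_r]),
    stringsAsFactors = FALSE)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' OccurrenceMatrix: motif presence across peak sequences
#'
#' @slot presence logical matrix, peaks x motifs: motif present at one or
#'   more positions above threshold on either strand.
#' @slot hits `data.frame` of individual hits (`peak_id`, `motif_id`,
#'   `start`, `strand`, `score`).
#' @slot score_fraction the threshold fraction used.
#' @export
setClass("OccurrenceMatrix",
         representation(presence = "matrix", hits = "data.frame",
                        score_fraction = "numeric"))

setValidity("OccurrenceMatrix", function(object) {
  if (!is.logical(object@presence)) return("presence must be logical")
  TRUE
})

#' @describeIn OccurrenceMatrix Logical presence matrix (peaks x motifs).
#' @param x an `OccurrenceMatrix`.
#' @export
occPresence <- function(x) x@presence

#' @describeIn OccurrenceMatrix Individual hit table.
#' @export
occHits <- function(x) x@hits

setMethod("show", "OccurrenceMatrix", function(object) {
  cat(sprintf("OccurrenceMatrix: %d peaks x %d motifs, %d hits (fraction %.2f)\n",
              nrow(object@presence), ncol(object@presence),
              nrow(object@hits), object@score_fraction))
})

#' Scan a sequence set against a PWM library
#'
#' @param sequences `DNAStringSet` named by peak id (duplicate ids are an
#'   error).
#' @param pwms a [PWMotifList-class].
#' @param score_fraction hit threshold as a fraction of each motif's maximum
#'   score (default 0.8).
#' @param required_ids optional peak ids that must all have a sequence;
#'   missing ones raise an error listing the ids.
#' @return An [OccurrenceMatrix-class].
#' @export
occurrenceMatrix <- function(sequences, pwms, score_fraction = 0.8,
                             required_ids = NULL) {
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids))
    .stopf("sequences must be uniquely named by peak id")
  if (!is.null(required_ids)) {
    missing <- setdiff(required_ids, ids)
    if (length(missing))
      .stopf("missing sequence for peak(s): %s",
             paste(head(missing, 5), collapse = ", "))
  }
  codes_list <- lapply(as.character(sequences), function(s) .BASE_CODE[utf8ToInt(s)])
  if (any(vapply(codes_list, anyNA, TRUE)))
    .stopf("sequence contains characters outside {A,C,G,T,N}")
  presence <- matrix(FALSE, length(ids), length(pwms),
                     dimnames = list(ids, names(pwms)))
  hits <- vector("list", length(pwms))
  for (mi in seq_along(pwms)) {
    pwm <- pwms[[mi]]
    lo5 <- .log_odds5(pwm)
    max_score <- sum(apply(lo5[1:4, , drop = FALSE], 2, max))
    thr <- score_fraction * max_score
    rev_lo <- rbind(.rc_matrix(lo5[1:4, , drop = FALSE]),
                    rep(-Inf, ncol(lo5)))
    mh <- vector("list", length(ids))
    for (si in seq_along(codes_list)) {
      f <- .scan_codes(codes_list[[si]], lo5, thr)
      r <- .scan_codes(codes_list[[si]], rev_lo, thr)
      if (length(f) || length(r)) {
        presence[si, mi] <- TRUE
        mh[[si]] <- data.frame(
          peak_id = ids[si], motif_id = pwmId(pwm),
          start = c(f, r),
          strand = rep(c("+", "-"), c(length(f), length(r))),
          stringsAsFactors = FALSE)
      }
    }
    hits[[mi]] <- do.call(rbind, mh[!vapply(mh, is.null, TRUE)])
  }
  hits <- do.call(rbind, hits[!vapply(hits, is.null, TRUE)])
  if (is.null(hits))
    hits <- data.frame(peak_id = character(), motif_id = character(),
                       start = integer(), strand = character(),
                       stringsAsFactors = FALSE)
  .log("occurrenceMatrix: %d peaks x %d motifs, %d hits",
       length(ids), length(pwms), nrow(hits))
  new("OccurrenceMatrix", presence = presence, hits = hits,
      score_fraction = score_fraction)
}

#' Per-bin hypergeometric motif enrichment across the ranked landscape
#'
#' For each motif and rank bin, computes the one-sided hypergeometric upper
#' tail p-value for the number of motif-bearing peaks in the bin, drawing
#' `n = bin size` peaks from a population of all binned peaks (`N` total,
#' `K` motif-bearing).  Entries are `-log10 p`.
#'
#' @param occ an [OccurrenceMatrix-class] covering all binned peaks.
#' @param bins output of [binPeaks].
#' @return Numeric matrix, motifs x bins, of `-log10` p-values.
#' @export
binEnrichment <- function(occ, bins) {
  pres <- occPresence(occ)
  unknown <- setdiff(bins$peak_id, rownames(pres))
  if (length(unknown))
    .stopf("bin references unknown peak(s): %s",
           paste(head(unknown, 5), collapse = ", "))
  pres <- pres[bins$peak_id, , drop = FALSE]
  N <- nrow(pres)
  K <- colSums(pres)
  bin_ids <- sort(unique(bins$bin))
  E <- matrix(0, ncol(pres), length(bin_ids),
              dimnames = list(colnames(pres), as.character(bin_ids)))
  for (b in seq_along(bin_ids)) {
    in_bin <- bins$bin == bin_ids[b]
    n <- sum(in_bin)
    k <- colSums(pres[in_bin, , drop = FALSE])
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    E[, b] <- -log10(pmax(p, .Machine$double.xmin))
  }
  E
}

#' Similarity of two PWMs
#'
#' Maximum Pearson correlation of aligned probability columns over all
#' ungapped offsets with at least `min_overlap` overlapping columns,
#' considering both `b` and its reverse complement.  Symmetric; identical
#' PWMs (or a PWM and its reverse complement) score 1.
#'
#' @param a,b [PWMotif-class] objects.
#' @param min_overlap minimum overlapping columns (default 4).
#' @return Similarity score in `[-1, 1]`.
#' @export
pwmSimilarity <- function(a, b, min_overlap = 4) {
  pa <- pwmMatrix(a)
  best <- -Inf
  for (pb in list(pwmMatrix(b), .rc_matrix(pwmMatrix(b)))) {
    La <- ncol(pa); Lb <- ncol(pb)
    if (min(La, Lb) < min_overlap) next
    for (s in seq(-(Lb - min_overlap), La - min_overlap)) {
      ia <- max(1, s + 1):min(La, s + Lb)
      ib <- ia - s
      va <- as.vector(pa[, ia, drop = FALSE])
      vb <- as.vector(pb[, ib, drop = FALSE])
      if (sd(va) == 0 || sd(vb) == 0) next
      best <- max(best, cor(va, vb))
    }
  }
  if (!is.finite(best))
    .stopf("PWMs too short for the minimum overlap of %d columns", min_overlap)
  best
}

## single-linkage closure of a boolean adjacency within one family
.connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

#' Filter the enrichment landscape and merge similar same-family motifs
#'
#' Drops motifs that are never enriched (no bin reaching `-log10 p >=
#' enrich_min`) or not changing across bins (`max - min < change_min`), then
#' merges motifs sharing a family label whose pairwise PWM similarity
#' exceeds `similarity_threshold`, by single-linkage closure.  A merged
#' row is the per-bin best (elementwise maximum of `-log10 p`).
#'
#' @param E enrichment matrix from [binEnrichment].
#' @param pwms the [PWMotifList-class] the matrix was computed from.
#' @param similarity_threshold merge threshold (default 0.90).
#' @param enrich_min,change_min filter thresholds in `-log10 p` units
#'   (defaults 3 and 1).
#' @return List with `scores` (merged matrix), `members` (list of member
#'   motif ids per merged row) and `flags` (per-motif filter flags).
#' @export
filterAndMerge <- function(E, pwms, similarity_threshold = 0.90,
                           enrich_min = 3, change_min = 1) {
  mx <- apply(E, 1, max)
  mn <- apply(E, 1, min)
  flags <- data.frame(motif_id = rownames(E),
                      enriched_anywhere = mx >= enrich_min,
                      changing = (mx - mn) >= change_min,
                      stringsAsFactors = FALSE)
  keep <- flags$enriched_anywhere & flags$changing
  .log("filterAndMerge: %d of %d motifs pass filters", sum(keep), nrow(E))
  Ek <- E[keep, , drop = FALSE]
  if (!nrow(Ek))
    return(list(scores = Ek, members = list(), flags = flags))
  fam <- vapply(pwms[rownames(Ek)], pwmFamily, "")
  rows <- list(); members <- list()
  for (f in unique(fam)) {
    ids <- rownames(Ek)[fam == f]
    if (length(ids) == 1L) {
      grp <- 1L
    } else {
      adj <- diag(length(ids)) > 0
      for (i in seq_along(ids)) for (j in seq_along(ids)) if (i < j) {
        s <- pwmSimilarity(pwms[[ids[i]]], pwms[[ids[j]]])
        adj[i, j] <- adj[j, i] <- s > similarity_threshold
      }
      grp <- .connected_components(adj)
    }
    for (g in unique(grp)) {
      gi <- ids[grp == g]
      nm <- if (length(gi) == 1L) gi else sprintf("%s/%d", f, g)
      rows[[nm]] <- apply(Ek[gi, , drop = FALSE], 2, max)
      members[[nm]] <- gi
    }
  }
  scores <- do.call(rbind, rows)
  colnames(scores) <- colnames(E)
  list(scores = scores, members = members, flags = flags)
}

#' Motif enrichment in a peak subset against a background
#'
#' One-sided hypergeometric test per motif for over-representation of
#' motif-bearing peaks in `subset` relative to `background`, with fold
#' enrichment (subset frequency / background frequency) and BH q-values.
#'
#' @param occ an [OccurrenceMatrix-class].
#' @param subset peak ids (must be contained in `background`).
#' @param background peak ids forming the population.
#' @return `data.frame` sorted by ascending p with columns `motif_id`, `k`,
#'   `n`, `K`, `N`, `fold`, `p`, `q`.
#' @export
subsetEnrichment <- function(occ, subset, background = rownames(occPresence(occ))) {
  if (!length(subset)) .stopf("empty subset")
  if (length(setdiff(subset, background)))
    .stopf("subset must be contained in the background")
  pres <- occPresence(occ)
  unknown <- setdiff(background, rownames(pres))
  if (length(unknown))
    .stopf("unknown peak id(s): %s", paste(head(unknown, 5), collapse = ", "))
  Pb <- pres[background, , drop = FALSE]
  Ps <- pres[subset, , drop = FALSE]
  N <- length(background); n <- length(subset)
  K <- colSums(Pb); k <- colSums(Ps)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- ifelse(K > 0, (k / n) / (K / N), NA_real_)
  out <- data.frame(motif_id = colnames(pres), k = k, n = n, K = K, N = N,
                    fold = fold, p = p, q = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  out[order(out$p, out$motif_id), , drop = FALSE]
}

#' Family co-occurrence across a peak subset
#'
#' Counts, for every family pair, the subset peaks carrying both families
#' (a family is present when any member motif is present); the diagonal
#' holds per-family counts.  A Jaccard-index version is emitted alongside.
#'
#' @param occ an [OccurrenceMatrix-class].
#' @param subset peak ids.
#' @param families named list of member motif ids per family (e.g. the
#'   `members` element of [filterAndMerge]).
#' @return List with `counts` (family x family), `jaccard` and
#'   `peak_families` (list of family sets per peak).
#' @export
motifCooccurrence <- function(occ, subset, families) {
  pres <- occPresence(occ)[subset, , drop = FALSE]
  fp <- vapply(families, function(ids)
    rowSums(pres[, intersect(ids, colnames(pres)), drop = FALSE]) > 0,
    logical(length(subset)))
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = length(subset))
  colnames(fp) <- names(families)
  counts <- crossprod(fp)
  union <- outer(diag(counts), diag(counts), "+") - counts
  jacc <- ifelse(union > 0, counts / union, NA_real_)
  peak_families <- apply(fp, 1, function(r) names(families)[r], simplify = FALSE)
  list(counts = counts, jaccard = jacc, peak_families = peak_families)
}
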