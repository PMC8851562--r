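suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
  library(Biostrings)
})

## small in-code fixtures --------------------------------------------------

tiny_peakset <- function() {
  gr <- GRanges("chr1", IRanges(c(101, 1001, 5001), width = c(1000, 500, 200)))
  names(gr) <- c("pkA", "pkB", "pkC")
  counts <- matrix(c(10, 12, 4, 6,
                     50, 55, 20, 25,
                     5, 6, 5, 7), nrow = 3, byrow = TRUE,
                   dimnames = list(names(gr),
                                   c("WT_1", "WT_2", "KO_1", "KO_2")))
  PeakSet(gr, counts, condition = c("WT", "WT", "KO", "KO"),
          lib_size = rep(1e6, 4))
}

tiny_genes <- function() {
  g <- GRanges("chr1", IRanges(c(2000, 12000), c(8000, 20000)),
               strand = c("+", "-"))
  names(g) <- c("gA", "gB")
  ex <- GRangesList(
    gA = GRanges("chr1", IRanges(c(2000, 5000), c(3000, 8000)), strand = "+"),
    gB = GRanges("chr1", IRanges(c(12000, 18000), c(14000, 20000)),
                 strand = "-"))
  GeneModels(g, ex)
}

random_peakset <- function(n, n_samples = 4, seed = 1) {
  set.seed(seed)
  starts <- sort(sample.int(1e6, n))
  gr <- GRanges("chr1", IRanges(starts, width = sample(200:900, n, TRUE)))
  names(gr) <- sprintf("p%05d", seq_len(n))
  counts <- matrix(rnbinom(n * n_samples, mu = 30, size = 5), n,
                   dimnames = list(names(gr),
                                   c(sprintf("WT_%d", seq_len(n_samples / 2)),
                                     sprintf("KO_%d", seq_len(n_samples / 2)))))
  PeakSet(gr, counts,
          condition = rep(c("WT", "KO"), each = n_samples / 2),
          lib_size = runif(n_samples, 5e5, 2e6))
}

random_pwm <- function(id, len, seed = 1, family = id) {
  set.seed(seed)
  m <- matrix(runif(4 * len, 0.05, 1), 4)
  m <- sweep(m, 2, colSums(m), "/")
  PWMotif(id, m, family = family, is_counts = FALSE)
}

random_dna <- function(len, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

## independent brute-force oracles -----------------------------------------

# per-offset log-odds recomputation, both strands, plain loops
bf_scan <- function(seq, pwm, score_fraction) {
  chars <- strsplit(toupper(seq), "")[[1]]
  p <- pwmMatrix(pwm)
  bg <- pwmBackground(pwm)
  L <- ncol(p)
  if (length(chars) < L)
    return(data.frame(start = integer(), strand = character(),
                      score = numeric()))
  lo <- log2(p / bg)
  max_score <- sum(apply(lo, 2, max))
  thr <- score_fraction * max_score
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- list()
  for (st in c("+", "-")) {
    for (i in seq_len(length(chars) - L + 1)) {
      win <- chars[i:(i + L - 1)]
      if (st == "-") win <- rev(comp[win])
      if (any(win == "N")) next
      s <- sum(vapply(seq_len(L), function(j) lo[win[j], j], 0))
      if (s >= thr)
        out[[length(out) + 1]] <- data.frame(start = i, strand = st,
                                             score = s)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), strand = character(),
                      score = numeric()))
  res <- do.call(rbind, out)
  res[order(res$start, res$strand), , drop = FALSE]
}

# all-pairs feature classification at the midpoint, plain loops
bf_annotate <- function(peaks, genes, cfg) {
  g <- geneRanges(genes)
  ex <- exonRanges(genes)
  out <- character(length(peaks))
  for (i in seq_along(peaks)) {
    mid <- (start(peaks)[i] + end(peaks)[i]) %/% 2
    chr <- as.character(seqnames(peaks)[i])
    cls <- "intergenic"
    in_prom <- in_tts <- in_exon <- in_span <- FALSE
    for (k in seq_along(g)) {
      if (as.character(seqnames(g)[k]) != chr) next
      plus <- as.character(strand(g)[k]) == "+"
      tss <- mcols(g)$tss[k]
      tts <- if (plus) end(g)[k] else start(g)[k]
      pw <- if (plus) c(tss - cfg@promoter_upstream,
                        tss + cfg@promoter_downstream)
            else c(tss - cfg@promoter_downstream, tss + cfg@promoter_upstream)
      if (mid >= pw[1] && mid <= pw[2]) in_prom <- TRUE
      if (mid >= tts - cfg@tts_window && mid <= tts + cfg@tts_window)
        in_tts <- TRUE
      e <- ex[[names(g)[k]]]
      if (any(mid >= start(e) & mid <= end(e))) in_exon <- TRUE
      if (mid >= start(g)[k] && mid <= end(g)[k]) in_span <- TRUE
    }
    if (in_prom) cls <- "promoter"
    else if (in_tts) cls <- "TTS"
    else if (in_exon) cls <- "exon"
    else if (in_span) cls <- "intron"
    out[i] <- cls
  }
  out
}

# nearest TSS by absolute midpoint distance, ties -> smaller gene id
bf_nearest_gene <- function(peaks, genes) {
  g <- geneRanges(genes)
  vapply(seq_along(peaks), function(i) {
    chr <- as.character(seqnames(peaks)[i])
    sel <- which(as.character(seqnames(g)) == chr)
    if (!length(sel)) return(NA_character_)
    mid <- (start(peaks)[i] + end(peaks)[i]) %/% 2
    d <- abs(mid - mcols(g)$tss[sel])
    cand <- sel[d == min(d)]
    sort(names(g)[cand])[1]
  }, "")
}

# all-offset Pearson similarity, plain loops
bf_similarity <- function(a, b, min_overlap = 4) {
  rc <- function(m) m[4:1, rev(seq_len(ncol(m))), drop = FALSE]
  best <- -Inf
  pa <- pwmMatrix(a)
  for (pb in list(pwmMatrix(b), rc(pwmMatrix(b)))) {
    for (s in -(ncol(pb)):(ncol(pa))) {
      ia <- intersect(seq_len(ncol(pa)), s + seq_len(ncol(pb)))
      if (length(ia) < min_overlap) next
      ib <- ia - s
      best <- max(best, cor(as.vector(pa[, ia]), as.vector(pb[, ib])))
    }
  }
  best
}
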