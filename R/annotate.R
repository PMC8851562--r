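## Genomic-feature annotation of peaks: every peak gets exactly one feature
## class (promoter > TTS > exon > intron > intergenic, decided at the peak
## midpoint) and one nearest gene (nearest TSS by absolute midpoint distance,
## ties to the lexicographically smaller gene id).

.peak_midpoints <- function(gr) (start(gr) + end(gr)) %/% 2L

.promoter_windows <- function(gm, upstream, downstream) {
  g <- geneRanges(gm)
  tss <- mcols(g)$tss
  plus <- as.character(strand(g)) == "+"
  st <- ifelse(plus, tss - upstream, tss - downstream)
  en <- ifelse(plus, tss + downstream, tss + upstream)
  GRanges(seqnames(g), IRanges(pmax(1, st), en), strand = strand(g),
          gene_id = names(g))
}

.tts_windows <- function(gm, win) {
  g <- geneRanges(gm)
  plus <- as.character(strand(g)) == "+"
  tts <- ifelse(plus, end(g), start(g))
  GRanges(seqnames(g), IRanges(pmax(1, tts - win), tts + win),
          strand = strand(g), gene_id = names(g))
}

#' Annotate peaks with feature class and nearest gene
#'
#' Classifies each peak at its midpoint with precedence
#' promoter > TTS > exon > intron > intergenic, where the promoter window is
#' `-promoter_upstream / +promoter_downstream` around the TSS on the gene
#' strand and the TTS window is `+/- tts_window` around the gene 3' end.
#' The nearest gene is the gene with the closest TSS to the peak midpoint
#' (absolute distance; ties go to the lexicographically smaller gene id) and
#' the signed distance is negative upstream of the TSS on the gene strand.
#' With an empty gene list every peak is intergenic with `NA` distance.
#'
#' @param peaks a [PeakSet-class] or named `GRanges`.
#' @param genes a [GeneModels-class].
#' @param config an [AnalysisConfig-class] supplying the windows.
#' @return `data.frame` with columns `peak_id`, `feature_class`,
#'   `nearest_gene`, `tss_distance`.
#' @export
annotatePeaks <- function(peaks, genes, config = analysisConfig()) {
  gr <- if (is(peaks, "PeakSet")) rowRanges(peaks) else peaks
  ids <- names(gr)
  mids <- .peak_midpoints(gr)
  pts <- GRanges(seqnames(gr), IRanges(mids, mids))
  n <- length(gr)
  cls <- rep("intergenic", n)
  nearest_gene <- rep(NA_character_, n)
  tss_dist <- rep(NA_real_, n)
  if (length(genes) > 0) {
    g <- geneRanges(genes)
    prom <- .promoter_windows(genes, config@promoter_upstream,
                              config@promoter_downstream)
    tts <- .tts_windows(genes, config@tts_window)
    ex <- unlist(exonRanges(genes), use.names = FALSE)
    hit <- function(subject) overlapsAny(pts, subject, ignore.strand = TRUE)
    in_prom <- hit(prom)
    in_tts <- hit(tts)
    in_exon <- hit(ex)
    in_span <- hit(g)
    cls[in_span] <- "intron"
    cls[in_exon] <- "exon"
    cls[in_tts] <- "TTS"
    cls[in_prom] <- "promoter"
    ## nearest TSS per chromosome; duplicate TSS positions collapse to the
    ## lexicographically smallest gene id so tie-breaking is well defined
    tss_all <- data.frame(chrom = as.character(seqnames(g)),
                          pos = mcols(g)$tss, gene_id = names(g),
                          plus = as.character(strand(g)) == "+",
                          stringsAsFactors = FALSE)
    tss_all <- tss_all[order(tss_all$chrom, tss_all$pos, tss_all$gene_id,
                             method = "radix"), ]
    tss_all <- tss_all[!duplicated(tss_all[c("chrom", "pos")]), ]
    by_chr <- split(tss_all, tss_all$chrom)
    pk_chr <- as.character(seqnames(gr))
    for (chr in unique(pk_chr)) {
      tb <- by_chr[[chr]]
      sel <- which(pk_chr == chr)
      if (is.null(tb)) next
      i <- findInterval(mids[sel], tb$pos)
      left <- pmax(i, 1L)
      right <- pmin(i + 1L, nrow(tb))
      dl <- abs(mids[sel] - tb$pos[left])
      dr <- abs(mids[sel] - tb$pos[right])
      dl[i < 1L] <- Inf
      use_left <- dl < dr |
        (dl == dr & tb$gene_id[left] <= tb$gene_id[right])
      j <- ifelse(use_left, left, right)
      nearest_gene[sel] <- tb$gene_id[j]
      tss_dist[sel] <- ifelse(tb$plus[j], mids[sel] - tb$pos[j],
                              tb$pos[j] - mids[sel])
    }
  } else {
    .log("annotatePeaks: empty gene list; all peaks intergenic")
  }
  data.frame(peak_id = ids, feature_class = cls,
             nearest_gene = nearest_gene, tss_distance = tss_dist,
             stringsAsFactors = FALSE)
}

#' Feature-class distribution of a peak subset
#'
#' @param annotations output of [annotatePeaks].
#' @param subset peak ids (default: all annotated peaks).
#' @return `data.frame` with `feature_class`, `count`, `proportion`
#'   (proportions sum to 1 over the subset).
#' @export
featureDistribution <- function(annotations, subset = annotations$peak_id) {
  unknown <- setdiff(subset, annotations$peak_id)
  if (length(unknown))
    .stopf("unknown peak id(s): %s", paste(head(unknown, 5), collapse = ", "))
  lev <- c("promoter", "exon", "intron", "TTS", "intergenic")
  cl <- annotations$feature_class[match(subset, annotations$peak_id)]
  counts <- table(factor(cl, levels = lev))
  data.frame(feature_class = lev, count = as.integer(counts),
             proportion = as.numeric(counts) / length(subset),
             stringsAsFactors = FALSE)
}

#' Histogram of absolute TSS distances
#'
#' Bins `|tss_distance|` into half-open bins `[lo, hi)`; defaults reproduce
#' the within-1-kb / 1-10 kb / >10 kb split.
#'
#' @param annotations output of [annotatePeaks].
#' @param subset peak ids.
#' @param breaks strictly increasing break points in bp; an implicit `Inf`
#'   closes the last bin.
#' @return `data.frame` with `bin` labels and `count`.
#' @export
tssDistanceHistogram <- function(annotations, subset = annotations$peak_id,
                                 breaks = c(0, 1000, 10000)) {
  if (is.unsorted(breaks, strictly = TRUE))
    .stopf("breaks must be strictly increasing")
  d <- abs(annotations$tss_distance[match(subset, annotations$peak_id)])
  edges <- c(breaks, Inf)
  idx <- findInterval(d, edges)   # half-open [lo, hi)
  labs <- paste0("[", edges[-length(edges)], ",", edges[-1], ")")
  counts <- tabulate(idx, nbins = length(labs))
  data.frame(bin = labs, count = counts, stringsAsFactors = FALSE)
}

#' Peaks assigned to a gene, and genes for a peak subset
#'
#' Proximity is the nearest-gene assignment from [annotatePeaks]: each peak
#' maps to exactly one gene, so `genesForPeaks` is the transpose of
#' `peaksNearGene`.
#'
#' @param gene_id a gene id present in the annotations.
#' @param annotations output of [annotatePeaks].
#' @return `peaksNearGene`: character vector of peak ids;
#'   `genesForPeaks`: character vector of unique gene ids.
#' @export
peaksNearGene <- function(gene_id, annotations) {
  if (!gene_id %in% annotations$nearest_gene)
    .stopf("gene id '%s' is not the nearest gene of any peak", gene_id)
  annotations$peak_id[!is.na(annotations$nearest_gene) &
                        annotations$nearest_gene == gene_id]
}

#' @rdname peaksNearGene
#' @param subset peak ids.
#' @export
genesForPeaks <- function(annotations, subset) {
  unknown <- setdiff(subset, annotations$peak_id)
  if (length(unknown))
    .stopf("unknown peak id(s): %s", paste(head(unknown, 5), collapse = ", "))
  g <- annotations$nearest_gene[match(subset, annotations$peak_id)]
  unique(g[!is.na(g)])
}

#' Mean accessibility change across gene bodies, by DE class
#'
#' For each gene, averages the per-peak RPKM difference (condition_b minus
#' condition_a) over all peaks overlapping the gene span extended by the
#' promoter window; summarizes the per-gene values within each DE class
#' (mean, median, bootstrap CI).  Genes with no overlapping peaks are
#' excluded and counted in the log.
#'
#' @param ps a [PeakSet-class].
#' @param genes a [GeneModels-class].
#' @param de_classes `data.frame` with `gene_id`, `class`
#'   (down/up/unchanged), e.g. from [classifyDE].
#' @param condition_a,condition_b condition labels (difference is b - a).
#' @param config an [AnalysisConfig-class].
#' @param n_boot bootstrap replicates for the class CI (default 500).
#' @return List with `gene_values` (per-gene `data.frame`) and `summary`
#'   (per-class mean, median, 95% CI, n).
#' @export
geneBodyAccessibility <- function(ps, genes, de_classes,
                                  condition_a = "WT", condition_b = "KO",
                                  config = analysisConfig(), n_boot = 500) {
  g <- geneRanges(genes)
  plus <- as.character(strand(g)) == "+"
  ext_start <- ifelse(plus, start(g) - config@promoter_upstream,
                      start(g) - config@promoter_downstream)
  ext_end <- ifelse(plus, end(g) + config@promoter_downstream,
                    end(g) + config@promoter_upstream)
  span <- GRanges(seqnames(g), IRanges(pmax(1, ext_start), ext_end))
  d <- .condition_means(ps, condition_b) - .condition_means(ps, condition_a)
  ov <- findOverlaps(span, rowRanges(ps), ignore.strand = TRUE)
  vals <- tapply(d[subjectHits(ov)], names(g)[queryHits(ov)], mean)
  skipped <- setdiff(names(g), names(vals))
  if (length(skipped))
    .log("geneBodyAccessibility: %d gene(s) without overlapping peaks excluded",
         length(skipped))
  gv <- data.frame(gene_id = names(vals), mean_diff = as.numeric(vals),
                   stringsAsFactors = FALSE)
  gv$class <- de_classes$class[match(gv$gene_id, de_classes$gene_id)]
  gv <- gv[!is.na(gv$class), ]
  summ <- do.call(rbind, lapply(split(gv$mean_diff, gv$class), function(v) {
    if (length(v) >= 2 && n_boot > 0) {
      bs <- vapply(seq_len(n_boot),
                   function(i) mean(sample(v, length(v), replace = TRUE)), 0)
      ci <- quantile(bs, c(0.025, 0.975), names = FALSE)
    } else ci <- c(NA_real_, NA_real_)
    data.frame(mean = mean(v), median = median(v),
               ci_lo = ci[1], ci_hi = ci[2], n = length(v))
  }))
  summ$class <- rownames(summ)
  rownames(summ) <- NULL
  list(gene_values = gv, summary = summ[, c("class", "mean", "median",
                                            "ci_lo", "ci_hi", "n")])
}
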