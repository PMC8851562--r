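## Cross-dataset integration: binding/expression cross-tabulation,
## accessibility at binding sites, large-loss flagging, the four-segment
## regulatory-mode classifier and its per-segment summaries.

#' Classify genes by differential-expression call
#'
#' `down` when `log2fc < -lfc_threshold` and `padj < alpha`; `up` mirrored;
#' otherwise `unchanged`.  `NA` adjusted p counts as not significant.
#'
#' @param de a [DETable-class].
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param lfc_threshold absolute log2FC gate (default 0: significance alone).
#' @return `data.frame` with `gene_id`, `class`; attribute `contrast`.
#' @export
classifyDE <- function(de, alpha = 0.05, lfc_threshold = 0) {
  stopifnot(alpha > 0, alpha < 1)
  tb <- deTable(de)
  sig <- !is.na(tb$padj) & tb$padj < alpha
  cls <- rep("unchanged", nrow(tb))
  cls[sig & tb$log2fc < -lfc_threshold] <- "down"
  cls[sig & tb$log2fc > lfc_threshold] <- "up"
  out <- data.frame(gene_id = tb$gene_id, class = cls, stringsAsFactors = FALSE)
  attr(out, "contrast") <- deContrast(de)
  out
}

#' Assign binding sites to genes
#'
#' Under the default `"span"` rule, a site belongs to every gene whose span
#' extended by the promoter window contains the site midpoint, falling back
#' to the nearest gene when none does.  Under the `"nearest"` rule, a site
#' belongs to the gene with the TSS closest to the site midpoint (ties to
#' the lexicographically smaller gene id).
#'
#' @param genes a [GeneModels-class].
#' @param sites a [BindingSites-class].
#' @param config an [AnalysisConfig-class].
#' @param rule `"span"` (default) or `"nearest"`.
#' @return `data.frame` with `gene_id` and `n_sites` (every gene appears,
#'   zero-count genes included); attribute `site_genes` maps each site index
#'   to its gene(s).
#' @export
assignBinding <- function(genes, sites, config = analysisConfig(),
                          rule = c("span", "nearest")) {
  rule <- match.arg(rule)
  s <- bindingRanges(sites)
  mids <- (start(s) + end(s)) %/% 2L
  pts <- GRanges(seqnames(s), IRanges(mids, mids))
  names(pts) <- sprintf("site%06d", seq_along(pts))
  ann <- annotatePeaks(pts, genes, config)
  assigned <- ann$nearest_gene
  if (rule == "span" && length(genes) > 0) {
    g <- geneRanges(genes)
    plus <- as.character(strand(g)) == "+"
    ext <- GRanges(seqnames(g), IRanges(
      pmax(1, ifelse(plus, start(g) - config@promoter_upstream,
                     start(g) - config@promoter_downstream)),
      ifelse(plus, end(g) + config@promoter_downstream,
             end(g) + config@promoter_upstream)))
    ov <- findOverlaps(pts, ext, ignore.strand = TRUE)
    span_genes <- split(names(g)[subjectHits(ov)], queryHits(ov))
    site_genes <- lapply(seq_along(pts), function(i) {
      sg <- span_genes[[as.character(i)]]
      if (is.null(sg)) assigned[i] else sg
    })
  } else {
    site_genes <- as.list(assigned)
  }
  tallied <- table(unlist(site_genes))
  ids <- geneIds(genes)
  out <- data.frame(gene_id = ids,
                    n_sites = as.integer(tallied[ids]),
                    stringsAsFactors = FALSE)
  out$n_sites[is.na(out$n_sites)] <- 0L
  attr(out, "site_genes") <- site_genes
  out
}

#' Proportion of bound genes per DE class, with Fisher tests
#'
#' @param classes output of [classifyDE].
#' @param binding output of [assignBinding] (a gene is a target when
#'   `n_sites > 0`).
#' @param binding_extended optional second assignment (e.g. agonist-extended
#'   site set), reported alongside.
#' @return List with `proportions` (per-class `data.frame`) and `tests`
#'   (pairwise Fisher exact p-values on target counts).
#' @export
bindingByClass <- function(classes, binding, binding_extended = NULL) {
  tgt <- binding$gene_id[binding$n_sites > 0]
  mk <- function(target_ids) {
    sp <- split(classes$gene_id, classes$class)
    do.call(rbind, lapply(names(sp), function(cl) {
      n <- length(sp[[cl]])
      k <- sum(sp[[cl]] %in% target_ids)
      data.frame(class = cl, n_genes = n, n_targets = k,
                 proportion = if (n > 0) k / n else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  props <- mk(tgt)
  if (!is.null(binding_extended)) {
    ext <- mk(binding_extended$gene_id[binding_extended$n_sites > 0])
    props$proportion_extended <- ext$proportion[match(props$class, ext$class)]
    props$n_targets_extended <- ext$n_targets[match(props$class, ext$class)]
  }
  cls <- props$class
  tests <- data.frame()
  if (length(cls) >= 2) {
    cmb <- utils::combn(cls, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      a <- props[props$class == cmb[1, i], ]
      b <- props[props$class == cmb[2, i], ]
      p <- if (a$n_genes > 0 && b$n_genes > 0)
        fisher.test(matrix(c(a$n_targets, a$n_genes - a$n_targets,
                             b$n_targets, b$n_genes - b$n_targets), 2))$p.value
      else NA_real_
      data.frame(class_a = cmb[1, i], class_b = cmb[2, i], p = p,
                 stringsAsFactors = FALSE)
    }))
  }
  list(proportions = props, tests = tests)
}

#' Accessibility change at binding-site peaks, by DE class of the peak's gene
#'
#' Intersects binding sites with ATAC peaks (any overlap), takes each
#' overlapping peak's RPKM difference (condition_b - condition_a) and the DE
#' class of its nearest gene, and compares the class distributions
#' (Mann-Whitney U against the unchanged class and down vs up).  Also
#' reports the global fraction of binding-site peaks with negative change.
#'
#' @param ps a [PeakSet-class].
#' @param sites a [BindingSites-class].
#' @param classes output of [classifyDE].
#' @param annotations output of [annotatePeaks] for `ps`.
#' @param condition_a,condition_b condition labels.
#' @return List with `peak_values`, `summary`, `tests`,
#'   `fraction_negative`.
#' @export
accessibilityAtBinding <- function(ps, sites, classes, annotations,
                                   condition_a = "WT", condition_b = "KO") {
  ov <- overlapsAny(rowRanges(ps), bindingRanges(sites), ignore.strand = TRUE)
  if (!any(ov)) .stopf("no peaks overlap the binding sites")
  d <- (.condition_means(ps, condition_b) - .condition_means(ps, condition_a))[ov]
  ids <- peakIds(ps)[ov]
  gene <- annotations$nearest_gene[match(ids, annotations$peak_id)]
  cls <- classes$class[match(gene, classes$gene_id)]
  pv <- data.frame(peak_id = ids, diff = unname(d), gene_id = gene,
                   class = cls, stringsAsFactors = FALSE)
  known <- pv[!is.na(pv$class), ]
  summ <- do.call(rbind, lapply(split(known$diff, known$class), function(v)
    data.frame(mean = mean(v), median = median(v), n = length(v))))
  summ$class <- rownames(summ); rownames(summ) <- NULL
  wtest <- function(a, b) {
    if (length(a) >= 2 && length(b) >= 2)
      suppressWarnings(wilcox.test(a, b)$p.value) else NA_real_
  }
  sp <- split(known$diff, known$class)
  tests <- data.frame(
    comparison = c("down_vs_unchanged", "up_vs_unchanged", "down_vs_up"),
    p = c(wtest(sp$down, sp$unchanged), wtest(sp$up, sp$unchanged),
          wtest(sp$down, sp$up)),
    stringsAsFactors = FALSE)
  list(peak_values = pv,
       summary = summ[, c("class", "mean", "median", "n")],
       tests = tests,
       fraction_negative = mean(pv$diff < 0))
}

#' Flag binding-site peaks with a large mean RPKM loss
#'
#' @param ps a [PeakSet-class].
#' @param sites a [BindingSites-class].
#' @param threshold_rpkm minimum loss (mean reference RPKM minus mean
#'   comparison RPKM) to flag; the threshold itself is flagged (`>=`).
#' @param condition_a,condition_b condition labels (loss is a - b).
#' @return Character vector of flagged peak ids.
#' @export
flagLargeLoss <- function(ps, sites, threshold_rpkm = 10,
                          condition_a = "WT", condition_b = "KO") {
  ov <- overlapsAny(rowRanges(ps), bindingRanges(sites), ignore.strand = TRUE)
  loss <- .condition_means(ps, condition_a) - .condition_means(ps, condition_b)
  peakIds(ps)[ov & loss >= threshold_rpkm]
}

.MODE_LEVELS <- c("ligand_activated", "ligand_repressed", "basal_required",
                  "basal_repressed", "agonist_only", "indirect",
                  "other_direct", "none")

#' Classify genes into regulatory modes
#'
#' Combines the knockout and agonist DE classifications with binding
#' evidence into mutually exclusive modes:
#' \describe{
#'   \item{ligand_activated}{down in knockout, up with agonist, bound}
#'   \item{ligand_repressed}{up in knockout, down with agonist, bound}
#'   \item{basal_required}{down in knockout, agonist-unchanged, bound}
#'   \item{basal_repressed}{up in knockout, agonist-unchanged, bound}
#'   \item{agonist_only}{knockout-unchanged, agonist-DE, bound}
#'   \item{indirect}{DE in knockout without binding evidence}
#'   \item{other_direct}{bound, DE in the same direction under both
#'     contrasts (outside the four canonical segments)}
#'   \item{none}{everything else}
#' }
#' Binding evidence is any site in either set; the flag distinguishes
#' `basal` from `agonist_only` evidence.
#'
#' @param ko_classes,agonist_classes outputs of [classifyDE] for the
#'   knockout-vs-WT and agonist-vs-vehicle contrasts.
#' @param binding_basal output of [assignBinding] for the basal site set.
#' @param binding_agonist optional assignment for the agonist site set.
#' @return `data.frame` with `gene_id`, `ko_class`, `agonist_class`,
#'   `binding`, `mode` covering the union of both gene universes.
#' @export
classifyModes <- function(ko_classes, agonist_classes, binding_basal,
                          binding_agonist = NULL) {
  genes <- union(ko_classes$gene_id, agonist_classes$gene_id)
  ko <- ko_classes$class[match(genes, ko_classes$gene_id)]
  ag <- agonist_classes$class[match(genes, agonist_classes$gene_id)]
  ko[is.na(ko)] <- "unchanged"
  ag[is.na(ag)] <- "unchanged"
  basal <- genes %in% binding_basal$gene_id[binding_basal$n_sites > 0]
  agon <- if (is.null(binding_agonist)) basal else
    basal | genes %in% binding_agonist$gene_id[binding_agonist$n_sites > 0]
  bound <- basal | agon
  evidence <- ifelse(basal, "basal", ifelse(agon, "agonist_only", "none"))
  mode <- rep("none", length(genes))
  de_ko <- ko != "unchanged"
  mode[de_ko & !bound] <- "indirect"
  mode[bound & ko == "down" & ag == "up"] <- "ligand_activated"
  mode[bound & ko == "up" & ag == "down"] <- "ligand_repressed"
  mode[bound & ko == "down" & ag == "unchanged"] <- "basal_required"
  mode[bound & ko == "up" & ag == "unchanged"] <- "basal_repressed"
  mode[bound & ko == "down" & ag == "down"] <- "other_direct"
  mode[bound & ko == "up" & ag == "up"] <- "other_direct"
  mode[bound & ko == "unchanged" & ag != "unchanged"] <- "agonist_only"
  data.frame(gene_id = genes, ko_class = ko, agonist_class = ag,
             binding = evidence, mode = factor(mode, .MODE_LEVELS),
             stringsAsFactors = FALSE)
}

#' Per-segment report: genes, motif enrichment, promoter fraction
#'
#' For each of the four direct-mode segments: the gene list; the segment's
#' binding-site peaks (peaks overlapping binding sites whose nearest gene is
#' in the segment); the top motif enrichments of those peaks against all
#' binding-site peaks; the promoter fraction of those peaks with a Fisher
#' test against the complementary segments; and their mean accessibility
#' change.  Segments with fewer than two genes are reported with tests
#' suppressed.
#'
#' @param modes output of [classifyModes].
#' @param occ an [OccurrenceMatrix-class] covering the binding-site peaks.
#' @param annotations output of [annotatePeaks].
#' @param ps a [PeakSet-class].
#' @param sites a [BindingSites-class] (typically the agonist-extended set).
#' @param condition_a,condition_b condition labels.
#' @param top_k motifs reported per segment (default 3).
#' @return Named list of per-segment reports.
#' @export
segmentSummary <- function(modes, occ, annotations, ps, sites,
                           condition_a = "WT", condition_b = "KO",
                           top_k = 3) {
  segs <- c("ligand_repressed", "basal_repressed",
            "ligand_activated", "basal_required")
  ov <- overlapsAny(rowRanges(ps), bindingRanges(sites), ignore.strand = TRUE)
  bind_peaks <- peakIds(ps)[ov]
  gene_of <- annotations$nearest_gene[match(bind_peaks, annotations$peak_id)]
  d <- .condition_means(ps, condition_b) - .condition_means(ps, condition_a)
  prom <- annotations$feature_class[match(bind_peaks, annotations$peak_id)] ==
    "promoter"
  scored <- intersect(bind_peaks, rownames(occPresence(occ)))
  out <- list()
  for (seg in segs) {
    gl <- modes$gene_id[modes$mode == seg]
    pk <- bind_peaks[!is.na(gene_of) & gene_of %in% gl]
    rep0 <- list(segment = seg, genes = gl, n_genes = length(gl),
                 peaks = pk, n_peaks = length(pk),
                 mean_accessibility_change =
                   if (length(pk)) mean(d[match(pk, peakIds(ps))]) else NA_real_,
                 promoter_fraction =
                   if (length(pk)) mean(prom[match(pk, bind_peaks)]) else NA_real_,
                 top_motifs = NULL, promoter_test_p = NA_real_)
    if (length(gl) >= 2 && length(pk)) {
      pk_sc <- intersect(pk, scored)
      if (length(pk_sc))
        rep0$top_motifs <- head(subsetEnrichment(occ, pk_sc, scored), top_k)
      in_seg <- bind_peaks %in% pk
      tab <- table(factor(in_seg, c(TRUE, FALSE)), factor(prom, c(TRUE, FALSE)))
      if (all(dim(tab) == 2) && sum(!in_seg) > 0)
        rep0$promoter_test_p <- fisher.test(tab)$p.value
    }
    out[[seg]] <- rep0
  }
  out
}

#' Promoter-gain analysis for one motif
#'
#' Among the top-N gain peaks carrying the motif: the associated (nearest)
#' genes; the fraction of those genes with basal binding, agonist-only
#' binding, or none; and the fraction differentially expressed in the
#' knockout.  An empty motif-bearing gain set yields a flagged empty report.
#'
#' @param ranked output of [rankPeaks].
#' @param annotations output of [annotatePeaks].
#' @param occ an [OccurrenceMatrix-class].
#' @param binding_basal,binding_agonist outputs of [assignBinding].
#' @param motif_id a motif present in `occ`.
#' @param top_n number of gain peaks to consider (default 1000).
#' @param ko_classes optional [classifyDE] output for the DE fraction.
#' @return List with `peaks`, `genes`, `fraction_basal`,
#'   `fraction_agonist_only`, `fraction_unbound`, `fraction_de_ko`, `empty`.
#' @export
promoterGainAnalysis <- function(ranked, annotations, occ, binding_basal,
                                 binding_agonist, motif_id, top_n = 1000,
                                 ko_classes = NULL) {
  pres <- occPresence(occ)
  if (!motif_id %in% colnames(pres))
    .stopf("motif '%s' is absent from the occurrence matrix", motif_id)
  gain <- topN(ranked, min(top_n, nrow(ranked)), "gain")
  carry <- gain[gain %in% rownames(pres)[pres[, motif_id]]]
  if (!length(carry))
    return(list(peaks = character(), genes = character(),
                fraction_basal = NA_real_, fraction_agonist_only = NA_real_,
                fraction_unbound = NA_real_, fraction_de_ko = NA_real_,
                empty = TRUE))
  genes <- genesForPeaks(annotations, carry)
  basal <- genes %in% binding_basal$gene_id[binding_basal$n_sites > 0]
  agon <- genes %in% binding_agonist$gene_id[binding_agonist$n_sites > 0]
  de <- if (is.null(ko_classes)) NA_real_ else
    mean(genes %in% ko_classes$gene_id[ko_classes$class != "unchanged"])
  list(peaks = carry, genes = genes,
       fraction_basal = mean(basal),
       fraction_agonist_only = mean(!basal & agon),
       fraction_unbound = mean(!basal & !agon),
       fraction_de_ko = de, empty = FALSE)
}

#' Expression report for a list of TF genes
#'
#' Verbatim lookup of log2FC and adjusted p for the listed genes, with DE
#' class labels; genes absent from the table are listed as `untested`.
#'
#' @param de a [DETable-class].
#' @param tf_gene_ids character vector of gene ids.
#' @param alpha adjusted-p cutoff for the class label (default 0.05).
#' @return `data.frame` with `gene_id`, `log2fc`, `padj`, `class`.
#' @export
tfExpressionReport <- function(de, tf_gene_ids, alpha = 0.05) {
  tb <- deTable(de)
  i <- match(tf_gene_ids, tb$gene_id)
  lfc <- tb$log2fc[i]; padj <- tb$padj[i]
  cls <- ifelse(is.na(i), "untested",
                ifelse(!is.na(padj) & padj < alpha,
                       ifelse(lfc < 0, "down", "up"), "unchanged"))
  data.frame(gene_id = tf_gene_ids, log2fc = lfc, padj = padj, class = cls,
             stringsAsFactors = FALSE)
}
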