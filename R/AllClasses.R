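## Central S4 containers. PeakSet rides on RangedSummarizedExperiment so that
## the usual Bioconductor accessors (rowRanges, assay, colData) work unchanged.

#' PeakSet: peak intervals with a raw count matrix
#'
#' A `PeakSet` is a [SummarizedExperiment::RangedSummarizedExperiment] whose
#' rows are ATAC peaks (a named `GRanges`) and whose single mandatory assay
#' `"counts"` holds non-negative raw read counts, peaks x samples.  Per-sample
#' metadata (`condition`, `lib_size` = total mapped reads used as the RPKM
#' denominator) live in `colData`.
#'
#' @slot ... see `RangedSummarizedExperiment`.
#' @export
setClass("PeakSet", contains = "RangedSummarizedExperiment")

setValidity("PeakSet", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- assay(object, "counts")
    if (any(!is.finite(cnt)) || any(cnt < 0))
      msg <- c(msg, "counts must be finite and non-negative")
  }
  ids <- rownames(object)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    msg <- c(msg, "peak ids (rownames) must be present, non-empty and unique")
  cd <- colData(object)
  if (!all(c("condition", "lib_size") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'condition' and 'lib_size'")
  else if (any(!is.finite(cd$lib_size)) || any(cd$lib_size <= 0))
    msg <- c(msg, "every sample needs a positive library size")
  if (length(msg)) msg else TRUE
})

#' Construct a PeakSet
#'
#' @param peaks `GRanges` of peak intervals.  Names are used as peak ids; if
#'   unnamed, ids are synthesized as `chrom:start-end` (BED-style 0-based
#'   coordinates, matching the ids a BED reader would produce).
#' @param counts integer-like matrix, peaks x samples, non-negative.
#' @param condition character vector of per-sample condition labels
#'   (e.g. `"WT"`, `"KO"`).
#' @param lib_size numeric vector of per-sample total mapped reads.
#' @return A validated [PeakSet-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 501), width = 200))
#' ps <- PeakSet(gr, matrix(1:8, 2, 4,
#'                dimnames = list(NULL, paste0("s", 1:4))),
#'               condition = c("WT", "WT", "KO", "KO"),
#'               lib_size = rep(1e6, 4))
#' @export
PeakSet <- function(peaks, counts, condition, lib_size) {
  counts <- as.matrix(counts)
  if (is.null(names(peaks)))
    names(peaks) <- sprintf("%s:%d-%d", as.character(seqnames(peaks)),
                            start(peaks) - 1L, end(peaks))
  rownames(counts) <- names(peaks)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  se <- SummarizedExperiment(
    assays = list(counts = counts), rowRanges = peaks,
    colData = DataFrame(condition = as.character(condition),
                        lib_size = as.numeric(lib_size),
                        row.names = colnames(counts)))
  new("PeakSet", se)
}

#' @describeIn PeakSet Peak ids (assay rownames).
#' @param x,object a `PeakSet`.
#' @export
peakIds <- function(x) rownames(x)

#' @describeIn PeakSet Per-sample condition labels.
#' @export
sampleConditions <- function(x) setNames(colData(x)$condition, colnames(x))

#' @describeIn PeakSet Per-sample library sizes (total mapped reads).
#' @export
librarySizes <- function(x) setNames(colData(x)$lib_size, colnames(x))

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet with %d peaks x %d samples (conditions: %s)\n",
              nrow(object), ncol(object),
              paste(unique(colData(object)$condition), collapse = ", ")))
  callNextMethod()
})

## ---------------------------------------------------------------------------

#' GeneModels: gene bodies, TSSs and exons
#'
#' Gene spans are a named `GRanges` (names = gene ids, strand `+`/`-`,
#' `mcols` column `gene_name`, `tss`); exon structures are a `GRangesList`
#' with matching names.
#'
#' @slot genes `GRanges` of gene spans.
#' @slot exons `GRangesList`, one element per gene.
#' @export
setClass("GeneModels",
         representation(genes = "GRanges", exons = "GRangesList"))

setValidity("GeneModels", function(object) {
  g <- object@genes
  msg <- character()
  if (length(g)) {
    if (is.null(names(g)) || anyDuplicated(names(g)))
      msg <- c(msg, "gene ids must be unique names on the gene GRanges")
    if (!all(as.character(strand(g)) %in% c("+", "-")))
      msg <- c(msg, "gene strand must be '+' or '-'")
    if (!all(c("gene_name", "tss") %in% colnames(mcols(g))))
      msg <- c(msg, "gene mcols need 'gene_name' and 'tss'")
    else if (any(mcols(g)$tss < start(g) - 1L | mcols(g)$tss > end(g) + 1L))
      msg <- c(msg, "tss must lie within or adjacent to the gene span")
    if (!identical(names(object@exons), names(g)))
      msg <- c(msg, "exons must be named identically to genes")
  }
  if (length(msg)) msg else TRUE
})

#' Construct GeneModels
#'
#' @param genes named `GRanges` of gene spans with strand; optional mcols
#'   `gene_name` and `tss`.  When `tss` is absent it is derived from strand:
#'   `start` for `+` genes, `end` for `-` genes.
#' @param exons `GRangesList` of exons per gene; defaults to one exon
#'   spanning each gene.
#' @return A validated [GeneModels-class] object.
#' @export
GeneModels <- function(genes, exons = NULL) {
  if (is.null(mcols(genes)$gene_name))
    mcols(genes)$gene_name <- names(genes)
  if (is.null(mcols(genes)$tss))
    mcols(genes)$tss <- ifelse(as.character(strand(genes)) == "+",
                               start(genes), end(genes))
  if (is.null(exons)) {
    exons <- as(split(granges(genes), factor(names(genes), names(genes))),
                "GRangesList")
  }
  new("GeneModels", genes = genes, exons = exons[names(genes)])
}

#' @describeIn GeneModels Gene spans as `GRanges`.
#' @param x a `GeneModels` object.
#' @export
geneRanges <- function(x) x@genes

#' @describeIn GeneModels Exons as a `GRangesList` named by gene id.
#' @export
exonRanges <- function(x) x@exons

#' @describeIn GeneModels Named integer vector of TSS positions (1-based).
#' @export
tssPositions <- function(x) setNames(mcols(x@genes)$tss, names(x@genes))

#' @describeIn GeneModels Gene ids.
#' @export
geneIds <- function(x) names(x@genes)

setMethod("show", "GeneModels", function(object) {
  cat(sprintf("GeneModels with %d genes on %d sequence(s)\n",
              length(object@genes),
              length(unique(as.character(seqnames(object@genes))))))
})

setMethod("length", "GeneModels", function(x) length(x@genes))

## ---------------------------------------------------------------------------

#' DETable: one differential-expression contrast
#'
#' Holds per-gene log2 fold changes (treatment vs reference) and
#' BH-adjusted p-values for a named contrast.
#'
#' @slot table `data.frame` with columns `gene_id`, `log2fc`, `padj`.
#' @slot contrast single character contrast name.
#' @export
setClass("DETable",
         representation(table = "data.frame", contrast = "character"))

setValidity("DETable", function(object) {
  tb <- object@table
  msg <- character()
  if (!all(c("gene_id", "log2fc", "padj") %in% colnames(tb)))
    msg <- c(msg, "table needs columns gene_id, log2fc, padj")
  else {
    if (anyDuplicated(tb$gene_id))
      msg <- c(msg, "one record per gene: duplicated gene_id")
    p <- tb$padj[!is.na(tb$padj)]
    if (any(p < 0 | p > 1))
      msg <- c(msg, "adjusted p-values must lie in [0, 1]")
  }
  if (length(object@contrast) != 1L)
    msg <- c(msg, "contrast must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a DETable
#'
#' @param gene_id character vector of gene ids.
#' @param log2fc numeric log2 fold changes (treatment vs reference).
#' @param padj numeric adjusted p-values in `[0, 1]` (NA allowed).
#' @param contrast contrast name, e.g. `"KO_vs_WT"`.
#' @return A validated [DETable-class].
#' @export
DETable <- function(gene_id, log2fc, padj, contrast) {
  new("DETable",
      table = data.frame(gene_id = as.character(gene_id),
                         log2fc = as.numeric(log2fc),
                         padj = as.numeric(padj),
                         stringsAsFactors = FALSE),
      contrast = as.character(contrast))
}

#' @describeIn DETable The underlying data.frame.
#' @param x a `DETable`.
#' @export
deTable <- function(x) x@table

#' @describeIn DETable The contrast name.
#' @export
deContrast <- function(x) x@contrast

setMethod("show", "DETable", function(object) {
  cat(sprintf("DETable '%s': %d genes, %d with padj < 0.05\n",
              object@contrast, nrow(object@table),
              sum(object@table$padj < 0.05, na.rm = TRUE)))
})

## ---------------------------------------------------------------------------

#' BindingSites: ChIP binding intervals for one condition
#'
#' @slot sites `GRanges`, sorted by (chrom, start) on construction.
#' @slot condition condition label, e.g. `"basal"` or `"agonist"`.
#' @export
setClass("BindingSites",
         representation(sites = "GRanges", condition = "character"))

setValidity("BindingSites", function(object) {
  if (length(object@condition) != 1L)
    return("condition must be a single label")
  if (is.unsorted(order(as.character(seqnames(object@sites)),
                        start(object@sites))))
    return("sites must be sorted by (chrom, start)")
  TRUE
})

#' Construct BindingSites (sorted on construction)
#'
#' @param sites `GRanges` of binding intervals.
#' @param condition condition label.
#' @return A validated [BindingSites-class].
#' @export
BindingSites <- function(sites, condition) {
  o <- order(as.character(seqnames(sites)), start(sites), end(sites))
  new("BindingSites", sites = sites[o], condition = as.character(condition))
}

#' @describeIn BindingSites The site intervals.
#' @param x a `BindingSites` object.
#' @export
bindingRanges <- function(x) x@sites

#' @describeIn BindingSites The condition label.
#' @export
bindingCondition <- function(x) x@condition

setMethod("show", "BindingSites", function(object) {
  cat(sprintf("BindingSites '%s': %d sites\n", object@condition,
              length(object@sites)))
})

setMethod("length", "BindingSites", function(x) length(x@sites))

## ---------------------------------------------------------------------------

#' PWMotif: a position weight matrix
#'
#' Base probabilities per motif position (4 x length, rows A/C/G/T), strictly
#' positive after pseudocount regularization, each column summing to 1, plus a
#' background base distribution used for log-odds scoring.
#'
#' @slot id motif id.
#' @slot family TF-family label used when merging similar motifs.
#' @slot prob 4 x L probability matrix, rownames `A C G T`.
#' @slot background named numeric of background base frequencies.
#' @export
setClass("PWMotif",
         representation(id = "character", family = "character",
                        prob = "matrix", background = "numeric"))

setValidity("PWMotif", function(object) {
  p <- object@prob
  msg <- character()
  if (!identical(rownames(p), c("A", "C", "G", "T")))
    msg <- c(msg, "prob rownames must be A, C, G, T")
  else {
    if (any(p <= 0)) msg <- c(msg, "all probabilities must be > 0 (pseudocount)")
    if (any(abs(colSums(p) - 1) > 1e-9))
      msg <- c(msg, "each column must sum to 1")
  }
  bg <- object@background
  if (!identical(names(bg), c("A", "C", "G", "T")) ||
      abs(sum(bg) - 1) > 1e-9 || any(bg <= 0))
    msg <- c(msg, "background must be positive A,C,G,T frequencies summing to 1")
  if (length(msg)) msg else TRUE
})

#' Construct a PWMotif
#'
#' @param id motif id.
#' @param prob 4 x L matrix of base probabilities (rows A, C, G, T) or raw
#'   counts; counts are converted with a pseudocount of 0.5 per cell.
#' @param family family label (defaults to the id).
#' @param background background base frequencies (default uniform).
#' @param is_counts treat `prob` as counts regardless of column sums.
#' @return A validated [PWMotif-class].
#' @export
PWMotif <- function(id, prob, family = id,
                    background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                    is_counts = NULL) {
  prob <- as.matrix(prob)
  rownames(prob) <- c("A", "C", "G", "T")
  if (is.null(is_counts))
    is_counts <- any(abs(colSums(prob) - 1) > 1e-3)
  if (is_counts) {
    prob <- sweep(prob + 0.5, 2, colSums(prob) + 2, "/")
  } else {
    # probability input: smooth only when zeros are present, so that
    # positive probability matrices round-trip unchanged
    if (any(prob <= 0)) prob <- prob + 1e-3
    prob <- sweep(prob, 2, colSums(prob), "/")
  }
  new("PWMotif", id = as.character(id), family = as.character(family),
      prob = prob, background = background[c("A", "C", "G", "T")])
}

#' @describeIn PWMotif Probability matrix.
#' @param x a `PWMotif`.
#' @export
pwmMatrix <- function(x) x@prob

#' @describeIn PWMotif Motif id.
#' @export
pwmId <- function(x) x@id

#' @describeIn PWMotif Family label.
#' @export
pwmFamily <- function(x) x@family

#' @describeIn PWMotif Background base frequencies.
#' @export
pwmBackground <- function(x) x@background

#' @describeIn PWMotif Motif length in bases.
#' @export
pwmLength <- function(x) ncol(x@prob)

setMethod("show", "PWMotif", function(object) {
  cons <- paste(c("A", "C", "G", "T")[apply(object@prob, 2, which.max)],
                collapse = "")
  cat(sprintf("PWMotif %s (family %s), length %d, consensus %s\n",
              object@id, object@family, ncol(object@prob), cons))
})

#' PWMotifList: an ordered collection of PWMotif objects
#'
#' A plain list subclass whose elements are [PWMotif-class] objects with
#' unique ids; names follow the ids.
#'
#' @export
setClass("PWMotifList", contains = "list")

setValidity("PWMotifList", function(object) {
  if (!all(vapply(object@.Data, is, TRUE, "PWMotif")))
    return("all elements must be PWMotif objects")
  ids <- vapply(object@.Data, pwmId, "")
  if (anyDuplicated(ids)) return("motif ids must be unique")
  if (!identical(names(object), ids)) return("names must equal motif ids")
  TRUE
})

#' Construct a PWMotifList
#'
#' @param ... `PWMotif` objects, or a single list of them.
#' @return A validated [PWMotifList-class].
#' @export
PWMotifList <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !is(xs[[1]], "PWMotif"))
    xs <- xs[[1]]
  names(xs) <- vapply(xs, pwmId, "")
  new("PWMotifList", xs)
}

#' @describeIn PWMotifList Subset to a new PWMotifList.
#' @param x a `PWMotifList`; `i` an index vector.
#' @param i,drop see `[`.
#' @export
setMethod("[", "PWMotifList", function(x, i, ..., drop = FALSE) {
  xs <- setNames(x@.Data, names(x))
  PWMotifList(xs[i])
})

setMethod("show", "PWMotifList", function(object) {
  cat(sprintf("PWMotifList of %d motifs: %s\n", length(object),
              paste(head(names(object), 8), collapse = ", ")))
})

## ---------------------------------------------------------------------------

#' FootprintProfile: aggregated cut-site profile around motif occurrences
#'
#' @slot motif_id motif id.
#' @slot condition condition label.
#' @slot positions integer grid, -window .. +window relative to motif center.
#' @slot rate mean normalized cut rate per position (sums to 1).
#' @slot site_matrix raw per-site cut vectors (sites x positions).
#' @slot motif_length motif width in bases, used to delimit the in-motif span.
#' @export
setClass("FootprintProfile",
         representation(motif_id = "character", condition = "character",
                        positions = "integer", rate = "numeric",
                        site_matrix = "matrix", motif_length = "integer"))

setValidity("FootprintProfile", function(object) {
  msg <- character()
  if (!identical(object@positions, -rev(object@positions)) &&
      !identical(object@positions, sort(object@positions)))
    msg <- c(msg, "position grid must be symmetric about 0")
  if (any(object@rate < 0)) msg <- c(msg, "rates must be non-negative")
  if (nrow(object@site_matrix) < 1L) msg <- c(msg, "site count must be > 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn FootprintProfile Number of aggregated sites.
#' @param x a `FootprintProfile`.
#' @export
footprintSites <- function(x) nrow(x@site_matrix)

setMethod("show", "FootprintProfile", function(object) {
  cat(sprintf("FootprintProfile %s [%s]: %d sites, window +/-%d\n",
              object@motif_id, object@condition, nrow(object@site_matrix),
              max(object@positions)))
})
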