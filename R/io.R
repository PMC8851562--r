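## Readers and writers for the external text formats.  Everything on disk is
## BED-convention 0-based half-open or 1-based TSV as noted; in memory all
## intervals are GRanges (1-based closed).  Readers reject malformed input
## with errors naming the file (and row where known); no silent coercion.

.read_tsv <- function(path, header = TRUE) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  read.delim(path, header = header, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "#", quote = "")
}

.bed_to_granges <- function(path) {
  tb <- .read_tsv(path, header = FALSE)
  if (ncol(tb) < 3) .stopf("%s: BED needs at least 3 columns", path)
  start0 <- suppressWarnings(as.numeric(tb[[2]]))
  end0 <- suppressWarnings(as.numeric(tb[[3]]))
  bad <- which(is.na(start0) | is.na(end0) | start0 < 0 | end0 <= start0 |
                 !nzchar(as.character(tb[[1]])))
  if (length(bad))
    .stopf("%s: malformed interval at line %d (need chrom, 0 <= start < end)",
           path, bad[1])
  strand <- if (ncol(tb) >= 6) as.character(tb[[6]]) else "*"
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GRanges(as.character(tb[[1]]),
                IRanges(start0 + 1, end0), strand = strand)
  nm <- if (ncol(tb) >= 4) as.character(tb[[4]]) else NULL
  if (!is.null(nm) && all(nzchar(nm)) && !any(nm == ".") && !anyDuplicated(nm))
    names(gr) <- nm
  else
    names(gr) <- sprintf("%s:%d-%d", as.character(seqnames(gr)),
                         start0, end0)
  if (anyDuplicated(names(gr)))
    names(gr) <- make.unique(names(gr), sep = "_")
  gr
}

#' Read a peak set: intervals + counts + sample metadata
#'
#' Accepts BED3/BED6 or ENCODE narrowPeak (10 columns) for the intervals —
#' both are parsed identically from the first columns.  `counts_path` is a
#' TSV with a header of sample names and one row per peak (an optional
#' leading peak-id column is matched against the interval ids).  `meta_path`
#' is a TSV with columns `sample`, `condition`, `lib_size` covering every
#' counts column.
#'
#' @param interval_path BED/narrowPeak file of peak intervals.
#' @param counts_path TSV of raw counts, peaks x samples.
#' @param meta_path TSV of sample metadata.
#' @return A [PeakSet-class].
#' @export
readPeakSet <- function(interval_path, counts_path, meta_path) {
  gr <- .bed_to_granges(interval_path)
  tb <- .read_tsv(counts_path)
  id_col <- !vapply(tb, is.numeric, TRUE)
  if (any(id_col)) {
    if (which(id_col)[1] != 1L || sum(id_col) > 1L)
      .stopf("%s: only a single leading peak-id column is allowed", counts_path)
    ids <- as.character(tb[[1]])
    tb <- tb[, -1, drop = FALSE]
  } else ids <- NULL
  if (nrow(tb) != length(gr))
    .stopf("row-count mismatch: %s has %d intervals but %s has %d count rows",
           interval_path, length(gr), counts_path, nrow(tb))
  cnt <- as.matrix(tb)
  neg <- which(cnt < 0, arr.ind = TRUE)
  if (nrow(neg))
    .stopf("%s: negative count at row %d", counts_path, neg[1, 1])
  if (!is.null(ids)) {
    if (!setequal(ids, names(gr)))
      .stopf("peak ids in %s do not match %s", counts_path, interval_path)
    cnt <- cnt[match(names(gr), ids), , drop = FALSE]
  }
  meta <- .read_tsv(meta_path)
  need <- c("sample", "condition", "lib_size")
  if (!all(need %in% colnames(meta)))
    .stopf("%s: needs columns %s", meta_path, paste(need, collapse = ", "))
  missing <- setdiff(colnames(cnt), meta$sample)
  if (length(missing))
    .stopf("%s: no metadata for sample(s) %s", meta_path,
           paste(missing, collapse = ", "))
  meta <- meta[match(colnames(cnt), meta$sample), ]
  ps <- PeakSet(gr, cnt, condition = meta$condition, lib_size = meta$lib_size)
  .log("readPeakSet: %d peaks, %d samples", nrow(ps), ncol(ps))
  ps
}

#' Read gene models from a gene table
#'
#' A GTF-like TSV with columns `gene_id`, `chrom`, `strand`, `start`, `end`
#' (1-based inclusive) and optionally `gene_name`, `tss`, `exon_starts`,
#' `exon_ends` (comma-separated, 1-based).  When `tss` is absent it is the
#' strand-appropriate gene end: `start` for `+`, `end` for `-` genes.
#'
#' @param path gene table path.
#' @return A [GeneModels-class].
#' @export
readGeneModels <- function(path) {
  tb <- .read_tsv(path)
  need <- c("gene_id", "chrom", "strand", "start", "end")
  if (!all(need %in% colnames(tb)))
    .stopf("%s: needs columns %s", path, paste(need, collapse = ", "))
  bad <- which(!tb$strand %in% c("+", "-"))
  if (length(bad))
    .stopf("%s: unknown strand '%s' at row %d", path, tb$strand[bad[1]], bad[1])
  g <- GRanges(tb$chrom, IRanges(tb$start, tb$end), strand = tb$strand)
  names(g) <- tb$gene_id
  mcols(g)$gene_name <- if ("gene_name" %in% colnames(tb)) tb$gene_name else tb$gene_id
  mcols(g)$tss <- if ("tss" %in% colnames(tb)) as.integer(tb$tss) else
    ifelse(tb$strand == "+", tb$start, tb$end)
  exons <- NULL
  if (all(c("exon_starts", "exon_ends") %in% colnames(tb))) {
    exl <- lapply(seq_len(nrow(tb)), function(i) {
      es <- as.integer(strsplit(as.character(tb$exon_starts[i]), ",")[[1]])
      ee <- as.integer(strsplit(as.character(tb$exon_ends[i]), ",")[[1]])
      GRanges(tb$chrom[i], IRanges(es, ee), strand = tb$strand[i])
    })
    names(exl) <- tb$gene_id
    exons <- as(GRangesList(exl), "GRangesList")
  }
  GeneModels(g, exons)
}

#' Write gene models back to the gene-table format read by [readGeneModels]
#'
#' @param gm a [GeneModels-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(gm, path) {
  g <- geneRanges(gm)
  ex <- exonRanges(gm)
  tb <- data.frame(
    gene_id = names(g), gene_name = mcols(g)$gene_name,
    chrom = as.character(seqnames(g)), strand = as.character(strand(g)),
    start = start(g), end = end(g), tss = mcols(g)$tss,
    exon_starts = vapply(ex, function(e) paste(start(e), collapse = ","), ""),
    exon_ends = vapply(ex, function(e) paste(end(e), collapse = ","), ""),
    stringsAsFactors = FALSE)
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' TSV with columns for gene id, log2 fold change and adjusted p; common
#' DESeq2-style spellings (`log2FoldChange`, `padj`) are recognized.  Rows
#' duplicated with identical statistics collapse to one record; conflicting
#' duplicates are an error.
#'
#' @param path DE table path.
#' @param contrast contrast name stored on the result.
#' @return A [DETable-class].
#' @export
readDETable <- function(path, contrast) {
  tb <- .read_tsv(path)
  pick <- function(cands, what) {
    hit <- intersect(cands, colnames(tb))
    if (!length(hit)) .stopf("%s: no %s column (tried %s)", path, what,
                             paste(cands, collapse = ", "))
    tb[[hit[1]]]
  }
  gid <- as.character(pick(c("gene_id", "gene", "id"), "gene id"))
  lfc <- as.numeric(pick(c("log2fc", "log2FoldChange", "log2_fold_change", "lfc"),
                         "log2 fold change"))
  padj <- as.numeric(pick(c("padj", "adjusted_p", "adj_p", "qvalue", "padjust"),
                          "adjusted p"))
  bad <- which(!is.na(padj) & (padj < 0 | padj > 1))
  if (length(bad))
    .stopf("%s: adjusted p outside [0,1] at row %d", path, bad[1])
  key <- paste(gid, signif(lfc, 12), signif(padj, 12))
  dup <- duplicated(key)
  gid2 <- gid[!dup]; lfc2 <- lfc[!dup]; padj2 <- padj[!dup]
  if (anyDuplicated(gid2))
    .stopf("%s: conflicting duplicate records for gene %s", path,
           gid2[duplicated(gid2)][1])
  DETable(gid2, lfc2, padj2, contrast)
}

#' Write a DETable as TSV (columns gene_id, log2fc, padj)
#' @param de a [DETable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDETable <- function(de, path) {
  write.table(deTable(de), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read ChIP binding sites from BED
#'
#' @param path BED file.
#' @param condition condition label, e.g. `"basal"`.
#' @return A [BindingSites-class] (sites sorted).
#' @export
readBindingSites <- function(path, condition) {
  BindingSites(.bed_to_granges(path), condition)
}

#' Write intervals as BED6 (0-based half-open on disk)
#'
#' @param gr a named `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
  nm <- if (is.null(names(gr))) rep(".", length(gr)) else names(gr)
  st <- as.character(strand(gr)); st[st == "*"] <- "."
  tb <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   nm, 0L, st)
  write.table(tb, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a named numeric matrix as TSV
#'
#' The written file has a header row and a leading row-name column;
#' `readMatrix(writeMatrix(m))` is the identity at the written precision.
#'
#' @param m numeric matrix with unique row and column names.
#' @param path file path.
#' @param digits significant digits written (default 10).
#' @return `writeMatrix`: `path` invisibly; `readMatrix`: the matrix.
#' @export
writeMatrix <- function(m, path, digits = 10) {
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    .stopf("matrix row/column names must be unique")
  rn <- if (is.null(rownames(m))) character(nrow(m)) else rownames(m)
  tb <- cbind(data.frame(id = rn, stringsAsFactors = FALSE),
              as.data.frame(signif(m, digits), check.names = FALSE))
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMatrix
#' @export
readMatrix <- function(path) {
  tb <- .read_tsv(path)
  if (!nrow(tb)) {
    m <- matrix(numeric(0), 0, ncol(tb) - 1,
                dimnames = list(NULL, colnames(tb)[-1]))
    return(m)
  }
  m <- as.matrix(tb[, -1, drop = FALSE])
  rownames(m) <- as.character(tb[[1]])
  m
}

#' Read a PWM library in JASPAR or minimal MEME text format
#'
#' JASPAR: `>ID NAME` headers followed by four `A [ n n ... ]` rows (bare
#' number rows also accepted).  MEME minimal: `MOTIF` blocks with a
#' `letter-probability matrix` section.  Count matrices are converted to
#' probabilities with a pseudocount of 0.5 per cell.
#'
#' @param path PWM library file.
#' @param families optional named character vector mapping motif id to family
#'   label; unmapped motifs get their own id as family.
#' @param background background base frequencies (default uniform).
#' @return A [PWMotifList-class].
#' @export
readPWMLibrary <- function(path,
                           families = NULL,
                           background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  fam_of <- function(id) {
    if (!is.null(families) && id %in% names(families)) families[[id]] else id
  }
  if (any(grepl("^MOTIF\\b", lines))) {
    idx <- grep("^MOTIF\\b", lines)
    bounds <- c(idx, length(lines) + 1L)
    for (k in seq_along(idx)) {
      block <- lines[idx[k]:(bounds[k + 1] - 1L)]
      id <- strsplit(trimws(block[1]), "\\s+")[[1]][2]
      mstart <- grep("letter-probability matrix", block)
      if (!length(mstart)) .stopf("%s: MOTIF %s lacks a probability matrix", path, id)
      rows <- list()
      for (ln in block[-seq_len(mstart)]) {
        if (grepl("^(MOTIF|URL)", ln)) break
        v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
        if (length(v) == 4 && !anyNA(v)) rows[[length(rows) + 1L]] <- v
      }
      if (!length(rows)) .stopf("%s: empty matrix for MOTIF %s", path, id)
      prob <- t(do.call(rbind, rows))
      out[[id]] <- PWMotif(id, prob, family = fam_of(id), background = background)
    }
  } else {
    idx <- grep("^>", lines)
    if (!length(idx)) .stopf("%s: not a JASPAR or MEME PWM file", path)
    bounds <- c(idx, length(lines) + 1L)
    for (k in seq_along(idx)) {
      hdr <- strsplit(sub("^>\\s*", "", lines[idx[k]]), "\\s+")[[1]]
      id <- hdr[1]
      body <- lines[(idx[k] + 1L):(bounds[k + 1] - 1L)]
      if (length(body) < 4) .stopf("%s: motif %s needs 4 base rows", path, id)
      mat <- matrix(NA_real_, 4, 0)
      vals <- lapply(body[1:4], function(ln) {
        ln <- gsub("^[ACGTacgt]\\s*", "", trimws(ln))
        ln <- gsub("[\\[\\]]", " ", ln, perl = TRUE)
        v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
        v[!is.na(v)]
      })
      L <- unique(lengths(vals))
      if (length(L) != 1L || L == 0)
        .stopf("%s: motif %s has ragged base rows", path, id)
      mat <- do.call(rbind, vals)
      if (any(colSums(mat) <= 0))
        .stopf("%s: motif %s has a column with non-positive total", path, id)
      out[[id]] <- PWMotif(id, mat, family = fam_of(id), background = background)
    }
  }
  PWMotifList(out)
}

#' Write a PWM library in JASPAR probability format
#'
#' @param pwms a [PWMotifList-class].
#' @param path output path.
#' @param digits significant digits (default 6).
#' @return `path`, invisibly.
#' @export
writePWMLibrary <- function(pwms, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in pwms) {
    writeLines(sprintf(">%s %s", pwmId(m), pwmFamily(m)), con)
    p <- signif(pwmMatrix(m), digits)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s [ %s ]", b, paste(p[b, ], collapse = " ")), con)
  }
  invisible(path)
}

#' Read / write a per-base cut-site track
#'
#' TSV with columns `chrom`, `pos` (1-based base position), `count`.
#' Positions absent from the file have zero cuts.
#'
#' @param path track path.
#' @return A `data.frame` with columns chrom, pos, count.
#' @export
readCutTrack <- function(path) {
  tb <- .read_tsv(path)
  if (!all(c("chrom", "pos", "count") %in% colnames(tb)))
    .stopf("%s: cut track needs columns chrom, pos, count", path)
  bad <- which(tb$count < 0 | tb$pos < 1)
  if (length(bad)) .stopf("%s: invalid cut record at row %d", path, bad[1])
  tb[order(tb$chrom, tb$pos), c("chrom", "pos", "count")]
}

#' @rdname readCutTrack
#' @param track data.frame with chrom, pos, count.
#' @export
writeCutTrack <- function(track, path) {
  write.table(track[order(track$chrom, track$pos), c("chrom", "pos", "count")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read peak sequences from FASTA keyed by peak id
#'
#' @param path FASTA path.
#' @return A `DNAStringSet` named by peak id.
#' @export
readPeakSequences <- function(path) {
  xs <- readDNAStringSet(path)
  names(xs) <- sub("\\s.*$", "", names(xs))
  if (anyDuplicated(names(xs)))
    .stopf("%s: duplicate FASTA ids", path)
  xs
}
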