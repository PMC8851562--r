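## Seeded synthetic study generator.  Emulates the statistical structure the
## analysis assumes: negative-binomial peak counts with condition effects
## stratified by genomic feature class, PWM occurrences whose frequency
## varies with accessibility-change rank, binding sites near differentially
## expressed genes, DE tables with planted mode structure, and
## footprint-shaped cut-count dips.  Every operation reseeds from
## `rng_seed` plus a fixed offset, so each stage is independently
## deterministic under a fixed seed.

#' Simulation configuration
#'
#' Holds every knob of the synthetic study.  Defaults mirror the structure
#' of a two-condition (WT vs knockout), two-replicates-per-condition liver
#' ATAC study: negative-binomial counts, loss effects concentrated on
#' intergenic/intronic peaks that nearly close, gain effects on already-open
#' promoter peaks, binding sites enriched near differentially expressed
#' genes, and a planted regulatory-mode structure.
#'
#' @slot n_chroms,chrom_length,n_genes,n_peaks genome scale.
#' @slot samples_per_condition replicates per condition (default 2).
#' @slot nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @slot baseline_meanlog,baseline_sdlog,promoter_meanlog log-normal
#'   baseline mean parameters for non-promoter and promoter peaks.
#' @slot peak_width_min,peak_width_max peak width range (bp).
#' @slot min_gene_gap minimum intergenic gap enforced when packing genes.
#' @slot feature_mix background-peak class proportions (promoter, exon,
#'   intron, intergenic).
#' @slot loss_effect_min,loss_effect_max,gain_effect_min,gain_effect_max
#'   planted log2 effect magnitudes.
#' @slot bg_loss_rate,bg_gain_rate effect rates on background peaks.
#' @slot mode_props named proportions of planted gene modes
#'   (ligand_activated, ligand_repressed, basal_required, basal_repressed,
#'   agonist_only, indirect); the remainder is unaffected.
#' @slot extra_loss_tendency fraction of unaffected genes that still lose
#'   nearby accessibility.
#' @slot bound_unaffected_rate fraction of unaffected genes given binding
#'   sites (bound but transcriptionally inert).
#' @slot basal_site_frac probability a site is present already in the basal
#'   ChIP set (the basal set is a subset of the agonist set).
#' @slot site_width ChIP site width (bp).
#' @slot de_lfc_min,de_lfc_max planted |log2FC| range for DE calls.
#' @slot de_padj_exp_min,de_padj_exp_max planted adjusted p is
#'   `10^-runif(exp_min, exp_max)` for DE calls, uniform on `[alpha, 1]`
#'   otherwise.
#' @slot de_alpha the significance gate the planted p-values respect.
#' @slot motif_plant `data.frame` (motif_id, target, rate_max, rate_base)
#'   controlling planting; target is `loss`, `gain`, `uniform` or
#'   `mode_<mode>`.
#' @slot footprint_depth named per-condition protection depths.
#' @slot cut_rate per-base cut-rate scale; `cut_pad` extends the cut region
#'   beyond each peak.
#' @slot rng_seed master seed.
#' @export
setClass("SimulationConfig", representation(
  n_chroms = "numeric", chrom_length = "numeric", n_genes = "numeric",
  n_peaks = "numeric", samples_per_condition = "numeric",
  nb_dispersion = "numeric",
  baseline_meanlog = "numeric", baseline_sdlog = "numeric",
  promoter_meanlog = "numeric",
  peak_width_min = "numeric", peak_width_max = "numeric",
  min_gene_gap = "numeric",
  feature_mix = "numeric",
  loss_effect_min = "numeric", loss_effect_max = "numeric",
  gain_effect_min = "numeric", gain_effect_max = "numeric",
  bg_loss_rate = "numeric", bg_gain_rate = "numeric",
  mode_props = "numeric", extra_loss_tendency = "numeric",
  bound_unaffected_rate = "numeric", basal_site_frac = "numeric",
  site_width = "numeric",
  de_lfc_min = "numeric", de_lfc_max = "numeric",
  de_padj_exp_min = "numeric", de_padj_exp_max = "numeric",
  de_alpha = "numeric",
  motif_plant = "data.frame",
  footprint_depth = "numeric", cut_rate = "numeric", cut_pad = "numeric",
  rng_seed = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (sum(object@mode_props) > 1 + 1e-9)
    msg <- c(msg, "mode proportions must sum to <= 1")
  for (s in c("n_chroms", "chrom_length", "n_genes", "n_peaks",
              "samples_per_condition"))
    if (slot(object, s) < 0) msg <- c(msg, paste(s, "must be non-negative"))
  if (object@samples_per_condition < 1)
    msg <- c(msg, "need at least one sample per condition")
  if (abs(sum(object@feature_mix) - 1) > 1e-9)
    msg <- c(msg, "feature_mix must sum to 1")
  if (any(object@footprint_depth < 0 | object@footprint_depth > 1))
    msg <- c(msg, "footprint depths must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimulationConfig Constructor with defaults; override by name.
#' @param ... named overrides.
#' @return A validated `SimulationConfig`.
#' @export
simulationConfig <- function(...) {
  defaults <- list(
    n_chroms = 1, chrom_length = 1e7, n_genes = 400, n_peaks = 4000,
    samples_per_condition = 2, nb_dispersion = 0.05,
    baseline_meanlog = log(60), baseline_sdlog = 0.5,
    promoter_meanlog = log(150),
    peak_width_min = 300, peak_width_max = 600,
    min_gene_gap = 2500,
    feature_mix = c(promoter = 0.10, exon = 0.08, intron = 0.32,
                    intergenic = 0.50),
    loss_effect_min = 1.2, loss_effect_max = 2.5,
    gain_effect_min = 0.8, gain_effect_max = 2.0,
    bg_loss_rate = 0.06, bg_gain_rate = 0.05,
    mode_props = c(ligand_activated = 0.06, ligand_repressed = 0.03,
                   basal_required = 0.08, basal_repressed = 0.04,
                   agonist_only = 0.02, indirect = 0.05),
    extra_loss_tendency = 0.05, bound_unaffected_rate = 0.15,
    basal_site_frac = 0.4, site_width = 200,
    de_lfc_min = 1, de_lfc_max = 3,
    de_padj_exp_min = 2, de_padj_exp_max = 6, de_alpha = 0.05,
    motif_plant = .default_motif_plant(),
    footprint_depth = c(WT = 0.5, KO = 0.1),
    cut_rate = 2, cut_pad = 150,
    rng_seed = 1)
  ov <- list(...)
  bad <- setdiff(names(ov), names(defaults))
  if (length(bad)) .stopf("unknown simulation key(s): %s",
                          paste(bad, collapse = ", "))
  defaults[names(ov)] <- ov
  do.call(new, c(list("SimulationConfig"), defaults))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %d chrom(s) x %.2g bp, %d genes, ",
                     "%d peaks, %d+%d samples, seed %d\n"),
              object@n_chroms, object@chrom_length, object@n_genes,
              object@n_peaks, object@samples_per_condition,
              object@samples_per_condition, object@rng_seed))
})

.default_motif_plant <- function() {
  data.frame(
    motif_id = c("DR4", "DR4", "DR1", "DR1", "CTCF", "FOXA", "FOXA",
                 "CEBP", "NFY", "ETS", "HNF1", "HNF6", "NR_half"),
    target = c("loss", "mode_ligand_activated", "loss", "mode_basal_required",
               "loss", "loss", "mode_ligand_repressed",
               "mode_ligand_repressed", "gain", "uniform", "loss", "loss",
               "loss"),
    rate_max = c(0.40, 0.80, 0.45, 0.80, 0.35, 0.30, 0.70,
                 0.60, 0.40, 0.15, 0.25, 0.25, 0.20),
    rate_base = c(0.02, 0.00, 0.03, 0.00, 0.02, 0.02, 0.00,
                  0.02, 0.03, 0.15, 0.02, 0.02, 0.02),
    stringsAsFactors = FALSE)
}

#' Build a PWM from a consensus string
#'
#' Dominant base gets `dominance`, the rest split the remainder; `N` gives a
#' uniform column.  A convenience for constructing synthetic motif models.
#'
#' @param id motif id.
#' @param consensus consensus string over `A C G T N`.
#' @param family family label.
#' @param dominance probability of the consensus base (default 0.95; sharp
#'   enough that an instance sampled from the matrix is usually recovered at
#'   the default 0.8 score-fraction threshold).
#' @return A [PWMotif-class].
#' @export
consensusPWM <- function(id, consensus, family = id, dominance = 0.95) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  off <- (1 - dominance) / 3
  cols <- vapply(bases, function(b) {
    if (b == "N") rep(0.25, 4)
    else { v <- rep(off, 4); v[match(b, c("A", "C", "G", "T"))] <- dominance; v }
  }, numeric(4))
  PWMotif(id, cols, family = family, is_counts = FALSE)
}

#' Built-in demo motif set
#'
#' Synthetic consensus-derived PWMs for the motif families discussed in the
#' analyses: nuclear-receptor direct repeats (DR4, DR1) and half-site, NF-Y
#' (CCAAT), CTCF, FOXA, C/EBP, ETS, HNF1 and HNF6.  These are constructed in
#' code from canonical consensus sequences and are meant for simulation and
#' demonstration, not as a curated motif database.
#'
#' @return A [PWMotifList-class].
#' @export
defaultPWMs <- function() {
  PWMotifList(
    consensusPWM("DR4", "AGGTCANNNNAGGTCA", family = "NR_DR4"),
    consensusPWM("DR1", "AGGTCANAGGTCA", family = "NR_DR1"),
    consensusPWM("NR_half", "AGGTCA", family = "NR_half"),
    consensusPWM("NFY", "AGCCAATCAG", family = "NFY"),
    consensusPWM("CTCF", "CCGCGAGGTGGCAG", family = "CTCF"),
    consensusPWM("FOXA", "TGTTTACTTA", family = "FOXA"),
    consensusPWM("CEBP", "TTGCGCAA", family = "CEBP"),
    consensusPWM("ETS", "ACAGGAAGTG", family = "ETS"),
    consensusPWM("HNF1", "GTTAATNATTAAC", family = "HNF1"),
    consensusPWM("HNF6", "TATTGATTT", family = "HNF6"))
}

.seed_off <- function(cfg, off) {
  s <- (as.integer(cfg@rng_seed) + off) %% .Machine$integer.max
  set.seed(s)
}

#' Simulate a genome of non-overlapping gene models
#'
#' Genes (2-8 exons each, random strand) are packed onto `n_chroms`
#' chromosomes with at least `min_gene_gap` between spans; placement is
#' deterministic under a fixed `rng_seed`.
#'
#' @param config a [SimulationConfig-class].
#' @return List with `genes` (a [GeneModels-class]) and `seq_lengths`
#'   (named numeric chromosome lengths).
#' @export
simulateGenome <- function(config) {
  .seed_off(config, 101L)
  n <- as.integer(config@n_genes)
  chroms <- sprintf("chr%d", seq_len(config@n_chroms))
  seq_lengths <- setNames(rep(config@chrom_length, config@n_chroms), chroms)
  if (n == 0) {
    gm <- GeneModels(GRanges())
    return(list(genes = gm, seq_lengths = seq_lengths))
  }
  lens <- as.integer(round(runif(n, 2000, 20000)))
  per_chr <- split(seq_len(n), rep(chroms, length.out = n))
  need <- vapply(per_chr, function(i) sum(lens[i]) +
                   (length(i) + 1) * config@min_gene_gap, 0)
  if (any(need > config@chrom_length))
    .stopf("infeasible packing: %d genes do not fit in %d x %.3g bp",
           n, config@n_chroms, config@chrom_length)
  rows <- list()
  for (chr in chroms) {
    idx <- per_chr[[chr]]
    if (!length(idx)) next
    k <- length(idx)
    slack <- config@chrom_length - sum(lens[idx]) - (k + 1) * config@min_gene_gap
    gaps <- config@min_gene_gap + slack * {
      u <- runif(k + 1); u / sum(u)
    }
    starts <- as.integer(round(cumsum(gaps[seq_len(k)]) +
                                 c(0, cumsum(lens[idx]))[seq_len(k)]))
    rows[[chr]] <- data.frame(chrom = chr, start = starts,
                              end = starts + lens[idx] - 1L,
                              stringsAsFactors = FALSE)
  }
  tb <- do.call(rbind, rows)
  tb$strand <- sample(c("+", "-"), nrow(tb), replace = TRUE)
  tb$gene_id <- sprintf("g%04d", seq_len(nrow(tb)))
  g <- GRanges(tb$chrom, IRanges(tb$start, tb$end), strand = tb$strand)
  names(g) <- tb$gene_id
  mcols(g)$gene_name <- tb$gene_id
  mcols(g)$tss <- ifelse(tb$strand == "+", tb$start, tb$end)
  em <- do.call(rbind, lapply(seq_len(nrow(tb)), function(i) {
    L <- tb$end[i] - tb$start[i] + 1L
    n_ex <- sample(2:8, 1)
    cuts <- sort(sample(seq_len(L - 1), 2 * (n_ex - 1)))
    es <- tb$start[i] + c(0L, cuts[seq(2, length(cuts), 2)])
    ee <- c(tb$start[i] + cuts[seq(1, length(cuts), 2)] - 1L, tb$end[i])
    cbind(i, es, ee)
  }))
  exgr <- GRanges(tb$chrom[em[, 1]], IRanges(em[, 2], em[, 3]),
                  strand = tb$strand[em[, 1]])
  exl <- split(exgr, factor(tb$gene_id[em[, 1]], levels = tb$gene_id))
  gm <- GeneModels(g, exl)
  list(genes = gm, seq_lengths = seq_lengths)
}

## draw planted gene modes i.i.d. from the configured proportions
.draw_modes <- function(gene_ids, config) {
  props <- config@mode_props
  labels <- c(names(props), "unaffected")
  p <- c(props, 1 - sum(props))
  modes <- sample(labels, length(gene_ids), replace = TRUE, prob = p)
  data.frame(gene_id = gene_ids, mode = modes, stringsAsFactors = FALSE)
}

.intron_position <- function(gene_row, exons) {
  # a position inside the gene span but outside exons (an intron), or NA
  gaps <- setdiff(IRanges(gene_row$start, gene_row$end), ranges(exons))
  if (!length(gaps)) return(NA_integer_)
  g <- gaps[sample.int(length(gaps), 1)]
  as.integer(round(runif(1, start(g), end(g))))
}

#' Simulate peaks with class-stratified condition effects
#'
#' Places peaks in promoter/exon/intron/intergenic positions, anchors
#' promoter and intragenic peaks to genes, plants log2 accessibility effects
#' (losses concentrated on intergenic/intronic peaks with low knockout
#' means; gains on already-open promoter peaks) and draws negative-binomial
#' counts per sample.  When `modes` (per-gene planted regulatory modes) are
#' supplied, effects are coupled to them: genes down in the knockout lose
#' accessibility at their intragenic peaks, genes up in the knockout gain at
#' their promoters.
#'
#' @param genome output of [simulateGenome].
#' @param config a [SimulationConfig-class].
#' @param modes optional `data.frame` (gene_id, mode) from the mode sampler;
#'   when `NULL` only background effects are planted.
#' @return List with `peakset` (a [PeakSet-class]) and `truth`
#'   (per-peak `data.frame`: feature_truth, role, anchor_gene, effect,
#'   mu_wt, mu_ko; per-gene modes carried through when given).
#' @export
simulatePeaks <- function(genome, config, modes = NULL) {
  .seed_off(config, 202L)
  gm <- genome$genes
  g <- geneRanges(gm)
  ex <- exonRanges(gm)
  seq_lengths <- genome$seq_lengths
  gene_tb <- if (length(g)) data.frame(
    gene_id = names(g), chrom = as.character(seqnames(g)),
    start = start(g), end = end(g), strand = as.character(strand(g)),
    tss = mcols(g)$tss, stringsAsFactors = FALSE) else NULL
  down_modes <- c("ligand_activated", "basal_required")
  up_modes <- c("ligand_repressed", "basal_repressed")
  mode_of <- function(id) {
    if (is.null(modes)) return("unaffected")
    m <- modes$mode[match(id, modes$gene_id)]
    if (is.na(m)) "unaffected" else m
  }
  rows <- list()
  add <- function(chrom, center, class, role, anchor) {
    k <- length(center)
    if (!k) return(invisible(NULL))
    w <- as.integer(round(runif(k, config@peak_width_min, config@peak_width_max)))
    st <- pmax(1L, as.integer(center) - w %/% 2L)
    en <- pmin(as.integer(seq_lengths[chrom]), st + w - 1L)
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, start = st, end = en, feature_truth = class,
      role = role, anchor_gene = anchor, stringsAsFactors = FALSE)
    invisible(NULL)
  }
  extra_loss <- character()
  if (!is.null(gene_tb)) {
    unaff <- gene_tb$gene_id[vapply(gene_tb$gene_id, mode_of, "") == "unaffected"]
    extra_loss <- unaff[runif(length(unaff)) < config@extra_loss_tendency]
    plus <- gene_tb$strand == "+"
    # promoter peaks (one for ~90% of genes)
    has_prom <- runif(nrow(gene_tb)) < 0.9
    offs <- as.integer(round(runif(nrow(gene_tb), -400, 25)))
    add(gene_tb$chrom[has_prom],
        (gene_tb$tss + ifelse(plus, offs, -offs))[has_prom],
        "promoter", "promoter", gene_tb$gene_id[has_prom])
    # intragenic peaks, in introns when possible
    n_intra <- 1 + rpois(nrow(gene_tb), 1)
    gi <- rep(seq_len(nrow(gene_tb)), n_intra)
    pos <- vapply(gi, function(i) {
      p <- .intron_position(gene_tb[i, ], ex[[gene_tb$gene_id[i]]])
      if (is.na(p)) p <- as.integer(round(runif(1, gene_tb$start[i] + 200,
                                                max(gene_tb$start[i] + 201,
                                                    gene_tb$end[i] - 200))))
      p
    }, integer(1))
    in_exon <- mapply(function(i, p)
      any(p >= start(ex[[gene_tb$gene_id[i]]]) &
            p <= end(ex[[gene_tb$gene_id[i]]])), gi, pos)
    add(gene_tb$chrom[gi], pos, ifelse(in_exon, "exon", "intron"),
        "intragenic", gene_tb$gene_id[gi])
    # upstream flanking intergenic peaks
    has_fl <- runif(nrow(gene_tb)) < 0.5
    d <- as.integer(round(runif(nrow(gene_tb), 2000, 8000)))
    fc <- gene_tb$tss + ifelse(plus, -d, d)
    ok <- has_fl & fc > 1000 & fc < seq_lengths[gene_tb$chrom] - 1000
    add(gene_tb$chrom[ok], fc[ok], "intergenic", "flank", gene_tb$gene_id[ok])
  }
  # background peaks fill to n_peaks
  n_bg <- max(0L, as.integer(config@n_peaks) -
                sum(vapply(rows, nrow, 0L)))
  if (n_bg > 0) {
    classes <- if (is.null(gene_tb)) rep("intergenic", n_bg) else
      sample(names(config@feature_mix), n_bg, replace = TRUE,
             prob = config@feature_mix)
    margin <- 1500
    # free intergenic space = chromosome minus extended gene spans
    free <- lapply(names(seq_lengths), function(chr) {
      lim <- IRanges(2000, seq_lengths[[chr]] - 2000)
      if (is.null(gene_tb)) return(lim)
      sub <- gene_tb[gene_tb$chrom == chr, , drop = FALSE]
      setdiff(lim, IRanges(pmax(1, sub$start - margin), sub$end + margin))
    })
    names(free) <- names(seq_lengths)
    if (!is.null(gene_tb)) {
      k <- sum(classes == "promoter")
      i <- sample.int(nrow(gene_tb), k, replace = TRUE)
      offs <- as.integer(round(runif(k, -700, 50)))
      add(gene_tb$chrom[i],
          gene_tb$tss[i] + ifelse(gene_tb$strand[i] == "+", offs, -offs),
          "promoter", "background", gene_tb$gene_id[i])
      k <- sum(classes == "exon")
      i <- sample.int(nrow(gene_tb), k, replace = TRUE)
      ec <- vapply(i, function(ii) {
        e <- ex[[gene_tb$gene_id[ii]]]
        e1 <- sample.int(length(e), 1)
        as.integer(round(runif(1, start(e)[e1], end(e)[e1])))
      }, integer(1))
      add(gene_tb$chrom[i], ec, "exon", "background", NA_character_)
      k <- sum(classes == "intron")
      i <- sample.int(nrow(gene_tb), k, replace = TRUE)
      ic <- vapply(i, function(ii)
        .intron_position(gene_tb[ii, ], ex[[gene_tb$gene_id[ii]]]),
        integer(1))
      keep <- !is.na(ic)
      add(gene_tb$chrom[i][keep], ic[keep], "intron", "background",
          NA_character_)
    }
    k <- sum(classes == "intergenic")
    freew <- vapply(free, function(x) sum(as.numeric(width(x))), 0)
    chrs <- sample(names(free), k, replace = TRUE, prob = freew)
    for (chr in unique(chrs)) {
      kk <- sum(chrs == chr)
      iv <- free[[chr]]
      j <- sample.int(length(iv), kk, replace = TRUE, prob = width(iv))
      pos <- start(iv)[j] +
        as.integer(floor(runif(kk) * width(iv)[j]))
      add(rep(chr, kk), pos, "intergenic", "background", NA_character_)
    }
  }
  tb <- do.call(rbind, rows)
  o <- order(tb$chrom, tb$start, method = "radix")
  tb <- tb[o, ]
  tb$peak_id <- sprintf("pk%05d", seq_len(nrow(tb)))
  # planted effects
  eff <- numeric(nrow(tb))
  anchor_mode <- vapply(tb$anchor_gene, function(a)
    if (is.na(a)) "none" else mode_of(a), "")
  loss_anchor <- anchor_mode %in% down_modes |
    (!is.na(tb$anchor_gene) & tb$anchor_gene %in% extra_loss)
  sel <- loss_anchor & tb$role %in% c("intragenic", "flank")
  eff[sel] <- -runif(sum(sel), config@loss_effect_min, config@loss_effect_max)
  sel <- anchor_mode %in% up_modes & tb$role == "promoter"
  eff[sel] <- runif(sum(sel), config@gain_effect_min, config@gain_effect_max)
  sel <- anchor_mode %in% up_modes & tb$role == "intragenic"
  eff[sel] <- -runif(sum(sel), 0.4, min(1, config@loss_effect_min))
  bg <- tb$role == "background"
  sel <- bg & tb$feature_truth %in% c("intergenic", "intron") &
    runif(nrow(tb)) < config@bg_loss_rate
  eff[sel] <- -runif(sum(sel), config@loss_effect_min, config@loss_effect_max)
  sel <- bg & tb$feature_truth %in% c("promoter", "exon") &
    runif(nrow(tb)) < config@bg_gain_rate & eff == 0
  eff[sel] <- runif(sum(sel), config@gain_effect_min, config@gain_effect_max)
  tb$effect <- eff
  # baselines and counts
  base <- exp(rnorm(nrow(tb),
                    ifelse(tb$feature_truth == "promoter",
                           config@promoter_meanlog, config@baseline_meanlog),
                    config@baseline_sdlog))
  mu_wt <- base
  mu_ko <- base * 2^tb$effect
  spc <- as.integer(config@samples_per_condition)
  size <- 1 / config@nb_dispersion
  cnt_wt <- vapply(seq_len(spc), function(s) rnbinom(nrow(tb), mu = mu_wt,
                                                     size = size),
                   numeric(nrow(tb)))
  cnt_ko <- vapply(seq_len(spc), function(s) rnbinom(nrow(tb), mu = mu_ko,
                                                     size = size),
                   numeric(nrow(tb)))
  cnt <- cbind(cnt_wt, cnt_ko)
  colnames(cnt) <- c(sprintf("WT_%d", seq_len(spc)), sprintf("KO_%d", seq_len(spc)))
  gr <- GRanges(tb$chrom, IRanges(tb$start, tb$end))
  names(gr) <- tb$peak_id
  seqlengths(gr) <- seq_lengths[seqlevels(gr)]
  ps <- PeakSet(gr, cnt,
                condition = rep(c("WT", "KO"), each = spc),
                lib_size = round(runif(2 * spc, 0.9e7, 1.1e7)))
  tb$mu_wt <- mu_wt
  tb$mu_ko <- mu_ko
  truth <- list(
    peaks = tb[, c("peak_id", "chrom", "start", "end", "feature_truth",
                   "role", "anchor_gene", "effect", "mu_wt", "mu_ko")],
    genes = if (!is.null(modes))
      merge(modes, data.frame(gene_id = extra_loss,
                              extra_loss = rep(TRUE, length(extra_loss))),
            all.x = TRUE) else NULL,
    rng_seed = config@rng_seed)
  if (!is.null(truth$genes))
    truth$genes$extra_loss[is.na(truth$genes$extra_loss)] <- FALSE
  .log("simulatePeaks: %d peaks (%d with planted effects)", nrow(tb),
       sum(tb$effect != 0))
  list(peakset = ps, truth = truth)
}

#' Plant motif occurrences in synthetic peak sequences
#'
#' Generates i.i.d. background sequence for every peak and plants, for each
#' configured motif, an instance sampled from its PWM with a probability
#' that depends on the peak's true-effect rank: `loss` targets follow a
#' logistic ramp peaking at the loss end, `gain` at the gain end, `uniform`
#' is flat, and `mode_<mode>` targets peaks anchored to genes of that
#' planted mode.  Optional `ramp_center` / `ramp_width` columns (defaults
#' 0.25 / 0.1, as rank fractions) control how gradual the ramp is.
#' Multiple rows for one motif combine by taking the maximum rate.
#'
#' @param peakset a [PeakSet-class] from [simulatePeaks].
#' @param pwms a [PWMotifList-class].
#' @param truth truth list from [simulatePeaks].
#' @param config a [SimulationConfig-class].
#' @param base_composition background base probabilities (default uniform).
#' @return List with `sequences` (`DNAStringSet` named by peak id) and
#'   `occurrences` (`data.frame`: peak_id, motif_id, start, strand, length).
#' @export
plantMotifOccurrences <- function(peakset, pwms, truth, config,
                                  base_composition = c(A = 0.25, C = 0.25,
                                                       G = 0.25, T = 0.25)) {
  .seed_off(config, 303L)
  tbp <- truth$peaks
  widths <- width(rowRanges(peakset))
  plant <- config@motif_plant
  plant <- plant[plant$motif_id %in% names(pwms), , drop = FALSE]
  too_long <- vapply(unique(plant$motif_id),
                     function(m) pwmLength(pwms[[m]]) > min(widths), TRUE)
  if (any(too_long))
    .stopf("motif longer than the shortest peak: %s",
           paste(unique(plant$motif_id)[too_long], collapse = ", "))
  n <- nrow(tbp)
  # effect rank: most negative first; ties by peak id for determinism
  rk <- order(order(tbp$effect, tbp$peak_id, method = "radix"))
  rf <- (rk - 0.5) / n
  gene_mode <- if (!is.null(truth$genes))
    setNames(truth$genes$mode, truth$genes$gene_id) else character()
  rate_for <- function(row) {
    rc <- if ("ramp_center" %in% names(row) && !is.na(row$ramp_center))
      row$ramp_center else 0.25
    rw <- if ("ramp_width" %in% names(row) && !is.na(row$ramp_width))
      row$ramp_width else 0.1
    if (row$target == "loss")
      row$rate_base + (row$rate_max - row$rate_base) * plogis((rc - rf) / rw)
    else if (row$target == "gain")
      row$rate_base + (row$rate_max - row$rate_base) *
        plogis((rf - (1 - rc)) / rw)
    else if (row$target == "uniform")
      rep(row$rate_max, n)
    else if (startsWith(row$target, "mode_")) {
      md <- sub("^mode_", "", row$target)
      hit <- !is.na(tbp$anchor_gene) &
        !is.na(gene_mode[tbp$anchor_gene]) &
        gene_mode[tbp$anchor_gene] == md
      ifelse(hit, row$rate_max, row$rate_base)
    } else .stopf("unknown plant target '%s'", row$target)
  }
  rates <- matrix(0, n, 0)
  for (m in unique(plant$motif_id)) {
    rws <- plant[plant$motif_id == m, , drop = FALSE]
    r <- do.call(pmax, lapply(seq_len(nrow(rws)),
                              function(i) rate_for(rws[i, ])))
    rates <- cbind(rates, r)
  }
  colnames(rates) <- unique(plant$motif_id)
  bases <- c("A", "C", "G", "T")
  seqs <- character(n)
  occ <- list()
  for (i in seq_len(n)) {
    s <- sample(bases, widths[i], replace = TRUE, prob = base_composition)
    for (m in colnames(rates)) {
      if (runif(1) >= rates[i, m]) next
      pm <- pwmMatrix(pwms[[m]])
      L <- ncol(pm)
      inst <- vapply(seq_len(L), function(j) sample(bases, 1, prob = pm[, j]), "")
      strand <- sample(c("+", "-"), 1)
      if (strand == "-")
        inst <- rev(c(T = "A", G = "C", C = "G", A = "T")[inst])
      pos <- sample.int(widths[i] - L + 1L, 1)
      s[pos:(pos + L - 1L)] <- inst
      occ[[length(occ) + 1L]] <- data.frame(
        peak_id = tbp$peak_id[i], motif_id = m, start = pos,
        strand = strand, length = L, stringsAsFactors = FALSE)
    }
    seqs[i] <- paste(s, collapse = "")
  }
  occurrences <- if (length(occ)) do.call(rbind, occ) else
    data.frame(peak_id = character(), motif_id = character(),
               start = integer(), strand = character(), length = integer(),
               stringsAsFactors = FALSE)
  sequences <- DNAStringSet(setNames(seqs, tbp$peak_id))
  .log("plantMotifOccurrences: %d occurrences over %d peaks",
       nrow(occurrences), n)
  list(sequences = sequences, occurrences = occurrences)
}

#' Simulate binding sites and the two DE tables from planted modes
#'
#' Assigns each gene a regulatory mode (drawn from the configured
#' proportions unless already present in `truth$genes`), emits knockout and
#' agonist DE tables whose log2FC signs and adjusted p-values follow the
#' mode (DE calls clear `de_alpha`, non-calls are uniform on `[alpha, 1]`),
#' and places ChIP sites inside the spans of bound genes — preferentially at
#' the gene's accessibility-losing anchored peaks.  The basal site set is a
#' subset of the agonist set; genes of the agonist_only mode have no basal
#' sites, and every other direct-mode gene keeps at least one.
#'
#' @param genome output of [simulateGenome].
#' @param peakset a [PeakSet-class] from [simulatePeaks].
#' @param truth truth list from [simulatePeaks] (modes are added/reused).
#' @param config a [SimulationConfig-class].
#' @return List with `binding_basal`, `binding_agonist`
#'   ([BindingSites-class]), `de_ko`, `de_agonist` ([DETable-class]) and
#'   `truth` (the input truth with `genes` and `sites` tables filled in).
#' @export
simulateBindingAndExpression <- function(genome, peakset, truth, config) {
  .seed_off(config, 404L)
  gm <- genome$genes
  if (!length(gm)) .stopf("gene list is empty")
  g <- geneRanges(gm)
  ids <- names(g)
  if (is.null(truth$genes)) {
    truth$genes <- .draw_modes(ids, config)
    truth$genes$extra_loss <- FALSE
  }
  modes <- setNames(truth$genes$mode, truth$genes$gene_id)[ids]
  alpha <- config@de_alpha
  n <- length(ids)
  lfc_mag <- function(k) runif(k, config@de_lfc_min, config@de_lfc_max)
  p_sig <- function(k) 10^-runif(k, config@de_padj_exp_min, config@de_padj_exp_max)
  p_null <- function(k) runif(k, alpha, 1)
  ko_lfc <- rnorm(n, 0, 0.15); ko_p <- p_null(n)
  ag_lfc <- rnorm(n, 0, 0.15); ag_p <- p_null(n)
  set_de <- function(idx, sign, contrast) {
    k <- length(idx)
    if (!k) return()
    if (contrast == "ko") {
      ko_lfc[idx] <<- sign * lfc_mag(k); ko_p[idx] <<- p_sig(k)
    } else {
      ag_lfc[idx] <<- sign * lfc_mag(k); ag_p[idx] <<- p_sig(k)
    }
  }
  set_de(which(modes == "ligand_activated"), -1, "ko")
  set_de(which(modes == "ligand_activated"), +1, "agonist")
  set_de(which(modes == "ligand_repressed"), +1, "ko")
  set_de(which(modes == "ligand_repressed"), -1, "agonist")
  set_de(which(modes == "basal_required"), -1, "ko")
  set_de(which(modes == "basal_repressed"), +1, "ko")
  idx <- which(modes == "agonist_only")
  set_de(idx, 1, "agonist")
  if (length(idx)) ag_lfc[idx] <- ag_lfc[idx] * sample(c(-1, 1), length(idx),
                                                       replace = TRUE)
  idx <- which(modes == "indirect")
  set_de(idx, 1, "ko")
  if (length(idx)) ko_lfc[idx] <- ko_lfc[idx] * sample(c(-1, 1), length(idx),
                                                       replace = TRUE)
  de_ko <- DETable(ids, ko_lfc, ko_p, "KO_vs_WT")
  de_agonist <- DETable(ids, ag_lfc, ag_p, "agonist_vs_vehicle")
  # binding sites
  direct <- c("ligand_activated", "ligand_repressed", "basal_required",
              "basal_repressed", "agonist_only")
  bound <- modes %in% direct
  unaff <- which(modes == "unaffected")
  bound[sample(unaff, round(config@bound_unaffected_rate * length(unaff)))] <- TRUE
  tbp <- truth$peaks
  sites <- list()
  for (i in which(bound)) {
    gid <- ids[i]
    n_sites <- if (modes[i] %in% direct) sample(2:5, 1) else sample(1:3, 1)
    anch <- tbp[!is.na(tbp$anchor_gene) & tbp$anchor_gene == gid &
                  tbp$role %in% c("promoter", "intragenic"), , drop = FALSE]
    pref <- anch[anch$effect < 0, , drop = FALSE]
    centers <- integer(0)
    if (nrow(pref))
      centers <- ((pref$start + pref$end) %/% 2L)[
        seq_len(min(n_sites, nrow(pref)))]
    extra <- n_sites - length(centers)
    if (extra > 0)
      centers <- c(centers, as.integer(round(
        runif(extra, start(g)[i] + 300, end(g)[i] - 300))))
    # keep site midpoints strictly inside the gene span (or its promoter)
    centers <- pmin(pmax(centers, start(g)[i] -
                           as.integer(config@site_width)), end(g)[i])
    basal <- runif(length(centers)) < config@basal_site_frac
    if (modes[i] == "agonist_only") basal[] <- FALSE
    else if (modes[i] %in% direct && !any(basal)) basal[1] <- TRUE
    sites[[gid]] <- data.frame(
      chrom = as.character(seqnames(g))[i], center = centers,
      basal = basal, gene_id = gid, mode = unname(modes[i]),
      stringsAsFactors = FALSE)
  }
  st <- do.call(rbind, sites)
  mk_sites <- function(rows, label) {
    if (is.null(rows) || !nrow(rows))
      return(BindingSites(GRanges(), label))
    gr <- GRanges(rows$chrom,
                  IRanges(rows$center - config@site_width %/% 2L,
                          rows$center + config@site_width %/% 2L))
    mcols(gr)$target_gene <- rows$gene_id
    BindingSites(gr, label)
  }
  binding_basal <- mk_sites(st[st$basal, , drop = FALSE], "basal")
  binding_agonist <- mk_sites(st, "agonist")
  truth$sites <- st
  truth$genes$bound <- truth$genes$gene_id %in% ids[bound]
  .log("simulateBindingAndExpression: %d bound genes, %d sites (%d basal)",
       sum(bound), if (is.null(st)) 0 else nrow(st),
       if (is.null(st)) 0 else sum(st$basal))
  list(binding_basal = binding_basal, binding_agonist = binding_agonist,
       de_ko = de_ko, de_agonist = de_agonist, truth = truth)
}

#' Simulate per-base cut-site tracks with footprint dips
#'
#' Poisson cut counts over each peak (extended by `cut_pad`) with per-base
#' rate proportional to the peak's per-condition negative-binomial mean,
#' multiplied by `1 - depth` across occupied motif spans; depth is
#' per-condition (`footprint_depth`).
#'
#' @param peakset a [PeakSet-class].
#' @param occurrences occurrence table from [plantMotifOccurrences].
#' @param truth truth list (for the per-condition means).
#' @param config a [SimulationConfig-class].
#' @return Named list of per-condition cut tracks (`data.frame` chrom, pos,
#'   count; zero positions omitted).
#' @export
simulateCutSites <- function(peakset, occurrences, truth, config) {
  .seed_off(config, 505L)
  tbp <- truth$peaks
  mu <- list(WT = tbp$mu_wt, KO = tbp$mu_ko)
  depths <- config@footprint_depth
  pad <- as.integer(config@cut_pad)
  occ_gs <- tbp$start[match(occurrences$peak_id, tbp$peak_id)] +
    occurrences$start - 1L
  occ_chr <- tbp$chrom[match(occurrences$peak_id, tbp$peak_id)]
  out <- list()
  for (cond in names(depths)) {
    tracks <- list()
    for (chr in unique(tbp$chrom)) {
      sel <- which(tbp$chrom == chr)
      w <- tbp$end[sel] - tbp$start[sel] + 1L
      npos <- w + 2L * pad
      pos <- unlist(lapply(seq_along(sel), function(k)
        (tbp$start[sel[k]] - pad):(tbp$end[sel[k]] + pad)))
      rate <- rep(config@cut_rate * mu[[cond]][sel] / w, npos)
      keep <- pos >= 1
      # overlapping peak windows: rates accumulate per genomic position
      agg <- rowsum(rate[keep], pos[keep])
      pos_u <- as.integer(rownames(agg))
      rate_u <- agg[, 1]
      oc <- which(occ_chr == chr)
      for (j in oc) {
        lo <- findInterval(occ_gs[j] - 1L, pos_u) + 1L
        hi <- findInterval(occ_gs[j] + occurrences$length[j] - 1L, pos_u)
        if (hi >= lo)
          rate_u[lo:hi] <- rate_u[lo:hi] * (1 - depths[[cond]])
      }
      cnt <- rpois(length(pos_u), rate_u)
      nz <- cnt > 0
      if (any(nz))
        tracks[[chr]] <- data.frame(chrom = chr, pos = pos_u[nz],
                                    count = cnt[nz], stringsAsFactors = FALSE)
    }
    tr <- do.call(rbind, tracks)
    rownames(tr) <- NULL
    out[[cond]] <- tr[order(tr$chrom, tr$pos), ]
  }
  out
}

#' Run the whole synthetic study
#'
#' Orchestrates genome, mode sampling, peaks, motif planting, binding and
#' expression, and (optionally) cut-site tracks, returning every input the
#' analysis layers need together with the ground-truth manifest.
#'
#' @param config a [SimulationConfig-class].
#' @param pwms a [PWMotifList-class] (default [defaultPWMs]).
#' @param cuts also simulate cut-site tracks (default `TRUE`).
#' @return List: `genome`, `peakset`, `sequences`, `pwms`, `binding_basal`,
#'   `binding_agonist`, `de_ko`, `de_agonist`, `cuts`, `truth`.
#' @export
simulateStudy <- function(config = simulationConfig(), pwms = defaultPWMs(),
                          cuts = TRUE) {
  genome <- simulateGenome(config)
  .seed_off(config, 150L)
  modes <- .draw_modes(geneIds(genome$genes), config)
  pk <- simulatePeaks(genome, config, modes = modes)
  planted <- plantMotifOccurrences(pk$peakset, pwms, pk$truth, config)
  be <- simulateBindingAndExpression(genome, pk$peakset, pk$truth, config)
  truth <- be$truth
  truth$occurrences <- planted$occurrences
  cut_tracks <- if (cuts)
    simulateCutSites(pk$peakset, planted$occurrences, truth, config) else NULL
  list(genome = genome, peakset = pk$peakset, sequences = planted$sequences,
       pwms = pwms, binding_basal = be$binding_basal,
       binding_agonist = be$binding_agonist, de_ko = be$de_ko,
       de_agonist = be$de_agonist, cuts = cut_tracks, truth = truth)
}

#' Write a simulated study to a directory of plain-text files
#'
#' Emits peaks.bed, counts.tsv, samples.tsv, genes.tsv, peaks.fa,
#' chip_basal.bed, chip_agonist.bed, de_ko.tsv, de_agonist.tsv, per-
#' condition cuts_*.tsv and truth.json, all readable by the package's
#' readers.
#'
#' @param sim output of [simulateStudy].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  ps <- sim$peakset
  writeBed(rowRanges(ps), fp("peaks.bed"))
  cnt <- cbind(peak_id = peakIds(ps),
               as.data.frame(assay(ps, "counts"), check.names = FALSE))
  write.table(cnt, fp("counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample = colnames(ps),
                         condition = sampleConditions(ps),
                         lib_size = librarySizes(ps)),
              fp("samples.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeGeneModels(sim$genome$genes, fp("genes.tsv"))
  writeXStringSet(sim$sequences, fp("peaks.fa"))
  writeBed(bindingRanges(sim$binding_basal), fp("chip_basal.bed"))
  writeBed(bindingRanges(sim$binding_agonist), fp("chip_agonist.bed"))
  writeDETable(sim$de_ko, fp("de_ko.tsv"))
  writeDETable(sim$de_agonist, fp("de_agonist.tsv"))
  if (!is.null(sim$cuts))
    for (cond in names(sim$cuts))
      writeCutTrack(sim$cuts[[cond]], fp(sprintf("cuts_%s.tsv", cond)))
  writePWMLibrary(sim$pwms, fp("pwms.jaspar"))
  truth <- sim$truth
  truth$seq_lengths <- as.list(sim$genome$seq_lengths)
  writeLines(toJSON(truth, dataframe = "columns", auto_unbox = TRUE,
                    digits = NA, na = "null"),
             fp("truth.json"))
  invisible(dir)
}
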