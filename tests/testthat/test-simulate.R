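test_that("the genome simulator is deterministic and packs genes disjointly", {
  cfg <- simulationConfig(n_genes = 50, n_peaks = 200, chrom_length = 5e6,
                          rng_seed = 1)
  g1 <- simulateGenome(cfg)
  g2 <- simulateGenome(cfg)
  expect_identical(geneRanges(g1$genes), geneRanges(g2$genes))
  expect_identical(as.list(exonRanges(g1$genes)),
                   as.list(exonRanges(g2$genes)))

  # all gene spans disjoint, verified by an interval sweep
  g <- geneRanges(g1$genes)
  o <- order(as.character(seqnames(g)), start(g))
  same_chr <- as.character(seqnames(g))[o][-1] ==
    as.character(seqnames(g))[o][-length(g)]
  expect_true(all(!same_chr | start(g)[o][-1] > end(g)[o][-length(g)]))

  # exon counts within 2..8, all inside the gene span
  for (id in geneIds(g1$genes)) {
    e <- exonRanges(g1$genes)[[id]]
    expect_true(length(e) >= 2 && length(e) <= 8)
    expect_true(all(start(e) >= start(g[id]) & end(e) <= end(g[id])))
  }

  # zero genes: empty list, valid chromosome sizes
  g0 <- simulateGenome(simulationConfig(n_genes = 0))
  expect_equal(length(g0$genes), 0)
  expect_equal(g0$seq_lengths, c(chr1 = 1e7))

  # infeasible packing is a config error
  expect_error(simulateGenome(simulationConfig(n_genes = 500,
                                               chrom_length = 1e6)),
               "infeasible")
})

test_that("with zero planted effects, condition means differ only by noise", {
  cfg <- simulationConfig(n_genes = 40, n_peaks = 400, chrom_length = 2e6,
                          mode_props = setNames(numeric(0), character(0)),
                          extra_loss_tendency = 0, bg_loss_rate = 0,
                          bg_gain_rate = 0, nb_dispersion = 0.001,
                          samples_per_condition = 4, rng_seed = 2)
  genome <- simulateGenome(cfg)
  pk <- simulatePeaks(genome, cfg)
  expect_true(all(pk$truth$peaks$effect == 0))
  m <- rpkm(pk$peakset)
  cond <- sampleConditions(pk$peakset)
  lr <- log2(rowMeans(m[, cond == "KO"]) + 1) -
    log2(rowMeans(m[, cond == "WT"]) + 1)
  expect_lt(mean(abs(lr)), 0.15)
})

test_that("planted log2 effects are recovered by the count model", {
  # every anchored loss effect fixed at -2: KO means should sit near WT / 4
  cfg <- simulationConfig(n_genes = 100, n_peaks = 1000, chrom_length = 5e6,
                          loss_effect_min = 2, loss_effect_max = 2,
                          rng_seed = 3)
  genome <- simulateGenome(cfg)
  set.seed(99)
  modes <- regmodes:::.draw_modes(geneIds(genome$genes), cfg)
  pk <- simulatePeaks(genome, cfg, modes = modes)
  tr <- pk$truth$peaks
  cnt <- assay(pk$peakset, "counts")
  cond <- sampleConditions(pk$peakset)
  sel <- tr$effect == -2
  expect_gt(sum(sel), 20)
  ratio <- sum(cnt[sel, cond == "KO"]) / sum(cnt[sel, cond == "WT"])
  expect_equal(ratio, 2^-2, tolerance = 0.15)
  expect_equal(tr$mu_ko[sel] / tr$mu_wt[sel], rep(0.25, sum(sel)))

  # parameter recovery: planted effects correlate with estimated differences
  ps <- filterLowCount(pk$peakset)
  rk <- rankPeaks(ps)
  est <- log2((rk$mean_b + 0.5) / (rk$mean_a + 0.5))
  truth_eff <- tr$effect[match(rk$peak_id, tr$peak_id)]
  expect_gte(cor(est, truth_eff, method = "spearman",
                 use = "complete.obs"), 0.3)
  strong <- abs(truth_eff) > 0 | seq_along(truth_eff) %% 7 == 0
  expect_gte(cor(est[strong], truth_eff[strong], method = "spearman"), 0.8)
})

test_that("planted mode counts fall within binomial sampling bounds", {
  cfg <- simulationConfig(n_genes = 500, rng_seed = 5)
  set.seed(11)
  modes <- regmodes:::.draw_modes(sprintf("g%04d", 1:500), cfg)
  tab <- table(factor(modes$mode, c(names(cfg@mode_props), "unaffected")))
  for (m in names(cfg@mode_props)) {
    p <- cfg@mode_props[[m]]
    expect_lt(abs(tab[[m]] - 500 * p), 3 * sqrt(500 * p * (1 - p)) + 1)
  }
})

test_that("motif planting rates follow their rank targets", {
  mp <- data.frame(motif_id = c("ETS", "DR4"),
                   target = c("uniform", "loss"),
                   rate_max = c(0.1, 0.5), rate_base = c(0.1, 0.05))
  cfg <- simulationConfig(n_genes = 60, n_peaks = 1000, chrom_length = 4e6,
                          motif_plant = mp, rng_seed = 7)
  genome <- simulateGenome(cfg)
  set.seed(12)
  modes <- regmodes:::.draw_modes(geneIds(genome$genes), cfg)
  pk <- simulatePeaks(genome, cfg, modes = modes)
  pl <- plantMotifOccurrences(pk$peakset, defaultPWMs(), pk$truth, cfg)
  tr <- pk$truth$peaks
  n <- nrow(tr)
  rk <- order(order(tr$effect, tr$peak_id, method = "radix"))
  decile <- ceiling(rk / (n / 10))

  # uniform motif: per-decile frequency flat within binomial error
  ets <- tr$peak_id %in% pl$occurrences$peak_id[pl$occurrences$motif_id == "ETS"]
  freq <- tapply(ets, decile, mean)
  expect_true(all(abs(freq - 0.1) < 3 * sqrt(0.1 * 0.9 / (n / 10))))

  # loss-targeted motif concentrates at the loss end
  dr4 <- tr$peak_id %in% pl$occurrences$peak_id[pl$occurrences$motif_id == "DR4"]
  f <- tapply(dr4, decile, mean)
  expect_gt(f[[1]], 5 * mean(f[5:10]))

  # every planted occurrence lies inside its peak
  w <- setNames(tr$end - tr$start + 1L, tr$peak_id)
  occ <- pl$occurrences
  expect_true(all(occ$start >= 1 &
                    occ$start + occ$length - 1 <= w[occ$peak_id]))
})

test_that("near-consensus planting is recovered exactly by the scanner", {
  mp <- data.frame(motif_id = "DR1", target = "uniform",
                   rate_max = 0.3, rate_base = 0.3)
  cfg <- simulationConfig(n_genes = 20, n_peaks = 150, chrom_length = 1e6,
                          motif_plant = mp, rng_seed = 8)
  pwms <- PWMotifList(consensusPWM("DR1", "AGGTCAAAGGTCA", dominance = 0.999))
  genome <- simulateGenome(cfg)
  pk <- simulatePeaks(genome, cfg)
  pl <- plantMotifOccurrences(pk$peakset, pwms, pk$truth, cfg)
  occ <- occurrenceMatrix(pl$sequences, pwms, 0.7)
  planted <- unique(pl$occurrences$peak_id)
  expect_gt(length(planted), 20)
  expect_true(all(occPresence(occ)[planted, "DR1"]))
})

test_that("planted modes shape DE tables and binding by construction", {
  cfg <- simulationConfig(n_genes = 300, n_peaks = 2000, chrom_length = 8e6,
                          rng_seed = 9)
  sim <- simulateStudy(cfg, cuts = FALSE)
  tr <- sim$truth$genes
  ko <- deTable(sim$de_ko); ag <- deTable(sim$de_agonist)
  alpha <- cfg@de_alpha
  st <- sim$truth$sites

  act <- tr$gene_id[tr$mode == "ligand_activated"]
  expect_gt(length(act), 0)
  i <- match(act, ko$gene_id); j <- match(act, ag$gene_id)
  expect_true(all(ko$log2fc[i] < 0 & ko$padj[i] < alpha))
  expect_true(all(ag$log2fc[j] > 0 & ag$padj[j] < alpha))
  # at least one basal site within the gene's assignment window
  expect_true(all(act %in% st$gene_id[st$basal]))

  unaff <- tr$gene_id[tr$mode == "unaffected"]
  i <- match(unaff, ko$gene_id); j <- match(unaff, ag$gene_id)
  expect_true(all(ko$padj[i] >= alpha & ag$padj[j] >= alpha))

  # indirect genes are DE without any site
  ind <- tr$gene_id[tr$mode == "indirect"]
  expect_false(any(ind %in% st$gene_id))

  # the basal site set is a subset of the agonist set
  b <- bindingRanges(sim$binding_basal); a <- bindingRanges(sim$binding_agonist)
  ov <- GenomicRanges::findOverlaps(b, a, type = "equal")
  expect_equal(length(unique(S4Vectors::queryHits(ov))), length(b))
  expect_gt(length(a), length(b))
})

test_that("cut-site dips average to the planted protection depth", {
  mp <- data.frame(motif_id = "ETS", target = "uniform",
                   rate_max = 0.5, rate_base = 0.5)
  cfg <- simulationConfig(n_genes = 60, n_peaks = 500, chrom_length = 2.5e6,
                          motif_plant = mp, rng_seed = 10,
                          footprint_depth = c(WT = 0.5, KO = 0))
  sim <- simulateStudy(cfg)
  occ <- sim$truth$occurrences
  gro <- occurrenceRanges(occ, rowRanges(sim$peakset), unique(occ$length))
  fw <- aggregateFootprint(sim$cuts$WT, gro, window = 100, condition = "WT")
  fk <- aggregateFootprint(sim$cuts$KO, gro, window = 100, condition = "KO")
  s <- protectionScore(fw, fk, n_boot = 0)
  expect_equal(s$depth_a, 0.5, tolerance = 0.1)
  # protection depth 0: flat expected profile around motifs
  expect_equal(s$depth_b, 0, tolerance = 0.05)
})

test_that("a written simulation reads back consistently with its truth", {
  cfg <- simulationConfig(n_genes = 30, n_peaks = 250, chrom_length = 1.5e6,
                          rng_seed = 13)
  sim <- simulateStudy(cfg)
  d <- withr::local_tempdir()
  writeSimulation(sim, d)
  for (f in c("peaks.bed", "counts.tsv", "samples.tsv", "genes.tsv",
              "peaks.fa", "chip_basal.bed", "chip_agonist.bed", "de_ko.tsv",
              "de_agonist.tsv", "cuts_WT.tsv", "cuts_KO.tsv", "truth.json",
              "pwms.jaspar"))
    expect_true(file.exists(file.path(d, f)), label = f)
  ps <- readPeakSet(file.path(d, "peaks.bed"), file.path(d, "counts.tsv"),
                    file.path(d, "samples.tsv"))
  expect_equal(assay(ps, "counts") * 1.0, assay(sim$peakset, "counts") * 1.0)
  expect_equal(start(rowRanges(ps)), start(rowRanges(sim$peakset)))
  expect_equal(end(rowRanges(ps)), end(rowRanges(sim$peakset)))
  expect_equal(as.character(seqnames(rowRanges(ps))),
               as.character(seqnames(rowRanges(sim$peakset))))
  gm <- readGeneModels(file.path(d, "genes.tsv"))
  expect_identical(geneRanges(gm), geneRanges(sim$genome$genes))
  seqs <- readPeakSequences(file.path(d, "peaks.fa"))
  expect_equal(as.character(seqs), as.character(sim$sequences))
  truth <- jsonlite::fromJSON(file.path(d, "truth.json"))
  expect_equal(truth$peaks$peak_id, sim$truth$peaks$peak_id)
  # every planted entity resolves in the emitted files
  expect_true(all(truth$occurrences$peak_id %in% names(seqs)))
  expect_true(all(truth$sites$gene_id %in% geneIds(gm)))
})
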