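test_that("DE classification gates on both significance and sign", {
  de <- DETable(c("a", "b", "c", "d"), c(-1, -1, 2, 0.1),
                c(0.01, 0.2, 0.001, NA), "ko")
  cls <- classifyDE(de)
  expect_equal(cls$class, c("down", "unchanged", "up", "unchanged"))
  # a log2FC gate keeps small significant changes unchanged
  cls2 <- classifyDE(DETable("x", 0.5, 0.001, "k"), lfc_threshold = 1)
  expect_equal(cls2$class, "unchanged")
})

test_that("binding assignment counts sites per gene like a brute-force scan", {
  gm <- tiny_genes()  # gA 2000-8000 (+), gB 12000-20000 (-)
  cfg <- analysisConfig()
  sites <- BindingSites(GRanges("chr1", IRanges(c(3000, 7000, 13000, 30000),
                                                width = 200)), "basal")
  bd <- assignBinding(gm, sites, cfg)
  expect_equal(bd$n_sites[bd$gene_id == "gA"], 2)  # both inside gA's span
  expect_equal(bd$n_sites[bd$gene_id == "gB"], 2)  # one in span + distal nearest

  # brute force for the span part: midpoints inside extended spans
  mids <- (start(bindingRanges(sites)) + end(bindingRanges(sites))) %/% 2
  inA <- sum(mids >= 2000 - 1000 & mids <= 8000 + 100)
  expect_equal(inA, 2)

  # a site equidistant between two TSSs goes to the smaller gene id
  g2 <- GRanges("chr1", IRanges(c(1000, 3000), width = 100), strand = "+")
  names(g2) <- c("gX", "gA2")
  gm2 <- GeneModels(g2)
  s2 <- BindingSites(GRanges("chr1", IRanges(1975, 2025)), "basal")
  bd2 <- assignBinding(gm2, s2, cfg, rule = "nearest")
  expect_equal(bd2$n_sites[bd2$gene_id == "gA2"], 1)
  expect_equal(bd2$n_sites[bd2$gene_id == "gX"], 0)
})

test_that("binding-by-class proportions and Fisher tests behave", {
  classes <- data.frame(
    gene_id = sprintf("g%02d", 1:30),
    class = rep(c("down", "up", "unchanged"), each = 10))
  binding <- data.frame(gene_id = sprintf("g%02d", 1:30),
                        n_sites = c(rep(1, 4), rep(0, 6),    # down: 4/10
                                    rep(1, 4), rep(0, 6),    # up: 4/10
                                    rep(1, 1), rep(0, 9)))   # unchanged: 1/10
  res <- bindingByClass(classes, binding)
  pr <- res$proportions
  expect_equal(pr$proportion[pr$class == "down"], 0.4)
  # identical margins -> Fisher p = 1
  p_du <- res$tests$p[res$tests$class_a == "down" & res$tests$class_b == "up"]
  expect_equal(p_du, 1)
})

test_that("accessibility at binding sites separates planted class shifts", {
  # 40 peaks at binding sites; down-gene peaks at -1, unchanged at 0
  n <- 40
  gr <- GRanges("chr1", IRanges(seq(1000, by = 3000, length.out = n),
                                width = 1000))
  names(gr) <- sprintf("p%02d", seq_len(n))
  down <- seq_len(n) <= 20
  wt <- ifelse(down, 5, 4)
  ko <- ifelse(down, 4, 4)
  cnt <- cbind(WT_1 = wt, WT_2 = wt, KO_1 = ko, KO_2 = ko)
  rownames(cnt) <- names(gr)
  ps <- PeakSet(gr, cnt, condition = c("WT", "WT", "KO", "KO"),
                lib_size = rep(1e6, 4))
  sites <- BindingSites(granges(gr), "basal")
  ann <- data.frame(peak_id = names(gr), feature_class = "intergenic",
                    nearest_gene = sprintf("g%02d", seq_len(n)),
                    tss_distance = 0)
  classes <- data.frame(gene_id = sprintf("g%02d", seq_len(n)),
                        class = ifelse(down, "down", "unchanged"))
  res <- accessibilityAtBinding(ps, sites, classes, ann)
  s <- res$summary
  expect_equal(s$mean[s$class == "down"], -1)
  expect_equal(s$mean[s$class == "unchanged"], 0)
  expect_lt(res$tests$p[res$tests$comparison == "down_vs_unchanged"], 1e-6)
  expect_equal(res$fraction_negative, 0.5)
})

test_that("large-loss flagging applies the >= threshold exactly", {
  gr <- GRanges("chr1", IRanges(c(1000, 3000, 5000), width = 1000))
  names(gr) <- c("at", "below", "away")
  # width 1 kb, lib 1e6: rpkm == counts; losses 10.0 and 9.9
  cnt <- rbind(at = c(20, 20, 10, 10),
               below = c(20, 20, 10.1, 10.1),
               away = c(50, 50, 10, 10))
  ps <- PeakSet(gr, cnt, condition = c("WT", "WT", "KO", "KO"),
                lib_size = rep(1e6, 4))
  sites <- BindingSites(GRanges("chr1", IRanges(c(1200, 3200), width = 100)),
                        "basal")
  flagged <- flagLargeLoss(ps, sites, 10)
  expect_equal(flagged, "at")   # 10.0 flagged, 9.9 not, non-overlapping not
})

test_that("mode classification implements the segment and binding gates", {
  mk_cls <- function(...) {
    x <- c(...)
    data.frame(gene_id = names(x), class = unname(x),
               stringsAsFactors = FALSE)
  }
  ko <- mk_cls(g1 = "down", g2 = "up", g3 = "down", g4 = "down",
               g5 = "up", g6 = "unchanged", g7 = "unchanged", g8 = "down")
  ag <- mk_cls(g1 = "up", g2 = "down", g3 = "unchanged", g4 = "unchanged",
               g5 = "unchanged", g6 = "up", g7 = "unchanged", g8 = "down")
  basal <- data.frame(gene_id = sprintf("g%d", 1:8),
                      n_sites = c(1, 1, 2, 0, 1, 1, 0, 1))
  mo <- classifyModes(ko, ag, basal)
  got <- setNames(as.character(mo$mode), mo$gene_id)
  expect_equal(got[["g1"]], "ligand_activated")
  expect_equal(got[["g2"]], "ligand_repressed")
  expect_equal(got[["g3"]], "basal_required")
  expect_equal(got[["g4"]], "indirect")       # down but unbound
  expect_equal(got[["g5"]], "basal_repressed")
  expect_equal(got[["g6"]], "agonist_only")
  expect_equal(got[["g7"]], "none")
  expect_equal(got[["g8"]], "other_direct")   # same direction both contrasts

  # modes partition the gene universe
  expect_equal(sort(mo$gene_id), sprintf("g%d", 1:8))
  expect_false(anyNA(mo$mode))

  # agonist-only binding evidence still gates direct modes
  agonist <- data.frame(gene_id = "g4", n_sites = 1)
  basal0 <- data.frame(gene_id = "g4", n_sites = 0)
  mo2 <- classifyModes(ko[ko$gene_id == "g4", ], ag[ag$gene_id == "g4", ],
                       basal0, agonist)
  expect_equal(as.character(mo2$mode), "basal_required")
  expect_equal(mo2$binding, "agonist_only")
})

test_that("mode classification is invariant to gene order", {
  cfg <- simulationConfig(n_genes = 120, n_peaks = 800, chrom_length = 4e6,
                          rng_seed = 17)
  sim <- simulateStudy(cfg, cuts = FALSE)
  bb <- assignBinding(sim$genome$genes, sim$binding_basal)
  ba <- assignBinding(sim$genome$genes, sim$binding_agonist)
  ko <- classifyDE(sim$de_ko); ag <- classifyDE(sim$de_agonist)
  m1 <- classifyModes(ko, ag, bb, ba)
  set.seed(1)
  perm <- sample(nrow(ko))
  m2 <- classifyModes(ko[perm, ], ag, bb, ba)
  m2 <- m2[match(m1$gene_id, m2$gene_id), ]
  expect_equal(as.character(m1$mode), as.character(m2$mode))
})

test_that("segment summaries report genes, motifs and promoter fractions", {
  cfg <- simulationConfig(n_genes = 250, n_peaks = 1600, chrom_length = 7e6,
                          rng_seed = 19)
  sim <- simulateStudy(cfg, cuts = FALSE)
  ann <- annotatePeaks(sim$peakset, sim$genome$genes)
  bb <- assignBinding(sim$genome$genes, sim$binding_basal)
  ba <- assignBinding(sim$genome$genes, sim$binding_agonist)
  mo <- classifyModes(classifyDE(sim$de_ko), classifyDE(sim$de_agonist),
                      bb, ba)
  # the half-site submotif of the direct repeats is excluded so segment
  # rankings reflect the full elements that were planted
  occ <- occurrenceMatrix(sim$sequences,
                          sim$pwms[setdiff(names(sim$pwms), "NR_half")])
  rep <- segmentSummary(mo, occ, ann, sim$peakset, sim$binding_agonist)
  expect_named(rep, c("ligand_repressed", "basal_repressed",
                      "ligand_activated", "basal_required"))
  act <- rep$ligand_activated
  expect_setequal(act$genes, mo$gene_id[mo$mode == "ligand_activated"])
  # ligand-activated binding peaks were planted with the DR4 element
  expect_equal(act$top_motifs$motif_id[1], "DR4")
  # basal-required peaks were planted with the DR1 element
  expect_equal(rep$basal_required$top_motifs$motif_id[1], "DR1")
  # accessibility of direct-target binding peaks decreases
  expect_lt(act$mean_accessibility_change, 0)

  # an empty segment yields a report, not a crash
  mo0 <- mo
  mo0$mode[mo0$mode == "ligand_repressed"] <- "none"
  rep0 <- segmentSummary(mo0, occ, ann, sim$peakset, sim$binding_agonist)
  expect_equal(rep0$ligand_repressed$n_genes, 0)
  expect_true(is.na(rep0$ligand_repressed$promoter_test_p))
})

test_that("promoter-gain reports cover binding fractions and empty cases", {
  cfg <- simulationConfig(n_genes = 250, n_peaks = 1600, chrom_length = 7e6,
                          rng_seed = 23)
  sim <- simulateStudy(cfg, cuts = FALSE)
  ps <- filterLowCount(sim$peakset)
  rk <- rankPeaks(ps)
  ann <- annotatePeaks(sim$peakset, sim$genome$genes)
  occ <- occurrenceMatrix(sim$sequences, sim$pwms[c("NFY", "DR4")])
  bb <- assignBinding(sim$genome$genes, sim$binding_basal)
  ba <- assignBinding(sim$genome$genes, sim$binding_agonist)
  res <- promoterGainAnalysis(rk, ann, occ, bb, ba, "NFY", top_n = 300,
                              ko_classes = classifyDE(sim$de_ko))
  expect_false(res$empty)
  expect_equal(res$fraction_basal + res$fraction_agonist_only +
                 res$fraction_unbound, 1, tolerance = 1e-9)
  expect_error(promoterGainAnalysis(rk, ann, occ, bb, ba, "nope"),
               "absent")

  # no gain peak carries the motif -> flagged empty report
  pres <- occPresence(occ)
  pres[, "NFY"] <- FALSE
  occ0 <- new("OccurrenceMatrix", presence = pres, hits = data.frame(),
              score_fraction = 0.8)
  res0 <- promoterGainAnalysis(rk, ann, occ0, bb, ba, "NFY", top_n = 300)
  expect_true(res0$empty)
  expect_true(is.na(res0$fraction_basal))
})

test_that("TF expression reports are verbatim lookups with class labels", {
  de <- DETable(c("Foxa2", "Ppara"), c(0.8, -0.4), c(0.5, 0.01), "ko")
  tb <- tfExpressionReport(de, c("Foxa2", "Ppara", "Hnf4a"))
  expect_equal(tb$class, c("unchanged", "down", "untested"))
  expect_equal(tb$log2fc[1], 0.8)
  expect_true(is.na(tb$log2fc[3]))
})

test_that("planted binding enrichment separates DE classes across seeds", {
  hits_prop <- 0
  for (seed in 1:3) {
    cfg <- simulationConfig(n_genes = 200, n_peaks = 1200, chrom_length = 6e6,
                            rng_seed = 100 + seed)
    sim <- simulateStudy(cfg, cuts = FALSE)
    classes <- classifyDE(sim$de_ko)
    bb <- assignBinding(sim$genome$genes, sim$binding_agonist)
    pr <- bindingByClass(classes, bb)$proportions
    if (pr$proportion[pr$class == "down"] >
        pr$proportion[pr$class == "unchanged"]) hits_prop <- hits_prop + 1
  }
  expect_gte(hits_prop, 3)
})
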