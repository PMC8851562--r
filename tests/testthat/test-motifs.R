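test_that("scanning finds the consensus and is strand-symmetric", {
  pw <- consensusPWM("M", "ACGGTCAT")
  h <- scanPWM("ACGGTCAT", pw)
  expect_true(any(h$start == 1 & h$strand == "+"))
  lo <- log2(pwmMatrix(pw) / 0.25)
  expect_equal(max(h$score), sum(apply(lo, 2, max)), tolerance = 1e-9)

  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ACGGTCAT")))
  h2 <- scanPWM(rc, pw)
  expect_true(any(h2$start == 1 & h2$strand == "-"))
  expect_equal(max(h2$score), max(h$score), tolerance = 1e-9)

  # shorter than the motif: empty, not an error
  expect_equal(nrow(scanPWM("ACG", pw)), 0)
  # N positions never score
  expect_equal(nrow(scanPWM("ACGGTCNT", pw)), 0)
})

test_that("hit sets equal brute-force per-offset recomputation", {
  for (seed in 1:5) {
    pw <- random_pwm("R", 8, seed = seed)
    seq <- random_dna(1000, seed = seed + 100)
    got <- scanPWM(seq, pw, 0.8)
    want <- bf_scan(seq, pw, 0.8)
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("forward-strand hits agree with Biostrings matchPWM", {
  pw <- random_pwm("R", 8, seed = 2)
  seq <- random_dna(1000, seed = 3)
  ours <- scanPWM(seq, pw, 0.8)
  lo <- log2(pwmMatrix(pw) / pwmBackground(pw))
  ext <- start(Biostrings::matchPWM(lo, Biostrings::DNAString(seq),
                                    min.score = "80%"))
  expect_equal(ours$start[ours$strand == "+"], ext)
})

test_that("occurrence matrices keep the bookkeeping identities", {
  pwms <- PWMotifList(consensusPWM("M1", "ACGGTCAT"),
                      consensusPWM("M2", "TTTTCCCC"))
  seqs <- Biostrings::DNAStringSet(c(
    pA = paste0(random_dna(80, 1), "ACGGTCAT", random_dna(80, 2)),
    pB = random_dna(150, 3),
    pC = paste0("TTTTCCCC", random_dna(100, 4))))
  occ <- occurrenceMatrix(seqs, pwms, 0.9)
  pres <- occPresence(occ)
  expect_true(pres["pA", "M1"])
  expect_true(pres["pC", "M2"])
  # presence equals per-peak/motif tallies of the hit table
  h <- occHits(occ)
  for (p in rownames(pres)) for (m in colnames(pres))
    expect_equal(pres[p, m], any(h$peak_id == p & h$motif_id == m))

  expect_error(occurrenceMatrix(seqs, pwms, required_ids = c("pA", "zz")),
               "missing sequence")
  dup <- seqs
  names(dup) <- c("pA", "pA", "pC")
  expect_error(occurrenceMatrix(dup, pwms), "uniquely named")
})

test_that("stringent thresholds keep motif-free background mostly empty", {
  pw <- random_pwm("R", 10, seed = 6)
  seqs <- Biostrings::DNAStringSet(setNames(
    vapply(1:20, function(i) random_dna(500, seed = 500 + i), ""),
    sprintf("bg%02d", 1:20)))
  occ <- occurrenceMatrix(seqs, PWMotifList(pw), 0.95)
  expect_lte(sum(occPresence(occ)), 2)
})

test_that("reverse-complementing every sequence leaves presence unchanged", {
  pwms <- defaultPWMs()[1:4]
  pwms <- PWMotifList(pwms)
  seqs <- Biostrings::DNAStringSet(setNames(
    vapply(1:15, function(i) random_dna(300, seed = i), ""),
    sprintf("s%02d", 1:15)))
  occ1 <- occPresence(occurrenceMatrix(seqs, pwms, 0.75))
  occ2 <- occPresence(occurrenceMatrix(Biostrings::reverseComplement(seqs),
                                       pwms, 0.75))
  expect_identical(occ1, occ2)
})

test_that("bin enrichment reproduces the exact hypergeometric tail", {
  # N = 10 peaks, K = 4 carriers, one bin of n = 5 holding k = 4:
  # p = C(4,4) C(6,1) / C(10,5) = 6/252
  pres <- matrix(c(rep(TRUE, 4), rep(FALSE, 6)), ncol = 1,
                 dimnames = list(sprintf("p%02d", 1:10), "m"))
  occ <- new("OccurrenceMatrix", presence = pres,
             hits = data.frame(), score_fraction = 0.8)
  bins <- data.frame(peak_id = sprintf("p%02d", 1:10),
                     bin = rep(1:2, each = 5))
  E <- binEnrichment(occ, bins)
  expect_equal(10^-E["m", "1"], 6 / 252, tolerance = 1e-12)

  # exhaustive enumeration over all C(10,5) draws as an independent oracle
  draws <- combn(10, 5)
  k_obs <- colSums(draws <= 4)
  expect_equal(mean(k_obs >= 4), 6 / 252)

  # background-frequency bin scores near zero
  pres2 <- matrix(rep(c(TRUE, FALSE), 10), ncol = 1,
                  dimnames = list(sprintf("q%02d", 1:20), "m"))
  occ2 <- new("OccurrenceMatrix", presence = pres2,
              hits = data.frame(), score_fraction = 0.8)
  bins2 <- data.frame(peak_id = sprintf("q%02d", 1:20),
                      bin = rep(1:2, each = 10))
  E2 <- binEnrichment(occ2, bins2)
  expect_true(all(10^-E2 >= 0.3))
  expect_error(binEnrichment(occ2, data.frame(peak_id = "zz", bin = 1)),
               "unknown peak")
})

test_that("PWM similarity is reflexive, RC-invariant and matches brute force", {
  a <- random_pwm("a", 8, seed = 1)
  expect_equal(pwmSimilarity(a, a), 1, tolerance = 1e-12)
  rc <- PWMotif("arc", pwmMatrix(a)[4:1, 8:1], is_counts = FALSE)
  expect_equal(pwmSimilarity(a, rc), 1, tolerance = 1e-9)
  for (seed in 1:5) {
    b <- random_pwm("b", 8, seed = seed + 50)
    expect_equal(pwmSimilarity(a, b), bf_similarity(a, b), tolerance = 1e-9)
    expect_equal(pwmSimilarity(a, b), pwmSimilarity(b, a), tolerance = 1e-9)
  }
  short <- random_pwm("s", 3, seed = 2)
  expect_error(pwmSimilarity(short, short), "overlap")
})

test_that("landscape filtering drops flat motifs and merges by closure", {
  pwms <- PWMotifList(consensusPWM("M1", "ACGGTCAT", family = "F1"),
                      consensusPWM("M1b", "ACGGTCAT", family = "F1"),
                      consensusPWM("M2", "TTTTCCCC", family = "F2"))
  E <- rbind(M1 = c(5, 3, 1, 0), M1b = c(4, 4, 2, 0),
             M2 = c(0.2, 0.2, 0.2, 0.2))  # flat and never enriched
  colnames(E) <- 1:4
  res <- filterAndMerge(E, pwms, 0.9)
  expect_false("M2" %in% unlist(res$members))
  expect_equal(length(res$members), 1)  # identical PWMs merged
  expect_equal(unname(res$scores[1, ]), c(5, 4, 2, 0))  # elementwise max
  expect_setequal(res$members[[1]], c("M1", "M1b"))

  # A~B > 0.9 and B~C > 0.9 but A~C <= 0.9: one family by single linkage
  set.seed(10)
  cons <- paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = "")
  swap <- function(x, i) {
    v <- strsplit(x, "")[[1]]
    v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
    paste(v, collapse = "")
  }
  A <- consensusPWM("A", cons, family = "FAM")
  B <- consensusPWM("B", swap(cons, 5), family = "FAM")
  C <- consensusPWM("C", swap(swap(cons, 5), 15), family = "FAM")
  expect_gt(pwmSimilarity(A, B), 0.9)
  expect_gt(pwmSimilarity(B, C), 0.9)
  expect_lte(pwmSimilarity(A, C), 0.9)
  E2 <- rbind(A = c(6, 1), B = c(5, 2), C = c(4, 1))
  colnames(E2) <- 1:2
  res2 <- filterAndMerge(E2, PWMotifList(A, B, C), 0.9)
  expect_equal(length(res2$members), 1)
  expect_setequal(res2$members[[1]], c("A", "B", "C"))
})

test_that("subset enrichment reduces to the null when subset == background", {
  pres <- matrix(c(rep(TRUE, 4), rep(FALSE, 6)), ncol = 1,
                 dimnames = list(sprintf("p%02d", 1:10), "m"))
  occ <- new("OccurrenceMatrix", presence = pres,
             hits = data.frame(), score_fraction = 0.8)
  all_ids <- rownames(pres)
  tb <- subsetEnrichment(occ, all_ids, all_ids)
  expect_equal(tb$fold, 1)
  expect_gte(tb$p, 0.5)
  # 5-of-10 subset holding all 4 carriers: same 6/252 enumeration
  tb2 <- subsetEnrichment(occ, sprintf("p%02d", 1:5), all_ids)
  expect_equal(tb2$p, 6 / 252, tolerance = 1e-12)
  expect_error(subsetEnrichment(occ, character(), all_ids), "empty")
  expect_error(subsetEnrichment(occ, "zz", all_ids), "contained")
})

test_that("family co-occurrence counts match brute-force set intersection", {
  pres <- cbind(m1 = c(TRUE, TRUE, FALSE, FALSE, TRUE),
                m2 = c(TRUE, TRUE, FALSE, FALSE, TRUE),
                m3 = c(FALSE, FALSE, TRUE, TRUE, FALSE))
  rownames(pres) <- sprintf("p%d", 1:5)
  occ <- new("OccurrenceMatrix", presence = pres,
             hits = data.frame(), score_fraction = 0.8)
  fams <- list(FA = c("m1"), FB = c("m2"), FC = c("m3"))
  co <- motifCooccurrence(occ, rownames(pres), fams)
  # disjoint families -> zero off-diagonal; always-together -> Jaccard 1
  expect_equal(co$counts["FA", "FC"], 0)
  expect_equal(co$jaccard["FA", "FB"], 1)
  for (f in names(fams)) for (g in names(fams)) {
    sf <- rownames(pres)[pres[, fams[[f]]]]
    sg <- rownames(pres)[pres[, fams[[g]]]]
    expect_equal(unname(co$counts[f, g]), length(intersect(sf, sg)))
  }
})

test_that("rank-targeted planting yields a monotone enrichment landscape", {
  mp <- data.frame(motif_id = c("DR4", "NFY"),
                   target = c("loss", "gain"),
                   rate_max = c(0.5, 0.5), rate_base = c(0.03, 0.03))
  # high background effect rates populate the whole rank axis, so the
  # true-effect ranks that drive planting line up with the measured bins
  cfg <- simulationConfig(n_genes = 60, n_peaks = 800, chrom_length = 3e6,
                          peak_width_min = 200, peak_width_max = 300,
                          bg_loss_rate = 0.3, bg_gain_rate = 0.3,
                          motif_plant = mp, rng_seed = 33)
  sim <- simulateStudy(cfg, cuts = FALSE)
  ps <- filterLowCount(sim$peakset)
  bins <- binPeaks(rankPeaks(ps), 100)
  occ <- occurrenceMatrix(sim$sequences, sim$pwms[c("DR4", "NFY")],
                          required_ids = bins$peak_id)
  E <- binEnrichment(occ, bins)
  nb <- ncol(E)
  # loss-targeted motif trends down across bins, gain-targeted up
  expect_lte(cor(E["DR4", ], seq_len(nb), method = "spearman"), -0.6)
  expect_gte(cor(E["NFY", ], seq_len(nb), method = "spearman"), 0.6)
  # the maxima sit on the planted halves of the axis
  expect_lte(unname(which.max(E["DR4", ])), nb / 2)
  expect_gte(unname(which.max(E["NFY", ])), nb / 2)
})
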