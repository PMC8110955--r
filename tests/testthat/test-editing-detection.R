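# Editing detection: base counting, Fisher/Hochberg/odds-ratio statistics,
# call generation, normalisation, effect annotation.

test_that("fisher_exact matches enumeration and the reference implementation", {
  expect_equal(fisher_exact(5, 5, 5, 5), 1)
  expect_equal(fisher_exact(0, 10, 0, 10), 1)
  # brute-force enumeration over all tables with margins (10, 14, 12, 12)
  expect_equal(fisher_exact(1, 9, 11, 3), oracle_fisher(1, 9, 11, 3),
               tolerance = 1e-7)
  set.seed(101)
  for (rep in 1:50) {
    t <- rpois(4, 8)
    expect_equal(fisher_exact(t[1], t[2], t[3], t[4]),
                 fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
  # one-sided modes agree with fisher.test alternatives
  expect_equal(fisher_exact(9, 1, 2, 8, alternative = "greater"),
               fisher.test(rbind(c(9, 1), c(2, 8)),
                           alternative = "greater")$p.value)
  expect_equal(fisher_exact(1, 9, 8, 2, alternative = "less"),
               fisher.test(rbind(c(1, 9), c(8, 2)),
                           alternative = "less")$p.value)
  expect_error(fisher_exact(-1, 2, 3, 4), "non-negative")
  # vectorised call equals scalar calls
  a <- c(0, 3, 7); b <- c(9, 2, 0); cc <- c(4, 4, 4); d <- c(1, 8, 2)
  expect_equal(fisher_exact(a, b, cc, d),
               mapply(fisher_exact, a, b, cc, d))
})

test_that("hochberg_adjust reproduces the step-up rule and its properties", {
  expect_equal(hochberg_adjust(0.5), 0.5)
  expect_equal(hochberg_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # step-up by hand: p sorted desc, adjusted(i) = min over j<=i of (j)*p(j)
  p <- c(0.001, 0.2, 0.8, 0.012, 0.04)
  manual <- function(p) {
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    adj <- pmin(1, cummin(seq_len(m) * p[o]))
    adj[order(o)]
  }
  expect_equal(hochberg_adjust(p), manual(p))
  set.seed(102)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- hochberg_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    perm <- sample(length(p))
    expect_equal(hochberg_adjust(p[perm]), adj[perm])
    # monotone coupling: increasing one raw p never decreases any adjusted p
    i <- sample(length(p), 1)
    p2 <- p
    p2[i] <- min(1, p[i] + runif(1))
    expect_true(all(hochberg_adjust(p2) >= adj - 1e-12))
  }
  expect_error(hochberg_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("pseudocounted odds ratio is finite, symmetric and exact", {
  z <- pseudo_odds_ratio(0, 0, 0, 0)
  expect_equal(z$odds_ratio, 1)
  expect_equal(z$log_odds_ratio, 0)
  # swapping rows gives the reciprocal OR and negated log OR
  set.seed(103)
  for (rep in 1:20) {
    t <- rpois(4, 5)
    fwd <- pseudo_odds_ratio(t[1], t[2], t[3], t[4])
    rev <- pseudo_odds_ratio(t[3], t[4], t[1], t[2])
    expect_equal(rev$odds_ratio, 1 / fwd$odds_ratio)
    expect_equal(rev$log_odds_ratio, -fwd$log_odds_ratio)
  }
  # configurable base and pseudocount
  expect_equal(pseudo_odds_ratio(3, 1, 1, 3, pseudocount = 1,
                                 log_base = 2)$log_odds_ratio,
               log2((4 * 4) / (2 * 2)))
  expect_error(pseudo_odds_ratio(1, 1, 1, 1, pseudocount = 0), "positive")
})

test_that("count_bases tallies strand-specific transcript-sense bases", {
  # 10 forward reads all matching a C at position 5
  fwd <- make_sam("ref", 20, data.frame(pos = 3, flag = 0,
                                        seq = rep("TTCTT", 10)))
  bc <- counts_from_sam_lines(fwd, sample_name = "s1")
  row <- bc[bc$position == 5 & bc$strand == "+", ]
  expect_equal(row$n_C, 10)
  expect_equal(row$n_A + row$n_G + row$n_T, 0)

  # 10 reverse-strand reads showing reference G with 2 A mismatches:
  # transcript sense on the minus strand is C8 / T2
  rev <- make_sam("ref", 20, data.frame(pos = 3, flag = 16,
                                        seq = c(rep("TTGTT", 8),
                                                rep("TTATT", 2))))
  bc <- counts_from_sam_lines(rev)
  row <- bc[bc$position == 5 & bc$strand == "-", ]
  expect_equal(row$n_C, 8)
  expect_equal(row$n_T, 2)

  # reverse-stranded library convention flips the assignment
  bc2 <- counts_from_sam_lines(rev, strandedness = "reverse")
  row2 <- bc2[bc2$position == 5 & bc2$strand == "+", ]
  expect_equal(row2$n_G, 8)
  expect_equal(row2$n_A, 2)
})

test_that("count_bases respects the base-quality floor", {
  low <- make_sam("ref", 20, data.frame(pos = 3, flag = 0, seq = "TTCTT",
                                        qual = "#####"))  # Q2
  hi <- make_sam("ref", 20, data.frame(pos = 3, flag = 0, seq = "TTCTT"))
  bc_lo <- counts_from_sam_lines(low, min_base_quality = 13)
  expect_equal(nrow(bc_lo), 0)
  bc_hi <- counts_from_sam_lines(hi, min_base_quality = 13)
  expect_equal(bc_hi[bc_hi$position == 5, "n_C"], 1)
})

test_that("count_bases agrees exactly with the SAM generator's truth", {
  sim <- simulate_genome(400, seed = 104, coverage = 50, error_rate = 0)
  sim <- plant_editing_sites(sim, 2, efficiency_treatment = 1)
  sam <- simulate_sam(sim, n_reads = 300, read_length = 40,
                      role = "treatment")
  bc <- counts_from_sam_lines(sam)
  chars <- strsplit(as.character(sim$genome[[1]]), "")[[1]]
  planted <- sim$truth$editing_sites$position
  # with efficiency 1 and no errors, planted C positions read all-T
  for (p in planted) {
    row <- bc[bc$position == p & bc$strand == "+", ]
    if (nrow(row)) expect_equal(row$n_C, 0)
    if (nrow(row)) expect_gt(row$n_T, 0)
  }
  # everywhere else the transcript-sense reference base is reported
  other <- bc[!(bc$position %in% planted & bc$strand == "+"), ]
  ref_base <- ifelse(other$strand == "+", chars[other$position],
                     chartr("ACGT", "TGCA", chars[other$position]))
  counts <- as.matrix(other[, c("n_A", "n_C", "n_G", "n_T")])
  hit <- counts[cbind(seq_len(nrow(counts)),
                      match(ref_base, c("A", "C", "G", "T")))]
  expect_equal(unname(rowSums(counts)), unname(hit))
})

test_that("base-count tables round-trip through TSV", {
  sim <- simulate_genome(50, seed = 105, coverage = 30)
  bc <- simulate_counts(sim, "treatment")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_base_counts(bc, f)
  bc2 <- read_base_counts(f)
  expect_equal(as.data.frame(bc2), as.data.frame(bc))
})

test_that("detect_editing recovers a strongly planted site uniquely", {
  sim <- simulate_genome(600, seed = 106, coverage = 500, error_rate = 0.001)
  sim <- plant_editing_sites(sim, 1, efficiency_treatment = 0.4,
                             efficiency_control = 0)
  calls <- detect_editing(simulate_counts(sim, "treatment"),
                          simulate_counts(sim, "control"), sim$genome)
  sig <- calls[calls$significant, ]
  expect_equal(nrow(sig), 1)
  expect_equal(sig$position, sim$truth$editing_sites$position)
  expect_gt(sig$log_odds_ratio, 2)
  expect_equal(sig$percent_edited_treat,
               100 * sig$edited_treat / (sig$edited_treat + sig$unedited_treat))
})

test_that("detect_editing is symmetric under swapping treatment and control", {
  sim <- simulate_genome(300, seed = 107, coverage = 100)
  sim <- plant_editing_sites(sim, 1, efficiency_treatment = 0.3)
  tr <- simulate_counts(sim, "treatment")
  ct <- simulate_counts(sim, "control")
  fwd <- detect_editing(tr, ct, sim$genome)
  rev <- detect_editing(ct, tr, sim$genome)
  expect_equal(rev$p_raw, fwd$p_raw)
  expect_equal(rev$log_odds_ratio, -fwd$log_odds_ratio)
  expect_equal(rev$edited_treat, fwd$edited_ctrl)
})

test_that("percent edited is scale-free while p-values sharpen", {
  ref <- c(r = "AACAA")
  small <- detect_editing(manual_counts("r", 3, "+", n_C = 6, n_T = 4),
                          manual_counts("r", 3, "+", n_C = 10, n_T = 0), ref)
  big <- detect_editing(manual_counts("r", 3, "+", n_C = 60, n_T = 40),
                        manual_counts("r", 3, "+", n_C = 100, n_T = 0), ref)
  expect_equal(small$percent_edited_treat, 40)
  expect_equal(big$percent_edited_treat, 40)
  expect_lt(big$p_raw, small$p_raw)
})

test_that("candidate family covers transcript-sense Cs on both strands", {
  ref <- c(r = "ACGTC")  # C at 2, 5 (+ strand); G at 3 (- strand)
  cand <- candidate_sites(ref)
  expect_equal(nrow(cand), 3)
  expect_setequal(cand$position[cand$strand == "+"], c(2, 5))
  expect_equal(cand$position[cand$strand == "-"], 3)
  # zero-coverage treatment: percent is NA, not 0
  calls <- detect_editing(manual_counts("r", 3, "-", n_C = 0, n_T = 0),
                          manual_counts("r", 3, "-", n_C = 10, n_T = 1), ref)
  site <- calls[calls$position == 3, ]
  expect_true(is.na(site$percent_edited_treat))
  # sites with no coverage anywhere are excluded from the family
  expect_false(any(calls$position == 2))
  # mismatched references error
  expect_error(
    detect_editing(manual_counts("other", 1, "+", 1, 1),
                   manual_counts("r", 3, "+", 1, 1), ref),
    "unknown sequence"
  )
})

test_that("null simulations keep the family-wise error within alpha", {
  false_runs <- 0L
  for (seed in 1:5) {
    sim <- simulate_genome(400, seed = seed, coverage = 200,
                           error_rate = 0.001)
    calls <- detect_editing(simulate_counts(sim, "treatment"),
                            simulate_counts(sim, "control"), sim$genome)
    false_runs <- false_runs + any(calls$p_adj < 0.05)
  }
  # FWER control: expect ~0.05 * 5 runs with any adjusted rejection
  expect_lte(false_runs, 1L)
})

test_that("size factors: closed forms and the DESeq2 reference agree", {
  m <- cbind(s1 = c(10, 25, 40), s2 = c(10, 25, 40))
  expect_equal(unname(size_factors(m)$size_factors), c(1, 1))

  m2 <- cbind(s1 = c(10, 25, 40), s2 = c(20, 50, 80))
  sf <- size_factors(m2, baseline = "s1")
  expect_equal(unname(sf$size_factors), c(1 / sqrt(2), sqrt(2)))
  expect_equal(sf$normalised[, "s1"], sf$normalised[, "s2"])
  expect_equal(unname(sf$log2_fold_vs_baseline[, "s2"]), rep(0, 3))

  set.seed(108)
  m3 <- matrix(rpois(60, 50) + 1, ncol = 3,
               dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(unname(size_factors(m3)$size_factors),
               unname(DESeq2::estimateSizeFactorsForMatrix(m3)),
               tolerance = 1e-10)

  expect_error(size_factors(cbind(a = c(0, 1), b = c(1, 0))), "no gene")
})

test_that("annotate_effect classifies coding, intron and intergenic sites", {
  # layout: CDS 11..40 (+, phase 0); gene2 61..120 with an intron 81..100
  ref_seq <- paste0(strrep("A", 10),
                    "ATGTCAGGCTGCAAATTTGGATCCTAGAAA",  # CDS, phase 0
                    strrep("A", 20),
                    "ATGGCATCATTTTTTGAAAA",              # exon1 61..80
                    strrep("A", 20),                     # intron 81..100
                    "CATCATCATCATCATCATAG")              # exon2 101..120
  ref <- c(chr = ref_seq)
  gff <- c("##gff-version 3",
           "chr\ttest\tgene\t11\t40\t.\t+\t.\tID=gene1",
           "chr\ttest\tmRNA\t11\t40\t.\t+\t.\tID=mrna1;Parent=gene1",
           "chr\ttest\tCDS\t11\t40\t.\t+\t0\tID=cds1;Parent=mrna1",
           "chr\ttest\tgene\t61\t120\t.\t+\t.\tID=gene2",
           "chr\ttest\tmRNA\t61\t120\t.\t+\t.\tID=mrna2;Parent=gene2",
           "chr\ttest\texon\t61\t80\t.\t+\t.\tParent=mrna2",
           "chr\ttest\texon\t101\t120\t.\t+\t.\tParent=mrna2")
  gf <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, gf)

  # position 15: codon 2 (TCA, Ser), codon position 2 -> TTA (Leu)
  # position 21: codon 4 (GGA)... use 18 GGC -> GGT check instead:
  # codon 3 spans 17..19 = GCT; choose positions accordingly
  calls <- data.frame(sequence = "chr", position = c(15, 90, 3),
                      strand = "+")
  ann <- annotate_effect(calls, gf, ref)
  expect_equal(ann$category,
               c("nonsynonymous", "intron", "UTR/intergenic"))
  expect_equal(ann$codon_before[1], "TCA")
  expect_equal(ann$codon_after[1], "TTA")
  expect_equal(ann$aa_before[1], "S")
  expect_equal(ann$aa_after[1], "L")
  expect_equal(ann$codon_position[1], 2L)
})

test_that("synonymous third-position edits and minus-strand CDS are handled", {
  # minus-strand CDS 6..17: transcript = revcomp(ref[6..17])
  # choose ref so transcript = ATG GGC TCA TAA; GGC codon pos 3: C->T = GGT
  tx <- "ATGGGCTCATAA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx)))
  ref <- c(chr = paste0("AAAAA", rc, "AAAAA"))
  gff <- c("##gff-version 3",
           "chr\ttest\tgene\t6\t17\t.\t-\t.\tID=g",
           "chr\ttest\tCDS\t6\t17\t.\t-\t0\tID=c;Parent=g")
  gf <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, gf)
  # transcript position 6 (C of GGC) is reverse coordinate 17 - 6 + 1 = 12
  calls <- data.frame(sequence = "chr", position = 12, strand = "-")
  ann <- annotate_effect(calls, gf, ref)
  expect_equal(ann$category, "synonymous")
  expect_equal(ann$codon_before, "GGC")
  expect_equal(ann$codon_after, "GGT")
  expect_equal(ann$aa_before, "G")
  expect_equal(ann$aa_after, "G")
  expect_equal(ann$codon_position, 3L)
})

test_that("CDS models with broken length are skipped with a warning", {
  ref <- c(chr = strrep("ACGT", 10))
  gff <- c("##gff-version 3",
           "chr\ttest\tCDS\t5\t11\t.\t+\t0\tID=bad")  # length 7
  gf <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, gf)
  calls <- data.frame(sequence = "chr", position = 7, strand = "+")
  expect_warning(ann <- annotate_effect(calls, gf, ref), "multiple of 3")
  expect_equal(ann$category, "UTR/intergenic")
})
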