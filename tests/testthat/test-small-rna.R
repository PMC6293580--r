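test_that("a planted 24-nt sequence is found at exactly its locus with 0 mismatches", {
  sim <- fixture_sim()
  sg <- sim$A
  chr <- names(sg$seqs)[1]
  planted <- as.character(Biostrings::subseq(sg$seqs[[chr]], 10001, 10024))
  loci <- find_target_loci(c(s1 = planted), list(sg), max_mismatches = 0)
  hit <- loci[loci$chrom == chr & loci$start == 10000, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$end - hit$start, 24L)
})

test_that("loci beyond the mismatch budget are not reported", {
  seq <- paste(rep("A", 500), collapse = "")
  target <- "ACGTACGTACGTACGTACGTACGT"
  sv <- strsplit(seq, "")[[1]]
  tv <- strsplit(target, "")[[1]]
  mutated <- tv; mutated[c(3, 9, 15)] <- c("T", "C", "A")  # 3 mismatches
  sv[101:124] <- mutated
  sg <- toy_subgenome(seq = paste(sv, collapse = ""), label = "A")
  expect_equal(nrow(find_target_loci(c(s = target), list(sg),
                                     max_mismatches = 2)), 0L)
  got <- find_target_loci(c(s = target), list(sg), max_mismatches = 3)
  expect_true(100 %in% got$start)
  # (ACGT)n is its own reverse complement, so both strands report the locus
  expect_equal(got$mismatches[got$start == 100], c(3L, 3L))
  expect_setequal(got$strand[got$start == 100], c("+", "-"))
})

test_that("target search matches the position-by-position scan oracle on both strands", {
  set.seed(71)
  seq <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
               collapse = "")
  sg <- toy_subgenome(seq = seq, label = "A")
  for (i in 1:10) {
    # sRNAs seeded from the genome with 0-2 mutations, so matches exist
    s0 <- sample(0:(20000 - 24), 1)
    pat <- strsplit(substr(seq, s0 + 1, s0 + 24), "")[[1]]
    nmut <- sample(0:2, 1)
    if (nmut > 0) {
      at <- sample(24, nmut)
      for (a in at) pat[a] <- sample(setdiff(c("A","C","G","T"), pat[a]), 1)
    }
    pat <- paste(pat, collapse = "")
    got <- find_target_loci(stats::setNames(pat, "s"), list(sg),
                            max_mismatches = 2)
    exp_plus <- oracle_srna_scan(pat, seq, 2)
    exp_minus <- oracle_srna_scan(rc(pat), seq, 2)
    expect_setequal(got$start[got$strand == "+"], exp_plus)
    expect_setequal(got$start[got$strand == "-"], exp_minus)
  }
})

test_that("target search is strand-symmetric under genome reverse-complement", {
  set.seed(72)
  seq <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
               collapse = "")
  sg_f <- toy_subgenome(seq = seq, label = "A")
  sg_r <- toy_subgenome(seq = rc(seq), label = "A")
  pat <- substr(seq, 1001, 1024)
  f <- find_target_loci(c(s = pat), list(sg_f), max_mismatches = 2)
  r <- find_target_loci(c(s = pat), list(sg_r), max_mismatches = 2)
  expect_equal(nrow(f), nrow(r))
  # a + locus at [s, e) maps to a - locus at [L - e, L - s)
  expect_setequal(5000 - f$end[f$strand == "+"],
                  r$start[r$strand == "-"])
})

test_that("ambiguous sRNAs are skipped with a warning", {
  sg <- toy_subgenome(label = "A")
  expect_warning(got <- find_target_loci(c(bad = "ACGTNNACGTACGTACGTACGTAC"),
                                         list(sg)), "ambiguous")
  expect_equal(nrow(got), 0L)
})

test_that("abundance/methylation direction pairing follows the RdDM pattern", {
  srna <- data.frame(srna_id = c("t1", "t2", "t3"),
                     S1 = c(50, 10, 20), S3 = c(0, 10, 35))
  lm <- data.frame(srna_id = c("t1", "t1", "t2", "t3"),
                   subgenome = "A", chrom = "chr1",
                   start = c(100, 900, 2000, 3000),
                   end = c(124, 924, 2024, 3024),
                   S1 = c(5, 4, 3, 1), S3 = c(1, 6, 3, 2))
  res <- associate_srna_methylation(srna, lm, c("S1", "S3"))
  r <- res$records
  # sRNA lost in S3 with methylation loss -> concordant
  expect_true(r$concordant[r$srna_id == "t1" & r$start == 100])
  # sRNA lost but methylation gained -> discordant
  expect_false(r$concordant[r$srna_id == "t1" & r$start == 900])
  # unchanged sRNA: not evaluated
  expect_true(is.na(r$concordant[r$srna_id == "t2"]))
  expect_equal(res$summary$n_evaluated, 3)
  expect_equal(res$summary$n_concordant, 2)
})

test_that("loci without methylation data are excluded and counted", {
  srna <- data.frame(srna_id = "t1", S1 = 10, S2 = 0)
  lm <- data.frame(srna_id = c("t1", "t1"), subgenome = "A", chrom = "chr1",
                   start = c(0, 50), end = c(24, 74),
                   S1 = c(2, NA), S2 = c(1, 3))
  res <- associate_srna_methylation(srna, lm, c("S1", "S2"))
  expect_equal(res$summary$n_missing_methylation, 1)
  expect_equal(res$summary$n_records, 1)
})

test_that("planted concordance is recovered from the simulated sRNA tables", {
  sim <- fixture_sim()
  sr <- simulate_srnas(sim, n_srna = 120, concordant_fraction = 0.8)
  res <- associate_srna_methylation(sr$srna_table, sr$locus_methylation,
                                    c("S1", "S3"))
  expect_gte(res$summary$n_evaluated, 60)
  expect_lt(abs(res$summary$concordant_fraction - 0.8), 0.1)
})

test_that("locus methylation RPM counts reads in the +/-100 bp window", {
  loci <- data.frame(srna_id = "t1", subgenome = "A", chrom = "chr1",
                     start = 1000, end = 1024)
  reads <- rbind(read_row("r1", a = iv("chr1", 950, 1050)),
                 read_row("r2", a = iv("chr1", 1100, 1200)),  # overlaps window end
                 read_row("r3", a = iv("chr1", 5000, 5100)))  # outside
  got <- locus_methylation_rpm(loci, reads, total_clean_reads = 1e6)
  expect_equal(got$rpm, 2)
})
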