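# tiny Smith-Waterman DP, used only as an oracle for the built-in aligner
sw_score <- function(a, b, mat, gap_open = 11, gap_ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- E <- F <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(E[i, j - 1] - gap_ext, H[i, j - 1] - gap_open - gap_ext)
    F[i, j] <- max(F[i - 1, j] - gap_ext, H[i - 1, j] - gap_open - gap_ext)
    H[i, j] <- max(0, H[i - 1, j - 1] + mat[av[i - 1], bv[j - 1]],
                   E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

test_that("identical proteins hit far below the E-value cutoff; unrelated ones do not", {
  set.seed(5)
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")
  p1 <- paste(sample(aa, 200, replace = TRUE), collapse = "")
  p2 <- paste(sample(aa, 200, replace = TRUE), collapse = "")
  A <- Biostrings::AAStringSet(c(a1 = p1, a2 = p2))
  B <- Biostrings::AAStringSet(c(b1 = p1))   # b1 identical to a1
  hits <- all_vs_all_similarity(A, B)
  expect_equal(hits$query_id, "a1")
  expect_lt(hits$evalue, 1e-100)

  # cross-check the retained score against a hand-rolled Smith-Waterman +
  # Karlin-Altschul conversion on shorter sequences
  q <- paste(sample(aa, 60, replace = TRUE), collapse = "")
  s <- paste(sample(aa, 60, replace = TRUE), collapse = "")
  bl62 <- get(data("BLOSUM62", package = "Biostrings",
                   envir = environment()), envir = environment())
  for (pair in list(c(q, q), c(q, s))) {
    raw <- sw_score(pair[1], pair[2], bl62)
    bit <- (0.267 * raw - log(0.041)) / log(2)
    ev <- 60 * 60 * 2^(-bit)
    got <- all_vs_all_similarity(
      Biostrings::AAStringSet(c(q = pair[1])),
      Biostrings::AAStringSet(c(s = pair[2])),
      evalue_cutoff = Inf)
    expect_equal(got$score, bit, tolerance = 1e-10)
    expect_equal(got$evalue, ev, tolerance = 1e-10)
  }
  # unrelated random pair is not retained at the 1e-20 cutoff
  got <- all_vs_all_similarity(Biostrings::AAStringSet(c(q = q)),
                               Biostrings::AAStringSet(c(s = s)))
  expect_equal(nrow(got), 0L)
})

test_that("external tabular hits are filtered by E-value on ingestion", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rows <- data.frame(q = c("A1", "A2", "A3", "A4", "A5"),
                     s = paste0("B", 1:5), pid = 90, len = 100, mm = 5,
                     go = 1, qs = 1, qe = 100, ss = 1, se = 100,
                     ev = c(1e-50, 1e-30, 1e-21, 1e-10, 0.5),
                     bits = c(200, 150, 120, 60, 30))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  got <- read_similarity_hits(path)
  expect_equal(nrow(got), 3L)   # two rows above the cutoff dropped
  expect_equal(got$query_id, c("A1", "A2", "A3"))
})

test_that("reciprocal best hits require agreement in both directions", {
  h <- data.frame(query_id = c("A1", "A1", "A2"),
                  subject_id = c("B1", "B2", "B2"),
                  score = c(300, 80, 250), evalue = c(1e-80, 1e-21, 1e-60))
  expect_equal(best_hit_pairs(h)$b_gene_id, c("B1", "B2"))

  # A1 -> B1 but B1 -> A2: reciprocity fails, no pair for A1
  h2 <- data.frame(query_id = c("A1", "A2"), subject_id = c("B1", "B1"),
                   score = c(100, 200), evalue = c(1e-30, 1e-60))
  expect_equal(best_hit_pairs(h2)$a_gene_id, "A2")
})

test_that("best-hit pairs equal the exhaustive reciprocal-best oracle on random tables", {
  set.seed(77)
  for (rep in 1:5) {
    h <- data.frame(
      query_id = sample(paste0("A", 1:20), 60, replace = TRUE),
      subject_id = sample(paste0("B", 1:20), 60, replace = TRUE),
      score = sample(50:300, 60, replace = TRUE),
      evalue = 10^-runif(60, 21, 80))
    h <- h[!duplicated(h[c("query_id", "subject_id")]), ]
    got <- best_hit_pairs(h)
    exp <- oracle_rbh(h)
    expect_equal(got$a_gene_id, exp$a)
    expect_equal(got$b_gene_id, exp$b)
    # determinism under row shuffling
    got2 <- best_hit_pairs(h[sample(nrow(h)), ])
    expect_equal(got2, got)
  }
})

test_that("synteny filter keeps blocks with >= 3 pairs and rejects isolated pairs", {
  mk_sg <- function(label, ids, starts, chrom = "chr1") {
    genes <- data.frame(gene_id = ids, chrom = chrom, start = starts,
                        end = starts + 1000, strand = "+",
                        has_protein = TRUE, stringsAsFactors = FALSE)
    structure(list(label = label, seqs = NULL,
                   seqlengths = c(chr1 = 10000000L), genes = genes,
                   proteins = NULL), class = "SubGenome")
  }
  # 3 pairs inside one A-block/B-block combination + 1 isolated pair
  a <- mk_sg("A", paste0("A", 1:4), c(1000, 20000, 50000, 500000))
  b <- mk_sg("B", paste0("B", 1:4), c(5000, 30000, 80000, 900000))
  pairs <- data.frame(a_gene_id = paste0("A", 1:4),
                      b_gene_id = paste0("B", 1:4),
                      score = 100, reciprocal = TRUE)
  got <- synteny_filter(pairs, a, b)
  expect_equal(got$a_gene_id, paste0("A", 1:3))
  expect_equal(got$block_support, rep(3L, 3))   # threshold met exactly
})

test_that("synteny filter matches brute-force block enumeration on random layouts", {
  set.seed(31)
  for (rep in 1:4) {
    n <- 60
    mk <- function(label, pre) {
      genes <- data.frame(
        gene_id = paste0(pre, 1:n),
        chrom = sample(c("c1", "c2"), n, replace = TRUE),
        start = sample.int(400000, n), stringsAsFactors = FALSE)
      genes$end <- genes$start + 1000; genes$strand <- "+"
      genes$has_protein <- TRUE
      structure(list(label = label, seqs = NULL,
                     seqlengths = c(c1 = 500000L, c2 = 500000L),
                     genes = genes, proteins = NULL), class = "SubGenome")
    }
    a <- mk("A", "A"); b <- mk("B", "B")
    pairs <- data.frame(a_gene_id = paste0("A", 1:n),
                        b_gene_id = paste0("B", 1:n),
                        score = runif(n, 50, 300), reciprocal = TRUE)
    got <- synteny_filter(pairs, a, b)
    exp <- oracle_synteny(pairs, a$genes, b$genes)
    expect_equal(got$a_gene_id, sort(exp$a_gene_id))
    expect_equal(got$block_support[order(got$a_gene_id)],
                 exp$block_support[order(exp$a_gene_id)])
  }
})

test_that("merged genes partition every input gene exactly once", {
  sim <- fixture_sim()
  mg <- build_merged_genes(sim$truth$pairs, sim$A, sim$B)
  n_pairs <- nrow(sim$truth$pairs)
  expect_equal(nrow(mg),
               nrow(sim$A$genes) + nrow(sim$B$genes) - n_pairs)
  expect_setequal(stats::na.omit(mg$a_gene_id), sim$A$genes$gene_id)
  expect_setequal(stats::na.omit(mg$b_gene_id), sim$B$genes$gene_id)
  expect_false(anyDuplicated(mg$merged_id) > 0)
  expect_equal(sum(mg$kind == "pair"), n_pairs)

  # 0 pairs: every gene its own merged gene
  mg0 <- build_merged_genes(sim$truth$pairs[0, ], sim$A, sim$B)
  expect_equal(nrow(mg0), nrow(sim$A$genes) + nrow(sim$B$genes))
  expect_true(all(mg0$kind != "pair"))

  # gene in two pairs is a hard error
  bad <- rbind(sim$truth$pairs, sim$truth$pairs[1, ])
  expect_error(build_merged_genes(bad, sim$A, sim$B), "more than one")
})

test_that("orthology recovers planted pairs from simulated proteomes", {
  sim <- fixture_sim()
  hits <- all_vs_all_similarity(sim$A$proteins, sim$B$proteins)
  op <- synteny_filter(best_hit_pairs(hits), sim$A, sim$B)
  truth_key <- paste(sim$truth$pairs$a_gene_id, sim$truth$pairs$b_gene_id)
  got_key <- paste(op$a_gene_id, op$b_gene_id)
  expect_true(all(got_key %in% truth_key))       # no false pairs
  expect_gte(nrow(op), 0.8 * nrow(sim$truth$pairs))
})
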