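test_that("FASTA/GFF3 round-trip preserves gene models and flags missing proteins", {
  sim <- fixture_sim()
  dir <- withr::local_tempdir()
  paths <- write_subgenome(sim$A, dir)
  sg <- suppressMessages(
    load_subgenome(paths$fasta, paths$gff, paths$proteins, label = "A"))
  expect_equal(nrow(sg$genes), nrow(sim$A$genes))
  expect_setequal(sg$genes$gene_id, sim$A$genes$gene_id)
  g0 <- sim$A$genes[match(sg$genes$gene_id, sim$A$genes$gene_id), ]
  expect_equal(sg$genes$start, g0$start)
  expect_equal(sg$genes$end, g0$end)
  expect_equal(sg$genes$strand, g0$strand)
  expect_true(all(sg$genes$has_protein))

  # drop one protein: gene retained, flagged proteinless, with a warning
  prot <- Biostrings::readAAStringSet(paths$proteins)
  Biostrings::writeXStringSet(prot[-1], paths$proteins)
  expect_warning(
    sg2 <- suppressMessages(
      load_subgenome(paths$fasta, paths$gff, paths$proteins)),
    "proteinless")
  expect_equal(sum(!sg2$genes$has_protein), 1L)
})

test_that("a GFF3 gene on an absent chromosome is a hard error naming the gene", {
  sim <- fixture_sim()
  dir <- withr::local_tempdir()
  paths <- write_subgenome(sim$A, dir)
  gff <- readLines(paths$gff)
  bad_id <- sim$A$genes$gene_id[1]
  # rewrite both the gene and its mRNA child onto an absent chromosome
  gff <- vapply(gff, function(l)
    if (grepl(paste0("ID=", bad_id, "(;|$|\\.)"), l) ||
        grepl(paste0("Parent=", bad_id, "($|;)"), l))
      sub("^chr1\t", "chrMissing\t", l) else l, "", USE.NAMES = FALSE)
  writeLines(gff, paths$gff)
  expect_error(suppressMessages(load_subgenome(paths$fasta, paths$gff)),
               bad_id)
})

test_that("promoter/body/TTR arithmetic is strand-aware and clipped at edges", {
  sg <- toy_subgenome(strands = "+")
  r <- derive_regions(sg)
  get <- function(k) unlist(r[r$kind == k, c("start", "end")], use.names = FALSE)
  expect_equal(get("promoter"), c(3000, 5000))
  expect_equal(get("body"), c(5000, 6000))
  expect_equal(get("ttr"), c(6000, 8000))

  sg_m <- toy_subgenome(strands = "-")
  rm_ <- derive_regions(sg_m)
  getm <- function(k) unlist(rm_[rm_$kind == k, c("start", "end")],
                             use.names = FALSE)
  # strand flip swaps promoter and TTR, mirrored about the gene
  expect_equal(getm("promoter"), c(6000, 8000))
  expect_equal(getm("ttr"), c(3000, 5000))
  expect_equal(getm("promoter"), get("ttr"))
  expect_equal(getm("ttr"), get("promoter"))

  # clipping: + strand gene starting at 500 has a 500 bp promoter
  sg_edge <- toy_subgenome(strands = "+")
  sg_edge$genes$start <- 500; sg_edge$genes$end <- 1500
  re <- derive_regions(sg_edge)
  expect_equal(unlist(re[re$kind == "promoter", c("start", "end")],
                      use.names = FALSE), c(0, 500))
})

test_that("no derived region extends past chromosome bounds", {
  sim <- fixture_sim()
  for (sg in list(sim$A, sim$B)) {
    r <- derive_regions(sg)
    expect_true(all(r$start >= 0))
    expect_true(all(r$end <= sg$seqlengths[r$chrom]))
    # body equals the gene interval
    b <- r[r$kind == "body", ]
    g <- sg$genes[match(b$owner_id, sg$genes$gene_id), ]
    expect_equal(b$start, g$start)
    expect_equal(b$end, g$end)
    # promoter/ttr never longer than the flank
    expect_true(all(r$end - r$start <= 2000 | r$kind == "body"))
  }
})

test_that("CpG island detector handles degenerate sequences", {
  at <- paste(rep(c("A", "T"), 500), collapse = "")
  sg <- toy_subgenome(seq = at)
  sg$genes <- sg$genes[0, ]
  expect_equal(nrow(detect_cpg_islands(sg)$islands), 0L)

  cg <- paste(rep("CG", 150), collapse = "")   # 300 bp of CpG repeats
  pad <- paste(rep(c("A", "T"), 1000), collapse = "")
  sg2 <- toy_subgenome(seq = paste0(pad, cg, pad))
  isl <- detect_cpg_islands(sg2)$islands
  expect_equal(nrow(isl), 1L)
  expect_lte(isl$start, 2000)
  expect_gte(isl$end, 2300)
  expect_gte(isl$gc_fraction, 0.5)
  expect_gte(isl$obs_exp_cpg, 0.6)
  expect_gte(isl$end - isl$start, 200)
})

test_that("island detection matches the exhaustive window-scan oracle on random sequence", {
  set.seed(2024)
  for (i in 1:4) {
    # CpG-poor background with an embedded CpG-rich stretch
    bg <- sample(c("A", "C", "G", "T"), 6000, replace = TRUE,
                 prob = c(0.3, 0.2, 0.2, 0.3))
    ins <- sample(c("CG", "A", "T", "C", "G"), 200, replace = TRUE,
                  prob = c(0.3, 0.15, 0.15, 0.2, 0.2))
    s <- paste(c(bg[1:3000], unlist(strsplit(ins, "")), bg[3001:6000]),
               collapse = "")
    got <- detect_cpg_islands(toy_subgenome(seq = s))$islands
    exp <- oracle_cpg_islands(s)
    expect_equal(got$start, exp$start)
    expect_equal(got$end, exp$end)
  }
})

test_that("island shores flank the island without overlapping it", {
  sim <- fixture_sim()
  ci <- detect_cpg_islands(sim$A)
  expect_gt(nrow(ci$islands), 0)
  sh <- ci$shores[ci$shores$kind == "shore", ]
  for (i in seq_len(nrow(ci$islands))) {
    isl <- ci$islands[i, ]
    s_i <- sh[sh$owner_id == isl$island_id, ]
    expect_equal(nrow(s_i), 2L)
    expect_true(all(s_i$end <= isl$start | s_i$start >= isl$end))
    expect_true(all(s_i$end - s_i$start <= 2000))
  }
})

test_that("BED export is 0-based half-open with one file per region kind", {
  sg <- toy_subgenome(strands = "+")
  dir <- withr::local_tempdir()
  paths <- write_regions_bed(derive_regions(sg), file.path(dir, "toy"))
  expect_length(paths, 3)
  prom <- read.table(grep("promoter", paths, value = TRUE), sep = "\t")
  expect_equal(prom$V2, 3000)
  expect_equal(prom$V3, 5000)
})
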