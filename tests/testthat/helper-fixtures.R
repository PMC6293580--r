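# Shared fixtures, built once per test run and cached.
.fix <- new.env(parent = emptyenv())

fixture_sim <- function() {
  if (is.null(.fix$sim))
    .fix$sim <- simulate_subgenomes(sim_config(seed = 11, n_genes = 40))
  .fix$sim
}

fixture_library <- function() {
  if (is.null(.fix$lib))
    .fix$lib <- simulate_reads(fixture_sim(), "S1", 1)
  .fix$lib
}

# hand-built two-gene sub-genome on one 10 kb chromosome
toy_subgenome <- function(strands = c("+", "-"), label = "A",
                          seq = NULL) {
  if (is.null(seq)) {
    set.seed(99)
    seq <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                 collapse = "")
  }
  genes <- data.frame(
    gene_id = paste0(label, "toy", seq_along(strands)),
    chrom = "chr1",
    start = 5000 + (seq_along(strands) - 1L) * 0L,  # overwritten below
    end = 6000, strand = strands, stringsAsFactors = FALSE)
  genes$start <- 5000; genes$end <- 6000
  genes <- genes[!duplicated(genes$gene_id), ]
  genes$has_protein <- FALSE
  structure(list(label = label,
                 seqs = Biostrings::DNAStringSet(c(chr1 = seq)),
                 seqlengths = c(chr1 = nchar(seq)),
                 genes = genes, proteins = NULL),
            class = "SubGenome")
}

# assignment table row constructor for hand-placed reads
read_row <- function(id, a = NULL, b = NULL) {
  klass <- if (!is.null(a) && !is.null(b)) "BOTH"
  else if (!is.null(a)) "A_ONLY" else if (!is.null(b)) "B_ONLY"
  else "UNMAPPED"
  data.frame(read_id = id, klass = klass,
             a_chrom = if (is.null(a)) NA_character_ else a$chrom,
             a_start = if (is.null(a)) NA_integer_ else a$start,
             a_end = if (is.null(a)) NA_integer_ else a$end,
             b_chrom = if (is.null(b)) NA_character_ else b$chrom,
             b_start = if (is.null(b)) NA_integer_ else b$start,
             b_end = if (is.null(b)) NA_integer_ else b$end,
             stringsAsFactors = FALSE)
}
iv <- function(chrom, start, end) list(chrom = chrom, start = start, end = end)
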