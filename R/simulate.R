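#' Simulation configuration for allotetraploid fixtures
#'
#' Collects every knob of the synthetic-data generator with defaults chosen
#' to emulate the allotetraploid regime the package targets: two
#' sub-genomes at ~1% nucleotide divergence (cultivated-peanut reads match
#' the two diploid ancestors at ~98-100% identity), a 60% orthologous gene
#' complement arranged so that syntenic 100 kb blocks carry several pairs,
#' three developmental stages with two replicates, and libraries in which
#' ~5% of reads are unmappable to either sub-genome.
#'
#' Genes are laid out on a fixed 6 kb "slot" grid (2 kb promoter, 1.2 kb
#' body, 2 kb downstream region plus spacers), which keeps every analysis
#' region inside its slot and makes A<->B coordinate bookkeeping exact
#' under the no-indel mutation model.
#'
#' @param seed integer seed; every derived library seed is below 2^31.
#' @param n_chromosomes chromosomes per sub-genome (default 2).
#' @param n_genes genes per sub-genome (default 40).
#' @param chromosome_length optional bp per chromosome; derived from the
#'   slot grid when `NULL`. Too short for the genes is an error.
#' @param fraction_orthologous fraction of genes with an ortholog in the
#'   other sub-genome (default 0.6).
#' @param nucleotide_divergence per-base substitution rate between
#'   orthologous sequence (default 0.01).
#' @param n_replicates replicates per stage (default 2).
#' @param stages stage labels (default `c("S1", "S2", "S3")`).
#' @param region_levels baseline methylation weight of each region kind.
#' @param frac_dmg,dmg_fold fraction of genes with a planted methylation
#'   shift and its fold (defaults 0.1 and 4).
#' @param frac_deg,deg_fold likewise for expression.
#' @param reads_per_library clean reads per library (default 20000).
#' @param read_length read length bp (default 100).
#' @param aligner_tolerance maximum within-read substitutions at which the
#'   emulated aligner still places the read on the homeologous copy
#'   (default 3); drives the type II fraction.
#' @param unmapped_fraction fraction of reads mapping to neither sub-genome
#'   (default 0.05).
#' @param replicate_sdlog lognormal sd of multiplicative replicate noise on
#'   region levels (default 0.25).
#' @param protein_length,protein_divergence protein fixture parameters.
#' @param n_cpg_islands_per_chrom CpG-rich segments planted per chromosome
#'   (default 2).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 2,
                       n_genes = 40,
                       chromosome_length = NULL,
                       fraction_orthologous = 0.6,
                       nucleotide_divergence = 0.01,
                       n_replicates = 2,
                       stages = c("S1", "S2", "S3"),
                       region_levels = c(promoter = 0.5, body = 1, ttr = 0.5),
                       frac_dmg = 0.1, dmg_fold = 4,
                       frac_deg = 0.1, deg_fold = 4,
                       reads_per_library = 20000,
                       read_length = 100,
                       aligner_tolerance = 3,
                       unmapped_fraction = 0.05,
                       replicate_sdlog = 0.25,
                       protein_length = 120,
                       protein_divergence = 0.02,
                       n_cpg_islands_per_chrom = 2) {
  stopifnot(fraction_orthologous >= 0, fraction_orthologous <= 1,
            nucleotide_divergence >= 0, nucleotide_divergence <= 1,
            unmapped_fraction >= 0, unmapped_fraction < 1,
            reads_per_library > 0, n_genes > 0)
  cfg <- as.list(environment())
  cfg$slot_bp <- 6000L
  cfg$gene_offset <- 2400L   # gene occupies [2400, 3600) of its slot
  cfg$gene_bp <- 1200L
  cfg$flank_bp <- 2000L
  cfg$block_bp <- 100000L
  structure(cfg, class = "sim_config")
}

.rand_dna <- function(n, probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# CpG-rich segment: drawn from dinucleotide tokens with a high CG share
.rand_island <- function(n) {
  tok <- sample(c("CG", "A", "T", "C", "G"), n,
                replace = TRUE, prob = c(0.3, 0.15, 0.15, 0.2, 0.2))
  out <- unlist(strsplit(paste(tok, collapse = ""), "", fixed = TRUE))
  out[seq_len(n)]
}

.rand_protein <- function(n) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

.mutate_chars <- function(v, pos) {
  bases <- c("A", "C", "G", "T")
  for (p in pos) v[p] <- sample(setdiff(bases, v[p]), 1)
  v
}

#' Simulate a pair of diverged homeologous sub-genomes with ground truth
#'
#' Builds sub-genome A slot by slot (random CpG-poor background, genes on
#' the slot grid, optional planted CpG-rich segments), then derives
#' sub-genome B: the orthologous fraction of slots is copied with uniform
#' point substitutions at the configured divergence and the slot order is
#' permuted within each 100 kb block (so syntenic blocks still carry >= 3
#' pairs), while the remaining slots are replaced by fresh sequence
#' carrying B-specific genes. Every mutated position is recorded, which
#' lets the read simulator decide exactly which reads an aligner could
#' place on both copies. Stage- and region-resolved methylation and
#' expression levels, with planted differential genes, complete the ground
#' truth.
#'
#' @param config a [sim_config()].
#' @return list of class `homeo_sim`: `A`, `B` (two `SubGenome`s),
#'   `truth` (list: `pairs`, `merged_genes`, `slots`, `mutations`,
#'   `meth_levels`, `expr_levels`, `planted_dmg`, `planted_deg`) and
#'   `config`.
#' @examples
#' sim <- simulate_subgenomes(sim_config(seed = 1, n_genes = 20))
#' sim$A; nrow(sim$truth$pairs)
#' @export
simulate_subgenomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed %% 2147483647L)
  slot_bp <- config$slot_bp
  slots_per_chrom <- ceiling(config$n_genes / config$n_chromosomes)
  if (!is.null(config$chromosome_length)) {
    have <- floor(config$chromosome_length / slot_bp) * config$n_chromosomes
    if (have < config$n_genes)
      .stopf("infeasible layout: %d genes need %d bp but chromosomes hold %d slots",
             config$n_genes, config$n_genes * slot_bp, have)
    slots_per_chrom <- floor(config$chromosome_length / slot_bp)
  }
  chrom_len <- slots_per_chrom * slot_bp
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))

  n_orth <- round(config$fraction_orthologous * config$n_genes)
  gene_idx <- seq_len(config$n_genes)
  orth_genes <- sort(sample(gene_idx, n_orth))
  is_orth <- gene_idx %in% orth_genes

  # --- sub-genome A ---------------------------------------------------
  a_seq <- list(); slot_tab <- list(); a_genes <- list()
  slot_seqs <- list()                      # char vectors, per slot id
  gi <- 0L
  for (ci in seq_along(chroms)) {
    v <- .rand_dna(chrom_len)
    island_slots <- if (config$n_cpg_islands_per_chrom > 0)
      sample(slots_per_chrom,
             min(config$n_cpg_islands_per_chrom, slots_per_chrom)) else integer()
    for (si in seq_len(slots_per_chrom)) {
      s0 <- (si - 1L) * slot_bp
      if (si %in% island_slots)
        v[(s0 + 5651L):(s0 + 5950L)] <- .rand_island(300L)
      if (gi < config$n_genes) {
        gi <- gi + 1L
        gid <- sprintf("Ag%04d", gi)
        slot_id <- sprintf("s%04d", gi)
        slot_seqs[[slot_id]] <- NULL   # filled after island planting
        slot_tab[[gi]] <- data.frame(
          slot_id = slot_id, chrom = chroms[ci], a_start = s0,
          a_gene = gid, orthologous = is_orth[gi], stringsAsFactors = FALSE)
        a_genes[[gi]] <- data.frame(
          gene_id = gid, chrom = chroms[ci],
          start = s0 + config$gene_offset,
          end = s0 + config$gene_offset + config$gene_bp,
          strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
      }
      if (gi > config$n_genes) break
    }
    a_seq[[chroms[ci]]] <- v
  }
  slot_tab <- do.call(rbind, slot_tab)
  a_genes <- do.call(rbind, a_genes)
  for (i in seq_len(nrow(slot_tab)))
    slot_seqs[[slot_tab$slot_id[i]]] <-
      a_seq[[slot_tab$chrom[i]]][(slot_tab$a_start[i] + 1L):(slot_tab$a_start[i] + slot_bp)]

  # --- sub-genome B: permute slots within 100 kb blocks ---------------
  slot_tab$block <- paste(slot_tab$chrom,
                          (slot_tab$a_start + config$gene_offset) %/% config$block_bp)
  slot_tab$b_start <- NA_integer_
  slot_tab$b_gene <- NA_character_
  b_seq <- lapply(chroms, function(ch) .rand_dna(chrom_len))
  names(b_seq) <- chroms
  mutations <- list()
  b_genes <- list(); bs_counter <- 0L
  for (blk in unique(slot_tab$block)) {
    rows <- which(slot_tab$block == blk)
    perm <- if (length(rows) > 1) sample(rows) else rows
    # the A slot at rows[k] lands at the slot position of perm[k] in B
    for (k in seq_along(rows)) {
      src <- rows[k]
      pos <- slot_tab$a_start[perm[k]]
      ch <- slot_tab$chrom[src]
      slot_tab$b_start[src] <- pos
      if (slot_tab$orthologous[src]) {
        sv <- slot_seqs[[slot_tab$slot_id[src]]]
        n_mut <- rbinom(1, slot_bp, config$nucleotide_divergence)
        mpos <- sort(sample(slot_bp, n_mut))
        sv <- .mutate_chars(sv, mpos)
        mutations[[slot_tab$slot_id[src]]] <- mpos
        b_seq[[ch]][(pos + 1L):(pos + slot_bp)] <- sv
        bgid <- sub("^Ag", "Bg", slot_tab$a_gene[src])
        slot_tab$b_gene[src] <- bgid
        b_genes[[length(b_genes) + 1L]] <- data.frame(
          gene_id = bgid, chrom = ch, start = pos + config$gene_offset,
          end = pos + config$gene_offset + config$gene_bp,
          strand = a_genes$strand[a_genes$gene_id == slot_tab$a_gene[src]],
          stringsAsFactors = FALSE)
      } else {
        # fresh B-specific slot (sequence already random); plant a gene
        bs_counter <- bs_counter + 1L
        bgid <- sprintf("Bs%04d", bs_counter)
        slot_tab$b_gene[src] <- bgid
        b_genes[[length(b_genes) + 1L]] <- data.frame(
          gene_id = bgid, chrom = ch, start = pos + config$gene_offset,
          end = pos + config$gene_offset + config$gene_bp,
          strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
      }
    }
  }
  b_genes <- do.call(rbind, b_genes)

  # --- proteins -------------------------------------------------------
  a_prot <- character(nrow(a_genes)); names(a_prot) <- a_genes$gene_id
  b_prot <- character(nrow(b_genes)); names(b_prot) <- b_genes$gene_id
  aa20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
            "T","W","Y","V")
  for (i in seq_len(nrow(slot_tab))) {
    p <- .rand_protein(config$protein_length)
    a_prot[slot_tab$a_gene[i]] <- p
    if (slot_tab$orthologous[i]) {
      pv <- strsplit(p, "", fixed = TRUE)[[1]]
      nm <- rbinom(1, length(pv), config$protein_divergence)
      if (nm > 0) {
        at <- sample(length(pv), nm)
        for (j in at) pv[j] <- sample(setdiff(aa20, pv[j]), 1)
      }
      b_prot[slot_tab$b_gene[i]] <- paste(pv, collapse = "")
    } else {
      b_prot[slot_tab$b_gene[i]] <- .rand_protein(config$protein_length)
    }
  }

  mk_subgenome <- function(label, seqlist, genes, prot) {
    seqs <- Biostrings::DNAStringSet(vapply(seqlist, paste, "",
                                            collapse = ""))
    genes$has_protein <- TRUE
    structure(list(label = label, seqs = seqs,
                   seqlengths = stats::setNames(Biostrings::width(seqs),
                                                names(seqs)),
                   genes = genes,
                   proteins = Biostrings::AAStringSet(prot)),
              class = "SubGenome")
  }
  A <- mk_subgenome("A", a_seq, a_genes, a_prot)
  B <- mk_subgenome("B", b_seq, b_genes, b_prot)

  pairs <- slot_tab[slot_tab$orthologous,
                    c("a_gene_id" = "a_gene", "b_gene_id" = "b_gene")]
  names(pairs) <- c("a_gene_id", "b_gene_id")
  rownames(pairs) <- NULL
  merged <- build_merged_genes(pairs, A, B)

  # --- methylation / expression truth ---------------------------------
  stages <- config$stages
  n_m <- nrow(merged)
  base <- rlnorm(n_m, 0, 0.5)
  lv <- expand.grid(merged_id = merged$merged_id, region =
                      names(config$region_levels), stage = stages,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lv$level <- base[match(lv$merged_id, merged$merged_id)] *
    config$region_levels[lv$region]

  # Planted methylation shifts come in mass-balanced up/down pairs: the
  # "up" gene gains fold F in one region from its change stage on, while
  # its partner (given F times the base level) loses the same absolute
  # mass (fold 1/F). Genome-wide methylation mass is thus conserved across
  # stages, so unplanted genes keep their expected read share - without
  # this, fixed-depth multinomial sampling would shift every null gene.
  n_dmg <- 2L * (round(config$frac_dmg * n_m) %/% 2L)
  planted_dmg <- data.frame(merged_id = character(), region = character(),
                            change_stage = character(), fold = numeric())
  if (n_dmg > 0) {
    pick <- sample(merged$merged_id, n_dmg)
    up <- pick[seq_len(n_dmg / 2)]
    dn <- pick[seq_len(n_dmg / 2) + n_dmg / 2]
    # partner base level = F x the up gene's, so the mass deltas cancel
    b_idx_up <- match(up, merged$merged_id)
    b_idx_dn <- match(dn, merged$merged_id)
    base[b_idx_dn] <- config$dmg_fold * base[b_idx_up]
    lv$level <- base[match(lv$merged_id, merged$merged_id)] *
      config$region_levels[lv$region]
    planted_dmg <- data.frame(
      merged_id = c(up, dn),
      region = rep(sample(names(config$region_levels), n_dmg / 2,
                          replace = TRUE), 2),
      change_stage = rep(sample(stages[-1], n_dmg / 2, replace = TRUE), 2),
      fold = rep(c(config$dmg_fold, 1 / config$dmg_fold), each = n_dmg / 2),
      stringsAsFactors = FALSE)
    for (i in seq_len(n_dmg)) {
      hit <- lv$merged_id == planted_dmg$merged_id[i] &
        lv$region == planted_dmg$region[i] &
        match(lv$stage, stages) >= match(planted_dmg$change_stage[i], stages)
      lv$level[hit] <- lv$level[hit] * planted_dmg$fold[i]
    }
  }

  ex <- expand.grid(merged_id = merged$merged_id, stage = stages,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base_ex <- rlnorm(n_m, 0, 0.5)
  n_deg <- 2L * (round(config$frac_deg * n_m) %/% 2L)
  planted_deg <- data.frame(merged_id = character(),
                            change_stage = character(), fold = numeric())
  if (n_deg > 0) {
    pick <- sample(merged$merged_id, n_deg)
    up <- pick[seq_len(n_deg / 2)]
    dn <- pick[seq_len(n_deg / 2) + n_deg / 2]
    base_ex[match(dn, merged$merged_id)] <-
      config$deg_fold * base_ex[match(up, merged$merged_id)]
    planted_deg <- data.frame(
      merged_id = c(up, dn),
      change_stage = rep(sample(stages[-1], n_deg / 2, replace = TRUE), 2),
      fold = rep(c(config$deg_fold, 1 / config$deg_fold), each = n_deg / 2),
      stringsAsFactors = FALSE)
  }
  ex$level <- base_ex[match(ex$merged_id, merged$merged_id)]
  if (n_deg > 0) {
    for (i in seq_len(n_deg)) {
      hit <- ex$merged_id == planted_deg$merged_id[i] &
        match(ex$stage, stages) >= match(planted_deg$change_stage[i], stages)
      ex$level[hit] <- ex$level[hit] * planted_deg$fold[i]
    }
  }

  structure(list(A = A, B = B,
                 truth = list(pairs = pairs, merged_genes = merged,
                              slots = slot_tab, mutations = mutations,
                              meth_levels = lv, expr_levels = ex,
                              planted_dmg = planted_dmg,
                              planted_deg = planted_deg),
                 config = config),
            class = "homeo_sim")
}

#' @export
print.homeo_sim <- function(x, ...) {
  cat(sprintf("homeo_sim: %d + %d genes, %d ortholog pairs, divergence %.3f, seed %d\n",
              nrow(x$A$genes), nrow(x$B$genes), nrow(x$truth$pairs),
              x$config$nucleotide_divergence, x$config$seed))
  invisible(x)
}

#' Merged genes a simulation truly shifted for a contrast
#'
#' @param sim a `homeo_sim`.
#' @param contrast length-2 stage labels.
#' @param what `"dmg"` or `"deg"`.
#' @return character vector of merged ids whose true level differs between
#'   the two stages (in at least one region, for methylation).
#' @export
true_differential <- function(sim, contrast, what = c("dmg", "deg")) {
  what <- match.arg(what)
  stages <- sim$config$stages
  i <- match(contrast, stages)
  pl <- if (what == "dmg") sim$truth$planted_dmg else sim$truth$planted_deg
  if (nrow(pl) == 0) return(character())
  cs <- match(pl$change_stage, stages)
  # the shift separates the two stages iff the change stage lies in (x, y]
  unique(pl$merged_id[cs > min(i) & cs <= max(i)])
}

.library_seed <- function(config, stage, replicate, kind) {
  si <- match(stage, config$stages)
  koff <- if (kind == "medip") 0L else 1L
  as.integer((as.numeric(config$seed) * 7 + si * 1009 +
                replicate * 9176 + koff * 131071) %% 2147483629)
}

#' Simulate one sequencing library with true read placements
#'
#' Draws reads multinomially over (merged gene, region) with weights equal
#' to the true level times region length (MeDIP) or the true expression
#' times body length (RNA), times per-library lognormal replicate noise.
#' Each read originates on one sub-genome (pairs: either, with equal
#' probability); a read from an orthologous slot is also placed on the
#' homeologous copy - becoming a type II read - exactly when the number of
#' recorded substitutions inside the read is at most the configured aligner
#' tolerance. A configured fraction of reads maps to neither sub-genome.
#' Alignments are emitted directly (as tables and, via [write_sam()], SAM
#' files), so no external aligner is required.
#'
#' @param sim a `homeo_sim`.
#' @param stage one of `sim$config$stages`.
#' @param replicate replicate number (drives the library seed and noise).
#' @param library_kind `"medip"` or `"rna"`.
#' @param reads library size; defaults to `config$reads_per_library`.
#' @return list of class `sim_library`: `sam_a`, `sam_b` (alignment tables
#'   accepted by [join_alignments()]), `truth_reads` (per read: origin,
#'   placement, true class, merged gene, region), `total_clean_reads`,
#'   `stage`, `replicate`, `kind`.
#' @export
simulate_reads <- function(sim, stage, replicate = 1,
                           library_kind = c("medip", "rna"),
                           reads = sim$config$reads_per_library) {
  library_kind <- match.arg(library_kind)
  config <- sim$config
  stopifnot(stage %in% config$stages)
  set.seed(.library_seed(config, stage, replicate, library_kind))

  merged <- sim$truth$merged_genes
  if (library_kind == "medip") {
    lv <- sim$truth$meth_levels
    W <- lv[lv$stage == stage, c("merged_id", "region", "level")]
    reg_len <- c(promoter = config$flank_bp, body = config$gene_bp,
                 ttr = config$flank_bp)
    W$len <- reg_len[W$region]
  } else {
    ex <- sim$truth$expr_levels
    W <- ex[ex$stage == stage, c("merged_id", "level")]
    W$region <- "body"; W$len <- config$gene_bp
  }
  W$w <- W$level * W$len * rlnorm(nrow(W), 0, config$replicate_sdlog)

  n_unmapped <- round(config$unmapped_fraction * reads)
  n_mapped <- reads - n_unmapped
  draw <- sample(nrow(W), n_mapped, replace = TRUE, prob = W$w)
  m_idx <- match(W$merged_id[draw], merged$merged_id)
  kind <- merged$kind[m_idx]
  src <- ifelse(kind == "pair",
                sample(c("A", "B"), n_mapped, replace = TRUE),
                ifelse(kind == "A_specific", "A", "B"))
  src_gene <- ifelse(src == "A", merged$a_gene_id[m_idx],
                     merged$b_gene_id[m_idx])

  # region interval of the source gene (strand-aware, all inside the slot)
  genes_a <- sim$A$genes; genes_b <- sim$B$genes
  g_idx_a <- match(src_gene, genes_a$gene_id)
  g_idx_b <- match(src_gene, genes_b$gene_id)
  g_chrom <- ifelse(src == "A", genes_a$chrom[g_idx_a], genes_b$chrom[g_idx_b])
  g_start <- ifelse(src == "A", genes_a$start[g_idx_a], genes_b$start[g_idx_b])
  g_end <- ifelse(src == "A", genes_a$end[g_idx_a], genes_b$end[g_idx_b])
  g_strand <- ifelse(src == "A", genes_a$strand[g_idx_a],
                     genes_b$strand[g_idx_b])
  region <- W$region[draw]
  plus <- g_strand != "-"
  upstream <- (region == "promoter") == plus   # left flank in chrom coords
  r_start <- ifelse(region == "body", g_start,
                    ifelse(upstream, g_start - config$flank_bp, g_end))
  r_end <- ifelse(region == "body", g_end,
                  ifelse(upstream, g_start, g_end + config$flank_bp))
  start <- r_start +
    floor(runif(n_mapped) * pmax(1, (r_end - r_start) - config$read_length + 1))
  end <- start + config$read_length

  # cross-mappability via recorded substitutions in the read span
  slots <- sim$truth$slots
  s_idx <- ifelse(src == "A", match(src_gene, slots$a_gene),
                  match(src_gene, slots$b_gene))
  slot_origin <- ifelse(src == "A", slots$a_start[s_idx], slots$b_start[s_idx])
  other_origin <- ifelse(src == "A", slots$b_start[s_idx], slots$a_start[s_idx])
  orth <- slots$orthologous[s_idx]
  off <- start - slot_origin
  n_mut_in_read <- vapply(seq_len(n_mapped), function(i) {
    if (!orth[i]) return(Inf)
    m <- sim$truth$mutations[[slots$slot_id[s_idx[i]]]]
    if (is.null(m) || !length(m)) return(0)
    sum(m > off[i] & m <= off[i] + config$read_length)
  }, numeric(1))
  both <- n_mut_in_read <= config$aligner_tolerance
  other_start <- other_origin + off
  other_chrom <- g_chrom   # permutation stays within the chromosome

  ids <- sprintf("%s_%s_r%d_%06d", library_kind, stage, replicate,
                 seq_len(reads))
  map_a <- c(src == "A" | both, rep(FALSE, n_unmapped))
  map_b <- c(src == "B" | both, rep(FALSE, n_unmapped))
  pos_a <- c(ifelse(src == "A", start, other_start), rep(NA, n_unmapped))
  pos_b <- c(ifelse(src == "B", start, other_start), rep(NA, n_unmapped))
  chr_all <- c(g_chrom, rep(NA, n_unmapped))

  mk <- function(mapped, pos, chr) data.frame(
    read_id = ids, mapped = mapped,
    chrom = ifelse(mapped, chr, NA_character_),
    start = ifelse(mapped, pos, NA_integer_),
    end = ifelse(mapped, pos + config$read_length, NA_integer_),
    stringsAsFactors = FALSE)

  truth_reads <- data.frame(
    read_id = ids,
    origin = c(src, rep(NA_character_, n_unmapped)),
    chrom = chr_all,
    start = c(start, rep(NA_integer_, n_unmapped)),
    merged_id = c(merged$merged_id[m_idx], rep(NA_character_, n_unmapped)),
    region = c(region, rep(NA_character_, n_unmapped)),
    klass = c(ifelse(both, "BOTH",
                     ifelse(src == "A", "A_ONLY", "B_ONLY")),
              rep("UNMAPPED", n_unmapped)),
    stringsAsFactors = FALSE)

  structure(list(sam_a = mk(map_a, pos_a, chr_all),
                 sam_b = mk(map_b, pos_b, chr_all),
                 truth_reads = truth_reads,
                 total_clean_reads = reads,
                 stage = stage, replicate = replicate, kind = library_kind),
            class = "sim_library")
}

#' Simulate a small-RNA abundance table with target-locus methylation truth
#'
#' Extracts `n_srna` 24-nt sequences from sub-genome A gene bodies (so each
#' sRNA has at least one genuine target locus), assigns per-stage
#' abundances in which each sRNA goes up, down or stays flat between the
#' first and last stage (including presence/absence patterns), and builds a
#' target-locus methylation table in which the methylation direction agrees
#' with the abundance direction for a planted fraction of loci.
#'
#' @param sim a `homeo_sim`.
#' @param n_srna number of sRNAs (default 30).
#' @param srna_length nt (default 24).
#' @param concordant_fraction planted probability that a locus's
#'   methylation moves with its sRNA (default 0.8).
#' @param seed seed (default derived from the simulation's).
#' @return list: `srna_table` (srna_id, sequence, length, one abundance
#'   column per stage), `locus_methylation` (srna_id, subgenome, chrom,
#'   start, end, one RPM column per stage), `planted_concordant` (logical
#'   per locus).
#' @export
simulate_srnas <- function(sim, n_srna = 30, srna_length = 24,
                           concordant_fraction = 0.8,
                           seed = sim$config$seed + 77) {
  set.seed(seed %% 2147483647L)
  stages <- sim$config$stages
  genes <- sim$A$genes
  pick <- sample(nrow(genes), n_srna, replace = n_srna > nrow(genes))
  start <- genes$start[pick] +
    floor(runif(n_srna) * (genes$end[pick] - genes$start[pick] - srna_length))
  seqs <- vapply(seq_len(n_srna), function(i)
    as.character(Biostrings::subseq(sim$A$seqs[[genes$chrom[pick[i]]]],
                                    start[i] + 1L, start[i] + srna_length)),
    "")
  ids <- sprintf("t%07d", sample(1e6, n_srna))
  dir <- sample(c("up", "down", "flat"), n_srna, replace = TRUE,
                prob = c(0.4, 0.4, 0.2))
  base_ab <- round(rlnorm(n_srna, 3, 1)) + 1
  tab <- data.frame(srna_id = ids, sequence = seqs, length = srna_length,
                    stringsAsFactors = FALSE)
  for (k in seq_along(stages)) {
    frac <- (k - 1) / max(1, length(stages) - 1)
    tab[[stages[k]]] <- round(ifelse(dir == "up", base_ab * (1 + 3 * frac),
                                     ifelse(dir == "down",
                                            base_ab * (1 - frac), base_ab)))
  }
  conc <- runif(n_srna) < concordant_fraction
  meth_dir <- ifelse(conc, dir, ifelse(dir == "up", "down", "up"))
  base_m <- rlnorm(n_srna, 1, 0.3)
  lm <- data.frame(srna_id = ids, subgenome = "A",
                   chrom = genes$chrom[pick], start = start,
                   end = start + srna_length, stringsAsFactors = FALSE)
  for (k in seq_along(stages)) {
    frac <- (k - 1) / max(1, length(stages) - 1)
    lm[[stages[k]]] <- ifelse(meth_dir == "up", base_m * (1 + 2 * frac),
                              ifelse(meth_dir == "down",
                                     base_m * pmax(0, 1 - frac), base_m))
  }
  list(srna_table = tab, locus_methylation = lm,
       planted_concordant = stats::setNames(conc, ids),
       planted_direction = stats::setNames(dir, ids))
}
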