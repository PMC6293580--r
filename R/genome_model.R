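#' Load one sub-genome: sequences, gene models, proteins
#'
#' Reads chromosome sequences from a FASTA file and protein-coding gene
#' models from a GFF3 file into a `SubGenome` object, the container every
#' downstream step works from. A gene is taken as protein-coding when its
#' GFF3 `gene` record has an `mRNA` child (other biotypes are ignored).
#' Coordinates are converted from GFF3 1-based inclusive to the package's
#' 0-based half-open convention on read.
#'
#' @param fasta_path path to the genome FASTA.
#' @param gff_path path to the GFF3 annotation; chromosome ids must match
#'   the FASTA.
#' @param protein_fasta_path optional protein FASTA; sequence names must be
#'   gene ids. Genes without a protein are retained but flagged
#'   (`has_protein = FALSE`) and excluded from orthology detection.
#' @param label sub-genome label, `"A"` or `"B"`.
#'
#' @return An object of class `SubGenome`: a list with `label`,
#'   `seqs` (a [Biostrings::DNAStringSet]), `seqlengths` (named integer),
#'   `genes` (data.frame: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `has_protein`; 0-based half-open) and `proteins`
#'   (a [Biostrings::AAStringSet] or `NULL`).
#'
#' @details A GFF3 gene on a chromosome absent from the FASTA is a hard
#'   error naming the offending gene id: it almost always means the two
#'   files come from different assembly versions.
#'
#' @examples
#' sim <- simulate_subgenomes(sim_config(seed = 1, n_genes = 20))
#' dir <- tempfile(); dir.create(dir)
#' paths <- write_subgenome(sim$A, dir)
#' sg <- load_subgenome(paths$fasta, paths$gff, paths$proteins, label = "A")
#' sg
#' @export
load_subgenome <- function(fasta_path, gff_path, protein_fasta_path = NULL,
                           label = "A") {
  label <- match.arg(label, c("A", "B"))
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqlengths <- stats::setNames(Biostrings::width(seqs), names(seqs))

  gff <- rtracklayer::import.gff3(gff_path)
  is_gene <- tolower(as.character(gff$type)) == "gene"
  is_mrna <- tolower(as.character(gff$type)) == "mrna"
  coding_parents <- unique(unlist(gff$Parent[is_mrna]))
  genes_gr <- gff[is_gene]
  ids <- as.character(genes_gr$ID)
  if (anyNA(ids) || any(ids == ""))
    .stopf("GFF3 gene records must carry an ID attribute")
  keep <- ids %in% coding_parents
  genes_gr <- genes_gr[keep]
  ids <- ids[keep]

  chrom <- as.character(GenomicRanges::seqnames(genes_gr))
  bad <- !(chrom %in% names(seqs))
  if (any(bad))
    .stopf("gene '%s' lies on chromosome '%s' absent from the FASTA",
           ids[which(bad)[1]], chrom[which(bad)[1]])

  genes <- data.frame(
    gene_id = ids,
    chrom = chrom,
    start = GenomicRanges::start(genes_gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(genes_gr),
    strand = as.character(GenomicRanges::strand(genes_gr)),
    stringsAsFactors = FALSE
  )
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  if (any(genes$end > seqlengths[genes$chrom]))
    .stopf("gene '%s' extends past the end of its chromosome",
           genes$gene_id[which(genes$end > seqlengths[genes$chrom])[1]])

  proteins <- NULL
  if (!is.null(protein_fasta_path)) {
    proteins <- Biostrings::readAAStringSet(protein_fasta_path)
    names(proteins) <- sub("\\s.*$", "", names(proteins))
    proteins <- proteins[names(proteins) %in% genes$gene_id]
  }
  genes$has_protein <- genes$gene_id %in% names(proteins)
  if (!is.null(proteins) && any(!genes$has_protein))
    .warnf("%d gene(s) have no protein sequence; retained, flagged proteinless",
           sum(!genes$has_protein))

  out <- structure(
    list(label = label, seqs = seqs, seqlengths = seqlengths,
         genes = genes, proteins = proteins),
    class = "SubGenome"
  )
  message(sprintf("sub-genome %s: %d chromosome(s), %d protein-coding gene(s)",
                  label, length(seqs), nrow(genes)))
  out
}

#' @export
print.SubGenome <- function(x, ...) {
  cat(sprintf("SubGenome %s: %d chromosome(s) (%.2f Mb), %d gene(s), %d with protein\n",
              x$label, length(x$seqs), sum(as.numeric(x$seqlengths)) / 1e6,
              nrow(x$genes), sum(x$genes$has_protein)))
  invisible(x)
}

#' Derive fixed analysis regions around each gene
#'
#' For every gene of a sub-genome, builds the three regions over which
#' methylation and expression are quantified: the promoter (`flank_bp`
#' upstream of the strand-aware 5' end), the gene body (the gene interval
#' itself) and the TTR (transcript terminal region, `flank_bp` downstream of
#' the strand-aware 3' end). Regions are clipped at chromosome bounds, so a
#' promoter at a chromosome edge may be shorter than `flank_bp`.
#'
#' @param subgenome a `SubGenome` from [load_subgenome()] or
#'   [simulate_subgenomes()].
#' @param flank_bp promoter/TTR width in bp (default 2000).
#'
#' @return data.frame with columns `owner_id`, `kind`
#'   (`promoter`/`body`/`ttr`), `chrom`, `start`, `end`, `strand`,
#'   `subgenome`; 0-based half-open.
#' @examples
#' sg <- simulate_subgenomes(sim_config(seed = 1, n_genes = 10))$A
#' head(derive_regions(sg))
#' @export
derive_regions <- function(subgenome, flank_bp = 2000) {
  stopifnot(inherits(subgenome, "SubGenome"), flank_bp >= 0)
  g <- subgenome$genes
  if (nrow(g) == 0) .stopf("no genes loaded")
  len <- subgenome$seqlengths[g$chrom]
  plus <- g$strand != "-"

  up_start <- ifelse(plus, g$start - flank_bp, g$end)
  up_end <- ifelse(plus, g$start, g$end + flank_bp)
  dn_start <- ifelse(plus, g$end, g$start - flank_bp)
  dn_end <- ifelse(plus, g$end + flank_bp, g$start)

  clip <- function(s, e) {
    s <- pmax(0L, as.integer(s)); e <- pmin(as.integer(len), as.integer(e))
    list(s = s, e = pmax(s, e))
  }
  up <- clip(up_start, up_end); dn <- clip(dn_start, dn_end)

  out <- rbind(
    data.frame(owner_id = g$gene_id, kind = "promoter", chrom = g$chrom,
               start = up$s, end = up$e, strand = g$strand,
               stringsAsFactors = FALSE),
    data.frame(owner_id = g$gene_id, kind = "body", chrom = g$chrom,
               start = g$start, end = g$end, strand = g$strand,
               stringsAsFactors = FALSE),
    data.frame(owner_id = g$gene_id, kind = "ttr", chrom = g$chrom,
               start = dn$s, end = dn$e, strand = g$strand,
               stringsAsFactors = FALSE)
  )
  out$subgenome <- subgenome$label
  out[out$end > out$start, , drop = FALSE]
}

#' Detect CpG islands and their shores
#'
#' Scans every chromosome with the Gardiner-Garden-Frommer rule: 200 bp
#' windows at 1 bp step qualify when GC fraction >= `min_gc` and the
#' observed/expected CpG ratio (`n_CpG * L / (n_C * n_G)`) >= `min_obs_exp`;
#' overlapping qualifying windows are merged into islands. Windows with more
#' than 10% ambiguous bases (N) are skipped. Each island receives two shore
#' regions of `shore_bp` on either side (clipped at chromosome bounds),
#' excluding the island itself.
#'
#' @param subgenome a `SubGenome`.
#' @param window_bp window size (default 200; also the minimum island size).
#' @param min_gc minimum window GC fraction (default 0.5).
#' @param min_obs_exp minimum observed/expected CpG ratio (default 0.6).
#' @param shore_bp shore width (default 2000).
#'
#' @return list with `islands` (data.frame: `island_id`, `chrom`, `start`,
#'   `end`, `gc_fraction`, `obs_exp_cpg`) and `shores` (a region data.frame
#'   as in [derive_regions()], `kind = "shore"`, plus `cpg_island` regions).
#' @examples
#' sg <- simulate_subgenomes(sim_config(seed = 3, n_genes = 10))$A
#' ci <- detect_cpg_islands(sg)
#' nrow(ci$islands)
#' @export
detect_cpg_islands <- function(subgenome, window_bp = 200, min_gc = 0.5,
                               min_obs_exp = 0.6, shore_bp = 2000) {
  stopifnot(inherits(subgenome, "SubGenome"))
  islands <- list()
  for (chr in names(subgenome$seqs)) {
    s <- as.character(subgenome$seqs[[chr]])
    iv <- .scan_cpg_windows(s, window_bp, min_gc, min_obs_exp)
    if (nrow(iv)) {
      iv$chrom <- chr
      islands[[chr]] <- iv
    }
  }
  if (length(islands)) {
    islands <- do.call(rbind, islands)
    islands <- islands[order(islands$chrom, islands$start), ]
    islands$island_id <- sprintf("%s_CGI_%s_%d", subgenome$label,
                                 islands$chrom, islands$start)
    rownames(islands) <- NULL
    islands <- islands[, c("island_id", "chrom", "start", "end",
                           "gc_fraction", "obs_exp_cpg")]
  } else {
    islands <- data.frame(island_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          gc_fraction = numeric(), obs_exp_cpg = numeric())
  }

  shores <- NULL
  if (nrow(islands)) {
    len <- subgenome$seqlengths[islands$chrom]
    left <- data.frame(owner_id = islands$island_id, kind = "shore",
                       chrom = islands$chrom,
                       start = pmax(0L, islands$start - as.integer(shore_bp)),
                       end = islands$start, strand = "+",
                       stringsAsFactors = FALSE)
    right <- data.frame(owner_id = islands$island_id, kind = "shore",
                        chrom = islands$chrom, start = islands$end,
                        end = pmin(as.integer(len),
                                   islands$end + as.integer(shore_bp)),
                        strand = "+", stringsAsFactors = FALSE)
    body <- data.frame(owner_id = islands$island_id, kind = "cpg_island",
                       chrom = islands$chrom, start = islands$start,
                       end = islands$end, strand = "+",
                       stringsAsFactors = FALSE)
    shores <- rbind(body, left, right)
    shores <- shores[shores$end > shores$start, ]
    shores$subgenome <- subgenome$label
    rownames(shores) <- NULL
  } else {
    shores <- data.frame(owner_id = character(), kind = character(),
                         chrom = character(), start = integer(),
                         end = integer(), strand = character(),
                         subgenome = character())
  }
  list(islands = islands, shores = shores)
}

# Sliding-window GGF scan of one chromosome string. Uses cumulative counts
# of C, G, CpG dinucleotides and N so each window is O(1).
.scan_cpg_windows <- function(s, window_bp, min_gc, min_obs_exp) {
  L <- nchar(s)
  empty <- data.frame(start = integer(), end = integer(),
                      gc_fraction = numeric(), obs_exp_cpg = numeric())
  if (L < window_bp) return(empty)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  isC <- v == "C"; isG <- v == "G"
  isN <- !(v %in% c("A", "C", "G", "T"))
  isCG <- c(isC[-L] & isG[-1], FALSE)  # CpG starting at each position
  cumC <- c(0, cumsum(isC)); cumG <- c(0, cumsum(isG))
  cumN <- c(0, cumsum(isN)); cumCG <- c(0, cumsum(isCG))

  starts <- seq_len(L - window_bp + 1L)            # 1-based window starts
  ends <- starts + window_bp - 1L
  nC <- cumC[ends + 1L] - cumC[starts]
  nG <- cumG[ends + 1L] - cumG[starts]
  nN <- cumN[ends + 1L] - cumN[starts]
  # CpG dinucleotides fully inside the window start at positions start..end-1
  nCG <- cumCG[ends] - cumCG[starts]

  gc <- (nC + nG) / window_bp
  obs_exp <- ifelse(nC * nG > 0, nCG * window_bp / (nC * nG), 0)
  ok <- nN <= 0.1 * window_bp & gc >= min_gc & obs_exp >= min_obs_exp
  if (!any(ok)) return(empty)

  # merge overlapping qualifying windows -> islands (0-based half-open)
  qstart <- starts[ok] - 1L
  r <- IRanges::reduce(IRanges::IRanges(start = qstart + 1L,
                                        width = window_bp))
  ist <- IRanges::start(r) - 1L
  ien <- IRanges::end(r)
  n <- length(ist)
  gcf <- oe <- numeric(n)
  for (i in seq_len(n)) {
    a <- ist[i] + 1L; b <- ien[i]
    nc <- cumC[b + 1L] - cumC[a]; ng <- cumG[b + 1L] - cumG[a]
    ncg <- cumCG[b] - cumCG[a]
    gcf[i] <- (nc + ng) / (b - a + 1L)
    oe[i] <- if (nc * ng > 0) ncg * (b - a + 1L) / (nc * ng) else 0
  }
  data.frame(start = ist, end = ien, gc_fraction = gcf, obs_exp_cpg = oe)
}

#' Write region tables as BED6
#'
#' One BED file per region kind, 0-based half-open as BED requires.
#'
#' @param regions a region data.frame ([derive_regions()] /
#'   [detect_cpg_islands()]`$shores`).
#' @param out_prefix path prefix; files are named
#'   `<prefix>_<kind>.bed`.
#' @return invisibly, the paths written.
#' @export
write_regions_bed <- function(regions, out_prefix) {
  paths <- character()
  for (k in unique(regions$kind)) {
    r <- regions[regions$kind == k, ]
    path <- paste0(out_prefix, "_", k, ".bed")
    bed <- data.frame(r$chrom, r$start, r$end, r$owner_id, 0L,
                      ifelse(r$strand %in% c("+", "-"), r$strand, "."))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
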