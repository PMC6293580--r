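#' Write a sub-genome as FASTA + GFF3 (+ protein FASTA)
#'
#' Emits the chromosome FASTA, a GFF3 with one `gene` record and one `mRNA`
#' child per gene (1-based inclusive coordinates, as GFF3 requires) and,
#' when proteins are present, a protein FASTA named by gene id. The files
#' round-trip through [load_subgenome()].
#'
#' @param subgenome a `SubGenome`.
#' @param dir output directory.
#' @param prefix file name prefix (default the sub-genome label).
#' @return named list of paths: `fasta`, `gff`, `proteins`.
#' @export
write_subgenome <- function(subgenome, dir, prefix = subgenome$label) {
  fasta <- file.path(dir, paste0(prefix, ".fa"))
  gff <- file.path(dir, paste0(prefix, ".gff3"))
  Biostrings::writeXStringSet(subgenome$seqs, fasta)
  g <- subgenome$genes
  gr <- GenomicRanges::GRanges(
    rep(g$chrom, 2), IRanges::IRanges(rep(g$start + 1L, 2), rep(g$end, 2)),
    strand = rep(g$strand, 2),
    type = rep(c("gene", "mRNA"), each = nrow(g)),
    ID = c(g$gene_id, paste0(g$gene_id, ".1")))
  gr$Parent <- IRanges::CharacterList(
    c(rep(list(character(0)), nrow(g)), as.list(g$gene_id)))
  rtracklayer::export.gff3(gr, gff)
  proteins <- NULL
  if (!is.null(subgenome$proteins) && length(subgenome$proteins)) {
    proteins <- file.path(dir, paste0(prefix, "_proteins.fa"))
    Biostrings::writeXStringSet(subgenome$proteins, proteins)
  }
  list(fasta = fasta, gff = gff, proteins = proteins)
}

#' Write a simulated library as a pair of SAM files
#'
#' One SAM per sub-genome, with `@SQ` headers from the simulated
#' chromosomes; reads unmapped in a sub-genome appear there as unmapped
#' records, so both files contain every read of the library.
#'
#' @param lib a `sim_library` from [simulate_reads()].
#' @param sim the `homeo_sim` the library came from.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return named list of paths `sam_a`, `sam_b`.
#' @export
write_sam <- function(lib, sim, dir,
                      prefix = sprintf("%s_%s_rep%d", lib$kind, lib$stage,
                                       lib$replicate)) {
  write_one <- function(al, sg, path) {
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", names(sg$seqlengths),
                     sg$seqlengths))
    rec <- ifelse(
      al$mapped,
      sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*", al$read_id,
              al$chrom, al$start + 1L, al$end - al$start),
      sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*", al$read_id))
    writeLines(c(hdr, rec), path)
    path
  }
  sam_a <- write_one(lib$sam_a, sim$A, file.path(dir, paste0(prefix, "_A.sam")))
  sam_b <- write_one(lib$sam_b, sim$B, file.path(dir, paste0(prefix, "_B.sam")))
  list(sam_a = sam_a, sam_b = sam_b)
}

#' Write a count table, RPM table or call table as TSV
#' @param x a `count_table`, or any data.frame from the pipeline.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  if (inherits(x, "count_table")) {
    df <- x$counts
    df$sample_id <- x$sample_id
    df <- df[, c("sample_id", "merged_id", "region", "count")]
  } else df <- as.data.frame(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
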