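#' Read primary alignments from a SAM/BAM file
#'
#' Returns one row per primary alignment (secondary and supplementary
#' records are dropped) plus one row per unmapped read. SAM text is
#' converted with [Rsamtools::asBam()] internally, so no external tools are
#' needed. Intervals are the reference span of the alignment (CIGAR-aware),
#' 0-based half-open.
#'
#' @param path SAM or BAM file.
#' @return data.frame: `read_id`, `mapped`, `chrom`, `start`, `end`.
#' @export
read_sam_primary <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- suppressMessages(
      Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE))
  }
  flag0 <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag0,
                                   what = c("qname", "flag", "rname",
                                            "pos", "cigar"))
  x <- Rsamtools::scanBam(path, param = param)[[1]]
  mapped <- !bitwAnd(x$flag, 4L)
  width <- rep(0L, length(x$qname))
  if (any(mapped))
    width[mapped] <- GenomicAlignments::cigarWidthAlongReferenceSpace(
      x$cigar[mapped])
  data.frame(
    read_id = x$qname,
    mapped = mapped,
    chrom = ifelse(mapped, as.character(x$rname), NA_character_),
    start = ifelse(mapped, x$pos - 1L, NA_integer_),
    end = ifelse(mapped, x$pos - 1L + width, NA_integer_),
    stringsAsFactors = FALSE
  )
}

#' Join per-sub-genome alignments of the same library by read id
#'
#' The same clean reads are aligned once against sub-genome A and once
#' against sub-genome B; this joins the two result files by read id and
#' classifies every read by its joint mapping status: `A_ONLY`, `B_ONLY`,
#' `BOTH` (a "type II" read, mappable to both sub-genomes) or `UNMAPPED`.
#' Reads present in only one file are treated as unmapped in the other, with
#' a warning. Two primary alignments for one read in one file is a hard
#' error (the upstream aligner was misconfigured).
#'
#' @param sam_a,sam_b SAM/BAM files of the same reads against sub-genomes A
#'   and B, or data.frames from [read_sam_primary()].
#' @return data.frame of `ReadAssignment`s: `read_id`, `klass`, and the
#'   primary placement in each sub-genome (`a_chrom`, `a_start`, `a_end`,
#'   `b_chrom`, `b_start`, `b_end`; `NA` where unmapped).
#' @examples
#' sim <- simulate_subgenomes(sim_config(seed = 1, n_genes = 20))
#' lib <- simulate_reads(sim, stage = "S1", replicate = 1)
#' asn <- join_alignments(lib$sam_a, lib$sam_b)
#' table(asn$klass)
#' @export
join_alignments <- function(sam_a, sam_b) {
  al_a <- if (is.data.frame(sam_a)) sam_a else read_sam_primary(sam_a)
  al_b <- if (is.data.frame(sam_b)) sam_b else read_sam_primary(sam_b)
  for (al in list(A = al_a, B = al_b)) {
    dup <- duplicated(al$read_id)
    if (any(dup))
      .stopf("duplicate primary alignment for read '%s'",
             al$read_id[dup][1])
  }
  ids <- union(al_a$read_id, al_b$read_id)
  only_one <- length(ids) - length(intersect(al_a$read_id, al_b$read_id))
  if (only_one > 0)
    .warnf("%d read(s) present in only one alignment file; treated as unmapped in the other",
           only_one)
  ma <- match(ids, al_a$read_id); mb <- match(ids, al_b$read_id)
  a_map <- !is.na(ma) & al_a$mapped[ma] %in% TRUE
  b_map <- !is.na(mb) & al_b$mapped[mb] %in% TRUE
  klass <- ifelse(a_map & b_map, "BOTH",
                  ifelse(a_map, "A_ONLY",
                         ifelse(b_map, "B_ONLY", "UNMAPPED")))
  data.frame(
    read_id = ids, klass = klass,
    a_chrom = ifelse(a_map, al_a$chrom[ma], NA_character_),
    a_start = ifelse(a_map, al_a$start[ma], NA_integer_),
    a_end = ifelse(a_map, al_a$end[ma], NA_integer_),
    b_chrom = ifelse(b_map, al_b$chrom[mb], NA_character_),
    b_start = ifelse(b_map, al_b$start[mb], NA_integer_),
    b_end = ifelse(b_map, al_b$end[mb], NA_integer_),
    stringsAsFactors = FALSE
  )
}

#' Count reads per merged gene and region, counting shared reads once
#'
#' The core of the joint quantification strategy. A read overlapping a
#' region of one sub-genome member contributes +1 to that
#' (merged gene, region kind); a type II read overlapping the corresponding
#' regions of *both* members of the same merged gene still contributes
#' exactly +1 there - counting it twice would overstate the signal. A read
#' overlapping regions of different merged genes contributes once to each;
#' such cross-merged-gene type II reads are reported in an audit table.
#' Region kinds are tallied independently, so a read spanning a promoter
#' and the adjacent gene body counts once in each kind.
#'
#' @param assignments data.frame from [join_alignments()].
#' @param merged_genes data.frame from [build_merged_genes()].
#' @param regions region data.frame covering both sub-genomes (rbind of
#'   [derive_regions()] on A and B; island/shore regions may be included -
#'   island regions are attributed to merged genes via their owning
#'   sub-genome gene only if `owner_id` is a gene id, otherwise kept under
#'   the island id).
#' @param total_clean_reads total sequenced clean reads of the library;
#'   defaults to `nrow(assignments)`.
#' @param sample_id label stored on the count table.
#' @param min_overlap minimum overlap in bp for a read to count (default 1).
#' @return object of class `count_table`: list with `sample_id`, `counts`
#'   (data.frame `merged_id`, `region`, `count`), `total_clean_reads`, and
#'   `audit` (read ids counted in more than one merged gene).
#' @export
count_reads <- function(assignments, merged_genes, regions,
                        total_clean_reads = nrow(assignments),
                        sample_id = "sample", min_overlap = 1) {
  if (total_clean_reads <= 0) .stopf("total_clean_reads must be positive")
  # map region owner gene -> merged gene
  owner2merged <- c(
    stats::setNames(merged_genes$merged_id, merged_genes$a_gene_id),
    stats::setNames(merged_genes$merged_id, merged_genes$b_gene_id)
  )
  owner2merged <- owner2merged[!is.na(names(owner2merged))]

  hit_one <- function(sub_label) {
    pre <- if (sub_label == "A") "a_" else "b_"
    ok <- !is.na(assignments[[paste0(pre, "chrom")]])
    reg <- regions[regions$subgenome == sub_label, , drop = FALSE]
    if (!any(ok) || nrow(reg) == 0) return(NULL)
    reads_gr <- GenomicRanges::GRanges(
      assignments[[paste0(pre, "chrom")]][ok],
      IRanges::IRanges(assignments[[paste0(pre, "start")]][ok] + 1L,
                       assignments[[paste0(pre, "end")]][ok]))
    reg_gr <- GenomicRanges::GRanges(
      reg$chrom, IRanges::IRanges(reg$start + 1L, reg$end))
    ov <- GenomicRanges::findOverlaps(reads_gr, reg_gr,
                                      minoverlap = min_overlap,
                                      ignore.strand = TRUE)
    if (length(ov) == 0) return(NULL)
    owner <- reg$owner_id[S4Vectors::subjectHits(ov)]
    merged <- unname(owner2merged[owner])
    merged[is.na(merged)] <- owner[is.na(merged)]  # island regions etc.
    data.frame(read_id = assignments$read_id[ok][S4Vectors::queryHits(ov)],
               merged_id = merged,
               region = reg$kind[S4Vectors::subjectHits(ov)],
               stringsAsFactors = FALSE)
  }
  hits <- rbind(hit_one("A"), hit_one("B"))
  if (is.null(hits) || nrow(hits) == 0) {
    counts <- data.frame(merged_id = character(), region = character(),
                         count = integer())
    audit <- character()
  } else {
    # once-only rule: a (read, merged gene, region kind) triple counts once,
    # even when both sub-genome members were hit
    hits <- hits[!duplicated(hits[c("read_id", "merged_id", "region")]), ]
    agg <- stats::aggregate(list(count = hits$read_id),
                            by = hits[c("merged_id", "region")], FUN = length)
    counts <- agg[order(agg$merged_id, agg$region), ]
    rownames(counts) <- NULL
    per_read <- unique(hits[c("read_id", "merged_id")])
    audit <- unique(per_read$read_id[duplicated(per_read$read_id)])
  }
  structure(list(sample_id = sample_id, counts = counts,
                 total_clean_reads = as.numeric(total_clean_reads),
                 audit = audit),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table '%s': %d (merged gene, region) entries, %d reads counted in >1 merged gene, %g total clean reads\n",
              x$sample_id, nrow(x$counts), length(x$audit),
              x$total_clean_reads))
  invisible(x)
}
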