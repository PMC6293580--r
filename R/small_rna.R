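#' Find genomic target loci of a small RNA by complementarity
#'
#' Exhaustively locates every position on either strand of either
#' sub-genome where the small RNA sequence matches with at most
#' `max_mismatches` substitutions (no indels). This is a deliberately
#' simple mismatch-count matcher: it trades the weighted scoring of
#' dedicated plant sRNA target tools for an exact, exhaustive and easily
#' verified rule. A plus-strand locus matches the sRNA sequence directly;
#' a minus-strand locus matches its reverse complement.
#'
#' @param srna named character vector (or single string) of sRNA sequences,
#'   A/C/G/U/T; 18-26 nt. Sequences with ambiguous bases are skipped with a
#'   warning.
#' @param subgenomes list of `SubGenome`s (typically `list(A, B)`).
#' @param max_mismatches maximum substitutions (default 2).
#' @return data.frame of `TargetLocus`: `srna_id`, `subgenome`, `chrom`,
#'   `start`, `end` (0-based half-open, length = sRNA length), `strand`,
#'   `mismatches`.
#' @examples
#' sg <- simulate_subgenomes(sim_config(seed = 1, n_genes = 5))$A
#' planted <- as.character(Biostrings::subseq(sg$seqs[[1]], 101, 124))
#' find_target_loci(c(s1 = planted), list(sg), max_mismatches = 0)
#' @export
find_target_loci <- function(srna, subgenomes, max_mismatches = 2) {
  if (is.null(names(srna))) names(srna) <- paste0("srna", seq_along(srna))
  out <- list()
  for (sid in names(srna)) {
    seq <- toupper(gsub("U", "T", srna[[sid]]))
    if (grepl("[^ACGT]", seq)) {
      .warnf("sRNA '%s' contains ambiguous bases; skipped", sid)
      next
    }
    pat <- Biostrings::DNAString(seq)
    rc <- Biostrings::reverseComplement(pat)
    for (sg in subgenomes) {
      for (chr in names(sg$seqs)) {
        subject <- sg$seqs[[chr]]
        for (str in c("+", "-")) {
          m <- Biostrings::matchPattern(
            if (str == "+") pat else rc, subject,
            max.mismatch = max_mismatches, with.indels = FALSE)
          if (length(m) == 0) next
          mm <- vapply(seq_along(m), function(i)
            Biostrings::neditAt(if (str == "+") pat else rc, subject,
                                at = IRanges::start(m)[i]), integer(1))
          out[[length(out) + 1L]] <- data.frame(
            srna_id = sid, subgenome = sg$label, chrom = chr,
            start = IRanges::start(m) - 1L, end = IRanges::end(m),
            strand = str, mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(srna_id = character(), subgenome = character(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$srna_id, res$subgenome, res$chrom, res$start,
                   res$strand), ]
  rownames(res) <- NULL
  res
}

#' Methylation RPM of sRNA target loci
#'
#' Quantifies the methylation level of each target locus as the MeDIP read
#' RPM in a window of `window_bp` on either side of the locus centre
#' (default +/-100 bp), from a joined read-assignment table.
#'
#' @param loci data.frame from [find_target_loci()].
#' @param assignments data.frame from [join_alignments()] (one library).
#' @param total_clean_reads the library's total clean reads.
#' @param window_bp half-window in bp (default 100).
#' @return `loci` with an added `rpm` column.
#' @export
locus_methylation_rpm <- function(loci, assignments, total_clean_reads,
                                  window_bp = 100) {
  if (total_clean_reads <= 0) .stopf("total_clean_reads must be positive")
  loci$rpm <- 0
  centre <- (loci$start + loci$end) %/% 2L
  win <- data.frame(chrom = loci$chrom,
                    start = pmax(0L, centre - as.integer(window_bp)),
                    end = centre + as.integer(window_bp))
  for (sub in c("A", "B")) {
    pre <- if (sub == "A") "a_" else "b_"
    sel_l <- loci$subgenome == sub
    sel_r <- !is.na(assignments[[paste0(pre, "chrom")]])
    if (!any(sel_l) || !any(sel_r)) next
    win_gr <- GenomicRanges::GRanges(win$chrom[sel_l],
                                     IRanges::IRanges(win$start[sel_l] + 1L,
                                                      win$end[sel_l]))
    reads_gr <- GenomicRanges::GRanges(
      assignments[[paste0(pre, "chrom")]][sel_r],
      IRanges::IRanges(assignments[[paste0(pre, "start")]][sel_r] + 1L,
                       assignments[[paste0(pre, "end")]][sel_r]))
    n <- GenomicRanges::countOverlaps(win_gr, reads_gr)
    loci$rpm[sel_l] <- n * 1e6 / total_clean_reads
  }
  loci
}

#' Associate stage-wise sRNA abundance change with target-locus methylation
#'
#' For one contrast (stage x vs stage y), pairs the direction of each
#' sRNA's abundance change (including presence/absence) with the direction
#' of the methylation change of each of its target loci. A record is
#' `concordant` when both move the same way - the pattern expected under
#' RNA-directed DNA methylation, where a siRNA that disappears should be
#' followed by loss of methylation at its targets. sRNAs with unchanged
#' abundance are reported as `no_change` and not scored for concordance;
#' loci without methylation data are excluded and counted.
#'
#' @param srna_table data.frame with `srna_id` and one abundance column per
#'   stage (column names = stage labels).
#' @param locus_methylation data.frame with `srna_id`, locus coordinates
#'   (`subgenome`, `chrom`, `start`, `end`) and one methylation column per
#'   stage, e.g. built by calling [locus_methylation_rpm()] per stage and
#'   merging.
#' @param contrast length-2 character: `c(stage_x, stage_y)`.
#' @param min_change minimum absolute change treated as a direction
#'   (default 0: any difference counts).
#' @return list with `records` (per sRNA x locus: abundance and methylation
#'   directions, `concordant`) and `summary` (counts: `n_records`,
#'   `n_evaluated`, `n_concordant`, `concordant_fraction`,
#'   `n_missing_methylation`).
#' @export
associate_srna_methylation <- function(srna_table, locus_methylation,
                                       contrast, min_change = 0) {
  sx <- contrast[1]; sy <- contrast[2]
  for (col in c(sx, sy)) {
    if (!col %in% names(srna_table))
      .stopf("stage column '%s' missing from srna_table", col)
    if (!col %in% names(locus_methylation))
      .stopf("stage column '%s' missing from locus_methylation", col)
  }
  dirn <- function(a, b) ifelse(is.na(a) | is.na(b), NA_character_,
                                ifelse(b - a > min_change, "up",
                                       ifelse(a - b > min_change, "down",
                                              "no_change")))
  ab <- dirn(srna_table[[sx]], srna_table[[sy]])
  names(ab) <- srna_table$srna_id
  lm <- locus_methylation
  missing_meth <- is.na(lm[[sx]]) | is.na(lm[[sy]])
  n_missing <- sum(missing_meth)
  lm <- lm[!missing_meth, , drop = FALSE]
  rec <- data.frame(
    srna_id = lm$srna_id, subgenome = lm$subgenome, chrom = lm$chrom,
    start = lm$start, end = lm$end,
    abundance_direction = unname(ab[lm$srna_id]),
    methylation_direction = dirn(lm[[sx]], lm[[sy]]),
    stringsAsFactors = FALSE)
  rec$concordant <- ifelse(
    rec$abundance_direction == "no_change" |
      rec$methylation_direction == "no_change", NA,
    rec$abundance_direction == rec$methylation_direction)
  eval_ok <- !is.na(rec$concordant)
  summary <- data.frame(
    contrast = paste(contrast, collapse = ":"),
    n_records = nrow(rec),
    n_evaluated = sum(eval_ok),
    n_concordant = sum(rec$concordant[eval_ok]),
    concordant_fraction = if (any(eval_ok))
      mean(rec$concordant[eval_ok]) else NA_real_,
    n_missing_methylation = n_missing)
  list(records = rec, summary = summary)
}
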