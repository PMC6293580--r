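#' Convert a count table to RPM
#'
#' RPM (reads per million) is the read count of a merged gene region divided
#' by the library's total sequenced clean reads in millions:
#' `rpm = count * 1e6 / total_clean_reads`. The denominator is the total
#' *sequenced* clean-read count, not the mapped-read count, so RPM values
#' are comparable across libraries of different mapping rate. Because the
#' two members of an ortholog pair can differ in length, no per-kb
#' normalisation (RPKM) is offered for merged genes.
#'
#' @param count_table a `count_table` from [count_reads()], or a data.frame
#'   with `merged_id`, `region`, `count` plus `total_clean_reads` given.
#' @param total_clean_reads required only when `count_table` is a plain
#'   data.frame.
#' @return data.frame of `RegionRPM`s: `sample_id`, `merged_id`, `region`,
#'   `count`, `rpm`.
#' @examples
#' ct <- data.frame(merged_id = "M1", region = "body", count = 50)
#' compute_rpm(ct, total_clean_reads = 2e6)$rpm  # 25
#' @export
compute_rpm <- function(count_table, total_clean_reads = NULL) {
  if (inherits(count_table, "count_table")) {
    counts <- count_table$counts
    total <- count_table$total_clean_reads
    sample_id <- count_table$sample_id
  } else {
    counts <- count_table
    total <- total_clean_reads
    sample_id <- "sample"
  }
  if (is.null(total) || total <= 0)
    .stopf("total_clean_reads must be a positive number")
  data.frame(sample_id = sample_id,
             merged_id = counts$merged_id,
             region = counts$region,
             count = counts$count,
             rpm = counts$count * 1e6 / total,
             stringsAsFactors = FALSE)
}

# per-(subgenome, chromosome) coverage RleList from read placements
.coverage_from_assignments <- function(assignments, sub_label, seqlengths) {
  pre <- if (sub_label == "A") "a_" else "b_"
  ok <- !is.na(assignments[[paste0(pre, "chrom")]])
  gr <- GenomicRanges::GRanges(
    factor(assignments[[paste0(pre, "chrom")]][ok], levels = names(seqlengths)),
    IRanges::IRanges(assignments[[paste0(pre, "start")]][ok] + 1L,
                     assignments[[paste0(pre, "end")]][ok]))
  GenomicRanges::coverage(gr, width = as.list(seqlengths))
}

#' Metagene / meta-island methylation depth profile
#'
#' Averages per-base read depth over all anchors of one sub-genome, in the
#' layout of a metagene plot: `flank_bp` upstream in fixed `flank_bin_bp`
#' bins, the anchor body length-normalised into `n_body_bins`, and
#' `flank_bp` downstream. Gene anchors are oriented by strand (upstream is
#' always 5'); island anchors use the chromosome orientation. Depth is mean
#' per-base coverage; `normalize = "rpm"` additionally divides by the
#' library size in millions.
#'
#' @param assignments data.frame from [join_alignments()].
#' @param subgenome the `SubGenome` whose anchors are profiled.
#' @param anchors `"gene"` or a data.frame of anchor intervals (`chrom`,
#'   `start`, `end`, optional `strand`), e.g. islands from
#'   [detect_cpg_islands()].
#' @param n_body_bins bins across the anchor body (default 40).
#' @param flank_bp flank width (default 2000).
#' @param flank_bin_bp flank bin width (default 100).
#' @param normalize `"depth"` (mean coverage) or `"rpm"`.
#' @param total_clean_reads library size, needed for `normalize = "rpm"`.
#' @return object of class `meta_profile`: data.frame with `bin`
#'   (ordered label), `zone` (`upstream`/`body`/`downstream`), `depth`.
#' @export
metagene_profile <- function(assignments, subgenome, anchors = "gene",
                             n_body_bins = 40, flank_bp = 2000,
                             flank_bin_bp = 100,
                             normalize = c("depth", "rpm"),
                             total_clean_reads = nrow(assignments)) {
  normalize <- match.arg(normalize)
  if (is.character(anchors) && identical(anchors, "gene")) {
    anchors <- subgenome$genes[, c("chrom", "start", "end", "strand")]
  }
  if (nrow(anchors) == 0) .stopf("anchor set is empty")
  if (is.null(anchors$strand)) anchors$strand <- "+"
  cov <- .coverage_from_assignments(assignments, subgenome$label,
                                    subgenome$seqlengths)
  n_fl <- as.integer(flank_bp / flank_bin_bp)
  n_bins <- 2L * n_fl + n_body_bins
  acc <- matrix(0, nrow = nrow(anchors), ncol = n_bins)
  for (i in seq_len(nrow(anchors))) {
    chr <- anchors$chrom[i]; L <- subgenome$seqlengths[[chr]]
    v <- as.numeric(cov[[chr]])
    s <- anchors$start[i]; e <- anchors$end[i]
    base_at <- function(pos) ifelse(pos >= 0 & pos < L, v[pos + 1L], NA_real_)
    # upstream bins (chromosome orientation, left of anchor)
    up <- vapply(seq_len(n_fl), function(k) {
      a <- s - flank_bp + (k - 1L) * flank_bin_bp
      mean(base_at(a:(a + flank_bin_bp - 1L)), na.rm = TRUE)
    }, numeric(1))
    # body bins, length-normalised
    body_pos <- s:(e - 1L)
    cut_idx <- as.integer(floor((seq_along(body_pos) - 1L) *
                                  n_body_bins / length(body_pos))) + 1L
    body <- vapply(seq_len(n_body_bins), function(k)
      mean(base_at(body_pos[cut_idx == k])), numeric(1))
    dn <- vapply(seq_len(n_fl), function(k) {
      a <- e + (k - 1L) * flank_bin_bp
      mean(base_at(a:(a + flank_bin_bp - 1L)), na.rm = TRUE)
    }, numeric(1))
    row <- c(up, body, dn)
    if (anchors$strand[i] == "-") row <- rev(row)
    acc[i, ] <- row
  }
  depth <- colMeans(acc, na.rm = TRUE)
  if (normalize == "rpm") depth <- depth * 1e6 / total_clean_reads
  zone <- c(rep("upstream", n_fl), rep("body", n_body_bins),
            rep("downstream", n_fl))
  out <- data.frame(bin = seq_len(n_bins), zone = zone, depth = depth)
  class(out) <- c("meta_profile", "data.frame")
  out
}

#' @export
plot.meta_profile <- function(x, ...) {
  graphics::plot(x$bin, x$depth, type = "l", xlab = "bin",
                 ylab = "mean depth", ...)
  b <- range(x$bin[x$zone == "body"])
  graphics::abline(v = b + c(-0.5, 0.5), lty = 2)
  invisible(x)
}

#' Windowed chromosome methylation depth track
#'
#' Mean per-base depth in fixed windows along every chromosome of one
#' sub-genome - the genome-wide view, suitable for circular plotting.
#'
#' @param assignments data.frame from [join_alignments()].
#' @param subgenome the `SubGenome` to profile.
#' @param window_bp window size (default 1e5).
#' @return data.frame: `chrom`, `start`, `end`, `depth` (0-based half-open
#'   windows; the last window of a chromosome may be shorter).
#' @export
chromosome_track <- function(assignments, subgenome, window_bp = 100000) {
  cov <- .coverage_from_assignments(assignments, subgenome$label,
                                    subgenome$seqlengths)
  out <- list()
  for (chr in names(subgenome$seqlengths)) {
    L <- subgenome$seqlengths[[chr]]
    starts <- seq(0L, L - 1L, by = window_bp)
    ends <- pmin(starts + window_bp, L)
    v <- cov[[chr]]
    sums <- vapply(seq_along(starts), function(i)
      sum(as.numeric(IRanges::Views(v, starts[i] + 1L, ends[i])[[1]])),
      numeric(1))
    out[[chr]] <- data.frame(chrom = chr, start = starts, end = ends,
                             depth = sums / (ends - starts))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a depth track as bedGraph
#' @param track data.frame from [chromosome_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "depth")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
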