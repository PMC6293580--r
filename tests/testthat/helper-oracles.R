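# Brute-force oracles, deliberately written along different routes than the
# implementation they check.

# CpG islands: per-window direct summation over a character vector, manual
# run merging (no cumulative sums, no IRanges).
oracle_cpg_islands <- function(seq, window = 200, min_gc = 0.5,
                               min_oe = 0.6) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(v)
  if (L < window) return(data.frame(start = integer(), end = integer()))
  ok <- logical(L - window + 1)
  for (s in seq_len(L - window + 1)) {
    w <- v[s:(s + window - 1)]
    if (sum(!(w %in% c("A", "C", "G", "T"))) > 0.1 * window) next
    nc <- sum(w == "C"); ng <- sum(w == "G")
    ncg <- sum(w[-window] == "C" & w[-1] == "G")
    gc <- (nc + ng) / window
    oe <- if (nc * ng > 0) ncg * window / (nc * ng) else 0
    ok[s] <- gc >= min_gc && oe >= min_oe
  }
  if (!any(ok)) return(data.frame(start = integer(), end = integer()))
  covered <- logical(L)
  for (s in which(ok)) covered[s:(s + window - 1)] <- TRUE
  d <- diff(c(FALSE, covered, FALSE))
  data.frame(start = which(d == 1) - 1L, end = which(d == -1) - 1L)
}

# reciprocal best hits by explicit per-gene maximisation
oracle_rbh <- function(hits) {
  best <- function(df, by, partner) {
    out <- character()
    for (g in unique(df[[by]])) {
      h <- df[df[[by]] == g, ]
      h <- h[order(-h$score, h$evalue, h[[partner]]), ]
      out[g] <- h[[partner]][1]
    }
    out
  }
  ba <- best(hits, "query_id", "subject_id")
  bb <- best(hits, "subject_id", "query_id")
  pairs <- data.frame(a = names(ba), b = unname(ba),
                      stringsAsFactors = FALSE)
  keep <- vapply(seq_len(nrow(pairs)),
                 function(i) identical(unname(bb[pairs$b[i]]), pairs$a[i]),
                 logical(1))
  pairs <- pairs[keep, ]
  pairs[order(pairs$a), ]
}

# synteny by exhaustive pair-vs-pair block comparison
oracle_synteny <- function(pairs, genes_a, genes_b, block_bp = 1e5,
                           min_pairs = 3) {
  n <- nrow(pairs)
  keep <- logical(n); support <- integer(n)
  for (i in seq_len(n)) {
    gi_a <- genes_a[genes_a$gene_id == pairs$a_gene_id[i], ]
    gi_b <- genes_b[genes_b$gene_id == pairs$b_gene_id[i], ]
    cnt <- 0L
    for (j in seq_len(n)) {
      gj_a <- genes_a[genes_a$gene_id == pairs$a_gene_id[j], ]
      gj_b <- genes_b[genes_b$gene_id == pairs$b_gene_id[j], ]
      same_a <- gj_a$chrom == gi_a$chrom &&
        gj_a$start %/% block_bp == gi_a$start %/% block_bp
      same_b <- gj_b$chrom == gi_b$chrom &&
        gj_b$start %/% block_bp == gi_b$start %/% block_bp
      if (same_a && same_b) cnt <- cnt + 1L
    }
    support[i] <- cnt
    keep[i] <- cnt >= min_pairs
  }
  cbind(pairs[keep, c("a_gene_id", "b_gene_id")],
        block_support = support[keep])
}

# read counting by exhaustive read x region iteration
oracle_count <- function(assignments, merged_genes, regions,
                         min_overlap = 1) {
  owner2merged <- c(stats::setNames(merged_genes$merged_id,
                                    merged_genes$a_gene_id),
                    stats::setNames(merged_genes$merged_id,
                                    merged_genes$b_gene_id))
  owner2merged <- owner2merged[!is.na(names(owner2merged))]
  tally <- new.env(parent = emptyenv())
  overlaps <- function(s1, e1, s2, e2)
    !is.na(s1) && min(e1, e2) - max(s1, s2) >= min_overlap
  for (i in seq_len(nrow(assignments))) {
    seen <- character()
    for (j in seq_len(nrow(regions))) {
      r <- regions[j, ]
      hit <- if (r$subgenome == "A")
        overlaps(assignments$a_start[i], assignments$a_end[i], r$start, r$end) &&
        identical(assignments$a_chrom[i], r$chrom)
      else
        overlaps(assignments$b_start[i], assignments$b_end[i], r$start, r$end) &&
        identical(assignments$b_chrom[i], r$chrom)
      if (!hit) next
      m <- owner2merged[[r$owner_id]]
      if (is.null(m)) m <- r$owner_id
      key <- paste(m, r$kind)
      if (key %in% seen) next     # once-only per read
      seen <- c(seen, key)
      tally[[key]] <- (if (is.null(tally[[key]])) 0L else tally[[key]]) + 1L
    }
  }
  keys <- ls(tally)
  parts <- strsplit(keys, " ", fixed = TRUE)
  out <- data.frame(merged_id = vapply(parts, `[`, "", 1),
                    region = vapply(parts, `[`, "", 2),
                    count = vapply(keys, function(k) tally[[k]], integer(1)),
                    stringsAsFactors = FALSE)
  out[order(out$merged_id, out$region), ]
}

# sRNA matching by shift-and-compare over every offset
oracle_srna_scan <- function(pattern, seq, max_mm) {
  pv <- strsplit(pattern, "", fixed = TRUE)[[1]]
  sv <- strsplit(seq, "", fixed = TRUE)[[1]]
  k <- length(pv); L <- length(sv)
  if (L < k) return(integer())
  mism <- integer(L - k + 1)
  for (j in seq_len(k))
    mism <- mism + (sv[j:(L - k + j)] != pv[j])
  which(mism <= max_mm) - 1L   # 0-based starts
}

rc <- function(s) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(s)))

# pooled-variance two-sample t, closed form
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(-abs(t), nx + ny - 2))
}
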