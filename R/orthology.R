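#' All-vs-all protein similarity between the two sub-genomes
#'
#' Scores every A protein against every B protein with local
#' Smith-Waterman alignment (BLOSUM62, affine gaps 11/1) and converts raw
#' scores to BLASTP-style E-values with the Karlin-Altschul formula
#' (gapped BLOSUM62 constants lambda = 0.267, K = 0.041; search space =
#' query length x summed subject lengths). Hits below `evalue_cutoff` are
#' retained, in both directions. The built-in aligner keeps small runs and
#' tests free of an external search tool; for genome-scale inputs, ingest an
#' external tabular hit file with [read_similarity_hits()] instead.
#'
#' @param proteins_a,proteins_b named [Biostrings::AAStringSet]s (names are
#'   gene ids), typically `subgenome$proteins`.
#' @param evalue_cutoff retain hits with E-value strictly below this
#'   (default 1e-20).
#'
#' @return data.frame of `SimilarityHit`s: `query_id`, `subject_id`,
#'   `score` (bit score), `evalue`, with `query_id` always the A gene.
#' @examples
#' aa <- Biostrings::AAStringSet(c(g1 = paste(rep("MKWVTFISLLFLFSSAYS", 8),
#'                                            collapse = "")))
#' hits <- all_vs_all_similarity(aa, stats::setNames(aa, "h1"))
#' hits$evalue < 1e-20
#' @export
all_vs_all_similarity <- function(proteins_a, proteins_b,
                                  evalue_cutoff = 1e-20) {
  if (length(proteins_a) == 0 || length(proteins_b) == 0) {
    .warnf("empty protein set; no similarity hits")
    return(data.frame(query_id = character(), subject_id = character(),
                      score = numeric(), evalue = numeric()))
  }
  bl62 <- get(utils::data("BLOSUM62", package = "Biostrings",
                          envir = environment()), envir = environment())
  lambda <- 0.267; K <- 0.041
  n_db <- sum(Biostrings::width(proteins_b))
  out <- vector("list", length(proteins_b))
  for (j in seq_along(proteins_b)) {
    raw <- Biostrings::pairwiseAlignment(
      pattern = proteins_a, subject = proteins_b[[j]], type = "local",
      substitutionMatrix = bl62, gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE
    )
    bit <- (lambda * raw - log(K)) / log(2)
    ev <- Biostrings::width(proteins_a) * n_db * 2^(-bit)
    keep <- ev < evalue_cutoff
    if (any(keep)) {
      out[[j]] <- data.frame(
        query_id = names(proteins_a)[keep],
        subject_id = names(proteins_b)[j],
        score = bit[keep], evalue = ev[keep],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(query_id = character(), subject_id = character(),
                      score = numeric(), evalue = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read an external 12-column tabular hit file
#'
#' Accepts the standard tabular protein-search dialect (query, subject,
#' pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore) and returns the retained hits in the same shape as
#' [all_vs_all_similarity()].
#'
#' @param path tabular file path.
#' @param evalue_cutoff retain rows with `evalue` below this.
#' @return data.frame with `query_id`, `subject_id`, `score`, `evalue`.
#' @export
read_similarity_hits <- function(path, evalue_cutoff = 1e-20) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 12) .stopf("expected 12 tab-separated columns, got %d",
                             ncol(tab))
  out <- data.frame(query_id = as.character(tab[[1]]),
                    subject_id = as.character(tab[[2]]),
                    score = as.numeric(tab[[12]]),
                    evalue = as.numeric(tab[[11]]),
                    stringsAsFactors = FALSE)
  out[out$evalue < evalue_cutoff, , drop = FALSE]
}

#' Reciprocal best-hit candidate pairs
#'
#' An A gene and a B gene form a candidate ortholog pair when each is the
#' other's highest-scoring hit. Ties on score are broken by lower E-value,
#' then lexicographically smaller partner id, so the pair set is
#' deterministic regardless of input order.
#'
#' @param hits a hit data.frame from [all_vs_all_similarity()] or
#'   [read_similarity_hits()] (queries = A genes, subjects = B genes).
#' @return data.frame of `CandidatePair`s: `a_gene_id`, `b_gene_id`,
#'   `score`, `reciprocal` (always `TRUE`).
#' @examples
#' h <- data.frame(query_id = c("A1", "A1", "A2"),
#'                 subject_id = c("B1", "B2", "B2"),
#'                 score = c(300, 80, 250), evalue = c(1e-80, 1e-21, 1e-60))
#' best_hit_pairs(h)
#' @export
best_hit_pairs <- function(hits) {
  if (nrow(hits) == 0)
    return(data.frame(a_gene_id = character(), b_gene_id = character(),
                      score = numeric(), reciprocal = logical()))
  best_of <- function(df, partner_col) {
    o <- order(-df$score, df$evalue, df[[partner_col]], method = "radix")
    df <- df[o, ]
    df[!duplicated(df[[setdiff(c("query_id", "subject_id"), partner_col)]]), ]
  }
  best_a <- best_of(hits, "subject_id")   # per A gene, its best B
  best_b <- best_of(hits, "query_id")     # per B gene, its best A
  key_a <- paste(best_a$query_id, best_a$subject_id)
  key_b <- paste(best_b$query_id, best_b$subject_id)
  rec <- best_a[key_a %in% key_b, ]
  out <- data.frame(a_gene_id = rec$query_id, b_gene_id = rec$subject_id,
                    score = rec$score, reciprocal = TRUE,
                    stringsAsFactors = FALSE)
  out <- out[order(out$a_gene_id), ]
  rownames(out) <- NULL
  out
}

#' Confirm candidate pairs by 100 kb synteny blocks
#'
#' Chromosomes are tiled into fixed, non-overlapping `block_bp` blocks from
#' the origin; a gene belongs to the tile containing its start coordinate.
#' A candidate pair is accepted as orthologous when the A block of its A
#' gene and the B block of its B gene jointly contain at least `min_pairs`
#' candidate pairs (the pair itself included) - i.e. the two blocks are a
#' syntenic block pair. `mode = "sliding"` instead centres a `block_bp`
#' window on each gene of the pair and counts candidate pairs whose members
#' fall in both windows. One pair per gene is enforced (highest
#' `block_support`, then score, then ids).
#'
#' @param pairs candidate pairs from [best_hit_pairs()].
#' @param subgenome_a,subgenome_b the two `SubGenome`s (for coordinates).
#' @param block_bp block size in bp (default 1e5).
#' @param min_pairs minimum joint candidate-pair count (default 3).
#' @param mode `"tiled"` (default) or `"sliding"`.
#' @return data.frame of `OrthologPair`s: `a_gene_id`, `b_gene_id`,
#'   `score`, `block_support`.
#' @export
synteny_filter <- function(pairs, subgenome_a, subgenome_b,
                           block_bp = 100000, min_pairs = 3,
                           mode = c("tiled", "sliding")) {
  mode <- match.arg(mode)
  empty <- data.frame(a_gene_id = character(), b_gene_id = character(),
                      score = numeric(), block_support = integer())
  if (nrow(pairs) == 0) return(empty)
  ga <- subgenome_a$genes; gb <- subgenome_b$genes
  ia <- match(pairs$a_gene_id, ga$gene_id)
  ib <- match(pairs$b_gene_id, gb$gene_id)
  has_coord <- !is.na(ia) & !is.na(ib)
  if (any(!has_coord)) {
    .warnf("%d pair(s) dropped: gene without coordinates", sum(!has_coord))
    pairs <- pairs[has_coord, ]; ia <- ia[has_coord]; ib <- ib[has_coord]
    if (nrow(pairs) == 0) return(empty)
  }
  a_chr <- ga$chrom[ia]; a_pos <- ga$start[ia]
  b_chr <- gb$chrom[ib]; b_pos <- gb$start[ib]

  if (mode == "tiled") {
    key <- paste(a_chr, a_pos %/% block_bp, b_chr, b_pos %/% block_bp)
    support <- as.integer(table(key)[key])
  } else {
    n <- nrow(pairs)
    support <- integer(n)
    for (i in seq_len(n)) {
      in_a <- a_chr == a_chr[i] & abs(a_pos - a_pos[i]) <= block_bp / 2
      in_b <- b_chr == b_chr[i] & abs(b_pos - b_pos[i]) <= block_bp / 2
      support[i] <- sum(in_a & in_b)
    }
  }
  keep <- support >= min_pairs
  out <- data.frame(a_gene_id = pairs$a_gene_id[keep],
                    b_gene_id = pairs$b_gene_id[keep],
                    score = pairs$score[keep],
                    block_support = support[keep],
                    stringsAsFactors = FALSE)
  # one pair per gene: highest support, then score, then ids
  o <- order(-out$block_support, -out$score, out$a_gene_id, out$b_gene_id,
             method = "radix")
  out <- out[o, ]
  out <- out[!duplicated(out$a_gene_id), ]
  out <- out[!duplicated(out$b_gene_id), ]
  out <- out[order(out$a_gene_id), ]
  rownames(out) <- NULL
  out
}

#' Merge ortholog pairs and sub-genome-specific genes into merged genes
#'
#' Every gene of both sub-genomes ends up in exactly one merged gene: an
#' ortholog pair spans both sub-genomes and is quantified as a single unit;
#' every unpaired gene becomes its own A- or B-specific merged gene.
#'
#' @param ortholog_pairs data.frame from [synteny_filter()] (or any
#'   one-pair-per-gene table with `a_gene_id`, `b_gene_id`).
#' @param subgenome_a,subgenome_b the two `SubGenome`s.
#' @return data.frame of `MergedGene`s: `merged_id`, `a_gene_id`,
#'   `b_gene_id` (`NA` when absent), `kind`
#'   (`pair`/`A_specific`/`B_specific`).
#' @examples
#' sim <- simulate_subgenomes(sim_config(seed = 1, n_genes = 20))
#' mg <- build_merged_genes(sim$truth$pairs, sim$A, sim$B)
#' table(mg$kind)
#' @export
build_merged_genes <- function(ortholog_pairs, subgenome_a, subgenome_b) {
  pa <- ortholog_pairs$a_gene_id; pb <- ortholog_pairs$b_gene_id
  if (anyDuplicated(pa) || anyDuplicated(pb))
    .stopf("a gene appears in more than one ortholog pair")
  a_ids <- subgenome_a$genes$gene_id
  b_ids <- subgenome_b$genes$gene_id
  if (!all(pa %in% a_ids) || !all(pb %in% b_ids))
    .stopf("ortholog pair references a gene absent from the sub-genomes")
  a_only <- setdiff(a_ids, pa)
  b_only <- setdiff(b_ids, pb)
  out <- rbind(
    data.frame(merged_id = sprintf("M_%s", pa), a_gene_id = pa, b_gene_id = pb,
               kind = rep("pair", length(pa)), stringsAsFactors = FALSE),
    data.frame(merged_id = sprintf("M_%s", a_only), a_gene_id = a_only,
               b_gene_id = rep(NA_character_, length(a_only)),
               kind = rep("A_specific", length(a_only)),
               stringsAsFactors = FALSE),
    data.frame(merged_id = sprintf("M_%s", b_only),
               a_gene_id = rep(NA_character_, length(b_only)),
               b_gene_id = b_only, kind = rep("B_specific", length(b_only)),
               stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  out
}
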