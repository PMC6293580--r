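#' Two-sample t-test on replicate RPM values, per merged gene and region
#'
#' Student's pooled-variance two-sided t-test on the replicate RPM values of
#' each (merged gene, region) between two stages. With the two biological
#' replicates typical of MeDIP designs, Welch degrees of freedom are
#' degenerate, hence the pooled-variance form. Degenerate zero-variance
#' cases: equal means give `p = 1` (no evidence of change); unequal means
#' with zero pooled variance give the smallest representable positive p and
#' are flagged in `degenerate`.
#'
#' @param rpm_x,rpm_y numeric matrices (rows = merged gene x region units,
#'   columns = replicates; >= 2 each) of RPM in stages x and y. Row names
#'   identify the unit as `"<merged_id>:<region>"`, or pass `units`.
#' @param contrast length-2 character, the stage labels `c(x, y)`.
#' @param alpha significance level on the raw p-value (default 0.05, the
#'   conventional cut for these designs). No multiple-testing correction is
#'   applied by default; `fdr = "bh"` adds a Benjamini-Hochberg adjusted
#'   column and bases `significant` on it.
#' @param units optional data.frame with `merged_id`, `region` matching the
#'   rows.
#' @param fdr `"none"` (default) or `"bh"`.
#' @return data.frame of `DifferentialCall`s: `merged_id`, `region`,
#'   `contrast`, `mean_rpm_x`, `mean_rpm_y`, `t_statistic`, `p_value`,
#'   `direction` (`up_in_y`/`down_in_y`/`no_change`), `significant`,
#'   `degenerate` (and `p_adjusted` when `fdr = "bh"`).
#' @examples
#' x <- matrix(c(10, 12), 1); y <- matrix(c(20, 22), 1)
#' differential_test(x, y, units = data.frame(merged_id = "M1",
#'                                            region = "body"))
#' @export
differential_test <- function(rpm_x, rpm_y, contrast = c("x", "y"),
                              alpha = 0.05, units = NULL,
                              fdr = c("none", "bh")) {
  fdr <- match.arg(fdr)
  rpm_x <- as.matrix(rpm_x); rpm_y <- as.matrix(rpm_y)
  if (ncol(rpm_x) < 2 || ncol(rpm_y) < 2)
    .stopf("at least 2 replicates per group are required")
  if (nrow(rpm_x) != nrow(rpm_y))
    .stopf("rpm_x and rpm_y must describe the same units")
  if (is.null(units)) {
    rn <- rownames(rpm_x)
    if (is.null(rn)) rn <- paste0("unit", seq_len(nrow(rpm_x)))
    parts <- strsplit(rn, ":", fixed = TRUE)
    units <- data.frame(
      merged_id = vapply(parts, `[`, "", 1),
      region = vapply(parts, function(p) if (length(p) > 1) p[2] else "gene",
                      ""),
      stringsAsFactors = FALSE)
  }
  n <- nrow(rpm_x)
  tstat <- pval <- numeric(n)
  degen <- logical(n)
  for (i in seq_len(n)) {
    x <- rpm_x[i, ]; y <- rpm_y[i, ]
    res <- tryCatch(stats::t.test(x, y, var.equal = TRUE),
                    error = function(e) NULL)
    if (is.null(res)) {   # zero pooled variance
      degen[i] <- TRUE
      if (isTRUE(all.equal(mean(x), mean(y)))) {
        tstat[i] <- 0; pval[i] <- 1
      } else {
        tstat[i] <- sign(mean(x) - mean(y)) * Inf
        pval[i] <- .Machine$double.xmin
      }
    } else {
      tstat[i] <- unname(res$statistic); pval[i] <- res$p.value
    }
  }
  mx <- rowMeans(rpm_x); my <- rowMeans(rpm_y)
  direction <- ifelse(my > mx, "up_in_y",
                      ifelse(my < mx, "down_in_y", "no_change"))
  out <- data.frame(units, contrast = paste(contrast, collapse = ":"),
                    mean_rpm_x = mx, mean_rpm_y = my,
                    t_statistic = tstat, p_value = pval,
                    direction = direction, degenerate = degen,
                    stringsAsFactors = FALSE)
  if (fdr == "bh") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjusted < alpha & out$direction != "no_change"
  } else {
    out$significant <- out$p_value < alpha & out$direction != "no_change"
  }
  rownames(out) <- NULL
  out
}

#' Collapse region-level differential calls to gene-level DMG/DEG calls
#'
#' A merged gene is differentially methylated (or expressed) for a contrast
#' when at least one of its promoter / body / TTR regions is significant.
#' The significant regions and their directions are recorded; the
#' gene-level direction follows the promoter first, then body, then TTR
#' (fixed precedence so a gene with conflicting regional directions is
#' resolved deterministically).
#'
#' @param calls data.frame from [differential_test()].
#' @param regions region kinds eligible for the gene-level call (default
#'   `c("promoter", "body", "ttr")`).
#' @return data.frame: `merged_id`, `contrast`, `regions`
#'   (comma-separated significant region kinds), `direction`.
#' @export
call_dmg <- function(calls, regions = c("promoter", "body", "ttr")) {
  sig <- calls[calls$significant & calls$region %in% regions, , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(merged_id = character(), contrast = character(),
                      regions = character(), direction = character()))
  sig$region <- factor(sig$region, levels = regions)
  sig <- sig[order(sig$merged_id, sig$region), ]
  sp <- split(sig, paste(sig$merged_id, sig$contrast, sep = "\r"))
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    merged_id = d$merged_id[1], contrast = d$contrast[1],
    regions = paste(as.character(d$region), collapse = ","),
    direction = d$direction[1],   # precedence: promoter > body > ttr
    stringsAsFactors = FALSE)))
  out <- out[order(out$merged_id), ]
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-set enrichment test
#'
#' For each gene set, tests whether the selected genes (e.g. DMGs) overlap
#' the set more than expected by chance, with the hypergeometric upper-tail
#' probability `P(X >= overlap)` over the supplied universe. Gene-set
#' membership comes from a user-supplied mapping; no live database is
#' consulted.
#'
#' @param selected_genes character vector of selected gene/merged ids; must
#'   all be in `universe`.
#' @param gene_set_map data.frame with columns `set_id`, `gene_id` (one row
#'   per membership), or a named list of character vectors.
#' @param universe character vector: all testable genes.
#' @return data.frame of `EnrichmentResult`s: `set_id`, `overlap`,
#'   `set_size`, `selected_size`, `universe_size`, `p_value`.
#' @examples
#' enrichment_test(c("g1", "g2"), list(S = c("g1", "g2", "g3")),
#'                 universe = paste0("g", 1:20))
#' @export
enrichment_test <- function(selected_genes, gene_set_map, universe) {
  if (!all(selected_genes %in% universe))
    .stopf("selected gene(s) absent from the universe: %s",
           paste(utils::head(setdiff(selected_genes, universe), 3),
                 collapse = ", "))
  if (is.data.frame(gene_set_map))
    gene_set_map <- split(gene_set_map$gene_id, gene_set_map$set_id)
  N <- length(unique(universe))
  k <- length(unique(selected_genes))
  out <- lapply(names(gene_set_map), function(sid) {
    set <- intersect(unique(gene_set_map[[sid]]), universe)
    m <- length(set)
    q <- length(intersect(set, selected_genes))
    p <- stats::phyper(q - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(set_id = sid, overlap = q, set_size = m, selected_size = k,
               universe_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
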