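#' Intersect differential methylation and expression calls into DMEGs
#'
#' A DMEG (differentially methylated and expressed gene) is a merged gene
#' significant in both the methylation calls (any of promoter/body/TTR) and
#' the expression calls for the same contrast. The methylation-expression
#' relation is `negative` when the two directions disagree (e.g.
#' hyper-methylated but down-regulated) and `positive` when they agree.
#' When a gene is differentially methylated in several regions, the
#' gene-level methylation direction follows promoter, then body, then TTR
#' precedence (set upstream by [call_dmg()]); per-region directions can be
#' retained by passing region-level calls through `meth_calls_by_region`.
#'
#' @param dmg_calls gene-level methylation calls from [call_dmg()].
#' @param deg_calls gene-level expression calls from [call_dmg()] on
#'   expression tests (region kind `"body"` or `"gene"`).
#' @param contrast the contrast label both call sets must share.
#' @param universe optional character vector; when given, both call sets
#'   must only reference genes in it (mismatched universes are an error).
#' @return data.frame of `DMEGRecord`s: `merged_id`, `contrast`,
#'   `meth_regions`, `meth_direction`, `expr_direction`, `relation`.
#' @examples
#' dmg <- data.frame(merged_id = "M1", contrast = "S1:S2",
#'                   regions = "promoter", direction = "up_in_y")
#' deg <- data.frame(merged_id = "M1", contrast = "S1:S2",
#'                   regions = "body", direction = "down_in_y")
#' identify_dmegs(dmg, deg, "S1:S2")
#' @export
identify_dmegs <- function(dmg_calls, deg_calls, contrast, universe = NULL) {
  dmg <- dmg_calls[dmg_calls$contrast == contrast, , drop = FALSE]
  deg <- deg_calls[deg_calls$contrast == contrast, , drop = FALSE]
  if (!is.null(universe)) {
    out_u <- setdiff(c(dmg$merged_id, deg$merged_id), universe)
    if (length(out_u))
      .stopf("call sets reference gene(s) outside the shared universe: %s",
             paste(utils::head(out_u, 3), collapse = ", "))
  }
  both <- intersect(dmg$merged_id, deg$merged_id)
  if (!length(both))
    return(data.frame(merged_id = character(), contrast = character(),
                      meth_regions = character(), meth_direction = character(),
                      expr_direction = character(), relation = character()))
  im <- match(both, dmg$merged_id); ie <- match(both, deg$merged_id)
  md <- dmg$direction[im]; ed <- deg$direction[ie]
  data.frame(merged_id = both, contrast = contrast,
             meth_regions = dmg$regions[im],
             meth_direction = md, expr_direction = ed,
             relation = ifelse(md == ed, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Summarize a DMEG set: region attribution and negative-relation fraction
#'
#' Counts DMEGs, how many are differentially methylated in each region
#' (a gene differentially methylated in several regions contributes to each,
#' so per-region counts may sum to more than `n_dmeg`), how many show a
#' negative methylation-expression relation, and the percentage of negative
#' relations (reported to two decimals).
#'
#' @param dmeg_records data.frame from [identify_dmegs()].
#' @return one-row data.frame (`relation_summary`): `contrast`, `n_dmeg`,
#'   `n_promoter`, `n_body`, `n_ttr`, `n_negative`, `pct_negative`
#'   (`NA` when `n_dmeg = 0`).
#' @examples
#' rec <- data.frame(merged_id = paste0("M", 1:69), contrast = "S1:S2",
#'                   meth_regions = "promoter",
#'                   meth_direction = "up_in_y",
#'                   expr_direction = rep(c("down_in_y", "up_in_y"),
#'                                        c(29, 40)))
#' rec$relation <- ifelse(rec$meth_direction == rec$expr_direction,
#'                        "positive", "negative")
#' summarize_relations(rec)$pct_negative  # 42.03
#' @export
summarize_relations <- function(dmeg_records) {
  contrast <- if (nrow(dmeg_records)) dmeg_records$contrast[1] else NA_character_
  n <- nrow(dmeg_records)
  in_region <- function(k)
    sum(vapply(strsplit(dmeg_records$meth_regions, ",", fixed = TRUE),
               function(r) k %in% r, logical(1)))
  n_neg <- sum(dmeg_records$relation == "negative")
  data.frame(contrast = contrast, n_dmeg = n,
             n_promoter = if (n) in_region("promoter") else 0L,
             n_body = if (n) in_region("body") else 0L,
             n_ttr = if (n) in_region("ttr") else 0L,
             n_negative = n_neg,
             pct_negative = if (n) round(100 * n_neg / n, 2) else NA_real_,
             stringsAsFactors = FALSE)
}
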