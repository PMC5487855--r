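## End-to-end prioritization over in-memory objects; the CLI wraps this.

#' Run the full prioritization pipeline on a cohort
#'
#' Filter cascade (QC, homopolymer indel, frequency, effect) ->
#' segregation-model selection -> deleteriousness vote -> composite ranking
#' -> structured report.
#'
#' @param ped pedigree table.
#' @param vt variant table.
#' @param ann annotation table.
#' @param config [filter_config()].
#' @param models inheritance models to test (see [select_candidates()]).
#' @param gene_scores named numeric vector of gene-evidence scores (optional).
#' @param truth optional planted-truth record for recovery reporting.
#' @param min_alt_depth,strict_missing,lenient_affected_female,par_regions
#'   passed to the segregation module.
#' @return list with `ranked`, `funnel`, `report`, `candidates`.
#' @export
prioritize_cohort <- function(ped, vt, ann, config = filter_config(),
                              models = c("de_novo", "autosomal_recessive_hom",
                                         "x_linked_recessive"),
                              gene_scores = numeric(), truth = NULL,
                              min_alt_depth = 5L, strict_missing = TRUE,
                              lenient_affected_female = TRUE,
                              par_regions = NULL) {
  casc <- run_filter_cascade(vt, ann, config)
  seg <- select_candidates(casc$variants, ped, models = models,
                           min_alt_depth = min_alt_depth,
                           strict_missing = strict_missing,
                           lenient_affected_female = lenient_affected_female,
                           par_regions = par_regions)
  funnel <- add_funnel_row(casc$funnel, "segregation",
                           seg$funnel_row$n_in, seg$funnel_row$n_out)
  cand <- seg$candidates
  n_tools <- length(tool_columns(ann))
  calls <- tool_calls(ann)
  votes <- lapply(setNames(cand$variant_key, cand$variant_key), function(k) {
    vote_deleteriousness(calls[[k]], n_tools)
  })
  cand_tab <- data.table(
    variant_key = cand$variant_key,
    gene = ann$gene[match(cand$variant_key, ann$variant_key)],
    conserved = ann$conserved_region[match(cand$variant_key, ann$variant_key)],
    low_confidence = if (nrow(cand)) cand$low_confidence else logical())
  ranked <- rank_candidates(cand_tab, votes, gene_scores)
  report <- build_report(funnel, ranked, ped, truth = truth)
  list(ranked = ranked, funnel = funnel, report = report, candidates = cand)
}
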