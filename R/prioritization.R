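## Candidate scoring and ranking: ensemble deleteriousness majority vote,
## additive gene-level evidence score, deterministic composite ranking and
## the structured run report.

#' Majority-vote deleteriousness over an ensemble of prediction tools
#'
#' Call weights: deleterious = 1, ambiguous = 0.5, tolerated = 0,
#' missing = 0 (the denominator stays at `n_tools`; missing calls are not
#' renormalized away). A variant is deleterious iff the summed score is
#' strictly greater than half the tool count, so a 5/10 split is not
#' deleterious.
#'
#' @param calls character vector of per-tool calls
#'   (deleterious/tolerated/ambiguous/missing).
#' @param n_tools expected ensemble size (default 10); `length(calls)` must
#'   equal it.
#' @return list with `score`, `n_tools`, `is_deleterious`.
#' @export
vote_deleteriousness <- function(calls, n_tools = 10L) {
  if (length(calls) != n_tools) {
    vk_stop("expected %d tool calls, got %d", n_tools, length(calls))
  }
  bad <- setdiff(calls, tool_call_levels)
  if (length(bad)) vk_stop("unknown tool call(s): %s", paste(bad, collapse = ", "))
  w <- c(deleterious = 1, ambiguous = 0.5, tolerated = 0, missing = 0)
  score <- sum(w[calls])
  list(score = score, n_tools = as.integer(n_tools),
       is_deleterious = score > n_tools / 2)
}

#' Additive gene-level evidence score
#'
#' Three unit-weight terms, each 0 when the evidence is missing:
#' +1 when any disease association matches the query phenotype terms,
#' +1 when expression in any relevant tissue is medium or high,
#' +1 when the RVIS percentile is <= `rvis_intolerant_max` (inclusive;
#' low percentile = intolerant gene). Weights are exposed for sensitivity
#' analysis.
#'
#' @param gene gene symbol (used only for error messages).
#' @param evidence list/row with `phenotypes` (character vector),
#'   `tissue_expression` (named character vector tissue -> level) and
#'   `rvis_percentile`; `NULL` scores 0.
#' @param phenotype_terms phenotype identifiers of the case.
#' @param relevant_tissues tissues relevant to the phenotype.
#' @param weights named numeric vector (disease, tissue, rvis).
#' @param rvis_intolerant_max RVIS percentile cutoff (default 25, inclusive).
#' @return numeric score.
#' @export
score_gene_evidence <- function(gene, evidence, phenotype_terms = character(),
                                relevant_tissues = character(),
                                weights = c(disease = 1, tissue = 1, rvis = 1),
                                rvis_intolerant_max = 25) {
  if (is.null(evidence)) return(0)
  ph <- evidence$phenotypes
  if (is.list(ph)) ph <- ph[[1L]]
  tx <- evidence$tissue_expression
  if (is.list(tx) && !is.character(tx)) tx <- tx[[1L]]
  rv <- evidence$rvis_percentile
  if (is.list(rv)) rv <- rv[[1L]]
  s <- 0
  if (length(ph) && length(intersect(ph, phenotype_terms))) s <- s + weights[["disease"]]
  if (length(tx)) {
    rel <- tx[names(tx) %in% relevant_tissues]
    if (length(rel) && any(rel %in% c("medium", "high"))) s <- s + weights[["tissue"]]
  }
  if (length(rv) && !is.na(rv) && rv <= rvis_intolerant_max) s <- s + weights[["rvis"]]
  s
}

#' Rank candidate variants
#'
#' Lexicographic sort key: deleterious first, then vote score, gene-evidence
#' score and conservation (all descending), with the variant key as a
#' deterministic tie-break. Rank 1 is the best candidate.
#'
#' @param candidates `data.table` with `variant_key`, `gene` and logical
#'   `conserved` columns (one row per candidate).
#' @param votes named list of [vote_deleteriousness()] results keyed by
#'   variant key.
#' @param gene_scores named numeric vector of gene-evidence scores keyed by
#'   gene (missing genes score 0).
#' @return `data.table` with vote columns and `composite_rank`, sorted by
#'   rank.
#' @export
rank_candidates <- function(candidates, votes, gene_scores = numeric()) {
  cand <- copy(as.data.table(candidates))
  if (!nrow(cand)) {
    return(data.table(variant_key = character(), gene = character(),
                      vote_score = numeric(), is_deleterious = logical(),
                      gene_evidence_score = numeric(), conserved = logical(),
                      composite_rank = integer()))
  }
  cand[, vote_score := vapply(variant_key, function(k) votes[[k]]$score, numeric(1L))]
  cand[, is_deleterious := vapply(variant_key, function(k) votes[[k]]$is_deleterious, logical(1L))]
  cand[, gene_evidence_score := vapply(gene, function(g) {
    if (g %in% names(gene_scores)) gene_scores[[g]] else 0
  }, numeric(1L))]
  if (!"conserved" %in% names(cand)) cand[, conserved := FALSE]
  ord <- order(-cand$is_deleterious, -cand$vote_score,
               -cand$gene_evidence_score, -cand$conserved, cand$variant_key)
  cand <- cand[ord]
  cand[, composite_rank := seq_len(.N)]
  cand[]
}

#' Build a structured prioritization report
#'
#' @param funnel funnel table (`stage`, `n_in`, `n_out`).
#' @param ranked output of [rank_candidates()].
#' @param ped pedigree table.
#' @param truth optional truth record (list with `variant_key`, `model`)
#'   from the synthetic generator; when supplied the report states the rank
#'   at which the planted variant was recovered (`NA` if lost).
#' @return list of class `varkin_report`.
#' @export
build_report <- function(funnel, ranked, ped, truth = NULL) {
  rep <- list(
    pedigree = list(n_samples = nrow(ped),
                    n_affected = length(affected_ids(ped))),
    funnel = as.data.frame(funnel),
    n_candidates = nrow(ranked),
    candidates = if (nrow(ranked)) {
      as.data.frame(ranked[, intersect(
        c("composite_rank", "variant_key", "gene", "vote_score",
          "is_deleterious", "gene_evidence_score", "conserved",
          "low_confidence"), names(ranked)), with = FALSE])
    } else list(),
    empty_result = nrow(ranked) == 0L
  )
  if (!is.null(truth) && length(truth$variant_key)) {
    hit <- match(truth$variant_key, ranked$variant_key)
    rep$truth <- list(variant_key = truth$variant_key,
                      model = truth$model %||% NA_character_,
                      recovered_at_rank = if (is.na(hit)) NA_integer_
                                          else ranked$composite_rank[hit])
  }
  structure(rep, class = "varkin_report")
}

#' Serialize / restore a report as JSON
#' @param report report from [build_report()].
#' @param path output path.
#' @return `path` invisibly (`write_report`) or restored list (`read_report`).
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE), class = "varkin_report")
}

#' @export
print.varkin_report <- function(x, ...) {
  cat("varkin prioritization report\n")
  cat(sprintf("  samples: %d (%d affected)\n",
              x$pedigree$n_samples, x$pedigree$n_affected))
  f <- x$funnel
  for (i in seq_len(nrow(f))) {
    cat(sprintf("  %-20s %7d -> %7d\n", f$stage[i], f$n_in[i], f$n_out[i]))
  }
  cat(sprintf("  candidates: %d\n", x$n_candidates))
  if (!is.null(x$truth)) {
    cat(sprintf("  planted %s recovered at rank %s\n",
                x$truth$variant_key, x$truth$recovered_at_rank))
  }
  invisible(x)
}
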