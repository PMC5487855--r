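## Pre-segregation filter cascade: QC flags -> homopolymer-adjacent indels
## -> population allele frequency -> coding effect, with a funnel report.
## Each stage is an independent predicate over (variant, annotation), so the
## terminal set equals the intersection of the per-stage passing sets; only
## the per-stage counts depend on stage order.

#' Filter cascade configuration
#'
#' @param mode `"monogenic"` (default, 1% allele-frequency ceiling) or
#'   `"polygenic_pharmacologic"` (10% ceiling).
#' @param monogenic_max_af frequency threshold for monogenic mode; a variant
#'   is excluded when any present database frequency is strictly greater
#'   than this, so AF exactly 0.01 passes.
#' @param polygenic_max_af threshold for polygenic/pharmacologic mode.
#' @param homopolymer_min_run minimum mononucleotide run length that marks
#'   an adjacent indel (default 6, i.e. runs longer than five bases).
#' @param flank_window half-width in bp of the reference context inspected
#'   around an indel (default 10).
#' @param adjacency_tol bases of slack allowed between the indel anchor and
#'   the repeat feature (default 1 = the feature must contain or abut the
#'   anchor).
#' @param excluded_qc_flags QC flags that remove a variant (default: all
#'   five).
#' @param keep_effects coding-effect classes retained by the effect filter
#'   (default: amino-acid-changing only; add `"splicing"` to keep splice
#'   variants).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(mode = c("monogenic", "polygenic_pharmacologic"),
                          monogenic_max_af = 0.01,
                          polygenic_max_af = 0.10,
                          homopolymer_min_run = 6L,
                          flank_window = 10L,
                          adjacency_tol = 1L,
                          excluded_qc_flags = qc_flag_levels,
                          keep_effects = "exonic_nonsynonymous") {
  mode <- match.arg(mode)
  stopifnot(monogenic_max_af > 0, monogenic_max_af < polygenic_max_af,
            polygenic_max_af <= 1, homopolymer_min_run >= 2L)
  structure(list(mode = mode,
                 monogenic_max_af = monogenic_max_af,
                 polygenic_max_af = polygenic_max_af,
                 homopolymer_min_run = as.integer(homopolymer_min_run),
                 flank_window = as.integer(flank_window),
                 adjacency_tol = as.integer(adjacency_tol),
                 excluded_qc_flags = excluded_qc_flags,
                 keep_effects = keep_effects),
            class = "filter_config")
}

active_max_af <- function(config) {
  if (config$mode == "monogenic") config$monogenic_max_af else config$polygenic_max_af
}

#' Remove variants carrying excluded QC flags
#'
#' @param vt variant table.
#' @param config [filter_config()].
#' @return subset of `vt` whose flag set does not intersect
#'   `config$excluded_qc_flags`.
#' @export
qc_filter <- function(vt, config = filter_config()) {
  keep <- !vapply(vt$qc_flags, function(f) {
    length(intersect(f, config$excluded_qc_flags)) > 0L
  }, logical(1L))
  vt[keep]
}

#' Build a context provider from an annotation table
#'
#' The default context source for [homopolymer_indel_filter()]: looks up the
#' `context` column (reference sequence of width `2*flank_window + 1`
#' centred on the indel anchor).
#'
#' @param ann annotation table with a `context` column.
#' @return function(variant_key) -> list(seq, pos).
#' @export
annotation_context_provider <- function(ann) {
  ctx <- setNames(ann$context, ann$variant_key)
  function(key) {
    s <- ctx[[key]]
    if (is.null(s) || is.na(s)) return(NULL)
    list(seq = s, pos = (nchar(s) + 1L) %/% 2L)
  }
}

#' Exclude indels adjacent to homopolymers or short tandem repeats
#'
#' SNVs always pass. An indel is excluded when a mononucleotide run of
#' length >= `homopolymer_min_run`, or a tandem repeat (unit 2-6 bp, >= 3
#' copies), includes or abuts its anchor position within `adjacency_tol`.
#'
#' @param vt variant table.
#' @param ann annotation table (supplies `is_indel` and, via the default
#'   provider, the reference contexts).
#' @param config [filter_config()].
#' @param context_provider function(variant_key) -> list(seq, pos) or NULL;
#'   defaults to [annotation_context_provider()] over `ann`.
#' @return subset of `vt`.
#' @export
homopolymer_indel_filter <- function(vt, ann, config = filter_config(),
                                     context_provider = annotation_context_provider(ann)) {
  is_indel <- setNames(ann$is_indel, ann$variant_key)
  keep <- vapply(vt$variant_key, function(key) {
    indel <- isTRUE(is_indel[[key]])
    if (!indel) return(TRUE)
    ctx <- context_provider(key)
    if (is.null(ctx)) vk_stop("no reference context for indel %s", key)
    if (nchar(ctx$seq) < config$flank_window) {
      vk_stop("context for indel %s shorter than flank window (%d < %d)",
              key, nchar(ctx$seq), config$flank_window)
    }
    !is_repeat_adjacent(ctx$seq, ctx$pos,
                        min_run = config$homopolymer_min_run,
                        tol = config$adjacency_tol)
  }, logical(1L))
  vt[keep]
}

#' Exclude variants prevalent in any population database
#'
#' A variant is excluded iff any *present* database frequency is strictly
#' greater than the active mode's threshold. Absence from a database is
#' treated as evidence of rarity, so variants missing from all databases
#' pass.
#'
#' @param vt variant table.
#' @param ann annotation table with `af_*` columns.
#' @param config [filter_config()].
#' @return subset of `vt`.
#' @export
frequency_filter <- function(vt, ann, config = filter_config()) {
  thr <- active_max_af(config)
  afc <- af_columns(ann)
  afm <- as.matrix(ann[, afc, with = FALSE])
  max_af <- apply(afm, 1L, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  prevalent_keys <- ann$variant_key[!is.na(max_af) & max_af > thr]
  vt[!vt$variant_key %in% prevalent_keys]
}

#' Retain variants in the configured coding-effect classes
#'
#' @param vt variant table.
#' @param ann annotation table.
#' @param config [filter_config()]; `keep_effects` defaults to
#'   amino-acid-changing variants only.
#' @return subset of `vt`.
#' @export
effect_filter <- function(vt, ann, config = filter_config()) {
  eff <- setNames(ann$effect, ann$variant_key)
  vt[vapply(vt$variant_key, function(k) {
    isTRUE(eff[[k]] %in% config$keep_effects)
  }, logical(1L))]
}

#' Run the full pre-segregation filter cascade
#'
#' Applies QC -> homopolymer indel -> frequency -> effect in order and
#' records a funnel row per stage.
#'
#' @param vt variant table.
#' @param ann annotation table.
#' @param config [filter_config()].
#' @return list with `variants` (surviving subset) and `funnel`
#'   (`data.table` with `stage`, `n_in`, `n_out`).
#' @export
run_filter_cascade <- function(vt, ann, config = filter_config()) {
  stages <- list(
    qc = function(v) qc_filter(v, config),
    homopolymer_indel = function(v) homopolymer_indel_filter(v, ann, config),
    frequency = function(v) frequency_filter(v, ann, config),
    effect = function(v) effect_filter(v, ann, config)
  )
  funnel <- funnel_report()
  for (nm in names(stages)) {
    n_in <- nrow(vt)
    vt <- stages[[nm]](vt)
    funnel <- add_funnel_row(funnel, nm, n_in, nrow(vt))
  }
  list(variants = vt, funnel = funnel)
}

#' Funnel report constructor and accumulator
#'
#' A funnel report records, per pipeline stage, the number of variants
#' entering and surviving. Invariants: `n_out <= n_in` and stage k's `n_in`
#' equals stage k-1's `n_out`.
#'
#' @return empty funnel `data.table`.
#' @export
funnel_report <- function() {
  data.table(stage = character(), n_in = integer(), n_out = integer())
}

#' @rdname funnel_report
#' @param funnel existing funnel table.
#' @param stage stage name.
#' @param n_in,n_out entering/surviving counts.
#' @export
add_funnel_row <- function(funnel, stage, n_in, n_out) {
  if (n_out > n_in) vk_stop("funnel stage '%s' grew: %d -> %d", stage, n_in, n_out)
  if (nrow(funnel) && funnel$n_out[nrow(funnel)] != n_in) {
    vk_stop("funnel stage '%s' n_in (%d) != previous n_out (%d)",
            stage, n_in, funnel$n_out[nrow(funnel)])
  }
  rbind(funnel, data.table(stage = stage, n_in = as.integer(n_in),
                           n_out = as.integer(n_out)))
}
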