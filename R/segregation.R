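## Pedigree-aware inheritance-model predicates: de novo, autosomal
## recessive (homozygous) and X-linked recessive, plus candidate selection
## over a variant table.
##
## Missing-genotype policy: with `strict_missing = TRUE` (default) a missing
## genotype in any sample whose genotype the model constrains blocks
## consistency; it is recorded as "missing_data", not as a violation, so the
## two causes are distinguishable downstream.

seg_result <- function(variant_key, model, per_sample, strict_missing,
                       low_confidence = FALSE) {
  violates <- any(per_sample == "violates")
  missing <- any(per_sample == "missing_data")
  consistent <- !violates && !(strict_missing && missing)
  structure(list(variant_key = variant_key, model = model,
                 consistent = consistent,
                 low_confidence = consistent && low_confidence,
                 per_sample_assessment = per_sample),
            class = "segregation_result")
}

assess <- function(gt, ok) {
  if (is.na(gt) || gt == "missing") "missing_data" else if (ok) "consistent" else "violates"
}

variant_gt <- function(variant) {
  gt <- variant$genotypes
  if (is.list(gt)) gt <- gt[[1L]]
  gt
}

#' De novo segregation check
#'
#' Consistent iff the proband carries at least one alternate allele while
#' both parents and all siblings are called non-carriers. The result is
#' flagged low-confidence when the proband's alternate-allele depth is
#' strictly below `min_alt_depth` (default 5).
#'
#' @param variant one-row variant table (or list with `variant_key`,
#'   `genotypes`, `alt_depth`).
#' @param ped pedigree table.
#' @param min_alt_depth low-coverage threshold (strict `<`).
#' @param proband proband sample id; defaults to [proband_id()].
#' @param strict_missing missing genotypes veto consistency (default TRUE).
#' @return `segregation_result`.
#' @export
check_de_novo <- function(variant, ped, min_alt_depth = 5L,
                          proband = proband_id(ped), strict_missing = TRUE) {
  gt <- variant_gt(variant)
  if (!proband %in% names(gt)) {
    vk_stop("proband '%s' absent from genotype map of %s", proband, variant$variant_key)
  }
  prow <- ped[ped$sample_id == proband, ]
  parents <- stats::na.omit(c(prow$father_id, prow$mother_id))
  sibs <- ped$sample_id[
    (!is.na(ped$father_id) & ped$father_id %in% parents) |
      (!is.na(ped$mother_id) & ped$mother_id %in% parents)]
  sibs <- setdiff(sibs, proband)
  per <- setNames(rep("consistent", length(gt)), names(gt))
  per[proband] <- assess(gt[[proband]], gt_is_carrier(gt[[proband]]))
  for (s in intersect(c(parents, sibs), names(gt))) {
    per[s] <- assess(gt[[s]], !gt_is_carrier(gt[[s]]))
  }
  for (s in setdiff(c(parents, sibs), names(gt))) per[s] <- "missing_data"
  ad <- variant$alt_depth
  if (is.list(ad)) ad <- ad[[1L]]
  pd <- if (proband %in% names(ad)) ad[[proband]] else NA_integer_
  low <- is.na(pd) || pd < min_alt_depth
  seg_result(variant$variant_key, "de_novo", per, strict_missing, low)
}

#' Autosomal recessive (homozygous) segregation check
#'
#' Consistent iff every affected sample is `hom_alt`, every parent of an
#' affected sample (an obligate carrier) is `het`, and no unaffected sample
#' is `hom_alt`.
#'
#' @inheritParams check_de_novo
#' @return `segregation_result`.
#' @export
check_autosomal_recessive_hom <- function(variant, ped, strict_missing = TRUE) {
  gt <- variant_gt(variant)
  per <- setNames(rep("consistent", length(gt)), names(gt))
  aff <- affected_ids(ped)
  obligate <- unique(stats::na.omit(unlist(
    ped[ped$sample_id %in% aff, c("father_id", "mother_id")])))
  obligate <- setdiff(obligate, aff)
  for (s in names(gt)) {
    srow <- ped[ped$sample_id == s, ]
    per[s] <- if (s %in% aff) {
      assess(gt[[s]], gt[[s]] == "hom_alt")
    } else if (s %in% obligate) {
      assess(gt[[s]], gt[[s]] == "het")
    } else if (srow$affected == "unaffected") {
      assess(gt[[s]], gt[[s]] != "hom_alt")
    } else "consistent"
  }
  seg_result(variant$variant_key, "autosomal_recessive_hom", per, strict_missing)
}

#' X-linked recessive segregation check
#'
#' For non-PAR X variants only (autosomal input errors). Consistent iff
#' every affected male is `hemi_alt`, the mother of each affected male is a
#' carrier (`het` or `hom_alt`), no unaffected male is `hemi_alt` and no
#' unaffected female is `hom_alt`. Affected females do not veto by default
#' (`lenient_affected_female = TRUE`), accommodating mildly affected females
#' whose status may reflect skewed X-inactivation or an unrelated cause;
#' when FALSE they must be carriers.
#'
#' @inheritParams check_de_novo
#' @param lenient_affected_female see Details.
#' @param par_regions pseudoautosomal intervals (see [is_x_nonpar()]).
#' @return `segregation_result`.
#' @export
check_x_linked_recessive <- function(variant, ped, strict_missing = TRUE,
                                     lenient_affected_female = TRUE,
                                     par_regions = NULL) {
  chrom <- if (is.list(variant$chrom)) variant$chrom[[1L]] else variant$chrom
  pos <- if (is.list(variant$pos)) variant$pos[[1L]] else variant$pos
  if (!is_x_nonpar(chrom, pos, par_regions)) {
    vk_stop("X-linked recessive check called on non-X (or PAR) variant %s",
            variant$variant_key)
  }
  gt <- variant_gt(variant)
  per <- setNames(rep("consistent", length(gt)), names(gt))
  aff_males <- affected_ids(ped, "male")
  carrier_mothers <- unique(stats::na.omit(
    ped$mother_id[ped$sample_id %in% aff_males]))
  for (s in names(gt)) {
    srow <- ped[ped$sample_id == s, ]
    per[s] <- if (s %in% aff_males) {
      assess(gt[[s]], gt[[s]] == "hemi_alt")
    } else if (s %in% carrier_mothers) {
      assess(gt[[s]], gt[[s]] %in% c("het", "hom_alt"))
    } else if (srow$sex == "male" && srow$affected == "unaffected") {
      assess(gt[[s]], gt[[s]] != "hemi_alt")
    } else if (srow$sex == "female" && srow$affected == "unaffected") {
      assess(gt[[s]], gt[[s]] != "hom_alt")
    } else if (srow$sex == "female" && srow$affected == "affected") {
      if (lenient_affected_female) "consistent"
      else assess(gt[[s]], gt[[s]] %in% c("het", "hom_alt"))
    } else "consistent"
  }
  seg_result(variant$variant_key, "x_linked_recessive", per, strict_missing)
}

#' Select variants consistent with any requested inheritance model
#'
#' The X-linked predicate is only evaluated for non-PAR X variants; the
#' autosomal models for all variants. Returns the union of consistent
#' variants, each tagged with the model(s) it satisfies, plus a funnel row.
#'
#' @param vt variant table.
#' @param ped pedigree table.
#' @param models subset of `de_novo`, `autosomal_recessive_hom`,
#'   `x_linked_recessive`.
#' @param min_alt_depth de novo low-coverage threshold.
#' @param strict_missing,lenient_affected_female,par_regions passed to the
#'   individual checks.
#' @return list with `candidates` (variant table plus list-column `models`
#'   and logical `low_confidence`), `results` (all segregation results) and
#'   `funnel_row`.
#' @export
select_candidates <- function(vt, ped,
                              models = c("de_novo", "autosomal_recessive_hom",
                                         "x_linked_recessive"),
                              min_alt_depth = 5L, strict_missing = TRUE,
                              lenient_affected_female = TRUE,
                              par_regions = NULL) {
  models <- match.arg(models, several.ok = TRUE)
  tags <- vector("list", nrow(vt))
  lowconf <- logical(nrow(vt))
  results <- list()
  for (i in seq_len(nrow(vt))) {
    v <- vt[i]
    hit <- character()
    if ("de_novo" %in% models) {
      r <- check_de_novo(v, ped, min_alt_depth, strict_missing = strict_missing)
      results[[length(results) + 1L]] <- r
      if (r$consistent) {
        hit <- c(hit, "de_novo")
        lowconf[i] <- lowconf[i] || r$low_confidence
      }
    }
    if ("autosomal_recessive_hom" %in% models &&
        !is_x_nonpar(v$chrom, v$pos, par_regions)) {
      r <- check_autosomal_recessive_hom(v, ped, strict_missing = strict_missing)
      results[[length(results) + 1L]] <- r
      if (r$consistent) hit <- c(hit, "autosomal_recessive_hom")
    }
    if ("x_linked_recessive" %in% models && is_x_nonpar(v$chrom, v$pos, par_regions)) {
      r <- check_x_linked_recessive(v, ped, strict_missing = strict_missing,
                                    lenient_affected_female = lenient_affected_female,
                                    par_regions = par_regions)
      results[[length(results) + 1L]] <- r
      if (r$consistent) hit <- c(hit, "x_linked_recessive")
    }
    tags[[i]] <- hit
  }
  keep <- lengths(tags) > 0L
  cand <- vt[keep]
  cand$models <- tags[keep]
  cand$low_confidence <- lowconf[keep]
  list(candidates = cand,
       results = results,
       funnel_row = data.table(stage = "segregation",
                               n_in = nrow(vt), n_out = nrow(cand)))
}
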