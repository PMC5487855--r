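# Pre-segregation filter cascade.

simple_vt <- function(rows) {
  variant_table(vapply(rows, `[[`, character(1L), "chrom"),
                vapply(rows, `[[`, integer(1L), "pos"),
                vapply(rows, `[[`, character(1L), "ref"),
                vapply(rows, `[[`, character(1L), "alt"),
                genotypes = rep(list(c(s1 = "het")), length(rows)),
                qc_flags = lapply(rows, function(r) r$flags %||% character()))
}

simple_ann <- function(vt, effect = "exonic_nonsynonymous", is_indel = FALSE,
                       context = NA_character_, af = list()) {
  n <- nrow(vt)
  ann <- data.table(chrom = vt$chrom, pos = vt$pos, ref = vt$ref, alt = vt$alt,
                    gene = paste0("G", seq_len(n)), effect = effect,
                    conserved_region = FALSE, is_indel = is_indel,
                    context = context)
  ann$af_exac <- af$exac %||% rep(NA_real_, n)
  ann$af_esp <- af$esp %||% rep(NA_real_, n)
  ann$af_kg <- af$kg %||% rep(NA_real_, n)
  ann$tool_1 <- "tolerated"
  annotation_table(ann)
}

test_that("qc_filter removes flagged variants only", {
  vt <- simple_vt(list(
    list(chrom = "1", pos = 100L, ref = "A", alt = "C", flags = "strand_bias"),
    list(chrom = "1", pos = 200L, ref = "A", alt = "C"),
    list(chrom = "1", pos = 300L, ref = "A", alt = "C",
         flags = c("low_base_quality", "aberrant_read_position"))))
  out <- qc_filter(vt)
  expect_equal(out$pos, 200L)
  # all-flagged input empties out
  allflag <- simple_vt(lapply(1:4, function(i) {
    list(chrom = "1", pos = i * 10L, ref = "A", alt = "C",
         flags = sample(qc_flag_levels, 1L))
  }))
  expect_equal(nrow(qc_filter(allflag)), 0L)
  # flags can be selectively excluded
  cfg <- filter_config(excluded_qc_flags = "strand_bias")
  expect_equal(qc_filter(vt, cfg)$pos, c(200L, 300L))
})

test_that("homopolymer filter excludes adjacent indels, passes SNVs and run-5 indels", {
  ctx_run6 <- "ACGTACGTACTAAAAAAGTCA"  # run of 6 A starting right of centre
  ctx_run5 <- "ACGTACGTACTAAAAAGTCCA"  # run of exactly 5
  vt <- simple_vt(list(
    list(chrom = "1", pos = 100L, ref = "AT", alt = "A"),
    list(chrom = "1", pos = 200L, ref = "AT", alt = "A"),
    list(chrom = "1", pos = 300L, ref = "A", alt = "C")))
  ann <- simple_ann(vt, is_indel = c(TRUE, TRUE, FALSE),
                    context = c(ctx_run6, ctx_run5, "AAAAAAAAAAAAAAAAAAAAA"))
  out <- homopolymer_indel_filter(vt, ann)
  # deletion beside the 6-run excluded; 5-run retained; SNV inside a long run retained
  expect_setequal(out$pos, c(200L, 300L))
})

test_that("homopolymer filter errors on missing or short contexts", {
  vt <- simple_vt(list(list(chrom = "1", pos = 100L, ref = "AT", alt = "A")))
  ann_na <- simple_ann(vt, is_indel = TRUE, context = NA_character_)
  expect_error(homopolymer_indel_filter(vt, ann_na), "no reference context")
  ann_short <- simple_ann(vt, is_indel = TRUE, context = "ACGT")
  expect_error(homopolymer_indel_filter(vt, ann_short), "shorter than flank window")
})

test_that("frequency filter excludes on any present database and passes missing", {
  vt <- simple_vt(lapply(1:3, function(i)
    list(chrom = "1", pos = i * 100L, ref = "A", alt = "C")))
  ann <- simple_ann(vt, af = list(exac = c(5e-4, 0.02, NA),
                                  esp = c(6e-4, NA, NA),
                                  kg = c(NA, NA, NA)))
  mono <- frequency_filter(vt, ann, filter_config("monogenic"))
  expect_setequal(mono$pos, c(100L, 300L))  # rare passes, 2% out, all-missing passes
  poly <- frequency_filter(vt, ann, filter_config("polygenic_pharmacologic"))
  expect_equal(nrow(poly), 3L)              # 2% passes the 10% ceiling
  # threshold is strict: AF exactly 0.01 passes monogenic
  ann2 <- simple_ann(vt, af = list(exac = c(0.01, 0.010001, NA)))
  expect_setequal(frequency_filter(vt, ann2, filter_config())$pos, c(100L, 300L))
})

test_that("effect filter keeps amino-acid-changing variants by default", {
  vt <- simple_vt(lapply(1:4, function(i)
    list(chrom = "1", pos = i * 100L, ref = "A", alt = "C")))
  ann <- simple_ann(vt, effect = c("exonic_nonsynonymous", "exonic_synonymous",
                                   "splicing", "other"))
  expect_equal(effect_filter(vt, ann)$pos, 100L)
  cfg <- filter_config(keep_effects = c("exonic_nonsynonymous", "splicing"))
  expect_setequal(effect_filter(vt, ann, cfg)$pos, c(100L, 300L))
})

test_that("cascade equals sequential stage application and is monotone", {
  co <- generate_cohort(cohort_spec(n_background_variants = 300, seed = 13))
  cfg <- filter_config()
  casc <- run_filter_cascade(co$variants, co$annotations, cfg)
  # oracle: apply the four operators by hand, in order
  manual <- effect_filter(
    frequency_filter(
      homopolymer_indel_filter(
        qc_filter(co$variants, cfg), co$annotations, cfg),
      co$annotations, cfg),
    co$annotations, cfg)
  expect_identical(casc$variants$variant_key, manual$variant_key)
  # stages are independent predicates: terminal set = intersection of
  # per-stage passing sets on the full input
  pass_sets <- list(
    qc_filter(co$variants, cfg)$variant_key,
    homopolymer_indel_filter(co$variants, co$annotations, cfg)$variant_key,
    frequency_filter(co$variants, co$annotations, cfg)$variant_key,
    effect_filter(co$variants, co$annotations, cfg)$variant_key)
  expect_setequal(casc$variants$variant_key, Reduce(intersect, pass_sets))
  # funnel bookkeeping
  expect_true(all(casc$funnel$n_out <= casc$funnel$n_in))
  expect_equal(casc$funnel$n_in[-1L], casc$funnel$n_out[-nrow(casc$funnel)])
  # every stage's output is a subset of its input
  expect_true(all(casc$variants$variant_key %in% co$variants$variant_key))
})

test_that("frequency filter is monotone in threshold (1% passing within 10%)", {
  co <- generate_cohort(cohort_spec(n_background_variants = 400, seed = 17))
  at1 <- frequency_filter(co$variants, co$annotations, filter_config("monogenic"))
  at10 <- frequency_filter(co$variants, co$annotations,
                           filter_config("polygenic_pharmacologic"))
  expect_true(all(at1$variant_key %in% at10$variant_key))
  expect_lt(nrow(at1), nrow(at10))
})

test_that("funnel accumulator rejects malformed funnels", {
  f <- add_funnel_row(funnel_report(), "a", 10, 5)
  expect_error(add_funnel_row(f, "b", 9, 5), "n_in")
  expect_error(add_funnel_row(f, "b", 5, 6), "grew")
})
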