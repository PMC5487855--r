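# Synthetic cohort / context / network / assay generators.

test_that("cohorts are byte-identical under a fixed seed", {
  spec <- cohort_spec(n_background_variants = 50, seed = 42)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    write_vcf(c1$variants, c1$pedigree, file.path(d, "c.vcf"))
    write_annotations(c1$annotations, file.path(d, "ann.tsv"))
  }
  expect_identical(readLines(file.path(d1, "c.vcf")),
                   readLines(file.path(d2, "c.vcf")))
  expect_identical(readLines(file.path(d1, "ann.tsv")),
                   readLines(file.path(d2, "ann.tsv")))
  c3 <- generate_cohort(cohort_spec(n_background_variants = 50, seed = 43))
  expect_false(identical(c1$variants, c3$variants))
})

test_that("planted variants satisfy their model exactly (generator/consumer cross-check)", {
  for (model in c("x_linked_recessive", "de_novo", "autosomal_recessive_hom")) {
    co <- generate_cohort(cohort_spec(n_background_variants = 30,
                                      planted_model = model, seed = 7))
    expect_equal(co$truth$model, model)
    v <- co$variants[co$variants$variant_key == co$truth$variant_key]
    expect_equal(nrow(v), 1L)
    res <- switch(model,
                  x_linked_recessive = check_x_linked_recessive(v, co$pedigree),
                  de_novo = check_de_novo(v, co$pedigree),
                  autosomal_recessive_hom = check_autosomal_recessive_hom(v, co$pedigree))
    expect_true(res$consistent, info = model)
  }
  # explicit X-linked pattern: proband hemizygous, mother het, others clear
  co <- generate_cohort(cohort_spec(n_background_variants = 0, seed = 1))
  gt <- co$variants$genotypes[[1L]]
  expect_equal(unname(gt[["p1"]]), "hemi_alt")
  expect_equal(unname(gt[["mo"]]), "het")
  others <- setdiff(names(gt), c("p1", "mo"))
  expect_true(all(gt[others] %in% c("hom_ref", "hemi_ref")))
})

test_that("planted_model none gives empty truth; X-linked needs an affected male", {
  co <- generate_cohort(cohort_spec(n_background_variants = 10,
                                    planted_model = "none", seed = 3))
  expect_length(co$truth, 0L)
  noaff <- pedigree(c("fa", "mo", "girl"), c(NA, NA, "fa"), c(NA, NA, "mo"),
                    c("male", "female", "female"),
                    c("unaffected", "unaffected", "affected"))
  expect_error(
    generate_cohort(cohort_spec("custom", 5, "x_linked_recessive", seed = 1,
                                custom_pedigree = noaff)),
    "affected male")
})

test_that("founder allele frequencies converge to spec frequencies (3 SE)", {
  co <- generate_cohort(cohort_spec(n_background_variants = 3000,
                                    planted_model = "none", seed = 99))
  founders <- c("fa", "mo")
  count_alt <- function(g, sex) {
    switch(g, hom_ref = 0L, het = 1L, hom_alt = 2L,
           hemi_ref = 0L, hemi_alt = 1L, NA_integer_)
  }
  obs <- 0; expct <- 0; varsum <- 0
  for (i in seq_len(nrow(co$variants))) {
    f <- co$meta$true_af[i]
    on_x <- co$variants$chrom[i] == "X"
    gt <- co$variants$genotypes[[i]]
    n_alleles <- if (on_x) 3L else 4L  # father contributes 1 X allele
    obs <- obs + sum(vapply(founders, function(s) count_alt(gt[[s]]), integer(1L)))
    expct <- expct + n_alleles * f
    varsum <- varsum + n_alleles * f * (1 - f)
  }
  expect_lt(abs(obs - expct), 3 * sqrt(varsum))
})

test_that("homopolymer context generator emits labeled boundary cases", {
  ctx <- generate_homopolymer_contexts(40, seed = 5)
  expect_equal(nrow(ctx), 40L)
  expect_equal(ctx$kind[1:4], c("run6", "run5", "dinucleotide", "clean"))
  expect_equal(ctx$expected_flag[1:4], c(TRUE, FALSE, TRUE, FALSE))
  # the scanner agrees with every constructed label
  got <- mapply(is_repeat_adjacent, ctx$context, ctx$indel_pos)
  expect_equal(unname(got), ctx$expected_flag)
  # determinism
  expect_identical(ctx, generate_homopolymer_contexts(40, seed = 5))
})

test_that("network fixture has 12 seeds, weak distractors and a STAT4 hub", {
  fix <- generate_network_fixture()
  expect_length(fix$seeds, 12L)
  expect_true(all(c("FHL1", "GATA3", "CASR", "PTH") %in% fix$seeds))
  deg_to_seeds <- function(node) {
    sum((fix$edges$node_a == node & fix$edges$node_b %in% fix$seeds) |
          (fix$edges$node_b == node & fix$edges$node_a %in% fix$seeds))
  }
  distractors <- grep("^DIST", unique(c(fix$edges$node_a, fix$edges$node_b)),
                      value = TRUE)
  expect_true(all(vapply(distractors, deg_to_seeds, integer(1L)) <= 1L))
  expect_gte(deg_to_seeds("STAT4"), 2L)
})

test_that("assay generator inverts exactly at zero noise", {
  # qPCR: planted fold 0.55 recovered in closed form
  q <- generate_assay_table(assay_spec("qpcr", noise_sd = 0, seed = 1))
  r <- delta_delta_ct(q, "actb", "control")
  expect_equal(r$fold_change[r$group == "treated"], 0.55)
  expect_equal(r$percent_knockdown[r$group == "treated"], 45)
  # luciferase: identical effects give ratio 1 across groups
  l <- generate_assay_table(assay_spec("luciferase",
                                       groups = c(control = 1, treated = 1),
                                       noise_sd = 0, seed = 1))
  nl <- normalize_luciferase(l, "control")
  expect_equal(nl$groups$fold_activation, c(1, 1))
  expect_equal(unique(nl$wells$ratio), 0.5)
  # calcium: noiseless standards recover the generating line exactly
  ca <- generate_assay_table(assay_spec("calcium", noise_sd = 0, seed = 1))
  std <- ca[ca$group == "standard"]
  cal <- calcium_from_standard_curve(
    data.frame(concentration = as.numeric(std$target), reading = std$value),
    data.frame(label = "x", reading = 0.05 + 0.02 * 10))
  expect_equal(cal$slope, 0.02)
  expect_equal(cal$intercept, 0.05)
  expect_equal(cal$r_squared, 1)
})

test_that("genotyping errors perturb genotypes at roughly the requested rate", {
  clean <- generate_cohort(cohort_spec(n_background_variants = 400,
                                       planted_model = "none", seed = 21))
  noisy <- generate_cohort(cohort_spec(n_background_variants = 400,
                                       planted_model = "none", seed = 21,
                                       genotyping_error_rate = 0.05))
  # same seed, error applied after transmission: frequency draws shared
  expect_identical(clean$meta$true_af, noisy$meta$true_af)
  diffs <- sum(mapply(function(a, b) sum(a != b),
                      clean$variants$genotypes, noisy$variants$genotypes))
  n_calls <- 400 * 9
  expect_gt(diffs, 0)
  expect_lt(abs(diffs / n_calls - 0.05), 3 * sqrt(0.05 * 0.95 / n_calls))
})
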