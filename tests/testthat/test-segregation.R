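# Inheritance-model predicates and candidate selection.

fam_variant <- function(gt, chrom = "1", pos = 1000L, ad = NULL) {
  if (is.null(ad)) ad <- setNames(rep(30L, length(gt)), names(gt))
  variant_table(chrom, pos, "C", "T", genotypes = list(gt),
                alt_depth = list(ad))
}

fig1_gts <- function(...) {
  base <- c(fa = "hom_ref", mo = "hom_ref", p1 = "hom_ref", s2 = "hom_ref",
            s3 = "hom_ref", s4 = "hom_ref", s5 = "hom_ref", s6 = "hom_ref",
            d7 = "hom_ref")
  over <- c(...)
  base[names(over)] <- over
  base
}

test_that("de novo: carrier proband with clear family, low-coverage boundary", {
  ped <- fig1_pedigree()
  gt <- fig1_gts(p1 = "het")
  ad <- setNames(rep(30L, 9L), names(gt))
  ad[["p1"]] <- 3L
  r <- check_de_novo(fam_variant(gt, ad = ad), ped)
  expect_true(r$consistent)
  expect_true(r$low_confidence)  # 3 < 5
  ad[["p1"]] <- 5L
  r5 <- check_de_novo(fam_variant(gt, ad = ad), ped)
  expect_true(r5$consistent)
  expect_false(r5$low_confidence)  # strict less-than
  # carrier father breaks it
  rf <- check_de_novo(fam_variant(fig1_gts(p1 = "het", fa = "het")), ped)
  expect_false(rf$consistent)
  expect_equal(unname(rf$per_sample_assessment[["fa"]]), "violates")
  # carrier sibling breaks it
  expect_false(check_de_novo(fam_variant(fig1_gts(p1 = "het", s3 = "het")), ped)$consistent)
  # non-carrier proband is not de novo
  expect_false(check_de_novo(fam_variant(fig1_gts()), ped)$consistent)
  # proband absent from genotype map errors
  expect_error(check_de_novo(fam_variant(c(fa = "hom_ref")), ped), "proband")
})

test_that("autosomal recessive: canonical pattern and violations", {
  ped <- fig1_pedigree()
  ok <- fig1_gts(p1 = "hom_alt", d7 = "hom_alt", fa = "het", mo = "het",
                 s2 = "het", s3 = "het")
  expect_true(check_autosomal_recessive_hom(fam_variant(ok), ped)$consistent)
  # homozygous unaffected sib vetoes
  bad1 <- ok; bad1[["s4"]] <- "hom_alt"
  expect_false(check_autosomal_recessive_hom(fam_variant(bad1), ped)$consistent)
  # heterozygous affected vetoes
  bad2 <- ok; bad2[["p1"]] <- "het"
  expect_false(check_autosomal_recessive_hom(fam_variant(bad2), ped)$consistent)
  # non-het obligate parent vetoes
  bad3 <- ok; bad3[["fa"]] <- "hom_ref"
  expect_false(check_autosomal_recessive_hom(fam_variant(bad3), ped)$consistent)
})

test_that("X-linked recessive: canonical pattern, vetoes, chromosome guard", {
  ped <- fig1_pedigree()
  xgt <- function(...) {
    g <- fig1_gts(...)
    males <- c("fa", "p1", "s2", "s3", "s4", "s5", "s6")
    g[males] <- sub("^hom_", "hemi_", g[males])
    g
  }
  ok <- xgt(p1 = "hemi_alt", mo = "het")
  r <- check_x_linked_recessive(fam_variant(ok, chrom = "X"), ped)
  expect_true(r$consistent)
  # unaffected brother carrying the allele vetoes
  bad <- ok; bad[["s2"]] <- "hemi_alt"
  expect_false(check_x_linked_recessive(fam_variant(bad, chrom = "X"), ped)$consistent)
  # non-carrier mother of an affected male vetoes
  bad2 <- ok; bad2[["mo"]] <- "hom_ref"
  expect_false(check_x_linked_recessive(fam_variant(bad2, chrom = "X"), ped)$consistent)
  # affected female: lenient by default, vetoes when strict
  expect_true(check_x_linked_recessive(fam_variant(ok, chrom = "X"), ped,
                                       lenient_affected_female = TRUE)$consistent)
  expect_false(check_x_linked_recessive(fam_variant(ok, chrom = "X"), ped,
                                        lenient_affected_female = FALSE)$consistent)
  carrier_sister <- ok; carrier_sister[["d7"]] <- "het"
  expect_true(check_x_linked_recessive(fam_variant(carrier_sister, chrom = "X"),
                                       ped, lenient_affected_female = FALSE)$consistent)
  # autosomal input is a usage error
  expect_error(check_x_linked_recessive(fam_variant(ok, chrom = "7"), ped),
               "non-X")
  # PAR regions are not hemizygous
  par <- data.frame(start = 1L, end = 2781479L)
  expect_error(check_x_linked_recessive(
    fam_variant(fig1_gts(p1 = "het"), chrom = "X", pos = 1000L), ped,
    par_regions = par), "non-X")
})

test_that("missing genotypes block consistency under strict mode only", {
  ped <- fig1_pedigree()
  gt <- fig1_gts(p1 = "het", s5 = "missing")
  r_strict <- check_de_novo(fam_variant(gt), ped, strict_missing = TRUE)
  expect_false(r_strict$consistent)
  expect_equal(unname(r_strict$per_sample_assessment[["s5"]]), "missing_data")
  r_lenient <- check_de_novo(fam_variant(gt), ped, strict_missing = FALSE)
  expect_true(r_lenient$consistent)
})

test_that("model predicates match the brute-force oracle on seeded cohorts", {
  ped <- fig1_pedigree()
  for (seed in 1:10) {
    model <- c("x_linked_recessive", "de_novo", "autosomal_recessive_hom",
               "none")[(seed %% 4L) + 1L]
    co <- generate_cohort(cohort_spec(n_background_variants = 80,
                                      planted_model = model, seed = seed,
                                      genotyping_error_rate = 0.03))
    sel <- select_candidates(co$variants, ped)
    got <- setNames(lapply(seq_len(nrow(sel$candidates)), function(i) {
      sort(sel$candidates$models[[i]])
    }), sel$candidates$variant_key)
    want <- setNames(list(), character(0))
    for (i in seq_len(nrow(co$variants))) {
      gt <- co$variants$genotypes[[i]]
      on_x <- co$variants$chrom[i] == "X"
      hits <- character()
      if (oracle_de_novo(gt, ped, "p1")) hits <- c(hits, "de_novo")
      if (!on_x && oracle_ar_hom(gt, ped)) hits <- c(hits, "autosomal_recessive_hom")
      if (on_x && oracle_xlr(gt, ped)) hits <- c(hits, "x_linked_recessive")
      if (length(hits)) want[[co$variants$variant_key[i]]] <- sort(hits)
    }
    expect_equal(got[sort(names(got))], want[sort(names(want))],
                 info = paste("seed", seed))
  }
})

test_that("planted variant is selected under its own model and not as de novo", {
  co <- generate_cohort(cohort_spec(n_background_variants = 50, seed = 77))
  sel <- select_candidates(co$variants, co$pedigree)
  i <- match(co$truth$variant_key, sel$candidates$variant_key)
  expect_false(is.na(i))
  expect_true("x_linked_recessive" %in% sel$candidates$models[[i]])
  # carrier mother makes de novo impossible for the same variant
  expect_false("de_novo" %in% sel$candidates$models[[i]])
  expect_equal(sel$funnel_row$n_in, nrow(co$variants))
})
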