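## Synthetic family cohorts with a planted causal variant and known ground
## truth. Background variants carry population frequencies drawn from a
## common/rare mixture; genotypes follow Mendelian transmission from founder
## genotypes drawn at the variant's allele frequency (Hardy-Weinberg), with
## an optional genotyping-error rate. The planted variant exactly satisfies
## its inheritance model's genotype pattern.

#' Nine-member nuclear family pedigree
#'
#' Two unaffected parents, six sons of whom the first (`p1`) is the affected
#' proband, and one affected daughter (`d7`, mildly affected).
#'
#' @return pedigree table.
#' @export
fig1_pedigree <- function() {
  pedigree(
    sample_id = c("fa", "mo", "p1", "s2", "s3", "s4", "s5", "s6", "d7"),
    father_id = c(NA, NA, rep("fa", 7L)),
    mother_id = c(NA, NA, rep("mo", 7L)),
    sex = c("male", "female", rep("male", 6L), "female"),
    affected = c("unaffected", "unaffected", "affected",
                 rep("unaffected", 5L), "affected")
  )
}

#' Parents + one affected male child
#' @return pedigree table.
#' @export
trio_pedigree <- function() {
  pedigree(sample_id = c("fa", "mo", "p1"),
           father_id = c(NA, NA, "fa"), mother_id = c(NA, NA, "mo"),
           sex = c("male", "female", "male"),
           affected = c("unaffected", "unaffected", "affected"))
}

#' Cohort simulation specification
#'
#' @param pedigree_template `"fig1_family"` (default), `"trio"`, or
#'   `"custom"` with `custom_pedigree` supplied.
#' @param n_background_variants number of background variants.
#' @param planted_model inheritance model of the planted causal variant:
#'   `"x_linked_recessive"` (default), `"de_novo"`,
#'   `"autosomal_recessive_hom"` or `"none"`.
#' @param rare_fraction fraction of background variants drawn from the rare
#'   (allele frequency < 1%) component of the frequency mixture
#'   (default 0.2; the remaining 80% are common, Beta-shaped).
#' @param tool_count size of the deleteriousness-prediction ensemble
#'   (default 10).
#' @param seed integer RNG seed; identical spec + seed gives byte-identical
#'   cohorts.
#' @param genotyping_error_rate per-sample probability of replacing a true
#'   genotype with a random different call (default 0, max 0.05).
#' @param databases population database names for `af_` columns.
#' @param custom_pedigree pedigree table when `pedigree_template = "custom"`.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(pedigree_template = c("fig1_family", "trio", "custom"),
                        n_background_variants = 1000L,
                        planted_model = c("x_linked_recessive", "de_novo",
                                          "autosomal_recessive_hom", "none"),
                        rare_fraction = 0.2, tool_count = 10L, seed = 1L,
                        genotyping_error_rate = 0,
                        databases = c("exac", "esp", "kg", "local"),
                        custom_pedigree = NULL) {
  pedigree_template <- match.arg(pedigree_template)
  planted_model <- match.arg(planted_model)
  stopifnot(n_background_variants >= 0L, rare_fraction >= 0, rare_fraction <= 1,
            tool_count >= 1L, genotyping_error_rate >= 0,
            genotyping_error_rate <= 0.05)
  structure(list(pedigree_template = pedigree_template,
                 n_background_variants = as.integer(n_background_variants),
                 planted_model = planted_model, rare_fraction = rare_fraction,
                 tool_count = as.integer(tool_count), seed = as.integer(seed),
                 genotyping_error_rate = genotyping_error_rate,
                 databases = databases, custom_pedigree = custom_pedigree),
            class = "cohort_spec")
}

template_pedigree <- function(spec) {
  switch(spec$pedigree_template,
         fig1_family = fig1_pedigree(),
         trio = trio_pedigree(),
         custom = {
           if (is.null(spec$custom_pedigree)) vk_stop("custom template needs custom_pedigree")
           validate_pedigree(spec$custom_pedigree)
           spec$custom_pedigree
         })
}

## Mendelian genotype draw for one variant across a nuclear family.
sample_family_genotypes <- function(ped, af, on_x) {
  ids <- ped$sample_id
  sex <- setNames(ped$sex, ids)
  founders <- ids[is.na(ped$father_id) & is.na(ped$mother_id)]
  alleles <- list()  # per sample: vector of 0/1 allele copies
  for (s in founders) {
    n_copies <- if (on_x && sex[[s]] == "male") 1L else 2L
    alleles[[s]] <- rbinom(n_copies, 1L, af)
  }
  remaining <- setdiff(ids, founders)
  while (length(remaining)) {
    progressed <- FALSE
    for (s in remaining) {
      row <- ped[ped$sample_id == s, ]
      fa <- row$father_id; mo <- row$mother_id
      if ((!is.na(fa) && is.null(alleles[[fa]])) ||
          (!is.na(mo) && is.null(alleles[[mo]]))) next
      pick <- function(p, n_default) {
        if (is.na(p) || is.null(alleles[[p]])) rbinom(1L, 1L, af)
        else sample(alleles[[p]], 1L)
      }
      mat <- pick(mo)
      if (on_x) {
        alleles[[s]] <- if (sex[[s]] == "male") mat else c(pick(fa), mat)
      } else {
        alleles[[s]] <- c(pick(fa), mat)
      }
      remaining <- setdiff(remaining, s)
      progressed <- TRUE
    }
    if (!progressed) vk_stop("unresolvable pedigree ordering")
  }
  vapply(ids, function(s) {
    a <- alleles[[s]]
    hemi <- on_x && sex[[s]] == "male"
    gt_from_allele_count(sum(a), length(a), hemi)
  }, character(1L))
}

## Replacement call for a genotyping error. `u` is a uniform already drawn
## for the error decision, rescaled to pick the replacement, so applying
## errors consumes no extra RNG draws and the background cohort stays
## identical across error rates at a fixed seed.
random_genotype_error <- function(gt, sex, on_x, u) {
  domain <- if (on_x && sex == "male") c("hemi_ref", "hemi_alt", "missing")
            else c("hom_ref", "het", "hom_alt", "missing")
  opts <- setdiff(domain, gt)
  opts[floor(u * length(opts)) + 1L]
}

## A 21-mer with no mononucleotide run >= 3 and no 2-6 bp tandem repeat with
## >= 3 copies, vetted by regular expressions (independent of the scanning
## code under test).
clean_context <- function(width = 21L) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
    if (!grepl("([ACGT])\\1\\1", s) && !grepl("([ACGT]{2,6})\\1\\1", s)) return(s)
  }
}

## Splice a feature starting right of the anchor (anchor = centre position).
splice_feature <- function(context, feature) {
  anchor <- (nchar(context) + 1L) %/% 2L
  left <- substr(context, 1L, anchor)
  right_start <- anchor + nchar(feature) + 1L
  right <- if (right_start <= nchar(context)) substr(context, right_start, nchar(context)) else ""
  out <- paste0(left, feature, right)
  substr(out, 1L, nchar(context))
}

planted_tool_calls <- function(n_tools) {
  if (n_tools >= 3L) {
    n_del <- max(ceiling(n_tools / 2) + 1L, n_tools - 2L)
    n_del <- min(n_del, n_tools - 2L)
    if (n_del <= n_tools / 2) n_del <- floor(n_tools / 2) + 1L
    calls <- c(rep("deleterious", min(n_del, n_tools)),
               rep("ambiguous", 1L), rep("tolerated", 1L))
    calls <- calls[seq_len(n_tools)]
    # guarantee strict majority
    score <- sum(calls == "deleterious") + 0.5 * sum(calls == "ambiguous")
    if (score <= n_tools / 2) calls[calls != "deleterious"][1L] <- "deleterious"
    calls
  } else rep("deleterious", n_tools)
}

#' Generate a synthetic annotated family cohort
#'
#' @param spec a [cohort_spec()].
#' @return list with `pedigree`, `variants` (variant table), `annotations`
#'   (annotation table), `truth` (list with `variant_key`, `model`, `gene`;
#'   empty when `planted_model = "none"`) and `meta` (seed and per-variant
#'   true allele frequencies, for calibration tests).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ped <- template_pedigree(spec)
  if (spec$planted_model == "x_linked_recessive" &&
      !length(affected_ids(ped, "male"))) {
    vk_stop("x_linked_recessive planted model requires an affected male")
  }
  set.seed(spec$seed)
  n <- spec$n_background_variants
  sex <- setNames(ped$sex, ped$sample_id)

  chroms <- character(n); poss <- integer(n)
  refs <- character(n); alts <- character(n)
  genos <- vector("list", n); depths <- vector("list", n)
  flags <- vector("list", n)
  effects <- character(n); genes <- character(n)
  conserved <- logical(n); is_indel <- logical(n)
  contexts <- character(n); true_af <- numeric(n)
  afmat <- matrix(NA_real_, nrow = n, ncol = length(spec$databases))
  toolmat <- matrix("tolerated", nrow = n, ncol = spec$tool_count)
  bases <- c("A", "C", "G", "T")

  for (i in seq_len(n)) {
    chroms[i] <- sample(c(as.character(1:22), "X"), 1L,
                        prob = c(rep(0.9 / 22, 22), 0.1))
    poss[i] <- sample.int(5e7L, 1L) + 1e4L
    on_x <- chroms[i] == "X"
    is_indel[i] <- runif(1) < 0.10
    if (is_indel[i]) {
      b <- sample(bases, 1L); b2 <- sample(bases, 1L)
      if (runif(1) < 0.5) { refs[i] <- b; alts[i] <- paste0(b, b2) }
      else { refs[i] <- paste0(b, b2); alts[i] <- b }
      ctx <- clean_context()
      u <- runif(1)
      if (u < 0.35) {        # repeat-adjacent: homopolymer run 6-8
        run_base <- sample(bases, 1L)
        ctx <- splice_feature(ctx, strrep(run_base, sample(6:8, 1L)))
      } else if (u < 0.45) { # boundary negative: run of exactly 5
        ctx <- splice_feature(ctx, strrep(sample(bases, 1L), 5L))
        # splice may merge with identical flanking bases; re-vet
        if (nrow(find_homopolymer_runs(ctx, 6L)) > 0L) ctx <- clean_context()
      } else if (u < 0.55) { # dinucleotide tandem repeat x4
        un <- paste(sample(bases, 2L, replace = FALSE), collapse = "")
        ctx <- splice_feature(ctx, strrep(un, 4L))
      }
      contexts[i] <- ctx
    } else {
      refs[i] <- sample(bases, 1L)
      alts[i] <- sample(setdiff(bases, refs[i]), 1L)
      contexts[i] <- NA_character_
    }
    rare <- runif(1) < spec$rare_fraction
    f <- if (rare) 10^runif(1, -4.3, log10(0.009)) else pmax(rbeta(1, 2, 5), 0.0101)
    true_af[i] <- f
    for (d in seq_along(spec$databases)) {
      present <- !rare || runif(1) < 0.7
      if (present) afmat[i, d] <- min(1, max(0, f * exp(rnorm(1, 0, 0.1))))
    }
    gt <- sample_family_genotypes(ped, f, on_x)
    # error draws are consumed even at rate 0 so the RNG stream (and hence
    # the background cohort) is identical across error rates at a fixed seed
    err_u <- runif(length(gt))
    for (s in which(err_u < spec$genotyping_error_rate)) {
      gt[s] <- random_genotype_error(gt[s], sex[[names(gt)[s]]], on_x,
                                     err_u[s] / spec$genotyping_error_rate)
    }
    genos[[i]] <- gt
    depth_draws <- rpois(length(gt), 40L)  # always drawn: keeps RNG aligned
    depths[[i]] <- setNames(ifelse(gt_is_carrier(gt), depth_draws, 0L), names(gt))
    flags[[i]] <- if (runif(1) < 0.05) sample(qc_flag_levels, 1L) else character()
    effects[i] <- sample(effect_levels, 1L, prob = c(0.25, 0.25, 0.05, 0.45))
    genes[i] <- sprintf("GENE%04d", i)
    conserved[i] <- runif(1) < 0.10
    toolmat[i, ] <- sample(tool_call_levels, spec$tool_count, replace = TRUE,
                           prob = c(0.05, 0.85, 0.05, 0.05))
  }

  truth <- list()
  if (spec$planted_model != "none") {
    ids <- ped$sample_id
    p <- list(gene = "FHL1", effect = "exonic_nonsynonymous",
              conserved = TRUE, is_indel = FALSE, context = NA_character_)
    if (spec$planted_model == "x_linked_recessive") {
      p$chrom <- "X"; p$pos <- 135292485L; p$ref <- "C"; p$alt <- "T"
      proband <- affected_ids(ped, "male")[1L]
      mother <- ped$mother_id[ped$sample_id == proband]
      gt <- vapply(ids, function(s) {
        if (s == proband) "hemi_alt"
        else if (!is.na(mother) && s == mother) "het"
        else if (sex[[s]] == "male") "hemi_ref" else "hom_ref"
      }, character(1L))
    } else if (spec$planted_model == "de_novo") {
      p$chrom <- sample(as.character(1:22), 1L)
      p$pos <- sample.int(5e7L, 1L); p$ref <- "G"; p$alt <- "A"
      proband <- proband_id(ped)
      gt <- vapply(ids, function(s) if (s == proband) "het" else "hom_ref",
                   character(1L))
    } else { # autosomal_recessive_hom
      p$chrom <- sample(as.character(1:22), 1L)
      p$pos <- sample.int(5e7L, 1L); p$ref <- "G"; p$alt <- "A"
      aff <- affected_ids(ped)
      parents <- unique(stats::na.omit(unlist(
        ped[ped$sample_id %in% aff, c("father_id", "mother_id")])))
      gt <- vapply(ids, function(s) {
        if (s %in% aff) "hom_alt"
        else if (s %in% parents) "het"
        else sample(c("het", "hom_ref"), 1L)
      }, character(1L))
    }
    n <- n + 1L
    chroms[n] <- p$chrom; poss[n] <- p$pos; refs[n] <- p$ref; alts[n] <- p$alt
    genos[[n]] <- setNames(gt, ids)
    depths[[n]] <- setNames(ifelse(gt_is_carrier(gt), 30L, 0L), ids)
    flags[[n]] <- character()
    effects[n] <- p$effect; genes[n] <- p$gene; conserved[n] <- p$conserved
    is_indel[n] <- p$is_indel; contexts[n] <- p$context
    true_af[n] <- 5e-4
    afmat <- rbind(afmat, rep(NA_real_, ncol(afmat)))
    afmat[n, seq_len(min(2L, ncol(afmat)))] <- c(5e-4, 6e-4)[seq_len(min(2L, ncol(afmat)))]
    toolmat <- rbind(toolmat, planted_tool_calls(spec$tool_count))
    truth <- list(variant_key = variant_key(p$chrom, p$pos, p$ref, p$alt),
                  model = spec$planted_model, gene = p$gene)
  }

  vt <- variant_table(chroms, poss, refs, alts, genos, depths, flags,
                      pedigree = ped)
  ann <- data.table(chrom = chroms, pos = poss, ref = refs, alt = alts,
                    gene = genes, effect = effects,
                    hgvs_c = NA_character_, hgvs_p = NA_character_,
                    conserved_region = conserved, is_indel = is_indel,
                    context = contexts)
  for (d in seq_along(spec$databases)) {
    ann[[paste0("af_", spec$databases[d])]] <- afmat[, d]
  }
  for (t in seq_len(spec$tool_count)) ann[[paste0("tool_", t)]] <- toolmat[, t]
  ann <- annotation_table(ann, n_tools = spec$tool_count)

  list(pedigree = ped, variants = vt, annotations = ann, truth = truth,
       meta = list(seed = spec$seed, true_af = true_af,
                   planted_model = spec$planted_model))
}
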