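## Labeled homopolymer-context fixtures, the hard-coded PPI network
## fixture, and synthetic assay tables with known true effects.

#' Generate labeled indel contexts for the homopolymer filter
#'
#' Emits reference contexts of width 21 with the indel anchor at the centre
#' and a ground-truth `expected_flag` assigned by construction (features are
#' spliced in deliberately; backgrounds are vetted repeat-free with regular
#' expressions, independently of the scanning code under test). The first
#' four rows are fixed boundary cases: an abutting run of 6 (flagged), an
#' abutting run of exactly 5 (not flagged), an abutting dinucleotide repeat
#' of 4 copies (flagged) and a clean context (not flagged); remaining rows
#' are randomly drawn from those four kinds.
#'
#' @param n number of contexts (>= 1).
#' @param seed RNG seed.
#' @return `data.table` with `context`, `indel_pos` (anchor), `indel`
#'   (description), `kind`, `expected_flag`.
#' @export
generate_homopolymer_contexts <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  kinds <- c("run6", "run5", "dinucleotide", "clean")
  kind <- c(kinds, if (n > 4L) sample(kinds, n - 4L, replace = TRUE))[seq_len(n)]
  rows <- lapply(kind, function(k) {
    ctx <- clean_context()
    if (k == "run6") {
      ctx <- splice_feature(ctx, strrep(sample(bases, 1L), sample(6:8, 1L)))
      flag <- TRUE
    } else if (k == "run5") {
      repeat {
        ctx2 <- splice_feature(clean_context(), strrep(sample(bases, 1L), 5L))
        # reject if splice joined identical neighbours into a longer run
        if (!grepl("([ACGT])\\1\\1\\1\\1\\1", ctx2)) { ctx <- ctx2; break }
      }
      flag <- FALSE
    } else if (k == "dinucleotide") {
      un <- paste(sample(bases, 2L, replace = FALSE), collapse = "")
      ctx <- splice_feature(ctx, strrep(un, 4L))
      flag <- TRUE
    } else flag <- FALSE
    data.table(context = ctx, indel_pos = (nchar(ctx) + 1L) %/% 2L,
               indel = sample(c("+A", "-A", "+T", "-C"), 1L),
               kind = k, expected_flag = flag)
  })
  rbindlist(rows)
}

#' Hard-coded PPI network fixture around hypocalcemia seed genes
#'
#' Twelve seed proteins (eleven hypocalcemia-related genes plus FHL1) with
#' the bridges FHL1-STAT4-GATA3 and FHL1-AKAP12-FLNA-CASR, a direct
#' GNA11-CASR seed edge, and distractor nodes each attached to at most one
#' seed.
#'
#' @return list with `edges` (edge list table) and `seeds`.
#' @export
generate_network_fixture <- function() {
  seeds <- c("FHL1", "PTH", "CALC1", "PTHRP", "TBX1", "GCM2", "CASR", "AIRE",
             "GNA11", "GATA3", "GNAS", "TRPM6")
  a <- c("FHL1", "STAT4", "FHL1", "AKAP12", "FLNA", "GNA11",
         "FHL1", "GATA3", "DIST1", "PTH", "TRPM6")
  b <- c("STAT4", "GATA3", "AKAP12", "FLNA", "CASR", "CASR",
         "DIST1", "DIST2", "DIST3", "DIST4", "DIST5")
  list(edges = edge_list(a, b, evidence = "ppi"), seeds = seeds)
}

#' Assay simulation specification
#'
#' `groups` is a named numeric vector of true effects; the first group is
#' the control. Effect meaning per assay: qpcr - expression fold change of
#' the target gene relative to the control group (default 0.55, a 45%
#' knockdown); luciferase - fold activation of the firefly/Renilla ratio
#' relative to control (default 3); calcium - true pool-total calcium
#' concentration in ug/ml of each sample group. `noise_sd` is the Ct
#' standard deviation (qpcr, additive), the lognormal sigma of luminescence
#' (luciferase) or the absorbance standard deviation (calcium); replicate
#' count defaults to 3 as in triplicate bench assays.
#'
#' @param assay one of `"qpcr"`, `"luciferase"`, `"calcium"`.
#' @param groups named numeric vector of (label, true_effect).
#' @param n_replicates replicates per group (>= 2, default 3).
#' @param noise_sd measurement noise (default 0.2 / 0.1 / 0.01 by assay).
#' @param seed RNG seed.
#' @return list of class `assay_spec`.
#' @export
assay_spec <- function(assay = c("qpcr", "luciferase", "calcium"),
                       groups = NULL, n_replicates = 3L, noise_sd = NULL,
                       seed = 1L) {
  assay <- match.arg(assay)
  if (is.null(groups)) {
    groups <- switch(assay,
                     qpcr = c(control = 1, treated = 0.55),
                     luciferase = c(control = 1, treated = 3),
                     calcium = c(low = 10, high = 25))
  }
  if (is.null(noise_sd)) {
    noise_sd <- switch(assay, qpcr = 0.2, luciferase = 0.1, calcium = 0.01)
  }
  stopifnot(n_replicates >= 2L, noise_sd >= 0, length(groups) >= 1L,
            !is.null(names(groups)))
  structure(list(assay = assay, groups = groups,
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "assay_spec")
}

#' Generate a long-format assay table with known ground truth
#'
#' qpcr mode emits target and reference (`actb`) Ct values whose expected
#' fold change versus the control group equals the group's true effect
#' (reference base Ct 15, target base Ct 22); luciferase mode emits paired
#' firefly/Renilla luminescence with the firefly signal scaled by the true
#' effect; calcium mode emits a CaCl2 standard series (0/5/10/25 ug/ml on
#' the line reading = 0.05 + 0.02 * concentration) plus sample readings on
#' the same line at each group's true concentration.
#'
#' @param spec an [assay_spec()].
#' @return assay `data.table` (`assay`, `group`, `replicate`, `target`,
#'   `value`).
#' @export
generate_assay_table <- function(spec) {
  stopifnot(inherits(spec, "assay_spec"))
  set.seed(spec$seed)
  reps <- seq_len(spec$n_replicates)
  rows <- list()
  add <- function(group, target, values) {
    rows[[length(rows) + 1L]] <<- data.table(
      assay = spec$assay, group = group, replicate = reps,
      target = target, value = values)
  }
  if (spec$assay == "qpcr") {
    control <- names(spec$groups)[1L]
    for (g in names(spec$groups)) {
      fold <- spec$groups[[g]] / spec$groups[[control]]
      add(g, "actb", 15 + rnorm(spec$n_replicates, 0, spec$noise_sd))
      add(g, "target", 22 - log2(fold) + rnorm(spec$n_replicates, 0, spec$noise_sd))
    }
  } else if (spec$assay == "luciferase") {
    control <- names(spec$groups)[1L]
    for (g in names(spec$groups)) {
      eff <- spec$groups[[g]] / spec$groups[[control]]
      add(g, "firefly", 500 * eff * exp(rnorm(spec$n_replicates, 0, spec$noise_sd)))
      add(g, "renilla", 1000 * exp(rnorm(spec$n_replicates, 0, spec$noise_sd)))
    }
  } else { # calcium
    for (conc in c(0, 5, 10, 25)) {
      add("standard", format(conc),
          0.05 + 0.02 * conc + rnorm(spec$n_replicates, 0, spec$noise_sd))
    }
    for (g in names(spec$groups)) {
      add(g, "sample",
          0.05 + 0.02 * spec$groups[[g]] + rnorm(spec$n_replicates, 0, spec$noise_sd))
    }
  }
  rbindlist(rows)
}
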