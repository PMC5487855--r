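---
title: "Family-exome variant prioritization: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-exome variant prioritization: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varkin)
```

# The problem

In a nuclear family with a single severely affected child, exome sequencing
produces on the order of a million called variants, of which exactly one is
(in the monogenic scenario) causal. varkin implements the standard
prioritization cascade for this setting — technical filtering, population
filtering, Mendelian segregation, and deleteriousness/gene-evidence
ranking — as composable, individually tested operators, together with the
downstream analyses used to build a biological case for a novel candidate
gene: induced interaction modules, over-representation analysis and bench
assay quantification. The motivating use case is an X-linked recessive
phenotype in a nine-member family (two unaffected parents, an affected boy,
five unaffected brothers, and a mildly affected younger sister), but every
operator works for arbitrary nuclear pedigrees.

# Filter cascade

The four pre-segregation filters are independent predicates over a variant
and its annotation, so the surviving *set* equals the intersection of the
per-stage passing sets; only the per-stage funnel counts depend on the
(fixed) order qc → homopolymer indel → frequency → effect. This is asserted
as a property test.

**QC flags.** Upstream callers mark variants with low base/mapping quality,
strand bias, aberrant read position distribution, or a reference/alternate
quality score discrepancy. varkin carries these five flags from the VCF
FILTER column and excludes on any of them by default
(`filter_config(excluded_qc_flags=)`). The statistics themselves are not
recomputed — the pipeline consumes called variants; re-calling is a
non-goal.

**Homopolymer/repeat-adjacent indels.** Indels abutting long homopolymers
are enriched for alignment artefacts. The rule: an indel is excluded iff a
mononucleotide run of length ≥ `homopolymer_min_run` (default 6, i.e.
"longer than five bases") or a short tandem repeat lies within
`adjacency_tol` bases of its left-normalized anchor. Two terms here are not
standardized in the field and are therefore explicit configuration with
documented defaults rather than hidden constants:

* *adjacency*: the feature must include the anchor (gap 0) or come within
  `adjacency_tol` = 1 base of it (directly abutting);
* *repeat*: a tandem array with unit length 2–6 bp and ≥ 3 exact copies,
  found by exhaustive scan over the ±`flank_window` = 10 bp context.

SNVs always pass — the artefact mechanism is indel-specific. The boundary
(run of exactly 5 passes, 6 fails) is pinned by an acceptance test.

**Population frequency.** A variant is excluded iff *any present* database
frequency is strictly greater than the mode's ceiling: 1% for monogenic
work, 10% for polygenic/pharmacogenomic work. Two deliberate choices:

* strict inequality — "higher than 1%" means AF exactly 0.01 passes;
* absence from a database is stored as missing, **not** as 0, and missing
  values never exclude: for rare-disease work, not being in a population
  panel is itself evidence of rarity. A variant absent from every database
  passes.

**Effect class.** Default retains amino-acid-changing variants
(`exonic_nonsynonymous`); splice variants can be added via
`keep_effects`. Synonymous and non-exonic classes are excluded.

# Segregation models

Genotypes use a six-state vocabulary (`hom_ref`, `het`, `hom_alt`,
`hemi_ref`, `hemi_alt`, `missing`); male genotypes on non-pseudoautosomal X
are hemizygous by construction at VCF ingestion (the PAR list is
configurable and empty by default).

* **De novo**: the proband carries ≥ 1 alternate allele; both parents and
  all siblings are called non-carriers. The result is flagged
  *low-confidence* when the proband's alternate-read depth is strictly
  below `min_alt_depth` = 5 — such calls are kept but downweighted in
  interpretation, mirroring how a single low-coverage de novo survivor is
  reported rather than promoted.
* **Autosomal recessive (homozygous)**: every affected sample `hom_alt`,
  every obligate-carrier parent `het`, no unaffected sample `hom_alt`.
  Compound heterozygotes are a stated non-goal.
* **X-linked recessive**: every affected male `hemi_alt`; the mother of an
  affected male `het` or `hom_alt`; no unaffected male `hemi_alt`; no
  unaffected female `hom_alt`. Affected females do **not** veto by default
  (`lenient_affected_female = TRUE`): a mildly affected sister may reflect
  skewed X-inactivation or an unrelated cause and typically has no genotype
  requirement that can be imposed a priori; with the strict flag she must
  be a carrier.

**Missing data.** By default (`strict_missing = TRUE`) a missing genotype
in any sample the model constrains blocks consistency — missingness is
never evidence. It is recorded as `missing_data`, distinct from `violates`,
so the stated invariant "consistent ⇔ no violations" holds exactly in
lenient mode and is strengthened (consistent ⇔ no violations and no
relevant missingness) in strict mode.

The homozygous-recessive and X-linked predicates are implemented separately
and unioned by `select_candidates()`; their union reproduces the pooled
"homozygous recessive/X-linked" funnel step while keeping the semantics
clean. All three predicates are verified against an independent brute-force
oracle on 100 seeded cohorts.

# Deleteriousness vote and ranking

Ten prediction tools vote per variant. Weights: deleterious 1, ambiguous
0.5, tolerated 0, missing 0. A variant is deleterious iff the score is
strictly greater than n/2. Two inferred conventions are worth stating:

* ambiguous = 0.5 — a reported ensemble score of 8.5/10 is impossible with
  unit weights, so half-votes for equivocal tool output are the minimal
  consistent reading;
* missing = 0 with the denominator kept at n — conservative: an untyped
  variant cannot be called deleterious by renormalization.

Gene evidence is an additive score with unit default weights: +1 for a
phenotype-matched disease association, +1 for expression ≥ medium in a
relevant tissue, +1 for RVIS percentile ≤ 25 (inclusive; low percentile =
intolerant). Each term is 0 when evidence is missing. Weights are
configuration, not constants, for sensitivity analysis.

Ranking is lexicographic over (is_deleterious, vote score, gene evidence,
conservation), descending, with the variant key as a deterministic
tie-break. A lexicographic composite — rather than a weighted sum — is the
minimal faithful reading of "combining variant severity and gene
information" when no formula is given; it is order-stable, permutation
invariant, and satisfies a monotone-insertion property (adding a candidate
never improves another's rank), all asserted as tests.

# Induced network modules

Given an undirected interaction network and a set of seed proteins, a
non-seed node is admitted as an *intermediate* iff it is interior to a
simple seed-to-seed path of at most `max_path_len` edges whose interior
contains no seed (a path through another seed decomposes into shorter
seed-to-seed connections). The default `max_path_len` = 3 admits both
one-intermediate bridges (seed–X–seed) and two-intermediate bridges
(seed–X–Y–seed); the exact induction rule used by public pathway portals is
not documented, so the bound is exposed rather than hard-coded. The module
keeps direct seed–seed edges and the subgraph induced on admitted nodes,
and reports one representative (shortest, then lexicographic) path per
connected seed pair. Induction is order-invariant and monotone in
`max_path_len`, and matches exhaustive path enumeration on small graphs.

Over-representation uses the exact upper-tail hypergeometric probability
P(X ≥ k) with Benjamini–Hochberg correction across all tested sets; the
background defaults to the gene-set universe (the original analysis does
not state its background, so it is configurable). A `min_overlap` filter
(applied after correction) supports reporting rules like "sets hit by at
least four query genes".

# Assay statistics

**qPCR (comparative Ct).** ΔCt = mean Ct(target) − mean Ct(reference gene)
per group; ΔΔCt = ΔCt(group) − ΔCt(control); fold = 2^(−ΔΔCt). Per-group
mean aggregation is used because replicate pairing across wells is rarely
recorded; the estimator is invariant to plate-wide Ct shifts and the
control group's fold is identically 1 (both tested). Knockdowns are also
reported as percentages: fold 0.55 ⇔ 45% knockdown.

**Dual luciferase.** Per-well firefly/Renilla ratio (Renilla = 0 is a hard
error), group mean ± SEM, fold activation versus the control group.

**Calcium.** Ordinary least squares on a CaCl₂ standard series (linear per
the assay's design; no 4-parameter logistic), inverse prediction for
samples, per-embryo value = pool total / pool size (default 20 embryos).
Readings outside the standard range extrapolate with a warning and an
explicit flag. R² is reported for the standards and for an optional
pool-size linearity series.

**Group comparisons.** The original figures mark significance but never
name the test; with n = 3 and unknown variances, Welch's two-sided t-test
is the defensible default and a permutation test is provided as an
alternative (`compare_groups(method=)`). Constant-equal groups return
p = 1 directly (the t statistic is undefined there). Stars: `*` p < 0.05,
`**` p < 0.01; summaries are mean ± SEM with SEM = sd/√n.

# Synthetic data: the stated world

The generator exists so that every stage has a recoverable ground truth; it
emulates the *design* of a family-exome study, not the full complexity of
real data.

* **Pedigree**: the nine-member family above (`fig1_family`), a trio, or a
  custom pedigree.
* **Background variants** (default 1000): 80% common with Beta(2, 5)-shaped
  frequencies floored at just above 1%, 20% rare with log-uniform
  frequencies in [5 × 10⁻⁵, 9 × 10⁻³] — the study reports only funnel
  proportions, not a site-frequency spectrum, so the mixture is tunable
  (`rare_fraction`). Observed per-database frequencies jitter around the
  true frequency; rare variants are absent from each database with
  probability 0.3. Genotypes follow Hardy–Weinberg founders plus faithful
  Mendelian transmission (X-aware), with an optional genotyping-error rate
  (default 0 so funnel tests are exact; capped at 5%). 10% of variants are
  indels with reference contexts, about half of them spliced next to a
  run/repeat; 5% carry a QC flag; effect classes are 25/25/5/45%
  nonsynonymous/synonymous/splicing/other.
* **Planted variant**: rare in all databases (present at 5 × 10⁻⁴ and
  6 × 10⁻⁴ in two panels, absent from the rest), amino-acid-changing,
  conserved, deleterious by 8 tools with 1 ambiguous call (score 8.5/10),
  alternate-read depth 30, and genotyped exactly per its model — for
  X-linked recessive: proband hemizygous-alt, mother heterozygous, all
  other members non-carriers.
* **Assays**: triplicates by default (n = 3 as on the bench). qPCR uses
  reference/target base Cts of 15/22 with additive Gaussian Ct noise
  (default sd 0.2, a typical replicate SD); the default planted effect is a
  0.55-fold (45%) knockdown. Luciferase uses lognormal multiplicative noise
  so signals stay positive (default 3-fold activation — the original effect
  is described only as "strong", so this is a package choice). Calcium
  standards are 0/5/10/25 µg/ml on the line reading = 0.05 + 0.02·conc,
  25 µg/ml being the high-physiological medium concentration.

Determinism: each generator call seeds the RNG once from its spec;
identical spec + seed gives byte-identical artifacts. Error draws are
consumed even at error rate 0, and error replacements reuse the decision
uniform, so cohorts at different error rates share the same background —
this makes error-rate robustness tests well-posed.

What a green test does **not** establish: the generator has no linkage
disequilibrium, no population structure, no read-level error model, no
relatedness beyond the single pedigree, and database frequencies that
jitter independently; recovery rates measured on it bound only the logic of
the cascade, not its performance on real exomes.

# Numerical and degenerate-input choices

* Frequencies compare with strict `>`; RVIS with inclusive `≤ 25`; the vote
  with strict `> n/2`; de novo coverage with strict `< 5`.
* Variant keys are `chrom:pos:ref:alt` with "chr" prefixes stripped;
  coordinates are 1-based inclusive (VCF convention).
* Multiallelic records split into biallelic records; alleles other than the
  active alternate count as reference. Alleles are parsimony-trimmed
  (shared suffix, then prefix, shifting pos); full left-alignment through
  repeat tracts would need the reference genome, which the pipeline does
  not consume. A diploid-coded heterozygous male X call is coerced to
  `hemi_alt` with a warning.
* All writers sort rows and emit plain text, so serialization is bit-stable
  and round-trips are testable with `identical()`.
* The ddCt recovery invariant is asserted on the log2 scale, where the
  estimator is unbiased; the fold itself is lognormally biased upward at
  finite replication (Jensen), which is a property of the method, not a
  bug.
* Hypergeometric p with an empty (post-intersection) gene set is 1;
  BH q-values are computed across all tested sets before any
  `min_overlap` reporting filter.

# Known limitations

Compound-heterozygous and dominant models are not implemented; segregation
assumes a single nuclear family (no multi-generation kindreds beyond
parent/child links); the frequency filter treats databases as independent
(no ancestry matching); the induction rule is a defined approximation to
portal behaviour, not a reimplementation of any specific portal; and CNVs,
annotation generation and read alignment are out of scope — the pipeline
starts from called, annotated variants.
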