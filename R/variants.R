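## In-memory variant container and allele normalization.
##
## A variant table is one row per biallelic variant with list-columns for
## the per-sample genotype map, per-sample alternate-allele depth and the
## set of upstream QC flags. All downstream filtering and segregation code
## operates on this container only.

#' Build a validated variant table
#'
#' @param chrom,pos,ref,alt per-variant coordinate/allele vectors.
#' @param genotypes list of named character vectors (sample id -> genotype
#'   call, one of `hom_ref`, `het`, `hom_alt`, `hemi_ref`, `hemi_alt`,
#'   `missing`).
#' @param alt_depth list of named integer vectors (sample id -> alternate
#'   allele read depth; `NA` when unknown).
#' @param qc_flags list of character vectors drawn from the five upstream
#'   quality flags (empty vector = clean variant).
#' @param pedigree optional pedigree; when supplied, genotype sample ids are
#'   checked against it and hemizygous calls are checked to occur only for
#'   males on non-PAR X.
#' @param par_regions optional pseudoautosomal intervals (see [is_x_nonpar()]).
#' @return `data.table` of class `varkin_variants` with a `variant_key` column.
#' @export
variant_table <- function(chrom, pos, ref, alt, genotypes, alt_depth = NULL,
                          qc_flags = NULL, pedigree = NULL, par_regions = NULL) {
  n <- length(chrom)
  if (is.null(alt_depth)) alt_depth <- rep(list(integer()), n)
  if (is.null(qc_flags)) qc_flags <- rep(list(character()), n)
  vt <- data.table(
    chrom = norm_chrom(chrom),
    pos = as.integer(pos),
    ref = as.character(ref),
    alt = as.character(alt),
    genotypes = genotypes,
    alt_depth = alt_depth,
    qc_flags = qc_flags
  )
  vt[, variant_key := variant_key(chrom, pos, ref, alt)]
  validate_variants(vt, pedigree = pedigree, par_regions = par_regions)
  setattr(vt, "class", c("varkin_variants", class(vt)))
  vt[]
}

#' Validate variant-table invariants
#'
#' @inheritParams variant_table
#' @param vt variant table.
#' @return `vt` invisibly; errors on violation.
#' @export
validate_variants <- function(vt, pedigree = NULL, par_regions = NULL) {
  if (any(vt$pos < 1L)) vk_stop("variant pos must be >= 1")
  if (any(!nzchar(vt$ref)) || any(!nzchar(vt$alt))) {
    vk_stop("ref and alt alleles must be non-empty")
  }
  for (i in seq_len(nrow(vt))) {
    gt <- vt$genotypes[[i]]
    bad <- setdiff(gt, gt_levels)
    if (length(bad)) vk_stop("unknown genotype call(s): %s", paste(bad, collapse = ", "))
    badf <- setdiff(vt$qc_flags[[i]], qc_flag_levels)
    if (length(badf)) vk_stop("unknown qc flag(s): %s", paste(badf, collapse = ", "))
    if (!is.null(pedigree)) {
      unknown <- setdiff(names(gt), pedigree$sample_id)
      if (length(unknown)) {
        vk_stop("genotype sample(s) absent from pedigree: %s",
                paste(unknown, collapse = ", "))
      }
      hemi <- names(gt)[gt %in% c("hemi_ref", "hemi_alt")]
      if (length(hemi)) {
        sexes <- pedigree$sex[match(hemi, pedigree$sample_id)]
        if (any(sexes != "male") ||
            !is_x_nonpar(vt$chrom[i], vt$pos[i], par_regions)) {
          vk_stop("hemizygous call outside male non-PAR X at %s", vt$variant_key[i])
        }
      }
    }
  }
  invisible(vt)
}

#' Trim shared allele sequence (parsimony normalization)
#'
#' Removes the longest shared suffix, then the longest shared prefix, from a
#' ref/alt allele pair, adjusting the 1-based position for removed prefix
#' bases. Full left-alignment through repeat tracts requires the reference
#' genome and is out of scope; trimming makes split multiallelic records
#' minimal and canonical.
#'
#' @param pos 1-based position.
#' @param ref,alt allele strings.
#' @return list with `pos`, `ref`, `alt`.
#' @export
normalize_alleles <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1L]]
  a <- strsplit(alt, "")[[1L]]
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
    r <- r[-1L]
    a <- a[-1L]
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

gt_from_allele_count <- function(n_alt, ploidy, hemi) {
  if (hemi) {
    if (n_alt >= 1L) "hemi_alt" else "hemi_ref"
  } else if (ploidy == 1L) {
    if (n_alt >= 1L) "hom_alt" else "hom_ref"
  } else {
    c("hom_ref", "het", "hom_alt")[min(n_alt, 2L) + 1L]
  }
}

#' Read a multi-sample VCF into a variant table
#'
#' Wraps `VariantAnnotation::readVcf`. Multiallelic records are split into
#' biallelic records (alleles other than the active alternate count as
#' reference) with parsimony-trimmed alleles; FILTER entries matching the
#' five known QC flags populate `qc_flags` (`PASS`/`.` give an empty set);
#' male genotypes on non-PAR X are coerced to `hemi_ref`/`hemi_alt` (a
#' diploid-coded heterozygous male X call is coerced to `hemi_alt` with a
#' warning). The alternate-allele depth comes from the AD field when present.
#'
#' @param path path to an uncompressed or bgzipped VCF 4.x file.
#' @param pedigree pedigree table; VCF samples must be a subset of it.
#' @param par_regions optional pseudoautosomal intervals on X.
#' @return variant table (see [variant_table()]).
#' @export
read_vcf <- function(path, pedigree, par_regions = NULL) {
  if (!file.exists(path)) vk_stop("VCF file not found: %s", path)
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown"))
  samples <- colnames(vcf)
  missing_s <- setdiff(samples, pedigree$sample_id)
  if (length(missing_s)) {
    vk_stop("VCF sample(s) absent from pedigree: %s", paste(missing_s, collapse = ", "))
  }
  gmat <- tryCatch(VariantAnnotation::geno(vcf)$GT, error = function(e) NULL)
  if (is.null(gmat)) vk_stop("VCF has no GT field: %s", path)
  admat <- tryCatch(VariantAnnotation::geno(vcf)$AD, error = function(e) NULL)

  rr <- SummarizedExperiment::rowRanges(vcf)
  chroms <- norm_chrom(as.character(GenomicRanges::seqnames(rr)))
  poss <- GenomicRanges::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)
  filts <- VariantAnnotation::filt(vcf)
  sexes <- setNames(pedigree$sex, pedigree$sample_id)

  out <- vector("list", sum(lengths(alts)))
  k <- 0L
  for (i in seq_along(rr)) {
    alt_i <- as.character(alts[[i]])
    flags <- setdiff(strsplit(filts[i] %||% "PASS", ";", fixed = TRUE)[[1L]],
                     c("PASS", ".", ""))
    flags <- sort(intersect(flags, qc_flag_levels))
    hemi_site <- is_x_nonpar(chroms[i], poss[i], par_regions)
    gts_raw <- gmat[i, , drop = TRUE]
    split_gt <- lapply(gts_raw, function(g) strsplit(g, "[/|]")[[1L]])
    for (a in seq_along(alt_i)) {
      if (alt_i[a] %in% c("*", "")) next
      norm <- normalize_alleles(poss[i], refs[i], alt_i[a])
      gt <- character(length(samples))
      names(gt) <- samples
      ad <- rep(NA_integer_, length(samples))
      names(ad) <- samples
      for (s in seq_along(samples)) {
        al <- split_gt[[s]]
        if (!length(al) || all(al == ".")) {
          gt[s] <- "missing"
        } else {
          al <- al[al != "."]
          n_alt <- sum(al == as.character(a))
          hemi <- hemi_site && sexes[[samples[s]]] == "male"
          if (hemi && length(al) == 2L && n_alt == 1L) {
            warning(sprintf(
              "heterozygous male X call for sample %s at %s:%d; coerced to hemi_alt",
              samples[s], chroms[i], poss[i]))
          }
          gt[s] <- gt_from_allele_count(n_alt, length(al), hemi)
        }
        if (!is.null(admat)) {
          adv <- admat[i, s][[1L]]
          if (length(adv) >= a + 1L) ad[s] <- suppressWarnings(as.integer(adv[a + 1L]))
        }
      }
      k <- k + 1L
      out[[k]] <- list(chrom = chroms[i], pos = norm$pos, ref = norm$ref,
                       alt = norm$alt, genotypes = gt, alt_depth = ad,
                       qc_flags = flags)
    }
  }
  out <- out[seq_len(k)]
  variant_table(
    chrom = vapply(out, `[[`, character(1L), "chrom"),
    pos = vapply(out, `[[`, integer(1L), "pos"),
    ref = vapply(out, `[[`, character(1L), "ref"),
    alt = vapply(out, `[[`, character(1L), "alt"),
    genotypes = lapply(out, `[[`, "genotypes"),
    alt_depth = lapply(out, `[[`, "alt_depth"),
    qc_flags = lapply(out, `[[`, "qc_flags"),
    pedigree = pedigree, par_regions = par_regions
  )
}

gt_to_vcf <- function(gt) {
  switch(gt,
         hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
         hemi_ref = "0", hemi_alt = "1", missing = "./.")
}

#' Write a variant table as VCF 4.2
#'
#' Emits a minimal multi-sample VCF with GT and AD (reference depth unknown,
#' written as "."), FILTER populated from the QC flag set, records sorted by
#' (chrom, pos, ref, alt) and samples in pedigree order, so output is
#' bit-stable.
#'
#' @param vt variant table.
#' @param pedigree pedigree supplying sample order.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, pedigree, path) {
  samples <- pedigree$sample_id
  ord <- order(vt$chrom, vt$pos, vt$ref, vt$alt)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf('##FILTER=<ID=%s,Description="%s">', qc_flag_levels,
            gsub("_", " ", qc_flag_levels)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(ord, function(i) {
    gts <- vt$genotypes[[i]]
    ads <- vt$alt_depth[[i]]
    cells <- vapply(samples, function(s) {
      g <- if (s %in% names(gts)) gts[[s]] else "missing"
      a <- if (s %in% names(ads) && !is.na(ads[[s]])) ads[[s]] else "."
      paste0(gt_to_vcf(g), ":.,", a)
    }, character(1L))
    filt <- if (length(vt$qc_flags[[i]])) {
      paste(sort(vt$qc_flags[[i]]), collapse = ";")
    } else "PASS"
    paste(c(vt$chrom[i], vt$pos[i], ".", vt$ref[i], vt$alt[i], ".", filt, ".",
            "GT:AD", cells), collapse = "\t")
  }, character(1L))
  writeLines(c(hdr, body), path)
  invisible(path)
}
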