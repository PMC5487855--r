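## Tabular formats: annotation TSV, gene-evidence TSV, edge lists, GMT gene
## sets, long-format assay CSV. All writers sort rows and emit plain
## tab/comma-separated text so round-trips are bit-stable.

#' Build a validated annotation table
#'
#' One row per variant with gene, coding-effect class, HGVS labels, per-tool
#' deleteriousness calls (`tool_1`..`tool_n` columns), per-database allele
#' frequencies (`af_<db>` columns; `NA` = absent from that database),
#' conservation and indel flags, and an optional `context` column holding
#' the reference sequence around an indel (used by the homopolymer filter).
#'
#' @param ann data.frame/data.table with at least `chrom`, `pos`, `ref`,
#'   `alt`, `gene`, `effect`, `conserved_region`, `is_indel`, one or more
#'   `af_*` columns and `tool_*` columns.
#' @param n_tools expected number of prediction tools (default: number of
#'   `tool_*` columns present).
#' @return `data.table` of class `varkin_annotations` keyed by `variant_key`.
#' @export
annotation_table <- function(ann, n_tools = NULL) {
  ann <- copy(as.data.table(ann))  # own the table before modifying in place
  req <- c("chrom", "pos", "ref", "alt", "gene", "effect",
           "conserved_region", "is_indel")
  if (!all(req %in% names(ann))) {
    vk_stop("annotation table missing columns: %s",
            paste(setdiff(req, names(ann)), collapse = ", "))
  }
  for (col in c("hgvs_c", "hgvs_p", "context")) {
    if (!col %in% names(ann)) set(ann, j = col, value = NA_character_)
  }
  ann[, chrom := norm_chrom(chrom)]
  ann[, pos := as.integer(pos)]
  ann[, variant_key := variant_key(chrom, pos, ref, alt)]
  bad_eff <- setdiff(unique(ann$effect), effect_levels)
  if (length(bad_eff)) vk_stop("unknown effect class(es): %s", paste(bad_eff, collapse = ", "))
  afc <- af_columns(ann)
  if (!length(afc)) vk_stop("annotation table has no af_<database> column")
  for (col in afc) {
    v <- as.numeric(ann[[col]])
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      vk_stop("frequency outside [0,1] in column %s", col)
    }
    set(ann, j = col, value = v)
  }
  tc <- tool_columns(ann)
  if (!length(tc)) vk_stop("annotation table has no tool_<i> column")
  if (!is.null(n_tools) && length(tc) != n_tools) {
    vk_stop("expected %d tool columns, found %d", n_tools, length(tc))
  }
  for (col in tc) {
    bad <- setdiff(unique(ann[[col]]), tool_call_levels)
    if (length(bad)) vk_stop("unknown tool call(s) in %s: %s", col, paste(bad, collapse = ", "))
  }
  ann[, conserved_region := as.logical(conserved_region)]
  ann[, is_indel := as.logical(is_indel)]
  setattr(ann, "class", unique(c("varkin_annotations", class(ann))))
  ann[]
}

#' @rdname annotation_table
#' @param ann annotation table.
#' @export
af_columns <- function(ann) grep("^af_", names(ann), value = TRUE)

#' @rdname annotation_table
#' @export
tool_columns <- function(ann) {
  cols <- grep("^tool_[0-9]+$", names(ann), value = TRUE)
  cols[order(as.integer(sub("tool_", "", cols)))]
}

#' Per-variant tool-call vectors from an annotation table
#' @param ann annotation table.
#' @return list (named by variant_key) of character vectors.
#' @export
tool_calls <- function(ann) {
  tc <- tool_columns(ann)
  out <- lapply(seq_len(nrow(ann)), function(i) unlist(ann[i, tc, with = FALSE], use.names = FALSE))
  names(out) <- ann$variant_key
  out
}

#' Per-variant database-frequency vectors
#' @param ann annotation table.
#' @return list (named by variant_key) of named numeric vectors; `NA` marks
#'   absence from a database.
#' @export
db_frequencies <- function(ann) {
  afc <- af_columns(ann)
  out <- lapply(seq_len(nrow(ann)), function(i) {
    setNames(as.numeric(ann[i, afc, with = FALSE]), sub("^af_", "", afc))
  })
  names(out) <- ann$variant_key
  out
}

#' Read / write the annotation TSV
#' @param path file path.
#' @param n_tools expected tool count (optional).
#' @return annotation table.
#' @export
read_annotations <- function(path, n_tools = NULL) {
  if (!file.exists(path)) vk_stop("annotation file not found: %s", path)
  ann <- fread(path, sep = "\t", header = TRUE, na.strings = c("NA", ""),
               colClasses = list(character = "chrom"))
  annotation_table(ann, n_tools = n_tools)
}

#' @rdname read_annotations
#' @param ann annotation table.
#' @export
write_annotations <- function(ann, path) {
  out <- as.data.table(ann)
  out <- out[order(chrom, pos, ref, alt)]
  lead <- c("chrom", "pos", "ref", "alt", "gene", "effect", "hgvs_c", "hgvs_p",
            "conserved_region", "is_indel", "context")
  setcolorder(out, c(lead, af_columns(out), tool_columns(out)))
  out[, variant_key := NULL]
  fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read / write gene-level evidence
#'
#' TSV with columns `gene`, `phenotypes` (";"-separated phenotype ids, may
#' be empty), `tissue_expression` (";"-separated `tissue:level` pairs with
#' level in not_detected/low/medium/high) and `rvis_percentile` (0-100 or
#' `NA`).
#'
#' @param path file path.
#' @return `data.table` with list-columns `phenotypes` and `tissue_expression`.
#' @export
read_gene_evidence <- function(path) {
  if (!file.exists(path)) vk_stop("gene evidence file not found: %s", path)
  ge <- fread(path, sep = "\t", header = TRUE, na.strings = c("NA", ""))
  req <- c("gene", "phenotypes", "tissue_expression", "rvis_percentile")
  if (!all(req %in% names(ge))) {
    vk_stop("gene evidence missing columns: %s", paste(setdiff(req, names(ge)), collapse = ", "))
  }
  if (any(!is.na(ge$rvis_percentile) & (ge$rvis_percentile < 0 | ge$rvis_percentile > 100))) {
    vk_stop("rvis_percentile outside [0,100]")
  }
  levels_ok <- c("not_detected", "low", "medium", "high")
  ge[, phenotypes := lapply(phenotypes, function(x) {
    if (is.na(x)) character() else strsplit(x, ";", fixed = TRUE)[[1L]]
  })]
  ge[, tissue_expression := lapply(tissue_expression, function(x) {
    if (is.na(x)) return(setNames(character(), character()))
    parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
    lv <- setNames(vapply(parts, `[`, character(1L), 2L),
                   vapply(parts, `[`, character(1L), 1L))
    bad <- setdiff(lv, levels_ok)
    if (length(bad)) vk_stop("unknown tissue level(s): %s", paste(bad, collapse = ", "))
    lv
  })]
  ge
}

#' Read / write an undirected edge list
#'
#' TSV with columns `node_a`, `node_b` and optional `evidence`. Edges are
#' stored canonically (lexicographically smaller node first); duplicates in
#' either orientation collapse to one edge; self-loops are rejected.
#'
#' @param path file path.
#' @return `data.table` with columns `node_a`, `node_b`, `evidence`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) vk_stop("edge list not found: %s", path)
  el <- fread(path, sep = "\t", header = TRUE, na.strings = c("NA", ""))
  if (!all(c("node_a", "node_b") %in% names(el))) {
    vk_stop("edge list must have node_a and node_b columns")
  }
  if (!"evidence" %in% names(el)) el$evidence <- NA_character_
  edge_list(el$node_a, el$node_b, el$evidence)
}

#' @rdname read_edge_list
#' @param node_a,node_b,evidence edge definition vectors.
#' @export
edge_list <- function(node_a, node_b, evidence = NA_character_) {
  el <- data.table(node_a = as.character(node_a), node_b = as.character(node_b),
                   evidence = as.character(evidence))
  if (any(el$node_a == el$node_b)) {
    vk_stop("self-loop edge(s): %s", paste(unique(el$node_a[el$node_a == el$node_b]), collapse = ", "))
  }
  swap <- el$node_a > el$node_b
  tmp <- el$node_a[swap]
  el$node_a[swap] <- el$node_b[swap]
  el$node_b[swap] <- tmp
  el <- unique(el, by = c("node_a", "node_b"))
  setorder(el, node_a, node_b)
  el[]
}

#' @rdname read_edge_list
#' @param el edge list table.
#' @export
write_edge_list <- function(el, path) {
  fwrite(el[order(node_a, node_b)], path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read / write GMT gene-set collections
#'
#' Standard GMT: one set per line, tab-separated name, description, then
#' member genes. Returned as a named list of character vectors with the
#' descriptions in attribute `descriptions`.
#'
#' @param path file path.
#' @return named list of gene sets.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) vk_stop("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[`, character(1L), 1L)
  if (anyDuplicated(nm)) vk_stop("duplicate gene-set name(s): %s",
                                 paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <- setNames(vapply(parts, `[`, character(1L), 2L), nm)
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene sets.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||% setNames(rep("", length(sets)), names(sets))
  nm <- sort(names(sets))
  lines <- vapply(nm, function(n) {
    paste(c(n, desc[[n]] %||% "", sort(sets[[n]])), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a long-format assay measurement CSV
#'
#' Columns: `assay` (qpcr/luciferase/calcium), `group`, `replicate`,
#' `target`, `value` (numeric).
#'
#' @param path file path.
#' @return `data.table`.
#' @export
read_assay_csv <- function(path) {
  if (!file.exists(path)) vk_stop("assay file not found: %s", path)
  tab <- fread(path, sep = ",", header = TRUE)
  req <- c("assay", "group", "replicate", "target", "value")
  if (!all(req %in% names(tab))) {
    vk_stop("assay table missing columns: %s", paste(setdiff(req, names(tab)), collapse = ", "))
  }
  if (!is.numeric(tab$value)) vk_stop("assay value column must be numeric")
  tab
}

#' @rdname read_assay_csv
#' @param tab assay table.
#' @export
write_assay_csv <- function(tab, path) {
  fwrite(as.data.table(tab)[order(assay, group, target, replicate)], path,
         sep = ",", quote = FALSE)
  invisible(path)
}
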