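## Pedigree container and 6-column PED input/output.

#' Build a validated pedigree table
#'
#' A pedigree is a `data.table` with one row per sample and columns
#' `sample_id`, `father_id`, `mother_id` (`NA` for founders), `sex`
#' (`"male"`/`"female"`) and `affected`
#' (`"affected"`/`"unaffected"`/`"unknown"`).
#'
#' @param sample_id,father_id,mother_id,sex,affected column vectors.
#' @return a `data.table` of class `varkin_pedigree`.
#' @export
pedigree <- function(sample_id, father_id, mother_id, sex, affected) {
  ped <- data.table(
    sample_id = as.character(sample_id),
    father_id = as.character(father_id),
    mother_id = as.character(mother_id),
    sex = as.character(sex),
    affected = as.character(affected)
  )
  validate_pedigree(ped)
  setattr(ped, "class", c("varkin_pedigree", class(ped)))
  ped[]
}

#' Validate pedigree invariants
#'
#' Checks id uniqueness, sex/phenotype vocabularies, that non-founder parent
#' ids refer to samples present in the pedigree, and that no sample is its
#' own ancestor.
#'
#' @param ped pedigree table.
#' @return `ped`, invisibly; errors otherwise.
#' @export
validate_pedigree <- function(ped) {
  req <- c("sample_id", "father_id", "mother_id", "sex", "affected")
  if (!all(req %in% names(ped))) {
    vk_stop("pedigree is missing columns: %s",
            paste(setdiff(req, names(ped)), collapse = ", "))
  }
  if (anyDuplicated(ped$sample_id)) {
    vk_stop("duplicate sample id(s): %s",
            paste(unique(ped$sample_id[duplicated(ped$sample_id)]), collapse = ", "))
  }
  if (!all(ped$sex %in% c("male", "female"))) {
    vk_stop("unknown sex value(s): %s",
            paste(setdiff(ped$sex, c("male", "female")), collapse = ", "))
  }
  if (!all(ped$affected %in% c("affected", "unaffected", "unknown"))) {
    vk_stop("unknown affected value(s): %s",
            paste(setdiff(ped$affected, c("affected", "unaffected", "unknown")),
                  collapse = ", "))
  }
  for (col in c("father_id", "mother_id")) {
    set_ids <- ped[[col]]
    bad <- !is.na(set_ids) & !(set_ids %in% ped$sample_id)
    if (any(bad)) {
      vk_stop("sample '%s': %s '%s' not present in pedigree",
              ped$sample_id[which(bad)[1L]], col, set_ids[which(bad)[1L]])
    }
  }
  # ancestor cycle check by repeated parent lookup
  for (id in ped$sample_id) {
    seen <- character()
    frontier <- id
    while (length(frontier)) {
      rows <- ped[ped$sample_id %in% frontier, ]
      frontier <- setdiff(stats::na.omit(c(rows$father_id, rows$mother_id)), seen)
      if (id %in% frontier) vk_stop("sample '%s' is its own ancestor", id)
      seen <- c(seen, frontier)
    }
  }
  invisible(ped)
}

#' Read a 6-column PED file
#'
#' Columns: family id, sample id, father id, mother id, sex (1 = male,
#' 2 = female), phenotype (2 = affected, 1 = unaffected, 0 or -9 = unknown).
#' A parent id of "0" marks a founder and is stored as `NA`.
#'
#' @param path path to a whitespace-delimited PED file.
#' @return pedigree table (see [pedigree()]).
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) vk_stop("PED file not found: %s", path)
  raw <- tryCatch(
    read.table(path, header = FALSE, stringsAsFactors = FALSE,
               colClasses = "character", comment.char = "#"),
    error = function(e) NULL
  )
  if (is.null(raw) || nrow(raw) == 0L) {
    warning("empty PED file: ", path)
    return(pedigree(character(), character(), character(), character(), character()))
  }
  if (ncol(raw) < 6L) vk_stop("PED file must have 6 columns, found %d", ncol(raw))
  sex <- c(`1` = "male", `2` = "female")[raw[[5L]]]
  if (anyNA(sex)) {
    vk_stop("unknown PED sex code '%s' for sample '%s'",
            raw[[5L]][which(is.na(sex))[1L]], raw[[2L]][which(is.na(sex))[1L]])
  }
  aff <- c(`2` = "affected", `1` = "unaffected", `0` = "unknown", `-9` = "unknown")[raw[[6L]]]
  if (anyNA(aff)) {
    vk_stop("unknown PED phenotype code '%s' for sample '%s'",
            raw[[6L]][which(is.na(aff))[1L]], raw[[2L]][which(is.na(aff))[1L]])
  }
  fid <- ifelse(raw[[3L]] == "0", NA_character_, raw[[3L]])
  mid <- ifelse(raw[[4L]] == "0", NA_character_, raw[[4L]])
  pedigree(raw[[2L]], fid, mid, sex, aff)
}

#' Write a pedigree as a 6-column PED file
#'
#' Output is sorted by sample id so serialization is bit-stable.
#'
#' @param ped pedigree table.
#' @param path output path.
#' @param family_id family identifier for column 1.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path, family_id = "FAM1") {
  validate_pedigree(ped)
  out <- data.table(
    fam = family_id,
    id = ped$sample_id,
    fa = ifelse(is.na(ped$father_id), "0", ped$father_id),
    mo = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex = ifelse(ped$sex == "male", "1", "2"),
    phe = c(affected = "2", unaffected = "1", unknown = "0")[ped$affected]
  )
  setorder(out, id)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Affected sample ids of a pedigree
#' @param ped pedigree table.
#' @param sex optional sex filter ("male"/"female").
#' @return character vector of sample ids.
#' @export
affected_ids <- function(ped, sex = NULL) {
  keep <- ped$affected == "affected"
  if (!is.null(sex)) keep <- keep & ped$sex == sex
  ped$sample_id[keep]
}

#' Default proband of a pedigree
#'
#' The proband is the first affected male if one exists, otherwise the first
#' affected sample in pedigree order.
#'
#' @param ped pedigree table.
#' @return sample id, or error when no sample is affected.
#' @export
proband_id <- function(ped) {
  am <- affected_ids(ped, "male")
  if (length(am)) return(am[1L])
  aa <- affected_ids(ped)
  if (!length(aa)) vk_stop("pedigree contains no affected sample")
  aa[1L]
}
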