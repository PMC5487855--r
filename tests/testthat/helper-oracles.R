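# Independent brute-force oracles. These deliberately re-derive each
# predicate from its definition with naive loops, sharing no code with the
# implementation under test.

oracle_carrier <- function(g) g %in% c("het", "hom_alt", "hemi_alt")

# de novo: proband carries alt; parents and siblings are called non-carriers
oracle_de_novo <- function(gt, ped, proband) {
  prow <- ped[ped$sample_id == proband, ]
  fam <- character()
  for (p in c(prow$father_id, prow$mother_id)) if (!is.na(p)) fam <- c(fam, p)
  for (i in seq_len(nrow(ped))) {
    if (ped$sample_id[i] == proband) next
    fi <- ped$father_id[i]; mi <- ped$mother_id[i]
    if ((!is.na(fi) && fi %in% fam) || (!is.na(mi) && mi %in% fam)) {
      fam <- unique(c(fam, ped$sample_id[i]))
    }
  }
  g <- gt[[proband]]
  if (is.na(g) || g == "missing" || !oracle_carrier(g)) return(FALSE)
  for (s in fam) {
    gs <- if (s %in% names(gt)) gt[[s]] else "missing"
    if (gs == "missing" || oracle_carrier(gs)) return(FALSE)
  }
  TRUE
}

oracle_ar_hom <- function(gt, ped) {
  aff <- ped$sample_id[ped$affected == "affected"]
  parents <- character()
  for (a in aff) {
    row <- ped[ped$sample_id == a, ]
    for (p in c(row$father_id, row$mother_id)) if (!is.na(p)) parents <- c(parents, p)
  }
  parents <- setdiff(unique(parents), aff)
  for (s in names(gt)) {
    g <- gt[[s]]
    status <- ped$affected[ped$sample_id == s]
    if (s %in% aff) {
      if (g != "hom_alt") return(FALSE)
    } else if (s %in% parents) {
      if (g != "het") return(FALSE)
    } else if (status == "unaffected") {
      if (g == "missing" || g == "hom_alt") return(FALSE)
    }
  }
  TRUE
}

oracle_xlr <- function(gt, ped, lenient_affected_female = TRUE) {
  aff_m <- ped$sample_id[ped$affected == "affected" & ped$sex == "male"]
  mothers <- unique(ped$mother_id[ped$sample_id %in% aff_m])
  mothers <- mothers[!is.na(mothers)]
  for (s in names(gt)) {
    g <- gt[[s]]
    row <- ped[ped$sample_id == s, ]
    if (s %in% aff_m) {
      if (g != "hemi_alt") return(FALSE)
    } else if (s %in% mothers) {
      if (!(g %in% c("het", "hom_alt"))) return(FALSE)
    } else if (row$sex == "male" && row$affected == "unaffected") {
      if (g == "missing" || g == "hemi_alt") return(FALSE)
    } else if (row$sex == "female" && row$affected == "unaffected") {
      if (g == "missing" || g == "hom_alt") return(FALSE)
    } else if (row$sex == "female" && row$affected == "affected" &&
               !lenient_affected_female) {
      if (!(g %in% c("het", "hom_alt"))) return(FALSE)
    }
  }
  TRUE
}

# weighted vote by explicit counting
oracle_vote_score <- function(calls) {
  s <- 0
  for (cl in calls) {
    if (cl == "deleterious") s <- s + 1
    if (cl == "ambiguous") s <- s + 0.5
  }
  s
}

# hypergeometric upper tail by exhaustive enumeration of all query draws
oracle_hyper_enum <- function(background_size, set_size, query_size, overlap) {
  draws <- combn(background_size, query_size)
  inset <- seq_len(set_size)  # wlog the set is the first set_size elements
  hits <- 0L
  for (j in seq_len(ncol(draws))) {
    if (sum(draws[, j] %in% inset) >= overlap) hits <- hits + 1L
  }
  hits / ncol(draws)
}

# BH step-up written from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# admitted intermediates by exhaustive simple-path enumeration (plain DFS)
oracle_intermediates <- function(edges, seeds, max_len) {
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    a <- edges$node_a[i]; b <- edges$node_b[i]
    adj[[a]] <- unique(c(adj[[a]], b))
    adj[[b]] <- unique(c(adj[[b]], a))
  }
  found <- character()
  walk <- function(path, target) {
    last <- path[length(path)]
    if (length(path) - 1L > max_len) return()
    if (last == target && length(path) > 1L) {
      interior <- path[-c(1L, length(path))]
      if (!any(interior %in% seeds)) found <<- unique(c(found, interior))
      return()
    }
    if (length(path) - 1L == max_len) return()
    for (nb in adj[[last]]) {
      if (nb %in% path) next
      if (nb %in% seeds && nb != target) next  # interior seeds never admit
      walk(c(path, nb), target)
    }
  }
  present <- intersect(seeds, names(adj))
  if (length(present) >= 2L) {
    prs <- combn(present, 2L)
    for (j in seq_len(ncol(prs))) walk(prs[1L, j], prs[2L, j])
  }
  sort(found)
}

# the four candidate variants as printed in the study narrative: gene,
# synthetic key, and per-tool outcomes (top candidate deleterious by 8.5/10,
# the other three by none)
worked_example_candidates <- function() {
  list(
    list(gene = "FHL1", key = "X:283:C:T", conserved = TRUE,
         calls = c(rep("deleterious", 8), "ambiguous", "tolerated")),
    list(gene = "ZNF366", key = "5:58:A:G", conserved = FALSE,
         calls = rep("tolerated", 10)),
    list(gene = "CORO1B", key = "11:1252:G:A", conserved = FALSE,
         calls = rep("tolerated", 10)),
    list(gene = "ZNF208", key = "19:986:T:C", conserved = FALSE,
         calls = rep("tolerated", 10))
  )
}
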