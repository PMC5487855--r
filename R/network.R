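## Induced network modules around seed proteins and hypergeometric gene-set
## over-representation with Benjamini-Hochberg correction.

#' Induce a network module around seed nodes
#'
#' A non-seed node is admitted as an intermediate iff it is interior to a
#' simple seed-to-seed path of at most `max_path_len` edges whose interior
#' contains no seed (paths passing through another seed decompose into
#' shorter seed-to-seed connections). The module keeps all direct seed-seed
#' edges plus the edges of the subgraph induced on seeds and admitted
#' intermediates; one representative connection (the shortest admissible
#' path, ties broken lexicographically) is reported for every connected
#' seed pair. Seeds absent from the edge list are reported as isolated.
#'
#' @param el edge list (see [edge_list()]).
#' @param seeds character vector of seed node names (non-empty).
#' @param max_path_len maximum connection length in edges (default 3,
#'   admitting one- and two-intermediate bridges); must be >= 1.
#' @return list of class `induced_module` with `seeds`, `intermediates`,
#'   `edges` (data.table `node_a`/`node_b`), `connections` (data.table
#'   `seed_a`, `seed_b`, `length`, `path` list-column) and `isolated`.
#' @export
induce_module <- function(el, seeds, max_path_len = 3L) {
  if (!length(seeds)) vk_stop("seed set must be non-empty")
  if (max_path_len < 1L) vk_stop("max_path_len must be >= 1")
  seeds <- sort(unique(as.character(seeds)))
  g <- igraph::graph_from_data_frame(el[, c("node_a", "node_b")], directed = FALSE)
  present <- intersect(seeds, igraph::V(g)$name)
  intermediates <- character()
  conns <- list()
  if (length(present) >= 2L) {
    pairs <- combn(present, 2L)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      paths <- igraph::all_simple_paths(g, from = a, to = b, cutoff = max_path_len)
      best <- NULL
      for (p in paths) {
        nodes <- igraph::V(g)$name[p]
        interior <- nodes[-c(1L, length(nodes))]
        if (any(interior %in% seeds)) next
        intermediates <- union(intermediates, interior)
        if (is.null(best) || length(nodes) < length(best) ||
            (length(nodes) == length(best) &&
             paste(nodes, collapse = "\r") < paste(best, collapse = "\r"))) {
          best <- nodes
        }
      }
      if (!is.null(best)) {
        conns[[length(conns) + 1L]] <-
          data.table(seed_a = a, seed_b = b, length = length(best) - 1L,
                     path = list(best))
      }
    }
  }
  keep_nodes <- union(present, intermediates)
  sub_el <- el[el$node_a %in% keep_nodes & el$node_b %in% keep_nodes]
  conn_dt <- if (length(conns)) rbindlist(conns) else
    data.table(seed_a = character(), seed_b = character(),
               length = integer(), path = list())
  connected_seeds <- unique(c(conn_dt$seed_a, conn_dt$seed_b))
  structure(list(seeds = seeds,
                 intermediates = sort(intermediates),
                 edges = sub_el[, c("node_a", "node_b", "evidence")],
                 connections = conn_dt,
                 isolated = setdiff(seeds, connected_seeds)),
            class = "induced_module")
}

#' @export
print.induced_module <- function(x, ...) {
  cat(sprintf("induced module: %d seeds, %d intermediates, %d edges, %d seed-pair connections\n",
              length(x$seeds), length(x$intermediates), nrow(x$edges),
              nrow(x$connections)))
  if (length(x$intermediates)) {
    cat("  intermediates:", paste(x$intermediates, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' Exact upper-tail hypergeometric test P(X >= overlap) per gene set, with
#' Benjamini-Hochberg q-values across all tested sets. Gene sets are
#' intersected with the background before testing; the background defaults
#' to the union of all gene-set members and the query.
#'
#' @param query character vector of query genes (must be a subset of the
#'   background).
#' @param gene_sets named list of gene sets (e.g. from [read_gmt()]).
#' @param background character vector of background genes, or `NULL`.
#' @param min_overlap report only sets with at least this many query genes
#'   (applied after multiple-testing correction; default 0 = report all).
#' @return `data.table` with `set_name`, `overlap_count`, `set_size`,
#'   `query_size`, `background_size`, `p_value`, `q_value`, sorted by
#'   p-value then set name.
#' @export
hypergeometric_enrichment <- function(query, gene_sets, background = NULL,
                                      min_overlap = 0L) {
  query <- unique(as.character(query))
  if (is.null(background)) background <- union(unlist(gene_sets, use.names = FALSE), query)
  background <- unique(as.character(background))
  outside <- setdiff(query, background)
  if (length(outside)) {
    vk_stop("query gene(s) absent from background: %s", paste(outside, collapse = ", "))
  }
  B <- length(background)
  q <- length(query)
  res <- rbindlist(lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], background)
    k <- length(intersect(query, s))
    p <- if (length(s) == 0L) 1 else
      phyper(k - 1L, length(s), B - length(s), q, lower.tail = FALSE)
    data.table(set_name = nm, overlap_count = k, set_size = length(s),
               query_size = q, background_size = B, p_value = min(p, 1))
  }))
  res[, q_value := p.adjust(p_value, method = "BH")]
  setorder(res, p_value, set_name)
  res[overlap_count >= min_overlap]
}

#' Export / import an induced module
#'
#' Writes `nodes.tsv` (node, role in seed/intermediate), `edges.tsv` and a
#' GraphML file `module.graphml` into a directory; `import_module()` reads
#' the two tables back (representative connections are recomputed on
#' demand, not serialized).
#'
#' @param module induced module.
#' @param dir output directory (created if needed).
#' @return `dir` invisibly (`export_module`); module-like list
#'   (`import_module`).
#' @export
export_module <- function(module, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- data.table(
    node = c(module$seeds, module$intermediates),
    role = c(rep("seed", length(module$seeds)),
             rep("intermediate", length(module$intermediates))))
  setorder(nodes, node)
  fwrite(nodes, file.path(dir, "nodes.tsv"), sep = "\t", quote = FALSE)
  write_edge_list(module$edges, file.path(dir, "edges.tsv"))
  g <- igraph::graph_from_data_frame(
    module$edges[, c("node_a", "node_b")], directed = FALSE,
    vertices = nodes[, c("node", "role")])
  igraph::write_graph(g, file.path(dir, "module.graphml"), format = "graphml")
  invisible(dir)
}

#' @rdname export_module
#' @param dir directory written by [export_module()].
#' @export
import_module <- function(dir) {
  nodes <- fread(file.path(dir, "nodes.tsv"), sep = "\t", header = TRUE,
                 colClasses = "character")
  edges <- if (file.size(file.path(dir, "edges.tsv")) > 1L) {
    read_edge_list(file.path(dir, "edges.tsv"))
  } else {
    data.table(node_a = character(), node_b = character(), evidence = character())
  }
  list(seeds = sort(nodes$node[nodes$role == "seed"]),
       intermediates = sort(nodes$node[nodes$role == "intermediate"]),
       edges = edges)
}
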