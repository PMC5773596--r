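#' Build a regulatory gene network from shared MORE sets
#'
#' Two genes are connected when they share at least one enriched MORE set
#' under the same sub-phenotype (parameter-sex-direction tag, e.g.
#' `"AUC-mh"`). Edges are annotated with all shared set ids and
#' sub-phenotype tags; the graph is undirected with no self-edges.
#'
#' @param set_gene_table `data.frame(more_set, sub_phenotype, gene)`: one row
#'   per (MORE set, gene) association
#' @return an undirected `igraph` graph; edge attributes `more_sets` and
#'   `sub_phenotypes` (comma-joined), vertex attribute `sub_phenotypes`
#' @export
build_more_network <- function(set_gene_table) {
  need <- c("more_set", "sub_phenotype", "gene")
  stop_if_not(all(need %in% names(set_gene_table)),
              "need columns more_set, sub_phenotype, gene")
  tab <- unique(set_gene_table[, need])
  edges <- list()
  for (key in unique(paste(tab$more_set, tab$sub_phenotype, sep = "\r"))) {
    parts <- strsplit(key, "\r")[[1]]
    genes <- sort(unique(tab$gene[tab$more_set == parts[1] &
                                    tab$sub_phenotype == parts[2]]))
    if (length(genes) < 2) next
    pairs <- utils::combn(genes, 2)
    for (c_i in seq_len(ncol(pairs)))
      edges[[length(edges) + 1]] <- data.frame(
        from = pairs[1, c_i], to = pairs[2, c_i],
        more_set = parts[1], sub_phenotype = parts[2],
        stringsAsFactors = FALSE)
  }
  nodes <- sort(unique(tab$gene))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  vtag <- vapply(nodes, function(gn)
    paste(sort(unique(tab$sub_phenotype[tab$gene == gn])), collapse = ","),
    character(1))
  igraph::V(g)$sub_phenotypes <- vtag
  if (length(edges)) {
    ed <- do.call(rbind, edges)
    key <- paste(ed$from, ed$to)
    agg_sets <- tapply(ed$more_set, key, function(x)
      paste(sort(unique(x)), collapse = ","))
    agg_phen <- tapply(ed$sub_phenotype, key, function(x)
      paste(sort(unique(x)), collapse = ","))
    uniq <- ed[!duplicated(key), c("from", "to")]
    ukey <- paste(uniq$from, uniq$to)
    g <- igraph::add_edges(g, as.vector(t(as.matrix(uniq))))
    igraph::E(g)$more_sets <- unname(agg_sets[ukey])
    igraph::E(g)$sub_phenotypes <- unname(agg_phen[ukey])
    igraph::E(g)$provenance <- "more"
  }
  g
}

#' Map genes to pathways from a membership table
#'
#' @param genes character vector
#' @param pathway_table `data.frame(gene, pathway_id, pathway_name, class)`
#' @param class optional class filter (e.g. `"Metabolism"`); `NULL` keeps all
#' @return named list: per gene, the character vector of pathway ids (empty
#'   for genes absent from the table)
#' @export
map_to_pathways <- function(genes, pathway_table, class = NULL) {
  stop_if_not(all(c("gene", "pathway_id") %in% names(pathway_table)),
              "pathway table needs columns gene, pathway_id")
  if (!is.null(class)) {
    stop_if_not("class" %in% names(pathway_table),
                "pathway table has no class column to filter on")
    pathway_table <- pathway_table[pathway_table$class %in% class, , drop = FALSE]
  }
  setNames(lapply(genes, function(g)
    sort(unique(pathway_table$pathway_id[pathway_table$gene == g]))), genes)
}

#' Build a knowledge-based pathway-sharing network
#'
#' Two genes are connected when both map to at least one common pathway.
#'
#' @param genes node universe
#' @param pathway_table `data.frame(gene, pathway_id, pathway_name, class)`
#' @param class optional class filter passed to [map_to_pathways()]
#' @return undirected `igraph` graph with edge attribute `pathway_ids`
#' @export
build_pathway_network <- function(genes, pathway_table, class = NULL) {
  pw <- map_to_pathways(genes, pathway_table, class = class)
  nodes <- sort(unique(genes))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  edges <- character(0); attrs <- character(0)
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (j <= i) next
    shared <- intersect(pw[[nodes[i]]], pw[[nodes[j]]])
    if (length(shared)) {
      edges <- c(edges, nodes[i], nodes[j])
      attrs <- c(attrs, paste(shared, collapse = ","))
    }
  }
  if (length(edges)) {
    g <- igraph::add_edges(g, edges)
    igraph::E(g)$pathway_ids <- attrs
    igraph::E(g)$provenance <- "pathway"
  }
  g
}

#' Overlay a MORE-set network and a pathway network
#'
#' Union graph over the shared node universe; every edge is labelled with its
#' provenance: `more`, `pathway`, or `both` when supported by both source
#' networks.
#'
#' @param more_net,pathway_net undirected `igraph` graphs over the same node
#'   universe
#' @return undirected `igraph` union graph with edge attribute `provenance`;
#'   graph attribute `n_both` counts doubly supported edges
#' @export
overlay_networks <- function(more_net, pathway_net) {
  nodes <- sort(union(igraph::V(more_net)$name, igraph::V(pathway_net)$name))
  ekey <- function(g) {
    if (igraph::ecount(g) == 0) return(character(0))
    el <- igraph::as_edgelist(g)
    apply(cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])), 1, paste,
          collapse = "\r")
  }
  em <- ekey(more_net); ep <- ekey(pathway_net)
  all_e <- sort(union(em, ep))
  prov <- ifelse(all_e %in% em & all_e %in% ep, "both",
                 ifelse(all_e %in% em, "more", "pathway"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(all_e)) {
    pairs <- do.call(rbind, strsplit(all_e, "\r"))
    g <- igraph::add_edges(g, as.vector(t(pairs)))
    igraph::E(g)$provenance <- prov
  }
  g <- igraph::set_graph_attr(g, "n_both", sum(prov == "both"))
  g
}

#' Validate cassette-based phenotype prediction
#'
#' Partitions genes into those with at least one cassette match and those
#' with none, builds the 2x2 contingency table against the has-metabolic-
#' phenotype flag and reports the two-sided Fisher's exact p-value (sum of
#' hypergeometric probabilities of tables at most as probable as the
#' observed one).
#'
#' @param match_counts named integer vector: cassette-match count per gene
#' @param phenotype_flags named logical vector: gene has a metabolic
#'   phenotype; names must cover the same genes
#' @return list of class `prediction_validation`: `table` (2x2),
#'   `p_value`, `prop_matched`, `prop_unmatched`
#' @export
validate_prediction <- function(match_counts, phenotype_flags) {
  genes <- names(match_counts)
  stop_if_not(!is.null(genes) && all(genes %in% names(phenotype_flags)),
              "match_counts and phenotype_flags must be named over the same genes")
  flags <- phenotype_flags[genes]
  matched <- match_counts >= 1
  stop_if_not(any(matched) && any(!matched),
              "both match strata must be non-empty")
  tab <- matrix(c(sum(matched & flags), sum(matched & !flags),
                  sum(!matched & flags), sum(!matched & !flags)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("matched", "unmatched"),
                                c("phenotype", "no_phenotype")))
  p <- fisher.test(tab)$p.value
  structure(list(table = tab, p_value = p,
                 prop_matched = tab[1, 1] / sum(tab[1, ]),
                 prop_unmatched = tab[2, 1] / sum(tab[2, ])),
            class = "prediction_validation")
}

#' @export
print.prediction_validation <- function(x, ...) {
  cat(sprintf("prediction validation: %.1f%% vs %.1f%% with phenotype, Fisher p = %.3g\n",
              100 * x$prop_matched, 100 * x$prop_unmatched, x$p_value))
  print(x$table)
  invisible(x)
}
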