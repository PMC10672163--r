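#' Build the bipartite miRNA-mRNA graph
#'
#' Nodes carry `kind` ("mirna"/"gene") and a bipartite `type` attribute
#' (FALSE = miRNA, TRUE = gene). Gene nodes carry `size` = max |CWCS| over
#' incident edges (display confidence) and `label_flag` = TRUE when any
#' incident edge is high-confidence (such targets are labeled with their
#' gene name in display). Edges carry `cwcs` and `tier`.
#'
#' @param edges edge data.frame (`mirna_id`, `gene_id`, `cwcs`, `tier`).
#' @return an igraph graph.
#' @export
build_network <- function(edges) {
  validate_edges(edges)
  mirnas <- unique(edges$mirna_id)
  genes <- unique(edges$gene_id)
  both <- intersect(mirnas, genes)
  if (length(both))
    stop("identifier(s) appear as both miRNA and gene: ",
         paste(both, collapse = ", "))
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(mirnas), name = mirnas, kind = "mirna",
                            type = FALSE, size = NA_real_, label_flag = FALSE)
  if (length(genes)) {
    size <- vapply(genes, function(gn)
      max(abs(edges$cwcs[edges$gene_id == gn])), numeric(1))
    flag <- vapply(genes, function(gn)
      any(edges$tier[edges$gene_id == gn] == "high"), logical(1))
    g <- igraph::add_vertices(g, length(genes), name = genes, kind = "gene",
                              type = TRUE, size = size, label_flag = flag)
  }
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(edges$mirna_id, edges$gene_id),
                           cwcs = edges$cwcs, tier = edges$tier)
  g
}

#' Summarize a miRNA-mRNA network
#'
#' @param graph graph from [build_network()].
#' @return list with `n_edges`, `n_mirna`, `n_gene`, `edges_high`,
#'   `edges_moderate`, and named degree vectors `mirna_degree`,
#'   `gene_degree`.
#' @export
network_summary <- function(graph) {
  kind <- igraph::V(graph)$kind
  deg <- igraph::degree(graph)
  tier <- if (igraph::ecount(graph)) igraph::E(graph)$tier else character(0)
  list(n_edges = igraph::ecount(graph),
       n_mirna = sum(kind == "mirna"),
       n_gene = sum(kind == "gene"),
       edges_high = sum(tier == "high"),
       edges_moderate = sum(tier == "moderate"),
       mirna_degree = deg[kind == "mirna"],
       gene_degree = deg[kind == "gene"])
}
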