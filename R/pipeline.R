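#' Run the full miRNA-mRNA network pipeline
#'
#' Convenience wrapper over the individual stages: per-cohort miRNA
#' differential expression (QC filter, NB Wald test), cross-cohort consensus
#' candidates, mRNA differential expression, gene-level collapsing and
#' CWCS tiering of the prediction table, integration to the edge set, and
#' the bipartite network with its summary.
#'
#' @param mirna_cohorts list of cohorts, each a list with `counts` and
#'   `sheet`.
#' @param mrna list with `counts` and `sheet` for the mRNA cohort.
#' @param predictions prediction table (`mirna_family`, `gene_id`,
#'   `transcript_id`, `cwcs`, `conserved_sites`).
#' @param alpha FDR threshold.
#' @param min_change minimum fractional expression change (0.5 = 50%).
#' @param min_assigned assigned-read QC threshold for mRNA samples.
#' @param family_map optional miRNA-to-family map (see [integrate_targets()]).
#' @param ref control condition label.
#' @return list with elements `mirna_de` (per-cohort tables), `candidates`,
#'   `mrna_de`, `down_genes`, `tiered`, `edges`, `graph`, `summary`.
#' @export
run_pipeline <- function(mirna_cohorts, mrna, predictions,
                         alpha = 0.05, min_change = 0.5, min_assigned = 1e6,
                         family_map = NULL, ref = "control") {
  mirna_de <- lapply(mirna_cohorts, function(co)
    wald_test(co$counts, co$sheet, ref = ref))
  candidates <- consensus_candidates(mirna_de, alpha = alpha,
                                     min_change = min_change)
  qc <- qc_filter_samples(mrna$counts, mrna$sheet, min_assigned = min_assigned)
  mrna_de <- wald_test(qc$counts, qc$sheet, ref = ref)
  calls <- call_de(mrna_de, alpha = alpha, min_change = min_change)
  down_genes <- calls$feature_id[calls$direction == "down"]
  tiered <- tier_predictions(gene_level_predictions(predictions))
  edges <- integrate_targets(candidates, tiered, down_genes,
                             family_map = family_map)
  graph <- build_network(edges)
  list(mirna_de = mirna_de, candidates = candidates, mrna_de = mrna_de,
       down_genes = down_genes, tiered = tiered, edges = edges,
       graph = graph, summary = network_summary(graph))
}
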