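#' Hypergeometric upper-tail probability
#'
#' P(X >= x) where X counts successes in a draw of size n from a universe of
#' N genes of which K belong to the set — the standard overrepresentation
#' test. Computed with the exact hypergeometric tail (stable in log space
#' for large N).
#'
#' @param x observed overlap.
#' @param K gene-set size within the universe.
#' @param n query size.
#' @param N universe size.
#' @return upper-tail probability in (0, 1].
#' @export
hypergeom_p <- function(x, K, n, N) {
  if (any(c(x, K, n, N) < 0) || K > N || n > N || x > min(K, n))
    stop("inconsistent hypergeometric parameters")
  if (x == 0) return(1)
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric overrepresentation analysis of an unranked gene list
#'
#' Each gene set is intersected with the universe; query genes outside the
#' universe are dropped (count reported). One test per set with at least one
#' universe member; p-values are Benjamini-Hochberg adjusted across all
#' tested sets. The top slice (default 12 terms, matching bar-graph
#' reporting) is ordered by ascending FDR, ties broken by ascending p-value
#' then term id.
#'
#' @param query character vector of gene ids.
#' @param sets list of gene sets ([read_gmt()] output).
#' @param universe character vector of background gene ids (conventionally
#'   all genes tested for differential expression).
#' @param top size of the reported top slice.
#' @return data.frame of all tested sets: `term_id`, `term_name`, `overlap`,
#'   `set_size`, `query_size`, `universe_size`, `pvalue`, `fdr`,
#'   `overlap_genes` (comma-separated), with attributes `top` (the top
#'   slice) and `dropped_query` (count of query genes outside the universe).
#' @export
ora <- function(query, sets, universe, top = 12) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query <- unique(query)
  dropped <- sum(!query %in% universe)
  if (dropped) message(dropped, " query gene(s) outside the universe dropped")
  query <- intersect(query, universe)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(sets, function(s) {
    members <- intersect(s$genes, universe)
    if (length(members) == 0) return(NULL)
    ov <- intersect(query, members)
    data.frame(term_id = s$term_id, term_name = s$term_name,
               overlap = length(ov), set_size = length(members),
               query_size = n, universe_size = N,
               pvalue = hypergeom_p(length(ov), length(members), n, N),
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    stop("no gene set overlaps the universe")
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$pvalue, method = "BH")
  res <- res[, c("term_id", "term_name", "overlap", "set_size", "query_size",
                 "universe_size", "pvalue", "fdr", "overlap_genes")]
  rownames(res) <- NULL
  ord <- order(res$fdr, res$pvalue, res$term_id)
  attr(res, "top") <- utils::head(res[ord, , drop = FALSE], top)
  attr(res, "dropped_query") <- dropped
  res
}
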