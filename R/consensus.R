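#' Cross-cohort consensus miRNA candidates
#'
#' Candidate miRNAs are those called differentially expressed (per
#' [call_de()] criteria) in every cohort. By default the direction of change
#' must also agree across cohorts; discordant miRNAs are excluded and
#' recorded. Candidates are ranked by the maximal -log10 FDR-adjusted
#' p-value across cohorts (most significant anywhere ranks first); FDR
#' values are floored at 1e-300 before taking logs, and rank ties are broken
#' by lexicographic miRNA identifier.
#'
#' @param cohort_results list (length >= 2) of [wald_test()] result tables
#'   sharing a feature namespace.
#' @param alpha FDR threshold passed to [call_de()].
#' @param min_change minimum fractional change passed to [call_de()].
#' @param require_concordance exclude miRNAs whose direction differs between
#'   cohorts (default TRUE).
#' @return data.frame with one row per candidate: `mirna`, `rank`,
#'   `rank_score`, `direction`, then per-cohort `lfc_<i>` and `fdr_<i>`
#'   columns. Discordant exclusions are in `attr(, "discordant")`.
#' @export
consensus_candidates <- function(cohort_results, alpha = 0.05, min_change = 0.5,
                                 require_concordance = TRUE) {
  if (!is.list(cohort_results) || length(cohort_results) < 2)
    stop("need at least two cohort result tables")
  k <- length(cohort_results)
  namespaces <- lapply(cohort_results, function(r) r$feature_id)
  shared <- Reduce(intersect, namespaces)
  if (length(shared) == 0)
    stop("cohort feature namespaces are disjoint (overlap size 0)")
  calls <- lapply(cohort_results, call_de, alpha = alpha, min_change = min_change)
  cand <- Reduce(intersect, lapply(calls, `[[`, "feature_id"))
  discordant <- character(0)
  if (length(cand)) {
    dirs <- sapply(calls, function(cl) cl$direction[match(cand, cl$feature_id)])
    if (length(cand) == 1) dirs <- matrix(dirs, nrow = 1)
    agree <- apply(dirs, 1, function(d) length(unique(d)) == 1)
    discordant <- cand[!agree]
    if (length(discordant) && require_concordance) {
      message(length(discordant), " candidate(s) excluded for discordant ",
              "direction: ", paste(discordant, collapse = ", "))
      cand <- cand[agree]
    }
  }
  if (length(cand) == 0) {
    out <- data.frame(mirna = character(0), rank = integer(0),
                      rank_score = numeric(0), direction = character(0))
  } else {
    per <- lapply(cohort_results, function(r) r[match(cand, r$feature_id), ])
    fdr_mat <- sapply(per, `[[`, "fdr")
    lfc_mat <- sapply(per, `[[`, "lfc")
    if (length(cand) == 1) {
      fdr_mat <- matrix(fdr_mat, nrow = 1)
      lfc_mat <- matrix(lfc_mat, nrow = 1)
    }
    rank_score <- apply(-log10(pmax(fdr_mat, 1e-300)), 1, max)
    dirs <- ifelse(lfc_mat[, 1] > 0, "up", "down")
    ord <- order(-rank_score, cand)
    out <- data.frame(mirna = cand, rank_score = rank_score, direction = dirs,
                      stringsAsFactors = FALSE)
    for (i in seq_len(k)) {
      out[[paste0("lfc_", i)]] <- lfc_mat[, i]
      out[[paste0("fdr_", i)]] <- fdr_mat[, i]
    }
    out <- out[ord, , drop = FALSE]
    # dense rank on the sorted unique scores
    out$rank <- match(out$rank_score, sort(unique(out$rank_score), decreasing = TRUE))
    rownames(out) <- NULL
    out <- out[, c("mirna", "rank", "rank_score", "direction",
                   setdiff(names(out), c("mirna", "rank", "rank_score", "direction")))]
  }
  attr(out, "discordant") <- discordant
  out
}

#' Candidate heatmap matrices
#'
#' Per cohort, the variance-stabilized expression submatrix of the consensus
#' candidates, rows in consensus rank order and columns grouped
#' control-then-case. Optionally row-scaled to z-scores for display.
#'
#' @param candidates consensus table from [consensus_candidates()].
#' @param vst_matrices list of transformed matrices ([vst()] output), one per
#'   cohort.
#' @param sheets list of sample sheets matching `vst_matrices`.
#' @param ref control level of `condition` (first level if NULL).
#' @param zscore row-scale each matrix to mean 0, sd 1.
#' @return list of numeric matrices, one per cohort.
#' @export
candidate_heatmap_matrix <- function(candidates, vst_matrices, sheets,
                                     ref = NULL, zscore = FALSE) {
  if (nrow(candidates) == 0) stop("no candidates to plot")
  lapply(seq_along(vst_matrices), function(i) {
    m <- vst_matrices[[i]]
    sheet <- sheets[[i]]
    missing <- setdiff(candidates$mirna, rownames(m))
    if (length(missing))
      stop("candidate(s) absent from matrix ", i, ": ",
           paste(missing, collapse = ", "))
    cond <- as.factor(sheet$condition)
    if (!is.null(ref)) cond <- stats::relevel(cond, ref = ref)
    ord_samples <- sheet$sample_id[order(cond)]
    sub <- m[candidates$mirna[order(candidates$rank, candidates$mirna)],
             ord_samples, drop = FALSE]
    if (zscore) sub <- t(scale(t(sub)))
    sub
  })
}
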