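.rna_complement <- c(A = "U", C = "G", G = "C", U = "A")

revcomp_rna <- function(s) {
  chars <- strsplit(s, "")[[1]]
  paste(rev(unname(.rna_complement[chars])), collapse = "")
}

check_rna <- function(s, what = "sequence") {
  if (grepl("[^ACGU]", s))
    stop(what, " contains characters outside {A,C,G,U}: ", s)
  invisible(s)
}

#' Seed of a mature miRNA sequence
#'
#' The seed is nucleotides 2-8 (5'->3') of the mature miRNA; its
#' complementarity to a 3'UTR defines canonical target sites.
#'
#' @param mirna_sequence RNA string, 5'->3', length >= 8, alphabet ACGU.
#' @return the 7-letter seed.
#' @export
seed_of <- function(mirna_sequence) {
  check_rna(mirna_sequence, "miRNA sequence")
  if (nchar(mirna_sequence) < 8)
    stop("miRNA sequence must be at least 8 nt to have a seed (positions 2-8)")
  substr(mirna_sequence, 2, 8)
}

#' Group miRNAs into seed families
#'
#' miRNAs sharing an identical seed (positions 2-8) form one family — e.g.
#' the miR-25 family (miR-25-3p/32-5p/92-3p/363-3p/367-3p, seed AUUGCAC).
#' The family label is the lexicographically first member plus "-family",
#' unless `labels` maps a seed to an explicit name.
#'
#' @param mirna_sequences named character vector, identifier -> sequence.
#' @param labels optional named character vector, seed -> family label.
#' @return data.frame with columns `mirna_id`, `seed`, `family`.
#' @export
seed_families <- function(mirna_sequences, labels = NULL) {
  if (length(mirna_sequences) == 0)
    return(data.frame(mirna_id = character(0), seed = character(0),
                      family = character(0), stringsAsFactors = FALSE))
  seeds <- vapply(mirna_sequences, seed_of, character(1))
  fam <- vapply(seeds, function(sd) {
    if (!is.null(labels) && sd %in% names(labels)) return(labels[[sd]])
    paste0(min(sort(names(mirna_sequences)[seeds == sd])), "-family")
  }, character(1))
  data.frame(mirna_id = names(mirna_sequences), seed = unname(seeds),
             family = unname(fam), stringsAsFactors = FALSE, row.names = NULL)
}

#' Scan a 3'UTR for canonical seed-match sites
#'
#' Site motifs are derived from the 7-nt seed (miRNA positions 2-8):
#' 7mer-m8 = reverse complement of the seed (match to positions 2-8);
#' 8mer = 7mer-m8 followed by an A (opposite miRNA position 1);
#' 7mer-A1 = reverse complement of positions 2-7 followed by an A;
#' 6mer = reverse complement of positions 2-7. Every seed-match core
#' (6mer occurrence) is classified once at its highest-priority type
#' (8mer > 7mer-m8 > 7mer-A1 > 6mer); positions are 1-based on the UTR
#' 5'->3' and give the 5'-most matched base of the site motif.
#'
#' @param utr RNA string (T is accepted and treated as U).
#' @param seed 7-letter RNA seed.
#' @return data.frame with columns `start`, `site_type`.
#' @export
scan_sites <- function(utr, seed) {
  utr <- chartr("Tt", "Uu", toupper(utr))
  check_rna(utr, "UTR")
  check_rna(seed, "seed")
  if (nchar(seed) != 7) stop("seed must be exactly 7 nt")
  core6 <- revcomp_rna(substr(seed, 1, 6))     # match to miRNA 2-7
  m8 <- .rna_complement[[substr(seed, 7, 7)]]  # base pairing miRNA position 8
  starts <- integer(0)
  types <- character(0)
  p <- 1L
  n <- nchar(utr)
  repeat {
    hit <- regexpr(core6, substr(utr, p, n), fixed = TRUE)
    if (hit == -1) break
    pos <- p + as.integer(hit) - 1L            # core start, 1-based
    has_m8 <- pos > 1 && substr(utr, pos - 1, pos - 1) == m8
    has_a1 <- pos + 6 <= n && substr(utr, pos + 6, pos + 6) == "A"
    if (has_m8 && has_a1) {
      starts <- c(starts, pos - 1L); types <- c(types, "8mer")
    } else if (has_m8) {
      starts <- c(starts, pos - 1L); types <- c(types, "7mer-m8")
    } else if (has_a1) {
      starts <- c(starts, pos); types <- c(types, "7mer-A1")
    } else {
      starts <- c(starts, pos); types <- c(types, "6mer")
    }
    p <- pos + 1L
  }
  data.frame(start = starts, site_type = types, stringsAsFactors = FALSE)
}

#' Collapse transcript-level predictions to gene level
#'
#' Multiple transcript rows per (family, gene) are collapsed to a single
#' record carrying the minimum (most negative, i.e. strongest) CWCS and the
#' maximum conserved-site count.
#'
#' @param predictions prediction data.frame (see [read_targetscan_table()]).
#' @return data.frame with one row per (mirna_family, gene_id): `cwcs`,
#'   `conserved_sites`.
#' @export
gene_level_predictions <- function(predictions) {
  validate_predictions(predictions)
  if (nrow(predictions) == 0)
    return(data.frame(mirna_family = character(0), gene_id = character(0),
                      cwcs = numeric(0), conserved_sites = integer(0)))
  key <- interaction(predictions$mirna_family, predictions$gene_id, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(predictions)), key), function(ix) {
    data.frame(mirna_family = predictions$mirna_family[ix[1]],
               gene_id = predictions$gene_id[ix[1]],
               cwcs = min(predictions$cwcs[ix]),
               conserved_sites = max(predictions$conserved_sites[ix]),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg[order(agg$mirna_family, agg$gene_id), , drop = FALSE]
}

#' Stratify gene-level predictions by CWCS confidence
#'
#' Records are retained only with CWCS strictly below `retain_below` (-0.2);
#' retained records are tiered "high" when CWCS is strictly below
#' `high_below` (-0.4) and "moderate" otherwise. Both boundaries are strict:
#' a CWCS of exactly -0.2 is dropped and exactly -0.4 is moderate.
#'
#' @param records gene-level records from [gene_level_predictions()].
#' @param retain_below retention boundary (default -0.2).
#' @param high_below high-confidence boundary (default -0.4).
#' @return the retained records with an added `tier` column.
#' @export
tier_predictions <- function(records, retain_below = -0.2, high_below = -0.4) {
  keep <- records$cwcs < retain_below
  out <- records[keep, , drop = FALSE]
  out$tier <- ifelse(out$cwcs < high_below, "high", "moderate")
  rownames(out) <- NULL
  out
}

#' Integrate candidate miRNAs, tiered predictions and down-regulated genes
#'
#' An edge (miRNA, gene) is retained iff the miRNA is an up-regulated
#' consensus candidate, its seed family has a tiered (CWCS < -0.2)
#' prediction for the gene, and the gene is significantly down-regulated in
#' the mRNA data. Candidates with no family mapping contribute no edges and
#' are reported with a warning.
#'
#' @param candidates consensus table from [consensus_candidates()].
#' @param tiered tiered records from [tier_predictions()].
#' @param down_genes character vector of down-regulated gene ids (from
#'   [call_de()] on the mRNA cohort, direction "down").
#' @param family_map data.frame mapping `mirna_id` to `family` (e.g. from
#'   [seed_families()]); if NULL, candidate miRNA ids are assumed to equal
#'   prediction family ids.
#' @return edge data.frame: `mirna_id`, `gene_id`, `cwcs`, `tier`.
#' @export
integrate_targets <- function(candidates, tiered, down_genes, family_map = NULL) {
  up <- candidates$mirna[candidates$direction == "up"]
  if (is.null(family_map)) {
    fam_of <- stats::setNames(up, up)
  } else {
    fam_of <- stats::setNames(family_map$family, family_map$mirna_id)[up]
    names(fam_of) <- up
  }
  unmapped <- up[is.na(fam_of) | !(fam_of %in% tiered$mirna_family)]
  if (length(unmapped))
    warning("candidate(s) with no mapped predictions: ",
            paste(unmapped, collapse = ", "))
  edges <- list()
  for (m in setdiff(up, unmapped)) {
    sub <- tiered[tiered$mirna_family == fam_of[[m]] &
                    tiered$gene_id %in% down_genes, , drop = FALSE]
    if (nrow(sub))
      edges[[m]] <- data.frame(mirna_id = m, gene_id = sub$gene_id,
                               cwcs = sub$cwcs, tier = sub$tier,
                               stringsAsFactors = FALSE)
  }
  out <- if (length(edges)) do.call(rbind, edges) else
    data.frame(mirna_id = character(0), gene_id = character(0),
               cwcs = numeric(0), tier = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  validate_edges(out)
  out
}

#' Ranked target table for one seed family
#'
#' Genes with a tiered prediction (CWCS < -0.2) for the family that are also
#' called down-regulated, sorted by ascending CWCS (strongest predicted
#' repression first) and annotated with conserved-site counts, an
#' experimental-validation flag, and the mRNA fold change and FDR.
#'
#' @param family family identifier present in `tiered$mirna_family`.
#' @param tiered tiered records from [tier_predictions()].
#' @param mrna_de mRNA [wald_test()] table.
#' @param validated character vector of experimentally validated gene ids.
#' @param alpha,min_change calling thresholds for down-regulation.
#' @return data.frame: `rank`, `gene_id`, `cwcs`, `conserved_sites`,
#'   `validated`, `lfc`, `fdr`.
#' @export
ranked_target_table <- function(family, tiered, mrna_de, validated = character(0),
                                alpha = 0.05, min_change = 0.5) {
  if (!family %in% tiered$mirna_family)
    stop("unknown family: ", family)
  down <- call_de(mrna_de, alpha = alpha, min_change = min_change)
  down <- down[down$direction == "down", , drop = FALSE]
  sub <- tiered[tiered$mirna_family == family &
                  tiered$gene_id %in% down$feature_id, , drop = FALSE]
  sub <- sub[order(sub$cwcs, sub$gene_id), , drop = FALSE]
  idx <- match(sub$gene_id, down$feature_id)
  out <- data.frame(rank = seq_len(nrow(sub)), gene_id = sub$gene_id,
                    cwcs = sub$cwcs, conserved_sites = sub$conserved_sites,
                    validated = sub$gene_id %in% validated,
                    lfc = down$lfc[idx], fdr = down$fdr[idx],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
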