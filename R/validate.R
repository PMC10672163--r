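#' Validate a count matrix
#'
#' A count matrix is an integer-valued, non-negative numeric matrix whose
#' rownames are unique feature identifiers (miRNAs or genes) and whose
#' colnames are unique sample identifiers.
#'
#' @param counts a numeric matrix with rownames and colnames.
#' @return the matrix, invisibly, with storage mode coerced to integer-valued
#'   double preserved as-is.
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-integer or negative count at feature '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  invisible(counts)
}

#' Validate a sample sheet
#'
#' @param sheet data.frame with columns `sample_id`, `condition` and
#'   optionally `cohort_id`, `assigned_reads`.
#' @param counts optional count matrix the sheet must describe.
#' @return the sheet, invisibly.
#' @export
validate_sample_sheet <- function(sheet, counts = NULL) {
  if (!is.data.frame(sheet)) stop("sample sheet must be a data.frame")
  need <- c("sample_id", "condition")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  if ("assigned_reads" %in% names(sheet) &&
      any(!is.na(sheet$assigned_reads) & sheet$assigned_reads < 0))
    stop("assigned_reads must be non-negative")
  if (!is.null(counts)) {
    if (!setequal(colnames(counts), sheet$sample_id))
      stop("sample sheet does not match count matrix columns")
  }
  invisible(sheet)
}

#' Validate a table of target predictions
#'
#' @param predictions data.frame with columns `mirna_family`, `gene_id`,
#'   `cwcs`, `conserved_sites` and optionally `transcript_id`.
#' @return the table, invisibly.
#' @export
validate_predictions <- function(predictions) {
  need <- c("mirna_family", "gene_id", "cwcs", "conserved_sites")
  miss <- setdiff(need, names(predictions))
  if (length(miss)) stop("prediction table lacks columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(predictions$cwcs)))
    stop("cwcs must be finite")
  if (any(predictions$conserved_sites < 0))
    stop("conserved_sites must be non-negative")
  invisible(predictions)
}

#' Validate network edges
#'
#' @param edges data.frame with columns `mirna_id`, `gene_id`, `cwcs`, `tier`.
#' @return the edges, invisibly.
#' @export
validate_edges <- function(edges) {
  need <- c("mirna_id", "gene_id", "cwcs", "tier")
  miss <- setdiff(need, names(edges))
  if (length(miss)) stop("edge table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(edges) == 0) return(invisible(edges))
  if (!all(edges$tier %in% c("high", "moderate")))
    stop("tier must be 'high' or 'moderate'")
  dup <- duplicated(edges[c("mirna_id", "gene_id")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicate edge %s -> %s", edges$mirna_id[i], edges$gene_id[i]))
  }
  invisible(edges)
}
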