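#' Read a count matrix from TSV or MatrixMarket files
#'
#' TSV layout: header row of sample identifiers, first column feature
#' identifiers, integer cells. MTX layout: a MatrixMarket triplet file plus
#' `<stem>.features.txt` and `<stem>.samples.txt` label sidecars (one
#' identifier per line). If a sidecar sample sheet `<stem>.samples.tsv`
#' exists next to a TSV matrix it is read and attached as
#' `attr(, "sample_sheet")`.
#'
#' @param path path to the matrix file.
#' @param format `"tsv"` or `"mtx"`.
#' @return an integer count matrix (features x samples) with identifiers in
#'   file order; possibly with a `sample_sheet` attribute.
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character")
    feats <- tab[[1]]
    body <- tab[-1]
    suppressWarnings(num <- vapply(body, as.numeric, numeric(nrow(tab))))
    if (nrow(tab) == 1) num <- matrix(num, nrow = 1)
    bad <- which(is.na(num) | num != round(num) | num < 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-integer count '%s' at feature '%s', sample '%s'",
                   body[bad[1, 1], bad[1, 2]], feats[bad[1, 1]],
                   names(body)[bad[1, 2]]))
    counts <- num
    dimnames(counts) <- list(feats, names(body))
  } else {
    m <- Matrix::readMM(path)
    stem <- sub("\\.mtx(\\.gz)?$", "", path)
    ff <- paste0(stem, ".features.txt")
    sf <- paste0(stem, ".samples.txt")
    if (!file.exists(ff) || !file.exists(sf))
      stop("MTX label sidecars not found: ", ff, " / ", sf)
    counts <- as.matrix(m)
    dimnames(counts) <- list(readLines(ff), readLines(sf))
  }
  validate_count_matrix(counts)
  sheet_path <- paste0(sub("\\.(tsv|txt)$", "", path), ".samples.tsv")
  if (format == "tsv" && file.exists(sheet_path)) {
    attr(counts, "sample_sheet") <- read_sample_sheet(sheet_path)
  }
  counts
}

#' Write a count matrix as TSV
#'
#' @param counts validated count matrix.
#' @param path output path.
#' @param id_column header for the feature-identifier column.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path, id_column = "feature_id") {
  validate_count_matrix(counts)
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet TSV
#'
#' Expected columns: `sample_id`, `condition`, optionally `cohort_id` and
#' `assigned_reads`.
#'
#' @param path path to a TSV file.
#' @return a validated sample sheet data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
  sheet
}

#' Write a sample sheet TSV
#'
#' @param sheet sample sheet data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TargetScan-style prediction table
#'
#' Two dialects are supported. `"targetscan8"` expects the tab-separated
#' context++ score layout: the gene-symbol, transcript and miRNA-family
#' columns are located by name (case-insensitive) and the cumulative weighted
#' context++ score column by a name containing "context++" or "cwcs".
#' `"simple"` expects the five columns `mirna_family`, `gene_id`,
#' `transcript_id`, `cwcs`, `conserved_sites` by name. Gzipped files are
#' accepted. Rows with an empty CWCS cell are dropped; the number dropped is
#' recorded in `attr(, "dropped_rows")` and reported via [message()].
#'
#' @param path path to the TSV (optionally `.gz`).
#' @param dialect `"targetscan8"` or `"simple"`.
#' @return data.frame of predictions (one row per input row retained).
#' @export
read_targetscan_table <- function(path, dialect = c("targetscan8", "simple")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  tab <- utils::read.delim(con, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  lower <- tolower(names(tab))
  pick <- function(patterns, what) {
    for (p in patterns) {
      hit <- grep(p, lower)
      if (length(hit)) return(hit[1])
    }
    stop(sprintf("missing mandatory column (%s); expected one of: %s; found: %s",
                 what, paste(patterns, collapse = ", "),
                 paste(names(tab), collapse = ", ")))
  }
  if (dialect == "simple") {
    need <- c("mirna_family", "gene_id", "transcript_id", "cwcs", "conserved_sites")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
           "; expected: ", paste(need, collapse = ", "))
    out <- tab[need]
  } else {
    gi <- pick(c("^gene symbol$", "gene.?symbol", "^gene"), "gene symbol")
    ti <- pick(c("transcript"), "transcript id")
    mi <- pick(c("mirna family", "mir.?na", "family"), "miRNA family")
    ci <- pick(c("cumulative weighted context\\+\\+", "context\\+\\+", "cwcs"),
               "cumulative weighted context++ score")
    si <- grep("conserved site|number of.*site", lower)
    out <- data.frame(mirna_family = tab[[mi]], gene_id = tab[[gi]],
                      transcript_id = tab[[ti]],
                      cwcs = tab[[ci]],
                      conserved_sites = if (length(si)) tab[[si[1]]] else 0L,
                      stringsAsFactors = FALSE)
  }
  suppressWarnings(out$cwcs <- as.numeric(out$cwcs))
  suppressWarnings(out$conserved_sites <- as.integer(out$conserved_sites))
  drop <- is.na(out$cwcs)
  if (any(drop)) message(sum(drop), " prediction row(s) dropped (empty CWCS)")
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  validate_predictions(out)
  attr(out, "dropped_rows") <- sum(drop)
  out
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: per line a term identifier, a description, then one or more
#' gene identifiers, tab-separated. Duplicate genes within a line are
#' de-duplicated.
#'
#' @param path path to GMT file.
#' @return a list of gene sets; each element is a list with `term_id`,
#'   `term_name`, `genes` (unique character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT parse error at line %d: fewer than 3 fields", i))
    out[[i]] <- list(term_id = f[1], term_name = f[2], genes = unique(f[-(1:2)]))
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets list of gene sets as returned by [read_gmt()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$term_id, s$term_name, s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a miRNA-mRNA network to disk
#'
#' Edge-list TSV columns are exactly `mirna`, `gene`, `cwcs`, `tier`.
#' GraphML output carries node attributes `kind` (mirna/gene) and, for gene
#' nodes, `size` = max |CWCS| over incident edges, plus an edge attribute
#' `cwcs`. Output is byte-stable for a fixed input edge order.
#'
#' @param edges edge data.frame (`mirna_id`, `gene_id`, `cwcs`, `tier`).
#' @param path output path.
#' @param format `"edgelist_tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path, format = c("edgelist_tsv", "graphml")) {
  format <- match.arg(format)
  validate_edges(edges)
  if (format == "edgelist_tsv") {
    df <- data.frame(mirna = edges$mirna_id, gene = edges$gene_id,
                     cwcs = edges$cwcs, tier = edges$tier,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- build_network(edges)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network edge list written by [write_network()]
#'
#' @param path edge-list TSV path.
#' @return edge data.frame with columns `mirna_id`, `gene_id`, `cwcs`, `tier`.
#' @export
read_network_edges <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  edges <- data.frame(mirna_id = as.character(df$mirna),
                      gene_id = as.character(df$gene),
                      cwcs = as.numeric(df$cwcs), tier = as.character(df$tier),
                      stringsAsFactors = FALSE)
  validate_edges(edges)
  edges
}

#' Read sequences from a FASTA file
#'
#' Minimal plain-text FASTA reader for 3'UTR fixtures; keeps the RNA/DNA
#' alphabet exactly as written (no coercion).
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("not a FASTA file: ", path)
  id <- cumsum(hdr)
  names_ <- sub("^>\\s*", "", lines[hdr])
  names_ <- sub("\\s.*$", "", names_)
  seqs <- vapply(split(lines[!hdr], id[!hdr]), paste, character(1), collapse = "")
  names(seqs) <- names_
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
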