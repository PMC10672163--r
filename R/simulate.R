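#' Simulation configuration
#'
#' Defaults emulate the study conditions of the motor-neuron profiling
#' design: two independent miRNA cohorts (5 vs 5 and 4 vs 4 samples), an
#' mRNA cohort of 5 control vs 4 case samples, 24 planted up-regulated
#' miRNAs with |log2 fold change| 2.5, negative-binomial noise with
#' dispersion 0.1 (variance mu + alpha mu^2), baseline means log-uniform in
#' [100, 2000], and a prediction table whose true edges carry CWCS in
#' [-0.9, -0.5] while decoys sit in [-0.15, -0.01], so the CWCS < -0.2
#' retention boundary separates them.
#'
#' @param seed integer RNG seed; every generator output is a deterministic
#'   function of it (separate substreams per output).
#' @param n_mirna number of miRNA features.
#' @param n_gene number of genes.
#' @param n_per_group samples per condition, one entry per miRNA cohort.
#' @param n_mrna_per_group c(control, case) samples in the mRNA cohort.
#' @param mean_range baseline NB mean range (log-uniform draw).
#' @param dispersion NB dispersion alpha.
#' @param n_planted number of planted deregulated miRNAs.
#' @param planted_lfc log2 fold change planted in case samples (shared
#'   across cohorts; the cross-cohort consistency is the signal).
#' @param target_density fraction of genes assigned as true targets of each
#'   planted up-regulated miRNA.
#' @param silencing_lfc negative log2 fold change applied to true targets in
#'   case samples.
#' @param cwcs_true_range,cwcs_decoy_range CWCS intervals for true and decoy
#'   predictions.
#' @param decoys_per_mirna decoy predictions per planted miRNA.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_mirna = 200L,
                       n_gene = 2000L,
                       n_per_group = c(5L, 4L),
                       n_mrna_per_group = c(5L, 4L),
                       mean_range = c(100, 2000),
                       dispersion = 0.1,
                       n_planted = 24L,
                       planted_lfc = 2.5,
                       target_density = 0.015,
                       silencing_lfc = -2.5,
                       cwcs_true_range = c(-0.9, -0.5),
                       cwcs_decoy_range = c(-0.15, -0.01),
                       decoys_per_mirna = 30L) {
  stopifnot(is.finite(planted_lfc), is.finite(silencing_lfc),
            target_density > 0, target_density <= 1,
            dispersion > 0, all(mean_range > 0))
  cfg <- list(seed = as.integer(seed), n_mirna = as.integer(n_mirna),
              n_gene = as.integer(n_gene),
              n_per_group = as.integer(n_per_group),
              n_mrna_per_group = as.integer(n_mrna_per_group),
              mean_range = mean_range, dispersion = dispersion,
              n_planted = as.integer(n_planted), planted_lfc = planted_lfc,
              target_density = target_density, silencing_lfc = silencing_lfc,
              cwcs_true_range = cwcs_true_range,
              cwcs_decoy_range = cwcs_decoy_range,
              decoys_per_mirna = as.integer(decoys_per_mirna))
  class(cfg) <- "sim_config"
  cfg
}

# Separate RNG substream per output: seeding with seed + a fixed offset
# keeps each generator's stream independent of the others, so adding an
# output does not shift existing ones. Offsets stay below 2^31.
.sim_seed <- function(cfg, offset) {
  set.seed((cfg$seed %% 2000000000L) + offset)
}

rnbinom_mu <- function(n, mu, alpha) {
  # NB with variance mu + alpha mu^2 (size = 1/alpha)
  stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

#' Simulate two independent miRNA cohorts
#'
#' Counts are drawn NB(mean * 2^(lfc * case), dispersion) independently per
#' cohort; the planted deregulated miRNAs share their effect across cohorts
#' (non-planted miRNAs have log2 fold change 0). Sample sheets carry
#' cohort ids, conditions (healthy control vs EAE case) and assigned-read
#' totals above the QC threshold.
#'
#' @param cfg configuration from [sim_config()].
#' @return list with `cohorts` (each a list of `counts` + `sheet`) and
#'   `truth` (data.frame `mirna_id`, `lfc` of planted miRNAs).
#' @export
simulate_mirna_cohorts <- function(cfg) {
  if (any(cfg$n_per_group < 2))
    stop("need at least 2 samples per group per cohort")
  .sim_seed(cfg, 101L)
  mirnas <- sprintf("miR-sim-%03d", seq_len(cfg$n_mirna))
  mu0 <- exp(stats::runif(cfg$n_mirna, log(cfg$mean_range[1]),
                          log(cfg$mean_range[2])))
  planted <- if (cfg$n_planted > 0)
    sort(sample(mirnas, cfg$n_planted)) else character(0)
  lfc <- stats::setNames(rep(0, cfg$n_mirna), mirnas)
  lfc[planted] <- cfg$planted_lfc
  cohorts <- lapply(seq_along(cfg$n_per_group), function(ci) {
    n <- cfg$n_per_group[ci]
    condition <- rep(c("control", "case"), each = n)
    mu <- mu0 * 2^outer(lfc, as.numeric(condition == "case"))
    counts <- matrix(rnbinom_mu(length(mu), mu, cfg$dispersion),
                     nrow = cfg$n_mirna)
    dimnames(counts) <- list(mirnas,
                             sprintf("c%d_s%02d", ci, seq_len(2 * n)))
    sheet <- data.frame(sample_id = colnames(counts),
                        cohort_id = paste0("cohort", ci),
                        condition = condition,
                        assigned_reads = round(stats::runif(2 * n, 2e6, 8e6)),
                        stringsAsFactors = FALSE)
    list(counts = counts, sheet = sheet)
  })
  list(cohorts = cohorts,
       truth = data.frame(mirna_id = planted,
                          lfc = rep(cfg$planted_lfc, length(planted)),
                          stringsAsFactors = FALSE))
}

#' Simulate an mRNA cohort with planted miRNA targets
#'
#' Each planted up-regulated miRNA is assigned `target_density * n_gene`
#' true target genes; in case samples those genes receive `silencing_lfc`
#' (down-regulation, as expected under effective miRNA-mediated silencing).
#' The returned prediction table contains every true edge with a CWCS drawn
#' from `cwcs_true_range` and 1-4 conserved sites, plus decoy edges to
#' non-regulated genes with CWCS from `cwcs_decoy_range`.
#'
#' @param cfg configuration from [sim_config()].
#' @param truth planted-miRNA truth table from [simulate_mirna_cohorts()].
#' @return list: `counts`, `sheet`, `predictions`, `truth` (data.frame of
#'   true edges `mirna_id`, `gene_id`, `cwcs`).
#' @export
simulate_mrna_with_targets <- function(cfg, truth) {
  n_targets <- round(cfg$target_density * cfg$n_gene)
  if (n_targets < 1)
    stop("target_density * n_gene < 1: no targets to plant")
  .sim_seed(cfg, 202L)
  genes <- sprintf("Gene%04d", seq_len(cfg$n_gene))
  mu0 <- exp(stats::runif(cfg$n_gene, log(cfg$mean_range[1]),
                          log(cfg$mean_range[2])))
  up <- truth$mirna_id[truth$lfc > 0]
  edges <- do.call(rbind, lapply(up, function(m)
    data.frame(mirna_id = m, gene_id = sample(genes, n_targets),
               stringsAsFactors = FALSE)))
  if (is.null(edges))
    edges <- data.frame(mirna_id = character(0), gene_id = character(0))
  edges$cwcs <- stats::runif(nrow(edges), cfg$cwcs_true_range[1],
                             cfg$cwcs_true_range[2])
  silenced <- unique(edges$gene_id)
  glfc <- stats::setNames(rep(0, cfg$n_gene), genes)
  if (cfg$silencing_lfc != 0) glfc[silenced] <- cfg$silencing_lfc
  n_ctrl <- cfg$n_mrna_per_group[1]
  n_case <- cfg$n_mrna_per_group[2]
  condition <- c(rep("control", n_ctrl), rep("case", n_case))
  mu <- outer(mu0, rep(1, n_ctrl + n_case))
  mu[, condition == "case"] <- mu0 * 2^glfc
  counts <- matrix(rnbinom_mu(length(mu), mu, cfg$dispersion),
                   nrow = cfg$n_gene)
  dimnames(counts) <- list(genes, sprintf("m_s%02d", seq_len(n_ctrl + n_case)))
  sheet <- data.frame(sample_id = colnames(counts), cohort_id = "mrna",
                      condition = condition,
                      assigned_reads = round(stats::runif(n_ctrl + n_case, 2e6, 8e6)),
                      stringsAsFactors = FALSE)
  # prediction table: true edges + decoys pointing at non-silenced genes
  true_pred <- data.frame(mirna_family = edges$mirna_id, gene_id = edges$gene_id,
                          transcript_id = paste0("T-", edges$gene_id),
                          cwcs = edges$cwcs,
                          conserved_sites = sample(1:4, nrow(edges), replace = TRUE),
                          stringsAsFactors = FALSE)
  decoy_pool <- setdiff(genes, silenced)
  decoys <- do.call(rbind, lapply(up, function(m)
    data.frame(mirna_family = m,
               gene_id = sample(decoy_pool, min(cfg$decoys_per_mirna,
                                                length(decoy_pool))),
               stringsAsFactors = FALSE)))
  if (!is.null(decoys)) {
    decoys$transcript_id <- paste0("T-", decoys$gene_id)
    decoys$cwcs <- stats::runif(nrow(decoys), cfg$cwcs_decoy_range[1],
                                cfg$cwcs_decoy_range[2])
    decoys$conserved_sites <- sample(0:2, nrow(decoys), replace = TRUE)
    predictions <- rbind(true_pred, decoys)
  } else predictions <- true_pred
  rownames(predictions) <- NULL
  list(counts = counts, sheet = sheet, predictions = predictions,
       truth = edges)
}

#' Simulate 3'UTR sequences with planted seed-match sites
#'
#' Random-background UTRs (uniform ACGU, lengths 200-2000) with sites for
#' the given seeds planted at random positions. The returned truth is the
#' post-scan site list ([scan_sites()] over the finished sequences), so it
#' includes chance background sites as well as the planted ones and
#' scanner tests can assert exact set equality.
#'
#' @param cfg configuration (only `seed` is used).
#' @param seeds character vector of 7-mer RNA seeds.
#' @param n_utr number of UTRs.
#' @param sites_per_utr planted sites per UTR.
#' @return list: `utrs` (named character vector), `truth` (data.frame
#'   `utr_id`, `seed`, `start`, `site_type`).
#' @export
simulate_utrs <- function(cfg, seeds, n_utr = 50L, sites_per_utr = 2L) {
  for (s in seeds) {
    check_rna(s, "seed")
    if (nchar(s) != 7) stop("seeds must be 7-mers")
  }
  .sim_seed(cfg, 303L)
  site_types <- c("8mer", "7mer-m8", "7mer-A1")
  utrs <- character(n_utr)
  names(utrs) <- sprintf("UTR%04d", seq_len(n_utr))
  for (i in seq_len(n_utr)) {
    len <- sample(200:2000, 1)
    sq <- paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
                collapse = "")
    for (k in seq_len(sites_per_utr)) {
      sd <- sample(seeds, 1)
      ty <- sample(site_types, 1)
      motif <- switch(ty,
                      "8mer" = paste0(revcomp_rna(sd), "A"),
                      "7mer-m8" = revcomp_rna(sd),
                      "7mer-A1" = paste0(revcomp_rna(substr(sd, 1, 6)), "A"))
      pos <- sample(seq_len(len - nchar(motif) + 1), 1)
      substr(sq, pos, pos + nchar(motif) - 1) <- motif
    }
    utrs[i] <- sq
  }
  truth <- do.call(rbind, lapply(names(utrs), function(u) {
    per_seed <- do.call(rbind, lapply(seeds, function(sd) {
      hits <- scan_sites(utrs[[u]], sd)
      if (nrow(hits) == 0) return(NULL)
      data.frame(utr_id = u, seed = sd, hits, stringsAsFactors = FALSE)
    }))
    per_seed
  }))
  if (is.null(truth))
    truth <- data.frame(utr_id = character(0), seed = character(0),
                        start = integer(0), site_type = character(0))
  list(utrs = utrs, truth = truth)
}

#' Simulate assay fixtures with planted effects
#'
#' Generates (i) qPCR Ct triplicates with technical SD ~0.2 cycles and a
#' planted ddCt between groups, (ii) real-time viability traces decaying
#' exponentially toward planted plateaus for vehicle, death-control and
#' treated wells, and (iii) EAE daily clinical scores on the
#' 0/1/2/3/3.5/4/5 scale with a planted group shift, randomly missing days
#' and a configurable number of symptom-free animals (to exercise
#' exclusion).
#'
#' @param cfg configuration (seed, used for substreams).
#' @param planted_ddct ddCt planted in the treated group (RQ = 2^-ddct).
#' @param n_per_group qPCR samples per group.
#' @param eae_shift additive shift of the case group's latent disease
#'   severity (0 = null).
#' @param n_animals animals per EAE group.
#' @param n_symptom_free all-zero animals appended per group.
#' @param missing_frac fraction of EAE animal-days set missing.
#' @return list: `ct` (CtRecord rows), `viability` (trace rows), `eae`
#'   (score rows), `truth` (list of the planted parameters).
#' @export
simulate_assays <- function(cfg, planted_ddct = -1, n_per_group = 4L,
                            eae_shift = 1, n_animals = 8L,
                            n_symptom_free = 1L, missing_frac = 0.05) {
  .sim_seed(cfg, 404L)
  # --- qPCR ---
  ct <- do.call(rbind, lapply(seq_len(2 * n_per_group), function(i) {
    grp <- if (i <= n_per_group) "control" else "treated"
    dd <- if (grp == "treated") planted_ddct else 0
    ref_ct <- 20 + stats::rnorm(1, 0, 0.3)
    target_ct <- ref_ct + 5 + dd + stats::rnorm(1, 0, 0.1)
    rbind(data.frame(sample_id = paste0("q", i), group = grp, assay = "target",
                     ct = target_ct + stats::rnorm(3, 0, 0.2)),
          data.frame(sample_id = paste0("q", i), group = grp, assay = "reference",
                     ct = ref_ct + stats::rnorm(3, 0, 0.2)))
  }))
  # --- viability traces ---
  times <- c(5, seq(12, 72, by = 12))
  plateau <- c(vehicle = 1.0, death = 0.1, treated = 0.6)
  viab <- do.call(rbind, lapply(names(plateau), function(g)
    do.call(rbind, lapply(1:3, function(w) {
      gain <- stats::runif(1, 0.5, 2)    # per-well multiplicative gain
      rel <- plateau[[g]] + (1 - plateau[[g]]) * exp(-(times - 5) / 24)
      data.frame(well_id = paste0(g, w), group = g, time = times,
                 luminescence = gain * rel * exp(stats::rnorm(length(times), 0, 0.02)),
                 stringsAsFactors = FALSE)
    }))))
  # --- EAE scores ---
  scale_pts <- c(0, 1, 2, 3, 3.5, 4, 5)
  days <- 1:28
  make_animal <- function(id, grp, severity) {
    onset <- sample(10:14, 1)
    peak_day <- onset + sample(4:7, 1)
    latent <- ifelse(days < onset, 0,
                     pmin(severity, severity * (days - onset) / (peak_day - onset)))
    latent <- pmax(0, latent - pmax(0, (days - peak_day - 5) * 0.1))
    latent <- latent + stats::rnorm(length(days), 0, 0.3)
    score <- vapply(latent, function(v) scale_pts[which.min(abs(scale_pts - v))],
                    numeric(1))
    data.frame(animal_id = id, group = grp, day = days, score = score,
               stringsAsFactors = FALSE)
  }
  eae <- rbind(
    do.call(rbind, lapply(seq_len(n_animals), function(i)
      make_animal(paste0("ctrl", i), "control", stats::runif(1, 1.5, 2.5)))),
    do.call(rbind, lapply(seq_len(n_animals), function(i)
      make_animal(paste0("case", i), "case",
                  stats::runif(1, 1.5, 2.5) + eae_shift))))
  if (n_symptom_free > 0) {
    zero <- do.call(rbind, lapply(seq_len(n_symptom_free), function(i)
      rbind(data.frame(animal_id = paste0("ctrlz", i), group = "control",
                       day = days, score = 0),
            data.frame(animal_id = paste0("casez", i), group = "case",
                       day = days, score = 0))))
    eae <- rbind(eae, zero)
  }
  n_missing <- round(missing_frac * nrow(eae))
  if (n_missing > 0) {
    # never blank a whole group-day: keep at least one observed score
    cand <- sample(seq_len(nrow(eae)), n_missing)
    eae$score[cand] <- NA
  }
  list(ct = ct, viability = viab, eae = eae,
       truth = list(planted_ddct = planted_ddct, eae_shift = eae_shift,
                    plateau = plateau,
                    n_symptom_free = if (n_symptom_free > 0) 2L * n_symptom_free else 0L))
}

#' Write a full set of simulated fixtures to a directory
#'
#' Runs all generators under one configuration and writes every output in
#' the package's interchange formats (TSV matrices and sheets, simple-
#' dialect prediction TSV, FASTA UTRs, tidy assay TSVs) plus truth TSVs.
#'
#' @param cfg configuration from [sim_config()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
simulate_to_dir <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mi <- simulate_mirna_cohorts(cfg)
  for (i in seq_along(mi$cohorts)) {
    write_count_matrix(mi$cohorts[[i]]$counts,
                       file.path(outdir, sprintf("mirna_cohort%d.tsv", i)))
    write_sample_sheet(mi$cohorts[[i]]$sheet,
                       file.path(outdir, sprintf("mirna_cohort%d.samples.tsv", i)))
  }
  mr <- simulate_mrna_with_targets(cfg, mi$truth)
  write_count_matrix(mr$counts, file.path(outdir, "mrna.tsv"))
  write_sample_sheet(mr$sheet, file.path(outdir, "mrna.samples.tsv"))
  utils::write.table(mr$predictions, file.path(outdir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(mi$truth, file.path(outdir, "truth_mirna.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(mr$truth, file.path(outdir, "truth_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ut <- simulate_utrs(cfg, seeds = "AUUGCAC")
  write_fasta(ut$utrs, file.path(outdir, "utrs.fa"))
  utils::write.table(ut$truth, file.path(outdir, "truth_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  as_ <- simulate_assays(cfg)
  utils::write.table(as_$ct, file.path(outdir, "ct.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as_$viability, file.path(outdir, "viability.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as_$eae, file.path(outdir, "eae.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
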