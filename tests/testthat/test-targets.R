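test_that("the seed is miRNA positions 2-8", {
  expect_equal(seed_of("UAUUGCACUUGUCCCGGCCUGU"), "AUUGCAC")  # miR-92a-3p
  expect_equal(seed_of("AAAAAAAA"), "AAAAAAA")
  expect_error(seed_of("AUUGCAC"), "at least 8")
  expect_error(seed_of("AUUGCACTT"), "A,C,G,U")
})

test_that("miRNAs sharing a seed form one family", {
  seqs <- c("miR-92a-3p" = "UAUUGCACUUGUCCCGGCCUGU",
            "miR-25-3p" = "CAUUGCACUUGUCUCGGUCUGA",
            "miR-999" = "UCCCCCCCCCC")
  fam <- seed_families(seqs)
  expect_equal(fam$seed[fam$mirna_id == "miR-25-3p"], "AUUGCAC")
  shared <- fam$family[fam$seed == "AUUGCAC"]
  expect_length(unique(shared), 1)
  expect_equal(unique(shared), "miR-25-3p-family")
  expect_equal(sum(fam$seed == "AUUGCAC"), 2)
  expect_equal(nrow(seed_families(c())), 0)
  labeled <- seed_families(seqs, labels = c(AUUGCAC = "miR-25 family"))
  expect_equal(unique(labeled$family[labeled$seed == "AUUGCAC"]), "miR-25 family")
})

test_that("the canonical 8mer example is found at its planted position", {
  hits <- scan_sites("AAGUGCAAUAAA", "AUUGCAC")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 3L)
  expect_equal(hits$site_type, "8mer")
})

test_that("site classification distinguishes all four canonical types", {
  seed <- "AUUGCAC"           # core match GUGCAAU (m8 = G), 6mer core UGCAAU
  expect_equal(scan_sites("CCGUGCAAUACC", seed)$site_type, "8mer")
  expect_equal(scan_sites("CCGUGCAAUCCC", seed)$site_type, "7mer-m8")
  expect_equal(scan_sites("CCUUGCAAUACC", seed)$site_type, "7mer-A1")
  expect_equal(scan_sites("CCUUGCAAUCCC", seed)$site_type, "6mer")
  expect_equal(nrow(scan_sites(strrep("C", 50), seed)), 0)
})

test_that("a site planted in a homopolymer background is reported exactly once", {
  utr <- strrep("C", 200)
  substr(utr, 50, 57) <- "GUGCAAUA"
  hits <- scan_sites(utr, "AUUGCAC")
  expect_equal(hits, data.frame(start = 50L, site_type = "8mer",
                                stringsAsFactors = FALSE))
})

test_that("the scanner matches the brute-force oracle on random UTRs", {
  set.seed(51)
  seeds <- c("AUUGCAC", "UUUUUUU", "ACGUACG")
  for (i in 1:60) {
    utr <- random_rna(sample(50:400, 1))
    sd_ <- sample(seeds, 1)
    got <- scan_sites(utr, sd_)
    want <- brute_scan(utr, sd_)
    expect_equal(got$start, want$start)
    expect_equal(got$site_type, want$site_type)
  }
})

test_that("gene-level collapsing keeps the strongest CWCS and the most sites", {
  pred <- data.frame(mirna_family = "miR-25-3p", gene_id = "Cpeb3",
                     transcript_id = c("T1", "T2"), cwcs = c(-0.3, -0.82),
                     conserved_sites = c(1L, 4L), stringsAsFactors = FALSE)
  g <- gene_level_predictions(pred)
  expect_equal(nrow(g), 1)
  expect_equal(g$cwcs, -0.82)
  expect_equal(g$conserved_sites, 4L)
  expect_equal(gene_level_predictions(pred[1, ])$cwcs, -0.3)
})

test_that("gene-level collapsing equals a brute-force group-by", {
  set.seed(52)
  pred <- data.frame(
    mirna_family = sample(c("fA", "fB"), 60, TRUE),
    gene_id = sample(paste0("g", 1:10), 60, TRUE),
    transcript_id = paste0("t", 1:60),
    cwcs = round(runif(60, -1, 0), 3),
    conserved_sites = sample(0:5, 60, TRUE), stringsAsFactors = FALSE)
  g <- gene_level_predictions(pred)
  manual <- aggregate(cbind(cwcs, conserved_sites) ~ mirna_family + gene_id,
                      data = pred,
                      FUN = function(x) x[1])  # placeholder frame
  for (i in seq_len(nrow(g))) {
    sel <- pred$mirna_family == g$mirna_family[i] & pred$gene_id == g$gene_id[i]
    expect_equal(g$cwcs[i], min(pred$cwcs[sel]))
    expect_equal(g$conserved_sites[i], max(pred$conserved_sites[sel]))
  }
  expect_equal(nrow(g), nrow(manual))
})

test_that("tiering uses strict boundaries at -0.2 and -0.4", {
  rec <- data.frame(mirna_family = "f", gene_id = paste0("g", 1:4),
                    cwcs = c(-0.82, -0.2, -0.4, -0.25),
                    conserved_sites = 1L, stringsAsFactors = FALSE)
  t <- tier_predictions(rec)
  expect_false("g2" %in% t$gene_id)                         # exactly -0.2 dropped
  expect_equal(t$tier[t$gene_id == "g1"], "high")           # -0.82
  expect_equal(t$tier[t$gene_id == "g3"], "moderate")       # exactly -0.4
  expect_equal(t$tier[t$gene_id == "g4"], "moderate")
  expect_true(all(t$tier %in% c("high", "moderate")))
  expect_equal(anyDuplicated(t[c("mirna_family", "gene_id")]), 0)
})

test_that("integration keeps only candidate-family edges to down genes", {
  cand <- data.frame(mirna = c("mUp", "mDown", "mWeak"), rank = 1:3,
                     rank_score = 3:1, direction = c("up", "down", "up"),
                     stringsAsFactors = FALSE)
  tiered <- data.frame(mirna_family = c("mUp", "mUp", "mDown"),
                       gene_id = c("gA", "gB", "gC"),
                       cwcs = c(-0.5, -0.3, -0.6),
                       conserved_sites = 1L,
                       tier = c("high", "moderate", "high"),
                       stringsAsFactors = FALSE)
  expect_warning(edges <- integrate_targets(cand, tiered, c("gA", "gC")),
                 "mWeak")
  expect_equal(edges$gene_id, "gA")        # gB not down; mDown not up-regulated
  expect_equal(edges$tier, "high")
  expect_equal(nrow(suppressWarnings(
    integrate_targets(cand, tiered, character(0)))), 0)
})

test_that("integration output is contained in the tiered prediction set", {
  set.seed(53)
  cfg <- sim_config(seed = 53, n_mirna = 60, n_gene = 400, n_planted = 6L,
                    target_density = 0.02)
  mi <- simulate_mirna_cohorts(cfg)
  mr <- simulate_mrna_with_targets(cfg, mi$truth)
  res <- run_pipeline(mi$cohorts, mr, mr$predictions)
  gl <- gene_level_predictions(mr$predictions)
  key <- function(a, b) paste(a, b)
  expect_true(all(key(res$edges$mirna_id, res$edges$gene_id) %in%
                    key(res$tiered$mirna_family, res$tiered$gene_id)))
  expect_true(all(key(res$tiered$mirna_family, res$tiered$gene_id) %in%
                    key(gl$mirna_family, gl$gene_id)))
})

test_that("separated CWCS ranges make tiering recover exactly the true edges", {
  cfg <- sim_config(seed = 54, n_mirna = 60, n_gene = 400, n_planted = 6L,
                    target_density = 0.02)
  mi <- simulate_mirna_cohorts(cfg)
  mr <- simulate_mrna_with_targets(cfg, mi$truth)
  tiered <- tier_predictions(gene_level_predictions(mr$predictions))
  expect_setequal(paste(tiered$mirna_family, tiered$gene_id),
                  paste(mr$truth$mirna_id, mr$truth$gene_id))
})

test_that("ranked target tables sort by ascending CWCS with annotations", {
  tiered <- data.frame(mirna_family = "miR-25-3p-family",
                       gene_id = c("Gna", "Cpeb3", "Gnb"),
                       cwcs = c(-0.5, -0.82, -0.3), conserved_sites = c(1L, 4L, 2L),
                       tier = c("high", "high", "moderate"),
                       stringsAsFactors = FALSE)
  de <- fake_de(c("Gna", "Cpeb3", "Gnb", "Gnc"),
                lfc = c(-1, -1.2, -0.9, -2), fdr = rep(1e-4, 4))
  tab <- ranked_target_table("miR-25-3p-family", tiered, de,
                             validated = "Cpeb3")
  expect_equal(tab$gene_id[1], "Cpeb3")            # most negative CWCS first
  expect_equal(tab$rank, 1:3)
  expect_true(tab$validated[tab$gene_id == "Cpeb3"])
  expect_false(any(tab$validated[tab$gene_id != "Cpeb3"]))
  expect_equal(tab$cwcs, sort(tab$cwcs))
  tab2 <- ranked_target_table("miR-25-3p-family", tiered, de)
  expect_false(any(tab2$validated))
  expect_error(ranked_target_table("nope", tiered, de), "unknown family")
})

test_that("ranked table ordering equals a brute-force sort", {
  set.seed(55)
  genes <- paste0("g", 1:30)
  tiered <- data.frame(mirna_family = "fam", gene_id = genes,
                       cwcs = round(runif(30, -1, -0.21), 4),
                       conserved_sites = sample(1:4, 30, TRUE), tier = "high",
                       stringsAsFactors = FALSE)
  de <- fake_de(genes, lfc = runif(30, -3, -1), fdr = rep(1e-5, 30))
  tab <- ranked_target_table("fam", tiered, de)
  o <- order(tiered$cwcs, tiered$gene_id)
  expect_equal(tab$gene_id, tiered$gene_id[o])
})
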