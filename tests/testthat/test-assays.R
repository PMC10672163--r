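ct_fixture <- function(ct_target_ctrl = 25, ct_target_trt = 24,
                       ct_ref = 20, reps = 1) {
  rows <- function(sid, grp, assay, ct)
    data.frame(sample_id = sid, group = grp, assay = assay,
               ct = rep(ct, reps), stringsAsFactors = FALSE)
  rbind(rows("c1", "control", "target", ct_target_ctrl),
        rows("c1", "control", "reference", ct_ref),
        rows("t1", "treated", "target", ct_target_trt),
        rows("t1", "treated", "reference", ct_ref))
}

test_that("a one-cycle target shift gives a relative quantity of 2", {
  rq <- ddct(ct_fixture(), "target", "reference", "control")
  expect_equal(rq$rq[rq$sample_id == "t1"], 2)
  expect_equal(rq$rq[rq$sample_id == "c1"], 1)
})

test_that("identical samples all have RQ 1 and triplicates act through their mean", {
  same <- ct_fixture(ct_target_trt = 25)
  expect_equal(ddct(same, "target", "reference", "control")$rq, c(1, 1))
  trip <- ct_fixture()
  trip$ct[trip$sample_id == "t1" & trip$assay == "target"] <- 24  # scalar row
  trip3 <- rbind(trip[trip$sample_id == "c1", ],
                 data.frame(sample_id = "t1", group = "treated", assay = "target",
                            ct = c(23.9, 24.0, 24.1)),
                 data.frame(sample_id = "t1", group = "treated",
                            assay = "reference", ct = 20))
  rq3 <- ddct(trip3, "target", "reference", "control")
  expect_equal(rq3$rq[rq3$sample_id == "t1"], 2)
})

test_that("RQ is invariant to a global Ct shift and missing references error", {
  shifted <- ct_fixture()
  shifted$ct <- shifted$ct + 3
  expect_equal(ddct(shifted, "target", "reference", "control")$rq,
               ddct(ct_fixture(), "target", "reference", "control")$rq)
  broken <- ct_fixture()
  broken <- broken[!(broken$sample_id == "t1" & broken$assay == "reference"), ]
  expect_error(ddct(broken, "target", "reference", "control"), "t1")
})

viability_fixture <- function() {
  times <- c(5, 24, 48)
  mk <- function(w, g, lum) data.frame(well_id = w, group = g, time = times,
                                       luminescence = lum,
                                       stringsAsFactors = FALSE)
  rbind(mk("v1", "vehicle", c(100, 100, 100)),
        mk("v2", "vehicle", c(200, 200, 200)),
        mk("d1", "death", c(100, 40, 10)),
        mk("d2", "death", c(50, 20, 5)),
        mk("t1", "treatment", c(80, 80 * 0.7, 80 * 0.55)))
}

test_that("viability maps vehicle mean to 100, death mean to 0, midpoint to 50", {
  v <- viability_normalize(viability_fixture(), baseline_time = 5,
                           vehicle_group = "vehicle", death_group = "death")
  expect_setequal(v$time, c(24, 48))     # baseline itself is the reference
  expect_equal(v$viability[v$well_id == "v1"], c(100, 100))
  expect_equal(v$viability[v$well_id == "d1"], c(0, 0))
  # treated trace sits halfway between group means at each later time
  expect_equal(v$viability[v$well_id == "t1"], c(50, 50))
})

test_that("per-well gain does not change viability and degenerate times error", {
  f <- viability_fixture()
  g <- f
  g$luminescence[g$well_id == "t1"] <- g$luminescence[g$well_id == "t1"] * 7.3
  v1 <- viability_normalize(f, 5, "vehicle", "death")
  v2 <- viability_normalize(g, 5, "vehicle", "death")
  expect_equal(v1$viability, v2$viability)
  flat <- f
  flat$luminescence[flat$group == "death"] <- 100  # death == vehicle after baseline
  expect_error(viability_normalize(flat, 5, "vehicle", "death"), "degenerate")
  nobase <- f[f$time != 5 | f$well_id != "t1", ]
  expect_error(viability_normalize(nobase, 5, "vehicle", "death"), "baseline")
})

test_that("luciferase RLU normalizes firefly by renilla then by control mean", {
  s <- data.frame(sample_id = paste0("s", 1:4),
                  group = c("sc", "sc", "mir", "mir"),
                  firefly = c(1000, 1000, 500, 500),
                  renilla = c(100, 100, 100, 100), stringsAsFactors = FALSE)
  out <- rlu_normalize(s, "sc")
  expect_equal(mean(out$normalized[out$group == "sc"]), 1)
  expect_equal(out$normalized[out$group == "mir"], c(0.5, 0.5))
  s2 <- s
  s2$firefly <- s2$firefly * 13
  s2$renilla <- s2$renilla * 5
  expect_equal(rlu_normalize(s2, "sc")$normalized, out$normalized)
  s3 <- s
  s3$renilla[1] <- 0
  expect_error(rlu_normalize(s3, "sc"), "renilla")
})

eae_fixture <- function() {
  rbind(data.frame(animal_id = "a1", group = "g1", day = 1:3, score = c(1, 2, 3)),
        data.frame(animal_id = "a2", group = "g1", day = 1:3, score = c(1, NA, 3)),
        data.frame(animal_id = "a3", group = "g1", day = 1:3, score = c(1, 1, 2)),
        data.frame(animal_id = "a4", group = "g1", day = 1:3, score = c(0, 0, 0)),
        data.frame(animal_id = "b1", group = "g2", day = 1:3, score = c(0, 1, 1)))
}

test_that("symptom-free animals are excluded and gaps imputed with the group day mean", {
  prep <- eae_prepare(eae_fixture())
  expect_equal(prep$excluded, "a4")
  # a2 day 2 imputed from observed g1 scores that day, excluding a4: (2, 1)
  expect_equal(prep$imputations$value, 1.5)
  expect_equal(prep$series$score[prep$series$animal_id == "a2"], c(1, 1.5, 3))
})

test_that("complete tables pass through unchanged and invalid scores are rejected", {
  complete <- eae_fixture()[1:6, ]
  complete$score[5] <- 2
  prep <- eae_prepare(complete)
  expect_equal(nrow(prep$imputations), 0)
  expect_length(prep$excluded, 0)
  expect_equal(prep$series$score, complete$score)
  bad <- complete
  bad$score[1] <- 2.7
  expect_error(eae_prepare(bad), "clinical scale")
})

test_that("imputation with no observed group scores on that day errors", {
  t <- rbind(data.frame(animal_id = "a1", group = "g1", day = 1:2, score = c(1, NA)),
             data.frame(animal_id = "a2", group = "g1", day = 1:2, score = c(2, NA)))
  expect_error(eae_prepare(t), "no observed score")
})

test_that("trapezoid AUC follows the textbook arithmetic", {
  s <- data.frame(animal_id = "a", group = "g", day = 1:3, score = c(0, 2, 0))
  expect_equal(eae_auc(s)$auc, 2)
  z <- data.frame(animal_id = "a", group = "g", day = 1:3, score = c(0, 0, 0))
  expect_equal(eae_auc(z)$auc, 0)
  const <- data.frame(animal_id = "a", group = "g", day = 1:6, score = 3)
  expect_equal(eae_auc(const)$auc, 3 * 5)          # c * (d - 1)
  expect_equal(eae_auc(const, method = "sum")$auc, 18)
  one <- data.frame(animal_id = "a", group = "g", day = 1, score = 2)
  expect_error(eae_auc(one), "fewer than 2 days")
})

test_that("the common window restricts AUC to days all animals share", {
  s <- rbind(data.frame(animal_id = "a", group = "g", day = 1:4, score = 1),
             data.frame(animal_id = "b", group = "g", day = 2:3, score = 1))
  auc <- eae_auc(s, window = "common")
  expect_equal(auc$auc, c(1, 1))
  full <- eae_auc(s, window = "full")
  expect_equal(full$auc[full$animal_id == "a"], 3)
})

test_that("Mann-Whitney exact path reproduces the enumeration benchmark", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$pvalue, 0.1)
  expect_equal(r$method, "exact")
})

test_that("identical groups give p 1 on the tie-corrected approximate path", {
  r <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$method, "normal-approx")
  expect_equal(r$pvalue, 1)
})

test_that("U statistics of the two groups sum to n1*n2 and swapping is symmetric", {
  set.seed(81)
  for (i in 1:20) {
    x <- round(runif(sample(2:8, 1), 0, 10), 1)
    y <- round(runif(sample(2:8, 1), 0, 10), 1)
    rx <- mann_whitney(x, y)
    ry <- mann_whitney(y, x)
    expect_equal(rx$U + ry$U, length(x) * length(y))
    expect_equal(rx$pvalue, ry$pvalue)
  }
})

test_that("the exact path agrees with brute-force enumeration and wilcox.test", {
  set.seed(82)
  for (i in 1:15) {
    x <- sample(1:100, sample(2:6, 1))
    y <- sample(101:200, sample(2:6, 1)) - sample(0:120, 1)
    if (any(duplicated(c(x, y)))) next
    got <- mann_whitney(x, y)
    want <- brute_mwu_two_sided(x, y)
    expect_equal(got$U, want$U)
    expect_equal(got$pvalue, want$pvalue)
    ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(got$pvalue, ref$p.value)
  }
})

test_that("one-sided alternatives orient as documented", {
  low <- mann_whitney(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(low$pvalue, 0.05)
  high <- mann_whitney(c(1, 2, 3), c(4, 5, 6), alternative = "greater")
  expect_gt(high$pvalue, 0.9)
})

test_that("the EAE comparison pipeline detects a planted shift monotonically", {
  cfg <- sim_config(seed = 83)
  ps <- vapply(c(0, 1, 2), function(shift) {
    a <- simulate_assays(sim_config(seed = 83), eae_shift = shift)
    eae_compare(a$eae, "control", "case")$test$pvalue
  }, numeric(1))
  expect_true(ps[3] <= ps[1])
  expect_lt(ps[3], 0.05)
})
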