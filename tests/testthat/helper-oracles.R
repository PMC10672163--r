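# Independent brute-force oracles. These deliberately re-derive each result
# from first principles so they share no code path with the implementation.

# Benjamini-Hochberg step-up, straight from the definition.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Median-of-ratios size factors from the definition, feature loop included.
brute_size_factors <- function(counts) {
  gm <- apply(counts, 1, function(r) prod(r)^(1 / length(r)))
  keep <- gm > 0
  s <- vapply(seq_len(ncol(counts)), function(j)
    median(counts[keep, j] / gm[keep]), numeric(1))
  s / prod(s)^(1 / length(s))
}

# Naive seed-site scanner: walks every UTR position and compares substrings
# against motifs built with its own complement table, applying the
# 8mer > 7mer-m8 > 7mer-A1 > 6mer priority per seed-match core.
brute_scan <- function(utr, seed) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  core <- rc(substr(seed, 1, 6))
  m8 <- comp[[substr(seed, 7, 7)]]
  n <- nchar(utr)
  res <- data.frame(start = integer(0), site_type = character(0))
  for (i in seq_len(max(0, n - 5))) {
    if (substr(utr, i, i + 5) != core) next
    pre <- i > 1 && substr(utr, i - 1, i - 1) == m8
    post <- i + 6 <= n && substr(utr, i + 6, i + 6) == "A"
    if (pre && post) res <- rbind(res, data.frame(start = i - 1L, site_type = "8mer"))
    else if (pre) res <- rbind(res, data.frame(start = i - 1L, site_type = "7mer-m8"))
    else if (post) res <- rbind(res, data.frame(start = i, site_type = "7mer-A1"))
    else res <- rbind(res, data.frame(start = i, site_type = "6mer"))
  }
  res
}

# Exact Mann-Whitney by enumeration of all group assignments.
brute_mwu_two_sided <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, u_of)
  p_le <- mean(us <= obs)
  p_ge <- mean(us >= obs)
  list(U = obs, pvalue = min(1, 2 * min(p_le, p_ge)))
}

# Hypergeometric upper tail by direct enumeration with binomial coefficients.
brute_hyper <- function(x, K, n, N) {
  ks <- x:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Minimal differential-expression-like table for consensus tests.
fake_de <- function(ids, lfc, fdr) {
  data.frame(feature_id = ids, base_mean = 100, lfc = lfc, se = 0.1,
             wald = lfc / 0.1, pvalue = fdr, fdr = fdr,
             stringsAsFactors = FALSE)
}

random_rna <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
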