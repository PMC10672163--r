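#' Exclude low-depth samples before differential expression
#'
#' Samples with fewer than `min_assigned` assigned reads are removed from
#' both the count matrix and the sample sheet. The comparison is strict
#' ("less than"), so a sample with exactly `min_assigned` reads is retained.
#'
#' @param counts count matrix.
#' @param sheet sample sheet with an `assigned_reads` column.
#' @param min_assigned read-count threshold (default one million).
#' @return list with `counts`, `sheet` and `excluded` (character vector of
#'   removed sample ids).
#' @export
qc_filter_samples <- function(counts, sheet, min_assigned = 1e6) {
  validate_count_matrix(counts)
  validate_sample_sheet(sheet, counts)
  if (!"assigned_reads" %in% names(sheet) || anyNA(sheet$assigned_reads))
    stop("assigned_reads must be present for all samples")
  drop <- sheet$sample_id[sheet$assigned_reads < min_assigned]
  keep_sheet <- sheet[!sheet$sample_id %in% drop, , drop = FALSE]
  if (nrow(keep_sheet) == 0)
    stop("all samples excluded by the assigned-reads filter")
  tab <- table(keep_sheet$condition)
  if (length(tab) < 2 || any(tab < 2))
    stop("fewer than 2 samples per condition remain after read filtering")
  list(counts = counts[, keep_sheet$sample_id, drop = FALSE],
       sheet = keep_sheet, excluded = as.character(drop))
}

#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over features (with a
#' positive geometric mean across samples) of count/geometric-mean. Factors
#' are rescaled so that their geometric mean is 1.
#'
#' @param counts count matrix.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  validate_count_matrix(counts)
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use))
    stop("no feature is expressed in all samples; cannot form a reference ",
         "(consider filtering or a pseudo-reference fallback)")
  s <- apply(counts[use, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - log_gm[use])))
  s <- s / exp(mean(log(s)))
  s
}

#' Per-feature negative-binomial dispersion estimates
#'
#' Method-of-moments estimates on normalized counts pooled within conditions
#' (variance = mu + alpha * mu^2), a fitted mean-dispersion trend
#' a1/mu + a0, and shrinkage of the per-feature estimate toward the trend on
#' the log scale with weight n_eff / (n_eff + n0), n0 = 4, where n_eff is
#' the residual degrees of freedom. Features whose moment estimate is zero
#' (no excess variance) take the trend value. All dispersions are floored at
#' 1e-8.
#'
#' @param counts count matrix.
#' @param sf size factors from [size_factors()].
#' @param condition factor/character of per-sample condition labels (2 levels).
#' @return numeric vector of final dispersions, one per feature, with
#'   attributes `raw` (moment estimates) and `trend` (trend values).
#' @export
estimate_dispersions <- function(counts, sf, condition) {
  validate_count_matrix(counts)
  condition <- as.factor(condition)
  if (nlevels(condition) < 2)
    stop("dispersion estimation needs at least two conditions")
  if (any(table(condition) < 2))
    stop("at least 2 samples per condition required")
  norm <- sweep(counts, 2, sf, "/")
  groups <- levels(condition)
  n <- ncol(counts)
  df_resid <- n - length(groups)
  mu <- rowMeans(norm)
  ss <- rep(0, nrow(counts))
  for (g in groups) {
    sub <- norm[, condition == g, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
  }
  v <- ss / df_resid
  raw <- pmax(0, (v - mu) / mu^2)
  raw[!is.finite(raw)] <- 0
  # trend a1/mu + a0 by least squares over positive raw estimates
  pos <- raw > 0 & mu > 0
  if (sum(pos) >= 3) {
    fit <- stats::lm.fit(cbind(1, 1 / mu[pos]), raw[pos])
    a0 <- max(fit$coefficients[1], 1e-8)
    a1 <- max(fit$coefficients[2], 0)
  } else {
    a0 <- max(mean(raw[pos]), 1e-8)
    a1 <- 0
  }
  trend <- a1 / pmax(mu, 1e-8) + a0
  n0 <- 4
  w <- df_resid / (df_resid + n0)
  final <- ifelse(raw > 0, exp(w * log(pmax(raw, 1e-300)) + (1 - w) * log(trend)),
                  trend)
  final <- pmax(final, 1e-8)
  names(final) <- rownames(counts)
  attr(final, "raw") <- raw
  attr(final, "trend") <- trend
  final
}

# One-feature NB GLM (log link, two-level design) by IRLS with fixed
# dispersion. Returns c(beta0, beta1, se1, converged) on the natural-log scale.
nb_irls <- function(y, x, offset, alpha, maxit = 100, tol = 1e-8) {
  # init from group means of offset-normalized counts
  m0 <- mean(y[x == 0] / exp(offset[x == 0]))
  m1 <- mean(y[x == 1] / exp(offset[x == 1]))
  beta <- c(log(max(m0, 0.1)), log(max(m1, 0.1)) - log(max(m0, 0.1)))
  X <- cbind(1, x)
  conv <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + offset
    mu <- pmin(exp(eta), 1e12)
    mu <- pmax(mu, 1e-10)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) break
    new_beta <- fit$coefficients
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta
      conv <- TRUE
      break
    }
    beta <- new_beta
    if (max(abs(beta)) > 50) break  # diverging
  }
  eta <- drop(X %*% beta) + offset
  mu <- pmax(pmin(exp(eta), 1e12), 1e-10)
  # observed Fisher information at the fitted coefficients
  w_obs <- mu * (1 + alpha * y) / (1 + alpha * mu)^2
  info <- crossprod(X * sqrt(w_obs))
  se1 <- tryCatch(sqrt(solve(info)[2, 2]), error = function(e) NA_real_)
  c(beta, se1, as.numeric(conv))
}

#' Negative-binomial Wald test for a two-level design
#'
#' Fits, per feature, an NB generalized linear model with log link and a
#' case-vs-control design (log size factors as offsets, dispersions fixed at
#' the [estimate_dispersions()] values), and tests the condition coefficient
#' with a Wald z-test. P-values are Benjamini-Hochberg adjusted over all
#' tested features. Features with all-zero counts are reported with an
#' undefined fold change and p = 1; non-converging fits are flagged and also
#' given p = 1.
#'
#' @param counts count matrix.
#' @param sheet sample sheet; `condition` must have exactly two levels.
#' @param ref reference (control) level of `condition`; defaults to the
#'   first level alphabetically.
#' @param sf optional size factors (computed if missing).
#' @param dispersions optional dispersions (computed if missing).
#' @return data.frame with columns `feature_id`, `base_mean`, `lfc` (log2
#'   case vs control), `se`, `wald`, `pvalue`, `fdr`, `converged`.
#' @export
wald_test <- function(counts, sheet, ref = NULL, sf = NULL, dispersions = NULL) {
  validate_count_matrix(counts)
  validate_sample_sheet(sheet, counts)
  counts <- counts[, sheet$sample_id, drop = FALSE]
  cond <- as.factor(sheet$condition)
  if (nlevels(cond) != 2) stop("condition must have exactly two levels")
  if (!is.null(ref)) cond <- stats::relevel(cond, ref = ref)
  x <- as.numeric(cond == levels(cond)[2])
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersions)) dispersions <- estimate_dispersions(counts, sf, cond)
  offset <- log(sf)
  norm <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(norm)
  n <- nrow(counts)
  res <- data.frame(feature_id = rownames(counts), base_mean = base_mean,
                    lfc = NA_real_, se = NA_real_, wald = NA_real_,
                    pvalue = 1, fdr = NA_real_, converged = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  tested <- rowSums(counts) > 0
  for (i in which(tested)) {
    fit <- nb_irls(counts[i, ], x, offset, dispersions[i])
    if (!is.na(fit[3]) && fit[3] > 0 && fit[4] == 1) {
      res$lfc[i] <- fit[2] / log(2)
      res$se[i] <- fit[3] / log(2)
      res$wald[i] <- res$lfc[i] / res$se[i]
      res$pvalue[i] <- 2 * stats::pnorm(-abs(res$wald[i]))
      res$converged[i] <- TRUE
    }
  }
  res$fdr <- 1
  res$fdr[tested] <- stats::p.adjust(res$pvalue[tested], method = "BH")
  res
}

#' Call differentially expressed features
#'
#' A feature is called iff fdr < `alpha` (strict) and |log2 fold change|
#' exceeds log2(1 + `min_change`) — with the defaults, an FDR-adjusted
#' p below 0.05 and a mean expression change of more than 50%
#' (|lfc| > log2(1.5)).
#'
#' @param results data.frame from [wald_test()].
#' @param alpha FDR threshold.
#' @param min_change minimum fractional change (0.5 = 50%).
#' @return data.frame with columns `feature_id`, `lfc`, `fdr`, `direction`
#'   ("up"/"down"), one row per called feature.
#' @export
call_de <- function(results, alpha = 0.05, min_change = 0.5) {
  lfc_min <- log2(1 + min_change)
  sel <- !is.na(results$fdr) & !is.na(results$lfc) &
    results$fdr < alpha & abs(results$lfc) > lfc_min
  out <- results[sel, c("feature_id", "lfc", "fdr"), drop = FALSE]
  out$direction <- ifelse(out$lfc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Variance-stabilizing transform for display
#'
#' log2(normalized count + 4). The fixed pseudocount of 4 keeps low counts
#' compressed; this transform is a display-only surrogate for heatmaps and
#' is never used in testing or calling.
#'
#' @param counts count matrix.
#' @param sf size factors.
#' @return numeric matrix of transformed values.
#' @export
vst <- function(counts, sf = size_factors(counts)) {
  validate_count_matrix(counts)
  log2(sweep(counts, 2, sf, "/") + 4)
}
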