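#' Relative quantification by the 2^-ddCt method
#'
#' Per sample, dCt = mean Ct of the target assay minus mean Ct of the
#' reference assay (means over technical replicates, typically triplicates);
#' ddCt referencing the mean dCt of the control group; relative quantity
#' RQ = 2^-ddCt. Amplification efficiency is fixed at exact doubling.
#'
#' @param records data.frame with columns `sample_id`, `group`, `assay`,
#'   and either a `ct` column (one row per replicate) or `ct_replicates`
#'   (list column of numeric vectors).
#' @param target_assay name of the target assay.
#' @param reference_assay name of the normalizer assay (e.g. Tbp, sno234).
#' @param control_group label of the control group.
#' @return data.frame: `sample_id`, `group`, `dct`, `ddct`, `rq`.
#' @export
ddct <- function(records, target_assay, reference_assay, control_group) {
  if ("ct_replicates" %in% names(records)) {
    records <- do.call(rbind, lapply(seq_len(nrow(records)), function(i)
      data.frame(sample_id = records$sample_id[i], group = records$group[i],
                 assay = records$assay[i],
                 ct = as.numeric(records$ct_replicates[[i]]),
                 stringsAsFactors = FALSE)))
  }
  if (!all(c("sample_id", "group", "assay", "ct") %in% names(records)))
    stop("records need columns sample_id, group, assay, ct")
  if (any(!is.finite(records$ct)) || any(records$ct <= 0))
    stop("Ct values must be positive and finite")
  samples <- unique(records[c("sample_id", "group")])
  mean_ct <- function(sid, assay) {
    v <- records$ct[records$sample_id == sid & records$assay == assay]
    if (length(v) == 0)
      stop(sprintf("sample '%s' lacks Ct values for assay '%s'", sid, assay))
    mean(v)
  }
  samples$dct <- vapply(samples$sample_id, function(sid)
    mean_ct(sid, target_assay) - mean_ct(sid, reference_assay), numeric(1))
  ctrl <- samples$dct[samples$group == control_group]
  if (length(ctrl) == 0) stop("control group '", control_group, "' is empty")
  samples$ddct <- samples$dct - mean(ctrl)
  samples$rq <- 2^(-samples$ddct)
  rownames(samples) <- NULL
  samples
}

#' Normalize real-time viability traces to percent viability
#'
#' Each well's luminescence is first divided by its own baseline reading
#' (the value at `baseline_time`, e.g. 5 hours). Per time point the
#' baseline-normalized signal is then mapped linearly so that the mean of
#' the vehicle group (unstimulated control) is 100% and the mean of the
#' death group (maximal-death control) is 0%. Values outside [0, 100] are
#' not clipped.
#'
#' @param traces data.frame with columns `well_id`, `group`, `time`,
#'   `luminescence`; times within a well strictly increasing.
#' @param baseline_time baseline time point (must be present in every well).
#' @param vehicle_group group label defining 100% viability.
#' @param death_group group label defining 0% viability.
#' @return data.frame: `well_id`, `group`, `time`, `viability` (percent),
#'   covering the post-baseline time points.
#' @export
viability_normalize <- function(traces, baseline_time = 5,
                                vehicle_group = "vehicle",
                                death_group = "death") {
  need <- c("well_id", "group", "time", "luminescence")
  if (!all(need %in% names(traces)))
    stop("traces need columns ", paste(need, collapse = ", "))
  if (any(traces$luminescence <= 0)) stop("luminescence must be positive")
  wells <- unique(traces$well_id)
  groups <- traces$group[match(wells, traces$well_id)]
  if (!any(groups == vehicle_group)) stop("vehicle group has no wells")
  if (!any(groups == death_group)) stop("death group has no wells")
  rel <- traces
  for (w in wells) {
    ix <- traces$well_id == w
    t0 <- which(ix & traces$time == baseline_time)
    if (length(t0) != 1)
      stop("well '", w, "' lacks a reading at baseline time ", baseline_time)
    if (is.unsorted(traces$time[ix], strictly = TRUE))
      stop("times within well '", w, "' must be strictly increasing")
    rel$luminescence[ix] <- traces$luminescence[ix] / traces$luminescence[t0]
  }
  # at the baseline time every well is 1 by construction, so percent
  # viability is defined for the post-baseline times only
  out <- rel[rel$time != baseline_time, , drop = FALSE]
  out$viability <- NA_real_
  for (tt in unique(out$time)) {
    at_t <- out$time == tt
    veh <- mean(out$luminescence[at_t & out$group == vehicle_group])
    dth <- mean(out$luminescence[at_t & out$group == death_group])
    if (!is.finite(veh) || !is.finite(dth) || veh == dth)
      stop("degenerate normalization at time ", tt,
           ": vehicle and death means coincide")
    out$viability[at_t] <- 100 * (out$luminescence[at_t] - dth) / (veh - dth)
  }
  rownames(out) <- NULL
  out[c("well_id", "group", "time", "viability")]
}

#' Dual-luciferase RLU normalization
#'
#' Firefly luminescence is divided by the paired renilla reading
#' (transfection-efficiency control) to give RLU, then scaled by the mean
#' RLU of the control (scrambled-miR) group.
#'
#' @param samples data.frame with columns `sample_id`, `group`, `firefly`,
#'   `renilla`.
#' @param control_group label of the control group.
#' @return data.frame: `sample_id`, `group`, `rlu`, `normalized`.
#' @export
rlu_normalize <- function(samples, control_group) {
  need <- c("sample_id", "group", "firefly", "renilla")
  if (!all(need %in% names(samples)))
    stop("samples need columns ", paste(need, collapse = ", "))
  if (any(samples$renilla == 0)) stop("renilla reading of zero")
  out <- samples
  out$rlu <- samples$firefly / samples$renilla
  ctrl <- out$rlu[out$group == control_group]
  if (length(ctrl) == 0) stop("control group '", control_group, "' is empty")
  out$normalized <- out$rlu / mean(ctrl)
  out[c("sample_id", "group", "rlu", "normalized")]
}

#' Prepare EAE clinical-score tables for analysis
#'
#' Animals with no disease symptoms (all observed scores zero, or nothing
#' observed) are excluded. Remaining missing (animal, day) scores are
#' conservatively imputed as the mean observed clinical score of the
#' animal's experimental group on that day.
#'
#' @param table data.frame with columns `animal_id`, `group`, `day`,
#'   `score` (NA = missing); scores on the 0/1/2/3/3.5/4/5 scale.
#' @return list with `series` (complete long data.frame), `excluded`
#'   (animal ids removed), `imputations` (data.frame animal_id/day/value).
#' @export
eae_prepare <- function(table) {
  need <- c("animal_id", "group", "day", "score")
  if (!all(need %in% names(table)))
    stop("EAE table needs columns ", paste(need, collapse = ", "))
  scale_ok <- is.na(table$score) | table$score %in% c(0, 1, 2, 3, 3.5, 4, 5)
  if (!all(scale_ok))
    stop("score outside the clinical scale {0,1,2,3,3.5,4,5}: ",
         table$score[!scale_ok][1])
  if (anyDuplicated(table[c("animal_id", "day")]))
    stop("more than one score for an animal-day")
  animals <- unique(table$animal_id)
  symptomatic <- vapply(animals, function(a) {
    sc <- table$score[table$animal_id == a]
    any(!is.na(sc) & sc > 0)
  }, logical(1))
  excluded <- animals[!symptomatic]
  kept <- table[table$animal_id %in% animals[symptomatic], , drop = FALSE]
  imput <- kept[0, c("animal_id", "day")]
  imput$value <- numeric(0)
  miss <- which(is.na(kept$score))
  for (i in miss) {
    grp <- kept$group[i]
    day <- kept$day[i]
    obs <- kept$score[kept$group == grp & kept$day == day & !is.na(kept$score)]
    if (length(obs) == 0)
      stop(sprintf("no observed score in group '%s' on day %s to impute from",
                   grp, day))
    kept$score[i] <- mean(obs)
    imput <- rbind(imput, data.frame(animal_id = kept$animal_id[i], day = day,
                                     value = mean(obs)))
  }
  rownames(kept) <- NULL
  list(series = kept, excluded = as.character(excluded), imputations = imput)
}

#' Per-animal area under the clinical-score curve
#'
#' Trapezoidal area of each animal's daily score series over the analysis
#' window; with unit day spacing this equals the sum of interior scores plus
#' half the two endpoint scores. The default window is the common range of
#' days observed for every animal; `window = "full"` uses each animal's own
#' observed range. `method = "sum"` gives the plain daily-sum alternative.
#'
#' @param series prepared long data.frame from [eae_prepare()]`$series`.
#' @param window `"common"` or `"full"`.
#' @param method `"trapezoid"` or `"sum"`.
#' @return data.frame: `animal_id`, `group`, `auc`.
#' @export
eae_auc <- function(series, window = c("common", "full"),
                    method = c("trapezoid", "sum")) {
  window <- match.arg(window)
  method <- match.arg(method)
  animals <- unique(series$animal_id)
  if (window == "common") {
    lo <- max(vapply(animals, function(a) min(series$day[series$animal_id == a]), numeric(1)))
    hi <- min(vapply(animals, function(a) max(series$day[series$animal_id == a]), numeric(1)))
    if (hi <= lo && method == "trapezoid")
      stop("common observation window has fewer than 2 days")
    series <- series[series$day >= lo & series$day <= hi, , drop = FALSE]
  }
  out <- do.call(rbind, lapply(animals, function(a) {
    sub <- series[series$animal_id == a, , drop = FALSE]
    sub <- sub[order(sub$day), , drop = FALSE]
    if (nrow(sub) < 2 && method == "trapezoid")
      stop("animal '", a, "' has fewer than 2 days of scores")
    auc <- if (method == "trapezoid") {
      sum(diff(sub$day) * (utils::head(sub$score, -1) + utils::tail(sub$score, -1)) / 2)
    } else {
      sum(sub$score)
    }
    data.frame(animal_id = a, group = sub$group[1], auc = auc,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test
#'
#' U is computed from midranks (ties share their average rank). When
#' n1 * n2 <= 400 and there are no ties the p-value comes from the exact
#' null distribution of U; otherwise a normal approximation with tie
#' correction and continuity correction is used. Two-sided p =
#' min(1, 2 * smaller one-sided tail).
#'
#' @param x,y numeric samples for groups A and B.
#' @param alternative `"two.sided"`, `"less"` (A shifted below B) or
#'   `"greater"`.
#' @return list: `U` (for group A), `n1`, `n2`, `pvalue`, `alternative`,
#'   `method` ("exact" or "normal-approx").
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("both groups must be nonempty")
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # pairs where x beats y (+0.5 ties)
  ties <- any(duplicated(pooled))
  if (!ties && n1 * n2 <= 400) {
    # exact null distribution of U (all C(n1+n2, n1) rank assignments)
    p_le <- stats::pwilcox(U, n1, n2)
    p_ge <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    tie_tab <- table(pooled)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_corr))
    if (sigma == 0) {
      p <- 1
    } else {
      z2 <- (max(0, abs(U - mu) - 0.5)) / sigma
      p <- switch(alternative,
                  two.sided = min(1, 2 * stats::pnorm(-z2)),
                  greater = stats::pnorm((U - mu - 0.5) / sigma, lower.tail = FALSE),
                  less = stats::pnorm((U - mu + 0.5) / sigma))
    }
    method <- "normal-approx"
  }
  list(U = U, n1 = n1, n2 = n2, pvalue = p, alternative = alternative,
       method = method)
}

#' EAE group comparison on per-animal AUC
#'
#' The complete clinical pipeline: exclusion of symptom-free animals,
#' group-mean imputation of missing days, per-animal trapezoidal AUC, and a
#' two-tailed Mann-Whitney U test between the two groups' AUC values.
#'
#' @param table raw EAE score table (see [eae_prepare()]).
#' @param group_a,group_b the two group labels to compare.
#' @param ... passed to [eae_auc()].
#' @return list: `auc` (per-animal table), `test` ([mann_whitney()] result),
#'   `excluded`, `imputations`.
#' @export
eae_compare <- function(table, group_a, group_b, ...) {
  prep <- eae_prepare(table)
  auc <- eae_auc(prep$series, ...)
  a <- auc$auc[auc$group == group_a]
  b <- auc$auc[auc$group == group_b]
  if (length(a) == 0 || length(b) == 0)
    stop("one of the compared groups has no symptomatic animals")
  list(auc = auc, test = mann_whitney(a, b, "two.sided"),
       excluded = prep$excluded, imputations = prep$imputations)
}
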