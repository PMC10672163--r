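---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromirnet)
```

This vignette is the package's own account of the statistical machinery:
what is modeled, which tunable parameters matter, what the synthetic-data
generator does and does not emulate, and where a genuinely open design
choice was resolved.

## The count model

Both miRNA and mRNA counts are modeled per feature $i$ and sample $j$ as
negative binomial,

$$K_{ij} \sim \mathrm{NB}(\mu_{ij},\ \alpha_i), \qquad
\mathrm{Var}(K_{ij}) = \mu_{ij} + \alpha_i \mu_{ij}^2,$$

with $\mu_{ij} = s_j\, q_{ij}$ and a two-level (case vs control) log-linear
design $\log q_{ij} = \beta_{0i} + \beta_{1i}\, x_j$. This mean–dispersion
parameterization is shared by the simulator and the test, so recovery tests
probe estimation, not model mismatch.

**Size factors.** Median-of-ratios: for each sample, the median of
count/geometric-mean over features whose geometric mean across samples is
positive, then rescaled to geometric mean 1. The rescaling makes factors
comparable across runs and gives the two-sample doubling case the symmetric
$(1/\sqrt2, \sqrt2)$ form. Samples sharing no universally expressed feature
are a hard error rather than a silent pseudo-reference fallback.

**Dispersion.** A method-of-moments estimate on normalized counts, pooling
the within-condition sums of squares ($\mathrm{df} = n - \#\mathrm{groups}$):
$\hat\alpha_i = \max\!\big(0, (v_i - \mu_i)/\mu_i^2\big)$. A mean–dispersion
trend $\alpha_{tr}(\mu) = a_1/\mu + a_0$ is fitted by least squares over
features with positive $\hat\alpha$, and the final value shrinks the
feature estimate toward the trend on the log scale with weight
$w = \mathrm{df}/(\mathrm{df} + n_0)$, $n_0 = 4$. Features with
$\hat\alpha_i = 0$ (no excess variance observed) take the trend value
directly — the geometric formula is undefined at zero, and the trend is the
best available estimate for such features. All dispersions are floored at
$10^{-8}$.

**Wald test.** Each feature is fitted by iteratively reweighted least
squares (weights $\mu/(1+\alpha\mu)$, log size factors as offsets,
convergence at $10^{-8}$ on the coefficients, 100-iteration cap); the
standard error comes from the observed Fisher information and the two-sided
p-value from the standard normal on $\hat\beta_1/\mathrm{se}$. Features with
all-zero counts are reported untested with $p = 1$; non-convergent fits are
flagged the same way. FDR is Benjamini–Hochberg over the tested features
with no independent filtering and no fold-change shrinkage — the simplest
defensible NB Wald pipeline, which keeps every reported log2 fold change an
unshrunken maximum-likelihood estimate.

**Calling.** A feature is differentially expressed iff
$\mathrm{FDR} < 0.05$ (strict) and $|\mathrm{log_2FC}| > \log_2 1.5
\approx 0.585$, i.e. a mean expression change of more than 50%. Both
inequalities are strict, and the boundary cases (FDR exactly 0.05, reads
exactly $10^6$, CWCS exactly $-0.2$) are pinned by unit tests.

A note on calibration: a normal-reference Wald test at four or five samples
per group is slightly anticonservative — even with the dispersion fixed at
its true value the null rejection rate at nominal 0.05 sits a little above
it, and dispersion-estimation noise adds to that. The test suite measures
this directly on null simulations; users who need exact finite-sample error
control at these group sizes should treat the raw p-values as approximate.

## Consensus across cohorts

Candidates are the intersection of the per-cohort call sets. Direction
concordance is required by default (`require_concordance = TRUE`): a miRNA
significantly up in one cohort and down in the other is excluded and
logged. Pure set intersection is available by flag since either convention
is defensible for "consistently deregulated". Ranking is by
$\max_c\big(-\log_{10}\mathrm{FDR}_c\big)$ with FDR floored at $10^{-300}$
so the score stays finite, dense ranks, and lexicographic identifier
tie-breaks for determinism. No meta-analytic p-value combination is
attempted — the procedure intersects calls, it does not pool evidence.

## CWCS stratification and integration

Transcript-level predictions are collapsed per (family, gene) to the
minimum (most negative) CWCS and the maximum conserved-site count; the
minimum is the confidence-maximizing convention consistent with reporting a
single score per gene. Retention requires CWCS strictly below $-0.2$; high
confidence requires strictly below $-0.4$, so a record at exactly $-0.4$ is
moderate and one at exactly $-0.2$ is dropped. The boundary assignment is a
package decision documented here because "between $-0.2$ and $-0.4$" is
ambiguous at its endpoints.

An edge (miRNA, gene) survives integration iff the miRNA is an
**up-regulated** consensus candidate (the silencing direction of interest),
its family has a retained prediction for the gene, and the gene is called
**down-regulated** by the same criteria as calling (the down call reuses
FDR < 0.05 and the 50% bound; no separate threshold is introduced).
Candidate miRNAs map to prediction families by seed identity
(`seed_families()`), with an explicit map overriding when a prediction
table keys families differently.

## Seed sites

For a 7-nt seed $s$ (miRNA positions 2–8), the scanner finds every
occurrence of the 6-nt core (reverse complement of positions 2–7) and
classifies it once, at its highest-priority type:

* **8mer** — core preceded by the position-8 complement and followed by `A`;
* **7mer-m8** — core preceded by the position-8 complement;
* **7mer-A1** — core followed by `A`;
* **6mer** — bare core.

The downstream `A` is matched literally (the adenine opposite position 1 is
a feature of the site, not a base pair). Positions are 1-based at the
5′-most matched base. Wobble pairs, 3′-supplementary pairing and
non-canonical classes are out of scope — CWCS is consumed from the
prediction table, never recomputed. The scanner is validated against a
brute-force substring oracle on randomized sequences, with exact set
equality.

## Enrichment

Overrepresentation uses the exact hypergeometric upper tail
$P(X \ge x)$ for an overlap of $x$ query genes with a $K$-gene set in an
$N$-gene universe. The universe is the caller's choice; the recommended
convention, used throughout the examples, is all genes tested for
differential expression rather than the whole annotation. Sets are
intersected with the universe, query genes outside it are dropped with a
count, BH runs across all tested sets, and the reported top slice (default
12) orders by FDR, then p, then term identifier. No ontology-hierarchy
redundancy trimming is applied.

## Assay computations

* **qPCR** — $\Delta C_T$ = mean target $C_T$ − mean reference $C_T$ over
  technical replicates; $\Delta\Delta C_T$ references the control-group
  mean; $RQ = 2^{-\Delta\Delta C_T}$ with amplification efficiency fixed at
  exact doubling. A global $C_T$ shift cancels, which the property tests
  assert.
* **Viability** — each well is divided by its own baseline reading (default
  5 h), then mapped linearly per time point so the vehicle-group mean is
  100% and the death-control mean 0%. Values are not clipped to [0, 100].
  The baseline time itself is the reference (all wells are identically 1
  there) and is therefore excluded from the output rather than reported as
  a degenerate 0/0.
* **Luciferase** — firefly/renilla per sample, then division by the mean
  ratio of the control group; invariant to rescaling either channel
  globally.
* **EAE scores** — animals with no symptoms ever are excluded; remaining
  missing days are imputed with the group mean of observed scores that day
  (a missing day with nothing observed in the group is an error, not a
  guess). Per-animal disease burden is the trapezoid area under the daily
  score curve; the default window is the common day range observed for all
  animals so burdens are comparable, with `window = "full"` and
  `method = "sum"` as documented alternatives. Groups are compared by a
  two-tailed Mann-Whitney U test on the per-animal areas: midranks for
  ties, the exact null distribution when $n_1 n_2 \le 400$ and no ties are
  present (enumeration cost bound), otherwise a normal approximation with
  tie and continuity corrections.

## What the simulator emulates — and what it does not

`sim_config()` defaults encode the study conditions: two miRNA cohorts of
5 vs 5 and 4 vs 4 samples, an mRNA cohort of 5 controls vs 4 cases, 200
miRNAs / 2,000 genes, NB dispersion 0.1, baseline means log-uniform on
[100, 2000] (typical IP-library depth for robustly detected features), 24
planted up-regulated miRNAs, and ~30 true targets each
(`target_density = 0.015`, ~720 true edges — the order of magnitude of a
real integration run). True-edge CWCS values are drawn from $[-0.9, -0.5]$
and decoy CWCS from $[-0.15, -0.01]$, so the $-0.2$ retention boundary
separates them by construction and filter-funnel tests can assert exact
set recovery.

The planted effect size defaults to $|\mathrm{log_2FC}| = 2.5$ for both the
miRNA induction and the target silencing. The package's recovery tests
require the planted edge set back at ≥95% precision and recall for an
arbitrary seed; at four samples per group and dispersion 0.1 that demands
per-feature calling power near 1, which a ~6-fold change provides while a
~3-fold change does not — with weaker planted effects a recovery failure
would reflect sampling noise rather than an implementation defect. Power at
moderate effects is probed separately by an explicit run at
$|\mathrm{log_2FC}| = 1.5$, mean 500.

Each generator output draws from its own seeded substream, so adding one
output never shifts the others, and a fixed seed reproduces every byte.

Deliberately **not** modeled: biological pooling of animals within a
replicate (replicates are drawn directly), batch effects, library-size
confounding beyond size-factor variation, read-level artifacts (the
simulator starts at counts), 3′UTR base composition beyond uniform
background, and correlation between a gene's CWCS and its silencing
magnitude. Passing recovery tests therefore demonstrates correctness of the
estimation chain under the stated model, not robustness to real-data
pathologies such as outlier replicates or composition bias.

Truth tables for simulated UTRs are produced by post-scanning the finished
sequences, so chance background sites are part of the truth and scanner
tests can assert exact equality instead of mere recall.

## Problem sizes

The shipped tests run the full pipeline at the default 2,000-gene / 200-miRNA
scale (about a second per end-to-end run), use 2,000-feature single-cohort
simulations for calibration and power, 1,000 random UTRs for the scanner
oracle, and full enumeration for the exact-test oracles (all group sizes up
to 6, universes up to 12). These sizes were chosen so the whole suite
exercises every stage at meaningful statistical resolution while staying
comfortably interactive.

## Known limitations

* The NB Wald p-values are asymptotic; see the calibration note above.
* Gene identifiers are opaque strings — no symbol/accession harmonization
  is attempted between count matrices and prediction tables.
* The enrichment module implements overrepresentation only; rank-based
  (KS-style) gene-set enrichment is out of scope.
* Display helpers (`vst()` is `log2(normalized + 4)`, chosen to compress
  low counts) are for heatmaps only and never feed any test or call.
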