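---
title: "Methods: consensus neutrophil classification and multi-model risk prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus neutrophil classification and multi-model risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis in one paragraph

`cccf` implements a peripheral-blood transcriptomic pipeline for estimating
intracerebral hemorrhage (ICH) risk in hypertensive patients. Single-cell
differential expression between case (microbleed, MB) and control
(hypertension-only, HBP) neutrophils defines an up-regulated gene set
(signature1) and a down-regulated one (signature2). Every cell is scored
for both signatures by a registry of k gene-set scoring algorithms
(default k = 19), each score is binarized at its median across cells, and
the 2k bits are summed: cells unanimous in the risk direction (sum 2k) are
called *high-risk*, cells unanimous in the opposite direction (sum 0)
*low-risk*, everything in between is *filtered*. A deterministic
pseudotime axis from low- to high-risk cells supplies a correlation-based
gene filter; its intersection with the bulk DEGs of two patient cohorts
defines the feature set for an ensemble of feature-selector x classifier
combinations, ranked by the mean AUC over a held-out test partition and an
external validation cohort.

# The consensus classifier (CCCF)

## Signature extraction

Single-cell counts are depth-normalized to a fixed target sum (10,000) and
log1p-transformed, the standard droplet-data convention. Differential
expression uses the two-sided Wilcoxon rank-sum test with the normal
approximation and tie correction — the convention of single-cell marker
testing — with an exact-test fallback for tiny groups (3 cells or fewer,
where the normal approximation is visibly off; the exact null for a 3v3
comparison has only 20 rank assignments). Log2 fold changes are computed on
group means of the de-logged normalized values with a pseudocount of 1 in
numerator and denominator. Thresholds are strict, as printed in the study
design: |log2FC| > 0.25 and BH-adjusted p < 0.05 for single-cell
signatures, |log2FC| > 1 for bulk DEGs. An empty signature in either
direction is an error rather than a silent degenerate run, because median
binarization of a constant score column is uninformative.

Genes detected in fewer than 3 cells per group are skipped and reported —
testing them would only dilute the BH correction.

## The scoring registry

The consensus idea needs many *different* per-cell scores of the same gene
set; the particular algorithm roster matters less than its diversity,
because the consensus sum only retains what the scorers agree on. The
registry therefore implements eight statistics from scratch, spanning the
main families in single-cell signature scoring:

| scorer | family | statistic |
|---|---|---|
| `zmean` | mean-based | mean per-gene z-score |
| `aucell05` | ranking/recovery | area under the signature recovery curve in the top 5% of each cell's ranking, normalized to 1 for a perfect top block |
| `ucell` | rank-sum | normalized Mann-Whitney U of signature vs non-signature genes within the cell |
| `meanrank` | rank-mean | centered mean within-cell rank |
| `ssgsea025` | running-sum | weighted KS-style running sum, exponent 0.25 |
| `plage` | factor-based | projection on the first right singular vector of the z-scored signature submatrix |
| `mscore24` | control-matched | signature mean minus mean of expression-bin-matched control genes (24 bins) |
| `droprank` | dropout-aware | mean rank among expressed genes; undetected signature genes contribute 0 |

Parameter variants (recovery cut-offs 10/25/50%, running-sum exponents
0/0.5/1, trimmed/median z, plain mean expression, 10 control bins, median
rank) extend the registry deterministically to k = 19, so each cell
receives 38 scores: 19 for signature1 and 19 for signature2. k is
configurable; the registry order is fixed and documented so `k = 8` is
exactly the core set.

Two deliberate conventions: all scorers are computed on the normalized
log1p matrix; within-cell rank ties are broken by average rank. The
control-matched scorer uses *all* genes of an expression bin as the
control set rather than a random sample, which removes the only source of
randomness in scoring. The factor-based scorer orients its singular vector
along the signature mean, making its sign deterministic.

## Binarization and labels

For each of the 2k score columns the median is taken over *all* scored
cells — both conditions pooled, since the full neutrophil matrix is scored
as one population. For signature1 a score strictly above the median maps
to 1, otherwise 0; for signature2 the coding is reversed. "Above" is read
literally: ties at the median fall to the "otherwise" branch. A constant
score column triggers a warning and assigns every cell the "otherwise"
value.

The per-cell total across 2k bits classifies: 2k = high, 0 = low,
intermediate = filtered. Filtered cells are retained with their label so
proportion analyses keep correct denominators. Unanimity is deliberately
harsh — enlarging the registry can only shrink the high and low sets — and
that is the point: surviving 38 median cuts from 19 different statistics is
strong evidence the cell sits in the tail of the signature axis, not in
the bulk of a single scorer's noise.

# Pseudotime and feature selection

A neural-ODE trajectory method is out of scope here; the downstream gene
filter needs only a monotone, identifiable axis from low- to high-risk
cells. We use the first principal axis of the normalized matrix, oriented
so the mean position of consensus-high cells exceeds that of
consensus-low cells, min-max rescaled to [0, 1]. The orientation rule
makes the axis invariant to sign flips and cell order; both high and low
cells must exist, otherwise the direction would be arbitrary.

Per-gene Pearson correlation with pseudotime is tested against the
t-distribution (n - 2 df). The selection rule keeps genes with *signed*
r > 0.6 and p < 0.05 — as printed, strongly negatively correlated genes
are not selected (an absolute-value switch exists but is off by default) —
in **both** single-cell datasets (human and a second replicate standing in
for the mouse data), intersected with the bulk DEG lists of **both**
cohorts. Constant genes are reported with `r = NA` and never selected.

# The multi-model integration framework

Cohort 1 is split 7:3 into train and test, stratified by outcome with
largest-remainder allocation; cohort 2 is the external validation set.
The model grid crosses 7 feature selectors (none, lasso, elastic-net,
forward/backward/both stepwise logistic by AIC, univariate filter) with 9
classifiers (logistic, ridge- and lasso-penalized logistic, LDA, naive
Bayes, kNN, random forest, linear SVM, gradient boosting), excluding the
one pair in which the selector re-runs the identical penalized fit
(lasso feeding lasso-logistic): 62 combinations. The original study's
grid size (134) is not published; the framework logic — enumerate, select
by mean AUC, count per-gene model membership — is what is reproduced, and
the grid here is documented and configurable rather than claimed
identical.

Selectors see only the training partition. Internal tuning
(cross-validated penalty paths, kNN's k by leave-one-out, boosting rounds
by 4-fold CV with early stopping) also uses the training partition only.
Stepwise selection is pre-screened to the top `n/3` univariate candidates
so the underlying logistic fit stays identifiable when features outnumber
samples. AUC is the rank-based (Mann-Whitney) estimator with midrank tie
handling. Models are ranked by `mean_auc = (auc_test + auc_valid)/2`; the
training AUC is reported but never used for selection. Ties break toward
fewer genes, then name, making the ranking a total order. A selector that
returns zero genes yields a flagged chance-level result (AUC 0.5) rather
than an error, so grid enumeration never aborts.

The constant batch offset carried by cohort 2 is handled by per-cohort
location handling only: before bulk DE, cohort 2 is shifted so its grand
mean matches cohort 1 (a constant offset inflates ratio-based fold-change
denominators); before model fitting, each cohort's features are centered.
Both operations are label-free, so they cannot leak outcome information.

# The synthetic study

The simulators define the study conditions the tests and the acceptance
script run under.

**Single cell.** Counts are gamma-Poisson (negative binomial) with a
shared dispersion of 0.2 — typical of UMI data — log-normal library-size
factors (sigma 0.3), and log-normal baseline means for background genes.
Each condition contributes 1,000 cells over 1,000 genes by default. Half
of the case-condition cells are flagged high-risk; they multiply the 50
planted signature1 genes by 2 (effect of 1 log2 unit) and divide the 50
signature2 genes by 2. Every cell carries a latent differentiation
coordinate in [0, 1]; high-risk cells occupy the upper half. Fifty
trajectory genes have means linear in the latent with a 16-fold dynamic
range, half induced and half repressed so the program is library-size
neutral — an earlier one-sided design inflated the depth of high-latent
cells and the depth normalization then swallowed part of the planted
signature, which is a real artifact worth avoiding in a generator. The
16-fold range is chosen so the planted genes genuinely belong to the
class the selection rule is defined on (Pearson r with the axis above
0.6); planted genes and signature genes get moderately expressed
baselines, as the detectable DE and trajectory genes of real data do.

**Bulk.** Features are Gaussian on an abundance-like scale (baselines
uniform on [2, 4], noise sd 1), 65 samples per cohort (130 patients
total), 64 features. Ten informative genes, drawn from the induced half
of the single-cell trajectory genes so the intersection step has support
by design, are shifted additively by 6 in cases — large relative to
noise, which is what a bulk DEG passing |log2FC| > 1 on this scale
requires. Cohort 2 adds a constant batch offset of 1 to every feature.

**What the generator does not emulate:** doublets, ambient RNA,
cell-type compositional shifts, gene-gene correlation beyond the planted
programs, per-gene dispersion variation, and bulk count overdispersion
(bulk features are Gaussian, not negative binomial). Passing tests
therefore demonstrate the pipeline's logic — recovery of planted
structure under realistic noise — not robustness to every failure mode of
real data.

# Numerical choices and degenerate inputs

- Median binarization uses strict `>`; all-tie columns warn and take the
  "otherwise" branch.
- BH adjustment delegates to the standard step-up implementation and is
  property-tested against a brute-force oracle.
- Cells with zero total counts are rejected by name at normalization.
- Constant genes: p = 1 in DE, `r = NA` in correlation, z = 0 in scoring.
- The rank-AUC normalizer is the best achievable partial-recovery area,
  so a perfect cell scores exactly 1 regardless of signature size.
- Seeds: simulators take an explicit seed and restore the caller's RNG
  state; pipeline stages and model fits derive their streams from the
  config seed, so a full run is reproducible to identical checksums.

# Problem sizes in the test suite

The unit suite works on 400–600-cell simulations (400 genes); the
end-to-end checks use the default study scale: two datasets of 2,000
cells x 1,000 genes and two bulk cohorts of 65 samples x 64 features,
with the 62-model grid evaluated once on planted cohorts and three times
on permuted labels. The permuted-label check compares each model's null
mean AUC *averaged over three permutations* against a chance band: with
a test partition of ~19 samples a single permutation draw of the extreme
over 62 correlated models regularly leaves a ±0.15 band by sampling noise
alone, whereas genuine label leakage would survive averaging. The sharp
leak test is separate and exact: refitting with corrupted test and
validation labels must leave selected genes and coefficients bit-identical.

# Known limitations

- The consensus labels depend on the scored cell population: medians are
  cohort-relative, so classifications are not transferable across datasets
  without rescoring.
- PC1 pseudotime assumes the dominant variance axis is the risk
  transition; a dataset whose main axis is cell cycle or depth would need
  the trajectory replaced, not the selection rule.
- The grid's stepwise selectors are greedy AIC searches after univariate
  pre-screening; they are not guaranteed to find the best subset.
- With 19 scorers sharing one expression matrix, the 38 bits are
  positively correlated; the consensus total is not a sum of independent
  evidence and its calibration is empirical, which is why planted-truth
  recovery, not a parametric error rate, is the validation target.
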