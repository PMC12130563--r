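# cccf — consensus neutrophil classification and multi-model ICH risk prediction

Hypertensive intracerebral hemorrhage (ICH) is preceded by immunological
changes that are visible in peripheral blood. `cccf` implements the
analysis chain for this setting, aimed at computational biologists working
with paired single-cell and bulk cohorts:

1. **Signature extraction** — Wilcoxon rank-sum differential expression
   between case (microbleed, MB) and control (hypertension, HBP)
   neutrophils; genes with |log2FC| > 0.25 and BH-adjusted p < 0.05 form
   an up-signature (signature1) and a down-signature (signature2).
2. **Cellular classification consensus framework (CCCF)** — every cell is
   scored for both signatures by k = 19 gene-set scoring algorithms. Each
   score column is binarized at its median (signature1: above → 1;
   signature2: above → 0), giving 38 bits per cell. A total of 38 calls a
   *high-risk* neutrophil, 0 a *low-risk* one; intermediate cells are
   filtered.
3. **Pseudotime feature filter** — a deterministic low-to-high-risk axis
   (first principal component, oriented by the consensus labels); genes
   with Pearson r > 0.6 (p < 0.05) against the axis in both single-cell
   datasets are intersected with the bulk DEGs (|log2FC| > 1) of two
   patient cohorts.
4. **Multi-model integration** — 62 feature-selector × classifier
   combinations (lasso, elastic-net, stepwise-AIC, univariate filtering ×
   logistic/penalized logistic, LDA, naive Bayes, kNN, random forest,
   linear SVM, gradient boosting) are trained on a stratified 7:3 split of
   cohort 1 and ranked by mean AUC over the test partition and the
   cohort-2 validation set; per-gene model membership counts summarize
   marker robustness.

A negative-binomial single-cell simulator and a Gaussian two-cohort bulk
simulator with planted ground truth (signatures, high-risk cells, latent
pseudotime, informative genes) make the whole chain testable end to end.

## Worked example

```r
library(cccf)

params <- sc_sim_params(n_cells_per_condition = 300, n_genes = 400,
                        n_sig_up = 30, n_sig_down = 30, n_monotone = 30,
                        seed = 7)
sim   <- simulate_sc(params)
cells <- normalize_cells(sim$cells)

de  <- rank_sum_de(cells, cells$cells$condition, case = "MB")
sig <- extract_signatures(de, lfc_thresh = 0.25, alpha = 0.05)
lengths(sig)
#> signature1 signature2
#>         47         45

tensor <- score_all(cells, sig, build_registry(19))
result <- classify_cells(tensor)
table(result$label)
#> filtered     high      low
#>      387      148       65

risk_proportions(result, cells$cells$condition)
#>   group        high        low  filtered n_cells
#> 1   HBP 0.003333333 0.14333333 0.8533333     300
#> 2    MB 0.490000000 0.07333333 0.4366667     300
```

Half of the simulated MB cells were planted as high-risk; the consensus
calls recover that: 49% of MB cells are labelled high against 0.3% of HBP
cells, and the remaining cells are mostly filtered as intermediate — the
framework prefers abstention over a noisy call.

The full chain (two single-cell datasets, two bulk cohorts, feature
selection, 62-model grid) runs from one seed:

```r
run_pipeline("my-run", run_config(seed = 1))
```

which logs each stage (shapes, thresholds, filter survivors) and writes
CSV/JSON artifacts plus a checksummed `manifest.json` into `my-run/`.
The same is available from a shell:

```sh
Rscript inst/scripts/cccf-pipeline.R run-all --dir my-run --seed 1
Rscript inst/scripts/cccf-pipeline.R classify --dir my-run   # single stage
```

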