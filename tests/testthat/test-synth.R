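test_that("simulated single-cell matrix has the requested shape and metadata", {
  p <- sc_sim_params(n_cells_per_condition = 200, n_genes = 500,
                     n_sig_up = 20, n_sig_down = 20, n_monotone = 20,
                     seed = 3)
  sim <- simulate_sc(p)
  expect_equal(dim(sim$cells), c(400L, 500L))
  expect_true(all(sim$cells$x >= 0))
  expect_true(all(sim$cells$x == round(sim$cells$x)))
  expect_equal(sort(unique(sim$cells$cells$condition)), c("HBP", "MB"))
  # high-risk cells only in the case condition, at the requested fraction
  hr <- sim$cells$cells$high_risk
  expect_true(all(sim$cells$cells$condition[hr] == "MB"))
  expect_equal(sum(hr), round(0.5 * 200))
  expect_setequal(sim$truth$high_risk_cell_ids,
                  sim$cells$cells$cell_id[hr])
})

test_that("planted gene sets are disjoint and resolve against the matrix", {
  sim <- small_sc()
  tr <- sim$truth
  all_planted <- c(tr$sig_up_genes, tr$sig_down_genes,
                   tr$monotone_pseudotime_genes)
  expect_equal(anyDuplicated(all_planted), 0L)
  expect_true(all(all_planted %in% sim$cells$genes))
  expect_setequal(c(tr$monotone_up_genes, tr$monotone_down_genes),
                  tr$monotone_pseudotime_genes)
})

test_that("identical parameters and seed reproduce identical matrices", {
  p <- sc_sim_params(n_cells_per_condition = 50, n_genes = 100,
                     n_sig_up = 10, n_sig_down = 10, n_monotone = 10,
                     seed = 42)
  s1 <- simulate_sc(p)
  s2 <- simulate_sc(p)
  expect_identical(s1$cells$x, s2$cells$x)
  expect_identical(s1$truth, s2$truth)
  p2 <- p; p2$seed <- 43L
  expect_false(identical(simulate_sc(p2)$cells$x, s1$cells$x))
})

test_that("invalid simulation parameters fail naming the offending field", {
  expect_error(sc_sim_params(nb_dispersion = 0), "nb_dispersion")
  expect_error(sc_sim_params(frac_high_risk_in_case = 1.5),
               "frac_high_risk_in_case")
  expect_error(sc_sim_params(n_genes = 50, n_sig_up = 30, n_sig_down = 30,
                             n_monotone = 0), "n_genes")
  expect_error(bulk_sim_params(noise_sd = 0), "noise_sd")
  expect_error(bulk_sim_params(n_informative = 100, n_features = 64),
               "n_informative")
})

test_that("a zero planted effect leaves conditions exchangeable for signature genes", {
  p <- sc_sim_params(n_cells_per_condition = 300, n_genes = 200,
                     n_sig_up = 20, n_sig_down = 20, n_monotone = 0,
                     effect_log2fc = 0, seed = 8)
  sim <- simulate_sc(p)
  cond <- sim$cells$cells$condition
  pvals <- vapply(sim$truth$sig_up_genes, function(g)
    wilcox.test(sim$cells$x[cond == "MB", g],
                sim$cells$x[cond == "HBP", g], exact = FALSE)$p.value,
    numeric(1))
  # null p-values: no enrichment of small values beyond chance
  expect_gt(min(pvals) * length(pvals), 0.001)   # Bonferroni-scale check
  expect_gt(mean(pvals > 0.1), 0.6)
})

test_that("planted effect of 1 log2 unit doubles up-gene means in high-risk cells", {
  p <- sc_sim_params(n_cells_per_condition = 500, n_genes = 300,
                     n_sig_up = 20, n_sig_down = 20, n_monotone = 0,
                     effect_log2fc = 1, seed = 9)
  sim <- simulate_sc(p)
  hr <- sim$cells$cells$high_risk
  # library-size normalize, then compare the generative mean ratio
  depth <- rowSums(sim$cells$x)
  normed <- sim$cells$x / depth * mean(depth)
  g <- sim$truth$sig_up_genes[1:10]
  ratio <- colMeans(normed[hr, g]) / colMeans(normed[!hr, g])
  expect_true(all(abs(ratio - 2) < 0.4))          # within 20% of 2.0
})

test_that("bulk simulator produces two cohorts with the planted structure", {
  bulk <- small_bulk()
  expect_equal(nrow(bulk$cohort1$x) + nrow(bulk$cohort2$x), 130L)
  expect_equal(ncol(bulk$cohort1$x), 64L)
  expect_length(bulk$truth$informative_genes, 10L)
  # cohort 2 carries a constant positive batch offset on every feature
  delta <- colMeans(bulk$cohort2$x) - colMeans(bulk$cohort1$x)
  null_genes <- setdiff(colnames(bulk$cohort1$x),
                        bulk$truth$informative_genes)
  expect_true(all(abs(delta[null_genes] - 1) < 1))
  expect_gt(mean(delta[null_genes]), 0.5)
  # determinism
  again <- simulate_bulk(bulk_sim_params(seed = 11))
  expect_identical(again$cohort1$x, bulk$cohort1$x)
})

test_that("single-feature AUC matches the closed-form binormal value", {
  # effect 2 at noise sd 1: AUC = pnorm(2 / sqrt(2)) ~ 0.921
  bp <- bulk_sim_params(n_samples_per_cohort = 4000, informative_effect = 2,
                        noise_sd = 1, seed = 21)
  bulk <- simulate_bulk(bp)
  g <- bulk$truth$informative_genes[1:5]
  aucs <- vapply(g, function(gg)
    auc(bulk$cohort1$x[, gg], bulk$cohort1$labels), numeric(1))
  expect_true(all(abs(aucs - pnorm(2 / sqrt(2))) < 0.02))
  # a null feature sits at 0.5
  null_g <- setdiff(colnames(bulk$cohort1$x),
                    bulk$truth$informative_genes)[1]
  expect_lt(abs(auc(bulk$cohort1$x[, null_g], bulk$cohort1$labels) - 0.5),
            0.03)
})
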