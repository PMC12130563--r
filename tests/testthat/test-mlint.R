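test_that("stratified splitting keeps the 7:3 ratio and class balance", {
  labels <- rep(c(0, 1), each = 50)
  sp <- split_samples(labels, ratio = 0.7, seed = 1)
  expect_length(sp$train, 70L)
  expect_length(sp$test, 30L)
  expect_equal(sum(labels[sp$train]), 35)
  expect_length(intersect(sp$train, sp$test), 0L)
  # n = 10 balanced: 7 train with at least 3 of each class
  sp10 <- split_samples(rep(c(0, 1), 5), ratio = 0.7, seed = 2)
  expect_length(sp10$train, 7L)
  expect_gte(min(table(rep(c(0, 1), 5)[sp10$train])), 3)
  # determinism and seed sensitivity
  expect_identical(split_samples(labels, seed = 9),
                   split_samples(labels, seed = 9))
  expect_error(split_samples(rep(1, 10)), "class absent")
})

test_that("AUC handles perfect separation, inversion, and ties", {
  expect_equal(auc(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(0.2, 0.8), c(1, 0)), 0)
  expect_equal(auc(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("rank-based AUC matches the brute-force pairwise oracle", {
  auc_oracle <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
    tot / (length(pos) * length(neg))
  }
  set.seed(13)
  for (i in 1:300) {
    n <- sample(4:40, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(round(rnorm(n), sample(0:2, 1)))  # induces ties
    expect_equal(auc(scores, labels), auc_oracle(scores, labels))
  }
})

test_that("the model grid is deterministic with coherent pairs only", {
  specs <- enumerate_combinations()
  nm <- vapply(specs, `[[`, "", "name")
  expect_length(specs, 62L)    # 9 single + 6 selectors x 9 - 1 incoherent
  expect_equal(anyDuplicated(nm), 0L)
  expect_false("lasso + lasso-logistic" %in% nm)
  expect_true("lasso + logistic" %in% nm)
  expect_identical(nm, vapply(enumerate_combinations(), `[[`, "", "name"))
  expect_length(enumerate_combinations(allow_two_stage = FALSE), 9L)
})

test_that("a feature identical to the label yields a perfect training AUC", {
  y <- rep(c(0L, 1L), each = 10)
  x <- matrix(as.numeric(y), ncol = 1,
              dimnames = list(sprintf("s%02d", 1:20), "g1"))
  part <- list(x = x, y = y)
  spec <- enumerate_combinations()[[1]]
  expect_equal(spec$name, "logistic")
  res <- fit_evaluate(spec, part, part, part, seed = 1)
  expect_equal(res$auc_train, 1)
  expect_equal(res$mean_auc, (res$auc_test + res$auc_valid) / 2)
})

test_that("selection and coefficients never see test or validation labels", {
  bulk <- small_bulk()
  x1 <- bulk$cohort1$x
  sp <- split_samples(bulk$cohort1$labels, seed = 3)
  train <- list(x = x1[sp$train, ], y = bulk$cohort1$labels[sp$train])
  test <- list(x = x1[sp$test, ], y = bulk$cohort1$labels[sp$test])
  valid <- list(x = bulk$cohort2$x, y = bulk$cohort2$labels)
  specs <- enumerate_combinations()
  pick <- specs[vapply(specs, function(s) s$name, "") %in%
                  c("lasso + logistic", "stepwise-forward + lda",
                    "univariate-filter + random-forest")]
  for (spec in pick) {
    r1 <- fit_evaluate(spec, train, test, valid, seed = 5)
    noise_test <- test; noise_test$y <- rev(test$y)
    noise_valid <- valid
    noise_valid$y <- c(0L, 1L, valid$y[-(1:2)])
    r2 <- fit_evaluate(spec, train, noise_test, noise_valid, seed = 5)
    expect_identical(r2$genes_used, r1$genes_used, label = spec$name)
    expect_identical(r2$coefficients, r1$coefficients, label = spec$name)
    expect_identical(r2$auc_train, r1$auc_train, label = spec$name)
  }
})

test_that("an empty selection is flagged with chance-level AUC", {
  # constant features: the univariate filter can select nothing
  x <- matrix(1, 40, 6,
              dimnames = list(sprintf("s%02d", 1:40), paste0("g", 1:6)))
  y <- rep(c(0L, 1L), 20)
  part <- list(x = x, y = y)
  spec <- structure(list(selector = "univariate-filter",
                         classifier = "logistic",
                         name = "univariate-filter + logistic"),
                    class = "model_spec")
  res <- fit_evaluate(spec, part, part, part, seed = 1)
  expect_true(res$flagged)
  expect_length(res$genes_used, 0L)
  expect_equal(res$mean_auc, 0.5)
})

test_that("model ranking is a total order with the documented tie rules", {
  mk <- function(name, mean_auc, n_genes) {
    structure(list(spec = structure(list(selector = "none",
                                         classifier = name, name = name),
                                    class = "model_spec"),
                   genes_used = paste0("g", seq_len(n_genes)),
                   coefficients = NULL, auc_train = 0.9,
                   auc_test = mean_auc, auc_valid = mean_auc,
                   mean_auc = mean_auc, flagged = FALSE),
              class = "model_result")
  }
  res <- list(mk("a", 0.90, 5), mk("b", 0.95, 12), mk("c", 0.95, 7),
              mk("d", 0.90, 5))
  rk <- rank_models(res)
  expect_equal(vapply(rk, function(r) r$spec$name, ""),
               c("c", "b", "a", "d"))   # 0.95 first, fewer genes, then name
  expect_identical(rank_models(res), rank_models(res))
  single <- rank_models(res[2])
  expect_equal(single[[1]]$spec$name, "b")
})

test_that("gene model frequency counts membership across the grid", {
  mk <- function(genes) structure(list(spec = list(name = "m"),
                                       genes_used = genes),
                                  class = "model_result")
  res <- list(mk(c("a", "b")), mk(c("a")), mk(c("a", "c")))
  fr <- gene_frequency(res, genes = c("a", "b", "c", "z"))
  expect_equal(fr[["a"]], 3L)
  expect_equal(fr[["b"]], 1L)
  expect_equal(fr[["z"]], 0L)
})
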