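test_that("normalization scales each cell to the target sum then log1p", {
  x <- matrix(c(2, 0, 2), nrow = 1,
              dimnames = list("c1", c("g1", "g2", "g3")))
  cm <- cell_matrix(x)
  out <- normalize_cells(cm, target_sum = 4)
  expect_equal(as.numeric(out$x), log1p(c(2, 0, 2)))  # depth already at 4
  expect_true(out$normalized)

  x2 <- matrix(c(10, 0), nrow = 1, dimnames = list("c1", c("g1", "g2")))
  out2 <- normalize_cells(cell_matrix(x2), target_sum = 10000)
  expect_equal(as.numeric(out2$x), c(log1p(10000), 0))
})

test_that("an all-zero gene stays zero and an all-zero cell is rejected by name", {
  x <- rand_mat(10, 5)
  x[, 3] <- 0
  out <- normalize_cells(cell_matrix(x))
  expect_true(all(out$x[, 3] == 0))
  x[4, ] <- 0
  expect_error(normalize_cells(cell_matrix(x)), "c004")
})

test_that("tiny groups fall back to the exact rank-sum test", {
  # all 20 assignments of ranks 1..6 to a group of 3: the observed split
  # (1,2,3 vs 4,5,6) is one extreme tail -> two-sided p = 2/20
  x <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1,
              dimnames = list(paste0("s", 1:6), "g1"))
  groups <- rep(c("a", "b"), each = 3)
  splits <- utils::combn(6, 3)
  w_obs <- 6
  w_all <- apply(splits, 2, sum)
  p_oracle <- mean(w_all <= w_obs) + mean(w_all >= (21 - w_obs))
  expect_equal(p_oracle, 0.1)
  expect_warning(res <- rank_sum_de(x, groups, case = "a", delog = FALSE,
                                    min_cells = 1),
                 "tiny group")
  expect_equal(res$p, 0.1)
})

test_that("log2 fold change follows the pseudocount convention and group swap negates it", {
  set.seed(1)
  x <- matrix(rpois(400, 8) + 1, 40, 10,
              dimnames = list(sprintf("s%02d", 1:40), sprintf("g%02d", 1:10)))
  x[1:20, 1] <- 3; x[21:40, 1] <- 1        # means 3 vs 1, pc 1 -> log2fc 1
  groups <- rep(c("a", "b"), each = 20)
  res <- rank_sum_de(x, groups, case = "a", delog = FALSE, min_cells = 1)
  expect_equal(res$log2fc[res$gene == "g01"], 1)
  swapped <- rank_sum_de(x, groups, case = "b", delog = FALSE, min_cells = 1)
  expect_equal(swapped$log2fc, -res$log2fc)
  expect_equal(swapped$p, res$p)
})

test_that("identical groups give zero fold change and p = 1", {
  set.seed(3)
  half <- matrix(rpois(60, 6) + 1, 6, 10)
  x <- rbind(half, half)
  dimnames(x) <- list(sprintf("s%02d", 1:12), sprintf("g%02d", 1:10))
  res <- rank_sum_de(x, rep(c("a", "b"), each = 6), case = "a",
                     delog = FALSE, min_cells = 1)
  expect_true(all(abs(res$log2fc) < 1e-12))
  expect_true(all(res$p == 1))
})

test_that("rank-sum p-values are invariant under strictly monotone transforms", {
  set.seed(5)
  x <- matrix(rgamma(600, 2, 1), 60, 10,
              dimnames = list(sprintf("s%02d", 1:60), sprintf("g%02d", 1:10)))
  groups <- rep(c("a", "b"), 30)
  p1 <- rank_sum_de(x, groups, case = "a", delog = FALSE, min_cells = 1)$p
  p2 <- rank_sum_de(exp(x), groups, case = "a", delog = FALSE,
                    min_cells = 1)$p
  p3 <- rank_sum_de(x^3, groups, case = "a", delog = FALSE, min_cells = 1)$p
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    for (i in seq_len(m))
      adj[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
    adj
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(2)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("signature extraction applies strict thresholds in both directions", {
  rec <- data.frame(gene = c("up", "edge_lfc", "down_ns", "down", "null"),
                    log2fc = c(0.3, 0.25, -0.4, -0.5, 0.01),
                    p = c(0.001, 0.001, 0.15, 0.001, 0.9),
                    p_adj = c(0.01, 0.01, 0.2, 0.01, 0.95),
                    mean_a = 1, mean_b = 1)
  sig <- extract_signatures(rec)
  expect_equal(sig$signature1, "up")       # 0.25 exactly is excluded
  expect_equal(sig$signature2, "down")     # non-significant down excluded
  rec_no_dn <- rec[rec$log2fc > 0, ]
  expect_error(extract_signatures(rec_no_dn), "empty signature2")
})

test_that("bulk DE recovers planted genes and controls null discoveries", {
  bulk <- small_bulk()
  degs1 <- bulk_de(bulk$cohort1$x, bulk$cohort1$labels)
  inf <- bulk$truth$informative_genes
  expect_true(all(inf %in% degs1))
  nulls <- setdiff(colnames(bulk$cohort1$x), inf)
  expect_lte(length(intersect(degs1, nulls)), 0.05 * length(nulls))
  # a gene at exactly the fold-change threshold is excluded (strict >)
  x <- matrix(rep(c(3, 1), each = 30), ncol = 1,
              dimnames = list(sprintf("s%02d", 1:60), "g1"))
  labels <- rep(c(1, 0), each = 30)
  expect_equal(log2((3 + 1) / (1 + 1)), 1)
  expect_length(bulk_de(x, labels, lfc_thresh = 1), 0L)
})
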