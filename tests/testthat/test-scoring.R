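test_that("registry composition is deterministic and bounded", {
  reg <- build_registry(19)
  nm <- vapply(reg, `[[`, "", "name")
  expect_length(nm, 19L)
  expect_equal(anyDuplicated(nm), 0L)
  expect_equal(vapply(build_registry(1), `[[`, "", "name"), "zmean")
  core <- vapply(build_registry(8), `[[`, "", "name")
  expect_equal(core, c("zmean", "aucell05", "ucell", "meanrank",
                       "ssgsea025", "plage", "mscore24", "droprank"))
  expect_error(build_registry(50), "maximum")
  expect_error(build_registry(0), ">= 1")
})

test_that("a one-gene signature scored by mean-z equals that gene's z-score", {
  x <- rand_mat(30, 20, seed = 2)
  s <- score_cells(x, "g005", "zmean")
  expect_equal(s, as.numeric(scale(x[, "g005"])), ignore_attr = TRUE)
})

test_that("rank-AUC reaches 1 when signature genes occupy the top ranks", {
  g <- 100
  x <- matrix(rep(seq_len(g), each = 5), 5, g,
              dimnames = list(paste0("c", 1:5), sprintf("g%03d", 1:g)))
  sig <- sprintf("g%03d", 96:100)          # the 5 highest-expressed genes
  for (sc in c("aucell05", "aucell10", "aucell25")) {
    s <- score_cells(x, sig, sc)
    expect_equal(unname(s), rep(1, 5), tolerance = 1e-12)
  }
  # ucell also maximal
  expect_equal(unname(score_cells(x, sig, "ucell")), rep(1, 5))
})

test_that("rank-based scores have the analytic null mean under permutation", {
  # a random signature in an exchangeable cell: E[ucell] = 1/2,
  # E[centered meanrank] = 0
  set.seed(4)
  g <- 60
  sig <- sprintf("g%03d", sample(g, 8))
  u <- numeric(500); mr <- numeric(500)
  for (i in 1:500) {
    x <- matrix(sample(1000, g), 1, g,
                dimnames = list("c1", sprintf("g%03d", 1:g)))
    x <- rbind(x, x + 1)                    # scorer needs >= 2 rows for sd
    rownames(x) <- c("c1", "c2")
    u[i] <- score_cells(x, sig, "ucell")[1]
    mr[i] <- score_cells(x, sig, "meanrank")[1]
  }
  expect_lt(abs(mean(u) - 0.5), 0.02)
  expect_lt(abs(mean(mr)), 0.02)
})

test_that("rank scorers are invariant to within-cell monotone transforms", {
  x <- rand_mat(25, 40, seed = 6) + matrix(runif(1000), 25, 40)
  sig <- colnames(x)[1:6]
  for (sc in c("ucell", "meanrank", "droprank", "aucell10", "medrank")) {
    s1 <- score_cells(x, sig, sc)
    s2 <- score_cells(x^3, sig, sc)        # strictly monotone, rank-safe
    expect_equal(s1, s2, tolerance = 1e-12, label = sc)
  }
})

test_that("permuting cell order permutes all scores identically", {
  nm <- small_sc_norm()
  sig <- small_signatures()
  sub <- cell_matrix(nm$x[1:80, ], nm$cells[1:80, ], normalized = TRUE)
  perm <- sample(80)
  permuted <- cell_matrix(nm$x[1:80, ][perm, ], nm$cells[1:80, ][perm, ],
                          normalized = TRUE)
  reg <- build_registry(19)
  t1 <- score_all(sub, sig, reg)
  t2 <- score_all(permuted, sig, reg)
  expect_equal(t2$values, t1$values[perm, , ], tolerance = 1e-10)
})

test_that("the score tensor has 2k finite values per cell", {
  nm <- small_sc_norm()
  sig <- small_signatures()
  sub <- cell_matrix(nm$x[1:10, ], nm$cells[1:10, ], normalized = TRUE)
  t3 <- score_all(sub, sig, build_registry(3))
  expect_equal(dim(t3$values), c(10L, 3L, 2L))
  expect_equal(length(t3$values), 60L)
  expect_true(all(is.finite(t3$values)))
  t19 <- score_all(sub, sig, build_registry(19))
  expect_equal(dim(t19$values)[2] * 2L, 38L)
})

test_that("duplicate and absent signature genes are handled with warnings", {
  x <- rand_mat(12, 30, seed = 8)
  sig <- list(signature1 = c("g001", "g002", "g002"),
              signature2 = c("g010", "g011"))
  expect_warning(tensor <- score_all(x, sig, build_registry(2)),
                 "deduplicated")
  expect_true(all(is.finite(tensor$values)))
  expect_warning(score_cells(x, c("g001", "nope"), "zmean"), "absent")
  expect_error(score_cells(x, c("foo", "bar"), "zmean"), "no signature")
})

test_that("every core scorer separates planted high-risk cells on average", {
  sim <- small_sc()
  nm <- small_sc_norm()
  hr <- nm$cells$cell_id %in% sim$truth$high_risk_cell_ids
  reg <- build_registry(8)
  tensor <- score_all(nm, list(signature1 = sim$truth$sig_up_genes,
                               signature2 = sim$truth$sig_down_genes), reg)
  for (j in seq_along(reg)) {
    s1 <- tensor$values[, j, 1]
    s2 <- tensor$values[, j, 2]
    expect_gt(mean(s1[hr]), mean(s1[!hr]), label = reg[[j]]$name)
    expect_lt(mean(s2[hr]), mean(s2[!hr]),
              label = paste(reg[[j]]$name, "signature2"))
  }
})
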