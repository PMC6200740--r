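test_that("expressed-gene background uses the reads-and-fraction rule", {
  counts <- rbind(g1 = c(12, 15, 0, 0),    # >= 10 reads in 2 of 4 lines
                  g2 = c(9, 9, 9, 9),      # never reaches 10
                  g3 = c(100, 100, 100, 100))
  colnames(counts) <- paste0("cl", 1:4)
  bg <- estimate_background(counts)
  expect_identical(bg$genes, c("g1", "g3"))
  all_in <- estimate_background(counts, min_reads = 5)
  expect_identical(all_in$genes, rownames(counts))
  expect_error(estimate_background(counts, min_reads = 1000), "no gene")
  expect_error(estimate_background(-counts), "non-negative")
})

test_that("v1 enrichment equals the textbook Welch t on set summaries", {
  # two sets over 10 genes; group A cells carry set means {1.0, 1.2},
  # group B {0.0, 0.2} for set S1
  genes <- sprintf("g%02d", 1:10)
  cells <- c("a1", "a2", "b1", "b2")
  arr <- array(0, dim = c(1, 4, 10), dimnames = list("d1", cells, genes))
  s1 <- genes[1:5]
  arr[1, "a1", s1] <- 1.0; arr[1, "a2", s1] <- 1.2
  arr[1, "b1", s1] <- 0.0; arr[1, "b2", s1] <- 0.2
  arr[1, , genes[6:10]] <- rnorm(20)
  tensor <- signature_tensor(arr, c(a1 = "NPC_control", a2 = "NPC_control",
                                    b1 = "CCL", b2 = "CCL"))
  sets <- gene_set_collection(list(S1 = s1, S2 = genes[6:10]), "toy")
  res <- set_enrichment(tensor, "d1", "NPC_control", "CCL", sets)
  expect_equal(res$t_statistic[res$set == "S1"],
               oracle_welch_t(c(1.0, 1.2), c(0.0, 0.2)))
  expect_equal(res$direction, sign(res$t_statistic))
  # v2 pools set-gene values with a Student t
  res2 <- set_enrichment(tensor, "d1", "NPC_control", "CCL", sets,
                         variant = "v2")
  tt <- t.test(as.vector(arr[1, c("a1", "a2"), s1]),
               as.vector(arr[1, c("b1", "b2"), s1]), var.equal = TRUE)
  expect_equal(res2$t_statistic[res2$set == "S1"], unname(tt$statistic))
})

test_that("swapping the groups negates every t exactly", {
  set.seed(21)
  tensor <- random_tensor(2, list(CCL = 3, NPC_control = 3), 100)
  sets <- gene_set_collection(list(S1 = sprintf("g%04d", 1:20),
                                   S2 = sprintf("g%04d", 21:60)), "toy")
  ab <- enrich_all_drugs(tensor, "NPC_control", "CCL", sets)
  ba <- enrich_all_drugs(tensor, "CCL", "NPC_control", sets)
  expect_equal(ab$t_statistic, -ba$t_statistic)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("identical group profiles give t = 0 exactly", {
  set.seed(3)
  genes <- sprintf("g%03d", 1:50)
  vals <- matrix(rnorm(100), 2, 50)
  arr <- array(0, dim = c(1, 4, 50),
               dimnames = list("d1", c("a1", "a2", "b1", "b2"), genes))
  arr[1, "a1", ] <- vals[1, ]; arr[1, "b1", ] <- vals[1, ]
  arr[1, "a2", ] <- vals[2, ]; arr[1, "b2", ] <- vals[2, ]
  tensor <- signature_tensor(arr, c(a1 = "NPC_SZ", a2 = "NPC_SZ",
                                    b1 = "NPC_control", b2 = "NPC_control"))
  sets <- gene_set_collection(list(S = genes[1:10]), "toy")
  res <- set_enrichment(tensor, "d1", "NPC_SZ", "NPC_control", sets)
  expect_equal(res$t_statistic, 0)
})

test_that("sets below the minimum size after background are untested", {
  set.seed(4)
  tensor <- random_tensor(1, list(CCL = 2, NPC_control = 2), 50)
  genes <- dimnames(tensor)[[3]]
  sets <- gene_set_collection(list(big = genes[1:20], tiny = genes[1:3],
                                   outside = c("x1", "x2", "x3", "x4", "x5")),
                              "toy")
  counts <- matrix(20, 50, 4, dimnames = list(genes, paste0("cl", 1:4)))
  bg <- estimate_background(counts)
  res <- set_enrichment(tensor, "d01", "NPC_control", "CCL", sets, bg)
  expect_identical(res$tested[match(c("big", "tiny", "outside"), res$set)],
                   c(TRUE, FALSE, FALSE))
  expect_true(all(is.na(res$t_statistic[!res$tested])))
})

test_that("BH adjustment matches its closed form and is order-equivariant", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.37), 0.37)
  set.seed(9)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(adjust_fdr(p)[perm], adjust_fdr(p[perm]))
  # monotone in p
  q <- adjust_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("landmark consistency is the Pearson correlation of matched stats", {
  df <- function(t) data.frame(drug = rep(c("d1", "d2"), each = 3),
                               set = rep(c("s1", "s2", "s3"), 2),
                               t_statistic = t)
  same <- landmark_consistency(df(1:6), df(1:6))
  expect_equal(same$correlation, 1.0)
  expect_identical(same$n_pairs, 6L)
  set.seed(2)
  a <- rnorm(6); b <- rnorm(6)
  got <- landmark_consistency(df(a), df(b))
  expect_equal(got$correlation, cor(a, b))
  expect_error(landmark_consistency(df(1:6)[1:2, ], df(1:6)[1:2, ]),
               ">= 3 matched")
})

test_that("full and landmark-subset enrichment correlate positively when
           effects touch the landmark genes", {
  set.seed(33)
  n_genes <- 400
  genes <- sprintf("g%04d", seq_len(n_genes))
  landmark <- genes[seq(1, n_genes, by = 2)]   # half the universe measured
  cells <- c(sprintf("n%02d", 1:4), sprintf("c%02d", 1:4))
  groups <- setNames(rep(c("NPC_control", "CCL"), each = 4), cells)
  sets <- simulate_gene_sets(genes, n_sets = 8, set_size = 40,
                             seed = 2)$collection
  arr <- array(rnorm(5 * 8 * n_genes), c(5, 8, n_genes),
               dimnames = list(sprintf("d%02d", 1:5), cells, genes))
  # planted group differences on a few sets, spanning landmark genes too
  for (k in 1:3)
    arr[k, 1:4, sets$sets[[k]]] <- arr[k, 1:4, sets$sets[[k]]] + 1.5
  tensor <- signature_tensor(arr, groups)
  lm_tensor <- signature_tensor(arr[, , landmark, drop = FALSE], groups)
  full <- enrich_all_drugs(tensor, "NPC_control", "CCL", sets,
                           min_set_size = 5)
  sub <- enrich_all_drugs(lm_tensor, "NPC_control", "CCL", sets,
                          min_set_size = 5)
  lc <- landmark_consistency(full, sub)
  expect_gt(lc$correlation, 0.3)
  expect_lt(lc$p_value, 0.05)
})
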