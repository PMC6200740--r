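test_that("connectivity score hits the KS extremes", {
  genes <- sprintf("g%03d", 1:100)
  rzs <- seq(100, 1, length.out = 100)   # descending: g001 ranks first
  names(rzs) <- genes
  disease <- disease_signature(up = genes[1:10], down = genes[91:100])
  # up genes at the very top, down at the very bottom: perfect concordance
  expect_equal(connectivity_score(rzs, disease)$score, 1)
  # perfect reversal
  flipped <- disease_signature(up = genes[91:100], down = genes[1:10])
  expect_equal(connectivity_score(rzs, flipped)$score, -1)
  # same-sign enrichments null out: both tag sets at the top
  both_top <- disease_signature(up = genes[1:5], down = genes[6:10])
  expect_equal(connectivity_score(rzs, both_top)$score, 0)
})

test_that("negating a signature negates every nonzero score", {
  set.seed(31)
  genes <- sprintf("g%03d", 1:200)
  disease <- disease_signature(up = genes[1:20], down = genes[101:120])
  for (i in 1:20) {
    rzs <- setNames(rnorm(200), genes)
    s <- connectivity_score(rzs, disease)$score
    s_neg <- connectivity_score(-rzs, disease)$score
    if (s != 0) expect_equal(s_neg, -s) else expect_equal(s_neg, 0)
  }
})

test_that("ties in the ranking break lexicographically by gene id", {
  genes <- c("gB", "gA", "gC", "gD")
  rzs <- setNames(c(1, 1, 1, 1), genes)   # full tie: order is gA gB gC gD
  disease <- disease_signature(up = "gA", down = "gD")
  rec <- connectivity_score(rzs, disease)
  expect_equal(rec$score, 1)  # gA ranks 1, gD ranks last
})

test_that("the connectivity matrix composes per-signature scores", {
  set.seed(17)
  tensor <- random_tensor(2, list(NPC_control = 1, NPC_SZ = 1), 100)
  genes <- dimnames(tensor)[[3]]
  disease <- disease_signature(genes[1:10], genes[51:60])
  mat <- build_connectivity_matrix(tensor, disease, aggregate = "none")
  for (d in dimnames(tensor)[[1]]) for (cl in dimnames(tensor)[[2]]) {
    sig <- tensor[d, cl, ]
    expect_equal(mat[d, cl], connectivity_score(sig, disease)$score)
  }
  # a group of identical cell lines aggregates to the individual score
  arr <- array(NA_real_, c(2, 2, 100),
               dimnames = list(dimnames(tensor)[[1]],
                               c("x1", "x2"), genes))
  arr[, 1, ] <- tensor[, 1, ]; arr[, 2, ] <- tensor[, 1, ]
  dup <- signature_tensor(arr, c(x1 = "NPC_control", x2 = "NPC_control"))
  agg <- build_connectivity_matrix(dup, disease, aggregate = "by_group")
  expect_equal(unname(agg[, "NPC_control"]), unname(mat[, "NPC_control_1"]))
})

test_that("reversal screening is reproducible and requires a seed", {
  set.seed(23)
  tensor <- random_tensor(5, list(NPC_control = 2, NPC_SZ = 2), 150)
  genes <- dimnames(tensor)[[3]]
  disease <- disease_signature(genes[1:15], genes[101:115])
  expect_error(reversal_screen(tensor, disease, n_permutations = 100),
               "seed")
  r1 <- reversal_screen(tensor, disease, seed = 99, n_permutations = 200)
  r2 <- reversal_screen(tensor, disease, seed = 99, n_permutations = 200)
  expect_identical(r1$table, r2$table)
  expect_true(all(r1$table$p_value > 0 & r1$table$p_value <= 1))
  expect_identical(sort(unique(r1$classification$classification %in%
                          c("both", "SZ-only", "control-only", "none"))), TRUE)
})

test_that("classical MDS recovers collinear orderings and duplicates", {
  # three profiles on a line at mutual distances 1, 2, 3
  m <- rbind(c(0, 1, 3), c(0, 0, 0))
  colnames(m) <- c("c1", "c2", "c3")
  xy <- mds_embed(m, n_dims = 1)
  o <- order(xy[, 1])
  expect_true(identical(o, 1:3) || identical(o, 3:1))
  # duplicated columns land on identical coordinates
  m2 <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  m2[, "d"] <- m2[, "a"]
  xy2 <- mds_embed(m2, n_dims = 2)
  expect_equal(xy2["a", ], xy2["d", ], ignore_attr = TRUE)
  # embedded distances reproduce the input for intrinsically 2-D profiles
  pts <- cbind(c(0, 3, 0, 3), c(0, 0, 4, 4))
  prof <- t(pts) ; colnames(prof) <- paste0("p", 1:4)
  # lift the 2-D points into a 2-row profile matrix: distances are euclidean
  xy3 <- mds_embed(prof, n_dims = 2)
  expect_equal(as.matrix(dist(xy3)), as.matrix(dist(pts)),
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_error(mds_embed(m[, 1:2], n_dims = 2), "more cell lines")
})

test_that("drug prioritization ranks a planted reverser first", {
  set.seed(41)
  n_genes <- 300
  genes <- sprintf("g%04d", seq_len(n_genes))
  sets <- gene_set_collection(list(SZ_DE = genes[1:30]), "SZ DE")
  arr <- array(rnorm(5 * 2 * n_genes, sd = 0.5), c(5, 2, n_genes),
               dimnames = list(sprintf("d%02d", 1:5), c("c1", "c2"), genes))
  arr[3, , genes[1:30]] <- arr[3, , genes[1:30]] - 5  # strong set regulation
  tensor <- signature_tensor(arr, c(c1 = "NPC_control", c2 = "NPC_SZ"))
  pri <- prioritize_drugs(tensor, sets, top_k = 3)
  expect_identical(pri$ranking$drug[1], "d03")
  # top_k larger than the library returns the full ranking
  all_ranked <- prioritize_drugs(tensor, sets, top_k = 50)
  expect_identical(nrow(all_ranked$ranking), 5L)
  # equal scores break ties by drug id
  arr2 <- arr[c(1, 1), , ]
  dimnames(arr2)[[1]] <- c("dB", "dA")
  t2 <- signature_tensor(arr2, c(c1 = "NPC_control", c2 = "NPC_SZ"))
  pr2 <- prioritize_drugs(t2, sets)
  expect_identical(pr2$ranking$drug, c("dA", "dB"))
})
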