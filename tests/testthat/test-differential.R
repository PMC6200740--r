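test_that("DE calls use the inclusive threshold on group median RZS", {
  arr <- array(0, dim = c(1, 3, 3),
               dimnames = list("d1", c("a1", "a2", "a3"),
                               c("g1", "g2", "g3")))
  arr[1, , 1] <- c(2.5, 2.5, 2.5)
  arr[1, , 2] <- c(2.0, 2.0, 2.0)
  arr[1, , 3] <- c(-1.99, -1.99, -1.99)
  tensor <- signature_tensor(arr, c(a1 = "CCL", a2 = "CCL", a3 = "CCL"))
  de <- call_de(tensor, "CCL")
  expect_identical(de$is_de[match(c("g1", "g2", "g3"), de$gene)],
                   c(TRUE, TRUE, FALSE))
  expect_error(call_de(tensor, "NPC_SZ"), "no cell lines")
})

test_that("differential DE flags |difference of medians| >= 2", {
  arr <- array(0, dim = c(1, 2, 3),
               dimnames = list("d1", c("a1", "b1"), c("g1", "g2", "g3")))
  arr[1, "a1", ] <- c(2.5, 2.5, -1.5)
  arr[1, "b1", ] <- c(0.4, 2.5, 1.5)
  tensor <- signature_tensor(arr, c(a1 = "CCL", b1 = "NPC_control"))
  dd <- differential_de(tensor, "CCL", "NPC_control")
  expect_equal(dd$delta[match(c("g1", "g2", "g3"), dd$gene)],
               c(2.1, 0, -3))
  # g3 is flagged although neither group is DE on its own
  expect_identical(dd$is_differential[match(c("g1", "g2", "g3"), dd$gene)],
                   c(TRUE, FALSE, TRUE))
})

test_that("response categories are assigned by the documented scheme", {
  expect_identical(categorize_response(2.5, -0.8), "opposite_subthreshold")
  expect_identical(categorize_response(2.5, 1.0), "same_direction_magnitude")
  expect_identical(categorize_response(2.5, 0.1), "single_group")
  expect_identical(categorize_response(2.5, -2.2), "opposite_de")
  expect_identical(categorize_response(2.2, 3.7), "same_direction_magnitude")
  expect_error(categorize_response(1.0, -1.0), "neither group")
})

test_that("category partition is disjoint and exhaustive over the universe", {
  set.seed(11)
  tensor <- random_tensor(20, list(CCL = 3, NPC_control = 2, NPC_SZ = 2), 500,
                          sd = 1.5)
  acc <- response_accounting(tensor, "NPC", "CCL")
  dd <- differential_de(tensor, "NPC", "CCL")
  universe <- abs(dd$median_a) >= 2 | abs(dd$median_b) >= 2
  expect_identical(nrow(acc$table), sum(universe))
  expect_identical(sum(acc$summary$n), sum(universe))
  expect_true(all(acc$table$category %in%
                    c("opposite_subthreshold", "single_group",
                      "same_direction_magnitude", "opposite_de")))
  # every row got exactly one category
  expect_false(anyNA(acc$table$category))
  expect_false(any(acc$table$category == ""))
})

test_that("Mantel-Haenszel reproduces closed-form odds ratios", {
  # three identical strata [[10,5],[5,10]]: common OR equals the stratum OR
  strata <- do.call(rbind, replicate(3, c(a = 10, b = 5, c = 5, d = 10),
                                     simplify = FALSE))
  mh <- mantel_haenszel_test(strata)
  expect_equal(mh$common_odds_ratio, 4.0)
  expect_identical(mh$n_strata, 3L)
  # all-null strata: OR 1, p ~ 1
  null_strata <- do.call(rbind, replicate(4, c(a = 5, b = 5, c = 5, d = 5),
                                          simplify = FALSE))
  mh0 <- mantel_haenszel_test(null_strata)
  expect_equal(mh0$common_odds_ratio, 1.0)
  expect_gt(mh0$p_value, 0.99)
  # Bonferroni never below the raw p
  mh3 <- mantel_haenszel_test(strata, n_comparisons = 6L)
  expect_equal(mh3$bonferroni_p, min(1, mh3$p_value * 6))
})

test_that("single-stratum CMH equals the uncorrected chi-square test", {
  tab <- matrix(c(12, 7, 5, 16), 2, byrow = TRUE)
  mh <- mantel_haenszel_test(cbind(a = 12, b = 7, c = 5, d = 16))
  cs <- chisq.test(tab, correct = FALSE)
  expect_equal(mh$chi_square, unname(cs$statistic))
  expect_equal(mh$p_value, cs$p.value)
})

test_that("stratified statistic tracks stats::mantelhaen.test on large strata", {
  set.seed(77)
  k <- 12
  strata <- cbind(a = rpois(k, 40) + 5, b = rpois(k, 30) + 5,
                  c = rpois(k, 25) + 5, d = rpois(k, 45) + 5)
  mh <- mantel_haenszel_test(strata)
  arr <- aperm(array(t(strata), dim = c(2, 2, k)), c(2, 1, 3))
  ref <- mantelhaen.test(arr, correct = FALSE)
  # the reference uses the hypergeometric (n - 1) variance; with strata of
  # this size the two agree to well under a percent
  expect_equal(mh$chi_square, unname(ref$statistic), tolerance = 0.01)
  expect_equal(mh$common_odds_ratio, unname(ref$estimate), tolerance = 1e-8)
})

test_that("DE and differential-DE agree with brute-force enumeration", {
  set.seed(5)
  for (rep in 1:3) {
    tensor <- random_tensor(6, list(CCL = 3, NPC_control = 3, NPC_SZ = 2), 40,
                            sd = 1.5)
    de <- call_de(tensor, "CCL")
    dd <- differential_de(tensor, "NPC", "CCL")
    ca <- group_cells(tensor, "CCL"); cn <- group_cells(tensor, "NPC")
    for (i in sample(nrow(de), 50)) {
      d <- de$drug[i]; g <- de$gene[i]
      expect_identical(de$is_de[i],
                       abs(median(tensor[d, ca, g])) >= 2)
      expect_equal(de$median_rzs[i], median(tensor[d, ca, g]))
    }
    for (i in sample(nrow(dd), 50)) {
      d <- dd$drug[i]; g <- dd$gene[i]
      delta <- median(tensor[d, cn, g]) - median(tensor[d, ca, g])
      expect_equal(dd$delta[i], delta)
      expect_identical(dd$is_differential[i], abs(delta) >= 2)
    }
  }
})

test_that("gene_drug_counts scores genes by their DE drug count", {
  de <- data.frame(
    drug = rep(c("d1", "d2", "d3"), each = 5),
    gene = rep(sprintf("g%d", 1:5), 3),
    group_label = "CCL",
    median_rzs = 0,
    is_de = c(TRUE, TRUE, FALSE, FALSE, FALSE,
              TRUE, FALSE, FALSE, FALSE, FALSE,
              TRUE, TRUE, FALSE, FALSE, FALSE))
  gc <- gene_drug_counts(de)
  expect_identical(gc$counts$n_drugs_de[gc$counts$gene == "g1"], 3L)
  expect_identical(gc$counts$n_drugs_de[gc$counts$gene == "g2"], 2L)
  expect_false("g3" %in% gc$counts$gene)     # never DE: excluded
  expect_identical(gc$summary$n_perturbed_genes, 2L)
  # mean equals brute-force sum / length
  expect_equal(gc$summary$mean_drugs_per_gene, (3 + 2) / 2)
})
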