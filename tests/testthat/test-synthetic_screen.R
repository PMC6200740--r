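small_cfg <- function(seed = 1, ...) {
  args <- modifyList(
    list(n_genes = 50, n_drugs = 4,
         n_cell_lines = c(CCL = 1, NPC_control = 1, NPC_SZ = 1),
         wells_per_plate = 25, n_vehicle_wells = 12, n_phases = 1,
         n_effect_pairs = 10, n_reversers = 1, disease_set_size = 5,
         seed = seed),
    list(...))
  do.call(screen_config, args)
}

test_that("the same config and seed reproduce the screen bit-exactly", {
  s1 <- simulate_screen(small_cfg(seed = 4))
  s2 <- simulate_screen(small_cfg(seed = 4))
  expect_identical(s1$screen$matrix, s2$screen$matrix)
  expect_identical(s1$screen$annotation, s2$screen$annotation)
  expect_identical(s1$truth$base_effect, s2$truth$base_effect)
  s3 <- simulate_screen(small_cfg(seed = 5))
  expect_false(identical(s1$screen$matrix, s3$screen$matrix))
})

test_that("every (plate, cell line) carries the configured vehicle wells", {
  sim <- simulate_screen(screen_config(n_genes = 30, n_drugs = 6,
                                       n_vehicle_wells = 12,
                                       disease_set_size = 5, seed = 2))
  ann <- sim$screen$annotation
  veh <- ann[ann$treatment == "VEHICLE", ]
  per_stratum <- table(paste(veh$plate_id, veh$cell_line_id))
  expect_true(all(per_stratum == 12))
  # layout: one empty well per plate, positive controls in duplicate
  expect_true(all(table(ann$plate_id[ann$treatment == "EMPTY"]) == 1))
  expect_true(all(table(ann$plate_id[ann$treatment == "POSITIVE_CONTROL"]) == 4))
})

test_that("config invariants are enforced", {
  expect_error(screen_config(n_vehicle_wells = 2), "need support|>= 3")
  expect_error(screen_config(wells_per_plate = 17), "no room")
  expect_error(screen_config(noise_sd = 0), "positive")
  expect_error(screen_config(n_cell_lines = c(CCL = 0, NPC_control = 1,
                                              NPC_SZ = 1)), "n_cell_lines")
  expect_error(screen_config(n_drugs = 2, n_reversers = 2), "non-reverser")
})

test_that("a strong planted effect yields median RZS beyond the DE threshold", {
  # Monte-Carlo over 100 seeds: effect 3.0 against noise_sd 0.1 must be
  # recovered in at least 95% of screens
  hits <- vapply(1:100, function(seed) {
    cfg <- small_cfg(seed = seed, noise_sd = 0.1, n_effect_pairs = 5)
    sim <- simulate_screen(cfg)
    tensor <- build_signatures(sim$screen)
    eff <- sim$truth$base_effect
    eff <- eff[!eff$drug %in% sim$truth$reverser_drugs, ][1, ]
    grp <- "CCL"  # base effects apply in every group
    m <- tensor[eff$drug, group_cells(tensor, grp), eff$gene]
    abs(median(m)) >= 2
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("gene-set simulation plants coherent shifts and flags them", {
  universe <- sprintf("g%03d", 1:200)
  gs <- simulate_gene_sets(universe, n_sets = 10, set_size = 50,
                           planted = list(set_03 = list(group = "NPC_SZ",
                                                        shift = 1.0)),
                           seed = 6)
  expect_identical(length(gs$collection), 10L)
  expect_true(all(lengths(gs$collection$sets) == 50))
  expect_true(all(unlist(gs$collection$sets) %in% universe))
  expect_identical(gs$enriched_sets$set, "set_03")
  expect_identical(sort(unique(gs$shifts$gene)),
                   sort(gs$collection$sets$set_03))
  expect_true(all(gs$shifts$shift == 1.0))
  # null sets have no planted shift
  expect_false(any(gs$collection$sets$set_01 %in%
                     gs$shifts$gene[gs$shifts$shift != 0] &
                     !gs$collection$sets$set_01 %in% gs$collection$sets$set_03))
  expect_error(simulate_gene_sets(universe, set_size = 500), "exceeds")
  expect_error(
    simulate_gene_sets(universe, planted = list(set_99 = list(group = "NPC",
                                                              shift = 1))),
    "not among")
})

test_that("planted sequence densities come out at the configured rate", {
  set.seed(0)
  m <- motif_pattern("ACUK")
  sv <- simulate_sequences_and_variants(n_seqs = 100, length = 1000,
                                        motif = m, density_high = 4,
                                        density_low = 1,
                                        n_variants = c(SZ = 20, control = 20),
                                        in_motif_fraction = c(SZ = 0,
                                                              control = 0),
                                        seed = 12)
  counts <- vapply(sv$sequences[sv$groups == "high"],
                   function(s) length(oracle_scan(s, "ACUK")), 1L)
  # mean brute-force count ~ 4 within Poisson sampling error (se ~ 0.2)
  expect_lt(abs(mean(counts) - 4), 0.6)
  # zero in-motif fraction: no variant offset overlaps an occurrence
  overlaps <- vapply(seq_len(nrow(sv$variants)), function(i)
    variant_in_motif(sv$variants$window_seq[i], sv$variants$offset[i], m),
    logical(1))
  expect_false(any(overlaps))
  # reproducibility
  sv2 <- simulate_sequences_and_variants(n_seqs = 5, length = 300, motif = m,
                                         seed = 12)
  sv3 <- simulate_sequences_and_variants(n_seqs = 5, length = 300, motif = m,
                                         seed = 12)
  expect_identical(sv2$sequences, sv3$sequences)
  expect_identical(sv2$variants, sv3$variants)
  expect_error(simulate_sequences_and_variants(length = 3, motif = m),
               "longer")
})

test_that("unplanted drug annotations have uniform feature prevalence", {
  drugs <- sprintf("drug_%02d", 1:60)
  sim <- simulate_drug_annotations(drugs, classes = "target",
                                   n_features = 10, background_prob = 0.3,
                                   unannotated_frac = 0, seed = 14)
  prev <- table(factor(sim$annotations$feature,
                       levels = paste0("target_", sprintf("f_%02d", 1:10))))
  # each feature ~ Binomial(60, 0.3): all within 5 sd of the mean
  expect_true(all(abs(prev - 18) < 5 * sqrt(60 * 0.3 * 0.7)))
  # every emitted feature belongs to the declared catalog
  expect_true(all(sim$annotations$feature %in% unlist(sim$catalog)))
})
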