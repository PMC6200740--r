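test_that("compute_rzs matches the printed definition on a hand fixture", {
  # vehicle values 1..5 per gene, treated 5: median 3, raw MAD of
  # {2,1,0,1,2} is 1, so RZS = (5 - 3) / 1 = 2
  scr <- make_plate_screen(
    vehicle = lapply(1:5, function(v) rep(v, 3)),
    treated = list(drugX = rep(5, 3)))
  sig <- compute_rzs(scr, "drugX", "CL1", "P1")
  expect_equal(unname(sig$rzs), rep(2, 3))

  # treated equal to the vehicle median gives 0
  scr0 <- make_plate_screen(
    vehicle = lapply(1:5, function(v) rep(v, 2)),
    treated = list(drugX = rep(3, 2)))
  expect_equal(unname(compute_rzs(scr0, "drugX", "CL1", "P1")$rzs), c(0, 0))
})

test_that("RZS is invariant to plate-wide location and scale changes", {
  set.seed(42)
  base <- make_plate_screen(
    vehicle = replicate(7, rnorm(20, 7, 1), simplify = FALSE),
    treated = list(drugX = rnorm(20, 8, 1), drugY = rnorm(20, 6, 1)))
  ref_x <- compute_rzs(base, "drugX", "CL1", "P1")$rzs
  for (c_shift in c(-3, 10)) {
    shifted <- base
    shifted$matrix <- base$matrix + c_shift
    expect_equal(compute_rzs(shifted, "drugX", "CL1", "P1")$rzs, ref_x)
  }
  for (c_scale in c(0.25, 4)) {
    scaled <- base
    scaled$matrix <- base$matrix * c_scale
    expect_equal(compute_rzs(scaled, "drugX", "CL1", "P1")$rzs, ref_x)
  }
})

test_that("multiple treated wells are averaged before the transform", {
  scr <- make_plate_screen(
    vehicle = lapply(1:5, function(v) rep(v, 2)),
    treated = list(drugX = c(4, 4), drugX = c(6, 8)))
  # wells average to (5, 6); vehicle median 3, MAD 1
  sig <- compute_rzs(scr, "drugX", "CL1", "P1")
  expect_equal(unname(sig$rzs), c(2, 3))
})

test_that("zero vehicle MAD is floored to the smallest positive stratum MAD", {
  # gene 1 constant across vehicles (MAD 0), gene 2 varies (MAD 1)
  scr <- make_plate_screen(
    vehicle = list(c(5, 1), c(5, 2), c(5, 3), c(5, 4), c(5, 5)),
    treated = list(drugX = c(6, 4)))
  sig <- compute_rzs(scr, "drugX", "CL1", "P1")
  expect_identical(sig$flagged, "g01")
  expect_equal(unname(sig$rzs), c((6 - 5) / 1, (4 - 3) / 1))
})

test_that("fewer than three vehicle wells is an error", {
  scr <- make_plate_screen(vehicle = list(c(1, 1), c(2, 2), c(3, 3)),
                           treated = list(drugX = c(5, 5)))
  keep <- scr$annotation$treatment != "VEHICLE" |
    scr$annotation$well_id %in% c("veh01", "veh02")
  expect_error(
    expression_screen(scr$matrix[, scr$annotation$well_id[keep]],
                      scr$annotation[keep, ]) |>
      compute_rzs("drugX", "CL1", "P1"),
    "vehicle wells")
})

test_that("collapse_probes keeps the highest-mean probe per gene", {
  m <- rbind(p1 = c(5, 5), p2 = c(7, 7), p3 = c(1, 2), p4 = c(1, 2))
  colnames(m) <- c("w1", "w2")
  mapping <- c(p1 = "G1", p2 = "G1", p3 = "G2", p4 = "G3")
  out <- collapse_probes(m, mapping)
  expect_identical(rownames(out), c("G1", "G2", "G3"))
  expect_equal(out["G1", ], c(w1 = 7, w2 = 7))          # p2 wins
  expect_equal(out["G2", ], c(w1 = 1, w2 = 2))          # single probe: identity
  # exact tie: lexicographically smaller probe id retained
  tie <- rbind(pB = c(3, 5), pA = c(5, 3))
  colnames(tie) <- c("w1", "w2")
  out2 <- collapse_probes(tie, c(pA = "G", pB = "G"))
  expect_equal(unname(out2["G", ]), c(5, 3))            # pA's row
  # unmapped probes dropped with a warning
  expect_warning(collapse_probes(m, mapping[-4]), "dropped")
})

test_that("collapse_replicates takes per-gene medians and counts replicates", {
  mk <- function(v) structure(list(drug = "d", cell_line = "c", plate = "p",
                                   rzs = setNames(v, c("g1", "g2", "g3")),
                                   n_replicates = 1L, flagged = character(0)),
                              class = "drug_signature")
  expect_equal(unname(collapse_replicates(list(mk(c(1, -1, 0)),
                                               mk(c(3, 0, 5))))$rzs),
               c(2, -0.5, 2.5))
  one <- collapse_replicates(list(mk(c(1, 2, 3))))
  expect_equal(unname(one$rzs), c(1, 2, 3))
  expect_identical(one$n_replicates, 1L)
  tri <- collapse_replicates(list(mk(c(-1, -1, -1)), mk(c(0, 0, 0)),
                                  mk(c(5, 5, 5))))
  expect_equal(unname(tri$rzs), c(0, 0, 0))
  expect_identical(tri$n_replicates, 3L)
  bad <- mk(c(1, 2, 3)); names(bad$rzs) <- c("x", "y", "z")
  expect_error(collapse_replicates(list(mk(c(1, 2, 3)), bad)), "mismatched")
})

test_that("vehicle pseudo-signatures have zero per-gene median for odd counts", {
  set.seed(7)
  scr <- make_plate_screen(
    vehicle = replicate(5, rnorm(10), simplify = FALSE),
    treated = list(drugX = rnorm(10)))
  vs <- vehicle_signatures(scr)
  expect_identical(ncol(vs$rzs), 5L)
  expect_equal(max(abs(apply(vs$rzs, 1, median))), 0)
})

test_that("tensor slices equal collapsed plate-level signatures", {
  sim <- simulate_screen(screen_config(n_genes = 60, n_drugs = 4,
                                       n_cell_lines = c(CCL = 1, NPC_control = 1,
                                                        NPC_SZ = 1),
                                       wells_per_plate = 25, n_phases = 2,
                                       n_effect_pairs = 20,
                                       disease_set_size = 10, seed = 3))
  tensor <- build_signatures(sim$screen)
  ann <- sim$screen$annotation
  for (d in dimnames(tensor)[[1]]) for (cl in dimnames(tensor)[[2]]) {
    plates <- unique(ann$plate_id[ann$treatment == d & ann$cell_line_id == cl])
    sigs <- lapply(plates, function(p) compute_rzs(sim$screen, d, cl, p))
    expect_equal(unname(tensor[d, cl, ]),
                 unname(collapse_replicates(sigs)$rzs))
  }
  expect_identical(unname(attr(tensor, "n_replicates")[1, 1]), 2L)
})
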