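# Fixtures and independent oracles shared across the suite.

# A minimal one-plate screen built well by well: `vehicle` is a list of
# per-gene vehicle-well value vectors (one element per well), `treated` a
# named list drug -> per-gene values (one well each).
make_plate_screen <- function(vehicle, treated, genes = NULL,
                              cell = "CL1", group = "CCL", plate = "P1",
                              phase = "phase_1") {
  n_genes <- length(vehicle[[1L]])
  genes <- genes %||% sprintf("g%02d", seq_len(n_genes))
  wells <- c(sprintf("veh%02d", seq_along(vehicle)),
             sprintf("trt%02d", seq_along(treated)))
  mat <- cbind(do.call(cbind, vehicle), do.call(cbind, treated))
  dimnames(mat) <- list(genes, wells)
  ann <- data.frame(
    well_id = wells, plate_id = plate, phase_id = phase,
    cell_line_id = cell, group_label = group,
    treatment = c(rep("VEHICLE", length(vehicle)), names(treated)),
    dose = 10, stringsAsFactors = FALSE)
  expression_screen(mat, ann)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A signature tensor assembled directly from per-(drug, cell) gene vectors.
# `values` is array-like [drug, cell, gene]; groups named per cell.
make_tensor <- function(values, groups) {
  signature_tensor(values, groups)
}

# Random tensor with dimnames, for property tests.
random_tensor <- function(n_drugs, cells_per_group, n_genes, sd = 1,
                          rfun = stats::rnorm) {
  cells <- unlist(lapply(names(cells_per_group), function(g)
    sprintf("%s_%d", g, seq_len(cells_per_group[[g]]))))
  groups <- rep(names(cells_per_group), unlist(cells_per_group))
  names(groups) <- cells
  arr <- array(rfun(n_drugs * length(cells) * n_genes, sd = sd),
               dim = c(n_drugs, length(cells), n_genes),
               dimnames = list(sprintf("d%02d", seq_len(n_drugs)), cells,
                               sprintf("g%04d", seq_len(n_genes))))
  signature_tensor(arr, groups)
}

# Oracle: per-gene robust Z-score evaluated literally from its definition.
oracle_rzs <- function(treated_wells, vehicle_wells) {
  # treated_wells: genes x wells matrix (averaged); vehicle: genes x wells
  treated <- rowMeans(treated_wells)
  vapply(seq_len(nrow(vehicle_wells)), function(g) {
    v <- vehicle_wells[g, ]
    med <- median(v)
    mad_raw <- median(abs(v - med))
    (treated[[g]] - med) / mad_raw
  }, numeric(1L))
}

# Oracle: one-sided Fisher/hypergeometric upper tail as an explicit
# binomial-coefficient sum (independent of phyper).
oracle_hyper_p <- function(a, b, c, d) {
  m <- a + b; K <- a + c; N <- a + b + c + d
  ks <- seq.int(a, min(m, K))
  if (!length(ks)) return(0)
  sum(choose(K, ks) * choose(N - K, m - ks)) / choose(N, m)
}

# Oracle: Welch two-sample t statistic from the textbook formula.
oracle_welch_t <- function(x, y) {
  (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
}

# Oracle: brute-force degenerate motif scan, character by character.
oracle_scan <- function(seq, pattern) {
  codes <- list(A = "A", C = "C", G = "G", U = "U",
                K = c("G", "U"), W = c("A", "U"), R = c("A", "G"),
                Y = c("C", "U"), S = c("C", "G"), M = c("A", "C"),
                N = c("A", "C", "G", "U", "N"))
  seq <- chartr("T", "U", toupper(seq))
  pc <- strsplit(chartr("T", "U", toupper(pattern)), "")[[1L]]
  sc <- strsplit(seq, "")[[1L]]
  hits <- integer(0L)
  if (length(sc) < length(pc)) return(hits)
  for (st in seq_len(length(sc) - length(pc) + 1L)) {
    ok <- TRUE
    for (k in seq_along(pc)) {
      if (!sc[[st + k - 1L]] %in% codes[[pc[[k]]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, st - 1L)
  }
  hits
}

random_rna <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
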