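# Synthetic plate-structured drug screens with planted ground truth.
#
# The generative model is additive on the log2 scale (the real screens
# arrive log2-normalized, so no count model is simulated):
#
#   expression[g, w] = baseline[g] + cell_offset + plate_offset
#                      + phase_offset + effect(drug, g, group) + noise
#
# Vehicle wells receive no drug effect. Plate/phase offsets are
# gene-independent scalars by default (a per-gene option exists), enough
# to exercise the RZS batch-cancellation property. Each plate hosts one
# cell line and mirrors the screening layout: one empty well, a block of
# vehicle wells, duplicated positive-control wells, and the remaining
# wells for test compounds; drugs overflow onto additional plates, and
# every (cell line, phase) receives the full drug panel, giving each
# (drug, cell line) one replicate signature per phase.

#' Configuration of a synthetic screen
#'
#' Defaults are the scaled-down study conditions used throughout the test
#' suite (20 drugs, 500 genes, 3+3+2 cell lines); \code{preset = "full"}
#' switches to the full screen dimensions (135 drugs, 8 cancer cell lines,
#' 12+12 neural progenitor lines, 96-well plates).
#'
#' @param n_genes Number of genes.
#' @param n_drugs Number of test compounds.
#' @param n_cell_lines Named integer vector: cell lines per group
#'   (\code{CCL}, \code{NPC_control}, \code{NPC_SZ}).
#' @param wells_per_plate Wells per plate (one empty + vehicle + positive
#'   controls + drug wells).
#' @param n_vehicle_wells Vehicle (DMSO) wells per plate per cell line
#'   (>= 3; default 12, the screening layout).
#' @param n_pos_control_wells Positive-control wells per plate (default 4:
#'   two controls in duplicate).
#' @param n_phases Screening phases; every cell line is re-screened in each
#'   phase (default 2).
#' @param noise_sd Per-well Gaussian noise sd (log2 units).
#' @param batch_sd Plate and phase offset sd (log2 units).
#' @param cell_sd Cell-line offset sd (log2 units).
#' @param baseline_mean,baseline_sd Per-gene baseline distribution.
#' @param per_gene_batch When TRUE, plate offsets vary per gene.
#' @param n_effect_pairs Number of planted (drug, gene) base effects
#'   (applied in every cell group).
#' @param effect_size Absolute planted log2 shift.
#' @param npc_extra_frac Fraction of NPC-active pairs that are NPC-only
#'   (cell-type modifier); makes the CCL group this much less responsive.
#' @param sz_extra_frac Additional diagnosis-specific pairs (active only in
#'   NPC_SZ lines), as a fraction of \code{n_effect_pairs}.
#' @param n_reversers Number of drugs planted to negate the disease
#'   signature.
#' @param reverser_strength Absolute shift applied by reverser drugs to the
#'   disease-signature genes (down on its up genes, up on its down genes).
#' @param disease_set_size Genes per side of the planted disease signature.
#' @param seed Integer seed fixing the full output.
#' @param preset \code{"scaled_down"} (default) or \code{"full"}.
#' @return A list of class \code{screen_config}.
#' @export
screen_config <- function(n_genes = 500L, n_drugs = 20L,
                          n_cell_lines = c(CCL = 3L, NPC_control = 3L,
                                           NPC_SZ = 2L),
                          wells_per_plate = 40L, n_vehicle_wells = 12L,
                          n_pos_control_wells = 4L, n_phases = 2L,
                          noise_sd = 0.3, batch_sd = 1.0, cell_sd = 1.0,
                          baseline_mean = 7, baseline_sd = 1.5,
                          per_gene_batch = FALSE,
                          n_effect_pairs = 200L, effect_size = 3.0,
                          npc_extra_frac = 0.15, sz_extra_frac = 0.10,
                          n_reversers = 2L, reverser_strength = 3.0,
                          disease_set_size = 50L, seed = 1L,
                          preset = c("scaled_down", "full")) {
  preset <- match.arg(preset)
  cfg <- as.list(environment())
  cfg$preset <- preset
  if (preset == "full") {
    defaults <- formals(screen_config)
    if (identical(n_drugs, eval(defaults$n_drugs))) cfg$n_drugs <- 135L
    if (identical(n_cell_lines, eval(defaults$n_cell_lines)))
      cfg$n_cell_lines <- c(CCL = 8L, NPC_control = 12L, NPC_SZ = 12L)
    if (identical(wells_per_plate, eval(defaults$wells_per_plate)))
      cfg$wells_per_plate <- 96L
    if (identical(n_effect_pairs, eval(defaults$n_effect_pairs)))
      cfg$n_effect_pairs <- 1500L
  }
  for (f in c("n_genes", "n_drugs", "wells_per_plate", "n_phases"))
    if (!is_count(cfg[[f]])) stop_fmt("%s must be a positive integer", f)
  if (!is_count(cfg$n_vehicle_wells, min = 3L))
    stop_fmt("n_vehicle_wells must be >= 3 (median/MAD need support)")
  if (length(cfg$n_cell_lines) != 3L ||
      !all(names(cfg$n_cell_lines) == c("CCL", "NPC_control", "NPC_SZ")) ||
      any(cfg$n_cell_lines < 1L))
    stop_fmt("n_cell_lines must be c(CCL, NPC_control, NPC_SZ), all >= 1")
  cfg$n_drug_wells <- cfg$wells_per_plate - 1L - cfg$n_vehicle_wells -
    cfg$n_pos_control_wells
  if (cfg$n_drug_wells < 1L)
    stop_fmt("wells_per_plate leaves no room for drug wells")
  if (cfg$noise_sd <= 0) stop_fmt("noise_sd must be positive")
  if (cfg$n_reversers >= cfg$n_drugs)
    stop_fmt("n_reversers must leave at least one non-reverser drug")
  if (!is_count(cfg$seed, min = 0L)) stop_fmt("seed must be an integer")
  if (2L * cfg$disease_set_size > cfg$n_genes)
    stop_fmt("disease signature (2 x %d genes) exceeds the gene universe (%d)",
             cfg$disease_set_size, cfg$n_genes)
  structure(cfg, class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  cat(sprintf("Screen config (%s): %d genes, %d drugs, %s cell lines, %d phases, seed %d\n",
              x$preset, x$n_genes, x$n_drugs,
              paste(x$n_cell_lines, collapse = "+"), x$n_phases, x$seed))
  invisible(x)
}

# sample n distinct (drug, gene) pairs from the given drugs, avoiding `used`
.sample_pairs <- function(n, drugs, genes, used) {
  if (n == 0L) return(character(0L))
  pool_size <- length(drugs) * length(genes)
  got <- character(0L)
  while (length(got) < n) {
    cand <- paste(sample(drugs, n - length(got), replace = TRUE),
                  sample(genes, n - length(got), replace = TRUE), sep = "\r")
    got <- unique(c(got, setdiff(cand, used)))
    if (length(got) + length(used) >= pool_size) break
  }
  got[seq_len(min(n, length(got)))]
}

.pairs_df <- function(keys, effect_size) {
  if (!length(keys))
    return(data.frame(drug = character(), gene = character(),
                      effect = numeric(), stringsAsFactors = FALSE))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(drug = vapply(parts, `[[`, "", 1L),
             gene = vapply(parts, `[[`, "", 2L),
             effect = sample(c(-1, 1), length(keys), replace = TRUE) * effect_size,
             stringsAsFactors = FALSE)
}

#' Simulate a plate-structured screen with planted ground truth
#'
#' @param config A [screen_config()].
#' @param planted_set_shifts Optional data.frame (gene, group, shift,
#'   drug) of extra drug-induced shifts, e.g. from [simulate_gene_sets()];
#'   \code{group} may be \code{NPC} (both NPC groups) or a group label;
#'   \code{drug = NA} applies to every drug.
#' @return A list with \code{screen} (an [expression_screen()]) and
#'   \code{truth} (class \code{screen_truth}): planted base effects,
#'   cell-type and diagnosis modifiers, reverser drugs, disease signature,
#'   batch offsets, and any planted set shifts.
#' @export
simulate_screen <- function(config = screen_config(),
                            planted_set_shifts = NULL) {
  stopifnot(inherits(config, "screen_config"))
  set.seed(config$seed)
  genes <- seq_ids("g", config$n_genes)
  drugs <- seq_ids("drug", config$n_drugs)
  cells <- c(seq_ids("CCL", config$n_cell_lines[["CCL"]]),
             seq_ids("NPCc", config$n_cell_lines[["NPC_control"]]),
             seq_ids("NPCsz", config$n_cell_lines[["NPC_SZ"]]))
  cell_group <- rep(c("CCL", "NPC_control", "NPC_SZ"), config$n_cell_lines)
  names(cell_group) <- cells

  baseline <- stats::rnorm(config$n_genes, config$baseline_mean,
                           config$baseline_sd)
  names(baseline) <- genes
  cell_offsets <- stats::rnorm(length(cells), 0, config$cell_sd)
  names(cell_offsets) <- cells
  phase_ids <- seq_ids("phase", config$n_phases)
  phase_offsets <- stats::rnorm(config$n_phases, 0, config$batch_sd)
  names(phase_offsets) <- phase_ids

  # planted disease signature and reverser drugs
  sig_genes <- sample(genes, 2L * config$disease_set_size)
  disease <- disease_signature(sig_genes[seq_len(config$disease_set_size)],
                               sig_genes[-seq_len(config$disease_set_size)],
                               label = "planted")
  reversers <- if (config$n_reversers > 0L)
    sort(sample(drugs, config$n_reversers)) else character(0L)

  # planted (drug, gene) effects on the non-reverser drugs
  free_drugs <- setdiff(drugs, reversers)
  base_keys <- .sample_pairs(config$n_effect_pairs, free_drugs, genes,
                             character(0L))
  n_extra <- round(config$npc_extra_frac / (1 - config$npc_extra_frac) *
                   length(base_keys))
  ct_keys <- .sample_pairs(n_extra, free_drugs, genes, base_keys)
  n_sz <- round(config$sz_extra_frac * length(base_keys))
  dx_keys <- .sample_pairs(n_sz, free_drugs, genes, c(base_keys, ct_keys))
  base_effect <- .pairs_df(base_keys, config$effect_size)
  celltype_modifier <- .pairs_df(ct_keys, config$effect_size)
  diagnosis_modifier <- .pairs_df(dx_keys, config$effect_size)
  if (length(reversers)) {
    rev_rows <- do.call(rbind, lapply(reversers, function(d) {
      data.frame(drug = d,
                 gene = c(disease$up, disease$down),
                 effect = c(rep(-config$reverser_strength, length(disease$up)),
                            rep(config$reverser_strength, length(disease$down))),
                 stringsAsFactors = FALSE)
    }))
    base_effect <- rbind(base_effect, rev_rows)
  }

  # per-group gene x drug effect matrices
  eff <- list()
  for (grp in c("CCL", "NPC_control", "NPC_SZ")) {
    m <- matrix(0, config$n_genes, config$n_drugs,
                dimnames = list(genes, drugs))
    m[cbind(base_effect$gene, base_effect$drug)] <- base_effect$effect
    if (grp != "CCL")
      m[cbind(celltype_modifier$gene, celltype_modifier$drug)] <-
        m[cbind(celltype_modifier$gene, celltype_modifier$drug)] +
        celltype_modifier$effect
    if (grp == "NPC_SZ")
      m[cbind(diagnosis_modifier$gene, diagnosis_modifier$drug)] <-
        m[cbind(diagnosis_modifier$gene, diagnosis_modifier$drug)] +
        diagnosis_modifier$effect
    if (!is.null(planted_set_shifts)) {
      ps <- planted_set_shifts
      applies <- ps$group == grp | (ps$group == "NPC" & grp != "CCL")
      for (i in which(applies)) {
        target_drugs <- if (is.na(ps$drug[[i]])) drugs else ps$drug[[i]]
        m[ps$gene[[i]], target_drugs] <- m[ps$gene[[i]], target_drugs] +
          ps$shift[[i]]
      }
    }
    eff[[grp]] <- m
  }

  # positive-control effect: fixed +2 shift on a fixed 5% gene subset
  pc_genes <- sample(genes, max(1L, round(0.05 * config$n_genes)))
  pc_effect <- numeric(config$n_genes); names(pc_effect) <- genes
  pc_effect[pc_genes] <- 2

  # plate layout: each plate hosts one cell line; the drug panel spans
  # ceiling(n_drugs / n_drug_wells) plates per (cell line, phase)
  plates_per_panel <- ceiling(config$n_drugs / config$n_drug_wells)
  drug_chunks <- split(drugs, ceiling(seq_along(drugs) / config$n_drug_wells))
  ann <- list(); plate_ids <- character(0L)
  for (ph in phase_ids) for (cl in cells) for (k in seq_len(plates_per_panel)) {
    plate <- sprintf("%s_%s_p%d", ph, cl, k)
    plate_ids <- c(plate_ids, plate)
    chunk <- drug_chunks[[k]]
    treatments <- c("EMPTY", rep("VEHICLE", config$n_vehicle_wells),
                    rep("POSITIVE_CONTROL", config$n_pos_control_wells),
                    chunk)
    ann[[length(ann) + 1L]] <- data.frame(
      well_id = sprintf("%s_w%02d", plate, seq_along(treatments)),
      plate_id = plate, phase_id = ph, cell_line_id = cl,
      group_label = unname(cell_group[[cl]]),
      treatment = treatments,
      dose = ifelse(treatments %in% c("EMPTY", "VEHICLE"), 0, 10),
      stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, ann)
  ann$cell_line_id[ann$treatment == "EMPTY"] <- ann$cell_line_id[ann$treatment == "EMPTY"]
  if (config$per_gene_batch) {
    plate_offsets <- matrix(stats::rnorm(config$n_genes * length(plate_ids),
                                         0, config$batch_sd),
                            config$n_genes, length(plate_ids),
                            dimnames = list(genes, plate_ids))
  } else {
    plate_offsets <- stats::rnorm(length(plate_ids), 0, config$batch_sd)
    names(plate_offsets) <- plate_ids
  }

  measured <- ann[ann$treatment != "EMPTY", , drop = FALSE]
  expr <- matrix(stats::rnorm(config$n_genes * nrow(measured),
                              0, config$noise_sd),
                 config$n_genes, nrow(measured),
                 dimnames = list(genes, measured$well_id))
  expr <- expr + baseline
  expr <- sweep(expr, 2L, cell_offsets[measured$cell_line_id] +
                            phase_offsets[measured$phase_id], `+`)
  if (config$per_gene_batch) {
    expr <- expr + plate_offsets[, measured$plate_id]
  } else {
    expr <- sweep(expr, 2L, plate_offsets[measured$plate_id], `+`)
  }
  is_drug <- !measured$treatment %in% c("VEHICLE", "POSITIVE_CONTROL")
  for (grp in c("CCL", "NPC_control", "NPC_SZ")) {
    idx <- which(is_drug & measured$group_label == grp)
    if (length(idx))
      expr[, idx] <- expr[, idx] + eff[[grp]][, measured$treatment[idx]]
  }
  pc_idx <- which(measured$treatment == "POSITIVE_CONTROL")
  expr[, pc_idx] <- expr[, pc_idx] + pc_effect
  attr(expr, "gct_version") <- "1.2"

  truth <- structure(list(
    base_effect = base_effect,
    celltype_modifier = celltype_modifier,
    diagnosis_modifier = diagnosis_modifier,
    reverser_drugs = reversers,
    disease_signature = disease,
    enriched_sets = planted_set_shifts,
    plate_offsets = plate_offsets,
    phase_offsets = phase_offsets,
    cell_offsets = cell_offsets,
    positive_control_genes = pc_genes,
    config = config), class = "screen_truth")
  list(screen = expression_screen(expr, ann), truth = truth)
}

#' @export
print.screen_truth <- function(x, ...) {
  cat(sprintf("Screen truth: %d base effects, %d cell-type and %d diagnosis modifiers, %d reverser drug(s)\n",
              nrow(x$base_effect), nrow(x$celltype_modifier),
              nrow(x$diagnosis_modifier), length(x$reverser_drugs)))
  invisible(x)
}

#' Simulate gene sets with planted group-specific regulation
#'
#' Draws \code{n_sets} disjoint-by-chance sets of size \code{set_size} from
#' the universe and records, for the planted sets, a coherent per-gene
#' drug-induced shift in the designated comparison group. Feed the
#' returned \code{shifts} to [simulate_screen()] as
#' \code{planted_set_shifts} to realize the regulation.
#'
#' @param universe Character vector of gene ids.
#' @param n_sets Number of sets.
#' @param set_size Genes per set (<= length(universe)).
#' @param planted Named list: set name (e.g. \code{"set_03"}) ->
#'   \code{list(group =, shift =, drug = NA)}; names must be unique and
#'   refer to generated sets.
#' @param seed Integer seed.
#' @param category Collection category label.
#' @return A list: \code{collection} (a [gene_set_collection()]),
#'   \code{shifts} (data.frame gene, group, shift, drug),
#'   \code{enriched_sets} (data.frame set, group, shift).
#' @export
simulate_gene_sets <- function(universe, n_sets = 10L, set_size = 50L,
                               planted = list(), seed = 1L,
                               category = "synthetic") {
  if (set_size > length(universe))
    stop_fmt("set_size (%d) exceeds the universe (%d)", set_size,
             length(universe))
  if (anyDuplicated(names(planted)))
    stop_fmt("planted set name collision: '%s'",
             names(planted)[duplicated(names(planted))][[1L]])
  set.seed(seed)
  nm <- seq_ids("set", n_sets)
  sets <- lapply(seq_len(n_sets), function(i) sample(universe, set_size))
  names(sets) <- nm
  unknown <- setdiff(names(planted), nm)
  if (length(unknown))
    stop_fmt("planted set '%s' is not among the generated sets", unknown[[1L]])
  shifts <- list(); enriched <- list()
  for (s in names(planted)) {
    p <- planted[[s]]
    shifts[[s]] <- data.frame(gene = sets[[s]], group = p$group,
                              shift = p$shift,
                              drug = p$drug %||% NA_character_,
                              stringsAsFactors = FALSE)
    enriched[[s]] <- data.frame(set = s, group = p$group, shift = p$shift,
                                stringsAsFactors = FALSE)
  }
  list(collection = gene_set_collection(sets, category),
       shifts = if (length(shifts)) do.call(rbind, shifts) else NULL,
       enriched_sets = if (length(enriched)) do.call(rbind, enriched) else NULL)
}

# Break every motif occurrence in `chars` whose start is not protected.
# `protected` is a logical vector marking positions that must not mutate.
.break_occurrences <- function(chars, motif, protected) {
  len <- length(motif$classes)
  alphabet <- c("A", "C", "G", "U")
  for (iter in seq_len(200L)) {
    starts <- scan_motif(paste(chars, collapse = ""), motif) + 1L
    starts <- starts[!starts %in% attr(protected, "starts")]
    if (!length(starts)) return(chars)
    for (st in starts) {
      span <- st:(st + len - 1L)
      free <- span[!protected[span]]
      if (!length(free)) next
      # mutate one free position to a base outside its motif class
      pos <- free[[1L]]
      cls <- motif$classes[[pos - st + 1L]]
      choices <- setdiff(alphabet, cls)
      if (!length(choices)) {  # N code: any base matches; pick another position
        pos <- if (length(free) > 1L) free[[2L]] else next
        cls <- motif$classes[[pos - st + 1L]]
        choices <- setdiff(alphabet, cls)
        if (!length(choices)) next
      }
      chars[[pos]] <- sample(choices, 1L)
    }
  }
  stop_fmt("could not generate a motif-free background (motif too permissive)")
}

# One sequence of the given length with exactly `k` planted occurrences.
.seq_with_occurrences <- function(length, motif, k) {
  len <- length(motif$classes)
  if (len > length) stop_fmt("motif longer than the sequence")
  alphabet <- c("A", "C", "G", "U")
  for (attempt in seq_len(50L)) {
    chars <- sample(alphabet, length, replace = TRUE)
    starts <- integer(0L)
    if (k > 0L) {
      # place k starts with pairwise gaps >= 2*len so repairs never collide
      avail <- seq_len(length - len + 1L)
      for (i in seq_len(k)) {
        if (!length(avail)) break
        st <- sample(avail, 1L)
        starts <- c(starts, st)
        avail <- avail[abs(avail - st) >= 2L * len]
      }
      if (length(starts) < k) next
      for (st in starts) {
        inst <- vapply(motif$classes,
                       function(cls) sample(setdiff(cls, "N"), 1L), "")
        chars[st:(st + len - 1L)] <- inst
      }
    }
    protected <- rep(FALSE, length)
    for (st in starts) protected[st:(st + len - 1L)] <- TRUE
    attr(protected, "starts") <- starts
    chars <- tryCatch(.break_occurrences(chars, motif, protected),
                      error = function(e) NULL)
    if (is.null(chars)) next
    if (length(scan_motif(paste(chars, collapse = ""), motif)) == k)
      return(paste(chars, collapse = ""))
  }
  stop_fmt("failed to plant %d motif occurrences in a %d nt sequence", k, length)
}

#' Simulate transcript sequences and variant cohorts with planted motifs
#'
#' Generates two groups of sequences whose total motif density is the
#' planted per-kb rate (the background is motif-free; a Poisson number of
#' concrete occurrences is seeded per sequence), and variant cohorts whose
#' reference windows contain a motif occurrence spanning the variant
#' offset with the configured per-cohort probability.
#'
#' @param n_seqs Sequences per group.
#' @param length Sequence length (nt).
#' @param motif A [motif_pattern()] (or pattern string).
#' @param density_high,density_low Planted occurrences per kb for the two
#'   groups.
#' @param n_variants Named integer vector: variants per cohort (e.g.
#'   \code{c(SZ = 200, control = 200)}).
#' @param in_motif_fraction Named numeric vector in \code{[0, 1]}, same
#'   names as \code{n_variants}: probability that a cohort variant lies in
#'   a motif occurrence.
#' @param seed Integer seed.
#' @param window Half-width of the variant reference window (default 10,
#'   i.e. 21 nt windows with the variant at offset 10).
#' @return A list: \code{sequences} (named character; names prefixed
#'   \code{high_}/\code{low_}), \code{groups} (factor per sequence),
#'   \code{variants} (variant_table data.frame), \code{truth} (per-variant
#'   planted in-motif flags and per-sequence planted counts).
#' @export
simulate_sequences_and_variants <- function(n_seqs = 50L, length = 1000L,
                                            motif = motif_pattern("ACUK"),
                                            density_high = 4, density_low = 1,
                                            n_variants = c(SZ = 200L,
                                                           control = 200L),
                                            in_motif_fraction = c(SZ = 0.3,
                                                                  control = 0.1),
                                            seed = 1L, window = 10L) {
  if (!inherits(motif, "motif_pattern")) motif <- motif_pattern(motif)
  len <- length(motif$classes)
  if (len > length) stop_fmt("motif longer than the sequences")
  if (any(in_motif_fraction < 0 | in_motif_fraction > 1))
    stop_fmt("in_motif_fraction must lie in [0, 1]")
  if (!identical(sort(names(n_variants)), sort(names(in_motif_fraction))))
    stop_fmt("n_variants and in_motif_fraction must share cohort names")
  set.seed(seed)
  make_group <- function(prefix, density) {
    counts <- stats::rpois(n_seqs, density * length / 1000)
    seqs <- vapply(counts, function(k) .seq_with_occurrences(length, motif, k),
                   "")
    names(seqs) <- paste0(prefix, "_", seq_ids("seq", n_seqs))
    list(seqs = seqs, counts = counts)
  }
  hi <- make_group("high", density_high)
  lo <- make_group("low", density_low)
  sequences <- c(hi$seqs, lo$seqs)
  groups <- factor(rep(c("high", "low"), each = n_seqs))

  wlen <- 2L * window + 1L
  if (len > wlen) stop_fmt("motif longer than the variant window")
  variants <- list()
  for (cohort in names(n_variants)) {
    n <- n_variants[[cohort]]
    planted <- stats::runif(n) < in_motif_fraction[[cohort]]
    for (i in seq_len(n)) {
      if (planted[[i]]) {
        w <- .seq_with_occurrences(wlen, motif, 0L)
        chars <- strsplit(w, "", fixed = TRUE)[[1L]]
        lo_st <- max(1L, window + 1L - len + 1L)
        hi_st <- min(window + 1L, wlen - len + 1L)
        st <- sample(seq.int(lo_st, hi_st), 1L)
        chars[st:(st + len - 1L)] <-
          vapply(motif$classes, function(cls) sample(setdiff(cls, "N"), 1L), "")
        w <- paste(chars, collapse = "")
      } else {
        w <- .seq_with_occurrences(wlen, motif, 0L)
      }
      ref <- substr(w, window + 1L, window + 1L)
      variants[[length(variants) + 1L]] <- data.frame(
        variant_id = sprintf("%s_v%04d", cohort, i),
        cohort = cohort,
        annotation = sample(c("missense", "essential_splice_site",
                              "synonymous"), 1L),
        window_seq = w, offset = window, ref = ref,
        alt = sample(setdiff(c("A", "C", "G", "U"), ref), 1L),
        planted_in_motif = planted[[i]],
        stringsAsFactors = FALSE)
    }
  }
  variants <- do.call(rbind, variants)
  truth <- list(planted_counts = c(hi$counts, lo$counts),
                planted_in_motif = variants$planted_in_motif)
  variants_out <- validate_variant_table(
    variants[, c("variant_id", "cohort", "annotation", "window_seq",
                 "offset", "ref", "alt")])
  list(sequences = sequences, groups = groups, variants = variants_out,
       truth = truth)
}

#' Simulate drug annotations with planted feature enrichment
#'
#' Emits (drug, class, feature) annotation rows where every feature
#' belongs to a declared per-class catalog. A configurable fraction of
#' drugs carries no annotation in a class (and so drops out of that
#' class's testing background). Planted (drug group, class, feature)
#' entries make the feature much more prevalent inside the group.
#'
#' @param drugs Character vector of screened drugs.
#' @param classes Character vector of annotation classes.
#' @param n_features Features per class (the catalog is
#'   \code{class_f01 ...}).
#' @param planted List of \code{list(drugs =, class =, feature =,
#'   prob =)}; \code{feature} must belong to the class catalog and
#'   \code{drugs} to the screened drugs.
#' @param background_prob Probability that an annotated drug carries any
#'   given feature (default 0.2).
#' @param unannotated_frac Fraction of drugs with no annotations in each
#'   class (default 0.2).
#' @param seed Integer seed.
#' @return A list: \code{annotations} (data.frame drug, class, feature)
#'   and \code{truth} (the planted entries).
#' @export
simulate_drug_annotations <- function(drugs, classes = c("target",
                                                         "side_effect"),
                                      n_features = 20L, planted = list(),
                                      background_prob = 0.2,
                                      unannotated_frac = 0.2, seed = 1L) {
  set.seed(seed)
  catalog <- lapply(classes, function(cl) paste0(cl, "_", seq_ids("f", n_features)))
  names(catalog) <- classes
  for (p in planted) {
    if (!p$class %in% classes) stop_fmt("planted class '%s' unknown", p$class)
    if (!p$feature %in% catalog[[p$class]])
      stop_fmt("planted feature '%s' outside the '%s' catalog", p$feature,
               p$class)
    if (length(setdiff(p$drugs, drugs)))
      stop_fmt("planted drugs outside the screened set")
  }
  rows <- list()
  for (cl in classes) {
    n_unann <- round(unannotated_frac * length(drugs))
    unannotated <- if (n_unann > 0L) sample(drugs, n_unann) else character(0L)
    annotated <- setdiff(drugs, unannotated)
    for (f in catalog[[cl]]) {
      prob <- rep(background_prob, length(annotated))
      names(prob) <- annotated
      for (p in planted) {
        if (p$class == cl && p$feature == f) {
          in_grp <- intersect(p$drugs, annotated)
          prob[in_grp] <- p$prob %||% 0.8
        }
      }
      hit <- annotated[stats::runif(length(annotated)) < prob]
      if (length(hit))
        rows[[length(rows) + 1L]] <- data.frame(drug = hit, class = cl,
                                                feature = f,
                                                stringsAsFactors = FALSE)
    }
    # guarantee every annotated drug keeps >= 1 annotation of the class
    have <- unique(unlist(lapply(rows, function(r)
      if (r$class[[1L]] == cl) r$drug else NULL)))
    for (d in setdiff(annotated, have))
      rows[[length(rows) + 1L]] <- data.frame(drug = d, class = cl,
                                              feature = sample(catalog[[cl]], 1L),
                                              stringsAsFactors = FALSE)
  }
  annotations <- validate_drug_annotation(do.call(rbind, rows))
  rownames(annotations) <- NULL
  list(annotations = annotations, truth = planted, catalog = catalog)
}
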