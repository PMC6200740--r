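# End-to-end pipeline runner over a single YAML configuration.
#
# Stages (in dependency order): simulate, signatures, de, enrich,
# connectivity, chemgen, motifs. Each stage consumes only files written by
# earlier stages into the output directory, so deleting downstream outputs
# and rerunning reproduces them; every randomized stage derives its seed
# from the single configured seed.

.pipeline_stages <- c("simulate", "signatures", "de", "enrich",
                      "connectivity", "chemgen", "motifs")
.stage_deps <- list(simulate = character(0L),
                    signatures = "simulate",
                    de = "signatures",
                    enrich = "signatures",
                    connectivity = "signatures",
                    chemgen = "enrich",
                    motifs = "simulate")

#' Serialize a signature tensor to GCT (columns = drug:cell)
#'
#' @param tensor A [signature_tensor()].
#' @param gct_path Output GCT path.
#' @param cells_path Output TSV path for the cell line -> group table.
#' @return Invisibly, \code{gct_path}.
#' @export
write_signature_gct <- function(tensor, gct_path, cells_path) {
  d <- dim(tensor); dn <- dimnames(tensor)
  m <- matrix(NA_real_, d[[3L]], d[[1L]] * d[[2L]],
              dimnames = list(dn[[3L]], NULL))
  cn <- character(d[[1L]] * d[[2L]]); k <- 0L
  for (dr in dn[[1L]]) for (cl in dn[[2L]]) {
    k <- k + 1L
    m[, k] <- tensor[dr, cl, ]
    cn[[k]] <- paste(dr, cl, sep = ":")
  }
  colnames(m) <- cn
  write_gct(m, gct_path)
  groups <- attr(tensor, "groups")
  write_screen_table(data.frame(cell_line_id = names(groups),
                                group_label = unname(groups)), cells_path)
  invisible(gct_path)
}

#' Read a signature tensor written by [write_signature_gct()]
#'
#' @param gct_path GCT path with \code{drug:cell} columns.
#' @param cells_path Cell line -> group TSV path.
#' @return A [signature_tensor()].
#' @export
read_signature_gct <- function(gct_path, cells_path) {
  m <- read_gct(gct_path)
  parts <- strsplit(colnames(m), ":", fixed = TRUE)
  drugs <- vapply(parts, `[[`, "", 1L); cells <- vapply(parts, `[[`, "", 2L)
  ud <- sort(unique(drugs)); uc <- sort(unique(cells))
  arr <- array(NA_real_, c(length(ud), length(uc), nrow(m)),
               dimnames = list(ud, uc, rownames(m)))
  for (k in seq_len(ncol(m))) arr[drugs[[k]], cells[[k]], ] <- m[, k]
  cells_df <- utils::read.delim(cells_path, stringsAsFactors = FALSE)
  groups <- cells_df$group_label; names(groups) <- cells_df$cell_line_id
  signature_tensor(arr, groups)
}

#' Validate a pipeline configuration
#'
#' Checks thresholds, stage names, stage dependencies and seed presence,
#' reporting every violation rather than stopping at the first.
#'
#' @param config Path to a YAML configuration or an equivalent list.
#' @return Character vector of violations (empty when valid).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_fmt("config file not found: %s", config)
    config <- tryCatch(yaml::read_yaml(config), error = function(e)
      stop_fmt("config does not parse: %s", conditionMessage(e)))
  }
  v <- character(0L)
  if (is.null(config$seed)) {
    v <- c(v, "seed: missing (randomized stages refuse to default silently)")
  } else if (!is_count(config$seed, min = 0L)) {
    v <- c(v, "seed: must be a non-negative integer")
  }
  stages <- config$stages %||% .pipeline_stages
  unknown <- setdiff(stages, .pipeline_stages)
  for (s in unknown) v <- c(v, sprintf("stages: unknown stage '%s'", s))
  stages <- intersect(.pipeline_stages, stages)
  for (s in stages) {
    miss <- setdiff(.stage_deps[[s]], stages)
    if (length(miss))
      v <- c(v, sprintf("stages: '%s' requires '%s'", s, miss[[1L]]))
  }
  for (f in c("de_threshold", "diff_threshold", "negligible_threshold")) {
    val <- config$de[[f]]
    if (!is.null(val) && (!is_number(val) || val <= 0))
      v <- c(v, sprintf("de.%s: must be positive", f))
  }
  for (f in c("fdr")) {
    val <- config$enrich[[f]] %||% config$connectivity[[f]]
    if (!is.null(val) && (!is_number(val) || val <= 0 || val >= 1))
      v <- c(v, sprintf("%s: fdr must lie in (0, 1)", f))
  }
  sim <- config$simulate %||% list()
  cfg_try <- tryCatch({
    do.call(screen_config, c(sim, list(seed = config$seed %||% 1L)))
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(cfg_try)) v <- c(v, sprintf("simulate: %s", cfg_try))
  groups_ok <- c("CCL", "NPC_control", "NPC_SZ", "NPC")
  for (g in c(config$enrich$group_a, config$enrich$group_b))
    if (!g %in% groups_ok)
      v <- c(v, sprintf("enrich: unknown group '%s'", g))
  v
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages in dependency order, writing every
#' intermediate to \code{output_dir} in the package's plain-text formats
#' and returning (and writing) a manifest of the run.
#'
#' @param config Path to a YAML configuration or an equivalent list.
#'   Recognized keys: \code{seed} (required), \code{output_dir},
#'   \code{stages}, and per-stage parameter blocks \code{simulate},
#'   \code{gene_sets}, \code{de}, \code{enrich}, \code{connectivity},
#'   \code{chemgen}, \code{motifs}.
#' @return A list of class \code{run_manifest}: config hash, seed, stage
#'   records (outputs and row counts), package version.
#' @export
run_pipeline <- function(config) {
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- yaml::read_yaml(config)
  }
  violations <- validate_config(config)
  if (length(violations))
    stop_fmt("invalid config:\n  %s", paste(violations, collapse = "\n  "))
  if (is.null(config_path)) {
    config_path <- tempfile(fileext = ".yaml")
    yaml::write_yaml(config, config_path)
    on.exit(unlink(config_path))
  }
  config_hash <- unname(tools::md5sum(config_path))
  out_dir <- config$output_dir %||% "pipeline_output"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  stages <- intersect(.pipeline_stages, config$stages %||% .pipeline_stages)
  path <- function(...) file.path(out_dir, paste0(...))
  record <- list()
  note <- function(stage, outputs, rows) {
    record[[stage]] <<- list(outputs = unname(outputs), rows = rows)
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                    paste(basename(outputs), collapse = ", ")))
  }

  if ("simulate" %in% stages) {
    sim_cfg <- do.call(screen_config,
                       c(config$simulate %||% list(), list(seed = seed)))
    gs_cfg <- config$gene_sets %||% list()
    gs <- simulate_gene_sets(seq_ids("g", sim_cfg$n_genes),
                             n_sets = gs_cfg$n_sets %||% 10L,
                             set_size = gs_cfg$set_size %||% 50L,
                             planted = gs_cfg$planted %||%
                               list(set_01 = list(group = "NPC", shift = 1.0)),
                             seed = seed + 1L)
    sim <- simulate_screen(sim_cfg, planted_set_shifts = gs$shifts)
    write_gct(sim$screen$matrix, path("screen.gct"))
    write_screen_table(sim$screen$annotation, path("annotation.tsv"))
    write_gmt(gs$collection, path("gene_sets.gmt"))
    ds <- sim$truth$disease_signature
    write_gmt(gene_set_collection(list(up = ds$up, down = ds$down),
                                  "disease_signature"),
              path("disease_signature.gmt"))
    writeLines(sim$truth$reverser_drugs, path("truth_reversers.txt"))
    sv <- do.call(simulate_sequences_and_variants,
                  c(config$sequences %||% list(), list(seed = seed + 2L)))
    write_fasta(sv$sequences, path("sequences.fasta"))
    write_screen_table(sv$variants, path("variants.tsv"))
    da <- simulate_drug_annotations(
      seq_ids("drug", sim_cfg$n_drugs),
      planted = config$drug_annotations$planted %||% list(),
      seed = seed + 3L)
    write_screen_table(da$annotations, path("drug_annotations.tsv"))
    note("simulate",
         c(path("screen.gct"), path("annotation.tsv"), path("gene_sets.gmt"),
           path("disease_signature.gmt"), path("sequences.fasta"),
           path("variants.tsv"), path("drug_annotations.tsv")),
         ncol(sim$screen$matrix))
  }

  if ("signatures" %in% stages) {
    screen <- expression_screen(read_gct(path("screen.gct")),
                                read_screen_table(path("annotation.tsv"),
                                                  "plate_annotation"))
    tensor <- build_signatures(screen,
                               mad_constant = config$signatures$mad_constant
                                 %||% "raw")
    write_signature_gct(tensor, path("signatures.gct"), path("cells.tsv"))
    note("signatures", c(path("signatures.gct"), path("cells.tsv")),
         dim(tensor)[[1L]] * dim(tensor)[[2L]])
  }

  if (any(c("de", "enrich", "connectivity") %in% stages))
    tensor <- read_signature_gct(path("signatures.gct"), path("cells.tsv"))

  if ("de" %in% stages) {
    cfg <- analysis_config(
      de_threshold = config$de$de_threshold %||% 2,
      diff_threshold = config$de$diff_threshold %||% 2,
      negligible_threshold = config$de$negligible_threshold %||% 0.5)
    de_npc <- call_de(tensor, "NPC", cfg)
    de_ccl <- call_de(tensor, "CCL", cfg)
    write_screen_table(rbind(de_npc, de_ccl), path("de_calls.tsv"))
    acc <- response_accounting(tensor, "NPC", "CCL", cfg)
    write_screen_table(acc$summary, path("response_categories.tsv"))
    mh <- mantel_haenszel_responsiveness(tensor, "NPC", "CCL", cfg)
    write_screen_table(data.frame(common_odds_ratio = mh$common_odds_ratio,
                                  chi_square = mh$chi_square,
                                  p_value = mh$p_value,
                                  bonferroni_p = mh$bonferroni_p,
                                  n_strata = mh$n_strata),
                       path("mh_summary.tsv"))
    note("de", c(path("de_calls.tsv"), path("response_categories.tsv"),
                 path("mh_summary.tsv")),
         nrow(de_npc) + nrow(de_ccl))
  }

  if ("enrich" %in% stages) {
    sets <- read_gmt(path("gene_sets.gmt"), "synthetic")
    enr <- enrich_all_drugs(tensor,
                            config$enrich$group_a %||% "NPC",
                            config$enrich$group_b %||% "CCL",
                            sets,
                            variant = config$enrich$variant %||% "v1")
    write_screen_table(enr, path("enrichment.tsv"))
    note("enrich", path("enrichment.tsv"), nrow(enr))
  }

  if ("connectivity" %in% stages) {
    ds_gmt <- read_gmt(path("disease_signature.gmt"), "disease_signature")
    disease <- disease_signature(ds_gmt$sets$up, ds_gmt$sets$down)
    rs <- reversal_screen(tensor, disease,
                          n_permutations = config$connectivity$n_permutations
                            %||% 1000L,
                          seed = seed + 4L,
                          fdr = config$connectivity$fdr %||% 0.1)
    write_screen_table(rs$table, path("connectivity.tsv"))
    note("connectivity", path("connectivity.tsv"), nrow(rs$table))
  }

  if ("chemgen" %in% stages) {
    enr <- utils::read.delim(path("enrichment.tsv"), stringsAsFactors = FALSE)
    ann <- read_screen_table(path("drug_annotations.tsv"), "drug_annotation")
    groups <- group_set_drugs(enr, fdr = config$chemgen$fdr %||% 0.1,
                              min_drugs = config$chemgen$min_drugs %||% 3L)
    cg <- chemogenomic_enrichment(groups, ann)
    if (is.null(cg))
      cg <- data.frame(set = character(), class = character(),
                       feature = character(), a = integer(), b = integer(),
                       c = integer(), d = integer(), odds_ratio = numeric(),
                       p_value = numeric(), drugs = character(),
                       q_value = numeric())
    write_screen_table(cg, path("chemgen.tsv"))
    note("chemgen", path("chemgen.tsv"), nrow(cg))
  }

  if ("motifs" %in% stages) {
    seqs <- read_fasta(path("sequences.fasta"))
    variants <- read_screen_table(path("variants.tsv"), "variant_table")
    catalog <- motif_catalog(config$motifs$catalog)
    groups <- ifelse(grepl("^high_", names(seqs)), "high", "low")
    md <- do.call(rbind, lapply(catalog, function(m) {
      r <- motif_density_test(seqs[groups == "high"], seqs[groups == "low"], m)
      data.frame(motif = r$motif, density_high = r$mean_density[[1L]],
                 density_low = r$mean_density[[2L]],
                 t_statistic = r$t_statistic, p_value = r$p_value)
    }))
    cohorts <- setdiff(unique(variants$cohort), "control")
    ce <- cohort_enrichment_scan(variants, catalog, cohorts)
    write_screen_table(md, path("motif_density.tsv"))
    write_screen_table(ce, path("motif_cohorts.tsv"))
    note("motifs", c(path("motif_density.tsv"), path("motif_cohorts.tsv")),
         nrow(md) + nrow(ce))
  }

  manifest <- structure(list(config_hash = config_hash, seed = seed,
                             stages = record,
                             version = as.character(utils::packageVersion("rzscreen"))),
                        class = "run_manifest")
  yaml::write_yaml(list(config_hash = manifest$config_hash,
                        seed = manifest$seed,
                        stages = manifest$stages,
                        version = manifest$version),
                   file.path(out_dir, "manifest.yaml"))
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d, config %s): %d stage(s)\n",
              x$seed, substr(x$config_hash, 1, 8), length(x$stages)))
  for (s in names(x$stages))
    cat(sprintf("  %-12s %d rows -> %s\n", s, x$stages[[s]]$rows,
                paste(basename(x$stages[[s]]$outputs), collapse = ", ")))
  invisible(x)
}
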