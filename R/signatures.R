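# Robust Z-score (RZS) drug signatures.
#
# Each treated well is compared with the vehicle (DMSO) wells of the same
# (plate, cell line) stratum:
#
#   RZS_gene = (treated - median(vehicle)) / MAD(vehicle)
#
# with MAD the raw median absolute deviation (no 1.4826 consistency
# constant by default). Replicate signatures of a drug on the same cell
# line (across plates/phases) are collapsed to the per-gene median.

.special_treatments <- c("VEHICLE", "POSITIVE_CONTROL", "EMPTY")

# row-wise medians without per-row function-call overhead for small counts
.row_medians <- function(m) {
  k <- ncol(m)
  if (k == 1L) return(m[, 1L])
  if (k == 2L) return((m[, 1L] + m[, 2L]) / 2)
  if (k == 3L) return(m[, 1L] + m[, 2L] + m[, 3L] -
                        pmax(m[, 1L], m[, 2L], m[, 3L]) -
                        pmin(m[, 1L], m[, 2L], m[, 3L]))
  apply(m, 1L, stats::median)
}

#' Collapse probe rows to one row per gene
#'
#' Where several probes map to one gene, the probe with the highest mean
#' expression across all samples is retained (ties broken by the
#' lexicographically smaller probe id). Probes absent from the mapping are
#' dropped with a warning.
#'
#' @param mat Numeric probes-by-wells matrix with probe rownames.
#' @param probe_to_gene Named character vector, probe id -> gene id.
#' @return Genes-by-wells matrix with gene rownames.
#' @export
collapse_probes <- function(mat, probe_to_gene) {
  if (is.null(names(probe_to_gene)))
    stop_fmt("probe_to_gene must be a named vector (probe -> gene)")
  known <- rownames(mat) %in% names(probe_to_gene)
  if (any(!known))
    warn_fmt("%d probe(s) absent from the mapping were dropped", sum(!known))
  mat <- mat[known, , drop = FALSE]
  if (!nrow(mat)) stop_fmt("no probes left after applying the mapping")
  genes <- unname(probe_to_gene[rownames(mat)])
  means <- rowMeans(mat)
  ord <- order(genes, -means, rownames(mat), method = "radix")
  keep <- ord[!duplicated(genes[ord])]
  out <- mat[keep, , drop = FALSE]
  rownames(out) <- genes[keep]
  out[order(rownames(out)), , drop = FALSE]
}

# Vehicle median and MAD per gene for one (plate, cell line) stratum.
# MAD = 0 entries are floored to the smallest positive MAD in the stratum
# (fallback `floor`), and the floored genes reported.
.vehicle_stats <- function(veh, mad_constant = c("raw", "normal"), floor = 1e-6) {
  mad_constant <- match.arg(mad_constant)
  med <- apply(veh, 1L, stats::median)
  mad <- apply(abs(veh - med), 1L, stats::median)
  if (mad_constant == "normal") mad <- mad * 1.4826
  flagged <- rownames(veh)[mad == 0]
  if (length(flagged)) {
    pos <- mad[mad > 0]
    mad[mad == 0] <- if (length(pos)) min(pos) else floor
  }
  list(median = med, mad = mad, flagged = flagged)
}

#' Robust Z-score signature of one drug on one plate
#'
#' Computes the per-gene RZS of a drug against the vehicle wells of the
#' same (plate, cell line) stratum. Multiple treated wells of the drug on
#' that plate are averaged before the transform. Requires at least three
#' vehicle wells (the median/MAD need support). Genes whose vehicle MAD is
#' zero use the smallest positive MAD of the stratum and are flagged.
#'
#' @param screen An [expression_screen()].
#' @param drug Drug identifier (a \code{treatment} value).
#' @param cell_line Cell line identifier.
#' @param plate Plate identifier.
#' @param mad_constant \code{"raw"} (default, bare median absolute
#'   deviation) or \code{"normal"} (scaled by 1.4826).
#' @return An object of class \code{drug_signature} with elements
#'   \code{drug}, \code{cell_line}, \code{plate}, \code{rzs} (named numeric
#'   over genes), \code{n_replicates}, \code{flagged}.
#' @export
compute_rzs <- function(screen, drug, cell_line, plate,
                        mad_constant = c("raw", "normal")) {
  stopifnot(inherits(screen, "expression_screen"))
  mad_constant <- match.arg(mad_constant)
  ann <- screen$annotation
  in_stratum <- ann$plate_id == plate & ann$cell_line_id == cell_line
  veh_wells <- ann$well_id[in_stratum & ann$treatment == "VEHICLE"]
  trt_wells <- ann$well_id[in_stratum & ann$treatment == drug]
  if (!length(trt_wells))
    stop_fmt("no '%s'-treated well on plate %s / cell line %s", drug, plate, cell_line)
  if (length(veh_wells) < 3L)
    stop_fmt("plate %s / cell line %s has %d vehicle wells (need >= 3)",
             plate, cell_line, length(veh_wells))
  vs <- .vehicle_stats(screen$matrix[, veh_wells, drop = FALSE], mad_constant)
  treated <- rowMeans(screen$matrix[, trt_wells, drop = FALSE])
  structure(list(drug = drug, cell_line = cell_line, plate = plate,
                 rzs = (treated - vs$median) / vs$mad,
                 n_replicates = 1L, flagged = vs$flagged),
            class = "drug_signature")
}

#' @export
print.drug_signature <- function(x, ...) {
  cat(sprintf("RZS signature: %s on %s (%s), %d genes, %d replicate(s)\n",
              x$drug, x$cell_line, x$plate %||% "collapsed",
              length(x$rzs), x$n_replicates))
  invisible(x)
}

#' All plate-level RZS signatures of a screen
#'
#' Computes the RZS signature of every (drug, cell line, plate) combination
#' present in the screen, in one pass per (plate, cell line) stratum.
#'
#' @inheritParams compute_rzs
#' @param treatments Optional character vector restricting the treatments
#'   scored (defaults to every non-control treatment; pass
#'   \code{"VEHICLE"}-containing vectors to score vehicle wells as
#'   pseudo-drugs for QC).
#' @return A list with \code{rzs} (genes x signatures matrix) and
#'   \code{meta} (data.frame with columns drug, cell_line, plate, phase,
#'   group_label per signature column).
#' @export
plate_signatures <- function(screen, treatments = NULL,
                             mad_constant = c("raw", "normal")) {
  stopifnot(inherits(screen, "expression_screen"))
  mad_constant <- match.arg(mad_constant)
  ann <- screen$annotation
  if (is.null(treatments))
    treatments <- setdiff(unique(ann$treatment), .special_treatments)
  strata <- unique(ann[ann$treatment %in% treatments,
                       c("plate_id", "cell_line_id", "phase_id", "group_label")])
  cols <- list(); meta <- list()
  for (i in seq_len(nrow(strata))) {
    pl <- strata$plate_id[[i]]; cl <- strata$cell_line_id[[i]]
    in_stratum <- ann$plate_id == pl & ann$cell_line_id == cl
    veh_wells <- ann$well_id[in_stratum & ann$treatment == "VEHICLE"]
    if (length(veh_wells) < 3L)
      stop_fmt("plate %s / cell line %s has %d vehicle wells (need >= 3)",
               pl, cl, length(veh_wells))
    vs <- .vehicle_stats(screen$matrix[, veh_wells, drop = FALSE], mad_constant)
    here <- ann[in_stratum & ann$treatment %in% treatments, , drop = FALSE]
    # average replicate wells of the same treatment before the transform
    drugs <- unique(here$treatment)
    trt <- vapply(drugs, function(d) {
      rowMeans(screen$matrix[, here$well_id[here$treatment == d], drop = FALSE])
    }, numeric(nrow(screen$matrix)))
    cols[[i]] <- (trt - vs$median) / vs$mad
    meta[[i]] <- data.frame(drug = drugs, cell_line = cl, plate = pl,
                            phase = strata$phase_id[[i]],
                            group_label = strata$group_label[[i]],
                            stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  rzs <- do.call(cbind, cols)
  colnames(rzs) <- paste(meta$drug, meta$cell_line, meta$plate, sep = ":")
  rownames(meta) <- NULL
  list(rzs = rzs, meta = meta)
}

#' Collapse replicate signatures to their per-gene median
#'
#' @param signatures Non-empty list of \code{drug_signature} objects for
#'   one (drug, cell line) pair over an identical gene universe.
#' @return A collapsed \code{drug_signature} with \code{n_replicates} set.
#' @export
collapse_replicates <- function(signatures) {
  if (!length(signatures)) stop_fmt("no signatures to collapse")
  genes <- names(signatures[[1L]]$rzs)
  for (s in signatures)
    if (!identical(names(s$rzs), genes))
      stop_fmt("signatures have mismatched gene universes")
  m <- vapply(signatures, function(s) s$rzs, numeric(length(genes)))
  med <- if (length(signatures) == 1L) signatures[[1L]]$rzs
         else apply(m, 1L, stats::median)
  out <- signatures[[1L]]
  out$rzs <- med
  out$plate <- NULL
  out$n_replicates <- length(signatures)
  out$flagged <- unique(unlist(lapply(signatures, `[[`, "flagged")))
  out
}

#' Construct a drug x cell line x gene signature tensor
#'
#' @param values 3-d numeric array with dimnames \code{[drug, cell, gene]}.
#' @param groups Named character vector mapping every cell line to its group
#'   (\code{CCL}, \code{NPC_control}, \code{NPC_SZ}).
#' @param n_replicates Optional drugs-by-cells integer matrix of replicate
#'   counts.
#' @return An object of class \code{signature_tensor}.
#' @export
signature_tensor <- function(values, groups, n_replicates = NULL) {
  if (length(dim(values)) != 3L || is.null(dimnames(values)))
    stop_fmt("values must be a named 3-d array [drug, cell, gene]")
  cells <- dimnames(values)[[2L]]
  if (!all(cells %in% names(groups)))
    stop_fmt("groups must name every cell line in the tensor")
  bad <- setdiff(unique(groups[cells]), .group_labels)
  if (length(bad)) stop_fmt("unknown group label '%s'", bad[[1L]])
  structure(values, groups = groups[cells], n_replicates = n_replicates,
            class = c("signature_tensor", "array"))
}

#' @export
print.signature_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Signature tensor: %d drugs x %d cell lines x %d genes\n",
              d[[1L]], d[[2L]], d[[3L]]))
  cat("  groups:", paste(sprintf("%s=%d", names(table(attr(x, "groups"))),
                                 table(attr(x, "groups"))), collapse = ", "), "\n")
  invisible(x)
}

#' Cell lines belonging to a group of a signature tensor
#'
#' @param tensor A [signature_tensor()].
#' @param group One of \code{CCL}, \code{NPC_control}, \code{NPC_SZ}, or
#'   \code{NPC} (union of the two NPC groups).
#' @return Character vector of cell line ids.
#' @export
group_cells <- function(tensor, group) {
  groups <- attr(tensor, "groups")
  cells <- if (identical(group, "NPC")) {
    names(groups)[groups %in% c("NPC_control", "NPC_SZ")]
  } else {
    if (!group %in% .group_labels) stop_fmt("unknown group '%s'", group)
    names(groups)[groups == group]
  }
  if (!length(cells)) stop_fmt("group '%s' has no cell lines", group)
  cells
}

#' Build the median-collapsed signature tensor of a screen
#'
#' Runs the full signature stage: optional probe collapsing, per-plate RZS
#' transformation, and per-(drug, cell line) median collapsing of replicate
#' signatures across plates and phases.
#'
#' @inheritParams plate_signatures
#' @param probe_to_gene Optional probe -> gene mapping applied first via
#'   [collapse_probes()].
#' @return A [signature_tensor()].
#' @export
build_signatures <- function(screen, probe_to_gene = NULL,
                             mad_constant = c("raw", "normal")) {
  mad_constant <- match.arg(mad_constant)
  if (!is.null(probe_to_gene)) {
    screen$matrix <- collapse_probes(screen$matrix, probe_to_gene)
  }
  ps <- plate_signatures(screen, mad_constant = mad_constant)
  drugs <- sort(unique(ps$meta$drug))
  cells <- sort(unique(ps$meta$cell_line))
  genes <- rownames(ps$rzs)
  arr <- array(NA_real_, dim = c(length(drugs), length(cells), length(genes)),
               dimnames = list(drugs, cells, genes))
  nrep <- matrix(0L, length(drugs), length(cells), dimnames = list(drugs, cells))
  key <- paste(ps$meta$drug, ps$meta$cell_line, sep = "\r")
  idx_by_key <- split(seq_along(key), key)
  for (idx in idx_by_key) {
    med <- .row_medians(ps$rzs[, idx, drop = FALSE])
    d <- ps$meta$drug[[idx[[1L]]]]; cl <- ps$meta$cell_line[[idx[[1L]]]]
    arr[d, cl, ] <- med
    nrep[d, cl] <- length(idx)
  }
  groups <- ps$meta$group_label[!duplicated(ps$meta$cell_line)]
  names(groups) <- ps$meta$cell_line[!duplicated(ps$meta$cell_line)]
  signature_tensor(arr, groups, nrep)
}

#' Per-well RZS signatures of the vehicle wells
#'
#' Scores every vehicle well against its own (plate, cell line) stratum's
#' vehicle statistics (the well included), yielding null pseudo-drug
#' signatures used for batch-effect QC: for an odd vehicle count the
#' per-gene median RZS across a stratum's wells is exactly 0.
#'
#' @inheritParams plate_signatures
#' @return Same shape as [plate_signatures()]: \code{rzs} (genes x wells)
#'   and \code{meta} (drug = well id, cell_line, plate, phase,
#'   group_label).
#' @export
vehicle_signatures <- function(screen, mad_constant = c("raw", "normal")) {
  stopifnot(inherits(screen, "expression_screen"))
  mad_constant <- match.arg(mad_constant)
  ann <- screen$annotation
  veh <- ann[ann$treatment == "VEHICLE", , drop = FALSE]
  strata <- unique(veh[, c("plate_id", "cell_line_id", "phase_id",
                           "group_label")])
  cols <- list(); meta <- list()
  for (i in seq_len(nrow(strata))) {
    pl <- strata$plate_id[[i]]; cl <- strata$cell_line_id[[i]]
    wells <- veh$well_id[veh$plate_id == pl & veh$cell_line_id == cl]
    if (length(wells) < 3L)
      stop_fmt("plate %s / cell line %s has %d vehicle wells (need >= 3)",
               pl, cl, length(wells))
    vs <- .vehicle_stats(screen$matrix[, wells, drop = FALSE], mad_constant)
    cols[[i]] <- (screen$matrix[, wells, drop = FALSE] - vs$median) / vs$mad
    meta[[i]] <- data.frame(drug = wells, cell_line = cl, plate = pl,
                            phase = strata$phase_id[[i]],
                            group_label = strata$group_label[[i]],
                            stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta); rownames(meta) <- NULL
  list(rzs = do.call(cbind, cols), meta = meta)
}

#' Fraction of signature variance attributable to a technical factor
#'
#' Per-gene one-way random-effects ANOVA of signatures against a technical
#' factor (plate or phase): the between-level variance component is
#' estimated by the method of moments, \code{(MSB - MSW) / n0} (clipped at
#' zero, \code{n0} the effective per-level size), and its share of the
#' total variance is averaged over genes. Unlike a raw R-squared this is
#' unbiased near zero, so a fully cancelled batch factor reports ~0 rather
#' than \code{(k - 1)/(N - 1)}.
#'
#' @param signatures Output of [plate_signatures()] or
#'   [vehicle_signatures()], or a plain genes-by-samples matrix (then
#'   \code{factor} must be a vector of level labels per sample).
#' @param factor \code{"plate"} or \code{"phase"} (or a label vector when
#'   \code{signatures} is a matrix).
#' @return Mean across genes of the between-level variance fraction, in
#'   \code{[0, 1]}.
#' @export
batch_variance_fraction <- function(signatures, factor = c("plate", "phase")) {
  if (is.list(signatures) && !is.null(signatures$rzs)) {
    x <- signatures$rzs
    f <- as.factor(signatures$meta[[match.arg(factor)]])
  } else {
    x <- signatures
    f <- as.factor(factor)
  }
  if (nlevels(f) < 2L) stop_fmt("batch factor has a single level")
  if (length(f) != ncol(x)) stop_fmt("factor length must match sample count")
  k <- nlevels(f); n <- length(f)
  sizes <- tabulate(f)
  n0 <- (n - sum(sizes^2) / n) / (k - 1)
  grand <- rowMeans(x)
  sst <- rowSums((x - grand)^2)
  ssb <- numeric(nrow(x))
  for (lev in seq_len(k)) {
    idx <- which(as.integer(f) == lev)
    ssb <- ssb + length(idx) * (rowMeans(x[, idx, drop = FALSE]) - grand)^2
  }
  msb <- ssb / (k - 1)
  msw <- (sst - ssb) / (n - k)
  sigma_b <- pmax(0, (msb - msw) / n0)
  frac <- sigma_b / (sigma_b + msw)
  mean(frac[is.finite(frac)])
}
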