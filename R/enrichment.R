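# Group-wise gene-set enrichment on RZS signatures.
#
# For one drug, the per-gene RZS signatures of two cell groups are compared
# set by set with an unpaired two-sample t statistic. Two variants are
# exposed: v1 (default) summarizes each cell line to its mean RZS over the
# set's genes and applies a Welch t across cell lines, treating the cell
# line as the replication unit; v2 pools the per-(cell line, gene) RZS
# values of the set in each group and applies a Student t.

#' Expressed-gene background from a counts matrix
#'
#' A gene enters the background when it has at least \code{min_reads}
#' mapped reads in at least \code{ceiling(min_fraction * n_lines)} of the
#' cell lines.
#'
#' @param counts Non-negative genes-by-cell-lines matrix.
#' @param min_reads Minimum read count (default 10).
#' @param min_fraction Minimum fraction of cell lines (default 0.5).
#' @return A list of class \code{background_set} with \code{genes} and the
#'   provenance thresholds.
#' @export
estimate_background <- function(counts, min_reads = 10, min_fraction = 0.5) {
  if (any(counts < 0, na.rm = TRUE)) stop_fmt("counts must be non-negative")
  need <- ceiling(min_fraction * ncol(counts))
  ok <- rowSums(counts >= min_reads, na.rm = TRUE) >= need
  if (!any(ok)) stop_fmt("no gene passes the background filter")
  structure(list(genes = rownames(counts)[ok],
                 min_reads = min_reads, min_fraction = min_fraction,
                 n_lines = ncol(counts)),
            class = "background_set")
}

#' @export
print.background_set <- function(x, ...) {
  cat(sprintf("Expressed-gene background: %d genes (>= %g reads in >= %g of %d lines)\n",
              length(x$genes), x$min_reads, x$min_fraction, x$n_lines))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p Numeric vector of p-values in \code{[0, 1]}.
#' @param method Adjustment method passed to [stats::p.adjust()]
#'   (default \code{"BH"}).
#' @return Vector of q-values, same order as \code{p}.
#' @export
adjust_fdr <- function(p, method = "BH") {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop_fmt("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Gene-set enrichment of one drug between two cell groups
#'
#' @param tensor A [signature_tensor()].
#' @param drug Drug identifier (a tensor row).
#' @param group_a,group_b Group labels (see [group_cells()]).
#' @param sets A [gene_set_collection()].
#' @param background Optional [estimate_background()] result restricting
#'   every set to expressed genes; \code{NULL} uses the full gene universe.
#' @param variant \code{"v1"} (cell-line set summaries, Welch t; default)
#'   or \code{"v2"} (pooled set-gene values, Student t).
#' @param min_set_size Minimum set size after background intersection
#'   (default 5); smaller sets are reported with \code{tested = FALSE}.
#' @return data.frame with one row per set: drug, set, category,
#'   t_statistic, p_value, q_value (BH within this comparison-by-category
#'   family), direction, n_a, n_b, set_size, tested, variant.
#' @export
set_enrichment <- function(tensor, drug, group_a, group_b, sets,
                           background = NULL, variant = c("v1", "v2"),
                           min_set_size = 5L) {
  variant <- match.arg(variant)
  stopifnot(inherits(sets, "gene_set_collection"))
  ca <- group_cells(tensor, group_a); cb <- group_cells(tensor, group_b)
  if (variant == "v1" && (length(ca) < 2L || length(cb) < 2L))
    stop_fmt("variant v1 needs >= 2 cell lines per group")
  if (!drug %in% dimnames(tensor)[[1L]]) stop_fmt("unknown drug '%s'", drug)
  genes <- dimnames(tensor)[[3L]]
  universe <- if (is.null(background)) genes else intersect(genes, background$genes)
  x <- tensor[drug, c(ca, cb), , drop = TRUE]           # cells x genes
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list(c(ca, cb), genes))
  in_a <- rownames(x) %in% ca
  rows <- lapply(names(sets$sets), function(nm) {
    g <- intersect(sets$sets[[nm]], universe)
    if (length(g) < min_set_size) {
      return(data.frame(drug = drug, set = nm, category = sets$category,
                        t_statistic = NA_real_, p_value = NA_real_,
                        direction = NA_real_, n_a = length(ca), n_b = length(cb),
                        set_size = length(g), tested = FALSE, variant = variant,
                        stringsAsFactors = FALSE))
    }
    if (variant == "v1") {
      smry <- rowMeans(x[, g, drop = FALSE])
      tt <- stats::t.test(smry[in_a], smry[!in_a], var.equal = FALSE)
    } else {
      tt <- stats::t.test(as.vector(x[in_a, g, drop = FALSE]),
                          as.vector(x[!in_a, g, drop = FALSE]),
                          var.equal = TRUE)
    }
    data.frame(drug = drug, set = nm, category = sets$category,
               t_statistic = unname(tt$statistic), p_value = tt$p.value,
               direction = sign(unname(tt$statistic)),
               n_a = length(ca), n_b = length(cb),
               set_size = length(g), tested = TRUE, variant = variant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  out$q_value[out$tested] <- adjust_fdr(out$p_value[out$tested])
  out[, c("drug", "set", "category", "t_statistic", "p_value", "q_value",
          "direction", "n_a", "n_b", "set_size", "tested", "variant")]
}

#' Gene-set enrichment of every drug between two cell groups
#'
#' Applies [set_enrichment()] to each drug and re-computes the BH
#' adjustment within the whole (comparison, set-category) family, i.e.
#' across all drug-set pairs of the collection.
#'
#' @inheritParams set_enrichment
#' @param drugs Drugs to test (default: all tensor rows).
#' @return Row-bound data.frame as in [set_enrichment()].
#' @export
enrich_all_drugs <- function(tensor, group_a, group_b, sets,
                             background = NULL, variant = c("v1", "v2"),
                             min_set_size = 5L, drugs = NULL) {
  variant <- match.arg(variant)
  drugs <- drugs %||% dimnames(tensor)[[1L]]
  out <- do.call(rbind, lapply(drugs, function(d) {
    set_enrichment(tensor, d, group_a, group_b, sets, background,
                   variant, min_set_size)
  }))
  out$q_value <- NA_real_
  out$q_value[out$tested] <- adjust_fdr(out$p_value[out$tested])
  out
}

#' Consistency of enrichment statistics between gene subsets
#'
#' Pearson correlation of matched (drug, set) t-statistics from two
#' enrichment runs (e.g. the full transcriptome versus the directly
#' measured landmark-probe subset), with the two-sided p-value of the
#' correlation.
#'
#' @param enrich_full,enrich_subset data.frames from [enrich_all_drugs()].
#' @return A list: correlation, p_value, n_pairs.
#' @export
landmark_consistency <- function(enrich_full, enrich_subset) {
  key <- function(df) paste(df$drug, df$set, sep = "\r")
  m <- merge(data.frame(k = key(enrich_full), t_full = enrich_full$t_statistic),
             data.frame(k = key(enrich_subset), t_sub = enrich_subset$t_statistic),
             by = "k")
  m <- m[is.finite(m$t_full) & is.finite(m$t_sub), , drop = FALSE]
  if (nrow(m) < 3L) stop_fmt("need >= 3 matched (drug, set) pairs, got %d", nrow(m))
  ct <- stats::cor.test(m$t_full, m$t_sub, method = "pearson")
  list(correlation = unname(ct$estimate), p_value = ct$p.value, n_pairs = nrow(m))
}
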