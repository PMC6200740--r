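# Chemogenomic feature enrichment with class-specific drug backgrounds.
#
# For each pharmacological annotation class (targets, enzymes,
# transporters, carriers, therapeutic classes, side effects, predicted
# targets), the testable universe is restricted to drugs carrying at least
# one annotation of that class: a side effect is only meaningful for a
# drug that has been used clinically, and the same logic is applied to
# every class. Over-representation is tested one-sided with the
# hypergeometric upper tail (the one-sided Fisher exact test) and adjusted
# with BH within each (set, class) family.

#' One-sided Fisher exact enrichment of a 2x2 table
#'
#' Computes the upper-tail (over-representation) p-value of the table
#' \code{[[a, b], [c, d]]}, i.e. the probability of drawing at least
#' \code{a} feature-positive items when sampling \code{a + b} items from a
#' universe of \code{a + b + c + d} containing \code{a + c} positives —
#' the exact one-sided Fisher p-value, evaluated as the hypergeometric
#' tail. All arguments are vectorized.
#'
#' @param a In-group, feature-positive count.
#' @param b In-group, feature-negative count.
#' @param c Out-group, feature-positive count.
#' @param d Out-group, feature-negative count.
#' @return A data.frame with columns a, b, c, d, odds_ratio (sample OR
#'   ad/bc), p_value.
#' @export
fisher_enrichment <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != floor(c(a, b, c, d))))
    stop_fmt("counts must be non-negative integers")
  p <- stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  or <- (a * d) / (b * c)
  or[b * c == 0 & a * d == 0] <- NaN
  data.frame(a = a, b = b, c = c, d = d, odds_ratio = or, p_value = p)
}

#' Drugs significantly regulating each gene set
#'
#' Groups drugs by the sets they regulate at \code{q < fdr} (strict) and
#' keeps the sets regulated by at least \code{min_drugs} drugs.
#'
#' @param enrichments data.frame from [enrich_all_drugs()] with q_value.
#' @param fdr Significance threshold on the q-value (default 0.1).
#' @param min_drugs Minimum group size for a set to be retained (default 3).
#' @return Named list, set name -> character vector of drugs.
#' @export
group_set_drugs <- function(enrichments, fdr = 0.1, min_drugs = 3L) {
  if (is.null(enrichments$q_value)) stop_fmt("enrichments lack q_value")
  hit <- enrichments[!is.na(enrichments$q_value) & enrichments$q_value < fdr, ,
                     drop = FALSE]
  groups <- lapply(split(hit$drug, hit$set), unique)
  groups <- groups[lengths(groups) >= min_drugs]
  if (!length(groups)) message("no set reaches ", min_drugs, " regulating drugs")
  groups
}

#' Feature over-representation within a drug group
#'
#' Tests every feature of one annotation class for over-representation
#' among the group's drugs, against the class-specific background (screened
#' drugs carrying at least one annotation of the class).
#'
#' @param group Character vector of drugs (e.g. one element of
#'   [group_set_drugs()]).
#' @param annotations Drug-annotation data.frame (columns drug, class,
#'   feature; see [read_screen_table()]).
#' @param class Annotation class to test.
#' @param screened_drugs All drugs in the screen; defaults to the drugs
#'   present in \code{annotations}.
#' @return data.frame, one row per feature: class, feature, a, b, c, d,
#'   odds_ratio, p_value, q_value (BH within this class), drugs
#'   (comma-separated contributing group drugs); \code{NULL} with a warning
#'   when the group is disjoint from the class background.
#' @export
feature_enrichment <- function(group, annotations, class,
                               screened_drugs = NULL) {
  ann <- annotations[annotations$class == class, , drop = FALSE]
  screened_drugs <- screened_drugs %||% unique(annotations$drug)
  background <- intersect(screened_drugs, unique(ann$drug))
  group_bg <- intersect(group, background)
  if (!length(group_bg)) {
    warn_fmt("drug group has no '%s' annotations; features untested", class)
    return(NULL)
  }
  features <- sort(unique(ann$feature))
  rows <- lapply(features, function(f) {
    with_f <- unique(ann$drug[ann$feature == f])
    a <- length(intersect(group_bg, with_f))
    b <- length(group_bg) - a
    c_ <- length(setdiff(intersect(background, with_f), group_bg))
    d <- length(background) - a - b - c_
    fe <- fisher_enrichment(a, b, c_, d)
    cbind(data.frame(class = class, feature = f, stringsAsFactors = FALSE),
          fe,
          data.frame(drugs = paste(sort(intersect(group_bg, with_f)),
                                   collapse = ","),
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  out$q_value <- adjust_fdr(out$p_value)
  out
}

#' Chemogenomic enrichment across set-drug groups and classes
#'
#' Convenience wrapper running [feature_enrichment()] for every
#' (set group, class) combination, with BH within each (set, class) family.
#'
#' @param groups Named list from [group_set_drugs()].
#' @inheritParams feature_enrichment
#' @param classes Annotation classes to test (default: all present).
#' @return Row-bound data.frame with a leading \code{set} column.
#' @export
chemogenomic_enrichment <- function(groups, annotations, classes = NULL,
                                    screened_drugs = NULL) {
  classes <- classes %||% sort(unique(annotations$class))
  out <- list()
  for (set_nm in names(groups)) for (cl in classes) {
    fe <- suppressWarnings(
      feature_enrichment(groups[[set_nm]], annotations, cl, screened_drugs))
    if (!is.null(fe))
      out[[length(out) + 1L]] <- cbind(data.frame(set = set_nm,
                                                  stringsAsFactors = FALSE), fe)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Rank drugs by target overlap with gene sets
#'
#' For every drug with at least one (referenced or predicted) gene target,
#' tests the overlap of its targets with each set by the one-sided Fisher
#' exact test over the gene universe, and ranks drugs by their best
#' p-value.
#'
#' @param annotations Drug-annotation data.frame; classes \code{target} and
#'   \code{predicted_target} are used as gene targets.
#' @param target_sets A [gene_set_collection()].
#' @param gene_universe Character vector of gene ids defining the testing
#'   universe.
#' @return A list: \code{ranking} (drug, best_set, best_p) and
#'   \code{table} (per drug-set Fisher rows).
#' @export
target_overlap_prioritization <- function(annotations, target_sets,
                                          gene_universe) {
  stopifnot(inherits(target_sets, "gene_set_collection"))
  tg <- annotations[annotations$class %in% c("target", "predicted_target"), ,
                    drop = FALSE]
  targets_by_drug <- lapply(split(tg$feature, tg$drug),
                            function(g) intersect(unique(g), gene_universe))
  dropped <- names(targets_by_drug)[lengths(targets_by_drug) == 0L]
  if (length(dropped))
    message(length(dropped), " drug(s) with no targets in the universe excluded")
  targets_by_drug <- targets_by_drug[lengths(targets_by_drug) > 0L]
  if (!length(targets_by_drug)) stop_fmt("no drug has targets in the universe")
  n_u <- length(gene_universe)
  rows <- list()
  for (d in names(targets_by_drug)) {
    tgt <- targets_by_drug[[d]]
    for (nm in names(target_sets$sets)) {
      s <- intersect(target_sets$sets[[nm]], gene_universe)
      if (!length(s)) next
      a <- length(intersect(tgt, s))
      fe <- fisher_enrichment(a, length(tgt) - a, length(s) - a,
                              n_u - length(tgt) - length(s) + a)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(drug = d, set = nm, stringsAsFactors = FALSE), fe)
    }
  }
  tab <- do.call(rbind, rows)
  best <- do.call(rbind, lapply(split(tab, tab$drug), function(df) {
    df[order(df$p_value, df$set), ][1L, c("drug", "set", "p_value")]
  }))
  names(best) <- c("drug", "best_set", "best_p")
  best <- best[order(best$best_p, best$drug), , drop = FALSE]
  rownames(best) <- NULL
  list(ranking = best, table = tab)
}
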