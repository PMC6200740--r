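# Threshold-based differential expression accounting on RZS tensors.
#
# A drug-gene perturbation is DE within a group when the absolute median
# RZS across the group's cell lines is >= de_threshold (default 2, the
# published convention); it is differentially DE between two groups when
# the absolute difference of the two group medians is >= diff_threshold.

#' Analysis thresholds for DE accounting
#'
#' @param de_threshold Absolute median RZS at or above which a drug-gene
#'   pair is called DE within a group (default 2).
#' @param diff_threshold Absolute between-group difference of median RZS at
#'   or above which a pair is called differentially DE (default 2).
#' @param negligible_threshold Absolute median RZS below which the
#'   non-DE group's response is treated as negligible when categorizing
#'   response patterns (default 0.5).
#' @return A list of class \code{analysis_config}.
#' @export
analysis_config <- function(de_threshold = 2, diff_threshold = 2,
                            negligible_threshold = 0.5) {
  if (de_threshold <= 0 || diff_threshold <= 0 || negligible_threshold <= 0)
    stop_fmt("all thresholds must be positive")
  structure(list(de_threshold = de_threshold, diff_threshold = diff_threshold,
                 negligible_threshold = negligible_threshold),
            class = "analysis_config")
}

# drugs x genes matrix of median RZS across a group's cell lines
group_median_matrix <- function(tensor, group) {
  cells <- group_cells(tensor, group)
  sub <- tensor[, cells, , drop = FALSE]
  if (length(cells) == 1L) {
    m <- sub[, 1L, ]
  } else {
    m <- apply(sub, c(1L, 3L), stats::median)
  }
  if (is.null(dim(m))) m <- matrix(m, nrow = dim(tensor)[[1L]],
                                   dimnames = dimnames(tensor)[c(1L, 3L)])
  m
}

#' Call within-group DE for every drug-gene pair
#'
#' @param tensor A [signature_tensor()].
#' @param group Group label (see [group_cells()]).
#' @param config An [analysis_config()].
#' @return data.frame with columns drug, gene, group_label, median_rzs,
#'   is_de; one row per drug-gene pair.
#' @export
call_de <- function(tensor, group, config = analysis_config()) {
  m <- group_median_matrix(tensor, group)
  data.frame(
    drug = rep(rownames(m), times = ncol(m)),
    gene = rep(colnames(m), each = nrow(m)),
    group_label = group,
    median_rzs = as.vector(m),
    is_de = as.vector(abs(m) >= config$de_threshold),
    stringsAsFactors = FALSE)
}

#' Differential DE between two groups
#'
#' @inheritParams call_de
#' @param group_a,group_b Disjoint group labels.
#' @return data.frame with columns drug, gene, median_a, median_b, delta
#'   (median_a - median_b), is_differential.
#' @export
differential_de <- function(tensor, group_a, group_b,
                            config = analysis_config()) {
  ca <- group_cells(tensor, group_a); cb <- group_cells(tensor, group_b)
  if (length(intersect(ca, cb)))
    stop_fmt("groups '%s' and '%s' share cell lines", group_a, group_b)
  ma <- group_median_matrix(tensor, group_a)
  mb <- group_median_matrix(tensor, group_b)
  delta <- ma - mb
  data.frame(
    drug = rep(rownames(ma), times = ncol(ma)),
    gene = rep(colnames(ma), each = nrow(ma)),
    median_a = as.vector(ma), median_b = as.vector(mb),
    delta = as.vector(delta),
    is_differential = as.vector(abs(delta) >= config$diff_threshold),
    stringsAsFactors = FALSE)
}

#' Categorize a drug-gene response pattern across two groups
#'
#' Classifies a pair that is DE in at least one of two groups into one of
#' four disjoint categories: \code{opposite_de} (DE in both, opposite
#' signs), \code{opposite_subthreshold} (DE in one, the other of opposite
#' sign but below the DE threshold), \code{single_group} (DE in one, the
#' other negligible), \code{same_direction_magnitude} (same sign, both
#' non-negligible, differing in magnitude).
#'
#' @param median_a,median_b Group median RZS values (vectorized).
#' @param config An [analysis_config()].
#' @return Character vector of categories.
#' @export
categorize_response <- function(median_a, median_b,
                                config = analysis_config()) {
  de_a <- abs(median_a) >= config$de_threshold
  de_b <- abs(median_b) >= config$de_threshold
  if (any(!de_a & !de_b))
    stop_fmt("pair DE in neither group is outside the accounting universe")
  both <- de_a & de_b
  one <- xor(de_a, de_b)
  other <- ifelse(de_a, median_b, median_a)
  lead <- ifelse(de_a, median_a, median_b)
  opposite <- sign(lead) * sign(other) < 0
  out <- character(length(median_a))
  out[both & sign(median_a) * sign(median_b) < 0] <- "opposite_de"
  out[both & sign(median_a) * sign(median_b) >= 0] <- "same_direction_magnitude"
  out[one & opposite] <- "opposite_subthreshold"
  out[one & !opposite & abs(other) < config$negligible_threshold] <- "single_group"
  out[one & !opposite & abs(other) >= config$negligible_threshold] <-
    "same_direction_magnitude"
  out
}

#' Response-category accounting over a two-group comparison
#'
#' Applies [categorize_response()] to every drug-gene pair DE in at least
#' one of the two groups and tabulates the category shares.
#'
#' @inheritParams differential_de
#' @return A list with \code{table} (per-pair data.frame) and
#'   \code{summary} (category counts and fractions).
#' @export
response_accounting <- function(tensor, group_a, group_b,
                                config = analysis_config()) {
  dd <- differential_de(tensor, group_a, group_b, config)
  in_universe <- abs(dd$median_a) >= config$de_threshold |
                 abs(dd$median_b) >= config$de_threshold
  tab <- dd[in_universe, , drop = FALSE]
  tab$category <- categorize_response(tab$median_a, tab$median_b, config)
  counts <- table(factor(tab$category,
                         levels = c("opposite_subthreshold", "single_group",
                                    "same_direction_magnitude", "opposite_de")))
  list(table = tab,
       summary = data.frame(category = names(counts),
                            n = as.integer(counts),
                            fraction = as.numeric(counts) / max(1L, nrow(tab))))
}

#' Mantel-Haenszel comparison of drug responsiveness between groups
#'
#' Stratifies by drug-gene perturbation: each stratum is the 2x2 table of
#' (group x DE/not-DE) counts over individual cell lines, where a cell line
#' is DE for a pair when its own |RZS| meets the DE threshold. Degenerate
#' strata (a zero row or column margin) are dropped. The common odds ratio
#' is the Mantel-Haenszel estimate sum(a*d/n)/sum(b*c/n); the chi-square
#' statistic and p-value come from the Cochran-Mantel-Haenszel test without
#' continuity correction, with optional Bonferroni correction across a
#' declared family of comparisons.
#'
#' @inheritParams differential_de
#' @param n_comparisons Size of the comparison family for the Bonferroni
#'   correction (default 1).
#' @return A list of class \code{mh_result}: common_odds_ratio, chi_square,
#'   p_value, bonferroni_p, n_strata.
#' @export
mantel_haenszel_responsiveness <- function(tensor, group_a, group_b,
                                           config = analysis_config(),
                                           n_comparisons = 1L) {
  ca <- group_cells(tensor, group_a); cb <- group_cells(tensor, group_b)
  if (length(intersect(ca, cb)))
    stop_fmt("groups '%s' and '%s' share cell lines", group_a, group_b)
  de_a <- abs(tensor[, ca, , drop = FALSE]) >= config$de_threshold
  de_b <- abs(tensor[, cb, , drop = FALSE]) >= config$de_threshold
  a <- colSums(aperm(de_a, c(2L, 1L, 3L))); b <- length(ca) - a   # group A: DE / not
  c_ <- colSums(aperm(de_b, c(2L, 1L, 3L))); d <- length(cb) - c_ # group B: DE / not
  strata <- cbind(a = as.vector(a), b = as.vector(b),
                  c = as.vector(c_), d = as.vector(d))
  keep <- (strata[, "a"] + strata[, "c"]) > 0 &           # some line DE
          (strata[, "b"] + strata[, "d"]) > 0             # some line not DE
  strata <- strata[keep, , drop = FALSE]
  mantel_haenszel_test(strata, n_comparisons = n_comparisons)
}

#' Mantel-Haenszel test on explicit 2x2 strata
#'
#' @param strata Matrix or data.frame with columns a, b, c, d: per stratum,
#'   rows are groups (a = group A DE, b = group A not DE, c = group B DE,
#'   d = group B not DE).
#' @inheritParams mantel_haenszel_responsiveness
#' @return A list of class \code{mh_result}.
#' @export
mantel_haenszel_test <- function(strata, n_comparisons = 1L) {
  strata <- as.matrix(strata)
  if (!nrow(strata)) stop_fmt("all strata degenerate: nothing to test")
  a <- strata[, "a"]; b <- strata[, "b"]
  c_ <- strata[, "c"]; d <- strata[, "d"]
  n <- a + b + c_ + d
  common_or <- sum(a * d / n) / sum(b * c_ / n)
  # Cochran form of the stratified chi-square: per-stratum variance
  # m1*m0*k1*k0/n^3, so a single stratum reduces exactly to the Pearson
  # chi-square without continuity correction
  e <- (a + b) * (a + c_) / n
  v <- (a + b) * (c_ + d) * (a + c_) * (b + d) / n^3
  chi <- (sum(a) - sum(e))^2 / sum(v)
  p <- stats::pchisq(chi, df = 1L, lower.tail = FALSE)
  structure(list(common_odds_ratio = common_or,
                 chi_square = chi,
                 p_value = p,
                 bonferroni_p = min(1, p * n_comparisons),
                 n_strata = nrow(strata)),
            class = "mh_result")
}

#' @export
print.mh_result <- function(x, ...) {
  cat(sprintf("Mantel-Haenszel: common OR %.3f, chi^2 %.2f, p %.3g (Bonferroni %.3g), %d strata\n",
              x$common_odds_ratio, x$chi_square, x$p_value, x$bonferroni_p,
              x$n_strata))
  invisible(x)
}

#' Per-gene counts of DE drugs
#'
#' Scores every gene by the number of drugs for which it is DE, and
#' summarizes the perturbed genes (those DE under at least one drug).
#'
#' @param de_table Output of [call_de()].
#' @return A list with \code{counts} (gene, n_drugs_de for perturbed genes)
#'   and \code{summary} (n_perturbed_genes, mean_drugs_per_gene).
#' @export
gene_drug_counts <- function(de_table) {
  cnt <- tapply(de_table$is_de, de_table$gene, sum)
  perturbed <- cnt[cnt > 0]
  counts <- data.frame(gene = names(perturbed),
                       n_drugs_de = as.integer(perturbed),
                       stringsAsFactors = FALSE)
  counts <- counts[order(-counts$n_drugs_de, counts$gene), , drop = FALSE]
  rownames(counts) <- NULL
  list(counts = counts,
       summary = data.frame(
         n_perturbed_genes = nrow(counts),
         mean_drugs_per_gene = if (nrow(counts)) mean(counts$n_drugs_de) else NA_real_))
}
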