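# Connectivity scoring of drug signatures against a disease signature.
#
# The score is the classic Kolmogorov-Smirnov tag-enrichment statistic:
# genes are ranked by descending RZS and, for each tag set (the disease
# signature's up- and down-regulated genes), the signed extremum of the
# two-sample KS running sum between tag and non-tag ranks is taken. When
# the up- and down-tag enrichments point the same way the score is 0;
# otherwise it is (es_up - es_down)/2, so +1 is perfect concordance with
# the disease signature and -1 a perfect reversal.

#' Construct a disease signature
#'
#' @param up,down Disjoint, non-empty character vectors of up- and
#'   down-regulated gene ids.
#' @param label Signature label.
#' @return An object of class \code{disease_signature}.
#' @export
disease_signature <- function(up, down, label = "disease") {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (!length(up) || !length(down)) stop_fmt("up and down sets must be non-empty")
  if (length(intersect(up, down)))
    stop_fmt("up and down sets overlap (e.g. '%s')", intersect(up, down)[[1L]])
  structure(list(up = up, down = down, label = label),
            class = "disease_signature")
}

# Signed KS extremum for tag ranks (1-based, within a universe of n).
# a = max_j( j/t - (r_j - j)/(n - t) ), b = max_j( (r_j - j)/(n - t) - (j-1)/t )
# es = a if a > b, -b if b > a, and 0 on an exact tie (equal evidence in
# both directions; keeps sign antisymmetry exact). Comparisons are done on
# integer numerators scaled by t*(n - t) so ties are detected exactly.
# Attains +1 when all tags lead the ranking and -1 when they trail it.
.ks_es <- function(ranks, n) {
  t <- length(ranks)
  if (t == 0L) stop_fmt("no tag genes in the signature's universe")
  if (t >= n) stop_fmt("tag set covers the whole universe")
  r <- sort(ranks)
  j <- seq_len(t)
  u <- (r - j) * t                        # integer-valued in double
  a_num <- max(j * (n - t) - u)
  b_num <- max(u - (j - 1) * (n - t))
  denom <- t * (n - t)
  if (a_num > b_num) a_num / denom
  else if (b_num > a_num) -b_num / denom
  else 0
}

# Rank positions (descending value, ties by gene id) of tag genes.
.tag_ranks <- function(rzs, tags) {
  ord <- order(-rzs, names(rzs), method = "radix")
  rank_of <- integer(length(rzs)); rank_of[ord] <- seq_along(rzs)
  names(rank_of) <- names(rzs)
  unname(rank_of[intersect(tags, names(rzs))])
}

#' Connectivity score of one signature against a disease signature
#'
#' @param signature A \code{drug_signature} or a named numeric RZS vector.
#' @param disease A [disease_signature()].
#' @return A list of class \code{connectivity_record}: es_up, es_down,
#'   score in \code{[-1, 1]} (0 when the two enrichments share sign),
#'   n_up, n_down.
#' @export
connectivity_score <- function(signature, disease) {
  rzs <- if (inherits(signature, "drug_signature")) signature$rzs else signature
  if (is.null(names(rzs))) stop_fmt("signature must be a named RZS vector")
  n <- length(rzs)
  up_ranks <- .tag_ranks(rzs, disease$up)
  down_ranks <- .tag_ranks(rzs, disease$down)
  if (!length(up_ranks) || !length(down_ranks))
    stop_fmt("disease signature has no genes in the signature's universe")
  es_up <- .ks_es(up_ranks, n)
  es_down <- .ks_es(down_ranks, n)
  score <- if (sign(es_up) == sign(es_down)) 0 else (es_up - es_down) / 2
  structure(list(es_up = es_up, es_down = es_down, score = score,
                 n_up = length(up_ranks), n_down = length(down_ranks)),
            class = "connectivity_record")
}

#' @export
print.connectivity_record <- function(x, ...) {
  cat(sprintf("Connectivity: score %.3f (es_up %.3f, es_down %.3f; %d up / %d down tags)\n",
              x$score, x$es_up, x$es_down, x$n_up, x$n_down))
  invisible(x)
}

#' Connectivity scores of every drug per cell line or group
#'
#' @param tensor A [signature_tensor()].
#' @param disease A [disease_signature()].
#' @param aggregate \code{"none"} (one column per cell line) or
#'   \code{"by_group"} (per-gene median RZS across each group's cell lines
#'   before scoring).
#' @return Drugs-by-columns numeric score matrix.
#' @export
build_connectivity_matrix <- function(tensor, disease,
                                      aggregate = c("none", "by_group")) {
  aggregate <- match.arg(aggregate)
  drugs <- dimnames(tensor)[[1L]]; genes <- dimnames(tensor)[[3L]]
  if (aggregate == "none") {
    cols <- dimnames(tensor)[[2L]]
    get_sig <- function(d, col) tensor[d, col, ]
  } else {
    cols <- unique(unname(attr(tensor, "groups")))
    get_sig <- function(d, col) {
      cells <- group_cells(tensor, col)
      sl <- tensor[d, cells, , drop = TRUE]
      if (is.null(dim(sl))) sl else apply(sl, 2L, stats::median)
    }
  }
  out <- matrix(NA_real_, length(drugs), length(cols),
                dimnames = list(drugs, cols))
  for (d in drugs) for (cl in cols) {
    sig <- get_sig(d, cl); names(sig) <- genes
    out[d, cl] <- connectivity_score(sig, disease)$score
  }
  out
}

# Null KS connectivity scores from random tag sets of the given sizes.
.null_scores <- function(n_genes, n_up, n_down, n_permutations) {
  vapply(seq_len(n_permutations), function(i) {
    eu <- .ks_es(sample.int(n_genes, n_up), n_genes)
    ed <- .ks_es(sample.int(n_genes, n_down), n_genes)
    if (sign(eu) == sign(ed)) 0 else (eu - ed) / 2
  }, numeric(1L))
}

#' Screen for drugs that reverse a disease signature
#'
#' Scores every drug against the disease signature (optionally after group
#' aggregation), attaches permutation p-values from re-sampled random tag
#' sets of matching sizes, adjusts with BH within each column, and flags a
#' drug as reversing when its score is negative with q below \code{fdr}.
#'
#' @inheritParams build_connectivity_matrix
#' @param n_permutations Number of random tag-set draws (>= 100).
#' @param seed Integer seed; required, so a screen is reproducible.
#' @param fdr Reversal FDR threshold (default 0.1).
#' @return A list of class \code{reversal_screen}: \code{scores} matrix,
#'   \code{table} (drug, column, score, p_value, q_value, reversing), and
#'   when the columns are the two NPC groups a per-drug
#'   \code{classification} (both / SZ-only / control-only / none).
#' @export
reversal_screen <- function(tensor, disease, aggregate = c("by_group", "none"),
                            n_permutations = 1000L, seed = NULL, fdr = 0.1) {
  aggregate <- match.arg(aggregate)
  if (is.null(seed)) stop_fmt("reversal_screen() requires an explicit seed")
  if (n_permutations < 100L) stop_fmt("need >= 100 permutations")
  set.seed(seed)
  scores <- build_connectivity_matrix(tensor, disease, aggregate)
  genes <- dimnames(tensor)[[3L]]
  n_up <- length(intersect(disease$up, genes))
  n_down <- length(intersect(disease$down, genes))
  null <- abs(.null_scores(length(genes), n_up, n_down, n_permutations))
  null <- sort(null)
  p_of <- function(s) {
    # two-sided: (1 + #{|null| >= |obs|}) / (n + 1)
    (1 + (length(null) - findInterval(abs(s) - 1e-12, null))) /
      (n_permutations + 1)
  }
  tab <- data.frame(
    drug = rep(rownames(scores), times = ncol(scores)),
    column = rep(colnames(scores), each = nrow(scores)),
    score = as.vector(scores), stringsAsFactors = FALSE)
  tab$p_value <- p_of(tab$score)
  tab$q_value <- NA_real_
  for (cl in colnames(scores)) {
    idx <- tab$column == cl
    tab$q_value[idx] <- adjust_fdr(tab$p_value[idx])
  }
  tab$reversing <- tab$score < 0 & tab$q_value < fdr
  out <- list(scores = scores, table = tab, fdr = fdr)
  if (all(c("NPC_SZ", "NPC_control") %in% colnames(scores))) {
    rev_sz <- tab$reversing[tab$column == "NPC_SZ"]
    rev_ct <- tab$reversing[tab$column == "NPC_control"]
    cls <- ifelse(rev_sz & rev_ct, "both",
           ifelse(rev_sz, "SZ-only", ifelse(rev_ct, "control-only", "none")))
    out$classification <- data.frame(drug = rownames(scores),
                                     classification = cls,
                                     stringsAsFactors = FALSE)
  }
  class(out) <- "reversal_screen"
  out
}

#' @export
print.reversal_screen <- function(x, ...) {
  n_rev <- length(unique(x$table$drug[x$table$reversing]))
  cat(sprintf("Reversal screen: %d drugs x %d columns; %d drugs reversing at FDR < %g\n",
              nrow(x$scores), ncol(x$scores), n_rev, x$fdr))
  invisible(x)
}

#' Classical MDS embedding of cell lines from their drug-score profiles
#'
#' Torgerson (classical) multidimensional scaling on pairwise Euclidean
#' distances between the columns of a drugs-by-cell-lines score matrix.
#'
#' @param score_matrix Drugs-by-cell-lines numeric matrix (e.g. from
#'   [build_connectivity_matrix()]).
#' @param n_dims Embedding dimension (default 2).
#' @return Cell-lines-by-n_dims coordinate matrix (centered; deterministic
#'   up to axis sign).
#' @export
mds_embed <- function(score_matrix, n_dims = 2L) {
  n <- ncol(score_matrix)
  if (n < n_dims + 1L)
    stop_fmt("need more cell lines (%d) than dimensions + 1 (%d)", n, n_dims + 1L)
  d <- stats::dist(t(score_matrix))
  coords <- stats::cmdscale(d, k = n_dims)
  # pad with zero coordinates when the configuration is lower-dimensional
  if (ncol(coords) < n_dims)
    coords <- cbind(coords, matrix(0, nrow(coords), n_dims - ncol(coords)))
  colnames(coords) <- paste0("dim", seq_len(n_dims))
  coords
}

#' Rank library drugs by their strongest set connectivity
#'
#' Aggregates each drug's signature to the per-gene median across all cell
#' lines, computes the single-tag-set KS enrichment of every target set,
#' and ranks drugs by their best absolute enrichment (ties broken by drug
#' id).
#'
#' @param tensor A [signature_tensor()] of the drug library.
#' @param target_sets A [gene_set_collection()].
#' @param top_k Number of drugs to return (capped at the library size).
#' @return A list: \code{ranking} (data.frame drug, best_set, best_score,
#'   abs_score) and \code{scores} (drugs-by-sets es matrix).
#' @export
prioritize_drugs <- function(tensor, target_sets, top_k = 15L) {
  stopifnot(inherits(target_sets, "gene_set_collection"))
  drugs <- dimnames(tensor)[[1L]]
  if (!length(drugs)) stop_fmt("empty drug library")
  genes <- dimnames(tensor)[[3L]]
  scores <- matrix(NA_real_, length(drugs), length(target_sets$sets),
                   dimnames = list(drugs, names(target_sets$sets)))
  for (d in drugs) {
    sl <- tensor[d, , , drop = TRUE]
    sig <- if (is.null(dim(sl))) sl else apply(sl, 2L, stats::median)
    names(sig) <- genes
    for (nm in names(target_sets$sets)) {
      ranks <- .tag_ranks(sig, target_sets$sets[[nm]])
      if (length(ranks) && length(ranks) < length(genes))
        scores[d, nm] <- .ks_es(ranks, length(genes))
    }
  }
  best_idx <- apply(abs(scores), 1L, which.max)
  ranking <- data.frame(
    drug = drugs,
    best_set = colnames(scores)[best_idx],
    best_score = scores[cbind(seq_along(drugs), best_idx)],
    stringsAsFactors = FALSE)
  ranking$abs_score <- abs(ranking$best_score)
  ranking <- ranking[order(-ranking$abs_score, ranking$drug), , drop = FALSE]
  rownames(ranking) <- NULL
  list(ranking = utils::head(ranking, top_k), scores = scores)
}
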