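# Degenerate RNA-motif scanning and enrichment.
#
# Motifs are written over the RNA alphabet with IUPAC degenerate codes
# (K = G/U, W = A/U, R = A/G, Y = C/U, S = C/G, M = A/C, N = any). DNA
# input is accepted; T is treated as U. Occurrences may overlap: every
# start position is tested.

.iupac_codes <- list(A = "A", C = "C", G = "G", U = "U",
                     K = c("G", "U"), W = c("A", "U"), R = c("A", "G"),
                     Y = c("C", "U"), S = c("C", "G"), M = c("A", "C"),
                     N = c("A", "C", "G", "U", "N"))

#' Construct a degenerate RNA motif pattern
#'
#' @param pattern String over A/C/G/U plus the degenerate codes K, W, R,
#'   Y, S, M, N; length >= 2. T is accepted and treated as U.
#' @param name Motif name (defaults to the pattern itself).
#' @return An object of class \code{motif_pattern}.
#' @export
motif_pattern <- function(pattern, name = pattern) {
  pattern <- chartr("T", "U", toupper(pattern))
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  if (length(chars) < 2L) stop_fmt("motif must have length >= 2")
  bad <- setdiff(chars, names(.iupac_codes))
  if (length(bad)) stop_fmt("illegal motif code '%s'", bad[[1L]])
  structure(list(pattern = pattern, name = name,
                 classes = .iupac_codes[chars]),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("Motif %s: %s (%d nt)\n", x$name, x$pattern,
              length(x$classes)))
  invisible(x)
}

#' Scan a sequence for motif occurrences
#'
#' Returns the 0-based start positions of all (possibly overlapping)
#' matches of a degenerate motif in a nucleotide sequence. T is treated as
#' U; an N in the sequence matches only the motif code N.
#'
#' @param seq Nucleotide string over A/C/G/T/U/N.
#' @param motif A [motif_pattern()] (or a pattern string).
#' @return Integer vector of 0-based start positions (empty when the motif
#'   is longer than the sequence).
#' @export
scan_motif <- function(seq, motif) {
  if (!inherits(motif, "motif_pattern")) motif <- motif_pattern(motif)
  seq <- chartr("T", "U", toupper(seq))
  if (!grepl("^[ACGUN]*$", seq))
    stop_fmt("sequence has characters outside ACGTUN")
  len <- length(motif$classes)
  n <- nchar(seq)
  if (n < len) return(integer(0L))
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  ok <- rep(TRUE, n - len + 1L)
  for (k in seq_len(len)) {
    ok <- ok & chars[seq.int(k, k + n - len)] %in% motif$classes[[k]]
  }
  which(ok) - 1L
}

#' Motif-density comparison between two sequence groups
#'
#' Per-sequence density is the occurrence count per kilobase of that
#' sequence; densities are compared with an unpaired two-sample t-test
#' (Welch), two-sided.
#'
#' @param group1,group2 Character vectors (>= 2 sequences each) at least
#'   as long as the motif.
#' @param motif A [motif_pattern()].
#' @return A list of class \code{motif_density_result}: motif, densities
#'   (list of the two per-sequence density vectors), mean_density,
#'   t_statistic, p_value.
#' @export
motif_density_test <- function(group1, group2, motif) {
  if (!inherits(motif, "motif_pattern")) motif <- motif_pattern(motif)
  if (length(group1) < 2L || length(group2) < 2L)
    stop_fmt("each group needs >= 2 sequences")
  density_of <- function(seqs) {
    vapply(seqs, function(s) {
      if (nchar(s) < length(motif$classes))
        stop_fmt("sequence shorter than the motif")
      length(scan_motif(s, motif)) * 1000 / nchar(s)
    }, numeric(1L), USE.NAMES = FALSE)
  }
  d1 <- density_of(group1); d2 <- density_of(group2)
  if (stats::sd(d1) == 0 && stats::sd(d2) == 0)
    stop_fmt("degenerate density variance in both groups")
  tt <- stats::t.test(d1, d2)
  structure(list(motif = motif$name, densities = list(d1, d2),
                 mean_density = c(mean(d1), mean(d2)),
                 t_statistic = unname(tt$statistic), p_value = tt$p.value),
            class = "motif_density_result")
}

#' @export
print.motif_density_result <- function(x, ...) {
  cat(sprintf("Motif %s density: %.2f vs %.2f per kb; t = %.2f, p = %.3g\n",
              x$motif, x$mean_density[[1L]], x$mean_density[[2L]],
              x$t_statistic, x$p_value))
  invisible(x)
}

#' Does a motif occurrence span a variant position?
#'
#' TRUE iff some full occurrence of the motif within the reference window
#' covers the variant offset (start <= offset < start + motif length).
#' Occurrences truncated by the window edge never count.
#'
#' @param window_seq Reference sequence window around the variant.
#' @param offset 0-based variant position within the window.
#' @param motif A [motif_pattern()].
#' @return Logical scalar.
#' @export
variant_in_motif <- function(window_seq, offset, motif) {
  if (!inherits(motif, "motif_pattern")) motif <- motif_pattern(motif)
  starts <- scan_motif(window_seq, motif)
  len <- length(motif$classes)
  any(starts <= offset & offset < starts + len)
}

#' Cohort enrichment of variants falling in a motif
#'
#' Compares the in-motif fraction of a case cohort's variants with a
#' control cohort by the one-sided (over-representation) Fisher exact
#' test, optionally restricted to one variant annotation stratum (e.g.
#' essential splice sites).
#'
#' @param variants Variant data.frame (schema \code{variant_table}; see
#'   [read_screen_table()]).
#' @param motif A [motif_pattern()].
#' @param case_cohort,control_cohort Cohort labels.
#' @param annotation_filter Optional annotation value to restrict to.
#' @return One-row data.frame: motif, cohort, annotation, a (case
#'   in-motif), b (case not), c (control in-motif), d (control not),
#'   odds_ratio, p_value.
#' @export
cohort_enrichment <- function(variants, motif, case_cohort,
                              control_cohort = "control",
                              annotation_filter = NULL) {
  if (!inherits(motif, "motif_pattern")) motif <- motif_pattern(motif)
  v <- variants
  if (!is.null(annotation_filter))
    v <- v[v$annotation == annotation_filter, , drop = FALSE]
  cases <- v[v$cohort == case_cohort, , drop = FALSE]
  ctrls <- v[v$cohort == control_cohort, , drop = FALSE]
  if (!nrow(cases) || !nrow(ctrls))
    stop_fmt("empty cohort after filtering (cases %d, controls %d)",
             nrow(cases), nrow(ctrls))
  in_motif <- function(df) vapply(seq_len(nrow(df)), function(i) {
    variant_in_motif(df$window_seq[[i]], df$offset[[i]], motif)
  }, logical(1L))
  ic <- in_motif(cases); it <- in_motif(ctrls)
  fe <- fisher_enrichment(sum(ic), sum(!ic), sum(it), sum(!it))
  cbind(data.frame(motif = motif$name, cohort = case_cohort,
                   annotation = annotation_filter %||% "all",
                   stringsAsFactors = FALSE),
        fe)
}

#' Cohort enrichment across motifs and cohorts with BH adjustment
#'
#' Runs [cohort_enrichment()] for every (motif, case cohort) pair and
#' adjusts the p-values with BH across the whole tested family.
#'
#' @inheritParams cohort_enrichment
#' @param motifs List of [motif_pattern()] objects (or pattern strings).
#' @param case_cohorts Character vector of case cohort labels.
#' @return Row-bound data.frame with a q_value column.
#' @export
cohort_enrichment_scan <- function(variants, motifs, case_cohorts,
                                   control_cohort = "control",
                                   annotation_filter = NULL) {
  rows <- list()
  for (m in motifs) for (cc in case_cohorts) {
    rows[[length(rows) + 1L]] <-
      cohort_enrichment(variants, m, cc, control_cohort, annotation_filter)
  }
  out <- do.call(rbind, rows)
  out$q_value <- adjust_fdr(out$p_value)
  out
}

#' The preloaded motif catalog
#'
#' The catalog ships with the ACUK pattern (K = G or U), the one named
#' motif of the RNA-binding-protein motif family analyzed here; the
#' remaining patterns of that family can be added by the caller or via a
#' YAML catalog file with entries \code{name: pattern}.
#'
#' @param path Optional YAML file of \code{name: pattern} entries replacing
#'   the default catalog.
#' @return Named list of [motif_pattern()] objects.
#' @export
motif_catalog <- function(path = NULL) {
  if (is.null(path)) {
    entries <- list(ACUK = "ACUK")
  } else {
    entries <- yaml::read_yaml(path)
  }
  out <- lapply(names(entries), function(nm) motif_pattern(entries[[nm]], nm))
  names(out) <- names(entries)
  out
}
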