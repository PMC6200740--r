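# Typed TSV readers for the pipeline's tabular inputs, plus the
# expression_screen container joining a GCT matrix to its plate annotation.

.table_schemas <- list(
  plate_annotation = c("well_id", "plate_id", "phase_id", "cell_line_id",
                       "group_label", "treatment", "dose"),
  drug_annotation  = c("drug", "class", "feature"),
  variant_table    = c("variant_id", "cohort", "annotation", "window_seq",
                       "offset", "ref", "alt"),
  counts_matrix    = c("gene_id")
)

.group_labels <- c("CCL", "NPC_control", "NPC_SZ")
.annotation_classes <- c("target", "enzyme", "transporter", "carrier",
                         "therapeutic_class", "side_effect", "predicted_target")

#' Read a typed TSV table used by the screening pipeline
#'
#' Reads a tab-separated file and validates it against one of the pipeline's
#' schemas. Unknown columns are preserved. For \code{counts_matrix} the
#' result is a numeric genes-by-cell-lines matrix; otherwise a data.frame.
#'
#' @param path Path to a TSV file with a header line.
#' @param schema One of \code{"plate_annotation"}, \code{"drug_annotation"},
#'   \code{"variant_table"}, \code{"counts_matrix"}.
#' @return A validated data.frame (or matrix for \code{counts_matrix}).
#' @export
read_screen_table <- function(path, schema = names(.table_schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop_fmt("table not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- .table_schemas[[schema]]
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_fmt("%s: schema '%s' requires column(s): %s",
             path, schema, paste(missing, collapse = ", "))
  switch(schema,
    plate_annotation = validate_plate_annotation(df),
    drug_annotation  = validate_drug_annotation(df),
    variant_table    = validate_variant_table(df),
    counts_matrix    = {
      m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
      storage.mode(m) <- "double"
      rownames(m) <- df$gene_id
      if (anyDuplicated(rownames(m))) stop_fmt("%s: duplicate gene_id", path)
      if (any(m < 0, na.rm = TRUE)) stop_fmt("%s: negative counts", path)
      m
    })
}

#' Validate a plate/well annotation table
#'
#' Checks the invariants of the screen layout: every non-EMPTY well belongs
#' to exactly one cell line, the group label is consistent within a cell
#' line, and every (plate, cell line) stratum that contains a treated well
#' also contains at least one vehicle well.
#'
#' @param df data.frame with the \code{plate_annotation} schema columns.
#' @return The validated data.frame (invisibly classed
#'   \code{plate_annotation}).
#' @export
validate_plate_annotation <- function(df) {
  required <- .table_schemas$plate_annotation
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_fmt("plate annotation missing column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(df$well_id))
    stop_fmt("duplicate well_id '%s'", df$well_id[duplicated(df$well_id)][[1L]])
  non_empty <- df[df$treatment != "EMPTY", , drop = FALSE]
  if (any(is.na(non_empty$cell_line_id) | !nzchar(non_empty$cell_line_id)))
    stop_fmt("non-EMPTY well without a cell line id")
  bad_group <- setdiff(unique(non_empty$group_label), .group_labels)
  if (length(bad_group))
    stop_fmt("unknown group_label '%s' (expected %s)", bad_group[[1L]],
             paste(.group_labels, collapse = "/"))
  gl <- tapply(non_empty$group_label, non_empty$cell_line_id,
               function(g) length(unique(g)))
  if (any(gl > 1L))
    stop_fmt("cell line '%s' carries more than one group_label",
             names(gl)[gl > 1L][[1L]])
  treated <- non_empty[!non_empty$treatment %in%
                         c("VEHICLE", "POSITIVE_CONTROL"), , drop = FALSE]
  vehicle <- non_empty[non_empty$treatment == "VEHICLE", , drop = FALSE]
  tk <- unique(paste(treated$plate_id, treated$cell_line_id, sep = "\r"))
  vk <- unique(paste(vehicle$plate_id, vehicle$cell_line_id, sep = "\r"))
  orphan <- setdiff(tk, vk)
  if (length(orphan))
    stop_fmt("treated wells on (plate, cell line) = (%s) have no vehicle well",
             gsub("\r", ", ", orphan[[1L]]))
  class(df) <- unique(c("plate_annotation", class(df)))
  df
}

validate_drug_annotation <- function(df) {
  bad <- setdiff(unique(df$class), .annotation_classes)
  if (length(bad))
    stop_fmt("unknown annotation class '%s' (expected %s)", bad[[1L]],
             paste(.annotation_classes, collapse = "/"))
  key <- paste(df$drug, df$class, df$feature, sep = "\r")
  if (anyDuplicated(key)) stop_fmt("duplicate (drug, class, feature) annotation")
  df
}

validate_variant_table <- function(df) {
  df$offset <- as.integer(df$offset)
  df$window_seq <- toupper(df$window_seq)
  ok_alpha <- grepl("^[ACGTUN]+$", df$window_seq)
  if (any(!ok_alpha))
    stop_fmt("variant '%s': window_seq has characters outside ACGTUN",
             df$variant_id[!ok_alpha][[1L]])
  bad <- df$offset < 0L | df$offset >= nchar(df$window_seq)
  if (any(bad))
    stop_fmt("variant '%s': offset %d outside window of length %d",
             df$variant_id[bad][[1L]], df$offset[bad][[1L]],
             nchar(df$window_seq[bad][[1L]]))
  df
}

#' Bundle an expression matrix with its plate annotation
#'
#' The screen container used by the signature stage. Every matrix column
#' must have an annotation row, and the annotation must satisfy
#' [validate_plate_annotation()].
#'
#' @param matrix Numeric genes-by-wells matrix (e.g. from [read_gct()]).
#' @param annotation Plate annotation data.frame.
#' @return An object of class \code{expression_screen}.
#' @export
expression_screen <- function(matrix, annotation) {
  annotation <- validate_plate_annotation(as.data.frame(annotation))
  if (is.null(colnames(matrix))) stop_fmt("expression matrix has no column names")
  missing <- setdiff(colnames(matrix), annotation$well_id)
  if (length(missing))
    stop_fmt("well '%s' present in matrix but absent from annotation", missing[[1L]])
  annotation <- annotation[match(colnames(matrix), annotation$well_id), , drop = FALSE]
  rownames(annotation) <- NULL
  structure(list(matrix = matrix, annotation = annotation),
            class = "expression_screen")
}

#' @export
print.expression_screen <- function(x, ...) {
  ann <- x$annotation
  cat(sprintf("Expression screen: %d genes x %d wells, %d plates, %d phases\n",
              nrow(x$matrix), ncol(x$matrix),
              length(unique(ann$plate_id)), length(unique(ann$phase_id))))
  drugs <- setdiff(unique(ann$treatment), c("VEHICLE", "POSITIVE_CONTROL", "EMPTY"))
  cat(sprintf("  %d drugs, %d cell lines (%s)\n", length(drugs),
              length(unique(ann$cell_line_id[ann$treatment != "EMPTY"])),
              paste(names(table(ann$group_label[!duplicated(ann$cell_line_id)])),
                    collapse = "/")))
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over \code{Biostrings::readBStringSet} returning a plain
#' named character vector in RNA alphabet (T converted to U).
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  chartr("T", "U", out)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a data.frame as TSV with a fixed column order
#'
#' @param df data.frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_screen_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
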