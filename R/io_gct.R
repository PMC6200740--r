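# GCT matrix input/output.
#
# Two dialects are supported: GCT 1.2 (the classic two-number header) and
# GCT 1.3 (the four-number header carrying embedded row/column metadata).
# Metadata rows and columns of the 1.3 dialect beyond the identifiers are
# skipped: the pipeline consumes processed expression matrices only.

#' Read an expression matrix in GCT format
#'
#' Parses a GCT 1.2 or 1.3 file into a numeric matrix (rows = probes or
#' genes, columns = wells or samples) with the declared identifiers as
#' dimnames. The declared dimensions are checked against the parsed body and
#' identifiers must be unique; violations raise an error naming the
#' offending line.
#'
#' @param path Path to a GCT file.
#' @return A numeric matrix with unique rownames and colnames and an
#'   attribute \code{gct_version} (\code{"1.2"} or \code{"1.3"}).
#' @seealso [write_gct()]
#' @export
read_gct <- function(path) {
  if (!file.exists(path)) stop_fmt("GCT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines, which = "right")) | seq_along(lines) <= 3]
  if (length(lines) < 3)
    stop_fmt("%s: truncated GCT file (%d lines)", path, length(lines))
  version <- trimws(lines[[1L]])
  if (!version %in% c("#1.2", "#1.3"))
    stop_fmt("%s line 1: unsupported GCT dialect '%s' (expected #1.2 or #1.3)",
             path, version)
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[[2L]]), "\t")[[1L]]))
  if (version == "#1.2") {
    if (length(dims) != 2L || anyNA(dims))
      stop_fmt("%s line 2: GCT 1.2 header needs two integers", path)
    n_rmeta <- 1L  # Description column
    n_cmeta <- 0L
  } else {
    if (length(dims) < 4L || anyNA(dims[1:4]))
      stop_fmt("%s line 2: GCT 1.3 header needs four integers", path)
    n_rmeta <- dims[[3L]]
    n_cmeta <- dims[[4L]]
  }
  nr <- dims[[1L]]; nc <- dims[[2L]]
  header <- strsplit(lines[[3L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) != 1L + n_rmeta + nc)
    stop_fmt("%s line 3: header has %d fields, expected %d (1 id + %d metadata + %d samples)",
             path, length(header), 1L + n_rmeta + nc, n_rmeta, nc)
  col_ids <- header[(2L + n_rmeta):length(header)]
  body_start <- 4L + n_cmeta  # 1.3 column-metadata lines are skipped
  body <- lines[seq.int(body_start, length.out = length(lines) - body_start + 1L)]
  if (length(body) != nr)
    stop_fmt("%s: header declares %d data rows but body has %d (body ends at line %d)",
             path, nr, length(body), length(lines))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 1L + n_rmeta + nc)
  if (length(bad))
    stop_fmt("%s line %d: row has %d fields, expected %d",
             path, body_start + bad[[1L]] - 1L, nf[[bad[[1L]]]], 1L + n_rmeta + nc)
  row_ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(row_ids))
    stop_fmt("%s: duplicate row id '%s'", path, row_ids[duplicated(row_ids)][[1L]])
  if (anyDuplicated(col_ids))
    stop_fmt("%s: duplicate column id '%s'", path, col_ids[duplicated(col_ids)][[1L]])
  vals <- vapply(fields, function(f) {
    suppressWarnings(as.numeric(f[(2L + n_rmeta):length(f)]))
  }, numeric(nc))
  mat <- if (nc == 1L) matrix(vals, ncol = 1L) else t(vals)
  dimnames(mat) <- list(row_ids, col_ids)
  attr(mat, "gct_version") <- sub("#", "", version, fixed = TRUE)
  mat
}

#' Write an expression matrix in GCT 1.2 format
#'
#' @param mat Numeric matrix with rownames and colnames.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_gct <- function(mat, path) {
  if (!is.matrix(mat) || is.null(rownames(mat)) || is.null(colnames(mat)))
    stop_fmt("write_gct() needs a matrix with row and column names")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(mat), ncol(mat), sep = "\t")), con)
  writeLines(paste(c("Name", "Description", colnames(mat)), collapse = "\t"), con)
  body <- paste(rownames(mat), rownames(mat),
                apply(mat, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t")),
                sep = "\t")
  writeLines(body, con)
  invisible(path)
}
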