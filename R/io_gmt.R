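# Gene-set collections (GMT) and their container.

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene ids.
#' @param category Free-text label for the collection (e.g. \code{"SZ DE"},
#'   \code{"Synapse PPI"}); used to group FDR families downstream.
#' @return An object of class \code{gene_set_collection}.
#' @export
gene_set_collection <- function(sets, category = "uncategorized") {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop_fmt("sets must be a named list of gene-id vectors")
  if (anyDuplicated(names(sets)))
    stop_fmt("duplicate set name '%s'", names(sets)[duplicated(names(sets))][[1L]])
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) stop_fmt("empty gene set after parsing")
  structure(list(sets = sets, category = as.character(category)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection '%s': %d sets, sizes %d-%d\n",
              x$category, length(x$sets),
              min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a gene-set collection from a GMT file
#'
#' Each line is \code{name<TAB>description<TAB>gene1<TAB>gene2...}. Duplicate
#' genes within a line are deduplicated; lines with no genes are skipped with
#' a warning; duplicate set names are an error.
#'
#' @param path Path to a GMT file.
#' @inheritParams gene_set_collection
#' @return A \code{gene_set_collection}.
#' @export
read_gmt <- function(path, category = "uncategorized") {
  if (!file.exists(path)) stop_fmt("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- lengths(fields) >= 3L
  if (any(!keep))
    warn_fmt("%s: skipped %d line(s) with no genes", path, sum(!keep))
  fields <- fields[keep]
  if (!length(fields)) stop_fmt("%s: no usable gene sets", path)
  nm <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(nm))
    stop_fmt("%s: duplicate set name '%s'", path, nm[duplicated(nm)][[1L]])
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  gene_set_collection(sets, category)
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection A \code{gene_set_collection}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$category, collection$sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
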