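#' @keywords internal
"_PACKAGE"

# Shared internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x) && x >= min
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Format ids like drug_01 ... drug_20 with a stable width.
seq_ids <- function(prefix, n) {
  sprintf("%s_%0*d", prefix, max(2L, nchar(as.character(n))), seq_len(n))
}
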