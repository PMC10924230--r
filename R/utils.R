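# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic locus order: chromosome name as exact string (lexicographic),
# then position. "chr1" != "1"; no natural-order tricks, so ordering is stable
# across locales given LC_COLLATE=C semantics of the C collation below.
#' @keywords internal
#' @noRd
locus_order <- function(chrom, pos) {
  order(chrom, pos, method = "radix")
}

#' @keywords internal
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
#' @noRd
is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

# Open a text connection, transparently gzipped when the path ends in .gz.
#' @keywords internal
#' @noRd
open_maybe_gz <- function(path, mode = "rt") {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}
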