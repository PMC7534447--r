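#' Sequence set container
#'
#' A `seq_set` is an ordered, case-preserving collection of named
#' nucleotide sequences (a genome assembly, or extracted gene sequences).
#' It is a named character vector with class `"seq_set"`; ids must be
#' unique and sequences non-empty. Character case is preserved exactly so
#' that soft-masked (lowercase) repeat tracts survive round-trips.
#'
#' @param x Named character vector of sequences.
#' @param source_path Optional path the sequences were read from.
#' @return A `seq_set` object.
#' @export
#' @examples
#' seq_set(c(chr1 = "ACGTacgtNN", chr2 = "GGCC"))
seq_set <- function(x, source_path = NULL) {
  if (!is.character(x) || length(x) == 0L)
    stop("a seq_set requires a non-empty character vector of sequences")
  ids <- names(x)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every sequence must be named with a non-empty id")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(x)))
    stop("empty sequence for id: ",
         paste(ids[!nzchar(x)], collapse = ", "))
  structure(x, class = "seq_set", source_path = source_path)
}

#' @export
print.seq_set <- function(x, ...) {
  n <- length(x)
  cat("seq_set with", n, if (n == 1L) "sequence\n" else "sequences\n")
  show <- utils::head(seq_len(n), 6L)
  len <- nchar(unclass(x))
  for (i in show) {
    s <- unclass(x)[[i]]
    prev <- if (nchar(s) > 40L) paste0(substr(s, 1L, 40L), "...") else s
    cat(sprintf("  %s (%s bp): %s\n", names(x)[i],
                format(len[i], big.mark = ","), prev))
  }
  if (n > 6L) cat("  ...", n - 6L, "more\n")
  invisible(x)
}

#' @export
`[.seq_set` <- function(x, i, ...) {
  out <- NextMethod()
  if (length(out) == 0L) stop("empty seq_set after subsetting")
  seq_set(out, source_path = attr(x, "source_path"))
}

#' @rdname seq_set
#' @export
is_seq_set <- function(x) inherits(x, "seq_set")

as_seq_set <- function(x) {
  if (is_seq_set(x)) x else seq_set(x)
}
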