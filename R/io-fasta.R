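#' Read a FASTA file into a seq_set
#'
#' Parsing is delegated to [Biostrings::readBStringSet()], which keeps the
#' original character case byte-for-byte (soft-masked lowercase tracts are
#' preserved; a DNA-alphabet container would uppercase them). Gzip
#' compression is detected from the `.gz`/`.bgz` extension. The record id
#' is the first whitespace-delimited token of the header; the full header
#' line is retained in the `"descriptions"` attribute.
#'
#' @param path Path to a FASTA file, optionally gzip-compressed.
#' @param preserve_case Keep lowercase (soft-masked) characters as-is
#'   (default `TRUE`). When `FALSE` sequences are uppercased on read.
#' @return A [seq_set] with one record per FASTA entry, in file order.
#' @export
read_fasta <- function(path, preserve_case = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  validate_fasta_head(path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  seqs <- as.character(set)
  if (!preserve_case) seqs <- toupper(seqs)
  names(seqs) <- ids
  out <- seq_set(seqs, source_path = path)
  attr(out, "descriptions") <- stats::setNames(headers, ids)
  out
}

# Cheap structural check so malformed input fails with a line number
# (Biostrings' own error does not report one).
validate_fasta_head <- function(path, max_lines = 1000L) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lineno <- 0L
  repeat {
    lines <- readLines(con, n = max_lines)
    if (length(lines) == 0L) break
    for (ln in lines) {
      lineno <- lineno + 1L
      if (!nzchar(trimws(ln)) || startsWith(ln, ";")) next
      if (!startsWith(ln, ">"))
        stop("malformed FASTA: sequence data before first header at line ",
             lineno)
      return(invisible(TRUE))
    }
  }
  stop("malformed FASTA: no header found in ", path)
}

#' Write a seq_set to a FASTA file
#'
#' Record order and character case are preserved; sequences are wrapped at
#' `line_width` characters. A `.gz` extension triggers gzip compression.
#'
#' @param seqs A [seq_set] (or named character vector of sequences).
#' @param path Output path.
#' @param line_width Sequence line width, >= 1 (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, line_width = 80L) {
  seqs <- as_seq_set(seqs)
  if (!is_scalar_number(line_width) || line_width < 1)
    stop("line_width must be >= 1")
  set <- Biostrings::BStringSet(unclass(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(line_width),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
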