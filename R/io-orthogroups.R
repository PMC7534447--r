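#' Orthogroup count table
#'
#' Container for species-by-orthogroup gene counts, the input to all
#' sharing, species-specificity and pan/core-genome computations.
#'
#' @param counts Integer matrix, rows = orthogroups (rownames = ids),
#'   columns = species (colnames = species names). Every orthogroup must
#'   have at least one positive count.
#' @param unassigned Optional named vector: per-species count of genes not
#'   assigned to any orthogroup (used only for gene-total percentages).
#' @return An `orthogroup_table` object.
#' @export
orthogroup_table <- function(counts, unassigned = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) || is.null(rownames(counts)))
    stop("counts needs species colnames and orthogroup rownames")
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  if (any(rowSums(counts > 0) == 0L))
    stop("every orthogroup must have at least one positive count")
  if (!is.null(unassigned)) {
    if (!all(colnames(counts) %in% names(unassigned)))
      stop("unassigned must name every species")
    unassigned <- unassigned[colnames(counts)]
    if (any(unassigned < 0)) stop("unassigned counts must be non-negative")
  }
  structure(list(species = colnames(counts), counts = counts,
                 unassigned = unassigned),
            class = "orthogroup_table")
}

#' @export
print.orthogroup_table <- function(x, ...) {
  cat("orthogroup_table:", nrow(x$counts), "orthogroups x",
      length(x$species), "species\n")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  if (!is.null(x$unassigned))
    cat("  unassigned genes per species recorded\n")
  invisible(x)
}

#' Read orthogroup tables in OrthoFinder dialects
#'
#' Supports the two tab-separated dialects OrthoFinder writes:
#' `Orthogroups.GeneCount.tsv` (integer counts, optional trailing `Total`
#' column, dropped) and `Orthogroups.tsv` (comma-separated gene lists per
#' cell; counts are the number of listed genes, empty cell = 0).
#'
#' @param path Path to the TSV file.
#' @param dialect `"gene_count_tsv"` or `"membership_tsv"`.
#' @return An [orthogroup_table].
#' @export
read_orthogroup_counts <- function(path,
                                   dialect = c("gene_count_tsv",
                                               "membership_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", blank.lines.skip = TRUE)
  if (length(unique(nf)) > 1L)
    stop("ragged orthogroup table: row ",
         which(nf != nf[1L])[1L], " has ", nf[nf != nf[1L]][1L],
         " fields, expected ", nf[1L])
  tab <- utils::read.delim(path, check.names = FALSE, quote = "",
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("orthogroup table needs an id column and >= 1 species")
  og_ids <- tab[[1L]]
  body <- tab[, -1L, drop = FALSE]
  if (dialect == "gene_count_tsv") {
    if (tolower(colnames(body)[ncol(body)]) == "total")
      body <- body[, -ncol(body), drop = FALSE]
    counts <- vapply(body, function(col) {
      v <- suppressWarnings(as.integer(col))
      if (anyNA(v)) stop("non-integer cell in gene_count_tsv")
      v
    }, integer(nrow(body)))
    counts <- matrix(counts, nrow = nrow(body),
                     dimnames = list(og_ids, colnames(body)))
  } else {
    count_cell <- function(cell) {
      if (!nzchar(trimws(cell))) return(0L)
      sum(nzchar(trimws(strsplit(cell, ",", fixed = TRUE)[[1L]])))
    }
    counts <- vapply(body, function(col) vapply(col, count_cell, integer(1),
                                                USE.NAMES = FALSE),
                     integer(nrow(body)))
    counts <- matrix(counts, nrow = nrow(body),
                     dimnames = list(og_ids, colnames(body)))
  }
  orthogroup_table(counts)
}
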