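#' Nucleotide and CpG dinucleotide counts
#'
#' Case-insensitive counts of A/C/G/T and of the CG dinucleotide; N and
#' IUPAC ambiguity codes are excluded everywhere, and a CG is counted
#' only when both positions are unambiguous (an intervening N breaks the
#' dinucleotide).
#'
#' @param sequence A single nucleotide string.
#' @return A `nucleotide_counts` list: `n_A`, `n_C`, `n_G`, `n_T`,
#'   `n_CpG`, `length` (number of unambiguous bases).
#' @export
#' @examples
#' count_nucleotides("CGCG")  # n_C = 2, n_G = 2, n_CpG = 2
count_nucleotides <- function(sequence) {
  r <- charToRaw(toupper(sequence))
  a <- sum(r == as.raw(0x41)); c_ <- sum(r == as.raw(0x43))
  g <- sum(r == as.raw(0x47)); t <- sum(r == as.raw(0x54))
  n_cpg <- if (length(r) >= 2L)
    sum(r[-length(r)] == as.raw(0x43) & r[-1L] == as.raw(0x47))
  else 0L
  structure(list(n_A = a, n_C = c_, n_G = g, n_T = t,
                 n_CpG = n_cpg, length = a + c_ + g + t),
            class = "nucleotide_counts")
}

#' CpG observed/expected ratio
#'
#' The observed/expected CpG ratio of a sequence. The `"literal"` form is
#' `n_CpG / (n_C * n_G)`; it scales as 1/length and is kept for fidelity
#' with the classical dinucleotide formula. The default
#' `"length_normalized"` form, `n_CpG * length / (n_C * n_G)`, is the
#' standard methylation-signature statistic whose expectation is 1 for
#' dinucleotide-random sequence and which is depleted below 1 by
#' historical germline CpG methylation. Undefined (`NA`) when the
#' sequence has no C, no G, or fewer than two unambiguous bases.
#'
#' @param counts A `nucleotide_counts` from [count_nucleotides()] (or a
#'   sequence string, counted on the fly).
#' @param normalization `"length_normalized"` (default) or `"literal"`.
#' @return A non-negative number, or `NA_real_` when undefined.
#' @export
cpg_oe <- function(counts, normalization = c("length_normalized", "literal")) {
  normalization <- match.arg(normalization)
  if (is.character(counts)) counts <- count_nucleotides(counts)
  if (counts$n_C == 0L || counts$n_G == 0L || counts$length < 2L)
    return(NA_real_)
  base <- counts$n_CpG / (counts$n_C * counts$n_G)
  if (normalization == "literal") base else base * counts$length
}

#' Per-gene CpG o/e table
#'
#' @param genes A [seq_set] of gene sequences (typically from
#'   [extract_gene_sequences()], coding sequences by default).
#' @param normalization Passed to [cpg_oe()].
#' @return A `cpg_table` data frame with one row per gene: `gene_id`,
#'   the nucleotide counts, `cpg_oe` and `defined`. Undefined rows are
#'   retained but flagged (`defined = FALSE`).
#' @export
cpg_table <- function(genes, normalization = c("length_normalized", "literal")) {
  normalization <- match.arg(normalization)
  genes <- as_seq_set(genes)
  counts <- lapply(unclass(genes), count_nucleotides)
  oe <- vapply(counts, cpg_oe, numeric(1), normalization = normalization)
  out <- data.frame(gene_id = names(genes),
                    n_A = vapply(counts, `[[`, numeric(1), "n_A"),
                    n_C = vapply(counts, `[[`, numeric(1), "n_C"),
                    n_G = vapply(counts, `[[`, numeric(1), "n_G"),
                    n_T = vapply(counts, `[[`, numeric(1), "n_T"),
                    n_CpG = vapply(counts, `[[`, numeric(1), "n_CpG"),
                    length = vapply(counts, `[[`, numeric(1), "length"),
                    cpg_oe = unname(oe),
                    defined = !is.na(unname(oe)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "normalization") <- normalization
  class(out) <- c("cpg_table", class(out))
  out
}

#' Histogram bins of CpG o/e values
#'
#' Bins the defined CpG o/e values into `[0, max]` with a fixed bin
#' width, for plotting frequency histograms of the per-gene distribution.
#'
#' @param table A `cpg_table`.
#' @param bin_width Bin width on the o/e axis (default 0.05).
#' @return Data frame with `bin_start`, `bin_end`, `count`.
#' @export
cpg_histogram <- function(table, bin_width = 0.05) {
  v <- table$cpg_oe[table$defined]
  if (length(v) == 0L) stop("no defined CpG o/e values to bin")
  if (!is_scalar_number(bin_width) || bin_width <= 0)
    stop("bin_width must be > 0")
  breaks <- seq(0, ceiling(max(v) / bin_width) * bin_width, by = bin_width)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE, right = FALSE)
  data.frame(bin_start = utils::head(breaks, -1L),
             bin_end = breaks[-1L], count = h$counts)
}
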