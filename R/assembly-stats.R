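#' Nx statistic of a set of sequence lengths
#'
#' `nx(lengths, 50)` is the N50: the largest length L such that sequences
#' of length >= L together cover at least x% of the total. Computed by the
#' standard sorted-cumulative definition.
#'
#' @param lengths Positive sequence lengths (bp).
#' @param x Percent threshold in (0, 100); default 50.
#' @return A length from `lengths` (bp).
#' @export
#' @examples
#' nx(c(5, 4, 3, 2, 1), 50)  # 4
nx <- function(lengths, x = 50) {
  if (length(lengths) == 0L) stop("empty length list")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("lengths must be positive and finite")
  if (!is_scalar_number(x) || x <= 0 || x >= 100)
    stop("x must be in (0, 100)")
  sorted <- sort(unname(lengths), decreasing = TRUE)
  target <- sum(sorted) * x / 100
  sorted[which(cumsum(sorted) >= target)[1L]]
}

# Per-sequence character tallies from raw bytes (fast on Mb-scale strings).
scan_sequence <- function(s) {
  r <- charToRaw(s)
  lower <- r >= as.raw(0x61) & r <= as.raw(0x7a)
  is_n <- r == as.raw(0x4e) | r == as.raw(0x6e)   # N or n
  runs <- rle(as.vector(is_n))
  list(length = length(r),
       n_count = sum(is_n),
       lowercase = sum(lower),
       n_runs = runs$lengths[runs$values])
}

#' Assembly summary statistics
#'
#' Computes the standard assembly QC bundle for a (case-preserving)
#' assembly: total and largest sequence length, scaffold count, N50,
#' N count, gap count and soft-masked repeat fraction. A gap is a maximal
#' run of >= `min_gap_run` consecutive N/n characters; repositories differ
#' on the run-length convention (some require >= 10), so it is a
#' parameter. The repeat fraction is the fraction of lowercase characters,
#' the soft-masking convention; by default the denominator includes N
#' characters.
#'
#' @param assembly A [seq_set].
#' @param min_gap_run Minimum N-run length counted as a gap (default 1).
#' @param exclude_n_from_repeat_denominator If `TRUE`, the repeat-fraction
#'   denominator is total length minus N count.
#' @return An `assembly_stats` object (list with fields `total_length`,
#'   `largest`, `n_scaffolds`, `n50`, `n_count`, `gap_count`,
#'   `repeat_fraction`).
#' @export
compute_stats <- function(assembly, min_gap_run = 1L,
                          exclude_n_from_repeat_denominator = FALSE) {
  assembly <- as_seq_set(assembly)
  scans <- lapply(unclass(assembly), scan_sequence)
  lens <- unname(vapply(scans, `[[`, numeric(1), "length"))
  n_count <- sum(vapply(scans, `[[`, numeric(1), "n_count"))
  lowercase <- sum(vapply(scans, `[[`, numeric(1), "lowercase"))
  gap_count <- sum(vapply(scans, function(sc)
    sum(sc$n_runs >= min_gap_run), numeric(1)))
  total <- sum(lens)
  denom <- if (exclude_n_from_repeat_denominator) total - n_count else total
  structure(list(total_length = total,
                 largest = max(lens),
                 n_scaffolds = length(lens),
                 n50 = nx(lens, 50),
                 n_count = n_count,
                 gap_count = gap_count,
                 repeat_fraction = if (denom > 0) lowercase / denom else NA_real_),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  fmt <- function(v) format(v, big.mark = ",")
  cat("Assembly statistics\n")
  cat("  total sequence:", fmt(x$total_length), "bp\n")
  cat("  largest:       ", fmt(x$largest), "bp\n")
  cat("  scaffolds:     ", fmt(x$n_scaffolds), "\n")
  cat("  N50:           ", fmt(x$n50), "bp\n")
  cat("  Ns:            ", fmt(x$n_count), "\n")
  cat("  gaps:          ", fmt(x$gap_count), "\n")
  cat("  repeat fraction:", sprintf("%.4f", x$repeat_fraction), "\n")
  invisible(x)
}

#' @export
as.data.frame.assembly_stats <- function(x, ...) {
  data.frame(total_length = x$total_length, largest = x$largest,
             n_scaffolds = x$n_scaffolds, n50 = x$n50, n_count = x$n_count,
             gap_count = x$gap_count, repeat_fraction = x$repeat_fraction)
}

#' Tabulate statistics for several assemblies
#'
#' @param assemblies Named list of [seq_set] objects (names are assembly
#'   labels; duplicates are an error). Row order follows input order.
#' @param ... Passed to [compute_stats()].
#' @return A data frame, one row per assembly, TSV-serializable.
#' @export
stats_table <- function(assemblies, ...) {
  if (length(assemblies) == 0L) stop("need at least one assembly")
  nm <- names(assemblies)
  if (is.null(nm) || any(!nzchar(nm))) stop("assemblies must be named")
  if (anyDuplicated(nm))
    stop("duplicate assembly names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  rows <- lapply(assemblies, function(a) as.data.frame(compute_stats(a, ...)))
  out <- cbind(data.frame(assembly = nm, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
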