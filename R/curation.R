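#' GC fraction of a sequence
#'
#' (G + C) / (A + C + G + T), case-insensitive. N and IUPAC ambiguity
#' codes are excluded from numerator and denominator. Returns `NA` when
#' the sequence has no unambiguous base.
#'
#' @param sequence A single nucleotide string.
#' @return Fraction in \[0, 1\], or `NA_real_`.
#' @export
#' @examples
#' gc_fraction("ACGTacgt")  # 0.5
gc_fraction <- function(sequence) {
  r <- charToRaw(toupper(sequence))
  gc <- sum(r == as.raw(0x43) | r == as.raw(0x47))          # C, G
  at <- sum(r == as.raw(0x41) | r == as.raw(0x54))          # A, T
  denom <- gc + at
  if (denom == 0L) NA_real_ else gc / denom
}

#' Three-rule contamination classification of contigs
#'
#' Classifies every contig of an assembly as keep/discard by a single,
#' strictly ordered pass:
#' \enumerate{
#'   \item Contigs with at least one taxonomy hit are KEPT
#'     (`taxonomy_keyword`) if any hit description contains any of the
#'     keep keywords (case-insensitive substring by default), otherwise
#'     DISCARDED (`taxonomy_mismatch`).
#'   \item Contigs with no hits are KEPT (`orthogroup_rescue`) if they
#'     carry at least one predicted gene assigned to an orthogroup of the
#'     reference clade.
#'   \item Remaining contigs are kept iff their GC fraction falls within
#'     `gc_sd_multiplier` sample standard deviations of the mean GC of the
#'     contigs kept by rules 1-2 (`gc_within_band` / `gc_outside_band`).
#'     The band is computed once and never updated (single pass).
#' }
#'
#' @param assembly A [seq_set].
#' @param taxonomy_hits Data frame with columns `contig_id`,
#'   `description`, one row per hit; contigs absent from it have no hits.
#' @param rescue Either a named vector of per-contig rescued-gene counts,
#'   or a data frame whose first column is `contig_id` (one row per
#'   rescued gene, e.g. `contig_id, gene_id, orthogroup_id`); `NULL`
#'   means no rescue evidence.
#' @param keep_keywords Keywords marking an on-target hit
#'   (default `c("Polistes", "Vespula", "wasp")`).
#' @param gc_sd_multiplier Width of the GC band in standard deviations
#'   (default 2).
#' @param case_sensitive Match keywords case-sensitively (default FALSE).
#' @param whole_word Require keywords to match as whole words rather than
#'   substrings (default FALSE).
#' @return A `curation_report`: data frame with columns `contig_id`,
#'   `verdict` (keep/discard), `rule`, `gc`; attributes `gc_mean` and
#'   `gc_sd` record the rule-3 band.
#' @export
classify_contigs <- function(assembly, taxonomy_hits = NULL, rescue = NULL,
                             keep_keywords = c("Polistes", "Vespula", "wasp"),
                             gc_sd_multiplier = 2,
                             case_sensitive = FALSE,
                             whole_word = FALSE) {
  assembly <- as_seq_set(assembly)
  if (length(keep_keywords) == 0L) stop("keep_keywords must be non-empty")
  if (!is_scalar_number(gc_sd_multiplier) || gc_sd_multiplier <= 0)
    stop("gc_sd_multiplier must be > 0")
  ids <- names(assembly)

  hits <- split(character(0), factor(character(0)))
  if (!is.null(taxonomy_hits) && nrow(taxonomy_hits) > 0L) {
    extra <- setdiff(unique(taxonomy_hits$contig_id), ids)
    if (length(extra))
      stop("taxonomy hits for unknown contigs: ", paste(extra, collapse = ", "))
    hits <- split(as.character(taxonomy_hits$description),
                  taxonomy_hits$contig_id)
  }

  rescue_counts <- stats::setNames(numeric(length(ids)), ids)
  if (!is.null(rescue)) {
    if (is.data.frame(rescue)) {
      tab <- table(as.character(rescue[[1L]]))
      rescue <- stats::setNames(as.numeric(tab), names(tab))
    }
    known <- intersect(names(rescue), ids)
    if (length(setdiff(names(rescue), ids)))
      stop("rescue evidence for unknown contigs: ",
           paste(setdiff(names(rescue), ids), collapse = ", "))
    rescue_counts[known] <- rescue[known]
  }

  gc <- vapply(unclass(assembly), gc_fraction, numeric(1))

  matches_keyword <- function(desc) {
    any(vapply(keep_keywords, function(kw) {
      pat <- if (whole_word) paste0("\\b", kw, "\\b") else kw
      any(grepl(pat, desc, ignore.case = !case_sensitive,
                fixed = !whole_word && case_sensitive))
    }, logical(1)))
  }

  rule <- character(length(ids)); names(rule) <- ids
  for (id in ids) {
    h <- hits[[id]] %||% character(0)
    if (length(h) > 0L) {
      rule[id] <- if (matches_keyword(h)) "taxonomy_keyword" else "taxonomy_mismatch"
    } else if (rescue_counts[id] >= 1) {
      rule[id] <- "orthogroup_rescue"
    } else {
      rule[id] <- "gc_pending"
    }
  }

  kept12 <- ids[rule %in% c("taxonomy_keyword", "orthogroup_rescue")]
  if (length(kept12) == 0L)
    stop("no contig kept by the taxonomy/rescue rules; the GC band is ",
         "undefined. Relax keep_keywords or supply rescue evidence.")
  gc_ref <- gc[kept12]
  gc_ref <- gc_ref[!is.na(gc_ref)]
  pending <- ids[rule == "gc_pending"]
  gc_mean <- mean(gc_ref)
  gc_sd <- if (length(gc_ref) >= 2L) stats::sd(gc_ref) else {
    if (length(pending))
      warning("only one contig defines the GC band; using sd = 0")
    0
  }
  lo <- gc_mean - gc_sd_multiplier * gc_sd
  hi <- gc_mean + gc_sd_multiplier * gc_sd

  for (id in pending) {
    if (is.na(gc[id])) {
      warning("contig ", id, " has undefined GC fraction; discarded")
      rule[id] <- "gc_outside_band"
    } else {
      rule[id] <- if (gc[id] >= lo && gc[id] <= hi) "gc_within_band"
                  else "gc_outside_band"
    }
  }

  verdict <- ifelse(rule %in% c("taxonomy_keyword", "orthogroup_rescue",
                                "gc_within_band"), "keep", "discard")
  out <- data.frame(contig_id = ids, verdict = unname(verdict),
                    rule = unname(rule), gc = unname(gc),
                    stringsAsFactors = FALSE)
  attr(out, "gc_mean") <- gc_mean
  attr(out, "gc_sd") <- gc_sd
  class(out) <- c("curation_report", class(out))
  out
}

#' @export
print.curation_report <- function(x, ...) {
  cat("curation_report:", nrow(x), "contigs;",
      sum(x$verdict == "keep"), "kept,",
      sum(x$verdict == "discard"), "discarded\n")
  cat(sprintf("  GC band: mean %.4f, sd %.4f\n",
              attr(x, "gc_mean"), attr(x, "gc_sd")))
  print(table(rule = x$rule, verdict = x$verdict))
  invisible(x)
}

#' Apply a curation report to an assembly
#'
#' @param assembly A [seq_set].
#' @param report A `curation_report` covering every contig.
#' @return A [seq_set] with only the kept contigs, original order and
#'   case preserved.
#' @export
apply_curation <- function(assembly, report) {
  assembly <- as_seq_set(assembly)
  if (!setequal(names(assembly), report$contig_id))
    stop("curation report does not cover the assembly contigs")
  keep <- report$contig_id[report$verdict == "keep"]
  if (length(keep) == 0L) stop("empty assembly after curation")
  assembly[names(assembly) %in% keep]
}

#' Rank-based chromosome and scaffold naming
#'
#' Records are ranked by length, descending (ties broken by input order).
#' The first `n_chromosomes` ranks become `"<chromosome_prefix><rank>"`;
#' the remainder become `"<scaffold_prefix>"` plus a zero-padded
#' four-digit index starting at 0001, still in descending length order.
#'
#' @param assembly A [seq_set].
#' @param n_chromosomes Number of top-ranked records named as chromosomes
#'   (default 25).
#' @param chromosome_prefix,scaffold_prefix Name prefixes.
#' @return A `naming_map` data frame with columns `old_id`, `new_id`,
#'   `length`, `rank`.
#' @export
assign_names <- function(assembly, n_chromosomes = 25L,
                         chromosome_prefix = "Chr",
                         scaffold_prefix = "Scaffold") {
  assembly <- as_seq_set(assembly)
  if (!is_scalar_number(n_chromosomes) || n_chromosomes < 0)
    stop("n_chromosomes must be >= 0")
  lens <- nchar(unclass(assembly))
  ord <- order(-lens)              # stable: ties keep input order
  n <- length(lens)
  if (n < n_chromosomes)
    warning("fewer records (", n, ") than n_chromosomes (", n_chromosomes,
            "); all records named as chromosomes")
  rank <- seq_len(n)
  new_id <- ifelse(rank <= n_chromosomes,
                   paste0(chromosome_prefix, rank),
                   sprintf("%s%04d", scaffold_prefix,
                           rank - min(n_chromosomes, n)))
  out <- data.frame(old_id = names(assembly)[ord],
                    new_id = new_id,
                    length = unname(lens[ord]),
                    rank = rank,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("naming_map", class(out))
  out
}

#' Rename assembly records using a naming map
#'
#' @param assembly A [seq_set].
#' @param map A `naming_map` from [assign_names()].
#' @return The assembly with renamed records, original record order kept.
#' @export
apply_naming <- function(assembly, map) {
  assembly <- as_seq_set(assembly)
  if (!setequal(names(assembly), map$old_id))
    stop("naming map does not cover the assembly contigs")
  lookup <- stats::setNames(map$new_id, map$old_id)
  out <- unclass(assembly)
  names(out) <- unname(lookup[names(out)])
  seq_set(out, source_path = attr(assembly, "source_path"))
}
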