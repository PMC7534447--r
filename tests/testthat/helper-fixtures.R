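# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures are stored.

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A random FASTA-ready sequence over the full soft-masked alphabet.
random_sequence <- function(len, alphabet = c("A", "C", "G", "T", "N",
                                              "a", "c", "g", "t", "n")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_seq_set <- function(n_records, min_len = 1L, max_len = 200L) {
  lens <- sample(min_len:max_len, n_records, replace = TRUE)
  seqs <- vapply(lens, random_sequence, character(1))
  names(seqs) <- sprintf("rec%03d", seq_len(n_records))
  seq_set(seqs)
}

# Minimal GFF3 with a gene -> (optional mRNA) -> CDS chain per entry.
# genes: list of lists with fields id, contig, start, end, strand,
#        cds (matrix or NULL), via_mrna (flag)
write_gff3 <- function(genes) {
  lines <- "##gff-version 3"
  for (g in genes) {
    lines <- c(lines, sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$contig, g$start, g$end, g$strand, g$id))
    parent <- g$id
    if (isTRUE(g$via_mrna)) {
      mid <- paste0(g$id, ".t1")
      lines <- c(lines, sprintf("%s\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                                g$contig, g$start, g$end, g$strand, mid, g$id))
      parent <- mid
    }
    if (!is.null(g$cds)) {
      for (r in seq_len(nrow(g$cds)))
        lines <- c(lines, sprintf("%s\ttest\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c%d;Parent=%s",
                                  g$contig, g$cds[r, 1], g$cds[r, 2],
                                  g$strand, g$id, r, parent))
    }
  }
  write_tmp(lines, ".gff3")
}

# The 3-species worked orthogroup example used across the orthogroup
# tests: A = [1,1,1], B = [1,1,0], C = [0,0,1].
worked_og_table <- function() {
  counts <- matrix(c(1, 1, 1,
                     1, 1, 0,
                     0, 0, 1),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("A", "B", "C"),
                                   c("sp1", "sp2", "sp3")))
  orthogroup_table(counts)
}

# Brute-force Nx oracle: test every candidate length L in the list.
nx_oracle <- function(lengths, x) {
  total <- sum(lengths)
  cands <- sort(unique(lengths), decreasing = TRUE)
  for (L in cands) {
    if (sum(lengths[lengths >= L]) >= total * x / 100) return(L)
  }
  min(lengths)
}
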