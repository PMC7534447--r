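#' Read gene models from a GFF3 file
#'
#' Uses [rtracklayer::readGFF()] and keeps only `gene`, `mRNA`/`transcript`
#' and `CDS` features. CDS features are linked to their gene either
#' directly (`Parent=gene`) or through an mRNA intermediary. Coordinates
#' stay 1-based inclusive, the native GFF3 convention used throughout this
#' package. When a gene has several transcripts, the CDS parts of the
#' transcript with the largest total CDS length are kept (longest-isoform
#' convention).
#'
#' @param path Path to a GFF3 file.
#' @return A `gene_annotation` data frame with columns `gene_id`,
#'   `contig_id`, `start`, `end`, `strand` and a list-column `cds_parts`
#'   (two-column matrix of CDS start/end per gene, or `NULL` when the gene
#'   has no CDS children).
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gff <- as.data.frame(rtracklayer::readGFF(
    path, columns = c("seqid", "type", "start", "end", "strand"),
    tags = c("ID", "Parent")))
  gff$Parent <- lapply(gff$Parent, as.character)

  genes <- gff[gff$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) stop("no gene features in ", path)
  if (anyNA(genes$ID) || any(!nzchar(genes$ID)))
    stop("gene feature without ID attribute in ", path)
  if (anyDuplicated(genes$ID))
    stop("duplicate gene IDs in ", path)

  # transcript id -> owning gene id
  tx <- gff[gff$type %in% c("mRNA", "transcript"), , drop = FALSE]
  tx_gene <- character(0)
  if (nrow(tx) > 0L) {
    parent1 <- vapply(tx$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
                      character(1))
    keep <- !is.na(tx$ID) & parent1 %in% genes$ID
    tx_gene <- stats::setNames(parent1[keep], tx$ID[keep])
  }

  cds <- gff[gff$type == "CDS", , drop = FALSE]
  cds_by_owner <- list()
  for (i in seq_len(nrow(cds))) {
    parents <- cds$Parent[[i]]
    if (length(parents) == 0L) parents <- NA_character_
    resolved <- FALSE
    for (p in parents) {
      owner <- if (!is.na(p) && p %in% genes$ID) paste0("g:", p)
               else if (!is.na(p) && p %in% names(tx_gene)) paste0("t:", p)
               else next
      cds_by_owner[[owner]] <- rbind(cds_by_owner[[owner]],
                                     c(cds$start[i], cds$end[i]))
      resolved <- TRUE
    }
    if (!resolved)
      warning("CDS with unresolvable Parent (", paste(parents, collapse = ","),
              ") skipped", call. = FALSE)
  }

  pick_parts <- function(gid) {
    direct <- cds_by_owner[[paste0("g:", gid)]]
    tx_ids <- names(tx_gene)[tx_gene == gid]
    tx_parts <- lapply(tx_ids, function(t) cds_by_owner[[paste0("t:", t)]])
    tx_parts <- tx_parts[!vapply(tx_parts, is.null, logical(1))]
    cand <- c(list(direct)[!is.null(direct)], tx_parts)
    if (length(cand) == 0L) return(NULL)
    totals <- vapply(cand, function(m) sum(m[, 2L] - m[, 1L] + 1), numeric(1))
    m <- cand[[which.max(totals)]]
    m <- m[order(m[, 1L]), , drop = FALSE]
    colnames(m) <- c("start", "end")
    m
  }

  out <- data.frame(gene_id = genes$ID,
                    contig_id = as.character(genes$seqid),
                    start = genes$start, end = genes$end,
                    strand = as.character(genes$strand),
                    stringsAsFactors = FALSE)
  out$cds_parts <- lapply(genes$ID, pick_parts)
  if (any(out$start > out$end)) stop("gene with start > end in ", path)
  class(out) <- c("gene_annotation", class(out))
  out
}

#' Extract gene sequences from an assembly
#'
#' @param assembly A [seq_set] holding the contigs/scaffolds.
#' @param annot A `gene_annotation` from [read_gff3_genes()].
#' @param mode `"gene_body"` extracts the genomic span `start..end`;
#'   `"cds"` concatenates the CDS parts in genomic order. Minus-strand
#'   genes are reverse-complemented after extraction/concatenation.
#'   Coordinates are 1-based inclusive.
#' @return A [seq_set] of gene sequences, ids = gene ids.
#' @export
extract_gene_sequences <- function(assembly, annot,
                                   mode = c("cds", "gene_body")) {
  mode <- match.arg(mode)
  assembly <- as_seq_set(assembly)
  missing_ctg <- setdiff(unique(annot$contig_id), names(assembly))
  if (length(missing_ctg))
    stop("genes on contigs absent from assembly: ",
         paste(missing_ctg, collapse = ", "))
  seqs <- character(nrow(annot))
  for (i in seq_len(nrow(annot))) {
    contig <- unclass(assembly)[[annot$contig_id[i]]]
    clen <- nchar(contig)
    spans <- if (mode == "gene_body" || is.null(annot$cds_parts[[i]]))
      matrix(c(annot$start[i], annot$end[i]), ncol = 2L)
    else annot$cds_parts[[i]]
    if (mode == "cds" && is.null(annot$cds_parts[[i]]))
      stop("gene ", annot$gene_id[i], " has no CDS parts (mode = \"cds\")")
    if (any(spans[, 2L] > clen) || any(spans[, 1L] < 1L))
      stop("gene ", annot$gene_id[i], " span exceeds contig ",
           annot$contig_id[i], " bounds")
    s <- paste0(substring(contig, spans[, 1L], spans[, 2L]), collapse = "")
    if (annot$strand[i] == "-") s <- reverse_complement(s)
    seqs[i] <- s
  }
  names(seqs) <- annot$gene_id
  seq_set(seqs)
}
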