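# Seeded generators producing inputs with the statistical structure each
# pipeline stage assumes. Every generator is a pure function of its
# arguments (seed included) and returns a machine-readable truth table
# alongside the simulated data, so each stage can be scored without
# re-deriving ground truth.

#' Simulate a contaminated genome assembly
#'
#' Generates host contigs at one GC level and planted contaminant contigs
#' at a shifted GC level, with soft-masked (lowercase) repeat tracts,
#' N-gap runs, a taxonomy hit table and an orthogroup-rescue table — the
#' full input bundle of the contamination filter. Host contigs receive a
#' keyword-bearing taxonomy description except for a `taxonomy_miss_rate`
#' fraction; hitless host contigs carry rescue genes with probability
#' `rescue_rate`. Contaminants receive a non-matching description with
#' probability `contaminant_hit_rate`, otherwise no hit (and never any
#' rescue genes). The default GC offset of 0.15 is far outside the
#' 2-standard-deviation GC band of the host contigs, so discard
#' decisions have an unambiguous truth.
#'
#' @param n_host_contigs,n_contaminant_contigs Contig counts (default
#'   50 host + 10 contaminant).
#' @param host_gc,contaminant_gc GC fractions (defaults 0.31 and 0.46).
#' @param length_meanlog,length_sdlog Log-normal contig-length law
#'   (default meanlog log(2e4), sdlog 0.4).
#' @param repeat_fraction Target soft-masked fraction per contig
#'   (default 0.18).
#' @param gap_rate Expected N-runs per contig (Poisson; default 2).
#' @param gap_run_mean Mean N-run length (geometric; default 100).
#' @param taxonomy_miss_rate Probability a host contig has no taxonomy
#'   hit (default 0.1).
#' @param contaminant_hit_rate Probability a contaminant has a
#'   (non-matching) taxonomy hit (default 0.5).
#' @param rescue_rate Probability a hitless host contig carries rescue
#'   genes (default 1: at typical insect gene densities of roughly one
#'   gene per 10 kb, a genuine host contig of the simulated lengths
#'   essentially always contains at least one gene assignable to a
#'   host-clade orthogroup, which is what the rescue rule models).
#' @param seed RNG seed.
#' @return List: `assembly` ([seq_set]), `truth` (per-contig class, GC,
#'   planted gaps, masked fraction, evidence flags), `taxonomy_hits`
#'   (data frame `contig_id`, `description`), `rescue` (data frame
#'   `contig_id`, `gene_id`, `orthogroup_id`).
#' @export
simulate_assembly <- function(n_host_contigs = 50L,
                              n_contaminant_contigs = 10L,
                              host_gc = 0.31, contaminant_gc = 0.46,
                              length_meanlog = log(2e4), length_sdlog = 0.4,
                              repeat_fraction = 0.18,
                              gap_rate = 2, gap_run_mean = 100,
                              taxonomy_miss_rate = 0.1,
                              contaminant_hit_rate = 0.5,
                              rescue_rate = 1,
                              seed = 1L) {
  for (f in c(host_gc, contaminant_gc, repeat_fraction,
              taxonomy_miss_rate, contaminant_hit_rate, rescue_rate))
    if (!is_scalar_number(f) || f < 0 || f > 1)
      stop("fractions and rates must be in [0, 1]")
  if (n_host_contigs < 1L) stop("need at least one host contig")

  n_total <- n_host_contigs + n_contaminant_contigs
  class_ <- c(rep("host", n_host_contigs),
              rep("contaminant", n_contaminant_contigs))
  ids <- c(sprintf("host_%03d", seq_len(n_host_contigs)),
           if (n_contaminant_contigs > 0L)
             sprintf("contam_%03d", seq_len(n_contaminant_contigs)))
  gc_target <- ifelse(class_ == "host", host_gc, contaminant_gc)

  lens <- local_seed(derive_seed(seed, "lengths"),
    pmax(1000L, as.integer(round(stats::rlnorm(n_total, length_meanlog,
                                               length_sdlog)))))

  seqs <- character(n_total)
  masked_frac <- numeric(n_total)
  gaps_planted <- integer(n_total)
  local_seed(derive_seed(seed, "sequences"), {
    for (i in seq_len(n_total)) {
      gc <- gc_target[i]
      chars <- sample(c("A", "C", "G", "T"), lens[i], replace = TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
      # N-gap runs (replacement keeps the contig length fixed)
      n_gaps <- stats::rpois(1L, gap_rate)
      for (g in seq_len(n_gaps)) {
        run <- min(1L + stats::rgeom(1L, 1 / gap_run_mean), lens[i])
        start <- sample.int(max(1L, lens[i] - run), 1L)
        chars[start:min(lens[i], start + run - 1L)] <- "N"
      }
      gaps_planted[i] <- n_gaps
      # soft-mask random tracts up to the target fraction
      mask <- logical(lens[i])
      target <- repeat_fraction * lens[i]
      guard <- 0L
      while (sum(mask) < target && guard < 10000L) {
        guard <- guard + 1L
        tract <- 1L + stats::rgeom(1L, 1 / 500)
        start <- sample.int(max(1L, lens[i] - tract), 1L)
        mask[start:min(lens[i], start + tract - 1L)] <- TRUE
      }
      chars[mask] <- tolower(chars[mask])
      masked_frac[i] <- mean(mask)
      seqs[i] <- paste(chars, collapse = "")
    }
  })
  names(seqs) <- ids
  assembly <- seq_set(seqs)

  host_desc <- c("Vespula vulgaris hypothetical protein",
                 "Polistes dominula uncharacterized locus",
                 "paper wasp venom allergen precursor")
  contam_desc <- c("Serratia marcescens chromosome, complete genome",
                   "Acinetobacter baumannii plasmid sequence",
                   "Saccharomyces cerevisiae chromosome IV")
  has_hit <- logical(n_total)
  desc <- character(n_total)
  local_seed(derive_seed(seed, "taxonomy"), {
    for (i in seq_len(n_total)) {
      if (class_[i] == "host") {
        has_hit[i] <- stats::runif(1) >= taxonomy_miss_rate
        if (has_hit[i]) desc[i] <- sample(host_desc, 1L)
      } else {
        has_hit[i] <- stats::runif(1) < contaminant_hit_rate
        if (has_hit[i]) desc[i] <- sample(contam_desc, 1L)
      }
    }
  })
  taxonomy_hits <- data.frame(contig_id = ids[has_hit],
                              description = desc[has_hit],
                              stringsAsFactors = FALSE)

  rescued <- integer(n_total)
  local_seed(derive_seed(seed, "rescue"), {
    idx <- which(class_ == "host" & !has_hit)
    for (i in idx)
      if (stats::runif(1) < rescue_rate) rescued[i] <- sample(1:3, 1L)
  })
  rescue <- if (sum(rescued) > 0L) {
    reps <- rep(seq_len(n_total), rescued)
    data.frame(contig_id = ids[reps],
               gene_id = sprintf("%s_g%d", ids[reps],
                                 sequence(rescued[rescued > 0L])),
               orthogroup_id = sprintf("OG%07d", seq_along(reps)),
               stringsAsFactors = FALSE)
  } else data.frame(contig_id = character(0), gene_id = character(0),
                    orthogroup_id = character(0))

  truth <- data.frame(contig_id = ids, class = class_,
                      length = lens, gc_target = gc_target,
                      gc_realized = vapply(seqs, gc_fraction, numeric(1),
                                           USE.NAMES = FALSE),
                      masked_fraction = masked_frac,
                      gaps_planted = gaps_planted,
                      has_hit = has_hit, rescued_genes = rescued,
                      stringsAsFactors = FALSE)
  list(assembly = assembly, truth = truth,
       taxonomy_hits = taxonomy_hits, rescue = rescue)
}

#' Simulate gene sequences with a mixture-structured CpG o/e distribution
#'
#' Each gene is assigned a mixture component by weight and a per-gene
#' CpG depletion/enrichment level drawn from that component's Gaussian
#' (truncated to \[0, 2\]). Sequences start as i.i.d. uniform A/C/G/T;
#' for a level d < 1 each CG occurrence is retained with probability d
#' (the G of a removed CG is substituted by a uniform non-G base), and
#' for d > 1 additional CG dinucleotides are created at random
#' C-followed-by-non-G sites until the CG count reaches d times the
#' initial count. Substitution can re-create a CG at a tract boundary;
#' the residual CG count at level 0 stays below 5% of the i.i.d.
#' expectation. The defaults emulate a trimodal per-gene CpG o/e
#' distribution with a methylation-depleted low mode.
#'
#' @param n_genes Number of genes (default 3000).
#' @param weights,means,sds Component weights (simplex), target o/e
#'   means (> 0) and SDs (defaults: equal thirds at 0.4/0.9/1.4, sd 0.08).
#' @param length_meanlog,length_sdlog Log-normal gene-length law
#'   (default meanlog log(1500), sdlog 0.3).
#' @param seed RNG seed.
#' @return List: `genes` ([seq_set]) and `truth` (data frame `gene_id`,
#'   `component`, `level` = realized depletion/enrichment level).
#' @export
simulate_cpg_genes <- function(n_genes = 3000L,
                               weights = c(1, 1, 1) / 3,
                               means = c(0.4, 0.9, 1.4),
                               sds = c(0.08, 0.08, 0.08),
                               length_meanlog = log(1500), length_sdlog = 0.3,
                               seed = 1L) {
  if (length(weights) != length(means) || length(means) != length(sds))
    stop("weights, means and sds must have equal length")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (any(means <= 0)) stop("component means must be > 0")
  k <- length(weights)
  genes <- character(n_genes)
  comp <- integer(n_genes)
  level <- numeric(n_genes)
  local_seed(derive_seed(seed, "cpg_genes"), {
    lens <- pmax(200L, as.integer(round(stats::rlnorm(n_genes, length_meanlog,
                                                      length_sdlog))))
    comp <- sample.int(k, n_genes, replace = TRUE, prob = weights)
    for (i in seq_len(n_genes)) {
      d <- stats::rnorm(1L, means[comp[i]], sds[comp[i]])
      guard <- 0L
      while ((d < 0 || d > 2) && guard < 100L) {
        d <- stats::rnorm(1L, means[comp[i]], sds[comp[i]])
        guard <- guard + 1L
      }
      d <- min(max(d, 0), 2)
      level[i] <- d
      chars <- sample(c("A", "C", "G", "T"), lens[i], replace = TRUE)
      is_cg <- which(chars[-lens[i]] == "C" & chars[-1L] == "G")
      n0 <- length(is_cg)
      if (d < 1 && n0 > 0L) {
        drop <- is_cg[stats::runif(n0) >= d]
        # substitute the G with a uniform non-G base, excluding C when
        # the following base is G so that no new CG is created
        for (pos in drop) {
          nxt <- if (pos + 2L <= lens[i]) chars[pos + 2L] else ""
          choices <- if (identical(nxt, "G")) c("A", "T") else c("A", "C", "T")
          chars[pos + 1L] <- sample(choices, 1L)
        }
      } else if (d > 1 && n0 > 0L) {
        need <- round((d - 1) * n0)
        nxt2 <- c(chars[-(1:2)], "")
        cand <- which(chars[-lens[i]] == "C" & chars[-1L] != "G" &
                        !(chars[-1L] == "C" & nxt2 == "G"))
        if (need > 0L && length(cand) > 0L) {
          pick <- sort(if (length(cand) <= need) cand else sample(cand, need))
          pick <- pick[c(TRUE, diff(pick) > 1L)]   # avoid overlapping edits
          chars[pick + 1L] <- "G"
        }
      }
      genes[i] <- paste(chars, collapse = "")
    }
  })
  names(genes) <- sprintf("gene_%05d", seq_len(n_genes))
  list(genes = seq_set(genes),
       truth = data.frame(gene_id = names(genes), component = comp,
                          level = level, stringsAsFactors = FALSE))
}

#' Simulate an orthogroup count table with known strata
#'
#' Builds a species-by-orthogroup count table from three strata: core
#' orthogroups present in every species, accessory orthogroups present in
#' each species independently with probability `accessory_presence_prob`
#' (redrawn if absent everywhere, since an all-absent orthogroup cannot
#' appear in a real table), and species-specific orthogroups present in
#' exactly one species. Gene counts per presence are 1 + Poisson(lambda).
#'
#' @param n_species Number of species (default 10).
#' @param n_core,n_accessory Stratum sizes (defaults 3000 and 4000).
#' @param accessory_presence_prob Per-species presence probability for
#'   accessory orthogroups (default 0.5).
#' @param n_specific Species-specific orthogroups per species; scalar or
#'   per-species vector (default 50).
#' @param count_lambda Poisson rate of extra gene copies (default 0.2).
#' @param unassigned_gene_rate Fraction of each species' genes left
#'   unassigned to any orthogroup (default 0.15).
#' @param seed RNG seed.
#' @return List: `table` ([orthogroup_table]) and `truth` (data frame
#'   `orthogroup_id`, `stratum`, `specific_species`).
#' @export
simulate_orthogroup_table <- function(n_species = 10L,
                                      n_core = 3000L, n_accessory = 4000L,
                                      accessory_presence_prob = 0.5,
                                      n_specific = 50L,
                                      count_lambda = 0.2,
                                      unassigned_gene_rate = 0.15,
                                      seed = 1L) {
  if (n_species < 2L) stop("need at least 2 species")
  if (accessory_presence_prob < 0 || accessory_presence_prob > 1)
    stop("accessory_presence_prob must be in [0, 1]")
  n_specific <- rep_len(n_specific, n_species)
  species <- sprintf("sp%02d", seq_len(n_species))
  n_og <- n_core + n_accessory + sum(n_specific)
  local_seed(derive_seed(seed, "orthogroups"), {
    presence <- matrix(FALSE, n_og, n_species)
    stratum <- c(rep("core", n_core), rep("accessory", n_accessory),
                 rep("specific", sum(n_specific)))
    specific_species <- rep(NA_character_, n_og)
    presence[seq_len(n_core), ] <- TRUE
    for (i in seq_len(n_accessory)) {
      row <- n_core + i
      repeat {
        p <- stats::runif(n_species) < accessory_presence_prob
        if (any(p)) break
      }
      presence[row, ] <- p
    }
    row <- n_core + n_accessory
    for (s in seq_len(n_species)) {
      for (j in seq_len(n_specific[s])) {
        row <- row + 1L
        presence[row, s] <- TRUE
        specific_species[row] <- species[s]
      }
    }
    counts <- matrix(0L, n_og, n_species,
                     dimnames = list(sprintf("OG%07d", seq_len(n_og)), species))
    counts[presence] <- 1L + stats::rpois(sum(presence), count_lambda)
    assigned <- colSums(counts)
    unassigned <- round(assigned * unassigned_gene_rate /
                          (1 - unassigned_gene_rate))
    names(unassigned) <- species
    truth <- data.frame(orthogroup_id = rownames(counts), stratum = stratum,
                        specific_species = specific_species,
                        stringsAsFactors = FALSE)
    list(table = orthogroup_table(counts, unassigned = unassigned),
         truth = truth)
  })
}

#' Simulate a random ultrametric tree
#'
#' Draws a random coalescent topology ([ape::rcoal()]) and rescales it so
#' every root-to-tip distance equals `root_height` exactly.
#'
#' @param n_taxa Number of tips, >= 2.
#' @param root_height Root-to-tip distance (default 1).
#' @param seed RNG seed.
#' @return An [ape::phylo] ultrametric tree with tips `t1..tn`.
#' @export
simulate_ultrametric_tree <- function(n_taxa, root_height = 1, seed = 1L) {
  if (!is_scalar_number(n_taxa) || n_taxa < 2L) stop("n_taxa must be >= 2")
  if (!is_scalar_number(root_height) || root_height <= 0)
    stop("root_height must be > 0")
  tree <- local_seed(derive_seed(seed, "tree"), ape::rcoal(as.integer(n_taxa)))
  depths <- ape::node.depth.edgelength(tree)[seq_len(as.integer(n_taxa))]
  tree$edge.length <- tree$edge.length * (root_height / max(depths))
  # snap residual floating-point noise so tip depths are exactly equal
  depths <- ape::node.depth.edgelength(tree)
  tip_edges <- tree$edge[, 2L] <= length(tree$tip.label)
  adj <- root_height - depths[tree$edge[tip_edges, 2L]]
  tree$edge.length[tip_edges] <- tree$edge.length[tip_edges] + adj
  tree
}
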