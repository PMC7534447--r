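#' Per-species orthogroup representation summary
#'
#' Reproduces the per-species "gene content and orthogroup
#' representation" summary: how many orthogroups each species is present
#' in, what fraction of all orthogroups that is, how many orthogroups are
#' species-specific (all member genes from that one species) and what
#' fraction of the species' genes sit in them. Gene totals (assigned +
#' unassigned) are reported only when the table carries unassigned
#' counts; percentages needing them are `NA` otherwise.
#'
#' @param table An [orthogroup_table].
#' @return A `species_summary` data frame, one row per species.
#' @export
species_summary <- function(table) {
  stopifnot(inherits(table, "orthogroup_table"))
  counts <- table$counts
  presence <- counts > 0
  n_og <- nrow(counts)
  specific <- rowSums(presence) == 1L
  out <- data.frame(species = table$species, stringsAsFactors = FALSE)
  out$genes_in_orthogroups <- colSums(counts)
  out$gene_total <- if (!is.null(table$unassigned))
    out$genes_in_orthogroups + as.numeric(table$unassigned)
  else NA_real_
  out$orthogroups_represented <- colSums(presence)
  out$orthogroups_represented_pct <- 100 * out$orthogroups_represented / n_og
  out$species_specific_orthogroups <- vapply(seq_along(table$species),
    function(j) sum(specific & presence[, j]), numeric(1))
  genes_in_specific <- vapply(seq_along(table$species),
    function(j) sum(counts[specific & presence[, j], j]), numeric(1))
  out$genes_in_specific <- genes_in_specific
  out$genes_in_specific_pct <- 100 * genes_in_specific / out$gene_total
  class(out) <- c("species_summary", class(out))
  out
}

#' Orthogroups shared by a set of species
#'
#' Counts orthogroups with a positive gene count in EVERY species of the
#' subset; presence in other species is unrestricted.
#'
#' @param table An [orthogroup_table].
#' @param species_subset Character vector of >= 2 species names.
#' @return Integer count.
#' @export
shared_orthogroups <- function(table, species_subset) {
  stopifnot(inherits(table, "orthogroup_table"))
  species_subset <- unique(species_subset)
  if (length(species_subset) < 2L) stop("need at least 2 species")
  unknown <- setdiff(species_subset, table$species)
  if (length(unknown)) stop("unknown species: ", paste(unknown, collapse = ", "))
  sub <- table$counts[, species_subset, drop = FALSE] > 0
  sum(rowSums(sub) == length(species_subset))
}

#' Three-way Venn region counts of orthogroup presence
#'
#' Counts orthogroups in each of the 7 presence/absence regions of three
#' species; presence in any other species is ignored. The regions
#' partition the orthogroups present in at least one of the three.
#'
#' @param table An [orthogroup_table].
#' @param species Character vector of 3 distinct species names.
#' @return Named integer vector of 7 region counts
#'   (`"A"`, `"B"`, `"C"`, `"A&B"`, `"A&C"`, `"B&C"`, `"A&B&C"` with the
#'   actual species names substituted).
#' @export
venn3_counts <- function(table, species) {
  stopifnot(inherits(table, "orthogroup_table"))
  if (length(species) != 3L || anyDuplicated(species))
    stop("need exactly 3 distinct species")
  unknown <- setdiff(species, table$species)
  if (length(unknown)) stop("unknown species: ", paste(unknown, collapse = ", "))
  p <- table$counts[, species, drop = FALSE] > 0
  pattern <- p[, 1L] + 2L * p[, 2L] + 4L * p[, 3L]
  region_names <- c(species[1L], species[2L],
                    paste(species[1L], species[2L], sep = "&"),
                    species[3L],
                    paste(species[1L], species[3L], sep = "&"),
                    paste(species[2L], species[3L], sep = "&"),
                    paste(species, collapse = "&"))
  counts <- vapply(1:7, function(code) sum(pattern == code), integer(1))
  stats::setNames(counts, region_names)
}

#' Pan/core-genome rarefaction curve
#'
#' For each subset size k of species, computes per-subset core (orthogroups
#' present in all k species) and pan (present in at least one) counts.
#' When the number of k-subsets is at most `cap`, all subsets are
#' enumerated (`exhaustive`); otherwise `cap` DISTINCT subsets are drawn
#' uniformly without replacement using a seeded generator (rejection
#' sampling with a seen-set), so the same seed reproduces the identical
#' subset list.
#'
#' @param table An [orthogroup_table] with >= 2 species.
#' @param cap Maximum subsets evaluated per k (default 1000).
#' @param seed RNG seed for subset sampling (default 1).
#' @return A `pan_core_curve` data frame with columns `k`,
#'   `subset_index`, `members` (comma-joined species), `core`, `pan`,
#'   `exhaustive`.
#' @export
pan_core_curve <- function(table, cap = 1000L, seed = 1L) {
  stopifnot(inherits(table, "orthogroup_table"))
  n <- length(table$species)
  if (n < 2L) stop("need at least 2 species")
  if (!is_scalar_number(cap) || cap < 1) stop("cap must be >= 1")
  presence <- table$counts > 0
  rows <- list()
  local_seed(derive_seed(seed, "pancore"), {
    for (k in seq_len(n)) {
      n_subsets <- choose(n, k)
      if (n_subsets <= cap) {
        subsets <- utils::combn(n, k, simplify = FALSE)
        exhaustive <- TRUE
      } else {
        seen <- new.env(hash = TRUE)
        subsets <- vector("list", cap)
        got <- 0L
        while (got < cap) {
          s <- sort(sample.int(n, k))
          key <- paste(s, collapse = ",")
          if (!is.null(seen[[key]])) next
          seen[[key]] <- TRUE
          got <- got + 1L
          subsets[[got]] <- s
        }
        exhaustive <- FALSE
      }
      core <- integer(length(subsets)); pan <- integer(length(subsets))
      for (i in seq_along(subsets)) {
        rs <- rowSums(presence[, subsets[[i]], drop = FALSE])
        core[i] <- sum(rs == k)
        pan[i] <- sum(rs > 0L)
      }
      rows[[k]] <- data.frame(
        k = k,
        subset_index = seq_along(subsets),
        members = vapply(subsets, function(s)
          paste(table$species[s], collapse = ","), character(1)),
        core = core, pan = pan, exhaustive = exhaustive,
        stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  attr(out, "cap") <- cap
  attr(out, "n_species") <- n
  class(out) <- c("pan_core_curve", class(out))
  out
}

#' @export
print.pan_core_curve <- function(x, ...) {
  agg <- pan_core_means(x)
  cat("pan/core rarefaction over", attr(x, "n_species"), "species",
      sprintf("(cap %d, seed %d)\n", attr(x, "cap"), attr(x, "seed")))
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Per-k mean core and pan sizes of a rarefaction curve
#'
#' @param curve A `pan_core_curve`.
#' @return Data frame with `k`, `n_evaluated`, `mean_core`, `mean_pan`,
#'   `exhaustive`.
#' @export
pan_core_means <- function(curve) {
  ks <- sort(unique(curve$k))
  data.frame(k = ks,
             n_evaluated = vapply(ks, function(k) sum(curve$k == k), integer(1)),
             mean_core = vapply(ks, function(k) mean(curve$core[curve$k == k]),
                                numeric(1)),
             mean_pan = vapply(ks, function(k) mean(curve$pan[curve$k == k]),
                               numeric(1)),
             exhaustive = vapply(ks, function(k)
               all(curve$exhaustive[curve$k == k]), logical(1)))
}

#' Closed-pan-genome diagnostic
#'
#' Reports the growth of the mean pan-genome size over the last step of a
#' rarefaction curve. A growth below `threshold` orthogroups per added
#' genome is flagged as consistent with a closed pan genome; this is a
#' numerical diagnostic, not a biological claim.
#'
#' @param curve A `pan_core_curve`.
#' @param threshold Growth threshold in orthogroups (default 10).
#' @return List with `final_pan`, `last_step_growth`, `closed`.
#' @export
pan_closure <- function(curve, threshold = 10) {
  agg <- pan_core_means(curve)
  n <- nrow(agg)
  if (n < 2L) stop("curve needs at least 2 subset sizes")
  growth <- agg$mean_pan[n] - agg$mean_pan[n - 1L]
  list(final_pan = agg$mean_pan[n], last_step_growth = growth,
       closed = growth < threshold)
}
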