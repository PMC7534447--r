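#' Check whether a tree is ultrametric
#'
#' Compares all root-to-tip path lengths; the tree is ultrametric iff the
#' maximum deviation from their mean, relative to the mean, is at most
#' `rel_tol`. A relative tolerance (default 1e-6) is used because
#' published ultrametric trees carry rounding noise in their branch
#' lengths.
#'
#' @param tree A rooted [ape::phylo] tree with branch lengths.
#' @param rel_tol Relative tolerance (default 1e-6).
#' @return List: `is_ultrametric` (flag), `max_relative_deviation`.
#' @export
check_ultrametric <- function(tree, rel_tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("branch lengths required")
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  m <- mean(depths)
  if (m == 0) stop("zero mean root-to-tip distance")
  dev <- max(abs(depths - m)) / m
  list(is_ultrametric = dev <= rel_tol, max_relative_deviation = dev)
}

#' Rescale an ultrametric tree to a target root age
#'
#' Multiplies every branch length by `root_age / current root height`, so
#' all root-to-tip distances equal `root_age`. Topology and all branch
#' length ratios are preserved exactly. Used to convert a relative
#' ultrametric phylogeny into absolute time given one fossil or
#' literature calibration at the root (e.g. a 51 Mya split at the root of
#' a clade pair).
#'
#' @param tree A rooted ultrametric [ape::phylo] tree.
#' @param root_age Target root age, > 0 (time units of your calibration).
#' @param clades Optional named list of tip-label vectors; the age of
#'   each clade's MRCA is reported.
#' @param rel_tol Ultrametricity tolerance (see [check_ultrametric()]).
#' @return List with `tree` (rescaled) and `report` (an `age_report`:
#'   `root_age`, `scale_factor`, `clade_ages`).
#' @export
scale_to_root_age <- function(tree, root_age, clades = NULL, rel_tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (!is_scalar_number(root_age) || root_age <= 0)
    stop("root_age must be > 0")
  chk <- check_ultrametric(tree, rel_tol)
  if (!chk$is_ultrametric)
    stop("tree is not ultrametric (max relative deviation ",
         signif(chk$max_relative_deviation, 3),
         "); see check_ultrametric()")
  height <- mean(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
  factor <- root_age / height
  scaled <- tree
  scaled$edge.length <- tree$edge.length * factor
  clade_ages <- if (!is.null(clades))
    vapply(clades, function(tips) mrca_age(scaled, tips), numeric(1))
  else NULL
  report <- structure(list(root_age = root_age, scale_factor = factor,
                           clade_ages = clade_ages),
                      class = "age_report")
  list(tree = scaled, report = report)
}

#' @export
print.age_report <- function(x, ...) {
  cat(sprintf("root age %.4g (branch scale factor %.6g)\n",
              x$root_age, x$scale_factor))
  if (!is.null(x$clade_ages))
    for (nm in names(x$clade_ages))
      cat(sprintf("  MRCA age of %s: %.4g\n", nm, x$clade_ages[[nm]]))
  invisible(x)
}

#' Age of the most recent common ancestor of a tip set
#'
#' On an ultrametric tree, the MRCA age is the root height minus the
#' MRCA's depth (equivalently, half the path length between any two tips
#' whose MRCA it is).
#'
#' @param tree A rooted ultrametric [ape::phylo] tree.
#' @param tips Character vector of >= 2 tip labels.
#' @return The MRCA age, in the tree's branch-length units.
#' @export
mrca_age <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo"))
  tips <- unique(tips)
  if (length(tips) < 2L) stop("need at least 2 tips")
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown)) stop("unknown tips: ", paste(unknown, collapse = ", "))
  depths <- ape::node.depth.edgelength(tree)
  height <- mean(depths[seq_along(tree$tip.label)])
  node <- ape::getMRCA(tree, tips)
  height - depths[node]
}
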