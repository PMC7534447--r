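#' Read and write Newick trees
#'
#' Thin validating wrappers around [ape::read.tree()] and
#' [ape::write.tree()]. The tree must be a single rooted tree with branch
#' lengths; topology, tip labels and branch lengths round-trip losslessly.
#'
#' @param path Path to a Newick file (read) or output path (write).
#' @return `read_newick` returns an [ape::phylo] tree; `write_newick`
#'   returns `path` invisibly.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in ", path,
                                            ": ", conditionMessage(e)),
                   warning = function(w) stop("Newick parse error in ", path,
                                              ": ", conditionMessage(w)))
  if (is.null(tree)) stop("Newick parse error in ", path)
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L) stop("expected a single tree in ", path)
    tree <- tree[[1L]]
  }
  if (is.null(tree$edge.length)) stop("branch lengths required")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  tree
}

#' @param tree A rooted [ape::phylo] tree with branch lengths.
#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("branch lengths required")
  ape::write.tree(tree, file = path)
  invisible(path)
}
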