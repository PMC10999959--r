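#' Parse a Newick string into a validated tree
#'
#' Thin wrapper around [ape::read.tree()] that enforces the input contract
#' shared by all downstream operations: a single well-formed Newick statement,
#' unique tip labels, and a branch length on every non-root edge. Internal
#' node labels (commonly branch supports) are retained and can be summarised
#' later by [annotate_space()].
#'
#' @param text A single Newick string terminated by `";"`.
#' @return An object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";", text, fixed = TRUE)) {
    stop("Newick string is not terminated by ';': ", abbreviate_str(text))
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("malformed Newick string: ", abbreviate_str(text))
  }
  validate_tree(tree)
}

#' Serialise a tree to Newick
#'
#' Round-trips through [parse_newick()] preserving topology, labels and
#' branch lengths to 10 significant digits.
#'
#' @param tree A `phylo` object.
#' @return A Newick string.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = 10)
}

#' Read a species time-tree from a Newick file
#'
#' @param path Path to a Newick file containing one tree.
#' @param ultrametric If `TRUE`, require the tree to be ultrametric within
#'   `tol` relative to root height (the contract for a rooted time-tree).
#' @param tol Relative ultrametricity tolerance.
#' @return A `phylo` object.
#' @export
read_species_tree <- function(path, ultrametric = FALSE, tol = 1e-6) {
  tree <- validate_tree(ape::read.tree(path))
  if (ultrametric && !is_ultrametric_tree(tree, tol = tol)) {
    stop("species tree in ", path, " is not ultrametric within tolerance ", tol)
  }
  tree
}

#' Read gene trees from one or more Newick files
#'
#' Each file may hold one tree or one tree per line. Locus ids default to the
#' file name (plus an index for multi-tree files).
#'
#' @param paths Character vector of file paths (e.g. from `Sys.glob()`).
#' @return A named `multiPhylo` list of validated trees.
#' @export
read_gene_trees <- function(paths) {
  stopifnot(length(paths) >= 1L)
  out <- list()
  for (p in paths) {
    trees <- ape::read.tree(p)
    if (inherits(trees, "phylo")) trees <- c(trees)
    base <- sub("\\.[^.]*$", "", basename(p))
    ids <- if (length(trees) == 1L) base else paste0(base, "_", seq_along(trees))
    names(trees) <- ids
    out <- c(out, lapply(trees, validate_tree))
  }
  class(out) <- "multiPhylo"
  out
}

# Shared validity checks: unique tips, finite non-negative lengths everywhere.
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree")
  if (anyDuplicated(tree$tip.label)) {
    dup <- tree$tip.label[duplicated(tree$tip.label)][1L]
    stop("duplicate tip label: ", dup)
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (length(tree$edge.length) != nrow(tree$edge)) {
    stop("tree has a missing branch length")
  }
  bad <- !is.finite(tree$edge.length) | tree$edge.length < 0
  if (any(bad)) stop("non-finite or negative branch length on edge ", which(bad)[1L])
  tree
}

#' Test ultrametricity relative to root height
#'
#' A rooted time-tree must have all tips equidistant from the root; the
#' tolerance is relative to the root height so it is scale-free.
#'
#' @param tree A rooted `phylo`.
#' @param tol Relative tolerance.
#' @return Logical scalar.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  h <- max(depths)
  if (h == 0) return(TRUE)
  (max(depths) - min(depths)) <= tol * h
}

is_rooted_binary_root <- function(tree) {
  ape::is.rooted(tree)
}

abbreviate_str <- function(x, n = 60L) {
  if (nchar(x) > n) paste0(substr(x, 1L, n), "...") else x
}
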