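# Bipartition (split) machinery. A split is the pair of taxon sets separated
# by removing one edge; equality must be order-independent and robust to
# restriction to a taxon subset, so splits are canonicalised as binary
# membership keys over a sorted taxon universe with the convention that the
# lexicographically smallest taxon is always on the "0" side.

# Logical matrix (edges x tips, tree tip order): child-side tip membership.
edge_clades <- function(tree) {
  nt <- ape::Ntip(tree)
  nn <- max(tree$edge)
  sets <- matrix(FALSE, nn, nt)
  sets[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  for (i in ape::postorder(tree)) {
    p <- tree$edge[i, 1L]
    ch <- tree$edge[i, 2L]
    sets[p, ] <- sets[p, ] | sets[ch, ]
  }
  sets[tree$edge[, 2L], , drop = FALSE]
}

# Canonical split keys over `taxa` (sorted labels, all present in the tree).
# Returns key strings plus the size of the side not containing taxa[1].
split_keys <- function(clades, tip_labels, taxa) {
  idx <- match(taxa, tip_labels)
  if (anyNA(idx)) stop("taxa not found in tree: ", paste(taxa[is.na(idx)], collapse = ", "))
  m <- clades[, idx, drop = FALSE]
  flip <- m[, 1L]
  if (any(flip)) m[flip, ] <- !m[flip, , drop = FALSE]
  keys <- apply(m, 1L, function(r) rawToChar(as.raw(48L + r)))
  list(key = keys, side = m, n_side = rowSums(m), n_taxa = length(taxa))
}

split_status <- function(n_side, n_taxa) {
  ifelse(n_side == 0L | n_side == n_taxa, "degenerate",
    ifelse(n_side == 1L | n_side == n_taxa - 1L, "trivial", "internal")
  )
}

#' Enumerate the bipartitions of a tree
#'
#' One split per edge (the two root-incident edges of a rooted binary tree
#' induce the same unrooted split and are collapsed), optionally restricted
#' to a taxon subset. Pendant splits are kept but flagged trivial; splits
#' whose restriction leaves one side empty are dropped.
#'
#' @param tree A `phylo` object.
#' @param restrict_to Optional character vector of tip labels to restrict to
#'   (must be a subset of the tree's tips).
#' @return A tibble with one row per distinct split: `key` (canonical binary
#'   membership string over the sorted restricted taxon set), `side_a` /
#'   `side_b` (list columns of labels; `side_a` is the side without the
#'   lexicographically smallest taxon), `trivial`, and `n_edges` (number of
#'   tree edges inducing the split).
#' @examples
#' bipartition_set(parse_newick("((A:1,B:1):1,(C:1,D:1):1);"))
#' @export
bipartition_set <- function(tree, restrict_to = NULL) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- sort(tree$tip.label)
  if (!is.null(restrict_to)) {
    if (!all(restrict_to %in% tree$tip.label)) {
      stop("restrict_to contains labels absent from the tree")
    }
    taxa <- sort(unique(restrict_to))
  }
  ks <- split_keys(edge_clades(tree), tree$tip.label, taxa)
  status <- split_status(ks$n_side, ks$n_taxa)
  keep <- status != "degenerate"
  keys <- ks$key[keep]
  side <- ks$side[keep, , drop = FALSE]
  status <- status[keep]
  first <- !duplicated(keys)
  n_edges <- as.integer(table(keys)[keys[first]])
  tibble::tibble(
    key = keys[first],
    side_a = lapply(which(first), function(i) taxa[side[i, ]]),
    side_b = lapply(which(first), function(i) taxa[!side[i, ]]),
    trivial = status[first] == "trivial",
    n_edges = n_edges
  )
}

# Species-tree branch table: one row per usable branch. The two edges
# incident to a binary root induce the same unrooted split (an unrooted gene
# tree cannot separate them) and are merged into a single branch whose
# duration is the sum of the two edge lengths.
species_branches <- function(species_tree) {
  tree <- validate_tree(species_tree)
  taxa <- sort(tree$tip.label)
  clades <- edge_clades(tree)
  ks <- split_keys(clades, tree$tip.label, taxa)
  groups <- split(seq_along(ks$key), ks$key)
  first_edge <- vapply(groups, `[`, integer(1L), 1L)
  ord <- order(first_edge)
  groups <- groups[ord]
  n <- length(groups)
  branch_id <- sprintf("b%0*d", nchar(n), seq_len(n))
  duration <- vapply(groups, function(e) sum(tree$edge.length[e]), numeric(1L))
  n_side <- ks$n_side[first_edge[ord]]
  label <- vapply(seq_len(n), function(i) {
    s <- ks$side[first_edge[ord][i], ]
    a <- taxa[s]
    b <- taxa[!s]
    side <- if (length(a) < length(b)) a else if (length(b) < length(a)) b else a
    paste(side, collapse = "|")
  }, character(1L))
  list(
    tree = tree,
    taxa = taxa,
    clades = clades,
    table = tibble::tibble(
      branch_id = branch_id,
      key = names(groups),
      split = label,
      duration = duration,
      pendant = pmin(n_side, length(taxa) - n_side) == 1L,
      edges = unname(groups)
    )
  )
}

# Restrict species branches to a shared taxon set; returns keys per branch
# (NA when the restriction is degenerate) and the nontrivial side matrix for
# compatibility checks.
restrict_species_branches <- function(sp, shared) {
  first_edge <- vapply(sp$table$edges, `[`, integer(1L), 1L)
  ks <- split_keys(sp$clades[first_edge, , drop = FALSE], sp$tree$tip.label, shared)
  status <- split_status(ks$n_side, ks$n_taxa)
  key <- ifelse(status == "degenerate", NA_character_, ks$key)
  nontrivial <- which(status == "internal")
  list(
    key = key,
    status = status,
    side = ks$side,
    nontrivial_side = ks$side[nontrivial, , drop = FALSE],
    key_to_branch = split(seq_along(key)[!is.na(key)], key[!is.na(key)])
  )
}

# TRUE when split `g` is compatible with every row of side matrix S (all
# canonical logical vectors over the same taxon set).
compatible_with_all <- function(g, S) {
  if (nrow(S) == 0L) return(TRUE)
  n <- length(g)
  a <- as.vector(S %*% g)
  sz <- rowSums(S)
  ng <- sum(g)
  ok <- (a == 0L) | (ng - a == 0L) | (sz - a == 0L) | (n - ng - sz + a == 0L)
  all(ok)
}
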