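#' Scale-minimised branch-score distance between two trees
#'
#' Branch lengths of branches uniquely matched between the two trees (by
#' restricted-split identity over the shared taxa) form vectors `a` and `b`.
#' The distance in one direction is `sqrt(sum((a - s* b)^2)) / sqrt(sum(a^2))`
#' with the closed-form scaling `s* = sum(a*b)/sum(b^2)` that minimises the
#' residual; the reported value is the minimum over both directions. The
#' distance is zero whenever one vector is a positive scalar multiple of the
#' other, making it insensitive to overall rate differences between trees —
#' it measures disagreement in the *pattern* of among-branch rates.
#'
#' @param tree_a,tree_b `phylo` objects sharing at least 4 taxa.
#' @return Non-negative scalar.
#' @examples
#' a <- parse_newick("((A:1,B:2):3,(C:1,D:1):1);")
#' sbsd_min(a, a)
#' @export
sbsd_min <- function(tree_a, tree_b) {
  ab <- matched_lengths(tree_a, tree_b)
  sbsd_pair(ab$a, ab$b)
}

sbsd_pair <- function(a, b) {
  if (length(a) < 3L) stop("fewer than 3 matched branches")
  sa2 <- sum(a^2)
  sb2 <- sum(b^2)
  if (sa2 == 0 && sb2 == 0) return(0)
  if (sa2 == 0 || sb2 == 0) return(1)
  d_ab <- sqrt(sum((a - (sum(a * b) / sb2) * b)^2)) / sqrt(sa2)
  d_ba <- sqrt(sum((b - (sum(a * b) / sa2) * a)^2)) / sqrt(sb2)
  min(d_ab, d_ba)
}

# Branch-length vectors of branches uniquely matched between two trees
# (restricted-split identity over the shared taxa; both trees unrooted).
matched_lengths <- function(tree_a, tree_b) {
  tree_a <- validate_tree(tree_a)
  tree_b <- validate_tree(tree_b)
  shared <- sort(intersect(tree_a$tip.label, tree_b$tip.label))
  if (length(shared) < 4L) stop("trees share fewer than 4 taxa")
  ka <- unrooted_keys(tree_a, shared)
  kb <- unrooted_keys(tree_b, shared)
  common <- intersect(names(ka), names(kb))
  list(a = unname(ka[common]), b = unname(kb[common]))
}

# Named vector of summed branch lengths per canonical restricted split,
# keeping only splits induced by exactly one edge (unique matches).
unrooted_keys <- function(tree, shared) {
  if (ape::is.rooted(tree) && ape::Ntip(tree) > 2L) tree <- ape::unroot(tree)
  ks <- split_keys(edge_clades(tree), tree$tip.label, shared)
  status <- split_status(ks$n_side, ks$n_taxa)
  ok <- status != "degenerate"
  key <- ks$key[ok]
  len <- tree$edge.length[ok]
  tab <- table(key)
  uni <- names(tab)[tab == 1L]
  out <- len[match(uni, key)]
  names(out) <- uni
  out
}

#' Pairwise scale-minimised branch-score distances
#'
#' @param trees List or `multiPhylo` of gene trees.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
sbsd_matrix <- function(trees) {
  n <- length(trees)
  stopifnot(n >= 2L)
  ids <- names(trees)
  if (is.null(ids)) ids <- paste0("L", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sbsd_min(trees[[i]], trees[[j]])
    }
  }
  d
}

#' Classical (Torgerson) metric MDS embedding in two dimensions
#'
#' Double-centres the squared distance matrix and embeds on the top two
#' eigenvectors; negative eigenvalues are truncated at zero, so
#' non-Euclidean distance matrices degrade gracefully.
#'
#' @param distances Square symmetric non-negative matrix with zero diagonal.
#' @return An n x 2 coordinate matrix with eigenvalues in attribute
#'   `"eigenvalues"`.
#' @export
mds_embed <- function(distances) {
  d <- as.matrix(distances)
  stopifnot(nrow(d) == ncol(d))
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is asymmetric beyond 1e-8")
  if (any(d < 0)) stop("negative distances")
  if (any(abs(diag(d)) > 1e-12)) stop("non-zero diagonal")
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d^2) %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  lam <- pmax(e$values[1:2], 0)
  coords <- e$vectors[, 1:2, drop = FALSE] %*% diag(sqrt(lam), 2L)
  rownames(coords) <- rownames(d)
  colnames(coords) <- c("MDS1", "MDS2")
  attr(coords, "eigenvalues") <- e$values
  coords
}
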