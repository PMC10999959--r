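# Shared fixtures, built in code.

quartet_species <- function() {
  parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
}

# Rooted caterpillar ((((A,B),C),D),E), ultrametric with unit steps.
caterpillar5 <- function() {
  parse_newick("((((A:1,B:1):1,C:2):1,D:3):1,E:4);")
}

# Independent split enumeration: label sets of the child side of every edge,
# restricted to `taxa`, canonicalised as sorted "side|side" strings with the
# smaller side first (ties by lexicographic order). Uses only ape plumbing.
oracle_splits <- function(tree, taxa = sort(tree$tip.label), nontrivial_only = FALSE) {
  keys <- character(0)
  for (i in seq_len(nrow(tree$edge))) {
    child <- tree$edge[i, 2]
    tips <- if (child <= ape::Ntip(tree)) {
      tree$tip.label[child]
    } else {
      ape::extract.clade(tree, child)$tip.label
    }
    a <- sort(intersect(tips, taxa))
    b <- sort(setdiff(taxa, a))
    if (length(a) == 0 || length(b) == 0) next
    if (nontrivial_only && min(length(a), length(b)) < 2) next
    sides <- c(paste(a, collapse = ","), paste(b, collapse = ","))
    pick <- if (length(a) != length(b)) which.min(c(length(a), length(b))) else if (sides[1] <= sides[2]) 1L else 2L
    keys <- c(keys, paste(sides[pick], sides[-pick], sep = "|"))
  }
  sort(unique(keys))
}

# bipartition_set() rows in the oracle's string representation.
splits_as_strings <- function(bs) {
  keys <- vapply(seq_len(nrow(bs)), function(i) {
    a <- sort(bs$side_a[[i]])
    b <- sort(bs$side_b[[i]])
    sides <- c(paste(a, collapse = ","), paste(b, collapse = ","))
    pick <- if (length(a) != length(b)) which.min(c(length(a), length(b))) else if (sides[1] <= sides[2]) 1L else 2L
    paste(sides[pick], sides[-pick], sep = "|")
  }, character(1))
  sort(unique(keys))
}

# Random ultrametric-free tree with seeded topology and lengths.
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- round(tr$edge.length, 6) + 0.01
  tr
}
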