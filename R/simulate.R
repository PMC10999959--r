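# Simulation engine: birth-death species trees, multispecies-coalescent
# (MSC) gene trees, and a white-noise clock with locus clusters and branch
# accelerations. Together these generate data sets with known pacemaker
# structure for validating the collection/embedding/testing pipeline.

#' Simulate a birth-death species time-tree conditioned on tip count
#'
#' Constant-rate birth-death simulation conditioned on the number of extant
#' tips (extinct lineages pruned), with all node times rescaled afterwards so
#' the root age equals `age` exactly. The conditioned simulation is delegated
#' to [ape::rphylo()]; the rescaling matches the convention of simulators
#' that use the tip count as a stopping criterion and then scale times.
#'
#' @param n_tips Number of extant tips (>= 3).
#' @param age Root age in time units after rescaling.
#' @param birth,death Speciation and extinction rates; `birth > death >= 0`.
#' @param seed Optional integer seed.
#' @return A rooted ultrametric `phylo` with `n_tips` tips and root age `age`.
#' @examples
#' tr <- sim_species_tree(10, age = 50, seed = 1)
#' max(ape::node.depth.edgelength(tr))
#' @export
sim_species_tree <- function(n_tips = 50L, age = 50, birth = 0.5, death = 0.1,
                             seed = NULL) {
  stopifnot(n_tips >= 3L, age > 0, death >= 0)
  if (death >= birth) stop("death rate must be smaller than birth rate")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth, death = death, fossils = FALSE)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (age / depth)
  tree
}

# Age (time before present) of every node of an ultrametric rooted tree.
node_ages <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  a <- max(d[seq_len(ape::Ntip(tree))]) - d
  a[seq_len(ape::Ntip(tree))] <- 0
  pmax(a, 0)
}

#' Simulate gene trees under the multispecies coalescent
#'
#' For each locus, one haploid lineage per species enters at the tips and
#' coalesces within species-tree branches: with `j` lineages present, the
#' waiting time to the next coalescence is exponential with rate
#' `j (j - 1) / theta` (each pair coalesces at rate `2 / theta`) in
#' species-tree time units; lineages that fail to coalesce before the top of
#' a branch enter the parent branch, and all remaining lineages coalesce
#' above the root. Gene trees are returned as rooted time-trees whose node
#' times are bounded below by the corresponding species divergences; small
#' `theta` gives near-instantaneous coalescence and gene trees that match
#' the species tree, large `theta` gives incomplete lineage sorting.
#'
#' @param species_tree Rooted ultrametric `phylo`.
#' @param theta Coalescent population-size parameter (> 0).
#' @param n_loci Number of gene trees.
#' @param seed Optional integer seed.
#' @return A named `multiPhylo` of `n_loci` gene time-trees.
#' @export
sim_gene_trees <- function(species_tree, theta, n_loci, seed = NULL) {
  stopifnot(theta > 0, n_loci >= 1L)
  if (!is_ultrametric_tree(species_tree)) stop("species tree must be ultrametric")
  if (!is.null(seed)) set.seed(seed)
  tree <- species_tree
  nt <- ape::Ntip(tree)
  ages <- node_ages(tree)
  po <- ape::postorder(tree)
  root <- nt + 1L

  sim_one <- function() {
    strs <- vector("list", max(tree$edge))
    ag <- vector("list", max(tree$edge))
    for (i in seq_len(nt)) {
      strs[[i]] <- list(tree$tip.label[i])
      ag[[i]] <- list(0)
    }
    for (ei in po) {
      p <- tree$edge[ei, 1L]
      ch <- tree$edge[ei, 2L]
      cs <- coalesce_in_branch(strs[[ch]], ag[[ch]], ages[ch], ages[p], theta)
      strs[[p]] <- c(strs[[p]], cs$strs)
      ag[[p]] <- c(ag[[p]], cs$ages)
    }
    cs <- coalesce_in_branch(strs[[root]], ag[[root]], ages[root], Inf, theta)
    paste0(cs$strs[[1L]], ";")
  }

  txt <- vapply(seq_len(n_loci), function(i) sim_one(), character(1L))
  trees <- ape::read.tree(text = paste(txt, collapse = "\n"))
  if (inherits(trees, "phylo")) trees <- c(trees)
  names(trees) <- paste0("L", seq_len(n_loci))
  trees
}

# Coalesce a set of lineages within one species-tree branch [t0, t1).
coalesce_in_branch <- function(strs, ages, t0, t1, theta) {
  t <- t0
  j <- length(strs)
  while (j > 1L) {
    t_next <- t + rexp(1L, j * (j - 1L) / theta)
    if (t_next >= t1) break
    t <- t_next
    pick <- sample.int(j, 2L)
    i1 <- pick[1L]
    i2 <- pick[2L]
    merged <- sprintf("(%s:%.10g,%s:%.10g)",
                      strs[[i1]], t - ages[[i1]], strs[[i2]], t - ages[[i2]])
    strs[[i1]] <- merged
    ages[[i1]] <- t
    strs[i2] <- NULL
    ages[i2] <- NULL
    j <- j - 1L
  }
  list(strs = strs, ages = ages)
}

# For each species tip label, the chain of species edges from tip to root
# with their age intervals, used to place gene-branch midpoints.
species_edge_paths <- function(tree) {
  nt <- ape::Ntip(tree)
  ages <- node_ages(tree)
  parent_edge <- integer(max(tree$edge))
  parent_edge[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  root <- nt + 1L
  paths <- vector("list", nt)
  for (tip in seq_len(nt)) {
    node <- tip
    edges <- integer(0)
    while (node != root) {
      e <- parent_edge[node]
      edges <- c(edges, e)
      node <- tree$edge[e, 1L]
    }
    paths[[tip]] <- list(
      edges = edges,
      lower = ages[tree$edge[edges, 2L]],
      upper = ages[tree$edge[edges, 1L]]
    )
  }
  names(paths) <- tree$tip.label
  paths
}

#' Convert a gene time-tree to a phylogram under a white-noise clock
#'
#' Each gene-tree branch receives an independent rate drawn from a gamma
#' distribution with mean `mean_rate` times the multiplier of the species
#' branch containing the midpoint of the gene branch, and standard deviation
#' `rate_sd` (`rate_sd = 0` degenerates to a strict clock); the branch
#' length in substitutions/site is rate times time duration. Gene branches
#' whose midpoint lies above the species root get multiplier 1.
#'
#' @param gene_tree Gene time-tree (from [sim_gene_trees()]).
#' @param species_tree The species time-tree it was embedded in.
#' @param mean_rate Mean rate, substitutions/site/time (> 0).
#' @param rate_sd Standard deviation of the white-noise rate (>= 0).
#' @param multipliers Optional numeric vector of per-species-edge rate
#'   multipliers (length `nrow(species_tree$edge)`, default all 1).
#' @param seed Optional integer seed.
#' @return The gene tree with phylogram branch lengths; realized per-edge
#'   rates in attribute `"rates"` and the species edge containing each
#'   midpoint in attribute `"species_edge"` (`NA` above the root).
#' @export
apply_clock <- function(gene_tree, species_tree, mean_rate, rate_sd = 0,
                        multipliers = NULL, seed = NULL) {
  stopifnot(mean_rate > 0, rate_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_sp_edge <- nrow(species_tree$edge)
  if (is.null(multipliers)) multipliers <- rep(1, n_sp_edge)
  stopifnot(length(multipliers) == n_sp_edge, all(multipliers > 0))
  paths <- species_edge_paths(species_tree)
  clocked <- apply_clock_impl(gene_tree, paths, node_ages(species_tree),
                              mean_rate, rate_sd, multipliers)
  clocked
}

apply_clock_impl <- function(gene_tree, paths, sp_ages, mean_rate, rate_sd,
                             multipliers) {
  ages <- node_ages(gene_tree)
  clades <- edge_clades(gene_tree)
  rep_tip <- gene_tree$tip.label[apply(clades, 1L, which.max)]
  mid <- (ages[gene_tree$edge[, 1L]] + ages[gene_tree$edge[, 2L]]) / 2
  root_age <- max(sp_ages)
  sp_edge <- rep(NA_integer_, nrow(gene_tree$edge))
  for (i in seq_along(sp_edge)) {
    if (mid[i] >= root_age) next
    path <- paths[[rep_tip[i]]]
    hit <- which(path$lower <= mid[i] & mid[i] < path$upper)
    if (length(hit) > 0L) sp_edge[i] <- path$edges[hit[1L]]
  }
  mult <- ifelse(is.na(sp_edge), 1, multipliers[sp_edge])
  mu <- mean_rate * mult
  rates <- if (rate_sd == 0) {
    mu
  } else {
    rgamma(length(mu), shape = (mu / rate_sd)^2, rate = mu / rate_sd^2)
  }
  duration <- ages[gene_tree$edge[, 1L]] - ages[gene_tree$edge[, 2L]]
  gene_tree$edge.length <- rates * duration
  attr(gene_tree, "rates") <- rates
  attr(gene_tree, "species_edge") <- sp_edge
  gene_tree
}

#' Assign loci to clock clusters with shared branch-multiplier vectors
#'
#' Loci are assigned to `k` clusters in near-equal contiguous blocks. Each
#' cluster draws one multiplier per species-tree edge from a lognormal
#' distribution with median 1 and log-scale spread `spread`; all loci in a
#' cluster share the vector exactly, creating the correlated rate structure
#' of a multiple-pacemaker model. `k = 1` yields all-ones multipliers (a
#' single universal clock).
#'
#' @param n_loci Number of loci (>= k).
#' @param k Number of clusters (>= 1).
#' @param species_tree Species tree whose edges are multiplied.
#' @param spread Log-scale standard deviation of the between-cluster
#'   multipliers.
#' @param seed Optional integer seed.
#' @return List with `labels` (integer vector, length `n_loci`) and
#'   `multipliers` (k x n_edges matrix).
#' @export
assign_clock_clusters <- function(n_loci, k, species_tree, spread = 0.5,
                                  seed = NULL) {
  stopifnot(k >= 1L, n_loci >= k)
  if (!is.null(seed)) set.seed(seed)
  sizes <- rep(n_loci %/% k, k)
  if (n_loci %% k > 0L) sizes[seq_len(n_loci %% k)] <- sizes[seq_len(n_loci %% k)] + 1L
  labels <- rep(seq_len(k), times = sizes)
  n_edge <- nrow(species_tree$edge)
  multipliers <- if (k == 1L) {
    matrix(1, 1L, n_edge)
  } else {
    matrix(rlnorm(k * n_edge, meanlog = 0, sdlog = spread), k, n_edge)
  }
  list(labels = labels, multipliers = multipliers, spread = spread)
}

#' Accelerate a random subset of species-tree branches
#'
#' Samples `round(fraction * n_edges)` species-tree edges uniformly without
#' replacement and sets their multiplier to `factor`; composed
#' multiplicatively with any cluster multipliers downstream.
#'
#' @param species_tree Species tree.
#' @param fraction Fraction of branches to accelerate, in `[0, 1)`.
#' @param factor Rate multiplier for accelerated branches (> 0).
#' @param seed Optional integer seed.
#' @return List with `flags` (logical per edge) and `multipliers` (numeric
#'   per edge: `factor` where flagged, 1 elsewhere).
#' @export
accelerate_branches <- function(species_tree, fraction, factor = 5, seed = NULL) {
  stopifnot(fraction >= 0, fraction < 1, factor > 0)
  if (!is.null(seed)) set.seed(seed)
  n_edge <- nrow(species_tree$edge)
  n_accel <- round(fraction * n_edge)
  flags <- rep(FALSE, n_edge)
  if (n_accel > 0L) flags[sample.int(n_edge, n_accel)] <- TRUE
  multipliers <- ifelse(flags, factor, 1)
  list(flags = flags, multipliers = multipliers)
}

#' Simulate a complete clock data set with known pacemaker structure
#'
#' Generates a birth-death species tree, assigns loci to clock clusters,
#' accelerates a subset of branches, simulates MSC gene trees, and converts
#' them to phylograms under the white-noise clock. Cluster and acceleration
#' multipliers compose multiplicatively and are fixed for the whole data
#' set.
#'
#' @param theta Coalescent population-size parameter.
#' @param mean_rate Mean rate, substitutions/site/time.
#' @param rate_sd White-noise standard deviation.
#' @param n_loci Number of loci.
#' @param k Number of clock clusters.
#' @param accel_fraction Fraction of branches accelerated.
#' @param accel_factor Acceleration multiplier.
#' @param n_tips,age,birth,death Species-tree parameters.
#' @param spread Between-cluster multiplier spread (log-scale sd).
#' @param seed Optional integer seed.
#' @return List with `species_tree`, `gene_trees` (named phylograms),
#'   `gene_time_trees`, and `truth` (cluster labels and multipliers,
#'   acceleration flags, composed per-cluster multiplier matrix).
#' @export
simulate_clock_data <- function(theta = 0.02, mean_rate = 0.05, rate_sd = 0.05,
                                n_loci = 100L, k = 1L, accel_fraction = 0,
                                accel_factor = 5, n_tips = 50L, age = 50,
                                birth = 0.5, death = 0.1, spread = 0.5,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  species_tree <- sim_species_tree(n_tips, age, birth, death)
  clusters <- assign_clock_clusters(n_loci, k, species_tree, spread = spread)
  accel <- accelerate_branches(species_tree, accel_fraction, accel_factor)
  combined <- sweep(clusters$multipliers, 2L, accel$multipliers, `*`)
  time_trees <- sim_gene_trees(species_tree, theta, n_loci)
  paths <- species_edge_paths(species_tree)
  sp_ages <- node_ages(species_tree)
  gene_trees <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    gene_trees[[i]] <- apply_clock_impl(
      time_trees[[i]], paths, sp_ages, mean_rate, rate_sd,
      combined[clusters$labels[i], ]
    )
  }
  names(gene_trees) <- names(time_trees)
  class(gene_trees) <- "multiPhylo"
  list(
    species_tree = species_tree,
    gene_trees = gene_trees,
    gene_time_trees = time_trees,
    truth = list(
      cluster_labels = clusters$labels,
      cluster_multipliers = clusters$multipliers,
      accel_flags = accel$flags,
      accel_multipliers = accel$multipliers,
      combined_multipliers = combined
    ),
    params = list(
      theta = theta, mean_rate = mean_rate, rate_sd = rate_sd,
      n_loci = n_loci, k = k, accel_fraction = accel_fraction,
      accel_factor = accel_factor, n_tips = n_tips, age = age,
      birth = birth, death = death, spread = spread
    )
  )
}
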