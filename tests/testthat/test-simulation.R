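test_that("birth-death trees honour tip count and rescaled root age", {
  tr <- sim_species_tree(50, 50, 0.5, 0.1, seed = 201)
  expect_equal(ape::Ntip(tr), 50L)
  expect_equal(max(ape::node.depth.edgelength(tr)), 50, tolerance = 1e-9)
  expect_true(is_ultrametric_tree(tr))

  yule <- sim_species_tree(3, 10, 1, 0, seed = 202)
  expect_equal(ape::Ntip(yule), 3L)
  expect_equal(max(ape::node.depth.edgelength(yule)), 10, tolerance = 1e-9)

  expect_error(sim_species_tree(10, 50, 0.1, 0.5), "death rate")
})

test_that("lineage counts at half the root age increase with birth rate", {
  nlin <- function(b, seeds) {
    vapply(seeds, function(s) {
      tr <- sim_species_tree(30, 50, b, 0.1, seed = s)
      ages <- clockspacer:::node_ages(tr)
      sum(ages[tr$edge[, 1]] > 25 & ages[tr$edge[, 2]] <= 25)
    }, numeric(1))
  }
  slow <- nlin(0.3, 1:500)
  fast <- nlin(0.7, 501:1000)
  expect_gt(mean(fast), mean(slow))
})

test_that("theta -> 0 reproduces the species tree; concordance decays with theta", {
  sp <- sim_species_tree(12, 50, 0.5, 0.1, seed = 211)
  gts <- sim_gene_trees(sp, theta = 1e-8, n_loci = 10, seed = 212)
  # oracle: Robinson-Foulds distance from an independent implementation
  expect_true(all(vapply(gts, function(g) phangorn::RF.dist(g, sp), 1) == 0))
  sp_ages <- sort(clockspacer:::node_ages(sp)[13:23])
  for (g in gts) {
    g_ages <- sort(clockspacer:::node_ages(g)[13:23])
    expect_lt(max(abs(g_ages - sp_ages)), 1e-4)
  }
  # every gene-tree root is at least as old as the species root
  deep <- sim_gene_trees(sp, theta = 1, n_loci = 20, seed = 213)
  expect_true(all(vapply(deep, function(g) max(clockspacer:::node_ages(g)), 1) >= 50))

  # missing data after collection increases with theta
  mf <- vapply(c(0.02, 0.5, 1), function(th) {
    g <- sim_gene_trees(sp, th, 50, seed = 214)
    g <- lapply(g, apply_clock, species_tree = sp, mean_rate = 0.05,
                rate_sd = 0.01, seed = 215)
    mean(is.na(collect_clocks(sp, g, "rates")$values))
  }, numeric(1))
  expect_true(mf[1] <= mf[2] && mf[2] < mf[3])
})

test_that("quartet concordance matches the closed-form coalescent probability", {
  # one short internal branch (duration 0.5) below a long mixing branch
  spq <- parse_newick("(((A:0.5,B:0.5):0.5,C:1):20,D:21);")
  gq <- sim_gene_trees(spq, theta = 1, n_loci = 2000, seed = 221)
  concordant <- vapply(gq, function(g) {
    bs <- bipartition_set(g)
    any(!bs$trivial & vapply(bs$side_a, function(s)
      setequal(s, c("A", "B")) || setequal(s, c("C", "D")), logical(1)))
  }, logical(1))
  expect_lt(abs(mean(concordant) - (1 - (2 / 3) * exp(-1))), 0.03)
})

test_that("white-noise clock has the requested mean, sd and strict-clock limit", {
  sp <- sim_species_tree(10, 50, 0.5, 0.1, seed = 231)
  gt <- sim_gene_trees(sp, 0.02, 1, seed = 232)[[1]]

  strict <- apply_clock(gt, sp, mean_rate = 0.01, rate_sd = 0)
  dur <- clockspacer:::node_ages(gt)[gt$edge[, 1]] -
    clockspacer:::node_ages(gt)[gt$edge[, 2]]
  expect_equal(strict$edge.length, 0.01 * dur, tolerance = 1e-12)

  big <- sim_species_tree(3000, 50, 0.5, 0.1, seed = 233)
  noisy <- apply_clock(big, big, mean_rate = 0.05, rate_sd = 0.05, seed = 234)
  r <- attr(noisy, "rates")
  expect_gt(length(r), 5000)
  expect_lt(abs(mean(r) - 0.05), 0.002)
  expect_lt(abs(sd(r) - 0.05), 0.002)
})

test_that("cluster assignment builds near-equal blocks sharing multipliers", {
  sp <- sim_species_tree(10, 50, 0.5, 0.1, seed = 241)

  k1 <- assign_clock_clusters(20, 1, sp, seed = 242)
  expect_true(all(k1$multipliers == 1))

  k3 <- assign_clock_clusters(100, 3, sp, seed = 243)
  expect_equal(as.integer(table(k3$labels)), c(34L, 33L, 33L))
  expect_equal(dim(k3$multipliers), c(3L, nrow(sp$edge)))
  # lognormal with median 1: log-multipliers centred near 0
  expect_lt(abs(mean(log(k3$multipliers))), 0.2)

  # under a noiseless clock with exact embedding, rows within a cluster are
  # perfectly correlated across branches
  set.seed(244)
  k3b <- assign_clock_clusters(12, 3, sp)
  gts <- lapply(seq_len(12), function(i) {
    apply_clock(sp, sp, mean_rate = 0.05, rate_sd = 0,
                multipliers = k3b$multipliers[k3b$labels[i], ])
  })
  names(gts) <- paste0("L", 1:12)
  cr <- collect_clocks(sp, gts, mode = "rates")
  same <- which(k3b$labels == k3b$labels[1])
  cc <- cor(t(cr$values[same, , drop = FALSE]))
  expect_true(all(cc > 1 - 1e-8))
})

test_that("branch acceleration flags the right count with exact multipliers", {
  sp <- sim_species_tree(50, 50, 0.5, 0.1, seed = 251)
  expect_equal(nrow(sp$edge), 98L)

  none <- accelerate_branches(sp, 0, seed = 252)
  expect_equal(sum(none$flags), 0L)
  expect_true(all(none$multipliers == 1))

  two <- accelerate_branches(sp, 0.02, seed = 253)
  expect_equal(sum(two$flags), 2L)  # round(0.02 * 98)
  expect_equal(unname(two$multipliers[two$flags]), c(5, 5))
  expect_true(all(two$multipliers[!two$flags] == 1))

  ten <- accelerate_branches(sp, 0.10, factor = 5, seed = 254)
  expect_equal(sum(ten$flags), 10L)
})

test_that("the factorial design expands to the full Cartesian product", {
  d <- clock_design()
  expect_equal(nrow(d), 729L)
  expect_equal(nrow(clock_design(replicates = 10)), 7290L)
  expect_equal(nrow(clock_design(theta = 0.02)), 243L)
  expect_false(anyDuplicated(d[, 1:6]) > 0)
  # derived seeds are deterministic and within integer range
  d2 <- clock_design()
  expect_identical(d$seed, d2$seed)
  expect_true(all(d$seed >= 1 & d$seed <= 2147483646))
})

test_that("a scenario run is deterministic and reports its scores", {
  sc <- list(theta = 0.02, mean_rate = 0.05, rate_sd = 0.05, n_loci = 60L,
             k = 3L, accel_fraction = 0.1, seed = 261L, n_tips = 12L)
  r1 <- run_scenario(sc, n_perm = 19)
  r2 <- run_scenario(sc, n_perm = 19)
  expect_identical(r1, r2)
  expect_equal(r1$status, "ok")
  expect_true(r1$sensitivity >= 0 && r1$sensitivity <= 1)
  expect_true(r1$specificity >= 0 && r1$specificity <= 1)

  null_sc <- list(theta = 0.02, mean_rate = 0.05, rate_sd = 0.05, n_loci = 40L,
                  k = 1L, accel_fraction = 0, seed = 262L, n_tips = 10L)
  r0 <- run_scenario(null_sc, n_perm = 19)
  expect_true(is.na(r0$sensitivity))  # no positives to recover
})
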