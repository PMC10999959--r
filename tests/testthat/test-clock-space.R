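test_that("prepare_rates standardises, drops and imputes as documented", {
  m <- matrix(rnorm(60, mean = 5), 12, 5,
              dimnames = list(paste0("L", 1:12), paste0("b", 1:5)))
  pr <- prepare_rates(m, log_transform = FALSE)
  expect_equal(unname(colMeans(pr$matrix)), rep(0, 5))
  expect_equal(unname(apply(pr$matrix, 2, sd)), rep(1, 5))

  m2 <- m
  m2[1:8, 2] <- NA  # 66% missing
  pr2 <- prepare_rates(m2, log_transform = FALSE, max_missing_col = 0.5)
  expect_equal(pr2$transform_log$dropped_columns, "b2")
  expect_equal(ncol(pr2$matrix), 4L)

  # single missing cell imputed with the observed column mean on a 5x3 fixture
  f <- matrix(c(1, 2, 3, 4, 5,
                10, 10, NA, 10, 14,
                2, 4, 6, 8, 10), 5, 3,
              dimnames = list(paste0("L", 1:5), c("x", "y", "z")))
  prf <- prepare_rates(f, log_transform = FALSE)
  imputed_raw <- mean(c(10, 10, 10, 14))
  centred <- (imputed_raw - mean(c(10, 10, imputed_raw, 10, 14))) /
    sd(c(10, 10, imputed_raw, 10, 14))
  expect_equal(prf$matrix[3, "y"], centred)
  expect_equal(prf$transform_log$n_imputed, 1L)
})

test_that("log transform maps zeros to missing before imputation", {
  m <- matrix(exp(rnorm(40)), 10, 4,
              dimnames = list(paste0("L", 1:10), paste0("b", 1:4)))
  m[2, 3] <- 0
  pr <- prepare_rates(m, log_transform = TRUE)
  expect_equal(pr$transform_log$n_imputed, 1L)
  expect_error(prepare_rates(m[1:2, ], log_transform = FALSE), "fewer than 3")
})

test_that("perfectly correlated columns collapse onto one component", {
  base <- rnorm(30)
  m <- matrix(base, 30, 5) * rep(c(1, 2, 5, 0.1, 3), each = 30)
  colnames(m) <- paste0("b", 1:5)
  cs <- clock_space(prepare_rates(m, log_transform = FALSE))
  expect_equal(cs$eigenvalues[1], 5, tolerance = 1e-8)
  expect_equal(cs$variance_proportions[1], 1, tolerance = 1e-8)
})

test_that("iid-noise eigenvalues stay in the Marchenko-Pastur range", {
  set.seed(77)
  m <- matrix(rnorm(50000), 5000, 10)
  cs <- clock_space(m)
  expect_true(all(cs$eigenvalues >= 0.8 & cs$eigenvalues <= 1.2))
})

test_that("eigenvalues match an independent SVD oracle on a fixture", {
  f <- matrix(c(4, 2, 7, 1, 9, 3,
                1, 5, 2, 8, 3, 6,
                7, 1, 4, 2, 6, 5,
                2, 8, 1, 9, 4, 3), 6, 4,
              dimnames = list(paste0("L", 1:6), paste0("b", 1:4)))
  cs <- clock_space(prepare_rates(f, log_transform = FALSE))
  # oracle: singular values of the standardised matrix
  lam_oracle <- svd(scale(f))$d^2 / (nrow(f) - 1)
  expect_equal(cs$eigenvalues, lam_oracle, tolerance = 1e-8)
  expect_equal(sum(cs$eigenvalues), 4, tolerance = 1e-8)
  # loadings orthonormal
  expect_equal(crossprod(cs$loadings), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("scores times loadings reconstructs the standardised matrix", {
  set.seed(5)
  m <- matrix(rnorm(200), 20, 10)
  pr <- prepare_rates(m, log_transform = FALSE)
  cs <- clock_space(pr)
  expect_equal(cs$scores %*% t(cs$loadings), pr$matrix,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("permuting locus order permutes scores and preserves eigenvalues", {
  set.seed(6)
  m <- matrix(rnorm(120), 15, 8, dimnames = list(paste0("L", 1:15), NULL))
  cs1 <- clock_space(prepare_rates(m, log_transform = FALSE))
  perm <- sample(15)
  cs2 <- clock_space(prepare_rates(m[perm, ], log_transform = FALSE))
  expect_equal(cs2$eigenvalues, cs1$eigenvalues, tolerance = 1e-10)
  expect_equal(cs2$scores, cs1$scores[perm, ], tolerance = 1e-8)
})

test_that("sbsd_min is zero on scalar multiples and symmetric", {
  a <- parse_newick("((A:1,B:2):3,(C:1,D:1.5):2);")
  expect_equal(sbsd_min(a, a), 0)
  b <- a
  b$edge.length <- a$edge.length * 2.7
  expect_equal(sbsd_min(a, b), 0, tolerance = 1e-12)

  set.seed(8)
  c_ <- a
  c_$edge.length <- a$edge.length + runif(6, 0, 2)
  expect_equal(sbsd_min(a, c_), sbsd_min(c_, a))
  expect_gt(sbsd_min(a, c_), 0)
})

test_that("sbsd closed-form scaling matches grid search and hand arithmetic", {
  d <- clockspacer:::sbsd_pair(c(1, 2, 3), c(1, 1, 1))
  expect_equal(d, 1 / sqrt(7), tolerance = 1e-12)
  # grid-search oracle over the scaling factor, both directions
  grid <- seq(0.01, 5, by = 1e-4)
  g1 <- min(vapply(grid, function(s) sqrt(sum((c(1, 2, 3) - s * c(1, 1, 1))^2)), 1)) / sqrt(14)
  g2 <- min(vapply(grid, function(s) sqrt(sum((c(1, 1, 1) - s * c(1, 2, 3))^2)), 1)) / sqrt(3)
  expect_equal(d, min(g1, g2), tolerance = 1e-6)

  a <- parse_newick("((A:1,B:2):3,(C:1,D:1.5):2);")
  b <- a
  set.seed(9)
  b$edge.length <- a$edge.length * 1.7 + runif(6, 0, 0.5)
  ml <- clockspacer:::matched_lengths(a, b)
  gd <- min(
    min(vapply(grid, function(s) sqrt(sum((ml$a - s * ml$b)^2)), 1)) / sqrt(sum(ml$a^2)),
    min(vapply(grid, function(s) sqrt(sum((ml$b - s * ml$a)^2)), 1)) / sqrt(sum(ml$b^2))
  )
  expect_equal(sbsd_min(a, b), gd, tolerance = 1e-6)
})

test_that("classical MDS embeds exact configurations exactly", {
  expect_equal(unname(mds_embed(matrix(0, 4, 4))), matrix(0, 4, 2),
               ignore_attr = TRUE)

  d3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  emb <- mds_embed(d3)
  expect_equal(as.matrix(dist(emb)), d3, tolerance = 1e-6, ignore_attr = TRUE)

  set.seed(10)
  pts <- matrix(rnorm(60), 30, 2)
  D <- as.matrix(dist(pts))
  emb2 <- mds_embed(D)
  expect_lt(sqrt(mean((as.matrix(dist(emb2)) - D)^2)), 1e-6)

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(mds_embed(bad), "asymmetric")
})

test_that("annotate_space joins coordinates, clusters, rates and supports", {
  sp <- sim_species_tree(10, 50, 0.5, 0.1, seed = 61)
  gts <- sim_gene_trees(sp, 0.02, 12, seed = 62)
  gts <- lapply(gts, apply_clock, species_tree = sp, mean_rate = 0.05,
                rate_sd = 0.01, seed = 63)
  cr <- collect_clocks(sp, gts, mode = "rates")
  cs <- clock_space(prepare_rates(cr))

  ann <- annotate_space(cs, rates = cr)
  expect_equal(nrow(ann), 12L)
  expect_equal(ann$mean_rate, unname(rowMeans(cr$values, na.rm = TRUE)))

  # supports: numeric internal-node labels average arithmetically
  gsup <- parse_newick("((A:1,B:1)90:1,(C:1,D:1)100:1);")
  expect_equal(clockspacer:::mean_node_support(gsup), 95)

  user <- tibble::tibble(locus = paste0("L", 1:6), coding = rep(c(TRUE, FALSE), 3))
  ann2 <- annotate_space(cs, user_table = user)
  expect_equal(sum(is.na(ann2$coding)), 6L)
  expect_error(annotate_space(cs, user_table = user[c(1, 1), ]), "duplicate")
})
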