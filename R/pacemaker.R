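#' Eigenvalue-dispersion statistics phi and psi
#'
#' Summaries of the overall degree of correlation among variables from the
#' eigenvalues of their correlation matrix. With `p'` variables and
#' eigenvalues `lambda` (which sum to `p'`):
#' `psi = sum((lambda - 1)^2)` and
#' `phi = sqrt((sum(lambda^2) - p') / (p' (p' - 1)))`.
#' Both are 0 when all eigenvalues equal 1 (mutually uncorrelated variables)
#' and maximal (`phi = 1`, `psi = p'(p'-1)`) when a single eigenvalue equals
#' `p'` (perfect correlation).
#'
#' @param eigenvalues Non-negative eigenvalues of a correlation matrix.
#' @param p_prime Number of variables; `sum(eigenvalues)` must equal it
#'   within `1e-6`.
#' @return A tibble with columns `phi`, `psi`, `p_prime`.
#' @examples
#' phi_psi(c(3, 0, 0), 3) # phi = 1, psi = 6
#' @export
phi_psi <- function(eigenvalues, p_prime) {
  stopifnot(is.numeric(eigenvalues), p_prime >= 2L)
  if (any(eigenvalues < -1e-8)) stop("negative eigenvalue")
  lam <- pmax(eigenvalues, 0)
  if (abs(sum(lam) - p_prime) > 1e-6 * max(1, p_prime)) {
    stop("eigenvalues must sum to p_prime (correlation-matrix eigenvalues)")
  }
  s2 <- sum(lam^2)
  tibble::tibble(
    phi = sqrt(max(s2 - p_prime, 0) / (p_prime * (p_prime - 1))),
    psi = sum((lam - 1)^2),
    p_prime = as.integer(p_prime)
  )
}

#' Permute values within each branch (column)
#'
#' Independently shuffles every column, preserving each branch's exact
#' multiset of rates while destroying the joint structure across branches —
#' the null model of fully independent rates across loci and branches.
#'
#' @param x Complete numeric matrix (loci x branches).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return Matrix of the same shape.
#' @export
permute_within_branches <- function(x, seed = NULL) {
  x <- as.matrix(x)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x)
  if (n > 1L) {
    for (j in seq_len(ncol(x))) x[, j] <- x[sample.int(n), j]
  }
  x
}

#' Add-one permutation p-value
#'
#' `p = (1 + #\{permuted >= observed\}) / (1 + n_permutations)`; ties count
#' toward the numerator, so p is never below `1/(n+1)` nor above 1.
#'
#' @param observed Observed statistic.
#' @param permuted Vector of permuted statistics.
#' @return p-value in `[1/(n+1), 1]`.
#' @export
permutation_pvalue <- function(observed, permuted) {
  stopifnot(length(permuted) >= 1L)
  (1 + sum(permuted >= observed)) / (1 + length(permuted))
}

#' Permutation tests of pacemaker hypotheses
#'
#' Runs the three permutation tests on a prepared rate matrix, all against
#' the same within-branch permutation null (fully independent rates across
#' loci and branches) and sharing one seeded permutation set:
#' \describe{
#'   \item{degenerate-pacemaker test (`pPhi`, `pPsi`)}{observed phi/psi of
#'     the correlation-matrix eigenvalues against their permutation
#'     distribution; a significant result rejects the degenerate multiple
#'     pacemaker model.}
#'   \item{number of pacemakers (`pPCs`)}{each component's variance
#'     proportion against the permutation distribution of the same rank's
#'     proportion; the number of significant components estimates the number
#'     of pacemakers.}
#'   \item{local pacemakers (`pIL`)}{each branch's absolute loading on each
#'     component against the permutation distribution for the same branch
#'     and rank, flagging branches that drive individual rate axes.}
#' }
#' Permuted replicates are re-standardised and eigendecomposed by the
#' identical code path as the observed matrix. p-values use the add-one
#' convention ([permutation_pvalue()]).
#'
#' @param x A `prepared_rates` object, `clock_rates` (prepared with default
#'   settings), or complete numeric matrix.
#' @param n_perm Number of permutations (>= 19).
#' @param seed Integer seed making the whole result reproducible.
#' @param alpha Significance level used for the significant-PC count and the
#'   implied-model summary.
#' @param adjust `"none"` or `"BH"`: optional Benjamini-Hochberg adjustment
#'   of `pIL` across branches within each component.
#' @param loadings Compute the per-branch loading test (set `FALSE` to skip
#'   the eigenvector work when only `pPhi`/`pPsi`/`pPCs` are needed).
#' @return A `pacemaker_test` object with elements `pPhi`, `pPsi`, `pPCs`,
#'   `pIL` (branches x components, `NULL` when `loadings = FALSE`),
#'   `pIL_adjusted`, `observed` (phi/psi, eigenvalues, variance proportions,
#'   loadings), `n_perm`, `seed`, `alpha`, `n_significant_pcs`,
#'   `implied_model`.
#' @export
pacemaker_test <- function(x, n_perm = 100L, seed = NULL, alpha = 0.05,
                           adjust = c("none", "BH"), loadings = TRUE) {
  adjust <- match.arg(adjust)
  if (inherits(x, "clock_rates")) x <- prepare_rates(x)
  m <- as.matrix(x)
  if (anyNA(m)) stop("matrix must be complete (use prepare_rates())")
  stopifnot(n_perm >= 19L)
  n <- nrow(m)
  p <- ncol(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("b", seq_len(p))

  obs_e <- corr_eigen(m, vectors = loadings)
  obs_lam <- obs_e$values
  obs_stats <- phi_psi(obs_lam, p)
  obs_vp <- obs_lam / sum(obs_lam)
  obs_load <- if (loadings) fix_signs(obs_e$vectors) else NULL

  if (!is.null(seed)) set.seed(seed)
  perm_phi <- perm_psi <- numeric(n_perm)
  perm_vp <- matrix(NA_real_, n_perm, p)
  ge_load <- if (loadings) matrix(0L, p, p) else NULL
  for (b in seq_len(n_perm)) {
    e <- corr_eigen(permute_within_branches(m), vectors = loadings)
    lam <- e$values
    st <- phi_psi(lam, p)
    perm_phi[b] <- st$phi
    perm_psi[b] <- st$psi
    perm_vp[b, ] <- lam / sum(lam)
    if (loadings) ge_load <- ge_load + (abs(e$vectors) >= abs(obs_load))
  }

  pPhi <- permutation_pvalue(obs_stats$phi, perm_phi)
  pPsi <- permutation_pvalue(obs_stats$psi, perm_psi)
  pPCs <- vapply(seq_len(p), function(i) permutation_pvalue(obs_vp[i], perm_vp[, i]),
                 numeric(1L))
  pIL <- pIL_adj <- NULL
  if (loadings) {
    pIL <- (1 + ge_load) / (1 + n_perm)
    dimnames(pIL) <- list(colnames(m), paste0("PC", seq_len(p)))
    if (adjust == "BH") {
      pIL_adj <- apply(pIL, 2L, stats::p.adjust, method = "BH")
      dimnames(pIL_adj) <- dimnames(pIL)
    }
  }

  n_sig <- sum(pPCs < alpha)
  reject <- pPhi < alpha || pPsi < alpha
  any_local <- loadings && n_sig > 0L &&
    any(pIL[, which(pPCs < alpha), drop = FALSE] < alpha)
  implied <- if (!reject) {
    "degenerate (not rejected)"
  } else if (n_sig <= 1L) {
    if (any_local) "universal with local pacemakers" else "universal pacemaker"
  } else {
    if (any_local) "multiple local pacemakers" else "multiple pacemakers"
  }

  structure(
    list(
      pPhi = pPhi, pPsi = pPsi, pPCs = pPCs,
      pIL = pIL, pIL_adjusted = pIL_adj,
      observed = list(
        phi = obs_stats$phi, psi = obs_stats$psi, p_prime = p,
        eigenvalues = obs_lam, variance_proportions = obs_vp,
        loadings = obs_load
      ),
      n_perm = as.integer(n_perm), seed = seed, alpha = alpha,
      n_significant_pcs = n_sig, implied_model = implied
    ),
    class = "pacemaker_test"
  )
}

#' @export
print.pacemaker_test <- function(x, ...) {
  cat(sprintf(
    "<pacemaker_test> %d permutations\n  phi = %.4f (p = %.4g), psi = %.4g (p = %.4g)\n",
    x$n_perm, x$observed$phi, x$pPhi, x$observed$psi, x$pPsi
  ))
  cat(sprintf(
    "  significant PCs at alpha = %.2g: %d\n  implied model: %s\n",
    x$alpha, x$n_significant_pcs, x$implied_model
  ))
  invisible(x)
}

#' Tidy per-component results of a pacemaker test
#'
#' @param x A `pacemaker_test` object.
#' @param ... Unused.
#' @return A tibble with one row per component: eigenvalue, variance
#'   proportion, `p_value`, and number of branches with significant loadings.
#' @export
tidy.pacemaker_test <- function(x, ...) {
  p <- length(x$pPCs)
  tibble::tibble(
    PC = paste0("PC", seq_len(p)),
    eigenvalue = x$observed$eigenvalues,
    variance_proportion = x$observed$variance_proportions,
    p_value = x$pPCs,
    n_significant_branches = if (is.null(x$pIL)) NA_integer_ else
      colSums(x$pIL < x$alpha)
  )
}

#' @export
glance.pacemaker_test <- function(x, ...) {
  tibble::tibble(
    phi = x$observed$phi,
    psi = x$observed$psi,
    pPhi = x$pPhi,
    pPsi = x$pPsi,
    n_significant_pcs = x$n_significant_pcs,
    n_perm = x$n_perm,
    implied_model = x$implied_model
  )
}
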