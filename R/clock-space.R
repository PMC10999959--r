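# Correlation-scaled eigendecomposition used identically for the observed
# matrix and for every permuted replicate: re-standardise columns, then
# eigendecompose the branch-branch correlation matrix. Eigenvalues sum to the
# number of columns; tiny negative values from floating point are clamped.
corr_eigen <- function(m, vectors = TRUE) {
  m <- scale(m)
  r <- crossprod(m) / (nrow(m) - 1L)
  e <- eigen(r, symmetric = TRUE, only.values = !vectors)
  e$values[e$values < 0] <- 0
  e
}

# Fix eigenvector signs so each column's largest-magnitude entry is positive.
fix_signs <- function(v) {
  flip <- apply(v, 2L, function(col) col[which.max(abs(col))] < 0)
  v[, flip] <- -v[, flip, drop = FALSE]
  v
}

#' Principal-component clock space of a rate matrix
#'
#' Eigendecomposition of the branch-branch correlation matrix of the
#' prepared (complete, standardised) rate matrix. Loci become points
#' (scores) and branches become axes weights (loadings) in a Euclidean
#' space whose first component captures the maximal correlation in rates
#' across branches — the signature of a shared pacemaker. Correlation
#' scaling (rather than covariance) is used throughout because branch
#' durations differ by orders of magnitude and the phi/psi statistics are
#' defined on correlation-matrix eigenvalues.
#'
#' @param x A `prepared_rates` object, a `clock_rates` object (prepared with
#'   defaults first), or a complete numeric matrix.
#' @param ... Passed to [prepare_rates()] when `x` is a `clock_rates`.
#' @return A `clock_space` object: `scores` (n x m), `loadings` (p' x m,
#'   orthonormal columns, signs fixed so each column's largest-magnitude
#'   entry is positive), `eigenvalues`, `variance_proportions`,
#'   `transform_log`, `branches`.
#' @examples
#' m <- matrix(rnorm(60), 15, 4, dimnames = list(NULL, paste0("b", 1:4)))
#' cs <- clock_space(prepare_rates(m))
#' glance(cs)
#' @export
clock_space <- function(x, ...) {
  if (inherits(x, "clock_rates")) x <- prepare_rates(x, ...)
  if (inherits(x, "prepared_rates")) {
    m <- x$matrix
    tl <- x$transform_log
    branches <- x$branches
  } else {
    m <- as.matrix(x)
    tl <- list()
    branches <- NULL
  }
  if (anyNA(m) || !all(is.finite(m))) stop("matrix contains non-finite entries")
  if (nrow(m) < 3L || ncol(m) < 3L) stop("need at least 3 loci and 3 branches")
  m <- scale(m)
  attr(m, "scaled:center") <- attr(m, "scaled:scale") <- NULL
  e <- corr_eigen(m)
  v <- fix_signs(e$vectors)
  pcs <- paste0("PC", seq_len(ncol(v)))
  dimnames(v) <- list(colnames(m), pcs)
  scores <- m %*% v
  structure(
    list(
      scores = scores,
      loadings = v,
      eigenvalues = e$values,
      variance_proportions = e$values / sum(e$values),
      transform_log = tl,
      branches = branches
    ),
    class = "clock_space"
  )
}

#' @export
print.clock_space <- function(x, ...) {
  vp <- x$variance_proportions
  cat(sprintf(
    "<clock_space> %d loci x %d branches; PC1/PC2 variance: %.1f%% / %.1f%%\n",
    nrow(x$scores), nrow(x$loadings), 100 * vp[1L], 100 * vp[2L]
  ))
  invisible(x)
}

#' Tidy a clock space
#'
#' @param x A `clock_space` object.
#' @param matrix Which component to tidy: locus `"scores"`, branch
#'   `"loadings"`, or `"eigenvalues"`.
#' @param n_components Number of components to keep.
#' @param ... Unused.
#' @return A tibble in long-friendly wide form (one row per locus/branch/PC).
#' @export
tidy.clock_space <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                             n_components = 5L, ...) {
  matrix <- match.arg(matrix)
  k <- min(n_components, length(x$eigenvalues))
  if (matrix == "eigenvalues") {
    return(tibble::tibble(
      PC = paste0("PC", seq_along(x$eigenvalues)),
      eigenvalue = x$eigenvalues,
      variance_proportion = x$variance_proportions
    ))
  }
  m <- x[[matrix]][, seq_len(k), drop = FALSE]
  id <- if (matrix == "scores") "locus" else "branch_id"
  as_tibble(m, rownames = id)
}

#' @export
glance.clock_space <- function(x, ...) {
  tibble::tibble(
    n_loci = nrow(x$scores),
    n_branches = nrow(x$loadings),
    pc1_variance = x$variance_proportions[1L],
    pc2_variance = x$variance_proportions[2L],
    total_eigenvalue = sum(x$eigenvalues)
  )
}

#' Scatter plot of loci in clock space
#'
#' @param object A `clock_space` object.
#' @param colour Optional vector (length = number of loci) to colour by.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clock_space <- function(object, colour = NULL, ...) {
  df <- tidy(object, "scores", n_components = 2L)
  vp <- object$variance_proportions
  p <- if (is.null(colour)) {
    ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2))
  } else {
    df$colour <- colour
    ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2, colour = .data$colour))
  }
  p + ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * vp[1L]),
      y = sprintf("PC2 (%.1f%%)", 100 * vp[2L])
    ) +
    ggplot2::theme_minimal()
}
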