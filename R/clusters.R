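# Within-cluster dispersion of Tibshirani's gap statistic:
# W_k = sum over clusters of (sum of pairwise squared Euclidean distances)
#       / (2 * cluster size), equal to the within-cluster sum of squares.
within_dispersion <- function(x, clustering) {
  w <- 0
  for (cl in unique(clustering)) {
    xi <- x[clustering == cl, , drop = FALSE]
    if (nrow(xi) > 1L) {
      ctr <- colMeans(xi)
      w <- w + sum(sweep(xi, 2L, ctr)^2)
    }
  }
  w
}

pam_clustering <- function(x, k) {
  if (k == 1L) {
    list(clustering = rep(1L, nrow(x)), medoids = matrix(colMeans(x), 1L))
  } else {
    fit <- cluster::pam(x, k, metric = "euclidean", keep.diss = FALSE, keep.data = FALSE)
    list(clustering = fit$clustering, medoids = x[fit$id.med, , drop = FALSE])
  }
}

#' Cluster loci in clock space with PAM and the gap statistic
#'
#' Runs k-medoids (PAM) on Euclidean distances in the embedding for
#' `k = 1..k_max` and selects the number of clusters with the gap statistic:
#' `gap(k) = mean_b log W_k(ref_b) - log W_k(data)` with `B` reference data
#' sets drawn uniformly over the data's bounding box and
#' `s_k = sd_b(log W_k(ref)) * sqrt(1 + 1/B)`. The selected `k` is the
#' smallest `k` with `gap(k) >= gap(k+1) - s_(k+1)` (`k_max` if none
#' qualifies). The whole procedure is deterministic given `seed`.
#'
#' @param x Coordinates: a numeric matrix (points x dimensions), or a
#'   `clock_space` (its first `dims` score columns are used).
#' @param k_max Largest number of clusters considered.
#' @param B Number of uniform reference data sets.
#' @param seed Integer seed for the reference draws.
#' @param dims Number of leading components used when `x` is a `clock_space`.
#' @return A `clock_clusters` object: `k_selected`, `assignments` (tibble
#'   locus/cluster), `gap_curve` (tibble k, log_w, gap, se), `medoids`.
#' @export
group_clocks <- function(x, k_max = 10L, B = 50L, seed = NULL, dims = 2L) {
  if (inherits(x, "clock_space")) {
    x <- x$scores[, seq_len(min(dims, ncol(x$scores))), drop = FALSE]
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  stopifnot(k_max >= 1L, n >= k_max + 1L, B >= 1L)
  if (is.null(rownames(x))) rownames(x) <- paste0("L", seq_len(n))
  if (!is.null(seed)) set.seed(seed)

  ks <- seq_len(k_max)
  fits <- lapply(ks, function(k) pam_clustering(x, k))
  log_w <- vapply(ks, function(k) log(within_dispersion(x, fits[[k]]$clustering)), numeric(1L))

  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  log_w_ref <- matrix(NA_real_, B, k_max)
  for (b in seq_len(B)) {
    ref <- vapply(seq_along(lo), function(j) runif(n, lo[j], hi[j]), numeric(n))
    for (k in ks) {
      log_w_ref[b, k] <- log(within_dispersion(ref, pam_clustering(ref, k)$clustering))
    }
  }
  gap <- colMeans(log_w_ref) - log_w
  se <- apply(log_w_ref, 2L, sd) * sqrt(1 + 1 / B)

  k_selected <- k_max
  if (k_max > 1L) {
    for (k in seq_len(k_max - 1L)) {
      if (gap[k] >= gap[k + 1L] - se[k + 1L]) {
        k_selected <- k
        break
      }
    }
  } else {
    k_selected <- 1L
  }

  best <- fits[[k_selected]]
  structure(
    list(
      k_selected = k_selected,
      assignments = tibble::tibble(
        locus = rownames(x),
        cluster = as.integer(best$clustering)
      ),
      gap_curve = tibble::tibble(k = ks, log_w = log_w, gap = gap, se = se),
      medoids = best$medoids,
      coordinates = x
    ),
    class = "clock_clusters"
  )
}

#' @export
print.clock_clusters <- function(x, ...) {
  cat(sprintf(
    "<clock_clusters> k = %d selected by the gap statistic (k_max = %d)\n",
    x$k_selected, max(x$gap_curve$k)
  ))
  print(table(x$assignments$cluster))
  invisible(x)
}

#' @export
tidy.clock_clusters <- function(x, ...) x$assignments

#' @export
glance.clock_clusters <- function(x, ...) {
  tibble::tibble(
    k_selected = x$k_selected,
    k_max = max(x$gap_curve$k),
    gap_at_k = x$gap_curve$gap[x$k_selected],
    n_loci = nrow(x$assignments)
  )
}

#' Gap-statistic curve plot
#'
#' @param object A `clock_clusters` object.
#' @param ... Unused.
#' @return A ggplot of gap(k) with one-standard-error bars.
#' @export
autoplot.clock_clusters <- function(object, ...) {
  gc <- object$gap_curve
  ggplot2::ggplot(gc, ggplot2::aes(.data$k, .data$gap)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$gap - .data$se, ymax = .data$gap + .data$se
    )) +
    ggplot2::geom_vline(xintercept = object$k_selected, linetype = 2) +
    ggplot2::scale_x_continuous(breaks = gc$k) +
    ggplot2::labs(x = "number of clusters k", y = "gap statistic") +
    ggplot2::theme_minimal()
}
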