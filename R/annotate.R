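#' Annotate loci in clock space with rate metrics and user covariates
#'
#' Joins, per embedded locus: PC1/PC2 coordinates, cluster label (when
#' clustering was run), overall locus rate (mean of the non-missing row
#' entries of the rate matrix, on the collected scale), mean branch support
#' (arithmetic mean of numeric internal-node labels of the gene tree, when
#' present), and arbitrary user columns. Loci missing from an optional
#' source get `NA` in its columns; user columns are passed through
#' untouched.
#'
#' @param space A `clock_space` object.
#' @param clusters Optional `clock_clusters` object.
#' @param gene_trees Optional named list/`multiPhylo` of gene trees carrying
#'   numeric internal-node labels (e.g. supports).
#' @param rates Optional `clock_rates` object for the overall locus rate.
#' @param user_table Optional data frame with a `locus` column (unique ids).
#' @return A tibble with one row per embedded locus.
#' @export
annotate_space <- function(space, clusters = NULL, gene_trees = NULL,
                           rates = NULL, user_table = NULL) {
  stopifnot(inherits(space, "clock_space"))
  out <- tidy(space, "scores", n_components = 2L)
  if (!is.null(clusters)) {
    stopifnot(inherits(clusters, "clock_clusters"))
    out <- dplyr::left_join(out, clusters$assignments, by = "locus")
  }
  if (!is.null(rates)) {
    stopifnot(inherits(rates, "clock_rates"))
    mr <- tibble::tibble(
      locus = rownames(rates$values),
      mean_rate = unname(rowMeans(rates$values, na.rm = TRUE))
    )
    out <- dplyr::left_join(out, mr, by = "locus")
  }
  if (!is.null(gene_trees)) {
    ids <- names(gene_trees)
    if (is.null(ids)) stop("gene_trees must be named by locus id")
    ms <- tibble::tibble(
      locus = ids,
      mean_support = vapply(gene_trees, mean_node_support, numeric(1L))
    )
    out <- dplyr::left_join(out, ms, by = "locus")
  }
  if (!is.null(user_table)) {
    user_table <- as_tibble(user_table)
    if (!"locus" %in% names(user_table)) stop("user_table must have a 'locus' column")
    if (anyDuplicated(user_table$locus)) stop("user_table has duplicate locus ids")
    out <- dplyr::left_join(out, user_table, by = "locus")
  }
  out
}

mean_node_support <- function(tree) {
  lab <- tree$node.label
  if (is.null(lab)) return(NA_real_)
  v <- suppressWarnings(as.numeric(lab))
  v <- v[!is.na(v)]
  if (length(v) == 0L) NA_real_ else mean(v)
}

#' Scatter plot of an annotated clock space
#'
#' @param annotation Tibble from [annotate_space()].
#' @param colour Name of the column to colour points by.
#' @return A ggplot of PC1 vs PC2.
#' @export
plot_space <- function(annotation, colour = NULL) {
  p <- ggplot2::ggplot(annotation, ggplot2::aes(.data$PC1, .data$PC2))
  if (!is.null(colour)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), alpha = 0.7)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7)
  }
  p + ggplot2::theme_minimal()
}
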