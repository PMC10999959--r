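#' Match gene-tree branches to species-tree branches
#'
#' Concordance-based matching: each gene-tree edge's split, restricted to the
#' taxa shared with the species tree, is compared with the species-tree
#' splits restricted to the same taxa. An edge is `matched` when exactly one
#' species branch restricts to the same split, `ambiguous` when two or more
#' do (taxon absence collapsed a species-tree path onto one restricted
#' split), `conflicting` when no species branch matches and the split is
#' incompatible with the restricted species tree, and `unmatched` when it is
#' compatible but corresponds to no species branch (e.g. it resolves a
#' collapsed region). Gene trees are treated as unrooted; a rooted input is
#' unrooted first (the two root edges merge, lengths summed). The two edges
#' incident to the species-tree root likewise form a single merged branch.
#'
#' @param species_tree Rooted or unrooted `phylo`.
#' @param gene_tree `phylo` whose tips are a subset of the species tree's.
#' @return A tibble with one row per (unrooted) gene-tree edge: `edge`,
#'   `length`, `status`, `branch_id` (`NA` unless matched), `trivial`.
#' @export
match_branches <- function(species_tree, gene_tree) {
  sp <- species_branches(species_tree)
  match_branches_impl(sp, gene_tree)
}

match_branches_impl <- function(sp, gene_tree, restricted = NULL) {
  gene_tree <- validate_tree(gene_tree)
  extra <- setdiff(gene_tree$tip.label, sp$taxa)
  if (length(extra) > 0L) {
    stop("gene tree has tips absent from the species tree: ",
         paste(head(extra, 5L), collapse = ", "))
  }
  if (ape::is.rooted(gene_tree) && ape::Ntip(gene_tree) > 2L) {
    gene_tree <- ape::unroot(gene_tree)
  }
  shared <- sort(gene_tree$tip.label)
  if (length(shared) < 4L) {
    cnd <- structure(
      class = c("locus_skip", "error", "condition"),
      list(message = sprintf("only %d taxa shared with the species tree", length(shared)),
           call = NULL)
    )
    stop(cnd)
  }
  if (is.null(restricted)) restricted <- restrict_species_branches(sp, shared)
  gk <- split_keys(edge_clades(gene_tree), gene_tree$tip.label, shared)
  n_edge <- length(gk$key)
  status <- character(n_edge)
  branch <- rep(NA_character_, n_edge)
  hits <- restricted$key_to_branch[gk$key]
  for (i in seq_len(n_edge)) {
    h <- hits[[i]]
    if (!is.null(h)) {
      if (length(h) == 1L) {
        status[i] <- "matched"
        branch[i] <- sp$table$branch_id[h]
      } else {
        status[i] <- "ambiguous"
      }
    } else if (compatible_with_all(gk$side[i, ], restricted$nontrivial_side)) {
      status[i] <- "unmatched"
    } else {
      status[i] <- "conflicting"
    }
  }
  tibble::tibble(
    edge = seq_len(n_edge),
    length = gene_tree$edge.length,
    status = status,
    branch_id = branch,
    trivial = split_status(gk$n_side, gk$n_taxa) == "trivial"
  )
}

#' Collect branch rates from gene trees into a loci-by-branches matrix
#'
#' For every gene tree, branch lengths of edges whose splits uniquely and
#' concordantly match a species-tree branch are recorded in that branch's
#' column; ambiguous and conflicting edges leave missing entries. In
#' `"rates"` mode the species tree must be a rooted ultrametric time-tree and
#' lengths are divided by the matching branch's time duration, giving rates
#' in substitutions/site/time; in `"lengths"` mode raw gene-tree branch
#' lengths are kept and the species tree may be unrooted. Pendant branches
#' are collected alongside internal ones (set `internal_only = TRUE` to
#' restrict to internal branches). Loci sharing fewer than 4 taxa with the
#' species tree are dropped with a warning.
#'
#' @param species_tree `phylo`; rooted ultrametric time-tree in `"rates"` mode.
#' @param gene_trees A `multiPhylo` or list of `phylo` gene trees (branch
#'   lengths in expected substitutions per site).
#' @param mode `"rates"` or `"lengths"`.
#' @param locus_ids Optional character vector of locus ids (defaults to the
#'   list names, else `L1`, `L2`, ...).
#' @param internal_only Drop pendant branches from the collected columns.
#' @param tol Ultrametricity tolerance (relative to root height).
#' @return An object of class `clock_rates`: list with `values` (numeric
#'   matrix, loci x branches, `NA` for missing), `branches` (tibble of branch
#'   metadata incl. `duration`), `mode`, `match_log` (per-locus match counts)
#'   and `dropped_loci`.
#' @examples
#' sp <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' gt <- parse_newick("((A:0.02,B:0.02):0.02,(C:0.02,D:0.02):0.02);")
#' cr <- collect_clocks(sp, list(g1 = gt), mode = "rates")
#' cr$values
#' @export
collect_clocks <- function(species_tree, gene_trees, mode = c("rates", "lengths"),
                           locus_ids = NULL, internal_only = FALSE, tol = 1e-6) {
  mode <- match.arg(mode)
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  n <- length(gene_trees)
  stopifnot(n >= 1L)
  if (is.null(locus_ids)) {
    locus_ids <- names(gene_trees)
    if (is.null(locus_ids) || any(locus_ids == "")) locus_ids <- paste0("L", seq_len(n))
  }
  stopifnot(length(locus_ids) == n, !anyDuplicated(locus_ids))

  if (mode == "rates") {
    if (!ape::is.rooted(species_tree)) {
      stop("mode 'rates' requires a rooted species time-tree")
    }
    if (!is_ultrametric_tree(species_tree, tol = tol)) {
      stop("mode 'rates' requires an ultrametric species tree (relative tolerance ", tol, ")")
    }
  }
  sp <- species_branches(species_tree)
  branches <- sp$table
  if (internal_only) branches <- branches[!branches$pendant, , drop = FALSE]
  p <- nrow(branches)
  keep_branch <- match(branches$branch_id, sp$table$branch_id)

  values <- matrix(NA_real_, n, p, dimnames = list(locus_ids, branches$branch_id))
  log_rows <- vector("list", n)
  dropped <- character(0)
  cache <- new.env(parent = emptyenv())

  for (i in seq_len(n)) {
    gt <- gene_trees[[i]]
    shared_key <- paste(sort(gt$tip.label), collapse = "\r")
    restricted <- cache[[shared_key]]
    m <- tryCatch(
      {
        if (is.null(restricted)) {
          shared <- sort(intersect(gt$tip.label, sp$taxa))
          if (length(shared) >= 4L && length(setdiff(gt$tip.label, sp$taxa)) == 0L) {
            restricted <- restrict_species_branches(sp, shared)
            cache[[shared_key]] <- restricted
          }
        }
        match_branches_impl(sp, gt, restricted = restricted)
      },
      locus_skip = function(e) e
    )
    if (inherits(m, "locus_skip")) {
      dropped <- c(dropped, locus_ids[i])
      next
    }
    hit <- m[m$status == "matched" & m$branch_id %in% branches$branch_id, ]
    j <- match(hit$branch_id, branches$branch_id)
    v <- hit$length
    if (mode == "rates") v <- v / branches$duration[j]
    values[i, j] <- v
    log_rows[[i]] <- tibble::tibble(
      locus = locus_ids[i],
      n_edges = nrow(m),
      matched = sum(m$status == "matched"),
      ambiguous = sum(m$status == "ambiguous"),
      conflicting = sum(m$status == "conflicting"),
      unmatched = sum(m$status == "unmatched")
    )
  }

  if (length(dropped) > 0L) {
    warning(length(dropped), " locus/loci dropped (< 4 taxa shared with the species tree): ",
            paste(head(dropped, 5L), collapse = ", "))
    values <- values[!(locus_ids %in% dropped), , drop = FALSE]
  }
  if (nrow(values) == 0L) stop("no usable loci after matching")

  structure(
    list(
      values = values,
      branches = branches,
      mode = mode,
      match_log = dplyr::bind_rows(log_rows),
      dropped_loci = dropped,
      species_tree = sp$tree
    ),
    class = "clock_rates"
  )
}

#' @export
print.clock_rates <- function(x, ...) {
  cat(sprintf(
    "<clock_rates> %d loci x %d species-tree branches (mode: %s)\n",
    nrow(x$values), ncol(x$values), x$mode
  ))
  cat(sprintf("  missing entries: %.1f%%\n", 100 * mean(is.na(x$values))))
  if (length(x$dropped_loci)) {
    cat("  dropped loci:", length(x$dropped_loci), "\n")
  }
  invisible(x)
}

#' @export
as.matrix.clock_rates <- function(x, ...) x$values

#' Tidy a clock_rates object into a long tibble
#'
#' @param x A `clock_rates` object.
#' @param ... Unused.
#' @return A tibble with columns `locus`, `branch_id`, `value` (missing
#'   entries omitted).
#' @export
tidy.clock_rates <- function(x, ...) {
  df <- as_tibble(x$values, rownames = "locus")
  out <- tidyr::pivot_longer(df, -"locus", names_to = "branch_id", values_to = "value")
  dplyr::filter(out, !is.na(.data$value))
}

#' @export
glance.clock_rates <- function(x, ...) {
  tibble::tibble(
    n_loci = nrow(x$values),
    n_branches = ncol(x$values),
    mode = x$mode,
    missing_fraction = mean(is.na(x$values)),
    n_dropped_loci = length(x$dropped_loci)
  )
}

#' Flag unusually long branches against an exponential fit
#'
#' Pools the non-missing values of the rate matrix (or any numeric vector),
#' fits an exponential distribution by maximum likelihood (rate = 1/mean)
#' and flags every value whose upper-tail probability `exp(-x/mean)` falls
#' below `alpha`. Filtering out such branches before embedding is a
#' recommended guard against rate-estimation artefacts.
#'
#' @param x A `clock_rates` object or numeric vector.
#' @param alpha Tail significance level, in (0, 0.5].
#' @return A `long_branch_report`: list with `flagged` (tibble of locus,
#'   branch_id, value, tail_prob), `mean`, `alpha`, `n`.
#' @export
flag_long_branches <- function(x, alpha = 0.01) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 0.5)
  if (inherits(x, "clock_rates")) {
    vals <- x$values
  } else {
    vals <- matrix(as.numeric(x), ncol = 1L,
                   dimnames = list(paste0("v", seq_along(x)), "pooled"))
  }
  pool <- vals[!is.na(vals)]
  if (length(pool) < 10L) stop("need at least 10 non-missing values to fit the tail")
  m <- mean(pool)
  tailp <- exp(-vals / m)
  idx <- which(!is.na(tailp) & tailp < alpha, arr.ind = TRUE)
  flagged <- tibble::tibble(
    locus = rownames(vals)[idx[, 1L]],
    branch_id = colnames(vals)[idx[, 2L]],
    value = vals[idx],
    tail_prob = tailp[idx]
  )
  structure(
    list(flagged = flagged, mean = m, alpha = alpha, n = length(pool)),
    class = "long_branch_report"
  )
}

#' @export
print.long_branch_report <- function(x, ...) {
  cat(sprintf(
    "<long_branch_report> %d of %d values flagged (exponential mean %.4g, alpha %.3g)\n",
    nrow(x$flagged), x$n, x$mean, x$alpha
  ))
  invisible(x)
}

#' @export
tidy.long_branch_report <- function(x, ...) x$flagged

#' Mask flagged long-branch entries to missing
#'
#' @param rates A `clock_rates` object.
#' @param report A `long_branch_report` from [flag_long_branches()].
#' @return The `clock_rates` object with flagged entries set to `NA`.
#' @export
mask_flagged <- function(rates, report) {
  stopifnot(inherits(rates, "clock_rates"), inherits(report, "long_branch_report"))
  if (nrow(report$flagged) > 0L) {
    i <- match(report$flagged$locus, rownames(rates$values))
    j <- match(report$flagged$branch_id, colnames(rates$values))
    ok <- !is.na(i) & !is.na(j)
    rates$values[cbind(i[ok], j[ok])] <- NA_real_
  }
  rates
}
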