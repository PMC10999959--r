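#' Prepare a rate matrix for embedding
#'
#' Turns a sparse loci-by-branches rate matrix into the complete,
#' column-standardised matrix required by PCA and the permutation tests.
#' Steps, in order: (1) optional natural-log transform (zeros become missing
#' first — a zero rate carries no information on the multiplicative scale);
#' (2) drop branches (columns) whose missing fraction exceeds
#' `max_missing_col`, then loci (rows) likewise; (3) impute remaining
#' missing entries with the column mean of observed values; (4) centre and
#' scale each column to unit variance, dropping zero-variance columns. The
#' full record of drops and imputations is kept in `transform_log`.
#'
#' @param x A `clock_rates` object or numeric matrix with dimnames.
#' @param log_transform Natural-log transform the values first. Defaults to
#'   `TRUE` for rates (right-skewed, multiplicative accelerations become
#'   additive) and `FALSE` otherwise.
#' @param max_missing_col,max_missing_row Maximum tolerated missing fraction
#'   per column / row.
#' @return A `prepared_rates` object: list with `matrix` (complete,
#'   standardised), `transform_log`, and `branches` (metadata for retained
#'   columns when available).
#' @export
prepare_rates <- function(x, log_transform = NULL,
                          max_missing_col = 0.5, max_missing_row = 0.5) {
  branches <- NULL
  if (inherits(x, "clock_rates")) {
    if (is.null(log_transform)) log_transform <- x$mode == "rates"
    branches <- x$branches
    m <- x$values
  } else {
    if (is.null(log_transform)) log_transform <- FALSE
    m <- as.matrix(x)
    storage.mode(m) <- "double"
  }
  stopifnot(nrow(m) > 0L, ncol(m) > 0L)
  if (is.null(rownames(m))) rownames(m) <- paste0("L", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("b", seq_len(ncol(m)))

  if (log_transform) {
    m[!is.na(m) & m <= 0] <- NA_real_
    m <- log(m)
  }

  col_miss <- colMeans(is.na(m))
  drop_cols <- colnames(m)[col_miss > max_missing_col]
  m <- m[, col_miss <= max_missing_col, drop = FALSE]
  row_miss <- rowMeans(is.na(m))
  drop_rows <- rownames(m)[row_miss > max_missing_row]
  m <- m[row_miss <= max_missing_row, , drop = FALSE]
  if (nrow(m) < 3L || ncol(m) < 3L) {
    stop("fewer than 3 rows or 3 columns survive the missing-data thresholds")
  }

  n_imputed <- sum(is.na(m))
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (any(nas)) m[nas, j] <- mean(m[!nas, j])
  }

  centers <- colMeans(m)
  scales <- apply(m, 2L, sd)
  zero_var <- scales <= 0 | !is.finite(scales)
  drop_zero <- colnames(m)[zero_var]
  m <- m[, !zero_var, drop = FALSE]
  if (ncol(m) < 3L) stop("fewer than 3 columns with non-zero variance")
  m <- scale(m, center = centers[!zero_var], scale = scales[!zero_var])
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL

  if (!is.null(branches)) {
    branches <- branches[match(colnames(m), branches$branch_id), , drop = FALSE]
  }
  structure(
    list(
      matrix = m,
      branches = branches,
      transform_log = list(
        log_transform = log_transform,
        max_missing_col = max_missing_col,
        max_missing_row = max_missing_row,
        dropped_columns = drop_cols,
        dropped_rows = drop_rows,
        dropped_zero_variance = drop_zero,
        n_imputed = n_imputed,
        centers = centers[!zero_var],
        scales = scales[!zero_var]
      )
    ),
    class = "prepared_rates"
  )
}

#' @export
print.prepared_rates <- function(x, ...) {
  tl <- x$transform_log
  cat(sprintf(
    "<prepared_rates> %d loci x %d branches (log: %s; imputed: %d; dropped: %d col, %d row)\n",
    nrow(x$matrix), ncol(x$matrix), tl$log_transform, tl$n_imputed,
    length(tl$dropped_columns) + length(tl$dropped_zero_variance), length(tl$dropped_rows)
  ))
  invisible(x)
}

#' @export
as.matrix.prepared_rates <- function(x, ...) x$matrix
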