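#' Principal component analysis of a trait matrix
#'
#' Eigen-decomposition of the covariance matrix of the column-centred data
#' (singular value decomposition internally). The covariance matrix — not
#' the correlation matrix — is used: all intended inputs (Procrustes
#' coordinates, suture length ratios) share a common scale. Rows with any
#' missing cell are dropped with a message listing their ids. Loadings carry
#' a deterministic sign convention: the largest-magnitude entry of each
#' loading column is positive.
#'
#' @param x Numeric matrix or data frame (specimens x variables); row names
#'   (or a `specimen_id` column) identify specimens.
#' @return An object of class `morph_pca` with `scores` (specimens x axes),
#'   `eigenvalues` (axis variances), `proportion` (fractions of total
#'   variance), `loadings` (variables x axes), `center`, `dropped_ids`.
#' @export
morph_pca <- function(x) {
  if (is.data.frame(x)) {
    ids <- if ("specimen_id" %in% names(x)) as.character(x$specimen_id) else rownames(x)
    x <- as.matrix(x[setdiff(names(x), "specimen_id")])
    rownames(x) <- ids
  }
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("row_%03d", seq_len(nrow(x)))
  keep <- complete.cases(x)
  dropped_ids <- rownames(x)[!keep]
  if (any(!keep)) {
    inform(sprintf("Dropping %d row(s) with missing cells from PCA: %s",
                   sum(!keep), paste(dropped_ids, collapse = ", ")))
    x <- x[keep, , drop = FALSE]
  }
  n <- nrow(x)
  if (n < 3) abort("PCA needs at least 3 complete rows")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc)
  n_axes <- sum(sv$d > max(sv$d) * 1e-12)
  d <- sv$d[seq_len(n_axes)]
  eigenvalues <- d^2 / (n - 1)
  loadings <- sv$v[, seq_len(n_axes), drop = FALSE]
  scores <- sv$u[, seq_len(n_axes), drop = FALSE] %*% diag(d, n_axes)
  # sign convention: largest-magnitude loading entry positive per axis
  for (j in seq_len(n_axes)) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  axis_names <- sprintf("PC%d", seq_len(n_axes))
  dimnames(scores) <- list(rownames(x), axis_names)
  dimnames(loadings) <- list(colnames(x), axis_names)
  structure(
    list(
      scores = scores,
      eigenvalues = setNames(eigenvalues, axis_names),
      proportion = setNames(eigenvalues / sum(eigenvalues), axis_names),
      loadings = loadings,
      center = ctr,
      dropped_ids = dropped_ids,
      axis_p = NULL
    ),
    class = "morph_pca"
  )
}

#' @export
print.morph_pca <- function(x, ...) {
  cat(sprintf("<morph_pca> %d specimens, %d axes; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), ncol(x$scores),
              100 * x$proportion[1],
              if (length(x$proportion) > 1) 100 * x$proportion[2] else NA))
  invisible(x)
}

#' @export
tidy.morph_pca <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "specimen_id")
}

#' @export
glance.morph_pca <- function(x, ...) {
  tibble::tibble(
    axis = names(x$eigenvalues),
    eigenvalue = unname(x$eigenvalues),
    proportion = unname(x$proportion),
    p_value = if (is.null(x$axis_p)) NA_real_ else unname(x$axis_p)
  )
}

#' Monte Carlo significance of PCA axes
#'
#' Permutation test of the variance fraction carried by each axis. The null
#' is built by independently permuting every column of the data within
#' itself, which preserves marginal distributions but destroys
#' inter-variable covariance; eigenvalue proportions are recomputed for each
#' permuted dataset and the p-value for axis k is
#' `(1 + #\{permuted proportion_k >= observed\}) / (n_perm + 1)`.
#'
#' @param x Trait matrix or data frame (complete rows used, as in
#'   [morph_pca]).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return A tibble with `axis`, `proportion`, `p_value`.
#' @export
axis_significance <- function(x, n_perm = 999, seed = NULL) {
  if (n_perm < 1) abort("n_perm must be at least 1")
  if (is.data.frame(x)) x <- as.matrix(x[setdiff(names(x), "specimen_id")])
  x <- as.matrix(x)
  x <- x[complete.cases(x), , drop = FALSE]
  prop_of <- function(m) {
    d2 <- svd(sweep(m, 2, colMeans(m)), nu = 0, nv = 0)$d^2
    d2 / sum(d2)
  }
  obs <- prop_of(x)
  n_axes <- length(obs)
  with_seed(seed, {
    exceed <- integer(n_axes)
    for (b in seq_len(n_perm)) {
      perm <- apply(x, 2, sample)
      p <- prop_of(perm)
      m <- min(length(p), n_axes)
      exceed[seq_len(m)] <- exceed[seq_len(m)] + (p[seq_len(m)] >= obs[seq_len(m)])
    }
    tibble::tibble(
      axis = sprintf("PC%d", seq_len(n_axes)),
      proportion = obs,
      p_value = (1 + exceed) / (n_perm + 1)
    )
  })
}

#' @export
autoplot.morph_pca <- function(object, data = NULL, colour = "group", ...) {
  df <- tidy(object)
  if (!is.null(data)) {
    df <- dplyr::left_join(df, tibble::as_tibble(data), by = "specimen_id")
  }
  p1 <- 100 * object$proportion[1]
  p2 <- if (length(object$proportion) > 1) 100 * object$proportion[2] else 0
  mapping <- if (!is.null(data) && colour %in% names(df)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data[[colour]])
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  }
  ggplot2::ggplot(df, mapping) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", p1),
      y = sprintf("PC2 (%.1f%%)", p2)
    ) +
    ggplot2::theme_minimal()
}
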