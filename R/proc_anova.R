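#' Procrustes ANOVA by residual-randomization permutation
#'
#' Sequential (Type I) linear-model decomposition of a multivariate response
#' (Procrustes coordinates or PC scores; a single column reduces to the
#' classical univariate sequential ANOVA). For each term, the sum of squares
#' is the trace of the difference between the residual cross-product
#' matrices of the nested fits excluding and including that term; F is the
#' term mean square over the full-model residual mean square. Significance
#' is assessed by residual randomization (RRPP): for every permutation the
#' reduced-model residuals are row-permuted, added back to the reduced-model
#' fitted values, and the term's F recomputed; the p-value is
#' `(1 + #\{F* >= F\}) / (n_perm + 1)`. The effect size Z is the standard
#' deviate of log(F) within the permuted log(F*) distribution (observed
#' included), the convention of the residual-randomization literature.
#'
#' @param y Numeric response matrix (n x q) or vector.
#' @param data Data frame with the predictor columns named in `terms`.
#' @param terms Ordered character vector of model terms, e.g.
#'   `c("group", "sex", "size", "group:size", "sex:size")`. Order matters:
#'   sums of squares are sequential.
#' @param n_perm Number of random permutations (default 999, plus the
#'   observed arrangement).
#' @param seed Optional integer seed for the permutations.
#' @return A `proc_anova` object; `tidy()` returns the table with columns
#'   `term`, `df`, `ss`, `ms`, `rsq`, `f`, `z`, `p` including `Residuals`
#'   and `Total` rows.
#' @export
procrustes_anova <- function(y, data, terms, n_perm = 999, seed = NULL) {
  y <- as.matrix(y)
  n <- nrow(y)
  if (nrow(data) != n) abort("`y` and `data` must have the same number of rows")
  if (anyNA(y)) abort("Response contains missing values; supply complete cases")
  data <- as.data.frame(data)
  # sequential design bases: Q_0 (intercept) .. Q_K (all terms)
  qs <- list(qr.Q(qr(matrix(1, n, 1))))
  ranks <- 1L
  for (i in seq_along(terms)) {
    x <- model.matrix(reformulate(terms[seq_len(i)]), data)
    if (nrow(x) != n) abort("Predictors contain missing values; supply complete cases")
    qr_x <- qr(x)
    if (qr_x$rank <= ranks[i]) {
      abort(sprintf("Term '%s' is aliased with earlier terms (rank-deficient design)",
                    terms[i]))
    }
    qs[[i + 1L]] <- qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
    ranks <- c(ranks, qr_x$rank)
  }
  rss <- function(yy, q) sum(yy^2) - sum(crossprod(q, yy)^2)
  k_terms <- length(terms)
  rss_seq <- vapply(qs, function(q) rss(y, q), 0)
  ss_total <- rss_seq[1]
  ss_terms <- -diff(rss_seq)
  df_terms <- diff(ranks)
  ss_resid <- rss_seq[k_terms + 1L]
  df_resid <- n - ranks[k_terms + 1L]
  if (df_resid <= 0) abort("No residual degrees of freedom")
  ms_resid <- ss_resid / df_resid
  f_obs <- (ss_terms / df_terms) / ms_resid
  # residual-randomization permutations (shared permutation schedule)
  perms <- with_seed(seed, {
    lapply(seq_len(n_perm), function(b) sample.int(n))
  })
  f_perm <- matrix(NA_real_, n_perm, k_terms)
  fitted_red <- vector("list", k_terms)
  resid_red <- vector("list", k_terms)
  for (i in seq_len(k_terms)) {
    proj <- crossprod(qs[[i]], y)
    fitted_red[[i]] <- qs[[i]] %*% proj
    resid_red[[i]] <- y - fitted_red[[i]]
  }
  for (b in seq_len(n_perm)) {
    p_idx <- perms[[b]]
    for (i in seq_len(k_terms)) {
      y_star <- fitted_red[[i]] + resid_red[[i]][p_idx, , drop = FALSE]
      ss_i <- rss(y_star, qs[[i]]) - rss(y_star, qs[[i + 1L]])
      ss_res_i <- rss(y_star, qs[[k_terms + 1L]])
      f_perm[b, i] <- (ss_i / df_terms[i]) / (ss_res_i / df_resid)
    }
  }
  p_vals <- vapply(seq_len(k_terms), function(i) {
    (1 + sum(f_perm[, i] >= f_obs[i])) / (n_perm + 1)
  }, 0)
  z_vals <- vapply(seq_len(k_terms), function(i) {
    all_f <- c(f_obs[i], f_perm[, i])
    if (any(all_f <= 0) || f_obs[i] <= 0) return(NA_real_)
    lf <- log(all_f)
    s <- sd(lf)
    if (s == 0) return(0)
    (log(f_obs[i]) - mean(lf)) / s
  }, 0)
  tab <- tibble::tibble(
    term = c(terms, "Residuals", "Total"),
    df = c(df_terms, df_resid, n - 1L),
    ss = c(ss_terms, ss_resid, ss_total),
    ms = c(ss_terms / df_terms, ms_resid, NA),
    rsq = c(ss_terms / ss_total, ss_resid / ss_total, 1),
    f = c(f_obs, NA, NA),
    z = c(z_vals, NA, NA),
    p = c(p_vals, NA, NA)
  )
  structure(
    list(table = tab, n = n, n_perm = n_perm, seed = seed, terms = terms,
         z_convention = "standard deviate of log(F) among permuted log(F*)"),
    class = "proc_anova"
  )
}

#' @export
print.proc_anova <- function(x, ...) {
  cat(sprintf("<proc_anova> n = %d, %d permutations (RRPP)\n", x$n, x$n_perm))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @export
tidy.proc_anova <- function(x, ...) x$table

#' @export
glance.proc_anova <- function(x, ...) {
  tibble::tibble(n = x$n, n_perm = x$n_perm,
                 seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}

#' Pairwise group contrasts on a multivariate response
#'
#' For every pair of groups the statistic is the Euclidean distance between
#' the group mean vectors (for Procrustes coordinates this is the Procrustes
#' distance between mean shapes). Raw p-values come from permutation of
#' group labels; the correction over all pairs defaults to Holm.
#'
#' @param y Numeric response matrix (n x q) or vector.
#' @param groups Factor or character vector of group labels, length n.
#' @param adjust One of `"holm"`, `"bonferroni"`, `"none"`.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Optional integer seed.
#' @return Tibble with `group_a`, `group_b`, `distance`, `p_raw`, `p_adj`.
#' @export
pairwise_groups <- function(y, groups, adjust = c("holm", "bonferroni", "none"),
                            n_perm = 999, seed = NULL) {
  adjust <- match.arg(adjust)
  y <- as.matrix(y)
  groups <- as.factor(as.character(groups))
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warn(sprintf("Excluding group(s) with fewer than 2 members: %s",
                 paste(small, collapse = ", ")))
    keep <- !(groups %in% small)
    y <- y[keep, , drop = FALSE]
    groups <- droplevels(groups[keep])
  }
  lev <- levels(groups)
  if (length(lev) < 2) abort("Pairwise contrasts need at least 2 groups")
  pair_dist <- function(g) {
    means <- rowsum(y, g) / as.vector(table(g))
    as.matrix(stats::dist(means))
  }
  d_obs <- pair_dist(groups)
  d_perm <- with_seed(seed, {
    arr <- array(NA_real_, c(length(lev), length(lev), n_perm))
    for (b in seq_len(n_perm)) {
      arr[, , b] <- pair_dist(sample(groups))
    }
    arr
  })
  pairs <- utils::combn(lev, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ia <- match(a, lev); ib <- match(b, lev)
    d <- d_obs[ia, ib]
    p_raw <- (1 + sum(d_perm[ia, ib, ] >= d)) / (n_perm + 1)
    tibble::tibble(group_a = a, group_b = b, distance = d, p_raw = p_raw)
  })
  res$p_adj <- p.adjust(res$p_raw, method = adjust)
  res
}
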