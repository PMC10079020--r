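# Centre a k x 2 configuration and scale it to unit centroid size.
center_and_scale <- function(m, id = "<config>") {
  centred <- sweep(m, 2, colMeans(m))
  cs <- sqrt(sum(centred^2))
  if (cs <= 0) abort(sprintf("Degenerate (zero-size) configuration: %s", id))
  list(coords = centred / cs, cs = cs)
}

# Optimal proper rotation (det = +1) taking centred shape `a` onto centred
# target `c`: closed form in 2-D from the cross-covariance of the two
# configurations. Reflections are never used.
optimal_rotation <- function(a, target) {
  m <- crossprod(a, target) # 2 x 2
  theta <- atan2(m[2, 1] - m[1, 2], m[1, 1] + m[2, 2])
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of landmark configurations: each shape is
#' centred, scaled to unit centroid size, and rotated onto the current
#' consensus by the closed-form 2-D orthogonal Procrustes solution restricted
#' to proper rotations (no reflections); the consensus is the coordinate-wise
#' mean, re-scaled to unit size each round. Iteration stops when the
#' consensus moves by less than `tol` (root-sum-square) or after `max_iter`
#' rounds. This is partial Procrustes superimposition: aligned shapes keep
#' unit centroid size and no tangent-space projection is applied.
#'
#' @param x List of [landmark_config] objects, or a k x 2 x n array.
#' @param tol Convergence tolerance on consensus change (default 1e-8).
#' @param max_iter Maximum iterations (default 100).
#' @param roles,curve Optional per-point role/curve vectors when `x` is an
#'   array (taken from the configurations otherwise).
#' @return An object of class `shape_gpa` with elements `aligned`
#'   (k x 2 x n array), `consensus` (k x 2, unit centroid size),
#'   `centroid_size` (named vector, input units), `log10_centroid_size`,
#'   `roles`, `curve`, `iterations`, `converged`.
#' @export
gpa <- function(x, tol = 1e-8, max_iter = 100, roles = NULL, curve = NULL) {
  if (is.list(x) && length(x) && inherits(x[[1]], "landmark_config")) {
    roles <- roles %||% x[[1]]$roles
    curve <- curve %||% x[[1]]$curve
    ids <- vapply(x, function(cfg) cfg$specimen_id, "")
    arr <- configs_to_array(x)
  } else if (is.array(x) && length(dim(x)) == 3) {
    arr <- x
    ids <- dimnames(arr)[[3]] %||% sprintf("config_%03d", seq_len(dim(arr)[3]))
  } else {
    abort("`x` must be a list of landmark_config objects or a k x 2 x n array")
  }
  n <- dim(arr)[3]
  if (n < 2) abort("GPA needs at least 2 configurations")
  k <- dim(arr)[1]
  aligned <- array(NA_real_, dim(arr))
  cs <- numeric(n)
  for (i in seq_len(n)) {
    sc <- center_and_scale(arr[, , i], ids[i])
    aligned[, , i] <- sc$coords
    cs[i] <- sc$cs
  }
  consensus <- aligned[, , 1]
  iterations <- 0L
  converged <- FALSE
  repeat {
    iterations <- iterations + 1L
    for (i in seq_len(n)) {
      aligned[, , i] <- aligned[, , i] %*% optimal_rotation(aligned[, , i], consensus)
    }
    new_consensus <- apply(aligned, c(1, 2), mean)
    new_consensus <- center_and_scale(new_consensus, "<consensus>")$coords
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
    if (iterations >= max_iter) break
  }
  # final rotation pass so every shape is optimally aligned to the converged
  # consensus
  for (i in seq_len(n)) {
    aligned[, , i] <- aligned[, , i] %*% optimal_rotation(aligned[, , i], consensus)
  }
  dimnames(aligned) <- list(NULL, c("x", "y"), ids)
  names(cs) <- ids
  structure(
    list(
      aligned = aligned,
      consensus = consensus,
      centroid_size = cs,
      log10_centroid_size = log10(cs),
      roles = roles %||% rep("fixed", k),
      curve = curve %||% rep(NA_integer_, k),
      iterations = iterations,
      converged = converged
    ),
    class = "shape_gpa"
  )
}

#' @export
print.shape_gpa <- function(x, ...) {
  cat(sprintf(
    "<shape_gpa> %d configurations x %d points; %d iteration(s), %s\n",
    dim(x$aligned)[3], dim(x$aligned)[1], x$iterations,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' @export
tidy.shape_gpa <- function(x, ...) {
  n <- dim(x$aligned)[3]
  k <- dim(x$aligned)[1]
  ids <- dimnames(x$aligned)[[3]]
  tibble::tibble(
    specimen_id = rep(ids, each = k),
    point = rep(seq_len(k), n),
    x = as.vector(x$aligned[, 1, ]),
    y = as.vector(x$aligned[, 2, ]),
    role = rep(x$roles, n),
    curve = rep(x$curve, n)
  )
}

#' @export
glance.shape_gpa <- function(x, ...) {
  tibble::tibble(
    n = dim(x$aligned)[3], n_points = dim(x$aligned)[1],
    iterations = x$iterations, converged = x$converged
  )
}

#' Procrustes distance between two configurations
#'
#' Partial Procrustes distance: both configurations are centred and scaled to
#' unit centroid size, the second is rotated onto the first by the optimal
#' proper rotation, and the root-sum-of-squares difference is returned.
#'
#' @param a,b k x 2 coordinate matrices (or `landmark_config` objects).
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  am <- if (inherits(a, "landmark_config")) a$coords else as.matrix(a)
  bm <- if (inherits(b, "landmark_config")) b$coords else as.matrix(b)
  if (!all(dim(am) == dim(bm))) abort("Configurations must have matching dimensions")
  au <- center_and_scale(am)$coords
  bu <- center_and_scale(bm)$coords
  sqrt(sum((bu %*% optimal_rotation(bu, au) - au)^2))
}

# Matrix of specimen-wise vectorized aligned coordinates (x block then y
# block), n x 2k — the response used by shape PCA and Procrustes ANOVA.
shape_matrix <- function(g) {
  stopifnot(inherits(g, "shape_gpa"))
  n <- dim(g$aligned)[3]
  k <- dim(g$aligned)[1]
  out <- t(vapply(seq_len(n), function(i) c(g$aligned[, , i]), numeric(2 * k)))
  rownames(out) <- dimnames(g$aligned)[[3]]
  out
}
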