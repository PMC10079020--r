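#' Thin-plate-spline bending-energy matrix
#'
#' For a 2-D reference configuration, builds the thin-plate-spline system
#' `L = [[K, Q], [Q', 0]]` with kernel `U(r) = r^2 log(r^2)` (and `U(0) = 0`)
#' and affine block `Q = [1, x, y]`, and returns the upper-left k x k block
#' of `L^{-1}`. The result is the bending-energy quadratic form: for a
#' per-point displacement field `d` (one coordinate at a time),
#' `t(d) %*% B %*% d` is the TPS bending energy of that field relative to
#' the reference. `B` is symmetric positive-semidefinite with exactly three
#' (near-)zero eigenvalues spanning the affine maps, which cost no bending.
#'
#' @param reference k x 2 matrix of reference landmarks (not all collinear).
#' @return Symmetric k x k matrix.
#' @export
bending_energy_matrix <- function(reference) {
  pts <- as.matrix(reference)
  if (ncol(pts) != 2) abort("`reference` must be a k x 2 matrix")
  k <- nrow(pts)
  if (k < 4) abort("Bending energy needs at least 4 reference points")
  if (qr(cbind(1, pts))$rank < 3) {
    abort("Reference points are collinear: the TPS system is singular")
  }
  d2 <- as.matrix(stats::dist(pts))^2
  kmat <- ifelse(d2 > 0, d2 * log(d2), 0)
  q <- cbind(1, pts)
  l <- rbind(cbind(kmat, q), cbind(t(q), matrix(0, 3, 3)))
  linv <- tryCatch(solve(l), error = function(e) {
    abort("TPS system is singular for this reference configuration")
  })
  b <- linv[seq_len(k), seq_len(k), drop = FALSE]
  (b + t(b)) / 2
}

# Unit tangent directions at the semilandmarks of one configuration:
# interior semilandmarks use the chord between their two curve neighbours,
# curve-endpoint semilandmarks the chord to their single neighbour.
# Returns a (k x n_semi) pair of direction component matrices via a
# 2k x n_semi design matrix U (x block stacked over y block).
sliding_design <- function(coords, roles, curve) {
  k <- nrow(coords)
  semi_idx <- which(roles == "semi")
  u <- matrix(0, 2 * k, length(semi_idx))
  for (j in seq_along(semi_idx)) {
    i <- semi_idx[j]
    cv <- curve[i]
    members <- which(!is.na(curve) & curve == cv)
    pos <- match(i, members)
    if (length(members) < 2) {
      abort(sprintf(
        "Curve %s has a single semilandmark (point %d): no sliding neighbour",
        cv, i
      ))
    }
    nb <- if (pos == 1) {
      coords[members[2], ] - coords[members[1], ]
    } else if (pos == length(members)) {
      coords[members[pos], ] - coords[members[pos - 1], ]
    } else {
      coords[members[pos + 1], ] - coords[members[pos - 1], ]
    }
    len <- sqrt(sum(nb^2))
    if (len <= 0) abort(sprintf("Zero-length tangent chord at point %d", i))
    u[i, j] <- nb[1] / len
    u[k + i, j] <- nb[2] / len
  }
  u
}

# Bending energy of configuration y relative to reference, under the
# expanded quadratic form diag(B, B) on the stacked (x, y) displacement.
bending_energy_of <- function(y, reference, b = NULL) {
  if (is.null(b)) b <- bending_energy_matrix(reference)
  d <- c(y - reference)
  k <- nrow(reference)
  dx <- d[seq_len(k)]
  dy <- d[k + seq_len(k)]
  drop(crossprod(dx, b %*% dx) + crossprod(dy, b %*% dy))
}

# One sliding pass for a single specimen: minimize the bending energy of
# (y0 + U t) relative to the consensus over sliding amounts t along the
# tangent directions; fixed landmarks are immobile. Exact linear
# least-squares solution; a Moore-Penrose fallback handles the (rare)
# singular normal matrix, still attaining the minimum.
slide_one <- function(coords, consensus, roles, curve, b) {
  u <- sliding_design(coords, roles, curve)
  if (ncol(u) == 0) return(list(coords = coords, t = numeric(0)))
  k <- nrow(coords)
  d <- c(coords - consensus)
  b2u <- rbind(b %*% u[seq_len(k), , drop = FALSE],
               b %*% u[k + seq_len(k), , drop = FALSE])
  a <- crossprod(u, b2u)
  rhs <- -crossprod(u, rbind(
    b %*% d[seq_len(k)],
    b %*% d[k + seq_len(k)]
  ))
  t_amt <- tryCatch(solve(a, rhs), error = function(e) MASS::ginv(a) %*% rhs)
  shift <- u %*% t_amt
  list(
    coords = coords + cbind(shift[seq_len(k)], shift[k + seq_len(k)]),
    t = drop(t_amt)
  )
}

#' Slide semilandmarks by the bending-energy criterion
#'
#' Starting from a completed GPA, each specimen's semilandmarks are allowed
#' to slide along the tangent direction of their curve (the unit chord
#' between curve neighbours; endpoint semilandmarks use their single
#' neighbour) so as to minimize the thin-plate-spline bending energy of the
#' specimen relative to the current consensus. The minimization is an exact
#' linear least-squares solve per specimen, so within a cycle the energy is
#' never increased. After all specimens slide, GPA is re-run and the cycle
#' repeats (`n_cycles`, default 3; sliding against the updated consensus).
#' No bounds are imposed on sliding amounts; the maximum slide magnitude per
#' cycle is recorded.
#'
#' @param g A `shape_gpa` object whose `roles`/`curve` mark the sliders.
#' @param n_cycles Number of slide + re-GPA cycles (default 3).
#' @param tol,max_iter Passed to the interleaved [gpa] calls.
#' @return A `shape_gpa` object with an additional `sliding` element: a
#'   tibble with per-specimen, per-cycle bending energy before and after the
#'   slide (both measured against that cycle's consensus and bending-energy
#'   matrix) and the maximum absolute slide amount.
#' @export
slide_semilandmarks <- function(g, n_cycles = 3, tol = 1e-8, max_iter = 100) {
  stopifnot(inherits(g, "shape_gpa"))
  roles <- g$roles
  curve <- g$curve
  if (!any(roles == "semi")) {
    g$sliding <- tibble::tibble(
      specimen_id = character(), cycle = integer(),
      energy_before = numeric(), energy_after = numeric(),
      max_slide = numeric()
    )
    return(g)
  }
  ids <- dimnames(g$aligned)[[3]]
  cs <- g$centroid_size
  log_rows <- list()
  for (cycle in seq_len(n_cycles)) {
    consensus <- g$consensus
    b <- bending_energy_matrix(consensus)
    n <- dim(g$aligned)[3]
    slid <- g$aligned
    for (i in seq_len(n)) {
      y <- g$aligned[, , i]
      e_before <- bending_energy_of(y, consensus, b)
      res <- slide_one(y, consensus, roles, curve, b)
      e_after <- bending_energy_of(res$coords, consensus, b)
      slid[, , i] <- res$coords
      log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
        specimen_id = ids[i], cycle = cycle,
        energy_before = e_before, energy_after = e_after,
        max_slide = if (length(res$t)) max(abs(res$t)) else 0
      )
    }
    g <- gpa(slid, tol = tol, max_iter = max_iter, roles = roles, curve = curve)
  }
  g$centroid_size <- cs
  g$log10_centroid_size <- log10(cs)
  g$sliding <- dplyr::bind_rows(log_rows)
  g
}
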