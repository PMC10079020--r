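#' Landmark configuration for one specimen
#'
#' A single digitized mandible: an ordered set of planar points, each flagged
#' as a fixed (homologous) landmark or a semilandmark, with semilandmarks
#' partitioned into ordered curves along which they may slide. The conforming
#' digitization scheme has 15 fixed landmarks followed by 45 semilandmarks on
#' curves; other counts are accepted but flagged non-conforming.
#'
#' @param specimen_id Single specimen identifier.
#' @param coords Numeric matrix, one row per point, two columns (x, y).
#' @param roles Character vector, one of `"fixed"` or `"semi"` per point.
#' @param curve Integer vector, curve membership per point (`NA` for fixed
#'   landmarks). Within a curve, point order is digitization order.
#' @param scale Optional units-per-pixel scale factor already applied to
#'   `coords` (kept as metadata).
#'
#' @return An object of class `landmark_config`.
#' @export
landmark_config <- function(specimen_id, coords, roles, curve = NULL,
                            scale = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2 || !is.numeric(coords)) {
    abort("`coords` must be a numeric matrix with two columns (x, y)")
  }
  if (anyNA(coords) || any(!is.finite(coords))) {
    abort(sprintf("Non-finite coordinates for specimen %s", specimen_id))
  }
  k <- nrow(coords)
  roles <- match.arg(as.character(roles), c("fixed", "semi"), several.ok = TRUE)
  if (length(roles) != k) abort("`roles` must have one entry per point")
  if (is.null(curve)) curve <- rep(NA_integer_, k)
  curve <- as.integer(curve)
  if (length(curve) != k) abort("`curve` must have one entry per point")
  if (any(roles == "semi" & is.na(curve))) {
    abort("Every semilandmark must belong to exactly one curve")
  }
  if (any(roles == "fixed" & !is.na(curve))) {
    abort("Fixed landmarks cannot belong to a curve")
  }
  x <- structure(
    list(
      specimen_id = as.character(specimen_id),
      coords = unname(coords),
      roles = roles,
      curve = curve,
      scale = scale
    ),
    class = "landmark_config"
  )
  x$conforming <- sum(roles == "fixed") == 15L && sum(roles == "semi") == 45L
  x
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf(
    "<landmark_config> %s: %d fixed + %d semilandmarks on %d curve(s)%s\n",
    x$specimen_id, sum(x$roles == "fixed"), sum(x$roles == "semi"),
    length(unique(stats::na.omit(x$curve))),
    if (isTRUE(x$conforming)) "" else " [non-conforming]"
  ))
  invisible(x)
}

#' @export
tidy.landmark_config <- function(x, ...) {
  tibble::tibble(
    specimen_id = x$specimen_id,
    point = seq_len(nrow(x$coords)),
    x = x$coords[, 1], y = x$coords[, 2],
    role = x$roles, curve = x$curve
  )
}

#' Centroid size of a landmark configuration
#'
#' The standard geometric-morphometric size measure: the square root of the
#' summed squared distances of all points from their centroid.
#'
#' @param x A `landmark_config` or a numeric k x 2 coordinate matrix.
#' @return Positive scalar, in the units of the input coordinates.
#' @export
#' @examples
#' centroid_size(rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) # sqrt(8)
centroid_size <- function(x) {
  m <- if (inherits(x, "landmark_config")) x$coords else as.matrix(x)
  if (nrow(m) < 2) abort("Centroid size needs at least two points")
  centred <- sweep(m, 2, colMeans(m))
  cs <- sqrt(sum(centred^2))
  if (cs <= 0) abort("All points are identical: centroid size is zero")
  cs
}

# Stack a list of landmark_config (same k and roles) into a k x 2 x n array.
configs_to_array <- function(configs) {
  stopifnot(length(configs) >= 1)
  k <- nrow(configs[[1]]$coords)
  roles <- configs[[1]]$roles
  for (cfg in configs) {
    if (nrow(cfg$coords) != k || !identical(cfg$roles, roles)) {
      abort(sprintf(
        "Specimen %s has a different landmark scheme (point count or roles)",
        cfg$specimen_id
      ))
    }
  }
  arr <- array(
    unlist(lapply(configs, function(cfg) cfg$coords)),
    dim = c(k, 2, length(configs)),
    dimnames = list(NULL, c("x", "y"),
                    vapply(configs, function(cfg) cfg$specimen_id, ""))
  )
  arr
}
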