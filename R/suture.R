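#' Length ratio of a suture trace
#'
#' Suture complexity as the total traced path length divided by the straight
#' chord between the first and last vertex. A perfectly straight suture has
#' LR = 1; interdigitated sutures have LR > 1. The statistic is invariant to
#' rigid motion and uniform scaling and to polyline refinement (inserting
#' points on existing segments), so tracing units are arbitrary.
#'
#' @param vertices Numeric matrix of ordered vertices (>= 2 rows, 2 columns).
#' @return Dimensionless length ratio >= 1.
#' @export
#' @examples
#' length_ratio(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0))) # 3
length_ratio <- function(vertices) {
  xy <- as.matrix(vertices)
  if (nrow(xy) < 2 || ncol(xy) != 2) {
    abort("A trace needs at least 2 planar vertices")
  }
  chord <- sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
  if (chord <= 0) abort("degenerate chord: first and last vertex coincide")
  segs <- diff(xy)
  sum(sqrt(rowSums(segs^2))) / chord
}

#' Assemble the per-specimen length-ratio table
#'
#' Computes the length ratio of every trace and pivots to a wide table with
#' one row per specimen and one column per suture. Missing sutures are left
#' `NA` (never zero-filled); a duplicated (specimen, suture) pair is an
#' error.
#'
#' @param traces Vertex tibble as returned by [read_suture_traces]:
#'   columns `specimen_id`, `suture`, `order`, `x`, `y`.
#' @return Wide tibble: `specimen_id` plus one LR column per suture, named
#'   `lr_<suture>` (lowercase).
#' @export
suture_length_ratios <- function(traces) {
  traces <- validate_traces(traces)
  dup <- traces |>
    dplyr::count(.data$specimen_id, .data$suture, .data$order) |>
    dplyr::filter(.data$n > 1) |>
    dplyr::distinct(.data$specimen_id, .data$suture)
  if (nrow(dup)) {
    abort(sprintf("Duplicate trace(s) for: %s",
                  paste(sprintf("%s/%s", dup$specimen_id, dup$suture), collapse = ", ")))
  }
  per_trace <- traces |>
    dplyr::arrange(.data$specimen_id, .data$suture, .data$order) |>
    dplyr::group_by(.data$specimen_id, .data$suture) |>
    dplyr::summarise(lr = length_ratio(cbind(.data$x, .data$y)), .groups = "drop")
  per_trace |>
    dplyr::mutate(suture = paste0("lr_", tolower(as.character(.data$suture)))) |>
    tidyr::pivot_wider(names_from = "suture", values_from = "lr")
}
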