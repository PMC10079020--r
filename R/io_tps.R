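#' Read a TPS landmark file
#'
#' Parses the TPS dialect used by this pipeline: each configuration starts
#' with `LM=<n fixed>` followed by one `x y` line per fixed landmark; an
#' optional `CURVES=<c>` block follows, with `POINTS=<m>` headers and `m`
#' coordinate lines per curve (the semilandmarks, appended after the fixed
#' landmarks in file order); then optional `IMAGE=` (ignored), `ID=`, and
#' `SCALE=` lines. When `SCALE=` is present all coordinates are multiplied by
#' it. The stored y-axis orientation is kept as-is (no image-origin flip);
#' generalized Procrustes analysis is rotation-invariant, so the convention
#' is documented rather than consequential.
#'
#' @param path Path to a TPS file.
#' @return A list of [landmark_config] objects, one per `LM=` block.
#' @export
read_tps <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines_trim <- trimws(lines)
  i <- 1L
  n <- length(lines)
  configs <- list()
  parse_error <- function(line, msg) {
    abort(sprintf("TPS parse error at line %d: %s", line, msg))
  }
  read_coords <- function(start, count, what) {
    if (start + count - 1L > n) {
      parse_error(start, sprintf("expected %d %s coordinate line(s), file ends", count, what))
    }
    out <- matrix(NA_real_, count, 2)
    for (j in seq_len(count)) {
      ln <- lines_trim[start + j - 1L]
      xy <- suppressWarnings(as.numeric(strsplit(ln, "[[:space:]]+")[[1]]))
      if (length(xy) != 2 || anyNA(xy)) {
        parse_error(start + j - 1L,
                    sprintf("expected two numeric coordinates, got %s", dQuote(ln)))
      }
      out[j, ] <- xy
    }
    out
  }
  idx <- 0L
  while (i <= n) {
    ln <- lines_trim[i]
    if (ln == "") { i <- i + 1L; next }
    if (!grepl("^LM=", ln)) {
      parse_error(i, sprintf("expected LM= header, got %s", dQuote(ln)))
    }
    n_fixed <- suppressWarnings(as.integer(sub("^LM=", "", ln)))
    if (is.na(n_fixed)) parse_error(i, "malformed LM= header")
    if (n_fixed == 0L) parse_error(i, "LM=0: a configuration needs landmarks")
    i <- i + 1L
    fixed <- read_coords(i, n_fixed, "fixed-landmark")
    i <- i + n_fixed
    semi <- matrix(numeric(0), 0, 2)
    curve_id <- integer(0)
    id <- NULL
    scale <- NULL
    while (i <= n && !grepl("^LM=", lines_trim[i])) {
      ln <- lines_trim[i]
      if (ln == "") { i <- i + 1L; next }
      if (grepl("^CURVES=", ln)) {
        n_curves <- suppressWarnings(as.integer(sub("^CURVES=", "", ln)))
        if (is.na(n_curves) || n_curves < 0) parse_error(i, "malformed CURVES= header")
        i <- i + 1L
        for (cidx in seq_len(n_curves)) {
          if (i > n || !grepl("^POINTS=", lines_trim[i])) {
            parse_error(i, sprintf("expected POINTS= header for curve %d", cidx))
          }
          m <- suppressWarnings(as.integer(sub("^POINTS=", "", lines_trim[i])))
          if (is.na(m) || m < 1) parse_error(i, "malformed POINTS= header")
          i <- i + 1L
          pts <- read_coords(i, m, "semilandmark")
          i <- i + m
          semi <- rbind(semi, pts)
          curve_id <- c(curve_id, rep(cidx, m))
        }
      } else if (grepl("^IMAGE=", ln)) {
        i <- i + 1L
      } else if (grepl("^ID=", ln)) {
        id <- sub("^ID=", "", ln)
        i <- i + 1L
      } else if (grepl("^SCALE=", ln)) {
        scale <- suppressWarnings(as.numeric(sub("^SCALE=", "", ln)))
        if (is.na(scale) || scale <= 0) parse_error(i, "malformed SCALE= value")
        i <- i + 1L
      } else {
        parse_error(i, sprintf("unrecognized line %s", dQuote(ln)))
      }
    }
    idx <- idx + 1L
    coords <- rbind(fixed, semi)
    if (!is.null(scale)) coords <- coords * scale
    configs[[idx]] <- landmark_config(
      specimen_id = id %||% sprintf("config_%03d", idx),
      coords = coords,
      roles = c(rep("fixed", n_fixed), rep("semi", nrow(semi))),
      curve = c(rep(NA_integer_, n_fixed), curve_id),
      scale = scale
    )
  }
  configs
}

#' Write landmark configurations to a TPS file
#'
#' Emits the same dialect [read_tps] accepts, so that
#' `read_tps(write_tps(x))` reproduces every field (coordinates to the
#' 6-decimal precision written). When a configuration carries a `scale`, the
#' stored coordinates are divided by it on output and a `SCALE=` line is
#' written, mirroring the multiplication applied on read.
#'
#' @param configs List of [landmark_config] objects (may be empty).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  out <- character(0)
  fmt <- function(m) sprintf("%.6f %.6f", m[, 1], m[, 2])
  for (cfg in configs) {
    coords <- cfg$coords
    if (!is.null(cfg$scale)) coords <- coords / cfg$scale
    fixed <- cfg$roles == "fixed"
    out <- c(out, sprintf("LM=%d", sum(fixed)), fmt(coords[fixed, , drop = FALSE]))
    curves <- sort(unique(cfg$curve[!is.na(cfg$curve)]))
    if (length(curves)) {
      out <- c(out, sprintf("CURVES=%d", length(curves)))
      for (cv in curves) {
        sel <- !is.na(cfg$curve) & cfg$curve == cv
        out <- c(out, sprintf("POINTS=%d", sum(sel)), fmt(coords[sel, , drop = FALSE]))
      }
    }
    out <- c(out, sprintf("ID=%s", cfg$specimen_id))
    if (!is.null(cfg$scale)) out <- c(out, sprintf("SCALE=%s", format(cfg$scale, digits = 15)))
  }
  writeLines(out, path)
  invisible(path)
}
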