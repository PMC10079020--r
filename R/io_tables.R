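#' Read a specimen table
#'
#' Reads the per-specimen CSV with required columns `specimen_id`, `group`,
#' `sex`, and optional `body_mass_g`, `admixture_q`, `incisor_ap_mm`,
#' `incisor_ml_mm`. Enum labels are parsed case-insensitively (`"HZ Red"` and
#' `"hz_red"` both map to `HZ_RED`); missing optional fields stay `NA` and
#' are never imputed. Specimens with missing sex are retained as `UNKNOWN`.
#'
#' @param path Path to a CSV file with a header row.
#' @return A tibble, one row per specimen, with `group` and `sex` as factors.
#' @export
read_specimen_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("specimen_id", "group", "sex")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("Specimen table is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  validate_specimens(raw)
}

# Shared validation for specimen tables (read from disk or built in memory).
validate_specimens <- function(raw) {
  out <- tibble::as_tibble(raw)
  out$specimen_id <- as.character(out$specimen_id)
  if (anyDuplicated(out$specimen_id)) {
    abort(sprintf("Duplicate specimen_id(s): %s",
                  paste(unique(out$specimen_id[duplicated(out$specimen_id)]),
                        collapse = ", ")))
  }
  out$group <- parse_enum(out$group, squirrel_groups(), "squirrel group")
  sex <- normalize_label(out$sex %||% rep(NA, nrow(out)))
  sex[is.na(sex) | sex == "" | sex == "NA"] <- "UNKNOWN"
  out$sex <- parse_enum(sex, sex_levels(), "sex")
  if ("body_mass_g" %in% names(out)) {
    bm <- out$body_mass_g
    if (any(!is.na(bm) & (!is.finite(bm) | bm <= 0))) {
      abort("body_mass_g must be strictly positive where present")
    }
  }
  if ("admixture_q" %in% names(out)) {
    q <- out$admixture_q
    if (any(!is.na(q) & (q < 0 | q > 1))) {
      abort("admixture_q must lie in [0, 1]")
    }
  } else {
    out$admixture_q <- NA_real_
  }
  hyb_no_q <- out$group == "HYBRID" & is.na(out$admixture_q)
  if (any(hyb_no_q)) {
    abort(sprintf("HYBRID specimens must carry admixture_q: %s",
                  paste(out$specimen_id[hyb_no_q], collapse = ", ")))
  }
  for (col in c("incisor_ap_mm", "incisor_ml_mm")) {
    if (col %in% names(out)) {
      v <- out[[col]]
      if (any(!is.na(v) & (!is.finite(v) | v <= 0))) {
        abort(sprintf("%s must be strictly positive where present", col))
      }
    }
  }
  out
}

#' Read suture traces
#'
#' Reads traced suture paths either from a long CSV (columns `specimen_id`,
#' `suture`, `order`, `x`, `y`; vertices sorted by `order`) or from a minimal
#' SVG subset in which each `<path>` element has an `id` of the form
#' `"<specimen_id>__<suture>"` and a `d` attribute using only absolute
#' `M`/`L`/`H`/`V` commands. Curved or relative commands (`C`, `Q`, `A`,
#' `Z`, lowercase) raise an explicit "unsupported path command" error rather
#' than being silently approximated.
#'
#' @param path Path to a CSV or SVG file.
#' @param format `"csv"` or `"svg"`.
#' @return A tibble of vertices with columns `specimen_id`, `suture`
#'   (factor), `order`, `x`, `y` — one ordered polyline per
#'   (specimen, suture) pair.
#' @export
read_suture_traces <- function(path, format = c("csv", "svg")) {
  format <- match.arg(format)
  traces <- switch(format,
    csv = read_suture_csv(path),
    svg = read_suture_svg(path)
  )
  validate_traces(traces)
}

read_suture_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("specimen_id", "suture", "order", "x", "y")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("Suture CSV is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  raw |>
    dplyr::mutate(specimen_id = as.character(.data$specimen_id)) |>
    dplyr::arrange(.data$specimen_id, .data$suture, .data$order)
}

read_suture_svg <- function(path) {
  doc <- xml2::read_xml(path)
  paths <- xml2::xml_find_all(doc, ".//*[local-name()='path']")
  if (!length(paths)) abort("SVG contains no <path> elements")
  rows <- purrr::map_dfr(paths, function(node) {
    id <- xml2::xml_attr(node, "id")
    if (is.na(id) || !grepl("__", id, fixed = TRUE)) {
      abort("Each SVG <path> needs an id of the form '<specimen_id>__<suture>'")
    }
    parts <- strsplit(id, "__", fixed = TRUE)[[1]]
    verts <- parse_svg_path(xml2::xml_attr(node, "d"))
    tibble::tibble(
      specimen_id = parts[1], suture = parts[2],
      order = seq_len(nrow(verts)), x = verts[, 1], y = verts[, 2]
    )
  })
  rows
}

# Parse an SVG path `d` string restricted to absolute M/L/H/V commands.
parse_svg_path <- function(d) {
  if (is.na(d) || !nzchar(trimws(d))) abort("Empty SVG path data")
  tokens <- regmatches(d, gregexpr("[A-Za-z]|-?[0-9.]+(?:[eE][+-]?[0-9]+)?", d))[[1]]
  pts <- matrix(numeric(0), 0, 2)
  cur <- c(NA_real_, NA_real_)
  cmd <- NULL
  i <- 1L
  take_num <- function(i) {
    if (i > length(tokens) || grepl("^[A-Za-z]$", tokens[i])) {
      abort("Malformed SVG path: expected a number")
    }
    as.numeric(tokens[i])
  }
  while (i <= length(tokens)) {
    tok <- tokens[i]
    if (grepl("^[A-Za-z]$", tok)) {
      if (!tok %in% c("M", "L", "H", "V")) {
        abort(sprintf(
          "unsupported path command '%s': only absolute M/L/H/V are accepted; sample curves to polylines upstream",
          tok
        ))
      }
      cmd <- tok
      i <- i + 1L
      next
    }
    if (is.null(cmd)) abort("Malformed SVG path: coordinates before any command")
    if (cmd %in% c("M", "L")) {
      x <- take_num(i); y <- take_num(i + 1L); i <- i + 2L
      cur <- c(x, y)
      if (cmd == "M") cmd <- "L" # subsequent pairs are implicit linetos
    } else if (cmd == "H") {
      cur[1] <- take_num(i); i <- i + 1L
    } else if (cmd == "V") {
      cur[2] <- take_num(i); i <- i + 1L
    }
    if (anyNA(cur)) abort("Malformed SVG path: H/V before an initial M")
    pts <- rbind(pts, cur)
  }
  if (nrow(pts) < 2) abort("SVG path has fewer than 2 vertices")
  unname(pts)
}

validate_traces <- function(traces) {
  traces$suture <- parse_enum(traces$suture, suture_names(), "suture")
  split_tr <- split(traces, list(traces$specimen_id, traces$suture), drop = TRUE)
  for (tr in split_tr) {
    key <- sprintf("%s/%s", tr$specimen_id[1], tr$suture[1])
    if (nrow(tr) < 2) abort(sprintf("Trace %s has fewer than 2 vertices", key))
    xy <- cbind(tr$x, tr$y)
    if (all(xy[, 1] == xy[1, 1] & xy[, 2] == xy[1, 2])) {
      abort(sprintf("Trace %s has all vertices identical", key))
    }
    if (all(xy[nrow(xy), ] == xy[1, ])) {
      abort(sprintf("Trace %s has coincident first and last vertices", key))
    }
  }
  tibble::as_tibble(traces)
}
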