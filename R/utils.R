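#' Squirrel group vocabulary
#'
#' The five genotype/geography classes used throughout the pipeline, ordered
#' from the Douglas squirrel side of the transect to the red squirrel side:
#' allopatric Douglas squirrels, hybrid-zone Douglas squirrels, hybrids,
#' hybrid-zone red squirrels, and allopatric red squirrels.
#'
#' @return Character vector of the five group labels.
#' @export
#' @examples
#' squirrel_groups()
squirrel_groups <- function() {
  c("ALLO_DOUG", "HZ_DOUG", "HYBRID", "HZ_RED", "ALLO_RED")
}

#' Cranial suture vocabulary
#'
#' The five dorsal cranial sutures traced for the complexity analysis.
#'
#' @return Character vector of the five suture labels.
#' @export
suture_names <- function() {
  c("NASOFRONTAL", "PREMAXILLOFRONTAL", "MAXILLOFRONTAL", "CORONAL", "SAGITTAL")
}

#' Sex vocabulary
#' @return Character vector of sex labels.
#' @export
sex_levels <- function() c("F", "M", "UNKNOWN")

# Normalise a free-text enum label: trim, uppercase, spaces/hyphens -> "_".
normalize_label <- function(x) {
  gsub("[ -]+", "_", toupper(trimws(as.character(x))))
}

# Parse labels against a closed vocabulary; error listing offenders.
parse_enum <- function(x, levels, what, allow_na = FALSE) {
  lab <- normalize_label(x)
  lab[lab %in% c("", "NA")] <- NA_character_
  bad <- !is.na(lab) & !(lab %in% levels)
  if (any(bad)) {
    abort(sprintf(
      "Unknown %s label(s): %s (expected one of %s)",
      what, paste(unique(lab[bad]), collapse = ", "),
      paste(levels, collapse = ", ")
    ))
  }
  if (!allow_na && anyNA(lab)) {
    abort(sprintf("Missing %s label(s) are not allowed here", what))
  }
  factor(lab, levels = levels)
}

# Evaluate code under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so pipeline stages do not interfere.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a per-stage child seed from a master seed; stays below 2^31.
derive_seed <- function(seed, stage_index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) %% 1000003) * 1009 + stage_index * 7919) %% 2147483647L
}

# Consistent positive-finite check for measurement columns.
assert_positive <- function(x, what) {
  if (any(!is.finite(x) | x <= 0)) {
    abort(sprintf("%s must be strictly positive and finite", what))
  }
  invisible(x)
}
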