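#' Univariate ANCOVA/ANOVA with sequential F-tests
#'
#' Ordinary-least-squares fit of a single trait with sequential (Type I)
#' parametric F-tests in the supplied term order, plus least-squares
#' (covariate-adjusted) group means. Parametric p-values are used for
#' univariate traits, matching mainstream ANCOVA practice; permutation
#' inference is reserved for shape data ([procrustes_anova]). Rows with
#' missing values in the named columns are dropped; empty factor levels are
#' dropped with a warning.
#'
#' @param data Tibble with the response and predictor columns.
#' @param response Name of the response column.
#' @param terms Ordered character vector of model terms (default
#'   `c("group", "sex")`, the bite-force design; use
#'   `c("group", "sex", "size")` for the suture PC design).
#' @return A `trait_ancova` object; `tidy()` gives the sequential ANOVA
#'   table (`term`, `df`, `ss`, `ms`, `rsq`, `f`, `p`),
#'   `adjusted_means()` the least-squares group means, and
#'   [posthoc_pairs()] the pairwise contrasts.
#' @export
trait_ancova <- function(data, response, terms = c("group", "sex")) {
  data <- tibble::as_tibble(data)
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  missing_cols <- setdiff(c(response, vars), names(data))
  if (length(missing_cols)) {
    abort(sprintf("trait_ancova() needs column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  use <- complete.cases(data[c(response, vars)])
  df <- data[use, , drop = FALSE]
  if ("sex" %in% vars && any(df$sex == "UNKNOWN")) {
    n_unk <- sum(df$sex == "UNKNOWN")
    inform(sprintf(
      "Excluding %d specimen(s) of unknown sex from the sex-adjusted model",
      n_unk
    ))
    df <- df[df$sex != "UNKNOWN", , drop = FALSE]
  }
  for (v in vars) {
    if (is.factor(df[[v]])) df[[v]] <- droplevels(df[[v]])
  }
  if ("group" %in% vars && length(unique(df$group)) < 2) {
    abort("ANCOVA needs at least 2 groups with data")
  }
  fml <- reformulate(terms, response = response)
  fit <- lm(fml, data = df)
  a <- anova(fit)
  ss_total <- sum(a$`Sum Sq`)
  tab <- tibble::tibble(
    term = rownames(a),
    df = a$Df,
    ss = a$`Sum Sq`,
    ms = a$`Mean Sq`,
    rsq = a$`Sum Sq` / ss_total,
    f = a$`F value`,
    p = a$`Pr(>F)`
  )
  structure(
    list(fit = fit, table = tab, response = response, terms = terms,
         n = nrow(df), data = df),
    class = "trait_ancova"
  )
}

#' @export
print.trait_ancova <- function(x, ...) {
  cat(sprintf("<trait_ancova> %s ~ %s (n = %d)\n",
              x$response, paste(x$terms, collapse = " + "), x$n))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @export
tidy.trait_ancova <- function(x, ...) x$table

#' @export
glance.trait_ancova <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r_squared = s$r.squared, sigma = s$sigma, n = x$n)
}

#' Covariate-adjusted group means
#'
#' Least-squares means of the grouping factor at the covariate means,
#' computed with \pkg{emmeans}.
#'
#' @param x A `trait_ancova` fit.
#' @param factor Name of the factor to summarise (default `"group"`).
#' @return Tibble with the factor level, adjusted mean, SE, and 95% CI.
#' @export
adjusted_means <- function(x, factor = "group") {
  stopifnot(inherits(x, "trait_ancova"))
  em <- emmeans::emmeans(x$fit, specs = factor, data = x$data)
  out <- tibble::as_tibble(as.data.frame(em))
  names(out)[1] <- factor
  dplyr::rename(out, adjusted_mean = "emmean")
}

#' Post-hoc pairwise comparisons of adjusted means
#'
#' t-tests on all pairwise differences of covariate-adjusted group means,
#' on the residual degrees of freedom of the ANCOVA fit, with multiplicity
#' correction (Holm by default; Tukey-Kramer and Bonferroni offered).
#'
#' @param x A `trait_ancova` fit.
#' @param adjust `"holm"`, `"tukey"`, `"bonferroni"`, or `"none"`.
#' @param factor Name of the factor to contrast (default `"group"`).
#' @return Tibble with `group_a`, `group_b`, `estimate` (difference of
#'   adjusted means), `se`, `t`, `p_adj`.
#' @export
posthoc_pairs <- function(x, adjust = c("holm", "tukey", "bonferroni", "none"),
                          factor = "group") {
  stopifnot(inherits(x, "trait_ancova"))
  adjust <- match.arg(adjust)
  em <- emmeans::emmeans(x$fit, specs = factor, data = x$data)
  pr <- as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = adjust))
  sides <- strsplit(as.character(pr$contrast), " - ", fixed = TRUE)
  tibble::tibble(
    group_a = gsub("[()]", "", vapply(sides, `[`, "", 1)),
    group_b = gsub("[()]", "", vapply(sides, `[`, "", 2)),
    estimate = pr$estimate,
    se = pr$SE,
    t = pr$t.ratio,
    p_adj = pr$p.value
  )
}

#' Genotype class from an admixture proportion
#'
#' Thresholds follow the standard assignment for this hybrid zone, boundary
#' values inclusive: pure red squirrel at Q >= 0.90, pure Douglas squirrel
#' at Q <= 0.10, hybrid strictly between.
#'
#' @param q Admixture proportion(s) in \[0, 1\] (fraction of the genome
#'   assigned to the red squirrel population).
#' @return Factor with levels `PURE_DOUGLAS`, `HYBRID`, `PURE_RED`.
#' @export
#' @examples
#' classify_admixture(c(0.10, 0.5, 0.90))
classify_admixture <- function(q) {
  if (any(!is.na(q) & (q < 0 | q > 1))) abort("admixture q must lie in [0, 1]")
  out <- rep(NA_character_, length(q))
  out[!is.na(q) & q >= 0.90] <- "PURE_RED"
  out[!is.na(q) & q <= 0.10] <- "PURE_DOUGLAS"
  out[!is.na(q) & q > 0.10 & q < 0.90] <- "HYBRID"
  factor(out, levels = c("PURE_DOUGLAS", "HYBRID", "PURE_RED"))
}

#' Trait-on-admixture regression for hybrids
#'
#' Simple least-squares regression of a trait on the admixture proportion Q,
#' restricted to hybrid individuals (0.10 < Q < 0.90), with the parametric
#' F-test p-value. Used to test for additive genetic (dosage) effects of
#' ancestry on each ecomorphological trait.
#'
#' @param data Tibble with the trait column and `admixture_q`.
#' @param trait Name of the trait column.
#' @param q Name of the admixture column (default `"admixture_q"`).
#' @return One-row tibble: `trait`, `slope`, `intercept`, `r_squared`, `p`,
#'   `n`.
#' @export
admixture_regression <- function(data, trait, q = "admixture_q") {
  data <- tibble::as_tibble(data)
  if (!all(c(trait, q) %in% names(data))) {
    abort(sprintf("admixture_regression() needs columns %s and %s", trait, q))
  }
  qv <- data[[q]]
  keep <- !is.na(qv) & !is.na(data[[trait]]) &
    classify_admixture(qv) == "HYBRID"
  keep[is.na(keep)] <- FALSE
  yv <- data[[trait]][keep]
  qv <- qv[keep]
  if (length(qv) < 3) abort("Admixture regression needs at least 3 hybrids")
  if (var(qv) == 0) abort("Constant admixture scores: regression is singular")
  fit <- lm(yv ~ qv)
  s <- summary(fit)
  fstat <- s$fstatistic
  tibble::tibble(
    trait = trait,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = s$r.squared,
    p = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    n = length(qv)
  )
}

#' Normal-theory summary of hybrid admixture scores
#'
#' Mean hybrid Q with its 95% confidence half-width (t-based), plus the
#' observed minimum and maximum.
#'
#' @param q Admixture proportions (hybrids are selected internally).
#' @return One-row tibble: `n`, `mean_q`, `ci_halfwidth`, `min_q`, `max_q`.
#' @export
hybrid_q_summary <- function(q) {
  q <- q[!is.na(q) & classify_admixture(q) == "HYBRID"]
  q <- q[!is.na(q)]
  if (length(q) < 2) abort("Need at least 2 hybrid Q values")
  n <- length(q)
  half <- stats::qt(0.975, n - 1) * sd(q) / sqrt(n)
  tibble::tibble(
    n = n, mean_q = mean(q), ci_halfwidth = half,
    min_q = min(q), max_q = max(q)
  )
}
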