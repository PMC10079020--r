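#' Run the full craniodental analysis pipeline
#'
#' Executes the analysis sequence on a conforming dataset: bite-force
#' quotients with group ANCOVA (sex covariate) and post-hoc contrasts;
#' suture length ratios with per-suture ANCOVAs and a five-suture PCA whose
#' leading PC scores get their own ANCOVAs; geometric morphometrics (GPA,
#' bending-energy sliding, PCA with Monte Carlo axis test, Procrustes ANOVA
#' with terms group, sex, size, group:size, sex:size, centroid-size ANOVA,
#' pairwise shape contrasts); Bayesian morphospace overlap on (PC1, PC2,
#' log10 centroid size); and admixture-trait regressions for hybrids. One
#' master seed is expanded into independent per-stage seeds, so disabling a
#' stage does not shift another stage's results; every stochastic output
#' records its seed in `parameters`.
#'
#' @param dataset A `squirrel_dataset` (from [generate_dataset]) or a list
#'   with elements `specimens`, `sutures`, `landmarks` read via the
#'   [read_specimen_table], [read_suture_traces], [read_tps] readers.
#' @param stages Character subset of
#'   `c("biteforce", "suture", "shape", "overlap", "admixture")`. The
#'   overlap and admixture stages draw on the shape stage, which is run
#'   (but not reported) if they need it.
#' @param n_perm Permutations for the shape permutation tests.
#' @param n_posterior,n_mc,alpha Overlap-stage settings (see
#'   [morphospace_overlap]).
#' @param posthoc_adjust Multiplicity correction for post-hoc contrasts.
#' @param seed Master seed (mandatory: every stochastic stage is seeded).
#' @return A `squirrel_report` list with one element per stage plus
#'   `parameters`.
#' @export
run_squirrel_analysis <- function(dataset,
                                  stages = c("biteforce", "suture", "shape",
                                             "overlap", "admixture"),
                                  n_perm = 999, n_posterior = 3000,
                                  n_mc = 10000, alpha = 0.95,
                                  posthoc_adjust = "holm", seed) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is mandatory: every stochastic stage must be reproducible")
  }
  stages <- match.arg(stages, several.ok = TRUE)
  specimens <- validate_specimens(dataset$specimens)
  report <- list()
  stage_seeds <- list(
    suture_pca = derive_seed(seed, 1), shape_axes = derive_seed(seed, 2),
    proc_anova = derive_seed(seed, 3), shape_pairs = derive_seed(seed, 4),
    overlap = derive_seed(seed, 5)
  )
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", stage, conditionMessage(e)))
    })
  }
  need_shape <- any(c("shape", "overlap") %in% stages)

  if ("biteforce" %in% stages) {
    report$biteforce <- run_stage("biteforce", {
      fit <- fit_bfq(specimens)
      tab <- tidy(fit)
      anc <- trait_ancova(tab, "bfq", c("group", "sex"))
      list(
        fit = fit,
        ancova = anc,
        adjusted_means = adjusted_means(anc),
        posthoc = posthoc_pairs(anc, adjust = posthoc_adjust)
      )
    })
  }

  if ("suture" %in% stages || "admixture" %in% stages) {
    report$suture <- run_stage("suture", {
      lr <- suture_length_ratios(dataset$sutures)
      lr_joined <- dplyr::left_join(specimens, lr, by = "specimen_id")
      lr_cols <- grep("^lr_", names(lr_joined), value = TRUE)
      per_suture <- lapply(setNames(lr_cols, lr_cols), function(col) {
        anc <- trait_ancova(lr_joined, col, c("group", "sex"))
        list(ancova = anc,
             posthoc = if (any(tidy(anc)$p[tidy(anc)$term == "group"] < 0.05,
                              na.rm = TRUE)) {
               posthoc_pairs(anc, adjust = posthoc_adjust)
             })
      })
      pca <- morph_pca(lr_joined[c("specimen_id", lr_cols)])
      scores <- tidy(pca)
      score_data <- dplyr::inner_join(specimens, scores, by = "specimen_id")
      pc_ancova <- lapply(c(PC1 = "PC1", PC2 = "PC2"), function(pc) {
        if (!pc %in% names(score_data)) return(NULL)
        trait_ancova(score_data, pc, c("group", "sex"))
      })
      pca_axes <- axis_significance(
        lr_joined[stats::complete.cases(lr_joined[lr_cols]), lr_cols],
        n_perm = n_perm, seed = stage_seeds$suture_pca
      )
      list(length_ratios = lr, pca = pca, pca_axes = pca_axes,
           per_suture = per_suture, pc_ancova = pc_ancova)
    })
  }

  shape <- NULL
  if (need_shape || "admixture" %in% stages) {
    shape <- run_stage("shape", {
      g <- gpa(dataset$landmarks)
      g <- slide_semilandmarks(g)
      y <- shape_matrix(g)
      pca <- morph_pca(y)
      axes <- axis_significance(y, n_perm = min(n_perm, 499),
                                seed = stage_seeds$shape_axes)
      meta <- specimens[match(rownames(y), specimens$specimen_id), ]
      meta$size <- g$log10_centroid_size[rownames(y)]
      scores <- tidy(pca)
      model_data <- dplyr::inner_join(meta, scores, by = "specimen_id")
      complete <- !is.na(model_data$size) & model_data$sex != "UNKNOWN"
      model_data <- droplevels(model_data[complete, , drop = FALSE])
      resp <- as.matrix(model_data[c("PC1", "PC2")])
      panova <- procrustes_anova(
        resp, model_data,
        terms = c("group", "sex", "size", "group:size", "sex:size"),
        n_perm = n_perm, seed = stage_seeds$proc_anova
      )
      size_anova <- trait_ancova(model_data, "size", c("group"))
      size_posthoc <- posthoc_pairs(size_anova, adjust = posthoc_adjust)
      pairwise <- pairwise_groups(resp, model_data$group,
                                  adjust = posthoc_adjust, n_perm = n_perm,
                                  seed = stage_seeds$shape_pairs)
      list(gpa = g, pca = pca, axes = axes, model_data = model_data,
           procrustes_anova = panova, size_anova = size_anova,
           size_posthoc = size_posthoc, pairwise = pairwise)
    })
  }
  if ("shape" %in% stages) report$shape <- shape

  if ("overlap" %in% stages) {
    report$overlap <- run_stage("overlap", {
      morphospace_overlap(
        shape$model_data, traits = c("PC1", "PC2", "size"),
        group = "group", alpha = alpha, n_posterior = n_posterior,
        n_mc = n_mc, seed = stage_seeds$overlap
      )
    })
  }

  if ("admixture" %in% stages) {
    report$admixture <- run_stage("admixture", {
      traits <- specimens["specimen_id"]
      traits$admixture_q <- specimens$admixture_q
      if (!is.null(report$biteforce)) {
        traits <- dplyr::left_join(
          traits, tidy(report$biteforce$fit)[c("specimen_id", "bfq")],
          by = "specimen_id")
      }
      if (!is.null(report$suture)) {
        traits <- dplyr::left_join(traits, report$suture$length_ratios,
                                   by = "specimen_id")
      }
      if (!is.null(shape)) {
        traits <- dplyr::left_join(
          traits,
          shape$model_data[c("specimen_id", "PC1", "size")],
          by = "specimen_id")
      }
      trait_cols <- setdiff(names(traits), c("specimen_id", "admixture_q"))
      regressions <- dplyr::bind_rows(
        lapply(trait_cols, function(tr) admixture_regression(traits, tr))
      )
      list(regressions = regressions,
           q_summary = hybrid_q_summary(specimens$admixture_q))
    })
  }

  report$parameters <- list(
    stages = stages, n_perm = n_perm, n_posterior = n_posterior,
    n_mc = n_mc, alpha = alpha, posthoc_adjust = posthoc_adjust,
    seed = seed, stage_seeds = stage_seeds,
    n_specimens = nrow(specimens)
  )
  structure(report, class = "squirrel_report")
}

#' @export
print.squirrel_report <- function(x, ...) {
  cat("<squirrel_report>\n")
  cat(sprintf("  stages: %s\n", paste(x$parameters$stages, collapse = ", ")))
  cat(sprintf("  n = %d specimens, seed = %s\n",
              x$parameters$n_specimens, x$parameters$seed))
  if (!is.null(x$biteforce)) {
    gp <- tidy(x$biteforce$ancova)
    grow <- gp[gp$term == "group", ]
    cat(sprintf("  BFQ group ANCOVA: F = %.2f, p = %.4g\n", grow$f, grow$p))
  }
  if (!is.null(x$shape)) {
    pr <- tidy(x$shape$procrustes_anova)
    grow <- pr[pr$term == "group", ]
    cat(sprintf("  Procrustes ANOVA group: F = %.2f, p = %.4g\n",
                grow$f, grow$p))
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Serializes every tabular result of a [run_squirrel_analysis] report as a
#' CSV and writes a `manifest.json` listing every emitted file together
#' with the parameters and seeds that produced it.
#'
#' @param report A `squirrel_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "squirrel_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(dir, name)
    readr::write_csv(tibble::as_tibble(df), path)
    files <<- c(files, name)
  }
  if (!is.null(report$biteforce)) {
    emit(tidy(report$biteforce$fit), "bfq_specimens.csv")
    emit(tidy(report$biteforce$ancova), "bfq_ancova.csv")
    emit(report$biteforce$posthoc, "bfq_posthoc.csv")
  }
  if (!is.null(report$suture)) {
    emit(report$suture$length_ratios, "suture_lr.csv")
    emit(glance(report$suture$pca), "suture_pca_variance.csv")
    emit(report$suture$pca_axes, "suture_pca_axes.csv")
  }
  if (!is.null(report$shape)) {
    anova_tab <- tidy(report$shape$procrustes_anova)
    names(anova_tab) <- c("term", "Df", "SS", "MS", "Rsq", "F", "Z", "P")
    emit(anova_tab, "procrustes_anova.csv")
    emit(tidy(report$shape$pca), "shape_pc_scores.csv")
    emit(report$shape$axes, "shape_pca_axes.csv")
    emit(report$shape$pairwise, "shape_pairwise.csv")
    emit(tidy(report$shape$size_anova), "centroid_size_anova.csv")
  }
  if (!is.null(report$overlap)) {
    emit(tidy(report$overlap), "overlap_summary.csv")
  }
  if (!is.null(report$admixture)) {
    emit(report$admixture$regressions, "admixture_regressions.csv")
    emit(report$admixture$q_summary, "hybrid_q_summary.csv")
  }
  manifest <- list(
    parameters = report$parameters,
    files = files
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
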