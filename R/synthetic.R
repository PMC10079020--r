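#' Deterministic mandible landmark template
#'
#' A mandible-like 2-D outline in lateral view with the conforming
#' digitization scheme: 15 fixed landmarks at salient loci (incisor
#' alveolus, diastema, tooth row ends, coronoid, condylar and angular
#' processes, ventral border) and 45 semilandmarks on three ordered curves
#' (ventral border, posterior margin, coronoid-sigmoid arc), sampled from
#' interpolating splines. Units are mm; mandible length is about 28 mm. The
#' template is topologically plausible, not an anatomical reconstruction.
#'
#' @return A [landmark_config] with 15 fixed + 45 semilandmarks.
#' @export
fixture_template <- function() {
  lm_fixed <- rbind(
    c(0.0, 5.0),   # anterior tip of incisor alveolus
    c(1.5, 3.5),   # ventral incisor base / symphysis
    c(6.0, 4.8),   # deepest point of diastema
    c(10.0, 6.0),  # anterior end of cheek-tooth row
    c(16.0, 6.5),  # posterior end of cheek-tooth row
    c(18.5, 9.0),  # anterior base of coronoid process
    c(21.0, 14.0), # coronoid tip
    c(22.5, 10.5), # deepest point of sigmoid notch
    c(25.0, 12.0), # anterior condyle
    c(27.0, 12.5), # posterior condyle tip
    c(26.5, 10.0), # ventral condyle base
    c(27.5, 5.5),  # posterior tip of angular process
    c(24.0, 2.5),  # ventral-most point of angular process
    c(14.0, 1.5),  # ventral corpus midpoint
    c(4.0, 2.5)    # ventral symphysis base
  )
  sample_curve <- function(ctrl, m) {
    chord <- c(0, cumsum(sqrt(rowSums(diff(ctrl)^2))))
    tt <- chord / max(chord)
    fx <- splinefun(tt, ctrl[, 1], method = "natural")
    fy <- splinefun(tt, ctrl[, 2], method = "natural")
    ts <- seq(0, 1, length.out = m + 2)[2:(m + 1)]
    cbind(fx(ts), fy(ts))
  }
  curve1 <- sample_curve(rbind( # ventral border, incisor base -> angular
    c(1.5, 3.5), c(4.0, 2.5), c(8.0, 1.8), c(14.0, 1.5),
    c(19.0, 1.7), c(24.0, 2.5)
  ), 15)
  curve2 <- sample_curve(rbind( # posterior margin, condyle base -> angular tip
    c(26.5, 10.0), c(27.2, 8.5), c(27.6, 7.0), c(27.5, 5.5)
  ), 15)
  curve3 <- sample_curve(rbind( # coronoid-sigmoid arc, coronoid base -> condyle
    c(18.5, 9.0), c(20.2, 12.5), c(21.0, 14.0), c(21.8, 12.5),
    c(22.5, 10.5), c(23.5, 11.0), c(25.0, 12.0)
  ), 15)
  landmark_config(
    specimen_id = "template",
    coords = rbind(lm_fixed, curve1, curve2, curve3),
    roles = c(rep("fixed", 15), rep("semi", 45)),
    curve = c(rep(NA_integer_, 15), rep(1L, 15), rep(2L, 15), rep(3L, 15))
  )
}

# Default per-group, per-suture target length ratios (rows = groups, cols =
# sutures). Red squirrels get the more interdigitated premaxillofrontal,
# maxillofrontal and sagittal sutures; nasofrontal and coronal are flat
# across groups; hybrids sit near hybrid-zone red squirrels.
default_lr_means <- function() {
  m <- rbind(
    ALLO_DOUG = c(1.60, 1.80, 1.70, 2.00, 2.20),
    HZ_DOUG   = c(1.60, 1.80, 1.70, 2.00, 2.20),
    HYBRID    = c(1.60, 2.05, 1.85, 2.00, 2.55),
    HZ_RED    = c(1.60, 2.10, 1.90, 2.00, 2.60),
    ALLO_RED  = c(1.60, 2.15, 1.95, 2.00, 2.70)
  )
  colnames(m) <- c("NASOFRONTAL", "PREMAXILLOFRONTAL", "MAXILLOFRONTAL",
                   "CORONAL", "SAGITTAL")
  m
}

#' Synthetic-dataset generator configuration
#'
#' Defaults encode the study conditions the pipeline expects: five groups
#' with the field sample sizes (14, 10, 19, 13, 14), bite-force offsets
#' ordered allopatric red > hybrid-zone red > hybrids > allopatric Douglas >
#' hybrid-zone Douglas (red squirrels bite harder; hybrid-zone populations
#' weaker than allopatric conspecifics; hybrids closest to hybrid-zone red
#' squirrels), greater suture complexity on the red squirrel side for the
#' premaxillofrontal, maxillofrontal and sagittal sutures, Douglas squirrels
#' smaller than red squirrels with hybrid-zone Douglas squirrels enlarged,
#' and hybrid admixture proportions drawn from a Beta distribution on the
#' open interval (0.10, 0.90). All effects are configuration-driven; setting
#' them to zero yields a null generator for calibration tests.
#'
#' @param n_per_group Named counts for the five groups.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @param group_bfq_offsets Additive group shifts on log10 bite force
#'   (log10 Newtons).
#' @param bf_noise_sd Residual sd of log10 bite force.
#' @param mass_mean,mass_sd Body-mass distribution per group (grams).
#' @param incisor_aspect Medio-lateral width as a fraction of
#'   antero-posterior length.
#' @param lr_means 5 x 5 matrix of target length ratios (groups x sutures),
#'   all >= 1.
#' @param lr_noise_sd Per-trace sd around the target LR.
#' @param shape_effect_scale Procrustes-distance magnitude of each group's
#'   mean-shape displacement from the template.
#' @param landmark_noise_sd Per-coordinate digitization noise in unit
#'   centroid-size shape space.
#' @param allometry_slope Procrustes magnitude of shape change per unit
#'   log10 centroid size.
#' @param size_means Mean mandible centroid size per group (mm).
#' @param size_sd_log10 sd of log10 centroid size within groups.
#' @param sex_effect_bfq Additive log10-bite-force shift for males.
#' @param q_beta_params Beta shape parameters for hybrid admixture Q.
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    n_per_group = c(ALLO_DOUG = 14, HZ_DOUG = 10, HYBRID = 19,
                    HZ_RED = 13, ALLO_RED = 14),
    seed = 1L,
    group_bfq_offsets = c(ALLO_DOUG = -0.045, HZ_DOUG = -0.075,
                          HYBRID = 0.015, HZ_RED = 0.035, ALLO_RED = 0.070),
    bf_noise_sd = 0.03,
    mass_mean = c(ALLO_DOUG = 225, HZ_DOUG = 230, HYBRID = 240,
                  HZ_RED = 240, ALLO_RED = 250),
    mass_sd = 18,
    incisor_aspect = 0.6,
    lr_means = default_lr_means(),
    lr_noise_sd = 0.05,
    shape_effect_scale = 0.02,
    landmark_noise_sd = 0.003,
    allometry_slope = 0.4,
    size_means = c(ALLO_DOUG = 24.5, HZ_DOUG = 26.0, HYBRID = 26.5,
                   HZ_RED = 26.5, ALLO_RED = 27.0),
    size_sd_log10 = 0.025,
    sex_effect_bfq = 0.01,
    q_beta_params = c(2, 2)) {
  groups <- squirrel_groups()
  n_per_group <- n_per_group[groups]
  if (anyNA(n_per_group) || any(n_per_group < 2)) {
    abort("n_per_group must name all five groups with counts >= 2")
  }
  lr_means <- as.matrix(lr_means)[groups, suture_names()]
  if (any(lr_means < 1)) {
    abort("Unattainable LR target: every target length ratio must be >= 1")
  }
  if (any(c(bf_noise_sd, lr_noise_sd, landmark_noise_sd, mass_sd,
            size_sd_log10) < 0)) {
    abort("All noise standard deviations must be >= 0")
  }
  structure(
    list(
      n_per_group = n_per_group, seed = as.integer(seed),
      group_bfq_offsets = group_bfq_offsets[groups],
      bf_noise_sd = bf_noise_sd,
      mass_mean = mass_mean[groups], mass_sd = mass_sd,
      incisor_aspect = incisor_aspect,
      lr_means = lr_means, lr_noise_sd = lr_noise_sd,
      shape_effect_scale = shape_effect_scale,
      landmark_noise_sd = landmark_noise_sd,
      allometry_slope = allometry_slope,
      size_means = size_means[groups], size_sd_log10 = size_sd_log10,
      sex_effect_bfq = sex_effect_bfq,
      q_beta_params = q_beta_params,
      calibration = c(slope = 0.566, intercept = 1.432),
      allometry_reference = bfq_reference_coefficients()[c("slope", "intercept")]
    ),
    class = "generator_config"
  )
}

# Build a sinusoidal suture polyline on a straight chord whose measured
# length ratio hits `target` within 1e-3 (solved numerically on the
# amplitude; exact polyline arithmetic, no arc-length approximation).
make_suture_trace <- function(target, chord_len = 10, n_vertices = 161,
                              cycles = 6) {
  if (target < 1) abort("Unattainable LR target (< 1)")
  xs <- seq(0, chord_len, length.out = n_vertices)
  poly <- function(a) cbind(xs, a * sin(2 * pi * cycles * xs / chord_len))
  if (target < 1 + 1e-9) return(poly(0))
  f <- function(a) length_ratio(poly(a)) - target
  upper <- chord_len
  while (f(upper) < 0) upper <- upper * 2
  a_star <- uniroot(f, c(0, upper), tol = 1e-10)$root
  poly(a_star)
}

# Smooth group/allometry displacement fields on the unit-size template.
# Raw smooth fields carry large components along translation, rotation and
# scaling, which Procrustes superimposition removes; each field is therefore
# projected onto the orthogonal complement of the similarity group at the
# template and the set is orthonormalized, so field coefficients are realized
# Procrustes-space magnitudes.
shape_basis_fields <- function(template_unit) {
  x <- template_unit[, 1]
  y <- template_unit[, 2]
  u <- (x - min(x)) / diff(range(x))
  v <- (y - min(y)) / diff(range(y))
  k <- length(x)
  raw <- cbind(
    c(cbind(0, sin(pi * u))),          # broad dorsoventral bump
    c(cbind(0, sin(2 * pi * u) * v)),  # ramus-vs-corpus seesaw
    c(cbind(cos(pi * v), 0)),          # anteroposterior shear
    c(cbind(u * (u - 0.5), 0.3 * v))   # allometric elongation
  )
  similarity <- cbind(
    c(rep(1, k), rep(0, k)),  # x translation
    c(rep(0, k), rep(1, k)),  # y translation
    c(-y, x),                 # infinitesimal rotation
    c(x, y)                   # scaling
  )
  s_basis <- qr.Q(qr(similarity))
  shape_part <- raw - s_basis %*% crossprod(s_basis, raw)
  ortho <- qr.Q(qr(shape_part))
  as_field <- function(col) cbind(col[seq_len(k)], col[k + seq_len(k)])
  list(
    g1 = as_field(ortho[, 1]),
    g2 = as_field(ortho[, 2]),
    g3 = as_field(ortho[, 3]),
    allo = as_field(ortho[, 4])
  )
}

# Fixed per-group weights on the three group basis fields.
group_field_weights <- function() {
  rbind(
    ALLO_DOUG = c(-1.0, -0.5, 0.0),
    HZ_DOUG   = c(-0.6, -0.3, 0.2),
    HYBRID    = c(0.4, 0.2, 0.1),
    HZ_RED    = c(0.5, 0.3, 0.0),
    ALLO_RED  = c(1.0, 0.5, -0.2)
  )
}

#' Generate a complete synthetic dataset
#'
#' Draws a five-group dataset with known ground truth: (a) body masses and
#' incisor dimensions such that the calibrated log10 bite force equals the
#' allometric reference baseline plus the group offset, sex effect and
#' Gaussian noise; (b) sinusoidal suture traces whose polyline length ratio
#' hits the group target within 1e-3, then rigidly moved at random; (c)
#' mandible landmark configurations built from the template plus a smooth
#' group mean-shape displacement, an allometric term in log10 centroid
#' size, and per-landmark isotropic noise, scaled to the drawn centroid
#' size and randomly rotated/translated to exercise the Procrustes
#' machinery; (d) admixture proportions by genotype class (Beta draws on
#' the open hybrid interval; parental groups at Q >= 0.90 or <= 0.10).
#' Fully reproducible from the configuration seed.
#'
#' @param cfg A [generator_config].
#' @return A `squirrel_dataset` list: `specimens` (tibble), `sutures`
#'   (vertex tibble), `landmarks` (list of [landmark_config]),
#'   `ground_truth` (per-specimen latent values plus the realized
#'   configuration).
#' @export
generate_dataset <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  groups <- squirrel_groups()
  n_total <- sum(cfg$n_per_group)
  template <- fixture_template()
  cs0 <- centroid_size(template)
  template_unit <- sweep(template$coords, 2, colMeans(template$coords)) / cs0
  fields <- shape_basis_fields(template_unit)
  gw <- group_field_weights()
  suture_pars <- data.frame(
    suture = suture_names(),
    chord = c(8, 9, 9, 12, 14),
    cycles = c(4, 6, 5, 6, 8)
  )
  with_seed(cfg$seed, {
    group_vec <- rep(groups, times = cfg$n_per_group)
    ids <- sprintf("SQ%03d", seq_len(n_total))
    sex <- ifelse(rbinom(n_total, 1, 0.5) == 1, "M", "F")
    q <- numeric(n_total)
    for (i in seq_len(n_total)) {
      q[i] <- switch(group_vec[i],
        ALLO_RED = , HZ_RED = runif(1, 0.90, 1.0),
        ALLO_DOUG = , HZ_DOUG = runif(1, 0.0, 0.10),
        HYBRID = {
          repeat {
            qq <- rbeta(1, cfg$q_beta_params[1], cfg$q_beta_params[2])
            if (qq > 0.10 && qq < 0.90) break
          }
          qq
        }
      )
    }
    mass <- pmax(50, rnorm(n_total, cfg$mass_mean[group_vec], cfg$mass_sd))
    log10_bf_true <- unname(
      cfg$allometry_reference[["slope"]] * log10(mass) +
        cfg$allometry_reference[["intercept"]] +
        cfg$group_bfq_offsets[group_vec] +
        cfg$sex_effect_bfq * (sex == "M") +
        rnorm(n_total, 0, cfg$bf_noise_sd)
    )
    zi <- 10^((log10_bf_true - cfg$calibration[["intercept"]]) /
                cfg$calibration[["slope"]])
    ap <- (6 * zi / cfg$incisor_aspect)^(1 / 3)
    ml <- cfg$incisor_aspect * ap
    specimens <- tibble::tibble(
      specimen_id = ids,
      group = factor(group_vec, levels = groups),
      sex = factor(sex, levels = sex_levels()),
      body_mass_g = mass,
      admixture_q = q,
      incisor_ap_mm = ap,
      incisor_ml_mm = ml
    )
    # suture traces
    suture_rows <- vector("list", n_total * 5L)
    lr_targets <- matrix(NA_real_, n_total, 5,
                         dimnames = list(ids, suture_names()))
    idx <- 0L
    for (i in seq_len(n_total)) {
      for (s in seq_len(5)) {
        target <- max(1, cfg$lr_means[group_vec[i], s] +
                        rnorm(1, 0, cfg$lr_noise_sd))
        lr_targets[i, s] <- target
        xy <- make_suture_trace(target, suture_pars$chord[s],
                                cycles = suture_pars$cycles[s])
        theta <- runif(1, 0, 2 * pi)
        rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
        xy <- sweep(xy %*% rot, 2, runif(2, -20, 20), `+`)
        idx <- idx + 1L
        suture_rows[[idx]] <- tibble::tibble(
          specimen_id = ids[i], suture = suture_pars$suture[s],
          order = seq_len(nrow(xy)), x = xy[, 1], y = xy[, 2]
        )
      }
    }
    sutures <- dplyr::bind_rows(suture_rows)
    # mandible configurations
    log10_cs <- rnorm(n_total, log10(cfg$size_means[group_vec]),
                      cfg$size_sd_log10)
    cs_centered <- log10_cs - mean(log10_cs)
    landmarks <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      g <- group_vec[i]
      disp <- cfg$shape_effect_scale *
        (gw[g, 1] * fields$g1 + gw[g, 2] * fields$g2 + gw[g, 3] * fields$g3) /
        sqrt(sum(gw[g, ]^2))
      shape_i <- template_unit + disp +
        cfg$allometry_slope * cs_centered[i] * fields$allo +
        matrix(rnorm(120, 0, cfg$landmark_noise_sd), 60, 2)
      coords <- shape_i / centroid_size(shape_i) * 10^log10_cs[i]
      theta <- runif(1, 0, 2 * pi)
      rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
      coords <- sweep(coords %*% rot, 2, runif(2, -50, 50), `+`)
      landmarks[[i]] <- landmark_config(
        specimen_id = ids[i], coords = coords,
        roles = template$roles, curve = template$curve
      )
    }
    ground_truth <- list(
      config = cfg,
      specimens = tibble::tibble(
        specimen_id = ids,
        group = group_vec,
        sex = sex,
        q_true = q,
        q_class_true = as.character(classify_admixture(q)),
        bfq_offset_true = unname(cfg$group_bfq_offsets[group_vec]),
        log10_bite_force_true = log10_bf_true,
        log10_centroid_size_true = log10_cs
      ),
      lr_targets = lr_targets
    )
    structure(
      list(specimens = specimens, sutures = sutures, landmarks = landmarks,
           ground_truth = ground_truth),
      class = "squirrel_dataset"
    )
  })
}

#' @export
print.squirrel_dataset <- function(x, ...) {
  cat(sprintf(
    "<squirrel_dataset> %d specimens (%s), %d suture traces, %d landmark configs\n",
    nrow(x$specimens),
    paste(sprintf("%s=%d", levels(x$specimens$group),
                  as.vector(table(x$specimens$group))), collapse = ", "),
    nrow(dplyr::distinct(x$sutures, .data$specimen_id, .data$suture)),
    length(x$landmarks)
  ))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits `specimens.csv`, `sutures.csv`, `landmarks.tps`, and
#' `ground_truth.json` in the formats the readers accept.
#'
#' @param dataset A `squirrel_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "squirrel_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(dataset$specimens, file.path(dir, "specimens.csv"))
  readr::write_csv(dataset$sutures, file.path(dir, "sutures.csv"))
  write_tps(dataset$landmarks, file.path(dir, "landmarks.tps"))
  gt <- dataset$ground_truth
  gt$config <- unclass(gt$config)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
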