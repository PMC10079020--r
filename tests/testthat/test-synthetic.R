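test_that("the template satisfies the conforming landmark scheme", {
  tpl <- fixture_template()
  expect_true(tpl$conforming)
  expect_equal(sum(tpl$roles == "fixed"), 15)
  expect_equal(sum(tpl$roles == "semi"), 45)
  expect_equal(sort(unique(tpl$curve[!is.na(tpl$curve)])), 1:3)
  expect_gt(centroid_size(tpl), 0)
  # TPS affine null space at the template
  b <- bending_energy_matrix(tpl$coords)
  ev <- eigen(b, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-9 * max(abs(ev))), 3)
})

test_that("the same seed reproduces the dataset byte-for-byte on disk", {
  cfg <- generator_config(seed = 123)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(generate_dataset(cfg), d1)
  write_dataset(generate_dataset(cfg), d2)
  for (f in c("specimens.csv", "sutures.csv", "landmarks.tps",
              "ground_truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # and a different seed gives different data
  d3 <- generate_dataset(generator_config(seed = 124))
  expect_false(identical(d3$specimens$body_mass_g,
                         generate_dataset(cfg)$specimens$body_mass_g))
})

test_that("group sizes, admixture classes, and Q supports follow the config", {
  cfg <- generator_config(seed = 31)
  ds <- generate_dataset(cfg)
  expect_equal(as.vector(table(ds$specimens$group)[squirrel_groups()]),
               unname(cfg$n_per_group))
  q <- ds$specimens$admixture_q
  grp <- as.character(ds$specimens$group)
  expect_true(all(q[grp %in% c("ALLO_RED", "HZ_RED")] >= 0.90))
  expect_true(all(q[grp %in% c("ALLO_DOUG", "HZ_DOUG")] <= 0.10))
  expect_true(all(q[grp == "HYBRID"] > 0.10 & q[grp == "HYBRID"] < 0.90))
  expect_equal(as.character(classify_admixture(q)),
               ds$ground_truth$specimens$q_class_true)
})

test_that("generated bite forces embed the configured group offsets", {
  cfg <- generator_config(seed = 77)
  ds <- generate_dataset(cfg)
  fit <- fit_bfq(ds$specimens)
  spec <- tidy(fit)
  # calibrated log10 force reproduces the generator's latent value
  expect_equal(spec$log10_bite_force,
               ds$ground_truth$specimens$log10_bite_force_true,
               tolerance = 1e-10)
  # group means of the mass-detrended force respect every offset contrast
  # that clearly exceeds the sampling noise of a group mean
  resid_true <- spec$log10_bite_force -
    (cfg$allometry_reference[["slope"]] * log10(spec$body_mass_g) +
       cfg$allometry_reference[["intercept"]])
  grp_means <- tapply(resid_true, spec$group, mean)
  offs <- cfg$group_bfq_offsets[names(grp_means)]
  for (i in seq_along(offs)) for (j in seq_along(offs)) {
    if (offs[i] >= offs[j] + 0.03) expect_gt(grp_means[i], grp_means[j])
  }
})

test_that("a null configuration yields calibrated group p-values", {
  withr::with_seed(500, {
    groups <- squirrel_groups()
    null_cfg <- function(seed) generator_config(
      seed = seed,
      group_bfq_offsets = setNames(rep(0, 5), groups),
      sex_effect_bfq = 0,
      mass_mean = setNames(rep(240, 5), groups)
    )
    p_vals <- vapply(1:60, function(i) {
      ds <- generate_dataset(null_cfg(i))
      tidy(trait_ancova(tidy(fit_bfq(ds$specimens)), "bfq",
                        c("group", "sex")))$p[1]
    }, 0)
    expect_lt(mean(p_vals < 0.05), 0.15)
    ks <- stats::ks.test(p_vals, "punif")
    expect_gt(ks$p.value, 0.01)
  })
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(lr_means = matrix(0.9, 5, 5,
    dimnames = list(squirrel_groups(), suture_names()))), "Unattainable")
  expect_error(generator_config(n_per_group = c(ALLO_DOUG = 1, HZ_DOUG = 10,
    HYBRID = 19, HZ_RED = 13, ALLO_RED = 14)), "counts >= 2")
  expect_error(generator_config(bf_noise_sd = -1), ">= 0")
})

test_that("generated data exercise every analysis module without error", {
  ds <- generate_dataset(generator_config(
    seed = 15, n_per_group = setNames(c(6, 6, 8, 6, 6), squirrel_groups())))
  expect_s3_class(fit_bfq(ds$specimens), "bfq_fit")
  expect_s3_class(suture_length_ratios(ds$sutures), "tbl_df")
  g <- slide_semilandmarks(gpa(ds$landmarks), n_cycles = 1)
  expect_s3_class(g, "shape_gpa")
  p <- morph_pca(sciuromorph:::shape_matrix(g))
  expect_s3_class(p, "morph_pca")
})
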