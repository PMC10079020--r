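test_that("centroid size follows the closed form and its invariances", {
  expect_equal(centroid_size(rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))),
               sqrt(8))
  shape <- asym_shape()
  expect_equal(centroid_size(2 * shape), 2 * centroid_size(shape))
  expect_equal(centroid_size(sweep(shape, 2, c(5, -3), `+`)),
               centroid_size(shape))
  expect_error(centroid_size(rbind(c(1, 1), c(1, 1))), "zero")
})

test_that("similarity-transformed copies align to numerically identical shapes", {
  withr::with_seed(42, {
    base <- asym_shape()
    copies <- c(list(base), lapply(1:9, function(i) random_similarity(base)))
    arr <- array(unlist(copies), dim = c(nrow(base), 2, 10))
    g <- gpa(arr)
    expect_true(g$converged)
    for (i in 1:9) for (j in (i + 1):10) {
      d <- sqrt(sum((g$aligned[, , i] - g$aligned[, , j])^2))
      expect_lt(d, 1e-9)
    }
  })
})

test_that("two-shape Procrustes distance matches a rotation-grid oracle", {
  withr::with_seed(8, {
    a <- asym_shape()
    b <- asym_shape() + matrix(rnorm(16, 0, 0.4), 8, 2)
    d_impl <- procrustes_distance(a, b)
    d_grid <- grid_procrustes_distance(a, b, n_grid = 1e6)
    expect_lt(abs(d_impl - d_grid), 1e-5)
    expect_lte(d_impl, d_grid + 1e-12) # closed form can only do better
  })
})

test_that("Procrustes distance agrees with an independent library implementation", {
  skip_if_not_installed("vegan")
  withr::with_seed(9, {
    a <- asym_shape()
    b <- asym_shape() + matrix(rnorm(16, 0, 0.3), 8, 2)
    au <- sweep(a, 2, colMeans(a)); au <- au / sqrt(sum(au^2))
    bu <- sweep(b, 2, colMeans(b)); bu <- bu / sqrt(sum(bu^2))
    v <- vegan::procrustes(au, bu, scale = FALSE, symmetric = FALSE)
    expect_equal(procrustes_distance(a, b), sqrt(sum((v$Yrot - au)^2)),
                 tolerance = 1e-6)
  })
})

test_that("reflected copies are not matched to zero distance", {
  shape <- asym_shape()
  mirrored <- shape %*% diag(c(-1, 1))
  expect_gt(procrustes_distance(shape, mirrored), 0.05)
})

test_that("GPA output is invariant to random similarity pre-transforms", {
  withr::with_seed(17, {
    ds <- generate_dataset(generator_config(
      seed = 3, n_per_group = setNames(rep(3, 5), squirrel_groups())))
    arr <- sciuromorph:::configs_to_array(ds$landmarks)
    g1 <- gpa(arr)
    arr2 <- arr
    for (i in seq_len(dim(arr)[3])) arr2[, , i] <- random_similarity(arr[, , i])
    g2 <- gpa(arr2)
    # consensus shapes agree up to a rotation
    expect_lt(procrustes_distance(g1$consensus, g2$consensus), 1e-7)
    for (i in seq_len(dim(arr)[3])) {
      expect_lt(procrustes_distance(g1$aligned[, , i], g2$aligned[, , i]), 1e-7)
    }
  })
})

test_that("aligned shapes are centred, unit-size, and average to the consensus", {
  ds <- generate_dataset(generator_config(
    seed = 4, n_per_group = setNames(rep(3, 5), squirrel_groups())))
  g <- gpa(ds$landmarks)
  n <- dim(g$aligned)[3]
  for (i in seq_len(n)) {
    m <- g$aligned[, , i]
    expect_lt(max(abs(colMeans(m))), 1e-8)
    expect_equal(sqrt(sum(m^2)), 1, tolerance = 1e-8)
  }
  mean_shape <- apply(g$aligned, c(1, 2), mean)
  # consensus is the (re-normalized) mean of aligned configurations
  expect_lt(procrustes_distance(mean_shape, g$consensus), 1e-7)
  expect_equal(sum(g$aligned), n * sum(mean_shape), tolerance = 1e-8)
})

test_that("degenerate configurations are rejected by name", {
  arr <- array(0, c(4, 2, 2))
  arr[, , 1] <- asym_shape()[1:4, ]
  arr[, , 2] <- matrix(3, 4, 2)
  dimnames(arr) <- list(NULL, NULL, c("ok", "flat"))
  expect_error(gpa(arr), "flat")
})
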