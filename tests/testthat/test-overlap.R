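test_that("posterior draws centre on the sample and match inverse-Wishart moments", {
  withr::with_seed(61, {
    n <- 40; d <- 3
    x <- matrix(rnorm(n * d), n, d) %*% chol(diag(c(1, 2, 0.5)))
    post <- mvn_posterior_draws(x, 3000, seed = 8)
    xbar <- colMeans(x)
    # posterior mean of mu is the sample mean; 3000 draws leave only a
    # Monte Carlo error of about se/sqrt(3000)
    mc_err <- sqrt(max(diag(stats::cov(x))) / n) / sqrt(3000)
    expect_lt(max(abs(colMeans(post$mu) - xbar)), 6 * mc_err)
    # closed-form oracle: E[Sigma] for IW(nu = n-1, scale = S) is
    # S / (nu - d - 1)
    s <- crossprod(sweep(x, 2, xbar))
    expected <- s / (n - 1 - d - 1)
    mean_sigma <- apply(post$sigma, c(1, 2), mean)
    expect_lt(max(abs(mean_sigma - expected) / max(abs(expected))), 0.1)
    # every covariance draw is symmetric positive definite
    for (j in seq(1, 3000, by = 97)) {
      sig <- post$sigma[, , j]
      expect_lt(max(abs(sig - t(sig))), 1e-10)
      expect_gt(min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
  })
  expect_error(mvn_posterior_draws(matrix(rnorm(9), 3, 3), 10, group = "G"),
               "insufficient group size")
})

test_that("overlap probability matches closed-form normal cases", {
  # identical distributions: the alpha-region has mass alpha by construction
  mu <- c(0, 1, 2); sig <- diag(c(1, 2, 0.5))
  ov <- overlap_probability(mu, sig, mu, sig, alpha = 0.95, n_mc = 2e5, seed = 1)
  expect_lt(abs(ov - 0.95), 0.005)
  # 1-D case with a wider region: Phi(3.92) - Phi(-3.92)
  ov1 <- overlap_probability(0, matrix(1), 0, matrix(4), alpha = 0.95,
                             n_mc = 2e5, seed = 2)
  target <- pnorm(2 * qnorm(0.975)) - pnorm(-2 * qnorm(0.975))
  expect_lt(abs(ov1 - target), 0.002)
  # far-displaced region: no overlap
  ov0 <- overlap_probability(c(0, 0), diag(2), c(100, 0), diag(2),
                             n_mc = 1e4, seed = 3)
  expect_equal(ov0, 0)
})

test_that("overlap is invariant under a common affine transformation", {
  withr::with_seed(71, {
    mu_a <- c(1, -1); sig_a <- matrix(c(2, 0.5, 0.5, 1), 2)
    mu_b <- c(0.5, 0); sig_b <- matrix(c(1, -0.3, -0.3, 1.5), 2)
    a <- matrix(rnorm(4), 2); while (abs(det(a)) < 0.3) a <- matrix(rnorm(4), 2)
    b <- rnorm(2)
    o1 <- overlap_probability(mu_a, sig_a, mu_b, sig_b, n_mc = 2e5, seed = 4)
    o2 <- overlap_probability(drop(a %*% mu_a + b), a %*% sig_a %*% t(a),
                              drop(a %*% mu_b + b), a %*% sig_b %*% t(a),
                              n_mc = 2e5, seed = 4)
    expect_lt(abs(o1 - o2), 0.01)
  })
})

test_that("increasing alpha increases every overlap draw at fixed seed", {
  withr::with_seed(81, {
    x <- matrix(rnorm(60), 20, 3)
    df <- tibble::tibble(group = rep(c("A", "B"), each = 10))
    df <- cbind(df, as.data.frame(rbind(x[1:10, ], x[11:20, ])))
    o1 <- morphospace_overlap(df, c("V1", "V2", "V3"), alpha = 0.90,
                              n_posterior = 50, n_mc = 500, seed = 5)
    o2 <- morphospace_overlap(df, c("V1", "V2", "V3"), alpha = 0.99,
                              n_posterior = 50, n_mc = 500, seed = 5)
    expect_true(all(o2$draws >= o1$draws))
  })
})

test_that("duplicated groups overlap at about the niche level in both directions", {
  withr::with_seed(91, {
    base <- matrix(rnorm(150 * 3), 150, 3)
    df <- tibble::tibble(group = rep(c("A", "B"), each = 150))
    df <- cbind(df, as.data.frame(rbind(base, base)))
    ov <- morphospace_overlap(df, c("V1", "V2", "V3"), alpha = 0.95,
                              n_posterior = 500, n_mc = 2000, seed = 6)
    s <- tidy(ov)
    expect_equal(nrow(s), 2)
    expect_lt(max(abs(s$mean - 0.95)), 0.03)
    expect_true(all(s$lo <= s$mean & s$mean <= s$hi))
  })
})

test_that("a tight group nested in a wide group overlaps asymmetrically", {
  withr::with_seed(101, {
    wide <- matrix(rnorm(40 * 3, 0, 3), 40, 3)
    tight <- matrix(rnorm(40 * 3, 0, 0.5), 40, 3)
    df <- tibble::tibble(group = rep(c("WIDE", "TIGHT"), each = 40))
    df <- cbind(df, as.data.frame(rbind(wide, tight)))
    ov <- tidy(morphospace_overlap(df, c("V1", "V2", "V3"),
                                   n_posterior = 300, n_mc = 2000, seed = 7))
    onto_wide <- ov$mean[ov$group_a == "TIGHT" & ov$group_b == "WIDE"]
    onto_tight <- ov$mean[ov$group_a == "WIDE" & ov$group_b == "TIGHT"]
    expect_gt(onto_wide, onto_tight + 0.3)
  })
})

test_that("five groups produce all twenty ordered pairs", {
  ds <- generate_dataset(generator_config(seed = 9))
  df <- ds$specimens
  withr::with_seed(5, {
    df$t1 <- rnorm(nrow(df)); df$t2 <- rnorm(nrow(df)); df$t3 <- rnorm(nrow(df))
  })
  ov <- morphospace_overlap(df, c("t1", "t2", "t3"), n_posterior = 20,
                            n_mc = 200, seed = 10)
  expect_equal(nrow(tidy(ov)), 20)
  expect_true(all(ov$draws >= 0 & ov$draws <= 1))
  expect_equal(nrow(ov$draws), 20)
})
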