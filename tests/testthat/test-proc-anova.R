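# A 12-row constructed design with a group factor, sex factor and a size
# covariate, used for the univariate oracle comparisons.
oracle_design <- function() {
  withr::with_seed(77, {
    df <- tibble::tibble(
      group = factor(rep(c("A", "B", "C"), each = 4)),
      sex = factor(rep(c("F", "M"), 6)),
      size = round(runif(12, 1, 2), 3)
    )
    df$y <- 2 + 0.8 * (df$group == "B") - 0.5 * (df$group == "C") +
      0.3 * (df$sex == "M") + 1.1 * df$size + rnorm(12, 0, 0.4)
    df
  })
}

# Independent textbook oracle: sequential F via explicit normal equations,
# no qr/lm shortcuts shared with the implementation.
normal_equations_ss <- function(y, x_red, x_full) {
  beta_hat <- function(x) solve(t(x) %*% x) %*% t(x) %*% y
  rss <- function(x) {
    r <- y - x %*% beta_hat(x)
    sum(r * r)
  }
  rss(x_red) - rss(x_full)
}

test_that("univariate sequential F matches a normal-equations oracle", {
  df <- oracle_design()
  terms <- c("group", "sex", "size")
  res <- procrustes_anova(df$y, df, terms, n_perm = 19, seed = 1)
  tab <- tidy(res)
  x0 <- matrix(1, 12, 1)
  x1 <- model.matrix(~group, df)
  x2 <- model.matrix(~group + sex, df)
  x3 <- model.matrix(~group + sex + size, df)
  ss_o <- c(
    normal_equations_ss(df$y, x0, x1),
    normal_equations_ss(df$y, x1, x2),
    normal_equations_ss(df$y, x2, x3)
  )
  resid_o <- df$y - x3 %*% solve(t(x3) %*% x3) %*% t(x3) %*% df$y
  ms_resid_o <- sum(resid_o^2) / (12 - ncol(x3))
  f_o <- (ss_o / c(2, 1, 1)) / ms_resid_o
  expect_equal(tab$ss[1:3], ss_o, tolerance = 1e-6)
  expect_equal(tab$f[1:3], f_o, tolerance = 1e-6)
  # and agrees with stats::anova on the same model
  a <- anova(lm(y ~ group + sex + size, df))
  expect_equal(tab$f[1:3], a$`F value`[1:3], tolerance = 1e-8)
})

test_that("ANOVA table invariants hold for multivariate responses", {
  withr::with_seed(33, {
    n <- 30
    df <- tibble::tibble(
      group = factor(sample(c("A", "B", "C"), n, replace = TRUE)),
      sex = factor(sample(c("F", "M"), n, replace = TRUE)),
      size = runif(n)
    )
    y <- matrix(rnorm(n * 5), n, 5)
    y[df$group == "B", 1] <- y[df$group == "B", 1] + 1
    res <- procrustes_anova(y, df, c("group", "sex", "size", "group:size"),
                            n_perm = 99, seed = 2)
    tab <- tidy(res)
    terms_only <- tab[!(tab$term %in% c("Residuals", "Total")), ]
    expect_equal(sum(terms_only$ss) + tab$ss[tab$term == "Residuals"],
                 tab$ss[tab$term == "Total"], tolerance = 1e-8)
    expect_equal(sum(terms_only$rsq) + tab$rsq[tab$term == "Residuals"], 1,
                 tolerance = 1e-8)
    expect_equal(sum(terms_only$df) + tab$df[tab$term == "Residuals"], n - 1)
    expect_true(all(terms_only$p > 0 & terms_only$p <= 1))
  })
})

test_that("a response constant across groups yields zero group SS and F", {
  df <- tibble::tibble(group = factor(rep(c("A", "B"), each = 4)))
  y <- matrix(rep(c(1, 2), 8), 8, 2)
  res <- procrustes_anova(y, df, "group", n_perm = 49, seed = 3)
  tab <- tidy(res)
  expect_equal(tab$ss[1], 0, tolerance = 1e-12)
  expect_equal(tab$f[1], 0, tolerance = 1e-12)
})

test_that("permutation p-values are invariant to rotation of the response", {
  withr::with_seed(44, {
    n <- 24
    df <- tibble::tibble(group = factor(sample(c("A", "B", "C"), n, TRUE)),
                         size = runif(n))
    y <- matrix(rnorm(n * 4), n, 4)
    res1 <- procrustes_anova(y, df, c("group", "size"), n_perm = 99, seed = 9)
    rot <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
    res2 <- procrustes_anova(y %*% rot, df, c("group", "size"),
                             n_perm = 99, seed = 9)
    expect_equal(tidy(res1)$p, tidy(res2)$p, tolerance = 1e-12)
    expect_equal(tidy(res1)$ss, tidy(res2)$ss, tolerance = 1e-8)
  })
})

test_that("null-effect permutation p-values are uniform", {
  withr::with_seed(55, {
    p_vals <- vapply(1:200, function(rep) {
      n <- 20
      df <- tibble::tibble(group = factor(rep(c("A", "B"), each = n / 2)))
      y <- rnorm(n)
      tidy(procrustes_anova(y, df, "group", n_perm = 199, seed = rep))$p[1]
    }, 0)
    ks <- suppressWarnings(stats::ks.test(p_vals, "punif"))
    expect_gt(ks$p.value, 0.01)
  })
})

test_that("aliased terms are reported", {
  df <- tibble::tibble(group = factor(rep(c("A", "B"), each = 4)))
  df$dup <- df$group # perfectly aliased
  y <- rnorm(8)
  expect_error(procrustes_anova(y, df, c("group", "dup"), n_perm = 9),
               "aliased")
})

test_that("pairwise distances, permutation p and corrections behave", {
  withr::with_seed(66, {
    base <- matrix(rnorm(10 * 3), 10, 3)
    y <- rbind(base, base)
    groups <- rep(c("A", "B"), each = 10)
    res <- pairwise_groups(y, groups, n_perm = 99, seed = 4)
    expect_equal(res$distance, 0, tolerance = 1e-12)
    expect_equal(res$p_raw, 1)

    # five groups, one displaced: its four pairs carry the smallest p_adj
    g5 <- rep(c("A", "B", "C", "D", "E"), each = 8)
    y5 <- matrix(rnorm(40 * 3), 40, 3)
    y5[g5 == "E", ] <- y5[g5 == "E", ] + 3
    res5 <- pairwise_groups(y5, g5, n_perm = 199, seed = 5)
    expect_equal(nrow(res5), 10)
    with_e <- res5$group_a == "E" | res5$group_b == "E"
    expect_lte(max(res5$p_adj[with_e]), min(res5$p_adj[!with_e]))
    expect_true(all(res5$p_adj >= res5$p_raw))

    bon <- pairwise_groups(y5, g5, adjust = "bonferroni", n_perm = 99, seed = 6)
    expect_equal(bon$p_adj, pmin(1, 10 * bon$p_raw))

    expect_warning(
      pairwise_groups(y5[c(1:16, 17), ], c(g5[1:16], "C"), n_perm = 49, seed = 7),
      "fewer than 2"
    )
  })
})
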