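test_that("one-way ANOVA F matches a hand-computed two-group oracle", {
  # 2 groups x 3 observations, hand-computed sums of squares:
  # A = (1, 2, 3), B = (5, 6, 7); SSB = 24, SSW = 4, F = 24 / (4/4) = 24
  df <- tibble::tibble(
    group = factor(rep(c("A", "B"), each = 3)),
    y = c(1, 2, 3, 5, 6, 7)
  )
  fit <- trait_ancova(df, "y", terms = "group")
  tab <- tidy(fit)
  expect_equal(tab$ss[1], 24, tolerance = 1e-8)
  expect_equal(tab$f[1], 24, tolerance = 1e-8)
})

test_that("group-independent responses give zero F and covariate shifts are absorbed", {
  df <- tibble::tibble(
    group = factor(rep(c("A", "B", "C"), each = 4)),
    sex = factor(rep(c("F", "M"), 6)),
    size = runif(12),
    y = rep(c(1, 2, 1, 2), 3)
  )
  fit <- trait_ancova(df, "y", terms = c("group"))
  expect_equal(tidy(fit)$f[1], 0, tolerance = 1e-12)
  # y is an exact function of sex, so base R warns about a perfect fit
  f1 <- suppressWarnings(
    tidy(trait_ancova(df, "y", terms = c("group", "sex", "size"))))
  df2 <- df; df2$size <- df$size + 100
  f2 <- suppressWarnings(
    tidy(trait_ancova(df2, "y", terms = c("group", "sex", "size"))))
  expect_equal(f1$f, f2$f, tolerance = 1e-8)
})

test_that("ancova and procrustes_anova agree on a univariate response", {
  withr::with_seed(88, {
    n <- 36
    df <- tibble::tibble(
      group = factor(sample(c("A", "B", "C"), n, TRUE)),
      sex = factor(sample(c("F", "M"), n, TRUE)),
      size = runif(n),
      y = rnorm(n)
    )
    df$y <- df$y + as.numeric(df$group) * 0.5
    para <- tidy(trait_ancova(df, "y", terms = c("group", "sex", "size")))
    perm <- tidy(procrustes_anova(df$y, df, c("group", "sex", "size"),
                                  n_perm = 49, seed = 1))
    expect_equal(para$f[1:3], perm$f[1:3], tolerance = 1e-6)
    expect_equal(para$ss[1:3], perm$ss[1:3], tolerance = 1e-6)
  })
})

test_that("post-hoc contrasts detect a shifted group and respect monotonicity", {
  withr::with_seed(20, {
    hits <- 0
    for (rep in 1:30) {
      n_per <- 12
      df <- tibble::tibble(
        group = factor(rep(c("A", "B", "C"), each = n_per)),
        y = rnorm(3 * n_per)
      )
      df$y[df$group == "C"] <- df$y[df$group == "C"] + 3
      fit <- trait_ancova(df, "y", terms = "group")
      ph <- posthoc_pairs(fit, adjust = "holm")
      with_c <- ph$group_a == "C" | ph$group_b == "C"
      if (all(ph$p_adj[with_c] < 0.05)) hits <- hits + 1
    }
    expect_gte(hits / 30, 0.95)
  })
  # duplicated groups: difference ~ 0, p ~ 1
  base <- tibble::tibble(y = rnorm(10))
  dup <- dplyr::bind_rows(
    dplyr::mutate(base, group = factor("A")),
    dplyr::mutate(base, group = factor("B"))
  )
  ph <- posthoc_pairs(trait_ancova(dup, "y", terms = "group"))
  expect_equal(ph$estimate, 0, tolerance = 1e-12)
  expect_gt(ph$p_adj, 0.99)
})

test_that("admixture classes use inclusive thresholds exactly", {
  cls <- classify_admixture(c(0.90, 0.10, 0.50, 0.899999, 0.100001, 0, 1))
  expect_equal(as.character(cls),
               c("PURE_RED", "PURE_DOUGLAS", "HYBRID", "HYBRID", "HYBRID",
                 "PURE_DOUGLAS", "PURE_RED"))
  expect_error(classify_admixture(1.2), "\\[0, 1\\]")
})

test_that("admixture regression recovers exact fits and stays calibrated under the null", {
  q <- seq(0.2, 0.8, length.out = 10)
  df <- tibble::tibble(admixture_q = q, trait = 2 * q + 1)
  res <- suppressWarnings(admixture_regression(df, "trait")) # exact fit
  expect_equal(res$slope, 2, tolerance = 1e-10)
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
  expect_equal(res$n, 10)

  withr::with_seed(41, {
    p_vals <- vapply(1:100, function(i) {
      d <- tibble::tibble(admixture_q = runif(19, 0.11, 0.89),
                          trait = rnorm(19))
      admixture_regression(d, "trait")$p
    }, 0)
    ks <- stats::ks.test(p_vals, "punif")
    expect_gt(ks$p.value, 0.01)
    expect_lt(mean(p_vals < 0.05), 0.12)
  })

  expect_error(
    admixture_regression(tibble::tibble(admixture_q = c(0.4, 0.5),
                                        trait = c(1, 2)), "trait"),
    "at least 3"
  )
  expect_error(
    admixture_regression(tibble::tibble(admixture_q = rep(0.5, 5),
                                        trait = rnorm(5)), "trait"),
    "singular"
  )
  # parental individuals are excluded before fitting
  mixed <- tibble::tibble(admixture_q = c(0.02, 0.95, runif(10, 0.2, 0.8)),
                          trait = rnorm(12))
  expect_equal(admixture_regression(mixed, "trait")$n, 10)
})

test_that("hybrid Q summary reports the normal-theory interval", {
  withr::with_seed(10, {
    q <- runif(19, 0.2, 0.8)
    s <- hybrid_q_summary(q)
    expect_equal(s$n, 19)
    expect_equal(s$mean_q, mean(q))
    expect_equal(s$ci_halfwidth, qt(0.975, 18) * sd(q) / sqrt(19))
  })
})
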