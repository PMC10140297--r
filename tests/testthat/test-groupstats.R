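toy_fit <- function() {
  fit_oneway(c(1, 2, 3, 2, 3, 4, 6, 7, 8), rep(c("g1", "g2", "g3"), each = 3))
}

test_that("one-way decomposition matches the hand-computed toy case", {
  fit <- toy_fit()
  expect_equal(unname(fit$means), c(2, 3, 7))
  expect_equal(fit$mse, 1)
  expect_equal(fit$f, 21)
  expect_equal(c(fit$df1, fit$df2), c(2, 6))
  expect_equal(fit$sem, sqrt(1 / 3), tolerance = 1e-9)

  expect_error(fit_oneway(1:4, c("a", "a", "a", "b")), "at least 2 samples")
  expect_error(fit_oneway(1:4, rep("a", 4)), "at least 2 groups")
  cfit <- fit_oneway(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_true(cfit$zero_variance)
  expect_true(is.na(cfit$f))
})

test_that("one-way fit agrees with the stats::aov oracle to 1e-8", {
  set.seed(42)
  for (i in 1:12) {
    k <- sample(2:4, 1)
    n_i <- sample(3:8, k, replace = TRUE)
    g <- factor(rep(letters[1:k], n_i))
    y <- stats::rnorm(sum(n_i), mean = rep(stats::runif(k, 0, 5), n_i))
    fit <- fit_oneway(y, g)
    a <- stats::anova(stats::aov(y ~ g))
    expect_equal(fit$f, a[["F value"]][1], tolerance = 1e-8)
    expect_equal(fit$p, a[["Pr(>F)"]][1], tolerance = 1e-8)
    expect_equal(fit$mse, a[["Mean Sq"]][2], tolerance = 1e-8)
    # contrast t^2 equals the F of the corresponding 1-df split (two groups)
    if (k == 2) {
      ct <- contrast_test(fit, c(1, -1))
      expect_equal(ct$t^2, a[["F value"]][1], tolerance = 1e-8)
    }
  }
})

test_that("contrast tests match the closed form and reject bad weights", {
  fit <- toy_fit()
  ct <- contrast_test(fit, c(1, -1, 0))
  expect_equal(ct$estimate, -1)
  expect_equal(ct$se, sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(ct$t, -1 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(ct$df, 6)
  expect_error(contrast_test(fit, c(1, 1, 0)), "sum to zero")

  # equal group means give estimate 0, p = 1
  efit <- fit_oneway(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  ec <- contrast_test(efit, c(1, -1))
  expect_equal(ec$estimate, 0)
  expect_equal(ec$p, 1)

  # built-in contrasts: orthogonal under balance, named matching works
  ctr <- cod_contrasts()
  expect_equal(sum(ctr$a_vs_p * ctr$n_vs_i), 0)
  expect_equal(sum(ctr$a_vs_p), 0)
  prof_fit <- fit_oneway(c(31.9, 32.0, 35.8, 35.9, 33.1, 33.1),
                         factor(rep(origin_levels(), each = 2),
                                levels = origin_levels()))
  ca <- contrast_test(prof_fit, ctr$a_vs_p)
  expect_equal(ca$estimate,
               0.5 * prof_fit$means[["Norway"]] +
                 0.5 * prof_fit$means[["Iceland"]] -
                 prof_fit$means[["Alaska"]], tolerance = 1e-12)
})

test_that("A-vs-P contrast on printed protein means gives the 0.80 estimate", {
  # printed group means as degenerate 'samples' only to carry the means
  fit <- list(levels = origin_levels(),
              n = stats::setNames(rep(15, 3), origin_levels()),
              means = stats::setNames(c(31.95, 35.85, 33.10), origin_levels()),
              mse = 1, df2 = 42)
  class(fit) <- "oneway_fit"
  ca <- contrast_test(fit, cod_contrasts()$a_vs_p)
  expect_equal(ca$estimate, 0.5 * 31.95 + 0.5 * 35.85 - 33.10, tolerance = 1e-12)
  expect_equal(ca$estimate, 0.80, tolerance = 1e-9)
})

test_that("Tukey pairwise adjustment behaves like the studentized range", {
  fit <- toy_fit()
  tk <- tukey_pairwise(fit)
  p13 <- tk$p_adj[tk$group1 == "g1" & tk$group2 == "g3"]
  p12 <- tk$p_adj[tk$group1 == "g1" & tk$group2 == "g2"]
  expect_lt(p13, 0.05)
  expect_gt(p12, 0.05)
  # cross-check against TukeyHSD on the same fit
  y <- c(1, 2, 3, 2, 3, 4, 6, 7, 8); g <- factor(rep(letters[1:3], each = 3))
  hsd <- stats::TukeyHSD(stats::aov(y ~ g))$g
  expect_equal(sort(tk$p_adj), sort(unname(hsd[, "p adj"])), tolerance = 1e-8)

  # equal means give adjusted p = 1
  efit <- fit_oneway(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(tukey_pairwise(efit)$p_adj, 1)

  # two groups: q = t * sqrt(2), Tukey p equals the two-sample pooled t p
  set.seed(9)
  y2 <- stats::rnorm(12); g2 <- rep(c("a", "b"), each = 6)
  f2 <- fit_oneway(y2, g2)
  tk2 <- tukey_pairwise(f2)
  tt <- stats::t.test(y2 ~ g2, var.equal = TRUE)
  expect_equal(tk2$q, abs(tt$statistic[[1]]) * sqrt(2), tolerance = 1e-8)
  expect_equal(tk2$p_adj, tt$p.value, tolerance = 1e-8)
})

test_that("compare_groups produces the table layout across variables", {
  cohort <- simulate_cohort(calibrate_generator(n = 6), seed = 8)
  gdat <- cda_candidates(cohort)
  tab <- compare_groups(gdat, c("His", "Arg", "TotalAA"))
  expect_identical(tab$variable, c("His", "Arg", "TotalAA"))
  expect_true(all(c("Norway", "Iceland", "Alaska", "sem", "p_avsp", "p_nvsi")
                  %in% names(tab)))
  expect_true(all(tab$sem > 0))
  expect_true(all(tab$p_avsp >= 0 & tab$p_avsp <= 1))
})
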