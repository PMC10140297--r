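test_that("basis conversion matches hand arithmetic and inverts cleanly", {
  prof <- make_profile(tp = 31.95, Thr = 1.89)
  expect_equal(convert_basis(prof, "protein")[1, "Thr"], 1.89 / 31.95 * 100,
               tolerance = 1e-12)
  expect_equal(convert_basis(prof, "protein")[1, "Thr"], 5.9155,
               tolerance = 1e-4)
  # tp = 100 leaves values unchanged; edible -> edible is the identity
  p100 <- make_profile(tp = 100, Thr = 1.89)
  expect_equal(convert_basis(p100, "protein")[1, ],
               convert_basis(p100, "edible")[1, ])
  # round trip protein -> edible
  m <- convert_basis(prof, "protein")
  expect_equal(m * prof$tp / 100, convert_basis(prof, "edible"),
               tolerance = 1e-12)
})

test_that("class partial sums reproduce the printed subtotals and partition TAA", {
  prof <- fixture_mean_profiles()
  ps <- partial_sums(prof, "edible")
  expect_equal(ps$iaa[ps$origin == "Norway"], 11.01, tolerance = 0.05)
  expect_equal(ps$daa[ps$origin == "Norway"], 11.30, tolerance = 0.05)
  expect_equal(ps$ciaa[ps$origin == "Iceland"], 10.47, tolerance = 0.05)

  # additivity in both bases, for arbitrary cohorts
  cohort <- simulate_cohort(calibrate_generator(n = 5), seed = 2)
  for (b in c("edible", "protein")) {
    s <- partial_sums(cohort, b)
    expect_equal(s$iaa + s$ciaa + s$daa, s$taa, tolerance = 1e-9)
  }

  zero <- make_profile(fill = 0)
  z <- partial_sums(zero)
  expect_equal(unlist(z[, c("taa", "iaa", "ciaa", "daa")]),
               c(taa = 0, iaa = 0, ciaa = 0, daa = 0))
})

test_that("ratios are basis-invariant and match the printed table", {
  prof <- fixture_mean_profiles()
  re <- aa_ratios(partial_sums(prof, "edible"))
  rp <- aa_ratios(partial_sums(prof, "protein"))
  for (v in c("iaa_taa", "daa_taa", "ciaa_taa", "iaa_daa"))
    expect_equal(re[[v]], rp[[v]], tolerance = 1e-9)
  # ratios from the printed protein-basis sums match the printed ratio rows
  t1 <- builtin_fixture("table1")
  sums <- data.frame(
    origin = origin_levels(),
    taa  = unlist(t1[t1$variable == "sum_TAA",  origin_levels()]),
    iaa  = unlist(t1[t1$variable == "sum_IAA",  origin_levels()]),
    ciaa = unlist(t1[t1$variable == "sum_CIAA", origin_levels()]),
    daa  = unlist(t1[t1$variable == "sum_DAA",  origin_levels()]))
  rt <- aa_ratios(sums)
  expect_lt(abs(rt$iaa_taa[rt$origin == "Norway"] - 0.37), 0.005)
  expect_lt(abs(rt$iaa_taa[rt$origin == "Alaska"] - 0.34), 0.005)
  expect_lt(abs(rt$iaa_daa[rt$origin == "Norway"] - 0.98), 0.005)
  # IAA/TAA + (CIAA + DAA)/TAA = 1
  expect_equal(re$iaa_taa + re$ciaa_taa + re$daa_taa, rep(1, 3),
               tolerance = 1e-9)
  # equal IAA and DAA sums give ratio 1
  eq <- aa_ratios(partial_sums(make_profile(fill = 1)))
  expect_equal(eq$iaa_daa, 9 / 6)  # 9 IAA vs 6 DAA members at equal conc
  expect_error(aa_ratios(partial_sums(make_profile(fill = 0))), "TAA")
})

test_that("flavour sums recompute every printed flavour cell within 0.05", {
  prof <- fixture_mean_profiles()
  fl <- flavor_sums(prof)
  t1 <- builtin_fixture("table1")
  for (grp in c("sweet", "bitter", "acidic", "umami")) {
    printed <- unlist(t1[t1$variable == grp, origin_levels()])
    expect_equal(unlist(fl[[grp]]), printed, tolerance = 0.05,
                 ignore_attr = TRUE)
  }
  expect_equal(fl$umami[fl$origin == "Norway"], 2.96 + 4.21, tolerance = 1e-9)
  z <- flavor_sums(make_profile(fill = 0))
  expect_equal(unlist(z[, c("sweet", "bitter", "acidic", "umami")]),
               c(sweet = 0, bitter = 0, acidic = 0, umami = 0))
})

test_that("superiority is symmetric, scale-invariant and zero at equality", {
  expect_equal(superiority(1.18, 0.65), 81.5, tolerance = 0.05)
  expect_equal(superiority(34.71, 30.32), 14.5, tolerance = 0.05)
  expect_equal(superiority(3, 3), 0)
  set.seed(5)
  for (i in 1:20) {
    a <- stats::runif(1, 0.1, 10); b <- stats::runif(1, 0.1, 10)
    k <- stats::runif(1, 0.1, 10)
    expect_equal(superiority(a, b), superiority(b, a))
    expect_equal(superiority(k * a, k * b), superiority(a, b),
                 tolerance = 1e-9)
    expect_gte(superiority(a, b), 0)
  }
  expect_error(superiority(1, 0), "> 0")
})
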