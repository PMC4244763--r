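test_that("Mann-Whitney wrapper covers exact, approximate and degenerate cases", {
  # exact enumeration: P(U <= 0) = 1/6 per tail -> two-sided 1/3
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
  expect_equal(mann_whitney_u(c(5, 5, 5), c(5, 5)), 1.0)
  x <- rnorm(60)
  expect_equal(mann_whitney_u(x, x), 1.0, tolerance = 1e-10)
})

test_that("Mann-Whitney p-values are uniform under the null", {
  set.seed(71)
  ps <- replicate(1000, mann_whitney_u(rnorm(500), rnorm(500)))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("compute_stats reproduces the hand-enumerated four-member ensemble", {
  s <- compute_stats(5, c(1, 2, 3, 4), "higher")
  expect_equal(s$p, 0.25)
  expect_true(s$p_is_bound)
  expect_equal(s$mean, 2.5)
  expect_equal(s$T, 2.0)
  expect_equal(s$z, (5 - 2.5) / sd(c(1, 2, 3, 4)), tolerance = 1e-12)
  # direction flips the more-nested count
  s2 <- compute_stats(2.5, c(1, 2, 3, 4), "lower")
  expect_equal(s2$p, 0.5)
  expect_false(s2$p_is_bound)
})

test_that("compute_stats identities and degenerate warnings hold", {
  set.seed(72)
  ens <- rnorm(500, 40, 3)
  s <- compute_stats(44, ens, "higher")
  expect_equal(s$T, 44 / mean(ens), tolerance = 1e-12)
  expect_equal(s$z, (44 - mean(ens)) / sd(ens), tolerance = 1e-12)
  expect_true(s$p >= 1 / s$N && s$p <= 1)
  expect_equal(s$p * s$N, round(s$p * s$N), tolerance = 1e-9)
  expect_warning(szero <- compute_stats(1, c(2, 2, 2), "higher"),
                 "zero variance")
  expect_true(is.na(szero$z))
})

test_that("fixed ensembles score every draw with every measure, reproducibly", {
  tri <- make_fixture("nested", 3, 3, fill = 6)
  ens <- run_fixed_ensemble(tri, "SS", "NODF", N = 10, seed = 1)
  expect_length(ens$scores$NODF, 10L)
  expect_true(all(ens$scores$NODF >= 0 & ens$scores$NODF <= 100))

  m <- make_fixture("random", 8, 8, fill = 24, seed = 73)
  e1 <- run_fixed_ensemble(m, "FF", c("NODF", "SR"), N = 200, seed = 9)
  e2 <- run_fixed_ensemble(m, "FF", c("NODF", "SR"), N = 200, seed = 9)
  expect_identical(e1$scores, e2$scores)
  expect_length(e1$scores$NODF, 200L)
  expect_length(e1$scores$SR, 200L)
  # same draws serve both measures: regenerate NODF alone on the same seed
  e3 <- run_fixed_ensemble(m, "FF", "NODF", N = 200, seed = 9)
  expect_identical(e3$scores$NODF, e1$scores$NODF)
})

test_that("adaptive ensembles merge at 1000 under the null and honour growth arithmetic", {
  m <- make_fixture("random", 7, 7, fill = 21, seed = 74)
  ad <- run_adaptive_ensemble(m, "SS", "NODF", seed = 4)
  expect_gte(ad$N, 1000L)
  expect_lte(ad$N, 100000L)
  expect_equal(ad$N %% 1000L, 0L)
  expect_true(ad$adaptive)
  expect_length(ad$scores$NODF, ad$N)
})

test_that("an always-rejecting comparison grows the ensemble to the cap", {
  m <- as_biadjacency(diag(2))
  ad <- run_adaptive_ensemble(m, "SS", "MD", seed = 5, sort = FALSE,
                              cap = 3000L, utest = function(x, y) 0.0)
  expect_identical(ad$N, 3000L)
})

test_that("fixed and adaptive ensembles estimate the same null mean", {
  m <- make_fixture("random", 6, 6, fill = 14, seed = 75)
  set.seed(76)
  fixed_means <- replicate(50, mean(run_fixed_ensemble(
    m, "SS", "NODF", N = 1000)$scores$NODF))
  adapt_means <- replicate(50, mean(run_adaptive_ensemble(
    m, "SS", "NODF")$scores$NODF))
  expect_gt(t.test(fixed_means, adapt_means)$p.value, 0.01)
})

test_that("nested_test wires observed scores, ensembles and stats together", {
  tri <- make_fixture("nested", 3, 3, fill = 6)
  fit <- nested_test(tri, measures = "NODF", nulls = "SS",
                     ensemble = "fixed", N = 100, seed = 6)
  s <- fit$stats[["SS.NODF"]]
  expect_equal(fit$observed[["NODF"]], 100)
  expect_equal(s$p, 1 / 100)       # no SS draw can beat a perfect staircase
  expect_true(s$p_is_bound)

  m <- make_fixture("random", 8, 8, fill = 24, seed = 77)
  fit2 <- nested_test(m, measures = c("NODF", "SR"), nulls = c("CC", "FF"),
                      ensemble = "fixed", N = 50, seed = 6)
  expect_equal(nrow(fit2$table), 4L)
  expect_setequal(paste(fit2$table$null_model, fit2$table$measure),
                  c("CC NODF", "CC SR", "FF NODF", "FF SR"))
  # per-model substreams: adding a model does not perturb the first
  fit3 <- nested_test(m, measures = c("NODF", "SR"), nulls = "CC",
                      ensemble = "fixed", N = 50, seed = 6)
  expect_identical(fit3$ensembles$CC$scores, fit2$ensembles$CC$scores)
})

test_that("nested_test validates measure/model/mode combinations upfront", {
  m <- make_fixture("random", 5, 5, fill = 10, seed = 78)
  expect_error(nested_test(m, measures = "WNODF", nulls = "SS"),
               "WNODF", class = "nk_validation_error")
  expect_error(nested_test(m, measures = "NODF", nulls = "CRT"),
               class = "nk_validation_error")
  expect_error(nested_test(m, measures = "NODF", nulls = "SS",
                           binary = FALSE),
               class = "nk_validation_error")
  expect_error(nested_test(m, measures = "XYZ", nulls = "SS"),
               class = "nk_validation_error")
  expect_error(nested_test(m, measures = "NODF", nulls = "QQ"),
               "valid models", class = "nk_validation_error")
})

test_that("disabling the sort changes order-sensitive observed scores", {
  # complete staircase: strictly distinct fills, so the sorted NODF is 100
  tri <- make_fixture("nested", 5, 5, fill = 10)
  perm <- tri[5:1, 5:1]          # reversed staircase: all fills increasing
  sorted <- nestedness_score(perm, "NODF", sort = TRUE)
  unsorted <- nestedness_score(perm, "NODF", sort = FALSE)
  expect_equal(sorted, 100)
  expect_equal(unsorted, 0)
})
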