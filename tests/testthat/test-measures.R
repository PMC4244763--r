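tri3 <- as_biadjacency(rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0)))

test_that("NODF matches hand-enumerated pair sums and its extremes", {
  expect_equal(nodf(tri3), 100)
  expect_equal(nodf(as_biadjacency(diag(2))), 0)
  expect_equal(nodf(as_biadjacency(rbind(c(1, 1, 1), c(1, 1, 1), c(1, 0, 0)))),
               400 / 6, tolerance = 1e-9)
  expect_error(nodf(as_biadjacency(matrix(c(2, 0, 0, 1), 2))),
               class = "nk_validation_error")
})

test_that("NODF agrees with the brute-force oracle and vegan on random matrices", {
  skip_if_not_installed("vegan")
  set.seed(51)
  for (k in 1:25) {
    b <- sorted_binary(rand_binary(7, 6, fill = sample(10:30, 1)))
    expect_equal(nodf(b), nodf_oracle(b), tolerance = 1e-10)
    expect_equal(nodf(b),
                 unname(vegan::nestednodf(b, order = FALSE)$statistic["NODF"]),
                 tolerance = 1e-10)
  }
})

test_that("WNODF requires strictly decreasing weights and fill", {
  set.seed(52)
  expect_equal(wnodf(rand_binary(6, 6, 18)), 0)           # equal weights
  fx <- direction_fixtures()
  expect_equal(wnodf(degree_sort(fx$nested, TRUE)$matrix), 100)
  expect_equal(wnodf(as_biadjacency(rbind(c(2, 1), c(1, 0)))), 100)
})

test_that("WNODF agrees with vegan's weighted NODF on sorted matrices", {
  skip_if_not_installed("vegan")
  set.seed(53)
  for (k in 1:15) {
    w <- rand_weighted(7, 5, fill = sample(12:25, 1))
    sw <- degree_sort(strip_empty(w), use_weights = TRUE)$matrix
    expect_equal(wnodf(sw),
                 unname(vegan::nestednodf(sw, order = FALSE,
                                          weighted = TRUE)$statistic["NODF"]),
                 tolerance = 1e-10)
  }
})

test_that("Manhattan distance sums 0-based offsets of presences", {
  expect_equal(manhattan_distance(as_biadjacency(matrix(1, 1, 1))), 0)
  expect_equal(manhattan_distance(as_biadjacency(diag(2))), 2)
  expect_equal(manhattan_distance(tri3), 8)
})

test_that("temperature is zero on perfect patterns and matches the geometry oracle", {
  expect_equal(ntc_temperature(make_fixture("nested", 10, 10, fill = 55)), 0,
               tolerance = 1e-6)
  expect_equal(ntc_temperature(as_biadjacency(matrix(1, 4, 5))), 0)
  expect_error(ntc_temperature(as_biadjacency(matrix(1, 1, 3))),
               class = "nk_validation_error")
  # arrangement-as-given temperatures against the independent oracle
  set.seed(54)
  for (k in 1:6) {
    b <- strip_empty(rand_binary(5, 5, fill = sample(8:17, 1)))
    expect_equal(ntc_temperature(b, sort = FALSE), temperature_oracle(b),
                 tolerance = 1e-6)
  }
  # a single defect outside a perfect staircase scores (d/D)^2, rescaled
  b <- make_fixture("nested", 5, 5, fill = 12)
  b[5, 5] <- 1
  b <- as_biadjacency(unname(b))
  expect_equal(ntc_temperature(b, sort = FALSE), temperature_oracle(b),
               tolerance = 1e-6)
})

test_that("JDM equals its configuration-model oracle and fixed points", {
  expect_equal(jdm(as_biadjacency(matrix(1, 3, 4))), 1.0)
  expect_equal(jdm(as_biadjacency(diag(2))), 0.0)
  expect_equal(jdm(tri3), 12 / 11, tolerance = 1e-12)
  set.seed(55)
  for (k in 1:20) {
    b <- strip_empty(rand_binary(6, 7, fill = sample(10:30, 1)))
    expect_equal(jdm(b), jdm_oracle(b), tolerance = 1e-10)
  }
  expect_error(jdm(as_biadjacency(matrix(1, 1, 1))),
               class = "nk_validation_error")
})

test_that("discrepancy counts presences outside the packed form", {
  expect_equal(discrepancy(tri3), 0L)
  expect_equal(discrepancy(as_biadjacency(rbind(c(1, 0, 1), c(1, 1, 0)))), 1L)
  expect_equal(discrepancy(as_biadjacency(diag(2))), 1L)
  skip_if_not_installed("vegan")
  # cross-check against vegan wherever column degrees are strict, so that
  # vegan's own tie-order search cannot diverge from the packed-row count
  checked <- 0L
  for (k in 1:100) {
    b <- strip_empty(make_fixture("random", 7, 4, fill = 12 + k %% 7,
                                  seed = k))
    sb <- degree_sort(b)$matrix
    if (anyDuplicated(colSums(sb))) next
    expect_equal(discrepancy(sb), unname(vegan::nesteddisc(sb)$statistic))
    checked <- checked + 1L
  }
  expect_gte(checked, 10L)
})

test_that("spectral radius equals the top singular value on small cases", {
  expect_equal(spectral_radius(as_biadjacency(matrix(1, 1, 1))), 1.0)
  expect_equal(spectral_radius(as_biadjacency(matrix(1, 2, 2))), 2.0)
  m <- as_biadjacency(rbind(c(3, 1), c(0, 2)))
  ev <- eigen(rbind(cbind(matrix(0, 2, 2), m),
                    cbind(t(m), matrix(0, 2, 2))))$values
  expect_equal(spectral_radius(m), max(Re(ev)), tolerance = 1e-10)
})

test_that("SR and JDM are order-invariant to numerical precision", {
  set.seed(56)
  b <- strip_empty(rand_binary(8, 7, fill = 24))
  w <- rand_weighted(8, 7, fill = 24)
  for (k in 1:50) {
    pr <- sample(8); pc <- sample(7)
    expect_equal(jdm(b[pr, pc]), jdm(b), tolerance = 1e-9)
    expect_equal(spectral_radius(w[pr, pc]), spectral_radius(w),
                 tolerance = 1e-9)
  }
})

test_that("measure ranges hold on random fixtures", {
  set.seed(57)
  for (k in 1:200) {
    b <- strip_empty(rand_binary(6, 6, fill = sample(6:30, 1)))
    expect_true(nestedness_score(b, "NODF") >= 0 &&
                  nestedness_score(b, "NODF") <= 100)
    ntc <- nestedness_score(b, "NTC")
    expect_gte(ntc, 0)
    expect_lte(ntc, 100 + 1e-9)
    md <- nestedness_score(b, "MD")
    expect_true(md >= 0 && md == round(md))
    br <- nestedness_score(b, "BR")
    expect_true(br >= 0 && br == round(br))
    expect_gte(nestedness_score(b, "JDM"), 0)
    expect_gte(nestedness_score(b, "SR"), 0)
    w <- rand_weighted(5, 5, fill = sample(6:20, 1))
    wn <- nestedness_score(w, "WNODF")
    expect_true(wn >= 0 && wn <= 100)
  }
})

test_that("direction fixtures satisfy their fill and sum constraints", {
  fx <- direction_fixtures()
  expect_equal(sum(fx$nested != 0), 55L)
  expect_equal(sum(fx$nested), 220)
  expect_equal(sum(fx$checkerboard != 0), 55L)
  expect_equal(sum(fx$checkerboard), 220)
  expect_equal(dim(fx$nested), c(10L, 10L))
  expect_equal(dim(fx$checkerboard), c(10L, 11L))
})

test_that("directions of increasing nestedness are detected as documented", {
  expect_equal(detect_direction("NODF"), "higher")
  expect_equal(detect_direction("JDM"), "higher")
  expect_equal(detect_direction("SR"), "higher")
  expect_equal(detect_direction("WNODF"), "higher")
  expect_equal(detect_direction("MD"), "lower")
  expect_equal(detect_direction("BR"), "lower")
  expect_equal(detect_direction("NTC"), "lower")
})
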