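test_that("tmm_reference picks the sample closest to the mean 75th-percentile fraction", {
  m <- rand_counts(30, 4, seed = 1)
  same <- m[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  expect_identical(tmm_reference(same), 1L)   # first among ties

  # random matrices: agree with a brute-force re-evaluation of the rule
  for (seed in 1:10) {
    mm <- rand_counts(50, 4, mu = 50, seed = seed)
    expect_identical(tmm_reference(mm), oracle_tmm_reference(mm))
  }

  zeros <- matrix(0L, 3, 2, dimnames = list(letters[1:3], c("x", "y")))
  expect_error(tmm_reference(zeros), "all-zero")
})

test_that("tmm_factors: identical columns give unit factors", {
  one <- rand_counts(40, 1, seed = 5)
  m <- one[, c(1, 1, 1, 1)]
  colnames(m) <- paste0("s", 1:4)
  f <- tmm_factors(m)
  expect_equal(unname(f$factors), rep(1, 4))
})

test_that("tmm_factors matches a brute-force trimmed weighted mean", {
  # 6-gene, 2-sample toy with one high-count gene dominating sample 2
  y <- matrix(c(100L, 120L, 80L, 90L, 110L, 100L,
                100L, 120L, 80L, 90L, 110L, 5000L), 6, 2,
              dimnames = list(paste0("g", 1:6), c("s1", "s2")))
  f <- tmm_factors(y, reference = 1L)
  expected <- oracle_tmm_pair(y[, 2], y[, 1])
  expected <- c(1, expected) / exp(mean(log(c(1, expected))))
  expect_equal(unname(f$factors), expected, tolerance = 1e-12)

  # and on random matrices against the same independent evaluation
  for (seed in 1:5) {
    m <- rand_counts(80, 3, mu = 200, seed = seed)
    m[m == 0L] <- 1L   # keep every gene in the pairwise comparison
    r <- tmm_reference(m)
    f <- tmm_factors(m)
    raw <- vapply(1:3, function(k)
      if (k == r) 1 else oracle_tmm_pair(m[, k], m[, r]), numeric(1))
    expect_equal(unname(f$factors), raw / exp(mean(log(raw))),
                 tolerance = 1e-12)
  }
})

test_that("tmm_factors agrees with the reference Bioconductor implementation", {
  skip_if_not_installed("edgeR")
  for (seed in 1:5) {
    m <- rand_counts(200, 5, mu = 150, size = 5, seed = seed)
    f <- tmm_factors(m)
    expect_equal(unname(f$factors),
                 unname(edgeR::calcNormFactors(m, method = "TMM")),
                 tolerance = 1e-10)
  }
})

test_that("tmm_factors invariants: geometric mean one, positive, errors", {
  m <- rand_counts(100, 5, seed = 9)
  f <- tmm_factors(m)
  expect_true(all(f$factors > 0))
  expect_lt(abs(mean(log(f$factors))), 1e-9)

  m0 <- m; m0[, 2] <- 0L
  expect_error(tmm_factors(m0), "zero library size")

  # scaling a single column leaves M and A (hence trimming) unchanged;
  # only the count-based precision weights drift, and only slightly
  m10 <- m; m10[, 3] <- m10[, 3] * 10L
  f10 <- tmm_factors(m10, reference = tmm_reference(m))
  expect_identical(tmm_reference(m10), tmm_reference(m))
  expect_lt(max(abs(f10$factors - f$factors)), 0.02)
})

test_that("logcpm_transform applies the voom-style formula", {
  # libraries forced to exactly 1e6, unit factors
  m <- matrix(c(0L, 1000000L, 50L, 999950L), 2, 2,
              dimnames = list(c("gA", "gB"), c("s1", "s2")))
  x <- logcpm_transform(m, factors = NULL, prior = 0.5)
  expect_equal(x["gA", "s1"], log2(0.5 * 1e6 / (1e6 + 1)), tolerance = 1e-12)
  expect_equal(x["gA", "s2"], log2(50.5 * 1e6 / (1e6 + 1)), tolerance = 1e-12)

  # value exactly 0 when (c + 0.5) * 1e6 == lib * factor + 1:
  # c = 3, library 3.5e6 - 1
  cc <- matrix(c(3L, 3499996L), 2, 1,
               dimnames = list(c("gA", "gB"), "s1"))
  x0 <- logcpm_transform(cc, factors = NULL, prior = 0.5)
  expect_identical(unname(x0["gA", "s1"]), 0)

  expect_error(logcpm_transform(m, factors = NULL, prior = 0), "prior")
  expect_error(logcpm_transform(m, factors = NULL, prior = -1), "prior")
})

test_that("logcpm_transform is finite, monotone in counts, and shape-preserving", {
  m <- rand_counts(60, 4, mu = 20, seed = 3)
  x <- logcpm_transform(m)
  expect_true(all(is.finite(x)))
  expect_identical(dimnames(x), dimnames(m))

  # strictly increasing in count within a sample
  ord <- order(m[, 1])
  expect_true(all(diff(x[ord, 1][!duplicated(m[ord, 1])]) > 0))
})
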