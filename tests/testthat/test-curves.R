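make_plan <- function(kind, pairs, group = c(1L, 1L, 2L, 2L)) {
  structure(list(kind = kind, B = length(pairs), seed = NULL,
                 group = group, pairs = pairs),
            class = "rots_plan")
}

toy_x <- function() {
  set.seed(5)
  matrix(round(rnorm(16, 5, 2), 2), 4, 4,
         dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
}

toy_boot <- function() make_plan("bootstrap", list(
  list(a = c(1L, 2L, 3L, 4L), b = c(1L, 1L, 3L, 4L)),
  list(a = c(2L, 1L, 4L, 4L), b = c(1L, 2L, 4L, 3L))))

toy_null <- function() make_plan("null", list(
  list(a = c(1L, 3L, 2L, 4L), b = c(4L, 2L, 3L, 1L)),
  list(a = c(2L, 4L, 1L, 3L), b = c(3L, 1L, 4L, 2L))))

test_that("curves on a fully enumerated 4-gene toy match frozen oracle values", {
  ag <- data.frame(alpha1 = c(0, 1), alpha2 = c(1, 0))
  kg <- c(1L, 3L)
  cv <- reproducibility_curves(toy_x(), toy_boot(), toy_null(), ag, kg)

  # frozen values computed with the independent loop/intersect oracle
  expect_equal(cv$R, rbind(c(0.5, 5 / 6), c(0.5, 5 / 6)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(cv$s, rbind(c(sqrt(0.5), sqrt(2) / 6), c(sqrt(0.5), sqrt(2) / 6)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(cv$R0, rbind(c(1, 1), c(1, 1)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(cv$Z, (cv$R - cv$R0) / cv$s, tolerance = 1e-12)

  # and the oracle agrees wholesale
  oc <- oracle_curves(toy_x(), toy_boot(), toy_null(), ag, kg)
  expect_equal(cv$R, oc$R, tolerance = 1e-12)
  expect_equal(cv$s, oc$s, tolerance = 1e-12)
  expect_equal(cv$R0, oc$R0, tolerance = 1e-12)
})

test_that("forcing identical pair members gives R = 1 everywhere", {
  x <- rand_expr(20, 4, seed = 7)
  pairs <- lapply(1:3, function(b) {
    idx <- c(sample(1:2, 2, TRUE), sample(3:4, 2, TRUE))
    list(a = idx, b = idx)
  })
  boot <- make_plan("bootstrap", pairs)
  null <- make_plan("null", lapply(1:3, function(b)
    list(a = sample(4L), b = sample(4L))))
  cv <- reproducibility_curves(x, boot, null,
                               data.frame(alpha1 = c(0, 0.5, 1),
                                          alpha2 = c(1, 1, 0)),
                               c(2L, 5L, 10L, 20L))
  expect_true(all(cv$R == 1))
  expect_true(all(cv$s == 0))
  expect_true(all(is.na(cv$Z)))   # s = 0 -> Z flagged undefined
  expect_true(all(cv$R0 >= 0 & cv$R0 <= 1))
})

test_that("curves agree with the slow oracle on random data", {
  set.seed(31)
  x <- rand_expr(12, 5)
  design <- group_design(colnames(x), c("A", "A", "A", "B", "B"))
  boot <- make_bootstrap_pairs(design, 6, seed = 1)
  null <- make_null_pairs(design, 6, seed = 2)
  ag <- data.frame(alpha1 = c(0, 0.2, 1, 1), alpha2 = c(1, 1, 1, 0))
  kg <- c(1L, 3L, 6L, 12L)
  cv <- reproducibility_curves(x, boot, null, ag, kg)
  oc <- oracle_curves(x, boot, null, ag, kg)
  expect_equal(cv$R, oc$R, tolerance = 1e-12)
  expect_equal(cv$s, oc$s, tolerance = 1e-12)
  expect_equal(cv$R0, oc$R0, tolerance = 1e-12)
  expect_equal(cv$Z, oc$Z, tolerance = 1e-12)
  expect_true(all(cv$R >= 0 & cv$R <= 1))
})

test_that("rots_optimize returns the lattice maximum with documented tie-breaks", {
  fake <- function(Z, a1, a2, k) {
    structure(list(alpha_grid = data.frame(alpha1 = a1, alpha2 = a2),
                   k_grid = k, R = Z * 0 + 0.5, s = Z * 0 + 1,
                   R0 = Z * 0, Z = Z, B_boot = 2L, B_null = 2L),
              class = "rots_curves")
  }
  # unique maximum
  Z <- rbind(c(1, 2), c(0.5, 3))
  opt <- rots_optimize(fake(Z, c(0, 1), c(1, 1), c(100L, 500L)))
  expect_identical(c(opt$alpha1, opt$k, opt$Z), c(1, 500, 3))

  # equal Z at k = 100 and k = 500 -> larger k wins
  Z <- rbind(c(3, 3), c(1, 2))
  opt <- rots_optimize(fake(Z, c(0, 1), c(1, 1), c(100L, 500L)))
  expect_identical(opt$k, 500L)
  expect_identical(opt$alpha1, 0)

  # same k: smaller alpha1 wins, then larger alpha2
  Z <- rbind(c(1, 3), c(1, 3), c(1, 3))
  opt <- rots_optimize(fake(Z, c(1, 1, 2), c(0, 1, 1), c(10L, 50L)))
  expect_identical(c(opt$alpha1, opt$alpha2, opt$k), c(1, 1, 50))

  # all Z undefined -> error
  Zna <- matrix(NA_real_, 2, 2)
  expect_error(rots_optimize(fake(Zna, c(0, 1), c(1, 1), c(5L, 10L))),
               "insufficient")
})

test_that("fdr_from_stats implements the permutation estimator", {
  fdr_from_stats <- rotsde:::fdr_from_stats
  # all permuted statistics below the observed minimum -> fdr 0 everywhere
  expect_identical(fdr_from_stats(c(3, 2, 1), cbind(c(0.5, 0.1, 0.2))),
                   c(0, 0, 0))
  # hand-computed example: raw = [0, 0.5, 1/3] -> adjusted [0, 1/3, 1/3]
  expect_equal(fdr_from_stats(c(3, 2, 1), cbind(c(2.5, 0.5, 0.1))),
               c(0, 1 / 3, 1 / 3), tolerance = 1e-12)
  # permuted identical to observed -> fdr 1 everywhere
  expect_identical(fdr_from_stats(c(3, 2, 1), cbind(c(3, 2, 1))), c(1, 1, 1))
  # several permutations average in the numerator:
  # raw = [0.5/1, 1/2] = [0.5, 0.25]; step-up -> [0.25, 0.25]
  expect_equal(fdr_from_stats(c(2, 1), cbind(c(3, 0), c(0, 0))),
               c(0.25, 0.25), tolerance = 1e-12)
})

test_that("estimate_fdr is deterministic, bounded and monotone along the ranking", {
  x <- rand_expr(40, 6, seed = 13)
  grp <- two_group(3, 3)
  f1 <- estimate_fdr(x, grp, 0.5, 1, P = 30, seed = 4)
  f2 <- estimate_fdr(x, grp, 0.5, 1, P = 30, seed = 4)
  expect_identical(f1, f2)
  expect_true(all(f1 >= 0 & f1 <= 1))
  d <- d_stat(x, grp, 0.5, 1)
  ord <- rank_genes(d)
  expect_true(all(diff(f1[ord]) >= 0))
  # tied statistics share the same fdr
  fdr_tied <- rotsde:::fdr_from_stats(c(2, 2, 1), cbind(c(2.5, 1.5, 0.5)))
  expect_identical(fdr_tied[1], fdr_tied[2])
  expect_error(estimate_fdr(x, grp, 0.5, 1, P = 0), "at least 1")
})
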