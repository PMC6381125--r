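test_that("median-of-ratios size factors match the definition", {
  # pure scaling: sample 2 has every count doubled
  m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2)
  sf <- size_factors(m)
  expect_equal(unname(sf[2] / sf[1]), 2)
  # worked example
  m2 <- matrix(c(2, 2, 4, 4), ncol = 2)
  expect_equal(unname(size_factors(m2)), c(2 / sqrt(8), 4 / sqrt(8)))
  # single sample convention
  expect_equal(unname(size_factors(matrix(c(5, 9), ncol = 1))), 1)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), ncol = 2)), "nonzero")
})

test_that("size factors agree with the DESeq reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(5)
  m <- matrix(rnbinom(200 * 6, mu = 50, size = 2), ncol = 6)
  m[m == 0] <- 1L
  # the reference takes the median on the log scale; with an even number of
  # species the two medians differ only by the averaging scale
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-3)
})

test_that("dispersion estimation recovers the generating parameter", {
  groups <- rep(c("a", "b"), each = 15)
  # identical constant rows: zero variance, zero dispersion
  cm <- matrix(50, nrow = 10, ncol = 30)
  expect_equal(estimate_dispersion(cm, groups), 0)
  expect_error(estimate_dispersion(matrix(0, 3, 30), groups), "all-zero")
  # Poisson data: dispersion about zero
  set.seed(8)
  mp <- matrix(rpois(1000 * 30, lambda = rep(exp(rnorm(1000, 4, 1)),
                                             30)), ncol = 30)
  expect_lt(abs(estimate_dispersion(mp, groups)), 0.01)
  # negative binomial, phi = 0.2
  mu <- exp(rnorm(800, 4, 1))
  mn <- matrix(rnbinom(800 * 30, mu = rep(mu, 30), size = 1 / 0.2),
               ncol = 30)
  expect_lt(abs(estimate_dispersion(mn, groups) - 0.2), 0.05)
})

test_that("the exact test reduces to known closed forms", {
  # symmetric null: identical counts in equal-sized groups
  expect_equal(nb_exact_test(rep(7, 6), rep(c(TRUE, FALSE), each = 3),
                             phi = 0.1), 1)
  # phi = 0, sums 20 vs 0: conditional binomial two-sided tail
  p <- nb_exact_test(c(10, 5, 5, 0, 0, 0), rep(c(TRUE, FALSE), each = 3),
                     phi = 0)
  expect_equal(p, 2 * 0.5^20, tolerance = 1e-12)
  # zero total count
  expect_equal(nb_exact_test(rep(0, 6), rep(c(TRUE, FALSE), each = 3),
                             phi = 0.1), 1)
  # p-values live in (0, 1]
  set.seed(9)
  for (i in 1:50) {
    x <- rnbinom(10, mu = 30, size = 5)
    p <- nb_exact_test(x, rep(c(TRUE, FALSE), each = 5), phi = 0.2)
    expect_gt(p, 0); expect_lte(p, 1)
  }
})

test_that("the null distribution of exact-test p-values is conservative-free", {
  set.seed(10)
  groups <- rep(c(TRUE, FALSE), c(8, 22))
  n <- 800
  mu <- exp(rnorm(n, log(100), 0.5))
  p <- vapply(seq_len(n), function(i)
    nb_exact_test(rnbinom(30, mu = mu[i], size = 1 / 0.1), groups,
                  phi = 0.1), numeric(1))
  # ties are expected for a discrete exact test; the KS warning is benign
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.08)
})

test_that("Benjamini-Hochberg adjustment follows the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  # invariant under permutation of the input order
  set.seed(11)
  p <- runif(50)
  o <- sample(50)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
  # q >= p always
  expect_true(all(bh_adjust(p) >= p))
})

test_that("cumulative expression ranking and quartile flags", {
  m <- matrix(c(50, 30, 15, 5), ncol = 1,
              dimnames = list(c("a", "b", "c", "d"), "s1"))
  ce <- cumulative_expression(m)
  expect_equal(ce$cumulative_fraction, c(0.5, 0.8, 0.95, 1))
  expect_equal(ce$species_id, c("a", "b", "c", "d"))
  expect_equal(ce$upper_quartile, c(TRUE, FALSE, FALSE, FALSE))
  # uniform totals
  mu <- matrix(rep(10, 5), ncol = 1,
               dimnames = list(letters[1:5], "s1"))
  expect_equal(cumulative_expression(mu)$cumulative_fraction,
               (1:5) / 5)
})

test_that("Kendall correlation handles concordance, ties and edge cases", {
  x <- c(1, 3, 5, 7, 9, 11)
  r <- correlate_pairs(x, x * 2 + 1)
  expect_equal(r$tau, 1)
  expect_lt(r$p, 0.01)
  r <- correlate_pairs(x, rev(x))
  expect_equal(r$tau, -1)
  expect_gt(r$p, 0.99)
  rc <- correlate_pairs(c(2, 2, 2, 2, 2), c(1, 2, 3, 4, 5))
  expect_true(is.na(rc$tau))
  # small-n exact p agrees with the reference exact test (no ties)
  set.seed(12)
  for (i in 1:10) {
    a <- sample(100, 6); b <- sample(100, 6)
    r <- correlate_pairs(a, b)
    want <- stats::cor.test(a, b, method = "kendall",
                            alternative = "greater", exact = TRUE)
    expect_equal(r$p, unname(want$p.value), tolerance = 1e-9)
    expect_equal(r$tau, unname(want$estimate), tolerance = 1e-9)
  }
  # large-n normal approximation is one-tailed and sane
  set.seed(13)
  a <- rnorm(30); b <- a + rnorm(30, sd = 0.5)
  r <- correlate_pairs(a, b)
  expect_lt(r$p, 0.001)
})

test_that("group-vs-rest testing flags the planted change", {
  set.seed(14)
  n <- 120
  groups <- rep(c("MAF", "other"), c(8, 22))
  mu <- exp(rnorm(n, log(80), 0.8))
  m <- matrix(rnbinom(n * 30, mu = rep(mu, 30), size = 1 / 0.15), ncol = 30)
  rownames(m) <- sprintf("sp%03d", seq_len(n))
  colnames(m) <- sprintf("S%02d", 1:30)
  # plant a 4-fold change in the MAF group for one abundant species
  m[1, groups == "MAF"] <- rnbinom(8, mu = 4 * 200, size = 1 / 0.15)
  m[1, groups == "other"] <- rnbinom(22, mu = 200, size = 1 / 0.15)
  de <- de_test(m, groups)
  hit <- de[de$species_id == "sp001" & de$contrast == "MAF", ]
  expect_lt(hit$qvalue, 0.05)
  expect_gt(hit$log2fc, 1)
  expect_true(all(de$qvalue >= de$pvalue - 1e-12))
})
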