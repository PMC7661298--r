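test_that("mean-LRS correction identity cases hold", {
  expect_equal(unbiased_mean_lrs(2.0, 100, 90, 50, 0), 2.0)
  expect_equal(unbiased_mean_lrs(2.0, 100, 100, 50, 0.3), 2.0)
  # direct arithmetic of the four correction steps
  expect_equal(unbiased_mean_lrs(2.0, 100, 90, 50, 0.05),
               2.0 - (10 / 50) * (0.05 / 0.95))
})

test_that("correction reproduces step-by-step hand arithmetic on random inputs", {
  set.seed(7)
  for (i in 1:25) {
    S <- sample(50:5000, 1)
    A <- sample(0:S, 1)
    N <- sample(1:500, 1)
    eps <- runif(1, 0, 0.5)
    raw <- runif(1, 0, 10)
    expect_equal(suppressWarnings(unbiased_mean_lrs(raw, S, A, N, eps)),
                 correction_steps_oracle(raw, S, A, N, eps),
                 tolerance = 1e-12)
  }
})

test_that("correction is monotone in epsilon and in unassigned offspring", {
  eps_grid <- seq(0, 0.9, by = 0.1)
  vals <- vapply(eps_grid, function(e)
    suppressWarnings(unbiased_mean_lrs(1.5, 200, 120, 40, e)), numeric(1))
  expect_true(all(diff(vals) < 0))
  gaps <- seq(0, 80, by = 20)
  vals2 <- vapply(gaps, function(g)
    unbiased_mean_lrs(1.5, 120 + g, 120, 40, 0.1), numeric(1))
  expect_true(all(diff(vals2) < 0))
  expect_equal(vals[1], 1.5)  # identity at epsilon = 0
})

test_that("correction validates inputs and warns on negative results", {
  expect_error(unbiased_mean_lrs(1, 10, 5, 0, 0.1), "n_parents")
  expect_error(unbiased_mean_lrs(1, 10, 5, 10, 1), "epsilon")
  expect_error(unbiased_mean_lrs(1, 10, 11, 10, 0.1), "exceed")
  expect_warning(v <- unbiased_mean_lrs(0.01, 1000, 0, 10, 0.5), "negative")
  expect_lt(v, 0)
  expect_equal(unbiased_mean_lrs(0.01, 1000, 0, 10, 0.5, clamp = TRUE), 0)
})

test_that("cohort RRS is ratio arithmetic with wild fixed at 1", {
  expect_equal(cohort_rrs(1.2, 1.2), 1)
  expect_equal(cohort_rrs(0.36, 1.0), 0.36)
  expect_equal(cohort_rrs(0, 2.5), 0)
  expect_error(cohort_rrs(0.5, 0), "positive")
  expect_error(cohort_rrs(0.5, -1, cohort = 1980), "1980")
})

test_that("permutation p matches exhaustive enumeration on tiny groups", {
  cap <- c(0, 0)
  wld <- c(5, 5)
  oracle <- enumerate_permutation_p(cap, wld)
  expect_equal(oracle$n_arrangements, choose(4, 2))
  expect_equal(oracle$p_strict, 0)
  expect_equal(oracle$p_weak_num, 1 / 6)
  strict <- permutation_test(cap, wld, n_perm = 20000, tie_rule = "strict",
                             seed = 1)
  expect_equal(strict$p, 0)
  weak <- permutation_test(cap, wld, n_perm = 20000, tie_rule = "weak",
                           seed = 1)
  sd3 <- 3 * sqrt(oracle$p_weak_num * (1 - oracle$p_weak_num) / 20000)
  expect_lt(abs(weak$p - oracle$p_weak_num), sd3 + 1e-4)
})

test_that("permutation test handles constant data, direction and errors", {
  expect_warning(res <- permutation_test(c(2, 2), c(2, 2, 2), n_perm = 50,
                                         seed = 1), "constant")
  expect_equal(res$observed_diff, 0)
  expect_equal(res$p, 1)
  expect_error(permutation_test(numeric(0), c(1, 2)), "non-empty")
  expect_error(permutation_test(c(1), c(1, 2), n_perm = 0), "n_perm")
  # weak-rule p is never exactly zero
  res2 <- permutation_test(c(0, 0, 0), c(9, 9, 9), n_perm = 500, seed = 2)
  expect_gt(res2$p, 0)
})

test_that("Fisher's combined test follows the closed form", {
  fc <- fisher_combined(rep(0.5, 6))
  expect_equal(fc$df, 12L)
  expect_equal(fc$chi2, -12 * log(0.5))
  expect_equal(fc$p, pchisq(-12 * log(0.5), 12, lower.tail = FALSE))
  # a p of 1 contributes nothing
  expect_equal(fisher_combined(c(0.2, 1))$chi2, fisher_combined(0.2)$chi2)
  expect_error(fisher_combined(numeric(0)), "non-empty")
  expect_error(fisher_combined(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("zero p-values are substituted by the conservative floor", {
  expect_error(fisher_combined(c(0, 0.5)), "substitute")
  fc <- fisher_combined(c(0, 0.5), zero_policy = "substitute", n_perm = 999)
  expect_equal(fc$substitutions$substituted, 1 / 1000)
  expect_equal(fc$chi2, -2 * (log(1 / 1000) + log(0.5)))
  # the larger (more conservative) of floor and alternative wins
  fc2 <- fisher_combined(c(0, 0.5), zero_policy = "substitute",
                         n_perm = 999, alt_p = c(0.01, NA))
  expect_equal(fc2$substitutions$substituted, 0.01)
})

test_that("overall RRS is a weighted geometric mean", {
  expect_equal(overall_rrs(c(0.25, 1.0), c(1, 1)), 0.5)
  expect_equal(overall_rrs(0.36, 1), 0.36)
  # invariance: all cohorts equal -> that value, any weights
  expect_equal(overall_rrs(rep(0.7, 4), c(5, 1, 9, 2)), 0.7)
  expect_warning(v <- overall_rrs(c(0, 0.5, 2), c(1, 1, 1)), "excluded")
  expect_equal(v, exp(mean(log(c(0.5, 2)))))
  expect_error(suppressWarnings(overall_rrs(c(0, 0), c(1, 1))), "undefined")
  expect_error(overall_rrs(c(0.5, 0.5), c(1, -1)), "positive")
})

test_that("zero-LRS proportion test matches 2x2 chi-squared arithmetic", {
  eq <- zero_lrs_proportion_test(30, 100, 30, 100)
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p, 0.5)
  ht <- zero_lrs_proportion_test(90, 100, 50, 100)
  expect_equal(ht$chi2, chi2_2x2(90, 10, 50, 50))
  swapped <- zero_lrs_proportion_test(50, 100, 90, 100)
  expect_equal(swapped$p, 1 - ht$p)
  expect_error(zero_lrs_proportion_test(5, 0, 1, 10), "positive")
  expect_error(zero_lrs_proportion_test(11, 10, 1, 10), "between")
})

test_that("zero-excluded RRS filters zeros and keeps the ratio of positives", {
  expect_warning(res <- zero_excluded_rrs(c(0, 2), c(0, 2), n_perm = 100,
                                          seed = 1), "constant")
  expect_equal(res$rrs, 1)
  expect_equal(res$n_captive, 1L)
  expect_error(zero_excluded_rrs(c(0, 0), c(1, 2), n_perm = 10),
               "captive")
})

test_that("zero excess drives all-records RRS below the zero-excluded RRS", {
  # equal positive-part means, more zeros among captive-bred
  set.seed(31)
  pos <- function(n) 1 + rpois(n, 1.2)
  wld <- ifelse(runif(4000) < 0.5, 0, pos(4000))
  cap <- ifelse(runif(4000) < 0.75, 0, pos(4000))
  all_rrs <- mean(cap) / mean(wld)
  zx <- zero_excluded_rrs(cap, wld, n_perm = 200, seed = 5)
  expect_lt(all_rrs, 0.6)
  expect_lt(abs(zx$rrs - 1), 0.1)
})

test_that("mixed-population reduction is the weighted-count formula", {
  expect_equal(mixed_population_reduction(c(10, 20), c(1, 1), c(30, 40)), 0)
  expect_equal(mixed_population_reduction(50, 0.36, 50), 32)
  expect_equal(mixed_population_reduction(c(0, 0), c(0.2, 0.5), c(10, 10)), 0)
  expect_error(mixed_population_reduction(c(1, 2), c(0.5), c(1, 2)),
               "equal length")
  # with no wild fish the reduction is bounded by the extreme cohort RRS
  r <- c(0.2, 0.8)
  red <- mixed_population_reduction(c(30, 70), r, c(0, 0))
  expect_gte(red, 100 * (1 - max(r)))
  expect_lte(red, 100 * (1 - min(r)))
})

test_that("combined chi2 of uniform p-values averages 2k", {
  set.seed(19)
  k <- 6
  chi2s <- replicate(400, fisher_combined(runif(k))$chi2)
  # mean of chi-squared(2k) is 2k; SE = sqrt(2 * 2k / 400)
  expect_lt(abs(mean(chi2s) - 2 * k), 4 * sqrt(4 * k / 400))
})
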