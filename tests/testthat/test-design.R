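# Validation experiment design: minimum sample size and design curves.

test_that("n_significant counts features below the q-value cutoff", {
  expect_equal(n_significant(c(0.001, 0.5, 0.9), 0.05), 1)
  p <- runif(50)
  expect_equal(n_significant(p, 1 - 1e-12), 50)
  expect_equal(n_significant(rep(1, 20), 0.05), 0)
  expect_error(n_significant(c(0.2, 1.5), 0.05), "\\[0, 1\\]")
})

test_that("minimum sample size matches a brute-force scan", {
  # independent scan written out longhand
  brute_force <- function(q, target, fp_rule, n_max = 2000) {
    for (n in 1:n_max) {
      nfp <- if (fp_rule == "floor") floor(q * n) else q * n
      if (pbeta(q, 1 + nfp, 1 + n - nfp) > target + 1e-12) return(n)
    }
    NA_integer_
  }
  for (q in c(0.1, 0.2, 0.3, 0.5, 0.8)) {
    for (target in c(0.3, 0.5, 0.7)) {
      for (rule in c("floor", "continuous")) {
        expected <- brute_force(q, target, rule)
        plan <- min_validation_sample_size(q, target, n_sig = 2000,
                                           fp_rule = rule,
                                           scan_limit = 2000)
        expect_equal(plan$min_n, expected,
                     info = sprintf("q=%g target=%g rule=%s", q, target, rule))
        expect_equal(plan$achievable, !is.na(expected))
      }
    }
  }
})

test_that("the worked minimum-sample-size example gives n = 6 at FDR 10%", {
  plan <- min_validation_sample_size(q = 0.10, target = 0.5, n_sig = 1000)
  expect_equal(plan$min_n, 6L)
  # the scan really is minimal: n = 1..5 all fail the target
  vp <- sapply(1:5, function(n) pbeta(0.1, 1 + floor(0.1 * n),
                                      1 + n - floor(0.1 * n)))
  expect_true(all(vp <= 0.5))
  expect_gt(pbeta(0.1, 1, 7), 0.5)
})

test_that("the continuous rule cannot reach target 0.5 below FDR 50%", {
  # symmetric case: posterior Beta(1 + n/2, 1 + n/2) sits exactly at 0.5
  plan <- min_validation_sample_size(q = 0.5, target = 0.5, n_sig = 5000,
                                     fp_rule = "continuous",
                                     scan_limit = 5000)
  expect_false(plan$achievable)
  expect_false(plan$capped_by_nsig)

  # q < 0.5: the posterior median always exceeds q when n_fp = q * n
  plan <- min_validation_sample_size(q = 0.05, target = 0.5, n_sig = 1000,
                                     fp_rule = "continuous")
  expect_false(plan$achievable)
  expect_false(plan$capped_by_nsig)
  expect_true(is.na(plan$min_n))
})

test_that("too few significant features flags capped_by_nsig", {
  plan <- min_validation_sample_size(q = 0.10, target = 0.5, n_sig = 3)
  expect_false(plan$achievable)
  expect_true(plan$capped_by_nsig)
  expect_true(is.na(plan$min_n))
})

test_that("achievable min_n shrinks as the target drops and the cutoff grows", {
  # at FDR 20% with the floor rule the probability peaks around 0.67, so
  # only targets below that peak are achievable
  targets <- c(0.1, 0.3, 0.5, 0.65)
  mins <- sapply(targets, function(t) {
    min_validation_sample_size(0.2, t, n_sig = 10000)$min_n
  })
  expect_false(anyNA(mins))
  expect_true(all(diff(mins) >= 0))  # nonincreasing as target decreases

  # unachievable at a target stays unachievable at any higher target
  p1 <- min_validation_sample_size(0.05, 0.5, n_sig = 1000,
                                   fp_rule = "continuous")
  p2 <- min_validation_sample_size(0.05, 0.8, n_sig = 1000,
                                   fp_rule = "continuous")
  expect_false(p1$achievable)
  expect_false(p2$achievable)
})

test_that("sample-size curve is monotone over achievable cutoffs", {
  set.seed(5)
  p <- c(runif(300, 0, 1e-4), runif(700))  # strong mix, large n_sig
  curve <- sample_size_curve(p, q_grid = c(0.1, 0.2, 0.5), target = 0.5)
  expect_true(all(curve$achievable))
  expect_true(all(diff(curve$min_n) <= 0))  # decreasing in q
  expect_true(all(diff(curve$n_sig) >= 0))  # n_sig nondecreasing in q

  # near-certain cutoff: a single confirmation suffices
  c1 <- sample_size_curve(p, q_grid = 1 - 1e-9, target = 0.5)
  expect_equal(c1$min_n, 1L)

  # tiny study: achievable in principle but capped by the list length
  c2 <- sample_size_curve(c(0.001, 0.002, 0.003), q_grid = 0.1,
                          target = 0.5)
  expect_false(c2$achievable)
  expect_true(c2$capped_by_nsig)
  expect_equal(c2$n_sig, 3L)
})

test_that("probability-vs-sample-size curve matches the binomial oracle", {
  out <- probability_vs_sample_size(q = 0.5, n_grid = 20, fp_multiplier = 0.7)
  # n_fp = 7 -> Beta(8, 14); exact tail of Binomial(21, 0.5)
  expect_equal(out$probability, binomial_tail_oracle(0.5, 8, 14),
               tolerance = 1e-12)
  expect_equal(out$probability, 1898712 / 2097152, tolerance = 1e-12)

  # n = 0 returns the prior CDF (identity under the uniform prior)
  for (q in c(0.05, 0.3, 0.8)) {
    expect_equal(probability_vs_sample_size(q, 0)$probability, q)
  }

  # nondecreasing in n; higher cutoffs dominate at fixed n
  grid <- seq(0, 200, by = 5)
  lo <- probability_vs_sample_size(0.05, grid)$probability
  hi <- probability_vs_sample_size(0.5, grid)$probability
  expect_true(all(diff(lo) >= -1e-12))
  expect_true(all(diff(hi) >= -1e-12))
  expect_true(all(hi[-1] > lo[-1]))
})

test_that("a full-FDR multiplier under the continuous rule never clears 0.5", {
  for (q in c(0.05, 0.2, 0.45)) {
    prob <- probability_vs_sample_size(q, n_grid = 1:500,
                                       fp_multiplier = 1)$probability
    expect_true(all(prob <= 0.5 + 1e-12))
  }
})
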