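# Beta-Binomial core: priors, conjugate update, validation probability,
# posterior mean, credible intervals.

test_that("adaptive prior pins the prior mean at the claimed FDR", {
  cases <- list(
    list(fdr = 0.05, a = 0.01, b = 0.19),
    list(fdr = 0.50, a = 0.01, b = 0.01),
    list(fdr = 0.10, a = 0.01, b = 0.09)
  )
  for (cs in cases) {
    pr <- adaptive_prior(cs$fdr)
    expect_equal(pr$a, cs$a)
    expect_equal(pr$b, cs$b, tolerance = 1e-12)
    expect_equal(pr$a / (pr$a + pr$b), cs$fdr, tolerance = 1e-12)
  }
  expect_error(adaptive_prior(0), "claimed_fdr")
  expect_error(adaptive_prior(1), "claimed_fdr")
  expect_error(beta_prior(a = -1), "`a`")
})

test_that("conjugate update adds failure and success counts to the shapes", {
  cases <- list(
    list(n = 31, n_fp = 3, a = 4, b = 29),      # validated exon subsample
    list(n = 0, n_fp = 0, a = 1, b = 1),        # no data leaves the prior
    list(n = 20, n_fp = 1.65, a = 2.65, b = 19.35)  # expected (real) count
  )
  for (cs in cases) {
    post <- update_posterior(uniform_prior(),
                             validation_outcome(cs$n, cs$n_fp, 0.1))
    expect_equal(post$a, cs$a)
    expect_equal(post$b, cs$b)
  }
  expect_error(validation_outcome(n = 5, n_fp = 6, claimed_fdr = 0.1),
               "n_fp")
  expect_error(validation_outcome(n = 5, n_fp = 1, claimed_fdr = 1.2),
               "claimed_fdr")
})

test_that("validation probability matches printed worked examples", {
  # 0 failures among 2 validated hits at a claimed 5% FDR
  post <- update_posterior(uniform_prior(), validation_outcome(2, 0, 0.05))
  expect_equal(validation_probability(post, 0.05), 1 - 0.95^3,
               tolerance = 1e-12)

  # 3 failures among 31 validated exons at a claimed 1% FDR
  post <- update_posterior(uniform_prior(), validation_outcome(31, 3, 0.01))
  expect_equal(validation_probability(post, 0.01), 2.87e-4,
               tolerance = 1e-2)

  # uniform posterior: the CDF is the identity
  post <- update_posterior(uniform_prior(), validation_outcome(0, 0, 0.5))
  for (alpha in c(0.01, 0.3, 0.9)) {
    expect_equal(validation_probability(post, alpha), alpha)
  }

  # 20/20 confirmed at a minuscule claimed FDR: closed form 1-(1-x)^21,
  # evaluated stably as -expm1(21 * log1p(-x))
  post <- update_posterior(uniform_prior(), validation_outcome(20, 0, 1e-7))
  expect_equal(validation_probability(post, 1.09e-7),
               -expm1(21 * log1p(-1.09e-7)), tolerance = 1e-10)
  expect_equal(validation_probability(post, 1.09e-7), 2.28e-6,
               tolerance = 1e-2)
})

test_that("posterior CDF agrees with the binomial-tail oracle at integer shapes", {
  xs <- seq(0.01, 0.99, by = 0.07)
  for (a in c(1L, 2L, 5L, 13L, 30L)) {
    for (b in c(1L, 3L, 21L, 44L, 60L)) {
      post <- structure(list(a = a, b = b), class = "beta_posterior")
      for (x in xs) {
        expect_equal(validation_probability(post, x),
                     binomial_tail_oracle(x, a, b), tolerance = 1e-10)
      }
    }
  }
})

test_that("posterior mean is (a + n_fp) / (a + b + n)", {
  post <- update_posterior(uniform_prior(), validation_outcome(31, 3, 0.01))
  expect_equal(posterior_mean_fdr(post), 4 / 33)
  expect_equal(posterior_mean_fdr(uniform_posterior()), 0.5)
  post <- update_posterior(uniform_prior(),
                           validation_outcome(20, 1.65, 0.10))
  expect_equal(posterior_mean_fdr(post), 2.65 / 22)
})

test_that("equal-tailed credible intervals reproduce the printed intervals", {
  post <- update_posterior(uniform_prior(), validation_outcome(31, 3, 0.01))
  ci <- credible_interval(post, 0.95)
  expect_equal(round(ci$lower, 2), 0.04)
  expect_equal(round(ci$upper, 2), 0.25)

  post <- update_posterior(uniform_prior(), validation_outcome(20, 0, 1e-7))
  ci <- credible_interval(post, 0.95)
  expect_equal(round(ci$lower, 3), 0.001)
  expect_equal(round(ci$upper, 3), 0.161)

  ci <- credible_interval(uniform_posterior(), 0.95)
  expect_equal(ci$lower, 0.025)
  expect_equal(ci$upper, 0.975)
})

test_that("credible intervals contain exactly the nominal posterior mass", {
  for (shapes in list(c(4, 29), c(1, 21), c(2.65, 19.35), c(0.01, 0.19))) {
    post <- structure(list(a = shapes[1], b = shapes[2]),
                      class = "beta_posterior")
    for (level in c(0.5, 0.9, 0.95, 0.99)) {
      ci <- credible_interval(post, level)
      mass <- pbeta(ci$upper, post$a, post$b) -
        pbeta(ci$lower, post$a, post$b)
      expect_equal(mass, level, tolerance = 1e-8)
      expect_lte(ci$lower, ci$upper)
    }
  }
})

test_that("validation probability is monotone in n_fp and in the claimed FDR", {
  n <- 25
  vp <- vapply(0:n, function(k) {
    post <- update_posterior(uniform_prior(), validation_outcome(n, k, 0.1))
    validation_probability(post, 0.1)
  }, numeric(1))
  expect_true(all(diff(vp) < 0))

  # below the saturation region where the CDF hits 1 in double precision
  post <- update_posterior(uniform_prior(), validation_outcome(25, 4, 0.1))
  alphas <- seq(0.02, 0.60, by = 0.02)
  vp_alpha <- vapply(alphas, validation_probability, numeric(1),
                     posterior = post)
  expect_true(all(diff(vp_alpha) > 0))
})

test_that("the worked exon example fails to validate under either prior", {
  for (prior in list(uniform_prior(), adaptive_prior(0.01))) {
    post <- update_posterior(prior, validation_outcome(31, 3, 0.01))
    expect_lt(validation_probability(post, 0.01), 0.01)
  }
})

test_that("validation probabilities are frequentist-calibrated", {
  # truth far below the claimed FDR: probabilities pile up near 1 as n
  # grows; truth far above: near 0
  set.seed(42)
  alpha <- 0.10
  for (pi0 in c(0.01, 0.40)) {
    for (n in c(50, 400)) {
      vp <- replicate(200, {
        k <- rbinom(1, n, pi0)
        post <- update_posterior(uniform_prior(),
                                 validation_outcome(n, k, alpha))
        validation_probability(post, alpha)
      })
      if (pi0 < alpha) {
        if (n == 400) expect_gt(median(vp), 0.99)
        else expect_gt(median(vp), 0.9)
      } else {
        expect_lt(median(vp), if (n == 400) 0.001 else 0.05)
      }
    }
  }
})

test_that("validate_fdr assembles the full report and accepts deltas", {
  r <- validate_fdr(n = 31, n_fp = 3, claimed_fdr = 0.01)
  expect_s3_class(r, "fdr_validation")
  expect_equal(r$posterior$a, 4)
  expect_equal(r$posterior$b, 29)

  d <- c(rep(1, 3), rep(0, 28))
  r2 <- validate_fdr(deltas = d, claimed_fdr = 0.01)
  expect_equal(r2$validation_probability, r$validation_probability)
  expect_error(validate_fdr(claimed_fdr = 0.01), "deltas")
})
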