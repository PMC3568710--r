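#' Summary of a validation experiment
#'
#' Bundles the three numbers a validation sub-study produces: the number of
#' randomly sampled significant results that were re-tested (`n`), how many
#' of them failed the independent confirmation (`n_fp`), and the FDR level
#' at which the original list was declared significant (`claimed_fdr`).
#'
#' `n_fp` may be non-integer: an *expected* number of false positives (for
#' instance the average over repeated random subsamples) is a legitimate
#' input, and the conjugate update is defined for real-valued counts.
#'
#' @param n Number of validated features (nonnegative).
#' @param n_fp Number of validation failures, `0 <= n_fp <= n`.
#' @param claimed_fdr Claimed FDR of the original analysis, in (0, 1).
#'
#' @return An object of class `validation_outcome`.
#' @export
#' @examples
#' validation_outcome(n = 31, n_fp = 3, claimed_fdr = 0.01)
validation_outcome <- function(n, n_fp, claimed_fdr) {
  check_scalar(n, "n", lower = 0)
  check_scalar(n_fp, "n_fp", lower = 0, upper = n)
  check_probability(claimed_fdr, "claimed_fdr")
  structure(list(n = n, n_fp = n_fp, claimed_fdr = claimed_fdr),
            class = "validation_outcome")
}

#' Conjugate posterior update for the false-discovery proportion
#'
#' Each validated feature fails independently with probability whose mean is
#' the true false-discovery proportion of the list, so the failure count is
#' Binomial(n, pi0). Under a Beta(a, b) prior the posterior is
#' Beta(a + n_fp, b + n - n_fp).
#'
#' @param prior A [beta_prior()].
#' @param outcome A [validation_outcome()].
#'
#' @return An object of class `beta_posterior`: a list with shape
#'   parameters `a` and `b`.
#' @export
#' @examples
#' update_posterior(uniform_prior(), validation_outcome(31, 3, 0.01))
update_posterior <- function(prior, outcome) {
  stopifnot(inherits(prior, "beta_prior"),
            inherits(outcome, "validation_outcome"))
  structure(
    list(a = prior$a + outcome$n_fp,
         b = prior$b + outcome$n - outcome$n_fp),
    class = "beta_posterior"
  )
}

#' Validation probability
#'
#' The posterior probability that the true false-discovery proportion of the
#' significant list is at or below the claimed FDR:
#' `Pr(pi0 <= claimed_fdr | n_fp, n)`, i.e. the posterior Beta CDF
#' (regularized incomplete beta function) evaluated at `claimed_fdr`.
#' Values above 0.5 lend support to the original FDR claim; strong support
#' requires values close to 1.
#'
#' @param posterior A `beta_posterior` from [update_posterior()].
#' @param claimed_fdr The claimed FDR, in (0, 1).
#'
#' @return A probability in \[0, 1\].
#' @export
#' @examples
#' post <- update_posterior(uniform_prior(), validation_outcome(2, 0, 0.05))
#' validation_probability(post, 0.05)   # 1 - 0.95^3 = 0.142625
validation_probability <- function(posterior, claimed_fdr) {
  stopifnot(inherits(posterior, "beta_posterior"))
  check_probability(claimed_fdr, "claimed_fdr")
  stats::pbeta(claimed_fdr, posterior$a, posterior$b)
}

#' Posterior-mean FDR
#'
#' The posterior expectation of the false-discovery proportion,
#' `(a + n_fp) / (a + b + n)`: a point estimate of the actual FDR of the
#' original list in light of the validation data.
#'
#' @param posterior A `beta_posterior`.
#' @return A value in (0, 1).
#' @export
posterior_mean_fdr <- function(posterior) {
  stopifnot(inherits(posterior, "beta_posterior"))
  posterior$a / (posterior$a + posterior$b)
}

#' Equal-tailed posterior credible interval for the FDR
#'
#' Quantile-based interval placing probability `(1 - level) / 2` in each
#' tail of the posterior.
#'
#' @param posterior A `beta_posterior`.
#' @param level Interval mass, in (0, 1); default 0.95.
#'
#' @return An object of class `credible_interval`: list with `lower`,
#'   `upper`, `level`.
#' @export
#' @examples
#' post <- update_posterior(uniform_prior(), validation_outcome(31, 3, 0.01))
#' credible_interval(post)   # approximately (0.04, 0.25)
credible_interval <- function(posterior, level = 0.95) {
  stopifnot(inherits(posterior, "beta_posterior"))
  check_probability(level, "level")
  tail <- (1 - level) / 2
  structure(
    list(lower = stats::qbeta(tail, posterior$a, posterior$b),
         upper = stats::qbeta(1 - tail, posterior$a, posterior$b),
         level = level),
    class = "credible_interval"
  )
}

#' One-call validation report
#'
#' Runs the full posterior analysis for a validation sub-study: conjugate
#' update, validation probability, posterior-mean FDR, and an equal-tailed
#' credible interval; optionally a bootstrap confidence interval for the
#' validation probability when per-feature outcomes are supplied.
#'
#' @param n,n_fp Validation sample size and failure count. Ignored (derived)
#'   when `deltas` is given.
#' @param claimed_fdr Claimed FDR of the original analysis.
#' @param deltas Optional vector of per-feature binary outcomes (1 = false
#'   positive, 0 = confirmed); supplies `n = length(deltas)` and
#'   `n_fp = sum(deltas)` and enables the bootstrap.
#' @param prior A [beta_prior()]; default uniform.
#' @param level Credible/confidence level; default 0.95.
#' @param bootstrap Number of bootstrap replicates, or `NULL` (default) to
#'   skip the bootstrap. Requires `deltas`.
#' @param seed RNG seed for the bootstrap.
#'
#' @return An object of class `fdr_validation` with elements `outcome`,
#'   `prior`, `posterior`, `validation_probability`, `posterior_mean_fdr`,
#'   `credible_interval`, and optionally `bootstrap`.
#' @export
#' @examples
#' validate_fdr(n = 31, n_fp = 3, claimed_fdr = 0.01)
validate_fdr <- function(n = NULL, n_fp = NULL, claimed_fdr,
                         deltas = NULL, prior = uniform_prior(),
                         level = 0.95, bootstrap = NULL, seed = NULL) {
  if (!is.null(deltas)) {
    check_deltas(deltas)
    n <- length(deltas)
    n_fp <- sum(deltas)
  }
  if (is.null(n) || is.null(n_fp)) {
    stop("supply either `n` and `n_fp`, or per-feature `deltas`",
         call. = FALSE)
  }
  outcome <- validation_outcome(n, n_fp, claimed_fdr)
  posterior <- update_posterior(prior, outcome)
  res <- structure(
    list(outcome = outcome,
         prior = prior,
         posterior = posterior,
         validation_probability = validation_probability(posterior,
                                                         claimed_fdr),
         posterior_mean_fdr = posterior_mean_fdr(posterior),
         credible_interval = credible_interval(posterior, level)),
    class = "fdr_validation"
  )
  if (!is.null(bootstrap)) {
    if (is.null(deltas)) {
      stop("the bootstrap needs per-feature `deltas`", call. = FALSE)
    }
    res$bootstrap <- bootstrap_validation_probability(
      deltas, claimed_fdr, prior = prior, B = bootstrap,
      level = level, seed = seed
    )
  }
  res
}

#' @export
print.fdr_validation <- function(x, ...) {
  o <- x$outcome
  ci <- x$credible_interval
  cat(sprintf("FDR validation (n = %g, n_fp = %g, claimed FDR = %g)\n",
              o$n, o$n_fp, o$claimed_fdr))
  cat(sprintf("  prior: Beta(%g, %g); posterior: Beta(%g, %g)\n",
              x$prior$a, x$prior$b, x$posterior$a, x$posterior$b))
  cat(sprintf("  validation probability: %.2f\n", x$validation_probability))
  cat(sprintf("  posterior mean FDR: %.2f\n", x$posterior_mean_fdr))
  cat(sprintf("  %g%% credible interval: (%.2f, %.2f)\n",
              100 * ci$level, ci$lower, ci$upper))
  if (!is.null(x$bootstrap)) {
    b <- x$bootstrap
    cat(sprintf("  bootstrap %g%% CI (B = %d): (%.2f, %.2f)\n",
                100 * b$level, b$replicates, b$lower, b$upper))
  }
  invisible(x)
}

#' @export
print.credible_interval <- function(x, ...) {
  cat(sprintf("%g%% equal-tailed credible interval: (%.4g, %.4g)\n",
              100 * x$level, x$lower, x$upper))
  invisible(x)
}

#' @export
print.beta_posterior <- function(x, ...) {
  cat(sprintf("Beta(%g, %g) posterior; mean %.4g\n",
              x$a, x$b, x$a / (x$a + x$b)))
  invisible(x)
}
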