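# Design of validation experiments: how many randomly sampled significant
# results must be confirmed, at a given FDR cutoff, for the validation
# probability to clear a target?

#' Number of significant features at an FDR cutoff
#'
#' Counts the features whose estimated q-value is at or below `q`, using
#' [estimate_qvalues()] (Benjamini-Hochberg by default).
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param q FDR cutoff in (0, 1\].
#' @param pi0_method Passed to [estimate_qvalues()].
#'
#' @return Integer count; nondecreasing in `q`.
#' @export
#' @examples
#' n_significant(c(0.001, 0.5, 0.9), 0.05)   # 1
n_significant <- function(pvalues, q, pi0_method = c("fixed", "storey")) {
  check_pvalues(pvalues)
  check_scalar(q, "q", lower = 0, upper = 1, open_lower = TRUE)
  sum(estimate_qvalues(pvalues, pi0_method = pi0_method) <= q)
}

#' Minimum validation sample size
#'
#' The smallest number `n` of randomly sampled significant results that must
#' be confirmed so that, assuming the claimed FDR is accurate and therefore
#' about `q * n` of them fail, the validation probability exceeds the
#' target:
#'
#'   min n  such that  Pr(pi0 < q | n_fp(n), n) > target,  n <= n_sig
#'
#' The expected failure count `n_fp(n)` is `floor(q * n)` under the default
#' `"floor"` rule, or the real value `q * n` under `"continuous"`. The floor
#' rule is the default because under the continuous rule the posterior
#' median never drops below `q` when `q < 0.5`, so no finite `n` can reach a
#' target of 0.5 — whereas observed failure counts are integers, which the
#' floor rule reflects.
#'
#' The search is a linear scan of `n = 1, 2, ...` (the floor rule makes the
#' probability a sawtooth in `n`, so bisection is unsafe), capped at
#' `scan_limit`. A cutoff is *achievable* when the smallest qualifying `n`
#' does not exceed `n_sig`, the number of significant features available to
#' sample from; when a qualifying `n` exists only beyond `n_sig`, the plan
#' is unachievable with `capped_by_nsig = TRUE`. If no `n` up to
#' `scan_limit` qualifies the plan is reported unachievable with
#' `capped_by_nsig = FALSE`.
#'
#' @param q FDR cutoff, in (0, 1).
#' @param target Target validation probability, in (0, 1).
#' @param n_sig Number of features significant at cutoff `q`.
#' @param fp_rule `"floor"` (default) or `"continuous"`: how the expected
#'   failure count is formed from `q * n`.
#' @param prior A [beta_prior()]; default uniform.
#' @param fp_multiplier Optional scaling of the expected FDR in the
#'   validation set relative to the cutoff (`n_fp` based on
#'   `fp_multiplier * q * n`); default 1.
#' @param scan_limit Upper bound of the scan over `n`; default 100000.
#'
#' @return An object of class `sample_size_plan`: list with `fdr_cutoff`,
#'   `target_probability`, `min_n` (`NA` when unachievable), `achievable`,
#'   `capped_by_nsig`, `n_sig`, `fp_rule`.
#' @export
#' @examples
#' min_validation_sample_size(q = 0.10, target = 0.5, n_sig = 1000)  # n = 6
min_validation_sample_size <- function(q, target, n_sig,
                                       fp_rule = c("floor", "continuous"),
                                       prior = uniform_prior(),
                                       fp_multiplier = 1,
                                       scan_limit = 100000L) {
  check_probability(q, "q")
  check_probability(target, "target")
  check_scalar(n_sig, "n_sig", lower = 0)
  check_scalar(fp_multiplier, "fp_multiplier", lower = 0, open_lower = TRUE,
               upper = 1)
  fp_rule <- match.arg(fp_rule)
  stopifnot(inherits(prior, "beta_prior"))

  limit <- max(as.integer(scan_limit), as.integer(n_sig))
  n <- seq_len(limit)
  n_fp <- expected_false_positives(n, q, fp_rule, fp_multiplier)
  vp <- stats::pbeta(q, prior$a + n_fp, prior$b + n - n_fp)
  # tie tolerance: the symmetric continuous case sits exactly at the target
  # and must not qualify through floating-point noise in pbeta
  hit <- which(vp > target + 1e-12)

  min_n <- NA_integer_
  achievable <- FALSE
  capped <- FALSE
  if (length(hit) > 0L) {
    first <- hit[1L]
    if (first <= n_sig) {
      min_n <- first
      achievable <- TRUE
    } else {
      capped <- TRUE
    }
  }
  structure(
    list(fdr_cutoff = q, target_probability = target, min_n = min_n,
         achievable = achievable, capped_by_nsig = capped,
         n_sig = as.integer(n_sig), fp_rule = fp_rule),
    class = "sample_size_plan"
  )
}

expected_false_positives <- function(n, q, fp_rule, fp_multiplier = 1) {
  nfp <- fp_multiplier * q * n
  if (fp_rule == "floor") nfp <- floor(nfp)
  nfp
}

#' @export
print.sample_size_plan <- function(x, ...) {
  if (x$achievable) {
    cat(sprintf(
      "FDR cutoff %g: validate >= %d of %d significant features (target %g)\n",
      x$fdr_cutoff, x$min_n, x$n_sig, x$target_probability
    ))
  } else {
    why <- if (x$capped_by_nsig) {
      "too few significant features to sample from"
    } else {
      "target validation probability not reachable"
    }
    cat(sprintf("FDR cutoff %g: UNACHIEVABLE (%s)\n", x$fdr_cutoff, why))
  }
  invisible(x)
}

#' Minimum validation sample size across FDR cutoffs
#'
#' Computes [min_validation_sample_size()] for each cutoff in `q_grid`,
#' taking `n_sig(q)` from the study's own p-values. Unachievable cutoffs get
#' `min_n = NA` (the "x" marks of a design plot). Over achievable cutoffs
#' the required sample size decreases as the cutoff grows: validation is
#' easier at higher FDR thresholds.
#'
#' @param pvalues P-values of the original analysis.
#' @param q_grid FDR cutoffs to evaluate.
#' @param target Target validation probability; default 0.5.
#' @inheritParams min_validation_sample_size
#' @param pi0_method Passed to [estimate_qvalues()].
#'
#' @return A data frame of class `sample_size_curve` with columns `q`,
#'   `n_sig`, `min_n`, `achievable`, `capped_by_nsig`.
#' @export
sample_size_curve <- function(pvalues, q_grid, target = 0.5,
                              fp_rule = c("floor", "continuous"),
                              prior = uniform_prior(),
                              fp_multiplier = 1,
                              pi0_method = c("fixed", "storey")) {
  check_pvalues(pvalues)
  fp_rule <- match.arg(fp_rule)
  qv <- estimate_qvalues(pvalues, pi0_method = pi0_method)
  rows <- lapply(q_grid, function(q) {
    plan <- min_validation_sample_size(
      q, target, n_sig = sum(qv <= q), fp_rule = fp_rule, prior = prior,
      fp_multiplier = fp_multiplier
    )
    data.frame(q = q, n_sig = plan$n_sig, min_n = plan$min_n,
               achievable = plan$achievable,
               capped_by_nsig = plan$capped_by_nsig)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sample_size_curve", "data.frame")
  out
}

#' @export
plot.sample_size_curve <- function(x, ...) {
  graphics::plot(x$q, x$min_n, type = "n", xlab = "FDR cutoff",
                 ylab = "Minimum validation sample size", ...)
  ok <- x$achievable
  graphics::points(x$q[ok], x$min_n[ok], pch = 19)
  if (any(!ok)) {
    graphics::points(x$q[!ok], rep(0, sum(!ok)), pch = 4, col = "red")
  }
  invisible(x)
}

#' Validation probability as a function of sample size
#'
#' For each candidate sample size `n`, the validation probability assuming
#' `fp_multiplier * q * n` false positives are observed — i.e. the
#' validation data come in somewhat better (multiplier < 1) than the claimed
#' FDR. The probability rises with `n`, and for a fixed `n` it is higher at
#' larger FDR cutoffs, which is why validating against a lenient cutoff is
#' statistically easier.
#'
#' @param q FDR cutoff, in (0, 1).
#' @param n_grid Sample sizes to evaluate (nonnegative integers; `n = 0`
#'   returns the prior CDF at `q`).
#' @param fp_multiplier Assumed ratio of realized to claimed FDR in the
#'   validation set; default 0.7.
#' @param prior A [beta_prior()]; default uniform.
#'
#' @return A data frame with columns `n` and `probability`.
#' @export
#' @examples
#' probability_vs_sample_size(0.5, n_grid = c(10, 20, 50))
probability_vs_sample_size <- function(q, n_grid, fp_multiplier = 0.7,
                                       prior = uniform_prior()) {
  check_probability(q, "q")
  check_scalar(fp_multiplier, "fp_multiplier", lower = 0, upper = 1,
               open_lower = TRUE)
  stopifnot(inherits(prior, "beta_prior"), all(n_grid >= 0))
  n_fp <- fp_multiplier * q * n_grid
  data.frame(
    n = n_grid,
    probability = stats::pbeta(q, prior$a + n_fp, prior$b + n_grid - n_fp)
  )
}
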