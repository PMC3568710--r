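# Per-feature outcome vectors: 1 = false positive under the independent
# assay, 0 = confirmed.
check_deltas <- function(deltas) {
  if (length(deltas) < 1L) {
    stop("outcome vector `deltas` must be nonempty", call. = FALSE)
  }
  if (!is.numeric(deltas) || anyNA(deltas) || !all(deltas %in% c(0, 1))) {
    stop("`deltas` must contain only 0 (confirmed) and 1 (false positive)",
         call. = FALSE)
  }
  invisible(deltas)
}

#' Bootstrap confidence interval for the validation probability
#'
#' Resamples the per-feature validation outcomes with replacement `B` times;
#' each replicate recomputes the false-positive count and the validation
#' probability `Pr(pi0 <= claimed_fdr | n_fp_b, n)`. The `(1 - level) / 2`
#' and `1 - (1 - level) / 2` empirical quantiles (type-7, linear
#' interpolation) of the replicate values form the interval. The point
#' estimate is the validation probability of the original, un-resampled
#' vector.
#'
#' The bootstrap is not justified for small validation samples; a warning is
#' issued when `n < 10` because the interval may not reach nominal coverage.
#'
#' @param deltas Binary outcome vector (1 = false positive, 0 = confirmed).
#' @param claimed_fdr Claimed FDR of the original analysis, in (0, 1).
#' @param prior A [beta_prior()]; default uniform.
#' @param B Number of bootstrap replicates; default 10000.
#' @param level Confidence level; default 0.95.
#' @param seed Optional RNG seed; identical seed and inputs give identical
#'   results, and the caller's RNG state is left untouched.
#'
#' @return An object of class `bootstrap_result`: list with
#'   `point_estimate`, `lower`, `upper`, `level`, `replicates`, `seed`.
#' @export
#' @examples
#' set.seed(1)
#' d <- c(rep(1, 2), rep(0, 18))
#' bootstrap_validation_probability(d, claimed_fdr = 0.10, B = 1000, seed = 7)
bootstrap_validation_probability <- function(deltas, claimed_fdr,
                                             prior = uniform_prior(),
                                             B = 10000L, level = 0.95,
                                             seed = NULL) {
  check_deltas(deltas)
  check_probability(claimed_fdr, "claimed_fdr")
  check_probability(level, "level")
  check_scalar(B, "B", lower = 1)
  stopifnot(inherits(prior, "beta_prior"))
  n <- length(deltas)
  if (n < 10L) {
    warning("bootstrap intervals may be unreliable for n < 10 validated ",
            "results", call. = FALSE)
  }
  B <- as.integer(B)

  n_fp_b <- with_seed(seed, {
    idx <- sample.int(n, n * B, replace = TRUE)
    colSums(matrix(deltas[idx], nrow = n, ncol = B))
  })
  vp_b <- stats::pbeta(claimed_fdr, prior$a + n_fp_b, prior$b + n - n_fp_b)
  qs <- stats::quantile(vp_b, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)

  point <- stats::pbeta(claimed_fdr, prior$a + sum(deltas),
                        prior$b + n - sum(deltas))
  structure(
    list(point_estimate = point,
         lower = qs[1],
         upper = qs[2],
         level = level,
         replicates = B,
         seed = seed),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "bootstrap validation probability: %.4g, %g%% CI (%.4g, %.4g) [B = %d]\n",
    x$point_estimate, 100 * x$level, x$lower, x$upper, x$replicates
  ))
  invisible(x)
}
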