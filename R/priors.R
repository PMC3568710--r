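#' Beta prior on the true false-discovery proportion
#'
#' Constructs a Beta(a, b) prior for the true proportion of false positives
#' among a list of significant results. The default `beta_prior(1, 1)` is
#' the uniform prior, a conservative choice since most validated results
#' are expected to be true positives.
#'
#' @param a Positive shape parameter (pseudo-count of false positives).
#' @param b Positive shape parameter (pseudo-count of confirmed results).
#'
#' @return An object of class `beta_prior`: a list with elements `a` and `b`.
#' @seealso [uniform_prior()], [adaptive_prior()]
#' @export
#' @examples
#' beta_prior(1, 1)            # uniform
#' adaptive_prior(0.05)        # mean pinned at the claimed FDR
beta_prior <- function(a = 1, b = 1) {
  check_scalar(a, "a", lower = 0, open_lower = TRUE)
  check_scalar(b, "b", lower = 0, open_lower = TRUE)
  structure(list(a = a, b = b), class = "beta_prior")
}

#' @rdname beta_prior
#' @export
uniform_prior <- function() {
  beta_prior(1, 1)
}

#' Adaptive prior centred at the claimed FDR
#'
#' Encodes the optimistic belief that most results will validate by setting
#' the prior mean `a / (a + b)` equal to the claimed FDR. Taking `a` small
#' (default 0.01) maximises the prior variance among such priors, so the
#' prior stays weak: `b = (1 - claimed_fdr) / claimed_fdr * a`. This prior
#' can be slightly anti-conservative, which is why the uniform prior is the
#' package default everywhere.
#'
#' @param claimed_fdr The FDR level at which the original list was declared
#'   significant, in (0, 1).
#' @param a Small positive shape parameter; default 0.01.
#'
#' @return A `beta_prior` whose mean equals `claimed_fdr` exactly.
#' @export
#' @examples
#' adaptive_prior(0.05)   # Beta(0.01, 0.19)
adaptive_prior <- function(claimed_fdr, a = 0.01) {
  check_probability(claimed_fdr, "claimed_fdr")
  check_scalar(a, "a", lower = 0, open_lower = TRUE)
  beta_prior(a = a, b = (1 - claimed_fdr) / claimed_fdr * a)
}

#' @export
print.beta_prior <- function(x, ...) {
  cat(sprintf("Beta(%g, %g) prior on the false-discovery proportion\n",
              x$a, x$b))
  cat(sprintf("  prior mean: %.4g\n", x$a / (x$a + x$b)))
  invisible(x)
}
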