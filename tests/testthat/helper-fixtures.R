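# Shared fixtures built in code.

# Write a per-feature outcome table (TSV) and return its path.
write_outcome_tsv <- function(deltas, ids = sprintf("f%03d", seq_along(deltas)),
                              path = withr::local_tempfile(fileext = ".tsv",
                                                           .local_envir = parent.frame())) {
  utils::write.table(
    data.frame(feature_id = ids, delta = deltas),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  path
}

write_pvalue_tsv <- function(pvalues,
                             path = withr::local_tempfile(fileext = ".tsv",
                                                          .local_envir = parent.frame())) {
  utils::write.table(
    data.frame(feature_id = sprintf("f%06d", seq_along(pvalues)),
               pvalue = pvalues),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  path
}

# The Beta(1, 1) posterior (prior untouched by data).
uniform_posterior <- function() {
  structure(list(a = 1, b = 1), class = "beta_posterior")
}

# Independent brute-force oracle for the regularized incomplete beta at
# integer shapes: I_x(a, b) = Pr(Binomial(a + b - 1, x) >= a).
binomial_tail_oracle <- function(x, a, b) {
  sum(stats::dbinom(a:(a + b - 1), size = a + b - 1, prob = x))
}
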