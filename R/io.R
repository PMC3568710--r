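# Tabular input (TSV, tab-separated with header, UTF-8, '.' decimal) and
# report rendering (json / tsv / text).

#' Read a per-feature validation outcome table
#'
#' Expects a TSV with a header containing at least `feature_id` and `delta`
#' columns; `delta` is 1 for a validation failure (false positive) and 0 for
#' a confirmed result. Feature ids must be unique. Parse errors name the
#' offending line (1-based, counting the header).
#'
#' @param path Path to the TSV file.
#'
#' @return A data frame of class `validation_table` with columns
#'   `feature_id` (character) and `delta` (integer). `nrow()` is the
#'   validation sample size `n` and `sum(delta)` the failure count `n_fp`;
#'   see [as_validation_outcome()].
#' @export
read_validation_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  tab <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE),
    error = function(e) {
      stop(sprintf("cannot parse %s: %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  missing <- setdiff(c("feature_id", "delta"), names(tab))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(tab) == 0L) {
    stop(sprintf("%s: no data rows", path), call. = FALSE)
  }
  bad <- which(is.na(tab$delta) | !tab$delta %in% c(0, 1))
  if (length(bad) > 0L) {
    stop(sprintf("%s: non-binary delta value(s) on line(s) %s", path,
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  dup <- which(duplicated(tab$feature_id))
  if (length(dup) > 0L) {
    stop(sprintf("%s: duplicate feature_id(s) on line(s) %s", path,
                 paste(dup + 1L, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(feature_id = as.character(tab$feature_id),
                    delta = as.integer(tab$delta),
                    stringsAsFactors = FALSE)
  class(out) <- c("validation_table", "data.frame")
  out
}

#' @describeIn read_validation_table Collapse an outcome table to a
#'   [validation_outcome()] at a claimed FDR.
#' @param table A `validation_table`.
#' @param claimed_fdr Claimed FDR of the original analysis.
#' @export
as_validation_outcome <- function(table, claimed_fdr) {
  stopifnot(inherits(table, "validation_table"))
  validation_outcome(n = nrow(table), n_fp = sum(table$delta),
                     claimed_fdr = claimed_fdr)
}

#' Read a p-value list
#'
#' TSV with header; uses a `pvalue` column if present, otherwise the last
#' column (allowing an optional id column first). Values outside \[0, 1\]
#' are rejected with the offending lines listed.
#'
#' @param path Path to the TSV file.
#' @return Numeric vector of p-values.
#' @export
read_pvalues <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    stop(sprintf("%s: no data rows", path), call. = FALSE)
  }
  col <- if ("pvalue" %in% names(tab)) "pvalue" else names(tab)[length(tab)]
  p <- suppressWarnings(as.numeric(tab[[col]]))
  bad <- which(is.na(p) | p < 0 | p > 1)
  if (length(bad) > 0L) {
    stop(sprintf("%s: p-values outside [0, 1] on line(s) %s", path,
                 paste(utils::head(bad + 1L, 10L), collapse = ", ")),
         call. = FALSE)
  }
  p
}

#' Flatten a report object into a plain named list
#'
#' Used by [render_report()]; exposed so callers can assemble composite
#' reports (e.g. manual-versus-statistical cost comparisons) themselves.
#'
#' @param x A result object.
#' @return A named list of scalar fields.
#' @export
report_fields <- function(x) {
  UseMethod("report_fields")
}

#' @export
report_fields.fdr_validation <- function(x) {
  out <- list(
    n = x$outcome$n,
    n_fp = x$outcome$n_fp,
    claimed_fdr = x$outcome$claimed_fdr,
    prior = list(a = x$prior$a, b = x$prior$b),
    posterior = list(a = x$posterior$a, b = x$posterior$b),
    validation_probability = x$validation_probability,
    posterior_mean_fdr = x$posterior_mean_fdr,
    credible_interval = list(lower = x$credible_interval$lower,
                             upper = x$credible_interval$upper),
    level = x$credible_interval$level
  )
  if (!is.null(x$bootstrap)) {
    out$bootstrap <- list(
      point_estimate = x$bootstrap$point_estimate,
      lower = x$bootstrap$lower, upper = x$bootstrap$upper,
      level = x$bootstrap$level, replicates = x$bootstrap$replicates
    )
  }
  out
}

#' @export
report_fields.cost_estimate <- function(x) {
  list(
    technology = x$technology, n_genes = x$n_genes, n_samples = x$n_samples,
    n_plates = x$n_plates, time_years = x$time_years, cost_usd = x$cost_usd,
    components = x$components
  )
}

#' @export
report_fields.default <- function(x) {
  as.list(x)
}

#' Render a result as JSON, TSV, or human-readable text
#'
#' JSON keeps full numeric precision and round-trips through
#' [jsonlite::fromJSON()]; TSV is a flat two-column key/value table; text
#' rounds to the 2-decimal display convention used throughout the package.
#'
#' @param x A result object ([validate_fdr()], [qpcr_cost()], or any
#'   list-like report).
#' @param format One of `"json"`, `"tsv"`, `"text"`.
#'
#' @return A single string containing the rendered document.
#' @export
#' @examples
#' r <- validate_fdr(n = 2, n_fp = 0, claimed_fdr = 0.05)
#' cat(render_report(r, "text"))
render_report <- function(x, format = c("json", "tsv", "text")) {
  format <- match.arg(format)
  fields <- report_fields(x)
  switch(format,
    json = as.character(
      jsonlite::toJSON(fields, auto_unbox = TRUE, digits = NA)
    ),
    tsv = {
      flat <- unlist(fields)
      paste0("key\tvalue\n",
             paste(names(flat), flat, sep = "\t", collapse = "\n"), "\n")
    },
    text = render_text(x, fields)
  )
}

render_text <- function(x, fields) {
  if (inherits(x, "fdr_validation")) {
    lines <- c(
      sprintf("n: %g", fields$n),
      sprintf("n_fp: %g", fields$n_fp),
      sprintf("claimed FDR: %g", fields$claimed_fdr),
      sprintf("posterior: Beta(%g, %g)", fields$posterior$a,
              fields$posterior$b),
      sprintf("validation probability: %.2f", fields$validation_probability),
      sprintf("posterior mean FDR: %.2f", fields$posterior_mean_fdr),
      sprintf("%g%% credible interval: (%.2f, %.2f)", 100 * fields$level,
              fields$credible_interval$lower, fields$credible_interval$upper)
    )
    if (!is.null(fields$bootstrap)) {
      lines <- c(lines, sprintf(
        "bootstrap %g%% CI: (%.2f, %.2f)", 100 * fields$bootstrap$level,
        fields$bootstrap$lower, fields$bootstrap$upper
      ))
    }
  } else if (inherits(x, "cost_estimate")) {
    lines <- c(
      sprintf("technology: %s", fields$technology),
      sprintf("genes: %g; samples: %g; plates: %g", fields$n_genes,
              fields$n_samples, fields$n_plates),
      sprintf("time: %.2f years", fields$time_years),
      sprintf("cost: $%.2f", fields$cost_usd),
      sprintf("  primer: $%.2f", fields$components$primer),
      sprintf("  reagent: $%.2f", fields$components$reagent),
      sprintf("  personnel: $%.2f", fields$components$personnel)
    )
  } else {
    flat <- unlist(fields)
    lines <- paste(names(flat), flat, sep = ": ")
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
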