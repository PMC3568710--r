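# Synthetic two-group expression experiments and the operating
# characteristics of the validation probability under three validation
# scenarios: errorless, noisy, and misspecified.

#' Simulate a two-group expression experiment
#'
#' Generates an expression matrix of `n_genes` genes over two groups, with
#' `n_de` genes carrying a between-group mean shift. Each value is gene
#' baseline + group shift + Gaussian noise; baselines are N(8, 2) on a
#' log2-like scale (they cancel in any two-group comparison), shifts are
#' drawn uniformly from `effect_range` with random sign, and the noise is
#' N(0, `noise_sd`).
#'
#' @param n_genes Number of genes; default 1000.
#' @param n_de Number of differentially expressed genes; default 300.
#' @param group_sizes Samples per group, a pair of counts >= 2; default
#'   `c(10, 10)`.
#' @param effect_range Range of absolute shift magnitudes; default
#'   `c(0.5, 2)`, giving a realistic mix of low- and high-powered genes at
#'   the default sample size.
#' @param noise_sd Within-group standard deviation; default 1.
#' @param seed Optional RNG seed; the run is fully reproducible given the
#'   seed and the caller's RNG state is restored afterwards.
#'
#' @return An object of class `sim_experiment`: list with `expr` (matrix,
#'   genes x samples), `group` (factor of length `sum(group_sizes)`),
#'   `is_de` (logical per gene), `effect` (signed shift per gene, 0 for
#'   nulls) and `config`.
#' @export
#' @examples
#' ex <- simulate_experiment(n_genes = 100, n_de = 30, seed = 1)
#' sum(ex$is_de)
simulate_experiment <- function(n_genes = 1000, n_de = 300,
                                group_sizes = c(10, 10),
                                effect_range = c(0.5, 2),
                                noise_sd = 1, seed = NULL) {
  check_scalar(n_genes, "n_genes", lower = 1)
  check_scalar(n_de, "n_de", lower = 0, upper = n_genes)
  stopifnot(length(group_sizes) == 2L, all(group_sizes >= 2),
            length(effect_range) == 2L, effect_range[1] <= effect_range[2])
  check_scalar(noise_sd, "noise_sd", lower = 0, open_lower = TRUE)
  n_genes <- as.integer(n_genes)
  n_de <- as.integer(n_de)

  with_seed(seed, {
    is_de <- rep(FALSE, n_genes)
    effect <- numeric(n_genes)
    if (n_de > 0L) {
      de_idx <- sample.int(n_genes, n_de)
      is_de[de_idx] <- TRUE
      effect[de_idx] <- stats::runif(n_de, effect_range[1], effect_range[2]) *
        sample(c(-1, 1), n_de, replace = TRUE)
    }
    n_total <- sum(group_sizes)
    group <- factor(rep(c("g1", "g2"), times = group_sizes))
    baseline <- stats::rnorm(n_genes, mean = 8, sd = 2)
    expr <- matrix(stats::rnorm(n_genes * n_total, sd = noise_sd),
                   nrow = n_genes, ncol = n_total)
    expr <- expr + baseline
    expr[, group == "g2"] <- expr[, group == "g2"] + effect
    structure(
      list(expr = expr, group = group, is_de = is_de, effect = effect,
           config = list(n_genes = n_genes, n_de = n_de,
                         group_sizes = as.integer(group_sizes),
                         effect_range = effect_range, noise_sd = noise_sd,
                         seed = seed)),
      class = "sim_experiment"
    )
  })
}

#' Per-gene two-sample t-test p-values
#'
#' Pooled-variance (equal-variance) two-sided t-tests computed row-wise over
#' the expression matrix. Genes with zero pooled variance get p = 1 with a
#' warning rather than NaN.
#'
#' @param expr Numeric matrix, genes in rows and samples in columns.
#' @param group Factor with exactly two levels and >= 2 samples per level.
#'
#' @return Numeric vector of p-values, one per gene.
#' @export
pvalues_from_experiment <- function(expr, group) {
  if (inherits(expr, "sim_experiment")) {
    group <- expr$group
    expr <- expr$expr
  }
  stopifnot(is.matrix(expr), is.factor(group) || is.character(group))
  group <- factor(group)
  if (nlevels(group) != 2L) {
    stop("`group` must have exactly two levels", call. = FALSE)
  }
  i1 <- group == levels(group)[1]
  i2 <- group == levels(group)[2]
  n1 <- sum(i1)
  n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  m1 <- rowMeans(expr[, i1, drop = FALSE])
  m2 <- rowMeans(expr[, i2, drop = FALSE])
  ss1 <- rowSums((expr[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((expr[, i2, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  degenerate <- se == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " gene(s) with zero pooled variance; p set to 1",
            call. = FALSE)
  }
  p <- rep(1, nrow(expr))
  tt <- (m1[!degenerate] - m2[!degenerate]) / se[!degenerate]
  p[!degenerate] <- 2 * stats::pt(-abs(tt), df = df)
  p
}

check_pvalues <- function(pvalues) {
  if (!is.numeric(pvalues) || length(pvalues) == 0L) {
    stop("`pvalues` must be a nonempty numeric vector", call. = FALSE)
  }
  bad <- which(is.na(pvalues) | pvalues < 0 | pvalues > 1)
  if (length(bad) > 0L) {
    stop(sprintf(
      "p-values outside [0, 1] at position(s) %s",
      paste(utils::head(bad, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(pvalues)
}

#' Estimate q-values from p-values
#'
#' Benjamini-Hochberg step-up adjusted p-values, optionally scaled by a
#' Storey-type estimate of the null proportion pi0. The default
#' (`pi0_method = "fixed"`, pi0 = 1) is the deterministic, conservative
#' choice; `"storey"` estimates `pi0 = min(1, mean(p > lambda) / (1 -
#' lambda))` at `lambda = 0.5` and multiplies the BH values by it. The
#' feature list significant at FDR level `q` is `which(qvalues <= q)`.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param pi0_method `"fixed"` (pi0 = 1, default) or `"storey"`.
#' @param lambda Tuning parameter of the Storey pi0 estimator; default 0.5.
#'
#' @return Numeric vector of q-values, nondecreasing in the p-values.
#' @export
#' @examples
#' estimate_qvalues(c(0.001, 0.5, 0.9))   # 0.003 0.75 0.90
estimate_qvalues <- function(pvalues, pi0_method = c("fixed", "storey"),
                             lambda = 0.5) {
  check_pvalues(pvalues)
  pi0_method <- match.arg(pi0_method)
  q <- stats::p.adjust(pvalues, method = "BH")
  if (pi0_method == "storey") {
    check_probability(lambda, "lambda")
    pi0 <- min(1, mean(pvalues > lambda) / (1 - lambda))
    q <- pmin(1, pi0 * q)
  }
  q
}

#' Apply a validation model to a significance list
#'
#' Produces the per-gene validation outcomes (delta = 1 for a validation
#' failure) for every gene in the significance list, under one of three
#' scenarios:
#'
#' \describe{
#'   \item{`errorless`}{The independent assay is perfect: delta = 1 exactly
#'     for the truly null genes in the list.}
#'   \item{`noisy_validation`}{Each listed gene is re-tested on freshly
#'     simulated data with `validation_sample_factor` times the original
#'     group sizes, using a two-sample t-test at level `test_level`;
#'     delta = 1 when the validation test fails to reject. The independent
#'     assay can thus miss weak true effects and occasionally confirm
#'     nulls.}
#'   \item{`misspecified`}{The original technology was wrong for a random
#'     fraction `misspecification_rate` of the truly differentially
#'     expressed genes: those genes are relabelled null for validation
#'     purposes, and the (perfect) independent assay scores against the
#'     corrected truth — so roughly that fraction of the original
#'     discoveries fail.}
#' }
#'
#' @param experiment A [simulate_experiment()] result.
#' @param sig_index Integer indices of the genes significant in the original
#'   analysis (nonempty).
#' @param scenario One of `"errorless"`, `"noisy_validation"`,
#'   `"misspecified"`.
#' @param validation_sample_factor Multiple of the original group sizes used
#'   by the noisy validation assay; default 3.
#' @param misspecification_rate Fraction of truly DE genes the original
#'   technology got wrong; default 1/3.
#' @param test_level Per-gene significance level of the noisy validation
#'   test; default 0.05.
#' @param seed Optional RNG seed for the random scenarios.
#'
#' @return Integer vector of 0/1 outcomes, one per entry of `sig_index`.
#' @export
apply_validation_model <- function(experiment, sig_index,
                                   scenario = c("errorless",
                                                "noisy_validation",
                                                "misspecified"),
                                   validation_sample_factor = 3,
                                   misspecification_rate = 1 / 3,
                                   test_level = 0.05, seed = NULL) {
  stopifnot(inherits(experiment, "sim_experiment"))
  scenario <- match.arg(scenario)
  if (length(sig_index) == 0L) {
    stop("the significance list is empty; nothing to validate",
         call. = FALSE)
  }
  is_de <- experiment$is_de

  switch(scenario,
    errorless = as.integer(!is_de[sig_index]),
    noisy_validation = with_seed(seed, {
      sizes <- round(validation_sample_factor *
                       experiment$config$group_sizes)
      n_total <- sum(sizes)
      group <- factor(rep(c("g1", "g2"), times = sizes))
      m <- length(sig_index)
      val <- matrix(stats::rnorm(m * n_total,
                                 sd = experiment$config$noise_sd),
                    nrow = m, ncol = n_total)
      val[, group == "g2"] <- val[, group == "g2"] +
        experiment$effect[sig_index]
      p_val <- pvalues_from_experiment(val, group)
      as.integer(p_val > test_level)
    }),
    misspecified = with_seed(seed, {
      check_scalar(misspecification_rate, "misspecification_rate",
                   lower = 0, upper = 1)
      truth <- is_de
      de_idx <- which(is_de)
      n_flip <- round(misspecification_rate * length(de_idx))
      if (n_flip > 0L) {
        truth[sample(de_idx, n_flip)] <- FALSE
      }
      as.integer(!truth[sig_index])
    })
  )
}

#' Operating characteristics of the validation probability
#'
#' Repeats the full pipeline `n_reps` times: simulate an experiment, compute
#' per-gene p-values and q-values, form the significance list at each FDR
#' level, validate it exhaustively under the chosen scenario, and compute
#' the validation probability, 95% credible interval, and posterior-mean
#' FDR. Summaries per FDR level are the median and interquartile range of
#' the validation probabilities, the fraction of replications whose
#' credible interval covers the claimed FDR level, and the median
#' posterior-mean FDR. Replications with an empty significance list are
#' excluded from the summaries and counted.
#'
#' @param scenario Validation scenario, see [apply_validation_model()].
#' @param prior_mode `"uniform"` (default) or `"adaptive"` (prior mean set
#'   to each claimed FDR level via [adaptive_prior()]).
#' @param fdr_levels FDR cutoffs at which lists are formed and validated;
#'   default `c(0.05, 0.10, 0.50)`.
#' @param n_reps Number of simulated experiments; default 100.
#' @param seed Master RNG seed; per-replication seeds are derived from it.
#' @param level Credible-interval mass; default 0.95.
#' @param pi0_method Passed to [estimate_qvalues()].
#' @inheritParams simulate_experiment
#' @inheritParams apply_validation_model
#'
#' @return An object of class `scenario_summary`: list with `summary` (data
#'   frame per FDR level: `fdr_level`, `median_vp`, `vp_q25`, `vp_q75`,
#'   `coverage`, `median_posterior_fdr`, `n_used`, `n_excluded`),
#'   `replicates` (long data frame of per-replication results), `scenario`
#'   and `prior_mode`.
#' @export
#' @examples
#' run_scenario("errorless", n_reps = 5, n_genes = 200, n_de = 60, seed = 1)
run_scenario <- function(scenario = c("errorless", "noisy_validation",
                                      "misspecified"),
                         prior_mode = c("uniform", "adaptive"),
                         fdr_levels = c(0.05, 0.10, 0.50),
                         n_reps = 100, seed = 1,
                         n_genes = 1000, n_de = 300,
                         group_sizes = c(10, 10),
                         effect_range = c(0.5, 2), noise_sd = 1,
                         validation_sample_factor = 3,
                         misspecification_rate = 1 / 3,
                         test_level = 0.05, level = 0.95,
                         pi0_method = c("fixed", "storey")) {
  scenario <- match.arg(scenario)
  prior_mode <- match.arg(prior_mode)
  pi0_method <- match.arg(pi0_method)
  check_scalar(n_reps, "n_reps", lower = 1)
  n_reps <- as.integer(n_reps)

  seeds <- with_seed(seed, matrix(sample.int(2^31 - 2, 2L * n_reps),
                                  nrow = n_reps, ncol = 2L))

  rows <- vector("list", n_reps * length(fdr_levels))
  k <- 0L
  for (r in seq_len(n_reps)) {
    ex <- simulate_experiment(n_genes = n_genes, n_de = n_de,
                              group_sizes = group_sizes,
                              effect_range = effect_range,
                              noise_sd = noise_sd, seed = seeds[r, 1L])
    qv <- estimate_qvalues(pvalues_from_experiment(ex),
                           pi0_method = pi0_method)
    for (fdr in fdr_levels) {
      k <- k + 1L
      sig <- which(qv <= fdr)
      if (length(sig) == 0L) {
        rows[[k]] <- data.frame(rep = r, fdr_level = fdr, n = 0L,
                                n_fp = NA_real_, vp = NA_real_,
                                lower = NA_real_, upper = NA_real_,
                                posterior_fdr = NA_real_, empty = TRUE)
        next
      }
      deltas <- apply_validation_model(
        ex, sig, scenario = scenario,
        validation_sample_factor = validation_sample_factor,
        misspecification_rate = misspecification_rate,
        test_level = test_level, seed = seeds[r, 2L]
      )
      prior <- switch(prior_mode,
                      uniform = uniform_prior(),
                      adaptive = adaptive_prior(fdr))
      post <- update_posterior(
        prior, validation_outcome(length(sig), sum(deltas), fdr)
      )
      ci <- credible_interval(post, level)
      rows[[k]] <- data.frame(
        rep = r, fdr_level = fdr, n = length(sig), n_fp = sum(deltas),
        vp = validation_probability(post, fdr),
        lower = ci$lower, upper = ci$upper,
        posterior_fdr = posterior_mean_fdr(post), empty = FALSE
      )
    }
  }
  reps <- do.call(rbind, rows)

  summ <- do.call(rbind, lapply(sort(unique(reps$fdr_level)), function(fdr) {
    d <- reps[reps$fdr_level == fdr & !reps$empty, , drop = FALSE]
    if (nrow(d) == 0L) {
      return(data.frame(fdr_level = fdr, median_vp = NA_real_,
                        vp_q25 = NA_real_, vp_q75 = NA_real_,
                        coverage = NA_real_,
                        median_posterior_fdr = NA_real_, n_used = 0L,
                        n_excluded = sum(reps$fdr_level == fdr & reps$empty)))
    }
    data.frame(
      fdr_level = fdr,
      median_vp = stats::median(d$vp),
      vp_q25 = unname(stats::quantile(d$vp, 0.25)),
      vp_q75 = unname(stats::quantile(d$vp, 0.75)),
      coverage = mean(d$lower <= fdr & fdr <= d$upper),
      median_posterior_fdr = stats::median(d$posterior_fdr),
      n_used = nrow(d),
      n_excluded = sum(reps$fdr_level == fdr & reps$empty)
    )
  }))

  structure(
    list(summary = summ, replicates = reps, scenario = scenario,
         prior_mode = prior_mode, seed = seed),
    class = "scenario_summary"
  )
}

#' @export
print.scenario_summary <- function(x, digits = 2, ...) {
  cat(sprintf("scenario: %s; prior: %s; %d replications (seed %g)\n",
              x$scenario, x$prior_mode,
              max(x$replicates$rep), x$seed))
  s <- x$summary
  out <- data.frame(
    `FDR` = s$fdr_level,
    `median VP` = round(s$median_vp, digits),
    `VP IQR` = sprintf("(%.*f, %.*f)", digits, s$vp_q25, digits, s$vp_q75),
    `CI coverage` = round(s$coverage, digits),
    `median post. FDR` = round(s$median_posterior_fdr, digits),
    `excluded` = s$n_excluded,
    check.names = FALSE
  )
  print(out, row.names = FALSE)
  invisible(x)
}
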