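---
title: "Statistical validation of significant result lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical validation of significant result lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valprob)
```

## The problem

A typical high-throughput experiment ends with a list of features — genes,
exons, proteins, SNPs — declared significant at a claimed false discovery
rate (FDR) $\hat\alpha$: if 100 features are significant at FDR 5%, at most
about 5 of them should be false discoveries. Confirming every feature with
an independent assay is usually too expensive, and confirming only the few
most significant hits is a strongly biased sample that says almost nothing
about the list as a whole. `valprob` implements the third option:
**confirm a small random sample** of the significant features and quantify,
with a posterior probability, how strongly the sample supports the FDR
claim.

## The model

Let $\Pi_0$ be the true (unknown) proportion of false positives among the
significant list. A randomly sampled feature fails the independent
confirmation ($\delta_i = 1$) with a feature-specific probability whose
mean over the list is $\Pi_0$; marginally each $\delta_i$ is Bernoulli
$(\Pi_0)$, so the failure count $n_{FP}$ among $n$ validated features is
Binomial$(n, \Pi_0)$ — provided the validation assays are independent
(batch effects that would break this are assumed to have been corrected
upstream). With a conjugate Beta$(a, b)$ prior on $\Pi_0$ the posterior is

$$\Pi_0 \mid n_{FP}, n \;\sim\; \mathrm{Beta}(a + n_{FP},\; b + n - n_{FP}),$$

and the **validation probability** is the posterior CDF at the claimed
FDR,

$$\Pr(\Pi_0 \le \hat\alpha \mid n_{FP}, n)
  = I_{\hat\alpha}(a + n_{FP},\, b + n - n_{FP}),$$

the regularized incomplete beta function. Values above 0.5 lend support to
the claim; strong support needs values near 1. The posterior mean
$(a + n_{FP}) / (a + b + n)$ estimates the actual FDR of the list, and
equal-tailed posterior quantiles give a credible interval for it.

`n_fp` may be non-integer: an expected failure count (for example the
average over many hypothetical random subsamples) is a legitimate input and
the Beta update is defined for real-valued counts. Because the posterior is
continuous, $\Pr(\Pi_0 < \hat\alpha)$ and $\Pr(\Pi_0 \le \hat\alpha)$
coincide and are both implemented as the CDF at $\hat\alpha$.

```{r}
validate_fdr(n = 31, n_fp = 3, claimed_fdr = 0.01)
```

### Priors

The default prior is uniform, $a = b = 1$. It is mildly conservative —
most validated results are expected to be true positives, and the uniform
prior does not encode that — but it keeps validation probabilities
comparable across FDR levels. The opt-in *adaptive* prior pins the prior
mean at the claimed FDR with a small first shape ($a = 0.01$,
$b = a(1-\hat\alpha)/\hat\alpha$), which maximizes the prior variance among
such priors; it yields slightly higher validation probabilities but can be
slightly anti-conservative, so it is never the default. For very small
$\hat\alpha$ the adaptive prior also makes comparisons across FDR levels
harder, another reason the uniform prior is preferred.

### Credible intervals

Intervals are equal-tailed (posterior quantiles at $(1-\text{level})/2$ and
$1-(1-\text{level})/2$), not highest-posterior-density: quantile intervals
are unambiguous for skewed Beta posteriors and are what the worked results
in the literature correspond to. Displayed values round to 2 decimals; all
APIs return full precision.

## Bootstrap confidence intervals

The validation probability itself is an estimate; its sampling variability
can be assessed by resampling the per-feature outcomes $\delta_i$ with
replacement $B$ times, recomputing the validation probability for each
replicate, and taking the 2.5th and 97.5th empirical percentiles. The
package uses type-7 (linearly interpolated) quantiles — the convention is
otherwise arbitrary — and defaults to $B = 10{,}000$, enough for stable
95% endpoints given that the replicate distribution has at most $n + 1$
support points. The reported point estimate is always computed on the
original, un-resampled vector. For a binary outcome vector, resampling is
exactly a Binomial$(n, \bar\delta)$ draw of the failure count, which gives
the test suite an exact enumeration oracle for the interval endpoints. The
bootstrap is not justified for small samples; the function warns (but
proceeds) when $n < 10$.

## Designing a validation experiment

Assume the claimed FDR is accurate, so about $q \times n$ of $n$ validated
features fail. The minimum validation sample size at cutoff $q$ is the
smallest $n$, not exceeding the number $n_{sig}(q)$ of available
significant features, with

$$\Pr(\Pi_0 < q \mid n_{FP}(n),\, n) > \text{target}.$$

Two conventions for $n_{FP}(n)$ are exposed:

* `"floor"` (default): $n_{FP} = \lfloor q n \rfloor$. Observed failure
  counts are integers, and this is the convention under which finite
  designs exist at common targets.
* `"continuous"`: $n_{FP} = q n$ exactly. Under this rule the posterior
  mode sits exactly at $q$ and the mean above it whenever $q < 0.5$, so the
  posterior median exceeds $q$ and the probability never clears a target of
  0.5 for any $n$ — the mathematically clean statement of why very low FDR
  cutoffs cannot be validated this way. A design plot then marks such
  cutoffs unachievable.

The scan over $n$ is linear with an early exit: under the floor rule the
probability is a sawtooth in $n$ (it jumps down each time $\lfloor q n
\rfloor$ increments), so bisection is unsafe. The scan is capped at
`scan_limit` (default $10^5$); a cutoff whose smallest qualifying $n$
exceeds $n_{sig}(q)$ is reported unachievable with `capped_by_nsig = TRUE`,
and one with no qualifying $n$ up to the cap as plainly unachievable. A tie
tolerance of $10^{-12}$ keeps floating-point noise in the Beta CDF from
letting the exactly-symmetric continuous case ($q = 0.5$, probability
exactly 0.5) sneak past a 0.5 target.

An `fp_multiplier` below 1 expresses the expectation that the validation
data will come in somewhat better than the claimed FDR;
`probability_vs_sample_size()` defaults to 0.7 for its design curves, while
the minimum-sample-size computation defaults to 1 (the claim itself).
Across all of these, the same qualitative fact holds: for a fixed sample
size, validation probabilities are higher at more lenient FDR cutoffs, so
validating a random sample against a 10–50% cutoff is statistically far
easier than validating the top hits against their minuscule q-values.

```{r}
min_validation_sample_size(q = 0.10, target = 0.5, n_sig = 1000)
min_validation_sample_size(q = 0.05, target = 0.5, n_sig = 1000,
                           fp_rule = "continuous")
```

## The qPCR cost model

To put numbers on "validation is expensive", the package includes a
deterministic cost and duration model for qPCR confirmation with two
chemistries. TaqMan multiplexes 3 genes plus a reference per well and needs
a $250 probe per gene; with 3 technical replicates the well count is
$n_{genes} \times n_{samples}$ and the plate count
$\lfloor n_{genes} n_{samples} / 96 \rfloor$. SYBrGreen cannot multiplex
(2 wells per gene-sample, 3 replicates, no probe costs), so it runs six
times the wells. One research assistant at \$40,000/year runs 4 plates a
day, 22 working days a month — 1056 plates a year — and each plate costs
\$154 in mastermix and plastic. Cost is primer + reagent + personnel, with
the *exact fractional year* entering the personnel term. The floor on the
plate count is applied exactly as stated (a real lab would round up; the
model's arithmetic is the published one, and the difference is at most one
plate). All constants live in `cost_parameters()` and are overridable.

```{r}
qpcr_cost("TaqMan", n_genes = 6742, n_samples = 58)
validation_savings(333, 8, validation_n = 241, technology = "TaqMan")
```

## The simulation engine

`run_scenario()` studies the operating characteristics of the validation
probability on synthetic two-group expression experiments. The generative
model: 1000 genes, 300 differentially expressed, two groups of 10 samples,
per-gene values = baseline (N(8, 2), irrelevant to any two-group contrast)
+ group shift + N(0, 1) noise, with shifts drawn uniformly from
[0.5, 2] in magnitude and random in sign. These defaults give a realistic
mix of low- and high-powered genes, so significance lists at FDR 5–50% are
nonempty and carry genuine false discoveries; they are choices, not
published constants, and everything is overridable. P-values come from
pooled-variance two-sample t-tests (vectorized; zero-variance genes get
p = 1 with a warning); q-values are Benjamini–Hochberg with $\pi_0 = 1$ by
default (deterministic and conservative), with a Storey-type
$\hat\pi_0$ at $\lambda = 0.5$ as an option.

Every gene significant at the FDR cutoff is validated (exhaustive
validation), under one of three scenarios:

1. **errorless** — the independent assay is perfect: a validated gene fails
   exactly when it is truly null.
2. **noisy_validation** — each listed gene is re-tested on freshly
   simulated data with 3× the original group sizes at level 0.05; the assay
   can miss weak true effects and (5% of the time) confirm nulls. The 3×
   factor and the 0.05 level are design choices for "a better-powered but
   imperfect second technology".
3. **misspecified** — the original technology was simply wrong for a
   random third of the truly DE genes: those genes are relabelled null for
   validation purposes and the (perfect) assay scores against the corrected
   truth, so roughly a third of the original discoveries fail. This
   relabelling is one concrete interpretation of "the original technology
   is incorrect 1/3 of the time"; other mechanisms (e.g. corrupting the
   measurements themselves) would be defensible too.

Per replication and FDR level the engine records the validation
probability, the 95% credible interval, and the posterior-mean FDR;
summaries are medians, interquartile ranges, the fraction of intervals
covering the claimed level, and the median posterior-mean FDR.
Replications with an empty significance list are excluded and counted. The
master seed drives derived per-replication seeds, so runs are exactly
reproducible, and the package restores the caller's RNG state after every
seeded operation.

```{r, eval = FALSE}
run_scenario("errorless", prior_mode = "uniform", n_reps = 100, seed = 101)
```

What these simulations show — and what they do not: with 100 replications
at the default sizes (seconds of compute) the qualitative patterns are
stable: validation probabilities rise with the FDR cutoff and approach 1 at
50% when the validation supports the claim; under misspecification they
collapse to 0 at strict cutoffs while the posterior-mean FDR rises above
the claimed level; credible-interval coverage of the *claimed* level falls
as the cutoff grows, because Benjamini–Hochberg's conservative bias widens
the gap between the claimed and the realized FDR; and the adaptive prior
gives mildly higher probabilities than the uniform. The exact medians
depend on generative details (effect-size mix, sample sizes) that real
experiments will not share, so the package's tests assert the patterns,
not the decimals. The generator also omits features of real data —
correlated genes, batch effects, heavy-tailed noise, technology-specific
biases — so passing simulations demonstrate the statistical machinery, not
robustness to those complications; the independence assumption in
particular must be defended per-study.

## Numerical notes and limitations

* The posterior CDF at integer shapes equals the binomial tail
  $I_x(a, b) = \Pr(\mathrm{Bin}(a + b - 1, x) \ge a)$; the tests verify
  agreement to $10^{-10}$ against direct enumeration, and the bootstrap
  against its exact resampling distribution.
* Published worked values in this literature are sometimes truncated rather
  than rounded at the printed precision (e.g. a probability of 0.4451
  printed as 0.44); comparisons at ~1% relative tolerance absorb this.
* The validation probability is only as meaningful as the random sampling
  behind it: a convenience or top-hits sample biases $n_{FP}$ downward and
  the probability upward in ways the model cannot correct.
* No cost-constrained optimization of the validation design is attempted —
  the cost model prices a chosen design; it does not choose one.
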