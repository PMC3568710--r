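# Deterministic cost and duration model for qPCR confirmation experiments.
# Two chemistries: TaqMan (multiplexed, per-gene probe costs) and SYBrGreen
# (no multiplexing, no probe costs).

#' qPCR cost-model parameters
#'
#' Laboratory assumptions behind the cost model, all overridable. Defaults:
#' $250 per TaqMan probe; $150 mastermix plus $4 plastic per 96-well plate;
#' one full-time research assistant at $40,000/year running 4 plates/day, 22
#' working days/month; every reaction replicated 3 times; TaqMan multiplexes
#' 3 genes plus a reference per well; SYBrGreen runs 2 wells (gene +
#' reference) per gene-sample without multiplexing.
#'
#' @param probe_cost_usd Cost of one TaqMan probe.
#' @param mastermix_cost_usd Mastermix cost per plate.
#' @param plate_cost_usd Plastic cost per 96-well plate.
#' @param salary_usd_per_year Research-assistant salary.
#' @param plates_per_day Plates one assistant can run and analyze per day.
#' @param working_days_per_month Working days per month.
#' @param months_per_year Months per year.
#' @param wells_per_plate Wells per plate.
#' @param replicates Technical replicates per reaction.
#' @param taqman_multiplex Genes multiplexed per TaqMan well (plus the
#'   reference gene).
#' @param sybr_wells_per_gene_sample SYBrGreen wells per gene and sample
#'   (gene + reference).
#'
#' @return An object of class `cost_parameters`.
#' @export
cost_parameters <- function(probe_cost_usd = 250,
                            mastermix_cost_usd = 150,
                            plate_cost_usd = 4,
                            salary_usd_per_year = 40000,
                            plates_per_day = 4,
                            working_days_per_month = 22,
                            months_per_year = 12,
                            wells_per_plate = 96,
                            replicates = 3,
                            taqman_multiplex = 3,
                            sybr_wells_per_gene_sample = 2) {
  params <- list(
    probe_cost_usd = probe_cost_usd,
    mastermix_cost_usd = mastermix_cost_usd,
    plate_cost_usd = plate_cost_usd,
    salary_usd_per_year = salary_usd_per_year,
    plates_per_day = plates_per_day,
    working_days_per_month = working_days_per_month,
    months_per_year = months_per_year,
    wells_per_plate = wells_per_plate,
    replicates = replicates,
    taqman_multiplex = taqman_multiplex,
    sybr_wells_per_gene_sample = sybr_wells_per_gene_sample
  )
  for (nm in names(params)) {
    check_scalar(params[[nm]], nm, lower = 0, open_lower = TRUE)
  }
  structure(params, class = "cost_parameters")
}

plates_per_year <- function(params) {
  params$plates_per_day * params$working_days_per_month *
    params$months_per_year
}

#' Plate counts for a qPCR validation experiment
#'
#' TaqMan: with `taqman_multiplex` genes per well and `replicates`
#' replicates the well count is
#' `n_genes / multiplex * n_samples * replicates`; at the defaults (3-plex,
#' 3 replicates) the two factors cancel and the plate count is
#' `floor(n_genes * n_samples / 96)`. SYBrGreen cannot be multiplexed and
#' burns `sybr_wells_per_gene_sample` wells per gene-sample-replicate, i.e.
#' `floor(n_genes * n_samples * 3 * 2 / 96)` plates at the defaults. The
#' floor is applied exactly as the model states it.
#'
#' @param n_genes,n_samples Experiment dimensions (nonnegative).
#' @param params A [cost_parameters()].
#'
#' @return Integer plate count.
#' @export
#' @examples
#' taqman_plates(6742, 58)   # 4073
taqman_plates <- function(n_genes, n_samples, params = cost_parameters()) {
  check_scalar(n_genes, "n_genes", lower = 0)
  check_scalar(n_samples, "n_samples", lower = 0)
  wells <- n_genes / params$taqman_multiplex * n_samples * params$replicates
  floor(wells / params$wells_per_plate)
}

#' @rdname taqman_plates
#' @export
sybrgreen_plates <- function(n_genes, n_samples, params = cost_parameters()) {
  check_scalar(n_genes, "n_genes", lower = 0)
  check_scalar(n_samples, "n_samples", lower = 0)
  wells <- n_genes * n_samples * params$replicates *
    params$sybr_wells_per_gene_sample
  floor(wells / params$wells_per_plate)
}

#' Cost and duration of a qPCR validation experiment
#'
#' Total cost is itemized into primer costs (TaqMan only:
#' `probe_cost * n_genes`), reagent costs (`(mastermix + plate) * plates`)
#' and personnel costs (`salary * time`), where the time in years is the
#' plate count divided by the assistant's annual plate throughput
#' (`4 * 22 * 12 = 1056` plates/year at the defaults). The exact fractional
#' year enters the personnel cost; no rounding is applied anywhere.
#'
#' @param technology `"TaqMan"` or `"SYBrGreen"` (case-insensitive).
#' @inheritParams taqman_plates
#'
#' @return An object of class `cost_estimate`: list with `technology`,
#'   `n_genes`, `n_samples`, `n_plates`, `time_years`, `cost_usd` and an
#'   itemized `components` list (primer, reagent, personnel).
#' @export
#' @examples
#' qpcr_cost("TaqMan", n_genes = 6742, n_samples = 58)
qpcr_cost <- function(technology, n_genes, n_samples,
                      params = cost_parameters()) {
  stopifnot(inherits(params, "cost_parameters"))
  tech <- normalize_technology(technology)
  plates <- switch(tech,
    TaqMan = taqman_plates(n_genes, n_samples, params),
    SYBrGreen = sybrgreen_plates(n_genes, n_samples, params)
  )
  time_years <- plates / plates_per_year(params)
  components <- list(
    primer = if (tech == "TaqMan") params$probe_cost_usd * n_genes else 0,
    reagent = (params$mastermix_cost_usd + params$plate_cost_usd) * plates,
    personnel = params$salary_usd_per_year * time_years
  )
  structure(
    list(technology = tech, n_genes = n_genes, n_samples = n_samples,
         n_plates = plates, time_years = time_years,
         cost_usd = sum(unlist(components)), components = components),
    class = "cost_estimate"
  )
}

normalize_technology <- function(technology) {
  if (!is.character(technology) || length(technology) != 1L) {
    stop("`technology` must be a single string", call. = FALSE)
  }
  switch(tolower(technology),
    taqman = "TaqMan",
    sybrgreen = "SYBrGreen",
    stop(sprintf("unknown qPCR technology '%s' (use TaqMan or SYBrGreen)",
                 technology), call. = FALSE)
  )
}

#' @export
print.cost_estimate <- function(x, ...) {
  cat(sprintf("%s qPCR: %g genes x %g samples -> %d plates\n",
              x$technology, x$n_genes, x$n_samples, x$n_plates))
  cat(sprintf("  time: %.2f years; cost: $%s\n", x$time_years,
              format(round(x$cost_usd), big.mark = ",")))
  cat(sprintf("  components: primer $%s, reagent $%s, personnel $%s\n",
              format(round(x$components$primer), big.mark = ","),
              format(round(x$components$reagent), big.mark = ","),
              format(round(x$components$personnel), big.mark = ",")))
  invisible(x)
}

#' Manual versus statistical validation costs
#'
#' Compares confirming every differentially expressed gene ("manual") with
#' confirming only a designed validation subsample of `validation_n` genes
#' ("statistical") on the same samples and technology.
#'
#' @param n_de_genes Number of differentially expressed genes in the list.
#' @param n_samples Number of samples assayed per gene.
#' @param validation_n Size of the statistical validation subsample; must
#'   not exceed `n_de_genes`.
#' @inheritParams qpcr_cost
#'
#' @return An object of class `validation_savings`: list with `manual` and
#'   `statistical` [qpcr_cost()] estimates and `fraction`
#'   (`validation_n / n_de_genes`).
#' @export
#' @examples
#' validation_savings(333, 8, validation_n = 241, technology = "TaqMan")
validation_savings <- function(n_de_genes, n_samples, validation_n,
                               technology = "TaqMan",
                               params = cost_parameters()) {
  check_scalar(n_de_genes, "n_de_genes", lower = 0)
  check_scalar(validation_n, "validation_n", lower = 0)
  if (validation_n > n_de_genes) {
    stop("`validation_n` cannot exceed `n_de_genes`", call. = FALSE)
  }
  manual <- qpcr_cost(technology, n_de_genes, n_samples, params)
  statistical <- qpcr_cost(technology, validation_n, n_samples, params)
  structure(
    list(manual = manual, statistical = statistical,
         fraction = validation_n / n_de_genes),
    class = "validation_savings"
  )
}

#' @export
print.validation_savings <- function(x, ...) {
  cat(sprintf("validating %.1f%% of the significant list\n",
              100 * x$fraction))
  cat(sprintf("  manual:      %.2f years, $%s\n", x$manual$time_years,
              format(round(x$manual$cost_usd), big.mark = ",")))
  cat(sprintf("  statistical: %.2f years, $%s\n", x$statistical$time_years,
              format(round(x$statistical$cost_usd), big.mark = ",")))
  invisible(x)
}
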