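#' Pipeline run configuration
#'
#' Bundles input paths and per-stage parameter blocks for [run_pipeline()].
#' All referenced files must exist; community tables are optional and the
#' corresponding stages are skipped when absent.
#'
#' @param diet,urine Paths to the diet and urine CSV tables (required).
#' @param pdu_genes,qpcr,scfa Optional paths to community tables.
#' @param outdir Output directory for per-stage CSVs and the report.
#' @param window A [window_spec()].
#' @param attribution An [attribution_config()].
#' @param constants An [analyte_constants()].
#' @param mass_balance A [mass_balance_params()].
#' @param rule A [classifier_rule()].
#' @param n_days Number of study days used to complete the daily grid.
#' @return A list of class `run_config`.
#' @export
run_config <- function(diet, urine, pdu_genes = NULL, qpcr = NULL,
                       scfa = NULL, outdir = tempfile("glycacro_run_"),
                       window = window_spec(),
                       attribution = default_attribution(),
                       constants = analyte_constants(),
                       mass_balance = mass_balance_params(),
                       rule = classifier_rule(),
                       n_days = 11) {
  paths <- c(diet = diet, urine = urine, pdu_genes = pdu_genes,
             qpcr = qpcr, scfa = scfa)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("input file(s) not found: ",
         paste(names(missing), "=", missing, collapse = "; "),
         call. = FALSE)
  }
  structure(list(diet = diet, urine = urine, pdu_genes = pdu_genes,
                 qpcr = qpcr, scfa = scfa, outdir = outdir,
                 window = window, attribution = attribution,
                 constants = constants, mass_balance = mass_balance,
                 rule = rule, n_days = n_days),
            class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full diet-to-biomarker pipeline
#'
#' Executes diet aggregation, urine processing, the exposure-group
#' comparison, phenotype classification, the mass-balance acrolein
#' estimates, and (when inputs are provided) the community summaries.
#' Each stage writes a CSV into `config$outdir`; a `report.json` records
#' the headline summaries and every parameter used. The run is fully
#' deterministic for fixed inputs.
#'
#' @param config A [run_config()].
#' @return (Invisibly) a list with all stage outputs and the report.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
  out <- function(name) file.path(config$outdir, name)

  diet <- run_stage("diet", read_diet(config$diet))
  day_glycerol <- run_stage("diet", diet_glycerol(diet))
  readr::write_csv(day_glycerol, out("day_glycerol.csv"))

  urine <- run_stage("urine", read_urine(config$urine))
  daily <- run_stage("urine",
                     daily_excretion(urine, config$window, config$constants,
                                     n_days = config$n_days))
  overnight <- run_stage("urine",
                         overnight_excretion(urine, config$window,
                                             config$constants,
                                             n_days = config$n_days))
  readr::write_csv(daily, out("daily.csv"))
  readr::write_csv(overnight, out("overnight.csv"))

  comparison <- run_stage("compare",
                          compare_exposure_groups(overnight,
                                                  config$attribution))
  readr::write_csv(comparison, out("comparison.csv"))

  calls <- run_stage("phenotype", classify_cohort(daily, config$rule))
  counts <- run_stage("phenotype", cohort_phenotype_counts(calls))
  readr::write_csv(calls, out("phenotypes.csv"))

  estimates <- run_stage("massbalance",
                         acrolein_estimates(overnight, day_glycerol,
                                            config$attribution,
                                            config$mass_balance))
  readr::write_csv(estimates, out("estimates.csv"))

  pdu <- NULL
  if (!is.null(config$pdu_genes)) {
    pdu_genes <- readr::read_csv(config$pdu_genes, show_col_types = FALSE)
    pdu <- run_stage("pdu", pdu_positive(pdu_genes))
    if (!is.null(config$qpcr)) {
      qpcr <- readr::read_csv(config$qpcr, show_col_types = FALSE)
      pdu$per_donor <- run_stage(
        "pdu", per_donor_pdu_species(pdu$positive_ids, qpcr))
      pdu$shares <- run_stage("pdu", taxon_share(qpcr))
      readr::write_csv(pdu$per_donor$per_donor, out("pdu_per_donor.csv"))
    }
  }
  scfa <- NULL
  if (!is.null(config$scfa)) {
    scfa_tab <- readr::read_csv(config$scfa, show_col_types = FALSE)
    scfa <- run_stage("scfa", scfa_proportions(scfa_tab))
    readr::write_csv(scfa, out("scfa_proportions.csv"))
  }

  valid_ratio <- daily$hpma_umol > 0 & !daily$missing
  report <- list(
    daily_medians = list(
      hpma_umol = stats::median(daily$hpma_umol[!daily$missing]),
      cema_umol = stats::median(daily$cema_umol[!daily$missing]),
      sum_umol = stats::median(daily$sum_umol[!daily$missing]),
      cema_hpma_ratio = stats::median(
        daily$cema_umol[valid_ratio] / daily$hpma_umol[valid_ratio])),
    overnight_comparison = comparison,
    phenotype_counts = stats::setNames(as.list(counts$n), counts$label),
    acrolein_estimates = estimates,
    pdu = if (!is.null(pdu)) list(
      n_positive = pdu$n_positive,
      percent_positive = pdu$percent_positive,
      per_donor_median = if (!is.null(pdu$per_donor))
        pdu$per_donor$cohort_median,
      per_donor_min = if (!is.null(pdu$per_donor))
        pdu$per_donor$cohort_min),
    scfa_median_pct = if (!is.null(scfa)) list(
      acetate = stats::median(scfa$acetate_pct, na.rm = TRUE),
      propionate = stats::median(scfa$propionate_pct, na.rm = TRUE),
      butyrate = stats::median(scfa$butyrate_pct, na.rm = TRUE),
      but_prop_ratio = stats::median(scfa$but_prop_ratio, na.rm = TRUE)),
    parameters = list(
      window = unclass(config$window[c("day_start", "night_start",
                                       "night_end")]),
      attribution = unclass(config$attribution),
      constants = unclass(config$constants),
      mass_balance = unclass(config$mass_balance),
      classifier_rule = unclass(config$rule),
      n_days = config$n_days))
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(list(day_glycerol = day_glycerol, daily = daily,
                 overnight = overnight, comparison = comparison,
                 phenotypes = calls, phenotype_counts = counts,
                 estimates = estimates, pdu = pdu, scfa = scfa,
                 report = report))
}
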