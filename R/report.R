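#' Run the full threshold-anchored analysis pipeline
#'
#' Orchestrates ingest -> metrics -> inference -> cross-validation ->
#' stratification on one cohort and returns a structured bundle mirroring
#' the analysis a study report needs:
#' per-patient metrics, the nerve-level summary, the three metric
#' correlations with Fisher-z intervals, the matched-subset Steiger
#' comparison of TRR vs percentage change, the linear and covariate-adjusted
#' dose-response models, the logistic complete-relief model with bootstrap
#' interval, the 2x2 contingency at the reference cutoff, TRR/TE stratified
#' outcome tables, the sufficiency-plateau check, the cut-point scans for
#' all three outcomes, and LOOCV of all metrics. Every excluded patient
#' (zero pain baseline; undefined TRR) is listed with the rule that removed
#' it.
#'
#' Correlations being compared by the Steiger test are computed on the
#' identical patient subset (defined TRR and baseline pain), so the two
#' metrics are judged on the same patients.
#'
#' @param cohort an `mmg_cohort` (from [read_cohort()] or
#'   [generate_cohort()]).
#' @param config a [metric_config()].
#' @param bootstrap_reps bootstrap resamples for the logistic interval.
#' @param seed seed for the bootstrap (and any other resampling); echoed in
#'   the bundle.
#' @param out_dir optional directory; when given, writes `metrics.csv`,
#'   `analysis.json`, `crossval.json`, `strata.csv`, `cutpoints.csv` and a
#'   human-readable `summary.txt`.
#' @return list of class `mmg_report` with elements `metrics`,
#'   `nerve_summary`, `correlations`, `steiger`, `dose_response`,
#'   `adjusted_trr`, `logistic`, `contingency`, `strata_trr`, `strata_te`,
#'   `plateau`, `cutpoints`, `crossval`, `exclusions`, `anomalies`, `seed`,
#'   `config`.
#' @export
run_full_analysis <- function(cohort, config = metric_config(),
                              bootstrap_reps = 2000, seed = 17,
                              out_dir = NULL) {
  stopifnot(inherits(cohort, "mmg_cohort"))
  metrics <- compute_metrics(cohort, config)
  anomalies <- validate_cohort(cohort)

  pain <- !is.na(metrics$pain_improvement_frac)
  trr_def <- pain & !is.na(metrics$trr)
  exclusions <- list(
    zero_baseline = metrics$patient_id[!pain],
    undefined_trr = metrics$patient_id[pain & is.na(metrics$trr)])

  correlations <- list(
    pct_change = pearson_with_ci(metrics$pct_change[pain],
                                 metrics$pain_improvement_frac[pain]),
    trr = pearson_with_ci(metrics$trr[trr_def],
                          metrics$pain_improvement_frac[trr_def]),
    te = pearson_with_ci(metrics$te[pain],
                         metrics$pain_improvement_frac[pain]))

  # matched subset: both metrics on exactly the patients where TRR exists
  r_trr <- stats::cor(metrics$trr[trr_def],
                      metrics$pain_improvement_frac[trr_def])
  r_pct <- stats::cor(metrics$pct_change[trr_def],
                      metrics$pain_improvement_frac[trr_def])
  r12 <- stats::cor(metrics$trr[trr_def], metrics$pct_change[trr_def])
  steiger <- c(steiger_test(r_trr, r_pct, r12, sum(trr_def)),
               list(r_trr = r_trr, r_pct_matched = r_pct, r12 = r12,
                    n = sum(trr_def)))

  dose_response <- ols_fit(metrics$pain_improvement_frac[pain],
                           data.frame(te = metrics$te[pain]))
  adjusted <- adjusted_trr_model(metrics)
  logit <- logistic_fit(metrics$complete_relief[pain], metrics$te[pain],
                        bootstrap_reps = bootstrap_reps, seed = seed)

  at_ref <- metrics$te[pain] == 0
  relief <- metrics$complete_relief[pain]
  contingency <- odds_ratio_2x2(sum(at_ref & relief), sum(at_ref & !relief),
                                sum(!at_ref & relief), sum(!at_ref & !relief))

  plateau <- tryCatch(plateau_check(metrics, config$reference_mA),
                      error = function(e) NULL)

  cutpoints <- lapply(
    stats::setNames(nm = c("complete_relief", "mcid", "any_improvement")),
    function(o) tryCatch(cutpoint_scan(metrics, o,
                                       reference_mA = config$reference_mA),
                         error = function(e) NULL))

  bundle <- structure(list(
    metrics = metrics,
    nerve_summary = nerve_level_summary(cohort, config),
    correlations = correlations,
    steiger = steiger,
    dose_response = dose_response,
    adjusted_trr = adjusted,
    logistic = logit,
    contingency = contingency,
    strata_trr = stratify(metrics, trr_default_strata()),
    strata_te = stratify(metrics, te_default_strata()),
    plateau = plateau,
    cutpoints = cutpoints,
    crossval = compare_metrics_cv(metrics),
    exclusions = exclusions,
    anomalies = anomalies,
    seed = seed,
    config = unclass(config)
  ), class = "mmg_report")

  if (!is.null(out_dir)) write_report(bundle, out_dir)
  bundle
}

# strip closures/fit objects so bundles serialize cleanly to JSON
json_safe <- function(x) {
  if (is.function(x)) return(NULL)
  if (inherits(x, "lm") || inherits(x, "glm")) return(NULL)
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, json_safe)
    return(x[!vapply(x, is.null, logical(1))])
  }
  x
}

#' Write a report bundle to disk
#'
#' The JSON files are the machine-readable source of truth; the CSV/text
#' views are derived from the same unrounded numbers, so no statistic is
#' computed in the formatting layer.
#'
#' @param bundle an `mmg_report` from [run_full_analysis()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "mmg_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    metrics = file.path(out_dir, "metrics.csv"),
    analysis = file.path(out_dir, "analysis.json"),
    crossval = file.path(out_dir, "crossval.json"),
    strata = file.path(out_dir, "strata.csv"),
    cutpoints = file.path(out_dir, "cutpoints.csv"),
    summary = file.path(out_dir, "summary.txt"))

  utils::write.csv(bundle$metrics, paths["metrics"], row.names = FALSE)

  analysis <- json_safe(list(
    seed = bundle$seed, config = bundle$config,
    correlations = lapply(bundle$correlations, unclass),
    steiger = bundle$steiger,
    dose_response = list(coefficients = bundle$dose_response$coefficients,
                         r_squared = bundle$dose_response$r_squared,
                         n = bundle$dose_response$n,
                         aic = bundle$dose_response$aic,
                         method = "OLS, t-based 95% CI"),
    adjusted_trr = list(coefficients = bundle$adjusted_trr$coefficients,
                        r_squared = bundle$adjusted_trr$r_squared,
                        n = bundle$adjusted_trr$n,
                        method = "OLS, t-based 95% CI"),
    logistic = unclass(bundle$logistic),
    contingency = unclass(bundle$contingency),
    plateau = if (!is.null(bundle$plateau)) unclass(bundle$plateau),
    exclusions = bundle$exclusions))
  jsonlite::write_json(analysis, paths["analysis"], auto_unbox = TRUE,
                       digits = NA, null = "null")

  cv <- lapply(bundle$crossval, function(v) unclass(v))
  jsonlite::write_json(json_safe(list(seed = bundle$seed, results = cv)),
                       paths["crossval"], auto_unbox = TRUE, digits = NA)

  strata <- rbind(cbind(metric = "trr", as.data.frame(bundle$strata_trr)),
                  cbind(metric = "te", as.data.frame(bundle$strata_te)))
  utils::write.csv(strata, paths["strata"], row.names = FALSE)

  cp <- do.call(rbind, lapply(names(bundle$cutpoints), function(nm) {
    x <- bundle$cutpoints[[nm]]
    if (is.null(x)) return(NULL)
    cbind(outcome = nm, as.data.frame(x), auc = attr(x, "auc"))
  }))
  utils::write.csv(cp, paths["cutpoints"], row.names = FALSE)

  writeLines(utils::capture.output(print(bundle)), paths["summary"])
  invisible(paths)
}

#' Format a fraction as a display percentage
#'
#' Percentages are printed to one decimal; interval endpoints for
#' proportions and means of fractions are truncated to the displayable
#' 0--100% range (truncation happens only here, never in the stored
#' numbers).
#'
#' @param x fractions (e.g. 0.7647).
#' @param digits decimals, default 1.
#' @param clamp truncate to `[0, 1]` before formatting, default TRUE.
#' @return character vector like `"76.5%"`.
#' @export
#' @examples
#' format_percent(c(0.7647, 1.01, 0.5))
format_percent <- function(x, digits = 1, clamp = TRUE) {
  if (clamp) x <- pmin(pmax(x, 0), 1)
  out <- sprintf(paste0("%.", digits, "f%%"), 100 * x)
  # a truncated upper endpoint prints as the bare bound
  out[x == 1] <- "100%"
  out
}

#' Paper-style stratified outcome table
#'
#' Renders a [stratify()] result with percentages to one decimal and CI
#' display truncated at 0--100%.
#'
#' @param strata an `mmg_strata`.
#' @return data.frame of display strings.
#' @export
format_strata <- function(strata) {
  data.frame(
    Category = strata$label,
    n = strata$n,
    `Mean Pain Improvement (95% CI)` = sprintf(
      "%s (%s-%s)", format_percent(strata$mean_improvement),
      format_percent(strata$improvement_lo),
      format_percent(strata$improvement_hi)),
    `Complete Relief Rate (95% CI)` = sprintf(
      "%s (%s-%s)", format_percent(strata$relief_rate),
      format_percent(strata$relief_lo), format_percent(strata$relief_hi)),
    check.names = FALSE)
}

#' @export
print.mmg_report <- function(x, ...) {
  m <- x$metrics
  pain <- !is.na(m$pain_improvement_frac)
  cat("Threshold-anchored MMG analysis\n")
  cat(sprintf("  %d patients (%d in pain analyses, %d in TRR analyses), %d nerves\n",
              nrow(m), sum(pain), sum(pain & !is.na(m$trr)),
              x$nerve_summary$n_nerves))
  if (length(x$exclusions$zero_baseline)) {
    cat("  excluded (zero pain baseline): ",
        paste(x$exclusions$zero_baseline, collapse = ", "), "\n", sep = "")
  }
  if (length(x$exclusions$undefined_trr)) {
    cat("  excluded from TRR analyses (no baseline elevation): ",
        paste(x$exclusions$undefined_trr, collapse = ", "), "\n", sep = "")
  }
  cat("\nNerve-level summary\n")
  print(x$nerve_summary)
  cat("\nCorrelations with pain improvement (Fisher-z 95% CI)\n")
  for (nm in names(x$correlations)) {
    cat("  ", format(nm, width = 11)); print(x$correlations[[nm]])
  }
  cat(sprintf("\nSteiger test, matched subset (n = %d): TRR r = %.3f vs %%change r = %.3f, Z = %.2f, p = %.3f\n",
              x$steiger$n, x$steiger$r_trr, x$steiger$r_pct_matched,
              x$steiger$z, x$steiger$p))
  sl <- x$dose_response$coefficients
  sl <- sl[sl$term == "te", ]
  cat(sprintf("\nTE dose-response: beta = %.3f (95%% CI %.3f to %.3f), p = %.4g\n",
              sl$estimate, sl$ci_lo, sl$ci_hi, sl$p))
  cat(sprintf("Logistic complete relief: OR/mA = %.2f (Wald %.2f-%.2f; bootstrap %.2f-%.2f)\n",
              x$logistic$or_per_unit, x$logistic$wald_ci_lo,
              x$logistic$wald_ci_hi, x$logistic$bootstrap_ci_lo,
              x$logistic$bootstrap_ci_hi))
  cat(sprintf("At-reference contingency: OR = %.2f, exact p = %.3f\n",
              x$contingency$odds_ratio, x$contingency$exact_p))
  cat("\nOutcomes by TRR category\n")
  print(format_strata(x$strata_trr), row.names = FALSE)
  cat("\nOutcomes by TE category\n")
  print(format_strata(x$strata_te), row.names = FALSE)
  if (!is.null(x$plateau)) {
    cat(sprintf("\nPlateau below reference (n = %d): r = %.3f, p = %.3f\n",
                x$plateau$n, x$plateau$r, x$plateau$p))
  }
  cat("\nCross-validation (LOOCV)\n")
  for (cv in x$crossval) {
    cat(sprintf("  %-10s apparent r %.3f -> cv r %.3f (shrinkage %.1f%%), RMSE %.3f\n",
                cv$metric_name, cv$apparent_r, cv$cv_r, cv$shrinkage_pct,
                cv$rmse))
  }
  invisible(x)
}
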