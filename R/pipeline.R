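#' Analysis scenario configuration
#'
#' Two clinical scenarios are analysed: a *non-invasive* scenario using
#' clinical, serum-biomarker and echocardiographic covariates (screening
#' setting), and an *invasive* scenario adding left-heart-catheterization
#' covariates (gold-standard setting). The invasive candidate set is always
#' a strict superset of the non-invasive one.
#'
#' @param scenario `"non_invasive"` or `"invasive"`.
#' @param candidates Optional character vector of candidate covariate
#'   columns; defaults to the scenario's standard list.
#' @param dichotomize Logical; dichotomize candidates at their sample
#'   medians before modelling (default `TRUE`).
#' @param seed Integer seed used for every stochastic step of the analysis.
#' @param bootstrap_B Number of bootstrap resamples for reported CIs.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("non_invasive", "invasive"),
                            candidates = NULL, dichotomize = TRUE,
                            seed = 1, bootstrap_B = 1000) {
  scenario <- match.arg(scenario)
  if (is.null(candidates))
    candidates <- default_candidates(scenario)
  if (scenario == "invasive" &&
      !all(default_candidates("non_invasive") %in% candidates))
    stop("invasive candidate set must contain the non-invasive set",
         call. = FALSE)
  structure(list(scenario = scenario, candidates = candidates,
                 dichotomize = dichotomize, seed = as.integer(seed),
                 bootstrap_B = bootstrap_B),
            class = "scenario_config")
}

default_candidates <- function(scenario) {
  non_invasive <- c("nt_probnp_pg_ml", "bnp_pg_ml", "mr_proanp_pg_ml",
                    "sst2_ng_ml", "galectin3_ng_ml", "mr_proadm_pg_ml",
                    "e_over_eprime", "lvef_pct", "lvedv_ml_m2",
                    "lvesv_ml_m2", "la_volume_ml_m2", "lars_pct")
  if (scenario == "non_invasive") return(non_invasive)
  c(non_invasive,
    "lvedp_mmhg", "min_dpdt_mmhg_s", "max_dpdt_mmhg_s",
    "contraction_integral_mmhg", "relaxation_integral_mmhg",
    "diastolic_integral_mmhg_s")
}

#' Cohort summary counts and rates
#'
#' @param cohort Data frame with `follow_up_years`, `event` and (optionally)
#'   `lvedp_mmhg` or `diastolic_dysfunction`.
#' @return List with `n`, `n_events`, `event_pct`, `n_events_1yr`,
#'   `event_1yr_pct`, `median_follow_up`, `follow_up_q1`, `follow_up_q3`
#'   and (when invasive data are present) `n_diastolic_dysfunction`,
#'   `diastolic_dysfunction_pct`. Percentages are rounded to 1 decimal.
#' @export
#' @examples
#' co <- simulate_cohort(cohort_config(n = 110, seed = 7))
#' summarize_cohort(co)
summarize_cohort <- function(cohort) {
  cohort <- as.data.frame(cohort)
  if (!nrow(cohort)) stop("cohort is empty", call. = FALSE)
  n <- nrow(cohort)
  ev <- sum(cohort$event == 1)
  ev1 <- sum(cohort$event == 1 & cohort$follow_up_years <= 1.0)
  out <- list(n = n, n_events = ev, event_pct = round(100 * ev / n, 1),
              n_events_1yr = ev1, event_1yr_pct = round(100 * ev1 / n, 1),
              median_follow_up = median(cohort$follow_up_years),
              follow_up_q1 = unname(quantile(cohort$follow_up_years, 0.25)),
              follow_up_q3 = unname(quantile(cohort$follow_up_years, 0.75)))
  dd <- if ("lvedp_mmhg" %in% names(cohort)) {
    classify_diastolic_dysfunction(cohort$lvedp_mmhg)
  } else if ("diastolic_dysfunction" %in% names(cohort)) {
    cohort$diastolic_dysfunction == 1
  } else NULL
  if (!is.null(dd)) {
    out$n_diastolic_dysfunction <- sum(dd)
    out$diastolic_dysfunction_pct <- round(100 * sum(dd) / n, 1)
  }
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("n = %d patients; %d deaths (%.1f%%), %d within year 1 (%.1f%%)\n",
              x$n, x$n_events, x$event_pct, x$n_events_1yr, x$event_1yr_pct))
  cat(sprintf("median follow-up %.2f (%.2f-%.2f) years\n",
              x$median_follow_up, x$follow_up_q1, x$follow_up_q3))
  if (!is.null(x$n_diastolic_dysfunction))
    cat(sprintf("diastolic dysfunction (LVEDP > 15 mmHg): %d (%.1f%%)\n",
                x$n_diastolic_dysfunction, x$diastolic_dysfunction_pct))
  invisible(x)
}

#' Run the full survival-analysis workflow for one clinical scenario
#'
#' Orchestrates, on a patient cohort: cohort summary; descriptive
#' comparisons grouped by 1-year mortality; per-candidate
#' median-dichotomization, univariate Cox regression and Kaplan-Meier
#' curves per stratum; forward-stepwise BIC multivariable Cox selection;
#' bootstrap percentile CIs for the final model's hazard ratios; and
#' Harrell's C-statistic of the final linear predictor.
#'
#' @param cohort A cohort data frame or a path to a cohort CSV
#'   (see [read_cohort_csv()]).
#' @param config A [scenario_config()].
#' @return Object of class `model_report`: list with `summary`,
#'   `descriptives`, `univariate` (data frame: variable, cutoff, HR,
#'   bootstrap-free Wald CI, p), `km_curves` (per candidate: cutoff and
#'   `km_curve`s for the below/above strata), `model` (the
#'   `selected_model`), `final_hr` (data frame with bootstrap CIs),
#'   `c_statistic` and `provenance`.
#' @export
run_analysis <- function(cohort, config) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  cohort <- as.data.frame(cohort)
  required <- c(config$candidates, "follow_up_years", "event")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols))
    stop("validation error: cohort lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  set.seed(config$seed)
  times <- cohort$follow_up_years
  events <- cohort$event

  smry <- summarize_cohort(cohort)
  descriptives <- compare_descriptives(cohort,
                                       variables = config$candidates)

  # median dichotomization of every candidate (degenerate columns dropped)
  dich <- list(); cutoffs <- c()
  for (v in config$candidates) {
    md <- try(median_dichotomize(cohort[[v]]), silent = TRUE)
    if (inherits(md, "try-error")) {
      warning(sprintf("candidate '%s' dropped: %s", v,
                      attr(md, "condition")$message), call. = FALSE)
      next
    }
    dich[[v]] <- md$indicator
    cutoffs[v] <- md$cutoff
  }
  dich <- as.data.frame(dich)

  x_model <- if (config$dichotomize) dich else
    cohort[, names(dich), drop = FALSE]

  univariate <- do.call(rbind, lapply(names(dich), function(v) {
    f <- try(fit_cox(x_model[, v, drop = FALSE], times, events),
             silent = TRUE)
    if (inherits(f, "try-error")) return(NULL)
    data.frame(variable = v, cutoff = unname(cutoffs[v]),
               hr = unname(f$hazard_ratios), ci_lower = unname(f$ci_lower),
               ci_upper = unname(f$ci_upper), p_value = unname(f$p_values))
  }))
  rownames(univariate) <- NULL

  km_curves <- lapply(names(dich), function(v) {
    idx <- dich[[v]] == 1
    list(cutoff = unname(cutoffs[v]),
         below = kaplan_meier(times[!idx], events[!idx]),
         above = kaplan_meier(times[idx], events[idx]))
  })
  names(km_curves) <- names(dich)

  model <- stepwise_bic(x_model, times, events)

  final_hr <- NULL
  if (length(model$selected)) {
    boot <- fit_cox(x_model[, model$selected, drop = FALSE], times, events,
                    boot_ci = TRUE, B = config$bootstrap_B,
                    seed = config$seed)
    final_hr <- data.frame(variable = model$selected,
                           cutoff = unname(cutoffs[model$selected]),
                           hr = unname(boot$hazard_ratios),
                           ci_lower = unname(boot$ci_lower),
                           ci_upper = unname(boot$ci_upper),
                           p_value = unname(boot$p_values))
    rownames(final_hr) <- NULL
  }

  report <- list(scenario = config$scenario, summary = smry,
                 descriptives = descriptives, univariate = univariate,
                 cutoffs = cutoffs, km_curves = km_curves, model = model,
                 final_hr = final_hr, c_statistic = model$c_statistic,
                 provenance = list(seed = config$seed,
                                   config_hash = config_hash(config),
                                   package_version =
                                     as.character(packageVersion("diastolica")),
                                   n = nrow(cohort)))
  class(report) <- "model_report"
  report
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config[setdiff(names(config), "seed")]), tf)
  unname(tools::md5sum(tf))
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("== %s scenario ==\n", gsub("_", "-", x$scenario)))
  print(x$summary)
  if (!is.null(x$final_hr)) {
    cat("\nFinal multivariable Cox model (bootstrap 95% CI):\n")
    df <- x$final_hr
    df$hr <- round(df$hr, 2); df$ci_lower <- round(df$ci_lower, 2)
    df$ci_upper <- round(df$ci_upper, 2); df$p_value <- signif(df$p_value, 2)
    df$cutoff <- signif(df$cutoff, 3)
    print(df)
  } else {
    cat("\nFinal model: empty (no candidate lowered BIC)\n")
  }
  cat(sprintf("\nC-statistic: %.3f\n", x$c_statistic))
  invisible(x)
}

#' Write a model report to disk (JSON plus KM curve CSVs)
#'
#' @param report A `model_report` from [run_analysis()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_model_report <- function(report, dir) {
  stopifnot(inherits(report, "model_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, "report.json")
  payload <- list(
    scenario = report$scenario,
    summary = unclass(report$summary),
    descriptives = report$descriptives,
    univariate = report$univariate,
    model = list(selected = report$model$selected,
                 bic_trajectory = report$model$bic_trajectory,
                 c_statistic = report$c_statistic),
    final_hr = report$final_hr,
    provenance = report$provenance)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  paths <- json_path
  for (v in names(report$km_curves)) {
    for (stratum in c("below", "above")) {
      p <- file.path(dir, sprintf("km_%s_%s.csv", v, stratum))
      write.csv(as.data.frame(report$km_curves[[v]][[stratum]]), p,
                row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
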