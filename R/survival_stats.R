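#' Dichotomize a continuous marker at its sample median
#'
#' Clinical survival analyses of biomarkers commonly split patients at the
#' sample median; the indicator is 1 for values strictly above the cut-off
#' (e.g. "NT-proBNP > 123 pg/mL").
#'
#' @param values Numeric vector with at least 2 finite values.
#' @return List with `cutoff` (the sample median) and `indicator`
#'   (integer 0/1, `NA` preserved).
#' @export
#' @examples
#' median_dichotomize(c(1, 2, 3))
median_dichotomize <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2L)
    stop("need at least 2 finite values to dichotomize", call. = FALSE)
  if (diff(range(v)) == 0)
    stop("degenerate split: all values identical", call. = FALSE)
  cutoff <- median(v)
  list(cutoff = cutoff, indicator = as.integer(values > cutoff))
}

#' Kaplan-Meier product-limit survival curve
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators (1 = death).
#' @return Object of class `km_curve`: data frame with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`, one row per distinct
#'   observed time. With no events the curve is flat at 1.
#' @export
#' @examples
#' kaplan_meier(c(1, 2, 3, 4), c(1, 1, 1, 0))
kaplan_meier <- function(times, events) {
  check_surv(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, n_censor = fit$n.censor,
                       survival = fit$surv),
            class = c("km_curve", "data.frame"))
}

check_surv <- function(times, events) {
  if (length(times) != length(events))
    stop("times and events must have equal length", call. = FALSE)
  if (any(!is.finite(times)) || any(times <= 0))
    stop("times must be positive and finite", call. = FALSE)
  if (!all(events %in% c(0, 1)))
    stop("events must be 0/1", call. = FALSE)
  invisible(NULL)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximises the Cox partial likelihood (Efron tie handling by default)
#' and reports hazard ratios with Wald p-values. Confidence intervals are
#' Wald by default; with `boot_ci = TRUE` percentile bootstrap intervals
#' over patient resamples are attached instead (the package convention for
#' reported intervals).
#'
#' @param x Data frame or matrix of covariates (one column per covariate).
#' @param times,events Follow-up times and 0/1 event indicators.
#' @param tie_method `"efron"` (default) or `"breslow"`.
#' @param boot_ci Logical; attach bootstrap percentile CIs.
#' @param B Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional seed for the bootstrap.
#' @return Object of class `cox_fit`: list with `coefficients`,
#'   `hazard_ratios`, `ci_lower`, `ci_upper` (on the HR scale), `ci_type`,
#'   `p_values` (Wald), `loglik` (maximised log partial likelihood),
#'   `loglik_null`, `n`, `n_events`, `tie_method`, and the underlying
#'   [survival::coxph()] fit in `$fit`.
#' @export
fit_cox <- function(x, times, events, tie_method = c("efron", "breslow"),
                    boot_ci = FALSE, B = 1000, level = 0.95, seed = NULL) {
  tie_method <- match.arg(tie_method)
  x <- as.data.frame(x)
  check_surv(times, events)
  if (sum(events) < 1) stop("need at least one event", call. = FALSE)
  if (nrow(x) != length(times))
    stop("covariate rows must match times", call. = FALSE)
  if (nrow(x) <= ncol(x))
    stop("need more observations than covariates", call. = FALSE)
  const <- vapply(x, function(v) diff(range(v, na.rm = TRUE)) == 0, logical(1))
  if (any(const))
    stop("degeneracy error: constant covariate(s): ",
         paste(names(x)[const], collapse = ", "), call. = FALSE)
  dat <- cbind(x, .time = times, .event = events)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(x)), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = tie_method),
    warning = function(w) {
      if (grepl("infinite|out of range|did not converge|beta may be infinite",
                conditionMessage(w)))
        stop("non-convergence: monotone partial likelihood (perfect ",
             "separation?): ", conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (any(!is.finite(coef(fit))) || any(abs(coef(fit)) > 15))
    stop("non-convergence: monotone partial likelihood (coefficient ",
         "diverged)", call. = FALSE)
  beta <- coef(fit)
  se <- sqrt(diag(fit$var))
  zq <- qnorm(1 - (1 - level) / 2)
  out <- list(coefficients = beta,
              hazard_ratios = exp(beta),
              ci_lower = exp(beta - zq * se),
              ci_upper = exp(beta + zq * se),
              ci_type = "wald",
              se = se,
              p_values = 2 * stats::pnorm(-abs(beta / se)),
              loglik = fit$loglik[2L],
              loglik_null = fit$loglik[1L],
              n = nrow(x), n_events = sum(events),
              tie_method = tie_method, fit = fit)
  class(out) <- "cox_fit"
  if (boot_ci) {
    # lenient refit: resamples with monotone likelihood contribute extreme
    # but finite HRs to the tails, which the percentile interval trims
    ci <- bootstrap_ci(
      statistic = function(d) {
        f <- suppressWarnings(
          survival::coxph(fml, data = d, ties = tie_method))
        exp(coef(f))
      },
      data = dat, B = B, level = level, seed = seed)
    out$ci_lower <- ci[, "lower"]
    out$ci_upper <- ci[, "upper"]
    out$ci_type <- sprintf("bootstrap percentile (B=%d)", B)
  }
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): %d subjects, %d events\n",
              x$tie_method, x$n, x$n_events))
  print(data.frame(HR = round(x$hazard_ratios, 3),
                   lower = round(x$ci_lower, 3),
                   upper = round(x$ci_upper, 3),
                   p = signif(x$p_values, 2)))
  cat(sprintf("CI type: %s; log partial likelihood %.3f\n", x$ci_type, x$loglik))
  invisible(x)
}

#' Percentile bootstrap confidence interval over patient resamples
#'
#' Resamples rows of `data` with replacement `B` times (keeping each
#' patient's time, event and covariates together), evaluates `statistic` on
#' each resample and returns percentile intervals. Resamples on which the
#' statistic fails are skipped; more than 10% failures is an error.
#'
#' @param statistic Function of a data frame returning a numeric (possibly
#'   named) vector.
#' @param data Data frame of patient rows.
#' @param B Number of resamples (>= 2; default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed; fixed seeds give bit-reproducible
#'   intervals.
#' @return Matrix with one row per statistic component and columns `lower`,
#'   `upper`.
#' @export
bootstrap_ci <- function(statistic, data, B = 1000, level = 0.95,
                         seed = NULL) {
  if (B < 2) stop("B must be at least 2", call. = FALSE)
  data <- as.data.frame(data)
  n <- nrow(data)
  if (!is.null(seed)) set.seed(seed)
  draws <- vector("list", B)
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    val <- try(statistic(data[idx, , drop = FALSE]), silent = TRUE)
    if (inherits(val, "try-error") || any(!is.finite(val))) {
      failed <- failed + 1L
    } else {
      draws[[b]] <- val
    }
  }
  if (failed > 0.1 * B)
    stop(sprintf("bootstrap error: statistic failed on %d of %d resamples",
                 failed, B), call. = FALSE)
  mat <- do.call(rbind, draws[!vapply(draws, is.null, logical(1))])
  alpha <- (1 - level) / 2
  ci <- t(apply(mat, 2L, quantile, probs = c(alpha, 1 - alpha), names = FALSE))
  colnames(ci) <- c("lower", "upper")
  ci
}

#' Forward stepwise Cox model selection by BIC
#'
#' Starting from the empty model, each step adds the candidate covariate
#' that most lowers `BIC = -2 logPL + k log(d)`, where `logPL` is the
#' maximised Cox log partial likelihood, `k` the number of covariates and
#' `d` the number of events (the effective sample size of the partial
#' likelihood). Selection stops when no addition lowers the BIC. Ties are
#' broken by candidate input order; candidates whose fit fails (e.g.
#' degenerate after an earlier addition) are skipped with a warning.
#'
#' @param candidates Data frame of candidate covariates (pre-dichotomized
#'   where the analysis scenario requires it).
#' @param times,events Follow-up times and 0/1 event indicators.
#' @param tie_method Passed to [fit_cox()].
#' @return Object of class `selected_model`: list with `selected` (ordered
#'   covariate names; may be empty), `bic_trajectory` (BIC of the null model
#'   followed by each accepted step; strictly decreasing), `fit` (final
#'   `cox_fit`, or `NULL` for the empty model) and `c_statistic` (Harrell's
#'   C of the final linear predictor; 0.5 for the empty model).
#' @export
stepwise_bic <- function(candidates, times, events,
                         tie_method = c("efron", "breslow")) {
  tie_method <- match.arg(tie_method)
  candidates <- as.data.frame(candidates)
  if (ncol(candidates) < 1L)
    stop("need at least one candidate covariate", call. = FALSE)
  check_surv(times, events)
  d <- sum(events)
  if (d < 1) stop("need at least one event", call. = FALSE)
  # null model: log partial likelihood of the empty risk-score model, k = 0
  null_fit <- survival::coxph(survival::Surv(times, events) ~ 1,
                              ties = tie_method)
  bic <- -2 * null_fit$loglik[1L]
  trajectory <- bic
  selected <- character(0)
  remaining <- names(candidates)
  best_fit <- NULL
  repeat {
    step_bics <- rep(NA_real_, length(remaining))
    step_fits <- vector("list", length(remaining))
    for (j in seq_along(remaining)) {
      cols <- c(selected, remaining[j])
      f <- try(fit_cox(candidates[, cols, drop = FALSE], times, events,
                       tie_method = tie_method), silent = TRUE)
      if (inherits(f, "try-error")) {
        warning(sprintf("candidate '%s' skipped: %s", remaining[j],
                        attr(f, "condition")$message), call. = FALSE)
        next
      }
      step_bics[j] <- -2 * f$loglik + length(cols) * log(d)
      step_fits[[j]] <- f
    }
    if (all(is.na(step_bics))) break
    j_best <- which.min(step_bics)  # ties resolved to the earliest candidate
    if (step_bics[j_best] >= bic) break
    bic <- step_bics[j_best]
    trajectory <- c(trajectory, bic)
    best_fit <- step_fits[[j_best]]
    selected <- c(selected, remaining[j_best])
    remaining <- remaining[-j_best]
    if (!length(remaining)) break
  }
  cstat <- if (is.null(best_fit)) 0.5 else {
    lp <- as.numeric(as.matrix(candidates[, selected, drop = FALSE]) %*%
                     best_fit$coefficients)
    harrell_c(lp, times, events)
  }
  structure(list(selected = selected, bic_trajectory = trajectory,
                 fit = best_fit, c_statistic = cstat),
            class = "selected_model")
}

#' @export
print.selected_model <- function(x, ...) {
  if (!length(x$selected)) {
    cat("Stepwise BIC selection: empty model (no candidate lowered BIC)\n")
  } else {
    cat("Stepwise BIC selection:", paste(x$selected, collapse = " + "), "\n")
    cat("BIC trajectory:", paste(sprintf("%.2f", x$bic_trajectory),
                                 collapse = " -> "), "\n")
    cat(sprintf("Harrell's C of final linear predictor: %.3f\n", x$c_statistic))
  }
  invisible(x)
}

#' Harrell's concordance index for censored survival data
#'
#' Over all usable pairs (the pair member with the shorter follow-up time
#' experienced the event; pairs with equal times or censored-before-event
#' ordering are unusable), counts the fraction in which the shorter-lived
#' subject carries the higher predicted risk; tied risks score 0.5.
#'
#' @param risk Numeric risk scores (higher = predicted shorter survival).
#' @param times,events Follow-up times and 0/1 event indicators.
#' @return Concordance in \[0, 1\].
#' @export
#' @examples
#' harrell_c(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1))
harrell_c <- function(risk, times, events) {
  check_surv(times, events)
  if (length(risk) != length(times))
    stop("risk scores must match times in length", call. = FALSE)
  if (any(!is.finite(risk)))
    stop("risk scores must be finite", call. = FALSE)
  ev <- which(events == 1)
  conc <- ties <- npairs <- 0
  for (i in ev) {
    later <- times > times[i]
    npairs <- npairs + sum(later)
    conc <- conc + sum(risk[i] > risk[later])
    ties <- ties + sum(risk[i] == risk[later])
  }
  if (npairs == 0)
    stop("undefined concordance: no usable pairs", call. = FALSE)
  (conc + 0.5 * ties) / npairs
}

#' Descriptive group comparison with normality-based test routing
#'
#' Compares every covariate between two groups (by default patients with
#' and without death within the first year of follow-up). Continuous
#' variables are tested for normality in each group with the Shapiro-Wilk
#' test at alpha = 0.05: if both groups are compatible with normality the
#' groups are compared with the unpaired Student t-test and summarised as
#' mean +/- SD, otherwise with the Mann-Whitney U test and summarised as
#' median (IQR). Binary variables are summarised as counts (%) and compared
#' with Fisher's exact test (two-sided). Variables with fewer than 3
#' observations in a group are skipped with a warning.
#'
#' @param cohort Data frame with covariates plus `follow_up_years` and
#'   `event` (used to build the default grouping).
#' @param group Optional logical/0-1 vector overriding the default 1-year
#'   mortality grouping (`event == 1 & follow_up_years <= 1`).
#' @param variables Optional character vector of columns to compare;
#'   defaults to all numeric columns except follow-up and event.
#' @return Data frame with one row per variable: `variable`, `type`
#'   (`continuous`/`binary`), group summaries, `test` and `p_value`.
#' @export
compare_descriptives <- function(cohort, group = NULL, variables = NULL) {
  cohort <- as.data.frame(cohort)
  if (is.null(group)) {
    if (!all(c("follow_up_years", "event") %in% names(cohort)))
      stop("cohort must contain follow_up_years and event (or supply `group`)",
           call. = FALSE)
    group <- cohort$event == 1 & cohort$follow_up_years <= 1.0
  }
  group <- as.logical(group)
  if (is.null(variables))
    variables <- setdiff(names(cohort)[vapply(cohort, is.numeric, logical(1))],
                         c("follow_up_years", "event"))
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    x0 <- x[!group & !is.na(x)]; x1 <- x[group & !is.na(x)]
    if (length(x0) < 3L || length(x1) < 3L) {
      warning(sprintf("variable '%s' skipped: a group has < 3 observations", v),
              call. = FALSE)
      return(NULL)
    }
    if (all(x %in% c(0, 1, NA))) {
      tab <- rbind(c(sum(x0 == 1), sum(x0 == 0)),
                   c(sum(x1 == 1), sum(x1 == 0)))
      p <- fisher.test(tab, alternative = "two.sided")$p.value
      data.frame(variable = v, type = "binary",
                 group0 = sprintf("%d (%.0f%%)", sum(x0 == 1),
                                  100 * mean(x0 == 1)),
                 group1 = sprintf("%d (%.0f%%)", sum(x1 == 1),
                                  100 * mean(x1 == 1)),
                 test = "fisher", p_value = p)
    } else {
      sw <- function(z) {  # Shapiro-Wilk defined for 3..5000 obs
        z <- z[seq_len(min(length(z), 5000L))]
        if (diff(range(z)) == 0) return(0)
        shapiro.test(z)$p.value
      }
      normal <- sw(x0) > 0.05 && sw(x1) > 0.05
      if (normal) {
        p <- t.test(x0, x1)$p.value
        fmt <- function(z) sprintf("%.1f +/- %.1f", mean(z), sd(z))
        test <- "t"
      } else {
        p <- suppressWarnings(wilcox.test(x0, x1, exact = FALSE)$p.value)
        fmt <- function(z) sprintf("%.1f (%.1f-%.1f)", median(z),
                                   quantile(z, 0.25), quantile(z, 0.75))
        test <- "mann-whitney"
      }
      data.frame(variable = v, type = "continuous", group0 = fmt(x0),
                 group1 = fmt(x1), test = test, p_value = p)
    }
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
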