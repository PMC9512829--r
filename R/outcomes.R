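#' Kaplan-Meier estimate for one group of subjects
#'
#' Product-limit estimator with a log-log transformed confidence interval.
#' The median is the earliest time at which the survival curve drops to
#' 0.5 or below; when the curve never reaches 0.5 (e.g. heavy censoring)
#' the median is not estimable and reported as `NA`.
#'
#' @param data Tibble with one row per subject.
#' @param time,event Column names (strings) holding the follow-up time
#'   (months) and the event indicator (1 = progressed/died, 0 = censored).
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `hrd_km`: the step function as a tibble
#'   (`$steps`), the `$median` with its CI, and the underlying
#'   [survival::survfit] fit.
#' @export
km_estimate <- function(data, time = "time", event = "event",
                        conf_level = 0.95) {
  if (nrow(data) == 0) stop("no subjects", call. = FALSE)
  fit <- survival::survfit(
    survival::Surv(data[[time]], data[[event]]) ~ 1,
    conf.type = "log-log", conf.int = conf_level
  )
  s <- summary(fit)
  steps <- tibble::tibble(
    time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    surv = s$surv, conf_low = s$lower, conf_high = s$upper
  )
  q <- stats::quantile(fit, probs = 0.5)
  structure(
    list(
      steps = steps,
      median = unname(q$quantile),
      median_low = unname(q$lower),
      median_high = unname(q$upper),
      n = fit$n, n_events = sum(fit$n.event),
      fit = fit
    ),
    class = "hrd_km"
  )
}

#' @export
print.hrd_km <- function(x, ...) {
  cat(sprintf(
    "Kaplan-Meier: n = %d, events = %d, median = %s (%s-%s)\n",
    x$n, x$n_events,
    ifelse(is.na(x$median), "NE", format(x$median)),
    ifelse(is.na(x$median_low), "NE", format(x$median_low)),
    ifelse(is.na(x$median_high), "NE", format(x$median_high))
  ))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square comparing the survival of two
#' groups.
#'
#' @param data Tibble with one row per subject.
#' @param group Column name (string) with exactly two levels.
#' @param time,event Column names as in [km_estimate()].
#' @return A tibble: `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(data, group, time = "time", event = "event") {
  g <- factor(data[[group]])
  if (nlevels(g) != 2) stop("log-rank test expects exactly two groups", call. = FALSE)
  sd <- survival::survdiff(
    survival::Surv(data[[time]], data[[event]]) ~ g
  )
  tibble::tibble(
    statistic = sd$chisq, df = 1,
    p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  )
}

#' Cox proportional-hazards fit with the trial covariate set
#'
#' Partial-likelihood fit with Efron handling of tied event times (times
#' at month resolution tie often). Hazard ratios are `exp(coef)` with
#' Wald confidence intervals. A fit with fewer than 10 events per model
#' term warns (estimates become unstable); monotone-likelihood
#' (separation) and non-convergence raise errors.
#'
#' @param data Tibble with one row per subject.
#' @param terms Character vector of covariate column names.
#' @param time,event Column names as in [km_estimate()].
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `hrd_cox` wrapping the
#'   [survival::coxph] fit; use [tidy()] for the per-term hazard ratios.
#' @export
cox_fit <- function(data, terms, time = "time", event = "event",
                    conf_level = 0.95) {
  stopifnot(length(terms) >= 1)
  fml <- stats::as.formula(
    paste0(
      "survival::Surv(", time, ", ", event, ") ~ ",
      paste(terms, collapse = " + ")
    ),
    env = environment()
  )
  n_events <- sum(data[[event]])
  if (n_events < 10 * length(terms)) {
    warning(
      "only ", n_events, " events for ", length(terms),
      " model term(s); hazard-ratio estimates may be unstable",
      call. = FALSE
    )
  }
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|Loglik converged", conditionMessage(w))) {
        stop("Cox fit failed: ", conditionMessage(w), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    }
  )
  if (any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) {
    stop("Cox fit failed: separation detected (diverging coefficient)",
      call. = FALSE
    )
  }
  structure(
    list(fit = fit, terms = terms, conf_level = conf_level, n_events = n_events),
    class = "hrd_cox"
  )
}

#' @export
print.hrd_cox <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}

#' Objective response rate with exact confidence interval
#'
#' Proportion of evaluable subjects with a complete or partial response;
#' `not_evaluable` subjects are excluded from the denominator. The CI is
#' the exact Clopper-Pearson interval. Optionally stratified by a
#' grouping column (e.g. an assay's HRD/HRP label).
#'
#' @param data Tibble with a `response` column (levels `complete`,
#'   `partial`, `stable`, `progression`, `not_evaluable`).
#' @param by Optional column name to stratify by.
#' @param conf_level Confidence level, default 0.95.
#' @return A tibble per stratum: `n_evaluable`, `n_responders`,
#'   `rate_pct`, `conf_low_pct`, `conf_high_pct`, `complete_pct`,
#'   `partial_pct`.
#' @export
response_rate <- function(data, by = NULL, conf_level = 0.95) {
  one <- function(d) {
    ev <- d[d$response != "not_evaluable", , drop = FALSE]
    n <- nrow(ev)
    x <- sum(ev$response %in% c("complete", "partial"))
    ci <- if (n > 0) clopper_pearson(x, n, conf_level) else c(lower = NA, upper = NA)
    tibble::tibble(
      n_evaluable = n, n_responders = x,
      rate_pct = 100 * x / n,
      conf_low_pct = 100 * ci[["lower"]], conf_high_pct = 100 * ci[["upper"]],
      complete_pct = 100 * sum(ev$response == "complete") / n,
      partial_pct = 100 * sum(ev$response == "partial") / n
    )
  }
  if (is.null(by)) {
    return(one(data))
  }
  data |>
    dplyr::group_by(.data[[by]]) |>
    dplyr::group_modify(function(d, key) one(d)) |>
    dplyr::ungroup()
}
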