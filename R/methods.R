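#' Tidy a concordance report into one row per statistic
#'
#' @param x A `concordance_report`.
#' @param ... Unused.
#' @return A tibble: `statistic`, `estimate`, `conf_low`, `conf_high`.
#' @export
tidy.concordance_report <- function(x, ...) {
  tibble::tibble(
    statistic = c("agreement_rate", "kappa", "sensitivity", "specificity"),
    estimate = c(
      x$agreement$estimate, x$kappa$kappa,
      x$sens_spec$estimate[1], x$sens_spec$estimate[2]
    ),
    conf_low = c(
      x$agreement$conf_low, x$kappa$conf_low,
      x$sens_spec$conf_low[1], x$sens_spec$conf_low[2]
    ),
    conf_high = c(
      x$agreement$conf_high, x$kappa$conf_high,
      x$sens_spec$conf_high[1], x$sens_spec$conf_high[2]
    )
  )
}

#' One-row summary of a concordance report
#'
#' @param x A `concordance_report`.
#' @param ... Unused.
#' @return A one-row tibble with the cell counts and headline statistics.
#' @export
glance.concordance_report <- function(x, ...) {
  tibble::tibble(
    n = x$table$n, n_excluded_missing = x$table$n_excluded_missing,
    a = x$table$a, b = x$table$b, c = x$table$c, d = x$table$d,
    agreement_rate = x$agreement$estimate,
    kappa = x$kappa$kappa, kappa_band = x$kappa$band,
    sensitivity = x$sens_spec$estimate[1],
    specificity = x$sens_spec$estimate[2]
  )
}

#' Tidy a Cox fit into one row per term
#'
#' @param x An `hrd_cox` from [cox_fit()].
#' @param ... Unused.
#' @return A tibble: `term`, `hr`, `conf_low`, `conf_high`, `p_value`,
#'   `log_hr`, `se`.
#' @export
tidy.hrd_cox <- function(x, ...) {
  s <- summary(x$fit, conf.int = x$conf_level)
  co <- s$coefficients
  ci <- s$conf.int
  tibble::tibble(
    term = rownames(co),
    hr = unname(co[, "exp(coef)"]),
    conf_low = unname(ci[, 3]),
    conf_high = unname(ci[, 4]),
    p_value = unname(co[, "Pr(>|z|)"]),
    log_hr = unname(co[, "coef"]),
    se = unname(co[, "se(coef)"])
  )
}

#' One-row summary of a Cox fit
#'
#' @param x An `hrd_cox`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `n_events`, `concordance`,
#'   `likelihood_ratio`, `p_value_lr`.
#' @export
glance.hrd_cox <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    n = s$n, n_events = x$n_events,
    concordance = unname(s$concordance[1]),
    likelihood_ratio = unname(s$logtest["test"]),
    p_value_lr = unname(s$logtest["pvalue"])
  )
}

#' Tidy a Kaplan-Meier estimate into its step table
#'
#' @param x An `hrd_km` from [km_estimate()].
#' @param ... Unused.
#' @return The step tibble: `time`, `n_risk`, `n_event`, `surv`,
#'   `conf_low`, `conf_high`.
#' @export
tidy.hrd_km <- function(x, ...) x$steps

#' One-row summary of a Kaplan-Meier estimate
#'
#' @param x An `hrd_km`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `n_events`, `median`, `median_low`,
#'   `median_high`.
#' @export
glance.hrd_km <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events, median = x$median,
    median_low = x$median_low, median_high = x$median_high
  )
}

#' Plot a shallow-WGS segmentation
#'
#' Draws the per-segment mean log2 ratios as horizontal bars along the
#' genome, faceted by chromosome.
#'
#' @param object An `hrd_segmentation` from [segment_bins()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hrd_segmentation <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$start / 1e6, xend = .data$end / 1e6,
      y = .data$mean_log2, yend = .data$mean_log2
    ), linewidth = 1.1, colour = "#2166ac") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(
      x = "position (Mb)", y = "mean log2 ratio",
      title = paste0(
        "Segmentation at ", attr(object, "window_kb"), " kb windows"
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a Kaplan-Meier curve
#'
#' @param object An `hrd_km` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hrd_km <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(
      time = 0, surv = 1, conf_low = 1, conf_high = 1
    ),
    object$steps[, c("time", "surv", "conf_low", "conf_high")]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::geom_step(ggplot2::aes(y = .data$conf_low),
      linetype = "dashed", alpha = 0.6
    ) +
    ggplot2::geom_step(ggplot2::aes(y = .data$conf_high),
      linetype = "dashed", alpha = 0.6
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Plot an allele-specific segment profile
#'
#' Total and minor copy number along the genome, faceted by chromosome.
#'
#' @param profile A `segment_profile` (single sample).
#' @return A ggplot object.
#' @export
plot_profile <- function(profile) {
  df <- tibble::as_tibble(profile) |>
    tidyr::pivot_longer(c("total_cn", "minor_cn"),
      names_to = "allele", values_to = "cn"
    )
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$start / 1e6, xend = .data$end / 1e6,
      y = .data$cn, yend = .data$cn, colour = .data$allele
    ), linewidth = 1) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "copy number") +
    ggplot2::theme_minimal()
}
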