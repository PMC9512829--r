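#' Construct a 2x2 contingency table of assay calls
#'
#' @param a Index HRD and reference HRD count.
#' @param b Index HRD and reference HRP count.
#' @param c Index HRP and reference HRD count.
#' @param d Index HRP and reference HRP count.
#' @param n_excluded_missing Pairs excluded because either call was
#'   missing or inconclusive.
#' @return An object of class `contingency_2x2`.
#' @export
contingency_table <- function(a, b, c, d, n_excluded_missing = 0L) {
  # note: `c` is an argument here, so base::c must not be called unqualified
  if (a < 0 || b < 0 || c < 0 || d < 0) {
    stop("cell counts must be non-negative", call. = FALSE)
  }
  structure(
    list(
      a = a, b = b, c = c, d = d, n = a + b + c + d,
      n_excluded_missing = as.integer(n_excluded_missing)
    ),
    class = "contingency_2x2"
  )
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d),
    nrow = 2,
    dimnames = list(index = c("HRD", "HRP"), reference = c("HRD", "HRP"))
  )
  cat("2x2 assay contingency table (complete cases, n = ", x$n, ")\n", sep = "")
  print(m)
  cat("excluded as missing:", x$n_excluded_missing, "\n")
  invisible(x)
}

#' Cross-tabulate an index assay against a reference assay
#'
#' Pairs where either assay is `Missing` (or any label other than
#' `HRD`/`HRP`) are excluded and counted in `n_excluded_missing`; the
#' remaining complete cases fill the 2x2 table.
#'
#' @param index_calls,ref_calls Call tibbles with columns `sample`,
#'   `label`; only samples present in both are considered.
#' @return A `contingency_2x2`.
#' @export
build_contingency <- function(index_calls, ref_calls) {
  m <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(index_calls), "sample", index = "label"),
    dplyr::select(tibble::as_tibble(ref_calls), "sample", ref = "label"),
    by = "sample"
  )
  if (nrow(m) == 0) stop("no shared samples between the two call sets", call. = FALSE)
  complete <- m$index %in% c("HRD", "HRP") & m$ref %in% c("HRD", "HRP")
  cc <- m[complete, ]
  if (nrow(cc) == 0) stop("no complete-case pairs", call. = FALSE)
  contingency_table(
    a = sum(cc$index == "HRD" & cc$ref == "HRD"),
    b = sum(cc$index == "HRD" & cc$ref == "HRP"),
    c = sum(cc$index == "HRP" & cc$ref == "HRD"),
    d = sum(cc$index == "HRP" & cc$ref == "HRP"),
    n_excluded_missing = sum(!complete)
  )
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Computed through the beta-quantile equivalence; the lower bound is 0
#' when `x = 0` and the upper bound 1 when `x = n`.
#'
#' @param x Number of successes, `0 <= x <= n`.
#' @param n Number of trials, `>= 1`.
#' @param conf_level Confidence level, default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' clopper_pearson(53, 54) # approx (0.901, 1.000)
#' @export
clopper_pearson <- function(x, n, conf_level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  alpha <- 1 - conf_level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Overall agreement rate of a 2x2 table
#'
#' `(a + d) / n`, with an exact Clopper-Pearson interval.
#'
#' @param t A `contingency_2x2`.
#' @param conf_level Confidence level, default 0.95.
#' @return A tibble with `estimate`, `conf_low`, `conf_high`, `n`.
#' @export
agreement_rate <- function(t, conf_level = 0.95) {
  ci <- clopper_pearson(t$a + t$d, t$n, conf_level)
  tibble::tibble(
    estimate = (t$a + t$d) / t$n,
    conf_low = ci[["lower"]], conf_high = ci[["upper"]], n = t$n
  )
}

kappa_band <- function(k) {
  dplyr::case_when(
    k < 0 ~ "no agreement",
    k <= 0.20 ~ "slight",
    k <= 0.40 ~ "fair",
    k <= 0.60 ~ "moderate",
    k <= 0.80 ~ "substantial",
    TRUE ~ "almost perfect"
  )
}

#' Cohen's kappa for a 2x2 table
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' `p_o = (a + d)/n` and `p_e` from the margins. The standard error is the
#' Fleiss-Cohen-Everitt asymptotic large-sample form, the CI is Wald on
#' that SE, and the interpretation band follows the conventional six
#' intervals (slight, fair, moderate, substantial, almost perfect).
#'
#' @param t A `contingency_2x2`.
#' @param conf_level Confidence level, default 0.95.
#' @return A tibble with `kappa`, `se`, `conf_low`, `conf_high`, `band`.
#' @export
cohens_kappa <- function(t, conf_level = 0.95) {
  n <- t$n
  if (n <= 0) stop("empty table", call. = FALSE)
  p <- matrix(c(t$a, t$c, t$b, t$d), nrow = 2) / n
  row_m <- rowSums(p)
  col_m <- colSums(p)
  p_o <- sum(diag(p))
  p_e <- sum(row_m * col_m)
  if (isTRUE(all.equal(p_e, 1))) {
    stop("kappa undefined: expected agreement is 1 (degenerate margins)",
      call. = FALSE
    )
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  # Fleiss, Cohen & Everitt asymptotic variance
  A <- sum(diag(p) * (1 - (row_m + col_m) * (1 - kappa))^2)
  B <- (1 - kappa)^2 *
    (p[1, 2] * (col_m[1] + row_m[2])^2 + p[2, 1] * (col_m[2] + row_m[1])^2)
  C <- (kappa - p_e * (1 - kappa))^2
  se <- sqrt(pmax(A + B - C, 0) / (n * (1 - p_e)^2))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    kappa = kappa, se = se,
    conf_low = max(-1, kappa - z * se), conf_high = min(1, kappa + z * se),
    band = kappa_band(kappa)
  )
}

#' Sensitivity and specificity against the reference assay
#'
#' Sensitivity `a/(a + c)` and specificity `d/(b + d)`, each with an exact
#' Clopper-Pearson interval.
#'
#' @param t A `contingency_2x2`.
#' @param conf_level Confidence level, default 0.95.
#' @return A two-row tibble: `metric`, `estimate`, `conf_low`,
#'   `conf_high`, `numerator`, `denominator`.
#' @export
sensitivity_specificity <- function(t, conf_level = 0.95) {
  ci_sens <- clopper_pearson(t$a, t$a + t$c, conf_level)
  ci_spec <- clopper_pearson(t$d, t$b + t$d, conf_level)
  tibble::tibble(
    metric = c("sensitivity", "specificity"),
    estimate = c(t$a / (t$a + t$c), t$d / (t$b + t$d)),
    conf_low = c(ci_sens[["lower"]], ci_spec[["lower"]]),
    conf_high = c(ci_sens[["upper"]], ci_spec[["upper"]]),
    numerator = c(t$a, t$d),
    denominator = c(t$a + t$c, t$b + t$d)
  )
}

#' Sample size for a target-width kappa confidence interval
#'
#' Inverts the normal-approximation interval for kappa:
#' `n = ceiling((z * sd / (width / 2))^2)`, where `sd` is the anticipated
#' standard deviation of the kappa estimate for one subject.
#'
#' @param kappa_sd Anticipated per-subject SD of kappa.
#' @param ci_width Total width of the two-sided interval.
#' @param conf_level Confidence level, default 0.95.
#' @return Required number of subjects (integer).
#' @examples
#' kappa_sample_size(0.60, 0.25) # 89
#' @export
kappa_sample_size <- function(kappa_sd, ci_width, conf_level = 0.95) {
  stopifnot(kappa_sd > 0, ci_width > 0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  as.integer(ceiling((z * kappa_sd / (ci_width / 2))^2))
}

#' Partition complete-case samples by the joint call of two assays
#'
#' @param calls_a,calls_b Call tibbles with columns `sample`, `label`.
#' @return A tibble with one row per joint group (`HRD/HRD`, `HRD/HRP`,
#'   `HRP/HRD`, `HRP/HRP`): `group`, `n`, and the sample ids as a
#'   list-column.
#' @export
cross_classify <- function(calls_a, calls_b) {
  m <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(calls_a), "sample", a = "label"),
    dplyr::select(tibble::as_tibble(calls_b), "sample", b = "label"),
    by = "sample"
  )
  if (nrow(m) == 0) stop("no shared samples between the two call sets", call. = FALSE)
  cc <- m[m$a %in% c("HRD", "HRP") & m$b %in% c("HRD", "HRP"), ]
  groups <- tidyr::expand_grid(a = c("HRD", "HRP"), b = c("HRD", "HRP"))
  purrr::pmap(groups, function(a, b) {
    ids <- cc$sample[cc$a == a & cc$b == b]
    tibble::tibble(
      group = paste(a, b, sep = "/"), n = length(ids), samples = list(ids)
    )
  }) |> purrr::list_rbind()
}

#' Full concordance report of an index assay against a reference
#'
#' Bundles [build_contingency()], [agreement_rate()], [cohens_kappa()] and
#' [sensitivity_specificity()] into one object with [tidy()] and
#' [glance()] methods.
#'
#' @param index_calls,ref_calls Call tibbles (`sample`, `label`).
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `concordance_report`.
#' @export
concordance_report <- function(index_calls, ref_calls, conf_level = 0.95) {
  t <- build_contingency(index_calls, ref_calls)
  structure(
    list(
      table = t,
      agreement = agreement_rate(t, conf_level),
      kappa = cohens_kappa(t, conf_level),
      sens_spec = sensitivity_specificity(t, conf_level),
      conf_level = conf_level
    ),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  print(x$table)
  cat(sprintf(
    "agreement %.2f (%.2f-%.2f)  kappa %.2f (%.2f-%.2f, %s)\n",
    x$agreement$estimate, x$agreement$conf_low, x$agreement$conf_high,
    x$kappa$kappa, x$kappa$conf_low, x$kappa$conf_high, x$kappa$band
  ))
  cat(sprintf(
    "sensitivity %.1f%%  specificity %.1f%%\n",
    100 * x$sens_spec$estimate[1], 100 * x$sens_spec$estimate[2]
  ))
  invisible(x)
}
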