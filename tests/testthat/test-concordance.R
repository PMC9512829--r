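test_that("contingency tables are built on complete cases only", {
  fx <- fixture_calls_table2("LAB1")
  t <- build_contingency(fx$index, fx$ref)
  expect_equal(c(t$a, t$b, t$c, t$d), c(53, 6, 1, 32))
  expect_equal(t$n, 92)
  expect_equal(t$n_excluded_missing, 8)

  fx3 <- fixture_calls_table2("LAB3")
  t3 <- build_contingency(fx3$index, fx3$ref)
  expect_equal(c(t3$a, t3$b, t3$c, t3$d), c(34, 16, 7, 8))
  expect_equal(t3$n, 65)

  all_missing <- dplyr::mutate(fx$index, label = "Missing")
  expect_error(build_contingency(all_missing, fx$ref), "complete")
  expect_error(
    build_contingency(
      dplyr::mutate(fx$index, sample = paste0("X", sample)), fx$ref
    ),
    "shared"
  )
})

test_that("agreement rate is (a+d)/n with an exact interval", {
  t <- contingency_table(53, 6, 1, 32)
  ar <- agreement_rate(t)
  expect_equal(ar$estimate, 85 / 92)
  expect_equal(agreement_rate(contingency_table(34, 16, 7, 8))$estimate, 42 / 65)
  perfect <- agreement_rate(contingency_table(10, 0, 0, 7))
  expect_equal(perfect$estimate, 1)
  expect_equal(perfect$conf_high, 1)
})

test_that("Cohen's kappa matches its closed form, bands and invariances", {
  t <- contingency_table(53, 6, 1, 32)
  k <- cohens_kappa(t)
  # closed form from the margins
  p_o <- 85 / 92
  p_e <- (59 * 54 + 33 * 38) / 92^2
  expect_equal(k$kappa, (p_o - p_e) / (1 - p_e))
  expect_equal(k$band, "almost perfect")

  k3 <- cohens_kappa(contingency_table(34, 16, 7, 8))
  expect_equal(round(k3$kappa, 2), 0.18)
  expect_equal(k3$band, "slight")

  # perfect agreement
  expect_equal(cohens_kappa(contingency_table(9, 0, 0, 6))$kappa, 1)

  # independent margins: p_o == p_e -> kappa 0
  expect_equal(cohens_kappa(contingency_table(9, 3, 6, 2))$kappa, 0)

  # rater-swap symmetry (transpose swaps b and c)
  expect_equal(
    cohens_kappa(contingency_table(34, 7, 16, 8))$kappa,
    k3$kappa
  )

  # p_o reconstruction: p_o = kappa (1 - p_e) + p_e exactly
  expect_equal(k$kappa * (1 - p_e) + p_e, p_o)

  # degenerate margins
  expect_error(cohens_kappa(contingency_table(5, 0, 0, 0)), "undefined")
})

test_that("sensitivity and specificity come with Clopper-Pearson intervals", {
  ss <- sensitivity_specificity(contingency_table(53, 6, 1, 32))
  expect_equal(ss$estimate, c(53 / 54, 32 / 38))
  ss2 <- sensitivity_specificity(contingency_table(48, 6, 5, 33))
  expect_equal(ss2$estimate, c(48 / 53, 33 / 39))
  perfect <- sensitivity_specificity(contingency_table(5, 0, 0, 9))
  expect_equal(perfect$estimate, c(1, 1))
})

test_that("Clopper-Pearson interval is exact and always contains x/n", {
  ci <- clopper_pearson(53, 54)
  expect_equal(round(100 * ci[["lower"]], 1), 90.1)
  expect_equal(round(100 * ci[["upper"]], 1), 100) # 99.953 prints as 100%
  ci2 <- clopper_pearson(8, 24)
  expect_equal(round(100 * ci2[["lower"]], 1), 15.6)
  expect_equal(round(100 * ci2[["upper"]], 1), 55.3)
  expect_equal(clopper_pearson(0, 10)[["lower"]], 0)

  set.seed(13)
  for (i in 1:50) {
    n <- sample(1:200, 1)
    x <- sample(0:n, 1)
    ci <- clopper_pearson(x, n)
    expect_lte(ci[["lower"]], x / n)
    expect_gte(ci[["upper"]], x / n)
  }
})

test_that("interval coverage at n=54, p=0.98 reaches the nominal level", {
  set.seed(99)
  p <- 0.98
  xs <- rbinom(2000, 54, p)
  covered <- vapply(xs, function(x) {
    ci <- clopper_pearson(x, 54)
    ci[["lower"]] <= p && p <= ci[["upper"]]
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("kappa-precision sample size inverts the Wald interval width", {
  expect_equal(kappa_sample_size(0.60, 0.25), 89L)
  expect_equal(kappa_sample_size(0.60, 0.50), 23L)
  # halving the sd quarters n before ceiling
  z <- qnorm(0.975)
  expect_equal(
    (z * 0.3 / 0.125)^2,
    (z * 0.6 / 0.125)^2 / 4
  )
})

test_that("cross-classification partitions the joint call groups", {
  myriad <- calls_tbl(c(rep("HRD", 34), rep("HRD", 5), rep("HRP", 6), rep("HRP", 6)))
  rad51 <- calls_tbl(c(rep("HRD", 34), rep("HRP", 5), rep("HRD", 6), rep("HRP", 6)))
  cc <- cross_classify(myriad, rad51)
  expect_equal(cc$group, c("HRD/HRD", "HRD/HRP", "HRP/HRD", "HRP/HRP"))
  expect_equal(cc$n, c(34, 5, 6, 6))

  ident <- cross_classify(myriad, myriad)
  expect_equal(ident$n[ident$group %in% c("HRD/HRP", "HRP/HRD")], c(0, 0))

  expect_error(
    cross_classify(myriad, dplyr::mutate(rad51, sample = paste0("Z", sample))),
    "shared"
  )
})

test_that("the assembled report tidies into one row per statistic", {
  fx <- fixture_calls_table2("LAB1")
  rep <- concordance_report(fx$index, fx$ref)
  td <- tidy(rep)
  expect_equal(td$statistic, c("agreement_rate", "kappa", "sensitivity", "specificity"))
  expect_equal(round(td$estimate, 2), c(0.92, 0.84, 0.98, 0.84))
  g <- glance(rep)
  expect_equal(g$n, 92)
  expect_equal(g$kappa_band, "almost perfect")
})
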