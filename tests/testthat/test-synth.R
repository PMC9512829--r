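build <- grid_build()

test_that("profile generator is deterministic and hits its scar targets", {
  p1 <- gen_profile(c(loh = 5, tai = 4, lst = 7), build, seed = 12)
  p2 <- gen_profile(c(loh = 5, tai = 4, lst = 7), build, seed = 12)
  expect_identical(as.data.frame(p1), as.data.frame(p2))

  sc <- compute_gi_score(p1, build)
  expect_equal(c(sc$loh_count, sc$tai_count, sc$lst_count), c(5, 4, 7))

  p0 <- gen_profile(c(0, 0, 0), build, seed = 1)
  sc0 <- compute_gi_score(p0, build)
  expect_equal(sc0$gi_score, 0L)
  # all-diploid balanced
  expect_true(all(p0$total_cn == 2 & p0$minor_cn == 1))

  expect_error(gen_profile(c(200, 200, 200), build, seed = 1), "infeasible")
})

test_that("generated profiles cover every chromosome without overlap", {
  p <- gen_profile(c(loh = 10, tai = 8, lst = 12), build, seed = 3)
  hrdkit:::validate_profile(p)
  covered <- p |>
    dplyr::group_by(chrom) |>
    dplyr::summarise(bases = sum(end - start))
  expect_equal(
    covered$bases[match(build$chrom, covered$chrom)],
    build$length
  )
})

test_that("coverage simulation tracks the copy profile in expectation", {
  p <- gen_profile(c(0, 0, 0), build, seed = 2)
  cov <- gen_coverage(p, build,
    window_kb = 100, depth_factor = 0.6,
    sigma = 0, seed = 5
  )
  mu <- 10 * 100 * 0.6 # reads_per_kb * window_kb * depth, diploid
  n <- nrow(cov)
  expect_lt(abs(mean(cov$count) - mu) / (sqrt(mu / n)), 2) # within 2 SE

  # sigma -> 0 on a flat profile: near-Poisson dispersion
  expect_lt(abs(var(cov$count) / mean(cov$count) - 1), 0.1)

  # determinism
  cov2 <- gen_coverage(p, build,
    window_kb = 100, depth_factor = 0.6,
    sigma = 0, seed = 5
  )
  expect_identical(cov$count, cov2$count)
})

test_that("cell generator controls the RAD51 positivity fraction", {
  s <- gen_cells(0, 0.5, 80, seed = 1)
  expect_equal(rad51_score(s), 0)
  expect_equal(classify_rad51(rad51_score(s)), "HRD")

  s39 <- gen_cells(0.3, 0.5, 39, seed = 2)
  expect_equal(qc_slide(s39), "fail_few_cells")

  exact <- gen_cells(0.25, 0.6, 80, seed = 3, exact = TRUE)
  expect_equal(rad51_score(exact), 25)
})

test_that("cohort generator reproduces designed concordance structure", {
  # no misclassification, no missingness: kappa 1 between any two assays
  perfect <- gen_cohort(
    n = 150, seed = 7,
    assays = list(
      a = list(sens = 1, spec = 1, miss = 0),
      b = list(sens = 1, spec = 1, miss = 0)
    )
  )
  ca <- perfect$calls[perfect$calls$assay == "a", ]
  cb <- perfect$calls[perfect$calls$assay == "b", ]
  expect_equal(cohens_kappa(build_contingency(ca, cb))$kappa, 1)

  # moment-matching arithmetic: designed rates against a perfect reference
  # reproduce the published LAB1-vs-Myriad table in expectation
  exp_cells <- expected_contingency(
    n = 92, hrd_frac = 54 / 92,
    index = list(sens = 53 / 54, spec = 32 / 38),
    ref = list(sens = 1, spec = 1)
  )
  expect_equal(unname(exp_cells), c(53, 6, 1, 32), tolerance = 1e-12)

  # and a large simulated draw lands near that expectation
  big <- gen_cohort(
    n = 4000, seed = 8, hrd_frac = 54 / 92,
    assays = list(
      lab1 = list(sens = 53 / 54, spec = 32 / 38, miss = 0),
      myriad = list(sens = 1, spec = 1, miss = 0)
    )
  )
  t <- build_contingency(
    big$calls[big$calls$assay == "lab1", ],
    big$calls[big$calls$assay == "myriad", ]
  )
  frac <- c(t$a, t$b, t$c, t$d) / t$n
  expect_equal(frac, c(53, 6, 1, 32) / 92, tolerance = 0.05)
})

test_that("published contingency fixtures are exact and immutable", {
  fx <- fixture_table2()
  expect_equal(
    vapply(fx$LAB1[c("a", "b", "c", "d")], identity, 0),
    c(a = 53, b = 6, c = 1, d = 32)
  )
  expect_equal(fx$LAB1$n + fx$LAB1$n_excluded_missing, 100)
  expect_equal(fx$LAB2$n, 92)
  expect_equal(fx$LAB3$n, 65)
  expect_equal(fx$LAB3$n + fx$LAB3$n_excluded_missing, 100)
  # margins sum to the 100-sample cohort per assay
  sums <- fx$margins |>
    dplyr::group_by(assay) |>
    dplyr::summarise(total = sum(ref_hrd + ref_hrp + ref_missing))
  expect_true(all(sums$total == 100))
  expect_identical(fixture_table2(), fx)
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_cells(0.3, 0.5, 50, seed = 42))
  invisible(gen_cohort(n = 20, seed = 42))
  expect_identical(.Random.seed, before)
})
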