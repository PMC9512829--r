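cfg <- shallow_config()

mk_bins <- function(counts, width = 5000, chrom = "chr1", sample = "S1") {
  hrdkit:::as_coverage_bins(
    tibble::tibble(
      sample = sample, chrom = chrom,
      start = (seq_along(counts) - 1) * width, count = counts
    ),
    width = width
  )
}

test_that("rebin sums counts and drops the trailing partial window", {
  b <- mk_bins(c(1, 2, 3, 4))
  expect_equal(rebin(b, 5)$count, c(1, 2, 3, 4)) # identity
  r <- rebin(b, 10)
  expect_equal(r$count, c(3, 7))
  expect_equal(r$start, c(0, 10000))

  b5 <- mk_bins(c(1, 2, 3, 4, 9))
  expect_equal(rebin(b5, 10)$count, c(3, 7)) # 5th bin dropped
  expect_error(rebin(b, 7), "multiple")
})

test_that("rebinning conserves total count up to the dropped tail", {
  set.seed(1)
  counts <- rpois(1001, 30)
  b <- mk_bins(counts)
  r <- rebin(b, 50) # 10 source bins per window; one source bin dropped
  expect_equal(sum(r$count), sum(counts[1:1000]))
})

test_that("segmentation finds no changepoints in constant signal", {
  b <- mk_bins(rep(100, 200))
  seg <- segment_bins(b, cfg = cfg)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_bins, 200)
})

test_that("single-step signal is located within 2 bins of the exhaustive fit", {
  set.seed(7)
  for (rep in 1:5) {
    x <- c(rnorm(100, 0, 0.05), rnorm(100, 0.58, 0.05))
    # exhaustive single-changepoint least squares
    rss <- vapply(1:199, function(k) {
      sum((x[1:k] - mean(x[1:k]))^2) + sum((x[-(1:k)] - mean(x[-(1:k)]))^2)
    }, numeric(1))
    k_best <- which.min(rss)
    counts <- round(pmax(2 ^ x * 100, 0))
    seg <- segment_bins(mk_bins(counts), cfg = cfg)
    expect_equal(nrow(seg), 2)
    expect_lte(abs(seg$n_bins[1] - k_best), 2)
    expect_lte(abs(seg$n_bins[1] - 100), 2)
  }
})

test_that("pruned segmentation equals exhaustive dynamic programming", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(50:300, 1)
    ncp <- sample(0:3, 1)
    cps <- sort(sample(seq(10, n - 10), ncp))
    mu <- rep(cumsum(c(0, runif(ncp, 0.3, 1))), diff(c(0, cps, n)))
    x <- mu + rnorm(n, 0, 0.1)
    beta <- runif(1, 0.2, 2)
    expect_equal(
      as.integer(hrdkit:::fpop_mean(x, beta)),
      as.integer(oracle_op_segment(x, beta))
    )
  }
})

test_that("LGA predicate needs >=10 Mb flanks and a >=0.2 log2 jump", {
  build <- toy_build(1)
  mk_seg <- function(df) {
    df$n_bins <- as.integer((df$end - df$start) / 5e4)
    structure(df, class = c("hrd_segmentation", class(tibble::tibble())))
  }
  # flat genome
  flat <- mk_seg(tibble::tibble(
    chrom = "chr1", start = 0, end = 95e6, mean_log2 = 0
  ))
  expect_equal(count_lga(flat, build, cfg), 0L)

  # qualifying 12 Mb / 15 Mb junction with a 0.58 jump
  one <- mk_seg(tibble::tibble(
    chrom = "chr1", start = c(0, 12e6), end = c(12e6, 27e6),
    mean_log2 = c(0, 0.58)
  ))
  expect_equal(count_lga(one, build, cfg), 1L)

  # jump below the gap threshold
  small <- mk_seg(tibble::tibble(
    chrom = "chr1", start = c(0, 12e6), end = c(12e6, 27e6),
    mean_log2 = c(0, 0.1)
  ))
  expect_equal(count_lga(small, build, cfg), 0L)

  # short flank
  short <- mk_seg(tibble::tibble(
    chrom = "chr1", start = c(0, 8e6), end = c(8e6, 27e6),
    mean_log2 = c(0, 0.58)
  ))
  expect_equal(count_lga(short, build, cfg), 0L)
})

test_that("consensus needs 4 of 6 agreeing models", {
  expect_equal(
    hrdkit:::consensus_from_labels(rep("HRD", 6), 4),
    list(label = "HRD", agreement = 1)
  )
  four_two <- hrdkit:::consensus_from_labels(c(rep("HRD", 4), rep("HRP", 2)), 4)
  expect_equal(four_two$label, "HRD")
  expect_equal(four_two$agreement, 4 / 6, tolerance = 1e-12)
  split33 <- hrdkit:::consensus_from_labels(c(rep("HRD", 3), rep("HRP", 3)), 4)
  expect_equal(split33$label, "Inconclusive")
})

test_that("segmentation is scale invariant and deterministic", {
  build <- grid_build()
  p <- gen_lga_profile(8, build, seed = 5)
  cov <- gen_coverage(p, build, window_kb = 100, sigma = 0.05, seed = 9)
  s1 <- segment_bins(cov, cfg = cfg)
  s2 <- segment_bins(cov, cfg = cfg)
  expect_identical(s1$start, s2$start) # determinism

  cov4 <- cov
  cov4$count <- cov4$count * 4
  cov4 <- hrdkit:::as_coverage_bins(tibble::as_tibble(cov4), width = 100e3)
  s4 <- segment_bins(cov4, cfg = cfg)
  expect_equal(s4$start, s1$start, tolerance = 0)
  expect_equal(count_lga(s4, build, cfg), count_lga(s1, build, cfg))
})

test_that("ground-truth LGA counts are recovered through the full pipeline", {
  build <- grid_build()
  for (g in c(0, 12)) {
    p <- gen_lga_profile(g, build, seed = 21 + g)
    cov <- gen_coverage(p, build, window_kb = 50, sigma = 0.05, seed = 22 + g)
    seg <- segment_bins(cov, cfg = cfg)
    expect_equal(count_lga(seg, build, cfg), g)
  }
})

test_that("ensemble call honors the coverage floor and the cutoff", {
  build <- grid_build()
  p <- gen_lga_profile(25, build, seed = 31)
  cov <- gen_coverage(p, build, window_kb = 100, sigma = 0.05, seed = 32)
  res <- classify_lab2(cov, build, shallow_config(
    window_sizes_kb = c(100, 200, 300, 400, 500, 1000)
  ))
  expect_equal(res$label, "HRD")
  expect_equal(res$agreement, 1)
  expect_true(all(res$models[[1]]$lga_count == 25))

  # starving the genome of bins triggers the insufficient-coverage failure
  few <- cov[cov$chrom == "chr1", ]
  few <- hrdkit:::as_coverage_bins(tibble::as_tibble(few), width = 100e3)
  starved <- classify_lab2(few, build, cfg)
  expect_equal(starved$label, "Inconclusive")
  expect_equal(starved$failure_reason, "insufficient coverage")
})

test_that("LGA cutoff calibration maximizes Youden's J with the tie rule", {
  set.seed(2)
  counts <- c(sample(0:5, 15, TRUE), 25, sample(25:40, 14, TRUE))
  labels <- rep(c("HRP", "HRD"), each = 15)
  cal <- calibrate_lga_cutoff(counts, labels)
  expect_equal(cal$cutoff, 25L) # highest threshold among perfect separators
  expect_equal(cal$youden_j, 1)

  set.seed(3)
  hrp <- rpois(30, 6)
  hrd <- rpois(30, 20)
  cal2 <- calibrate_lga_cutoff(c(hrp, hrd), rep(c("HRP", "HRD"), each = 30))
  # exhaustive reference scan
  js <- vapply(0:60, function(t) mean(hrd >= t) + mean(hrp < t) - 1, numeric(1))
  expect_equal(cal2$youden_j, max(js))

  same <- rep(c(2, 9, 4), 10)
  expect_warning(
    cal3 <- calibrate_lga_cutoff(c(same, same), rep(c("HRP", "HRD"), each = 30)),
    "not separable"
  )
  expect_equal(cal3$youden_j, 0)

  expect_error(calibrate_lga_cutoff(1:20, rep("HRD", 20)), "per group")
})
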