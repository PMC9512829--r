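build <- toy_build() # 200 Mb chromosomes, centromere 95-105 Mb
cfg <- scar_config()

test_that("LOH runs are counted above 15 Mb, excluding whole chromosomes", {
  # heterozygous genome: no LOH
  p <- fill_diploid(prof(), build)
  expect_equal(unname(compute_loh_score(p, build, cfg)), 0L)

  # one 20 Mb and one 16 Mb run on chr1, chr2 entirely LOH
  p <- fill_diploid(
    prof(
      list("chr1", 10e6, 30e6, 2, 0),
      list("chr1", 60e6, 76e6, 2, 0),
      list("chr2", 0, 200e6, 2, 0)
    ),
    build
  )
  expect_equal(unname(compute_loh_score(p, build, cfg)), 2L)

  # exactly 15 Mb does not qualify (strictly greater required)
  p <- fill_diploid(prof(list("chr1", 10e6, 25e6, 2, 0)), build)
  expect_equal(unname(compute_loh_score(p, build, cfg)), 0L)

  # abutting same-state segments merge into one run
  p <- fill_diploid(
    prof(list("chr1", 10e6, 20e6, 2, 0), list("chr1", 20e6, 30e6, 2, 0)),
    build
  )
  expect_equal(unname(compute_loh_score(p, build, cfg)), 1L)
})

test_that("TAI requires telomere contact, centromere avoidance and >11 Mb", {
  # balanced diploid: nothing
  p <- fill_diploid(prof(), build)
  expect_equal(unname(compute_tai_score(p, build, cfg)), 0L)

  # 20 Mb AI abutting the p-telomere, clear of the centromere
  p <- fill_diploid(prof(list("chr1", 0, 20e6, 3, 1)), build)
  expect_equal(unname(compute_tai_score(p, build, cfg)), 1L)

  # the same run extended across the centromere no longer counts
  p <- fill_diploid(prof(list("chr1", 0, 120e6, 3, 1)), build)
  expect_equal(unname(compute_tai_score(p, build, cfg)), 0L)

  # 15 Mb runs at both telomeres of one chromosome
  p <- fill_diploid(
    prof(list("chr1", 0, 15e6, 3, 1), list("chr1", 185e6, 200e6, 3, 1)),
    build
  )
  expect_equal(unname(compute_tai_score(p, build, cfg)), 2L)

  # interior AI run never counts
  p <- fill_diploid(prof(list("chr1", 30e6, 60e6, 3, 1)), build)
  expect_equal(unname(compute_tai_score(p, build, cfg)), 0L)

  # 11 Mb exactly is not enough
  p <- fill_diploid(prof(list("chr1", 0, 11e6, 3, 1)), build)
  expect_equal(unname(compute_tai_score(p, build, cfg)), 0L)

  # missing centromere annotation is an error
  b2 <- build
  b2$cen_start[1] <- NA
  expect_error(compute_tai_score(p, b2, cfg), "centromere")
})

test_that("LST counts >=10 Mb junctions per arm after 3 Mb smoothing", {
  # single state genome
  p <- fill_diploid(prof(), build)
  expect_equal(unname(compute_lst_score(p, build, cfg)), 0L)

  # 12 Mb state-A next to 15 Mb state-B alone on the p arm: one junction
  p <- prof(list("chr1", 40e6, 52e6, 3, 1), list("chr1", 52e6, 67e6, 4, 1))
  expect_equal(unname(compute_lst_score(p, build, cfg)), 1L)

  # inserting a 2 Mb sliver between them changes nothing (smoothed away)
  p <- prof(
    list("chr1", 40e6, 52e6, 3, 1),
    list("chr1", 52e6, 54e6, 2, 0),
    list("chr1", 54e6, 69e6, 4, 1)
  )
  expect_equal(unname(compute_lst_score(p, build, cfg)), 1L)

  # embedded in a fully covered diploid chromosome the two outer
  # junctions to the long diploid flanks count as well
  p <- fill_diploid(
    prof(list("chr1", 40e6, 52e6, 3, 1), list("chr1", 52e6, 67e6, 4, 1)),
    build
  )
  expect_equal(unname(compute_lst_score(p, build, cfg)), 3L)

  # a junction straddling the centromere is not counted
  p <- fill_diploid(prof(list("chr1", 0, 100e6, 3, 1)), build)
  # junction at 100 Mb sits inside the centromere (95-105): arms are
  # evaluated separately, so no LST
  expect_equal(unname(compute_lst_score(p, build, cfg)), 0L)

  # same junction away from the centromere counts
  p <- fill_diploid(prof(list("chr1", 0, 60e6, 3, 1)), build)
  expect_equal(unname(compute_lst_score(p, build, cfg)), 1L)
})

test_that("GI score is the sum of components and rejects empty profiles", {
  p <- gen_profile(c(loh = 2, tai = 1, lst = 3), build, seed = 4)
  sc <- compute_gi_score(p, build, cfg)
  expect_equal(sc$gi_score, sc$loh_count + sc$tai_count + sc$lst_count)
  expect_equal(sc$gi_score, 6L)

  expect_error(compute_gi_score(prof(), build, cfg), "insufficient data")
})

test_that("component counts are invariant under segment subdivision", {
  b <- grid_build()
  for (seed in 1:8) {
    p <- gen_random_profile(30, b, seed = seed)
    before <- compute_gi_score(p, b, cfg)
    # split every segment longer than 1 Mb in half
    halves <- purrr::pmap(p, function(sample, chrom, start, end, total_cn, minor_cn) {
      if (end - start < 1e6) {
        return(tibble::tibble(
          sample = sample, chrom = chrom, start = start, end = end,
          total_cn = total_cn, minor_cn = minor_cn
        ))
      }
      mid <- floor((start + end) / 2 / 1e5) * 1e5
      tibble::tibble(
        sample = sample, chrom = chrom,
        start = c(start, mid), end = c(mid, end),
        total_cn = total_cn, minor_cn = minor_cn
      )
    }) |> purrr::list_rbind()
    after <- compute_gi_score(halves, b, cfg)
    expect_equal(after, before)
  }
})

test_that("adding a disjoint qualifying LOH run increments the count by 1", {
  p <- fill_diploid(prof(list("chr1", 10e6, 30e6, 2, 0)), build)
  base <- unname(compute_loh_score(p, build, cfg))
  p2 <- fill_diploid(
    prof(list("chr1", 10e6, 30e6, 2, 0), list("chr2", 110e6, 130e6, 2, 0)),
    build
  )
  expect_equal(unname(compute_loh_score(p2, build, cfg)), base + 1L)
})

test_that("threshold calibration uses the nearest-rank fifth percentile", {
  expect_equal(calibrate_threshold(1:100), 5)
  expect_equal(calibrate_threshold(rep(42, 30)), 42)
  scores <- c(7, 21:39) # 20 scores; ceil(0.05*20) = 1st order statistic
  expect_equal(calibrate_threshold(scores), 7)
  expect_error(calibrate_threshold(1:19), "at least 20")
})

test_that("HRD call uses strict >42 with the BRCA override", {
  mk <- function(gi) tibble::tibble(sample = "S1", gi_score = gi)
  expect_equal(classify_lab1(mk(43), "wild_type")$label, "HRD")
  expect_equal(classify_lab1(mk(43), "wild_type")$rationale, "score")
  ov <- classify_lab1(mk(30), "mutated")
  expect_equal(ov$label, "HRD")
  expect_equal(ov$rationale, "brca_override")
  expect_equal(classify_lab1(mk(30), "wild_type")$label, "HRP")
  expect_warning(
    at42 <- classify_lab1(mk(42), "wild_type"),
    "threshold"
  )
  expect_equal(at42$label, "HRP")
})

test_that("scar scoring matches the per-base oracle on random profiles", {
  b <- grid_build()
  for (seed in 1:20) {
    p <- gen_random_profile(sample(10:50, 1), b, seed = seed)
    got <- compute_gi_score(p, b, cfg)
    want <- oracle_scar_scores(p, b, cfg)
    expect_equal(
      c(got$loh_count, got$tai_count, got$lst_count),
      unname(want),
      info = paste("seed", seed)
    )
  }
})
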