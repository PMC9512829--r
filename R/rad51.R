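#' Configuration for RAD51 functional HRD scoring
#'
#' @param foci_min A geminin-positive cell counts as RAD51-positive when
#'   it shows at least this many nuclear foci; default 5.
#' @param score_cutoff_pct RAD51 score at or below which a tumor is
#'   called HRD; default 10 (percent).
#' @param min_geminin_cells Slides with fewer geminin-positive cells fail
#'   QC (`fail_few_cells`); default 40. Failure is strict `<`, so exactly
#'   40 cells pass.
#' @param min_gh2ax_pct Slides with a lower percentage of
#'   geminin-positive cells showing gammaH2AX foci fail QC
#'   (`fail_low_gh2ax`); default 25. Failure is strict `<`, so exactly
#'   25\% passes.
#' @param target_cells Number of geminin-positive cells scored per sample
#'   when subsampling; default 100.
#' @param min_areas Distinct slide areas the subsample should represent;
#'   default 3.
#' @return A list of class `rad51_config`.
#' @export
rad51_config <- function(foci_min = 5, score_cutoff_pct = 10,
                         min_geminin_cells = 40, min_gh2ax_pct = 25,
                         target_cells = 100, min_areas = 3) {
  stopifnot(
    foci_min > 0, score_cutoff_pct > 0, min_geminin_cells > 0,
    min_gh2ax_pct > 0, target_cells > 0, min_areas > 0
  )
  structure(
    list(
      foci_min = foci_min, score_cutoff_pct = score_cutoff_pct,
      min_geminin_cells = min_geminin_cells, min_gh2ax_pct = min_gh2ax_pct,
      target_cells = target_cells, min_areas = min_areas
    ),
    class = "rad51_config"
  )
}

#' Quality-control gates for one slide
#'
#' Gates are evaluated in order: no cells at all means no tumor tissue
#' (`fail_no_tumor`); fewer than `min_geminin_cells` geminin-positive
#' cells means too little S/G2-phase tumor (`fail_few_cells`); a
#' gammaH2AX percentage among geminin-positive cells below
#' `min_gh2ax_pct` means insufficient endogenous DNA damage to license
#' RAD51 focus formation (`fail_low_gh2ax`). Both failure comparisons are
#' strict, so a slide with exactly 40 geminin-positive cells, 25\% of
#' them gammaH2AX-positive, passes.
#'
#' @param cells Per-cell tibble for one sample (columns `geminin_pos`,
#'   `gh2ax_pos`, ...).
#' @param cfg A [rad51_config()].
#' @return One of `"pass"`, `"fail_no_tumor"`, `"fail_few_cells"`,
#'   `"fail_low_gh2ax"`.
#' @export
qc_slide <- function(cells, cfg = rad51_config()) {
  if (nrow(cells) == 0) {
    return("fail_no_tumor")
  }
  gem <- cells[as.logical(cells$geminin_pos), , drop = FALSE]
  if (nrow(gem) < cfg$min_geminin_cells) {
    return("fail_few_cells")
  }
  gh2ax_pct <- 100 * mean(as.logical(gem$gh2ax_pos))
  if (gh2ax_pct < cfg$min_gh2ax_pct) {
    return("fail_low_gh2ax")
  }
  "pass"
}

#' RAD51 score of a QC-passing slide
#'
#' Percentage of geminin-positive cells with at least `cfg$foci_min`
#' RAD51 nuclear foci. Geminin-negative cells are ignored entirely.
#' Calling this on a slide that fails QC is an error; gate first with
#' [qc_slide()].
#'
#' @param cells Per-cell tibble for one sample.
#' @param cfg A [rad51_config()].
#' @return Score in percent (0-100).
#' @export
rad51_score <- function(cells, cfg = rad51_config()) {
  qc <- qc_slide(cells, cfg)
  if (qc != "pass") {
    stop("rad51_score() called on a slide that fails QC (", qc, ")",
      call. = FALSE
    )
  }
  gem <- cells[as.logical(cells$geminin_pos), , drop = FALSE]
  100 * mean(gem$rad51_foci >= cfg$foci_min)
}

#' Classify a RAD51 score as HRD or HRP
#'
#' HRD when the score is at or below `cfg$score_cutoff_pct` (a low
#' percentage of focus-forming cells means non-functional homologous
#' recombination); HRP above it.
#'
#' @param score_pct RAD51 score in percent, within \[0, 100\].
#' @param cfg A [rad51_config()].
#' @return `"HRD"` or `"HRP"` (vectorized).
#' @export
classify_rad51 <- function(score_pct, cfg = rad51_config()) {
  stopifnot(all(score_pct >= 0 & score_pct <= 100))
  ifelse(score_pct <= cfg$score_cutoff_pct, "HRD", "HRP")
}

#' Subsample geminin-positive cells to the scoring target
#'
#' When a slide carries more than `cfg$target_cells` geminin-positive
#' cells, exactly that many are drawn without replacement, stratified so
#' that at least `cfg$min_areas` distinct slide areas are represented
#' when available; with fewer areas the draw proceeds with a warning.
#' Geminin-negative cells are passed through untouched. Deterministic for
#' a fixed seed.
#'
#' @param cells Per-cell tibble for one sample.
#' @param cfg A [rad51_config()].
#' @param seed Integer seed.
#' @return A tibble with at most `cfg$target_cells` geminin-positive
#'   cells.
#' @export
subsample_cells <- function(cells, cfg = rad51_config(), seed = 1L) {
  gem_idx <- which(as.logical(cells$geminin_pos))
  if (length(gem_idx) <= cfg$target_cells) {
    return(cells)
  }
  areas <- unique(cells$area_id[gem_idx])
  if (length(areas) < cfg$min_areas) {
    warning(
      "only ", length(areas), " distinct area(s) available (",
      cfg$min_areas, " requested); proceeding",
      call. = FALSE
    )
  }
  take <- with_seed(seed, {
    picked <- integer(0)
    # guarantee representation of up to min_areas areas first
    for (a in head(sample(areas), min(length(areas), cfg$min_areas))) {
      pool <- gem_idx[cells$area_id[gem_idx] == a]
      picked <- c(picked, if (length(pool) == 1) pool else sample(pool, 1))
    }
    rest <- setdiff(gem_idx, picked)
    c(picked, sample(rest, cfg$target_cells - length(picked)))
  })
  keep <- sort(c(take, which(!as.logical(cells$geminin_pos))))
  cells[keep, , drop = FALSE]
}

#' Score and classify every sample of a per-cell table
#'
#' Applies the QC gates, the RAD51 score and the HRD/HRP cutoff per
#' sample. Samples failing QC are labeled `Inconclusive` with the failure
#' reason recorded. With `subsample = TRUE` slides exceeding the target
#' cell count are first reduced via [subsample_cells()]; the default
#' scores all cells.
#'
#' @param cells Per-cell tibble (as from [read_cell_table()] or
#'   [gen_cells()]), any number of samples.
#' @param cfg A [rad51_config()].
#' @param subsample Draw down to `cfg$target_cells` geminin-positive
#'   cells before scoring?
#' @param seed Seed for the subsample draw.
#' @return A tibble with one row per sample: `sample`, `n_geminin`,
#'   `gh2ax_pct`, `rad51_score_pct`, `qc`, `label`, `failure_reason`.
#' @export
classify_lab3 <- function(cells, cfg = rad51_config(), subsample = FALSE,
                          seed = 1L) {
  samples <- unique(cells$sample)
  purrr::map(samples, function(s) {
    cs <- cells[cells$sample == s, , drop = FALSE]
    qc <- qc_slide(cs, cfg)
    gem <- cs[as.logical(cs$geminin_pos), , drop = FALSE]
    n_gem <- nrow(gem)
    gh2ax_pct <- if (n_gem > 0) 100 * mean(as.logical(gem$gh2ax_pos)) else NA_real_
    if (qc != "pass") {
      return(tibble::tibble(
        sample = s, n_geminin = n_gem, gh2ax_pct = gh2ax_pct,
        rad51_score_pct = NA_real_, qc = qc, label = "Inconclusive",
        failure_reason = qc
      ))
    }
    if (subsample) cs <- subsample_cells(cs, cfg, seed = seed)
    score <- rad51_score(cs, cfg)
    tibble::tibble(
      sample = s, n_geminin = n_gem, gh2ax_pct = gh2ax_pct,
      rad51_score_pct = score, qc = qc,
      label = classify_rad51(score, cfg), failure_reason = NA_character_
    )
  }) |> purrr::list_rbind()
}
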