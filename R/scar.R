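#' Configuration for genomic-scar scoring
#'
#' Houses every tunable of the scar engine. The component definitions
#' (lengths in bp) follow the established scar literature: LOH runs longer
#' than 15 Mb that do not span a whole chromosome; telomeric allelic
#' imbalance longer than 11 Mb that avoids the centromere; large-scale
#' state transitions between segments of at least 10 Mb after smoothing
#' away sub-3 Mb slivers. All are configurable so published variants can
#' be reproduced.
#'
#' @param loh_min_len Minimum LOH run length in bp (strictly greater
#'   than); default 15 Mb.
#' @param tai_min_len Minimum telomeric-imbalance run length in bp
#'   (strictly greater than); default 11 Mb.
#' @param lst_min_seg Minimum flanking-segment length for an LST junction
#'   in bp (at least); default 10 Mb.
#' @param lst_smooth_len Segments shorter than this are smoothed away
#'   before LST counting; default 3 Mb.
#' @param gi_threshold Genomic-instability score threshold; scores
#'   strictly above it call HRD. Default 42.
#' @param threshold_percentile Percentile used by [calibrate_threshold()];
#'   default 5.
#' @param gap_tol Segments separated by an assembly gap shorter than this
#'   are treated as adjacent when merging runs; default 1 Mb.
#' @return A list of class `scar_config`.
#' @export
scar_config <- function(loh_min_len = 15e6, tai_min_len = 11e6,
                        lst_min_seg = 10e6, lst_smooth_len = 3e6,
                        gi_threshold = 42, threshold_percentile = 5,
                        gap_tol = 1e6) {
  stopifnot(
    loh_min_len > 0, tai_min_len > 0, lst_min_seg > 0, lst_smooth_len > 0,
    threshold_percentile > 0, threshold_percentile < 100, gap_tol >= 0
  )
  structure(
    list(
      loh_min_len = loh_min_len, tai_min_len = tai_min_len,
      lst_min_seg = lst_min_seg, lst_smooth_len = lst_smooth_len,
      gi_threshold = gi_threshold, threshold_percentile = threshold_percentile,
      gap_tol = gap_tol
    ),
    class = "scar_config"
  )
}

# Round half away from zero; allele copy numbers are integerized with this
# convention before any state comparison (purity/ploidy-adjusted inputs are
# rarely exact integers).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Integerize allele states and drop chromosomes absent from the build
# (sex chromosomes are excluded by using an autosome-only build).
prep_profile <- function(profile, build) {
  segs <- tibble::as_tibble(profile)
  keep <- segs$chrom %in% build$chrom
  segs <- segs[keep, , drop = FALSE]
  segs$total_cn <- round_half_away(segs$total_cn)
  segs$minor_cn <- round_half_away(segs$minor_cn)
  segs$minor_cn <- pmin(segs$minor_cn, segs$total_cn - segs$minor_cn)
  segs |>
    dplyr::arrange(.data$sample, match(.data$chrom, build$chrom), .data$start)
}

# Maximal runs of flagged segments within one chromosome. Segments are
# assumed sorted and non-overlapping; a run breaks at an unflagged segment
# or at a gap >= gap_tol. Returns a tibble with run start/end (span) and
# bases (sum of covered widths).
merge_flag_runs <- function(start, end, flag, gap_tol) {
  n <- length(start)
  if (n == 0 || !any(flag)) {
    return(tibble::tibble(
      run_start = numeric(), run_end = numeric(), bases = numeric()
    ))
  }
  prev_flag <- c(FALSE, flag[-n])
  prev_end <- c(-Inf, end[-n])
  new_run <- flag & (!prev_flag | (start - prev_end) >= gap_tol)
  run_id <- cumsum(new_run)
  keep <- flag
  grp <- factor(run_id[keep], levels = unique(run_id[keep]))
  tibble::tibble(
    run_start = tapply(start[keep], grp, min) |> as.numeric(),
    run_end = tapply(end[keep], grp, max) |> as.numeric(),
    bases = tapply((end - start)[keep], grp, sum) |> as.numeric()
  )
}

per_sample_count <- function(profile, build, fun) {
  segs <- prep_profile(profile, build)
  samples <- unique(segs$sample)
  counts <- vapply(
    samples,
    function(s) fun(segs[segs$sample == s, , drop = FALSE]),
    integer(1)
  )
  stats::setNames(counts, samples)
}

#' Count long loss-of-heterozygosity (LOH) runs
#'
#' An LOH run is a maximal stretch of segments with minor allele copy
#' number 0 and total copy number at least 1 (the allele is lost, the
#' locus is not). Runs longer than `cfg$loh_min_len` (strictly) that do
#' not span an entire chromosome are counted. Run length is the sum of
#' covered bases; segments separated by a gap shorter than `cfg$gap_tol`
#' belong to the same run.
#'
#' @param profile A segment tibble (`sample`, `chrom`, `start`, `end`,
#'   `total_cn`, `minor_cn`), 0-based half-open.
#' @param build An `hrd_build`.
#' @param cfg A [scar_config()].
#' @return Named integer vector of LOH counts, one per sample.
#' @export
compute_loh_score <- function(profile, build, cfg = scar_config()) {
  per_sample_count(profile, build, function(segs) {
    total <- 0L
    for (ch in unique(segs$chrom)) {
      cs <- segs[segs$chrom == ch, ]
      len <- build_row(build, ch)$length
      runs <- merge_flag_runs(
        cs$start, cs$end,
        cs$minor_cn == 0 & cs$total_cn >= 1, cfg$gap_tol
      )
      ok <- runs$bases > cfg$loh_min_len &
        !(runs$run_start <= 0 & runs$run_end >= len)
      total <- total + sum(ok)
    }
    as.integer(total)
  })
}

#' Count telomeric allelic-imbalance (TAI) runs
#'
#' An allelic-imbalance run is a maximal stretch of segments whose two
#' parental allele copy numbers differ (minor != total - minor, on
#' integerized states). A run is counted when it touches a chromosome end
#' (starts at 0 or ends at the chromosome length), does not intersect the
#' centromere interval, and is longer than `cfg$tai_min_len` (strictly).
#'
#' @inheritParams compute_loh_score
#' @return Named integer vector of TAI counts, one per sample.
#' @export
compute_tai_score <- function(profile, build, cfg = scar_config()) {
  if (anyNA(build$cen_start) || anyNA(build$cen_end)) {
    stop("build lacks centromere annotation", call. = FALSE)
  }
  per_sample_count(profile, build, function(segs) {
    total <- 0L
    for (ch in unique(segs$chrom)) {
      cs <- segs[segs$chrom == ch, ]
      b <- build_row(build, ch)
      runs <- merge_flag_runs(
        cs$start, cs$end,
        cs$minor_cn != (cs$total_cn - cs$minor_cn), cfg$gap_tol
      )
      touches <- runs$run_start <= 0 | runs$run_end >= b$length
      crosses_cen <- runs$run_start < b$cen_end & runs$run_end > b$cen_start
      ok <- touches & !crosses_cen & runs$bases > cfg$tai_min_len
      total <- total + sum(ok)
    }
    as.integer(total)
  })
}

# Clip segments of one sample to chromosome arms, then smooth: merge
# identical adjacent states, iteratively drop sub-smooth_len segments and
# re-merge until stable. Returns a tibble of arm-wise smoothed segments.
smooth_arm_segments <- function(segs, build, smooth_len, gap_tol) {
  arms <- build_arms(build)
  pieces <- purrr::pmap(arms, function(chrom, arm, arm_start, arm_end) {
    cs <- segs[segs$chrom == chrom &
      segs$end > arm_start & segs$start < arm_end, , drop = FALSE]
    if (nrow(cs) == 0) {
      return(NULL)
    }
    cs$start <- pmax(cs$start, arm_start)
    cs$end <- pmin(cs$end, arm_end)
    cs$arm <- arm
    cs
  })
  pieces <- purrr::list_rbind(purrr::compact(pieces))
  if (is.null(pieces) || nrow(pieces) == 0) {
    return(tibble::tibble(
      chrom = character(), arm = character(), start = numeric(),
      end = numeric(), total_cn = numeric(), minor_cn = numeric(),
      bases = numeric()
    ))
  }
  pieces$bases <- pieces$end - pieces$start
  out <- pieces |>
    dplyr::group_by(.data$chrom, .data$arm) |>
    dplyr::group_modify(function(df, key) {
      smooth_one_arm(df, smooth_len, gap_tol)
    }) |>
    dplyr::ungroup()
  out
}

smooth_one_arm <- function(df, smooth_len, gap_tol) {
  df <- df[order(df$start), c("start", "end", "total_cn", "minor_cn", "bases")]
  merge_identical <- function(d, max_gap) {
    if (nrow(d) <= 1) {
      return(d)
    }
    same <- d$total_cn[-1] == d$total_cn[-nrow(d)] &
      d$minor_cn[-1] == d$minor_cn[-nrow(d)] &
      (d$start[-1] - d$end[-nrow(d)]) < max_gap
    grp <- cumsum(c(TRUE, !same))
    grp <- factor(grp, levels = unique(grp))
    tibble::tibble(
      start = tapply(d$start, grp, min) |> as.numeric(),
      end = tapply(d$end, grp, max) |> as.numeric(),
      total_cn = tapply(d$total_cn, grp, function(x) x[1]) |> as.numeric(),
      minor_cn = tapply(d$minor_cn, grp, function(x) x[1]) |> as.numeric(),
      bases = tapply(d$bases, grp, sum) |> as.numeric()
    )
  }
  # abutting same-state pieces are one segment regardless of smoothing
  d <- merge_identical(df, gap_tol)
  repeat {
    n0 <- nrow(d)
    d <- d[d$bases >= smooth_len, , drop = FALSE]
    d <- merge_identical(d, smooth_len)
    if (nrow(d) == n0) break
  }
  d
}

#' Count large-scale state transitions (LST)
#'
#' After smoothing away segments shorter than `cfg$lst_smooth_len` and
#' merging flanking segments with identical allele-specific state, every
#' junction between adjacent segments on the same chromosome arm is
#' counted when both flanks cover at least `cfg$lst_min_seg` and the copy
#' state changes. Arms are evaluated separately, so a junction straddling
#' the centromere never counts.
#'
#' @inheritParams compute_loh_score
#' @return Named integer vector of LST counts, one per sample.
#' @export
compute_lst_score <- function(profile, build, cfg = scar_config()) {
  per_sample_count(profile, build, function(segs) {
    sm <- smooth_arm_segments(segs, build, cfg$lst_smooth_len, cfg$gap_tol)
    if (nrow(sm) == 0) {
      return(0L)
    }
    total <- sm |>
      dplyr::group_by(.data$chrom, .data$arm) |>
      dplyr::summarise(
        n_lst = count_arm_junctions(
          .data$start, .data$end, .data$total_cn, .data$minor_cn, .data$bases,
          cfg$lst_min_seg, cfg$lst_smooth_len
        ),
        .groups = "drop"
      )
    as.integer(sum(total$n_lst))
  })
}

count_arm_junctions <- function(start, end, total_cn, minor_cn, bases,
                                min_seg, max_gap) {
  n <- length(start)
  if (n <= 1) {
    return(0L)
  }
  i <- seq_len(n - 1)
  adjacent <- (start[i + 1] - end[i]) < max_gap
  changed <- total_cn[i + 1] != total_cn[i] | minor_cn[i + 1] != minor_cn[i]
  long_both <- bases[i] >= min_seg & bases[i + 1] >= min_seg
  sum(adjacent & changed & long_both)
}

#' Compute all three scar components and the genomic-instability score
#'
#' The genomic-instability (GI) score is the unweighted sum of the three
#' scar components: LOH + TAI + LST counts. Components are reported
#' individually alongside the sum.
#'
#' @inheritParams compute_loh_score
#' @return A tibble with one row per sample: `sample`, `loh_count`,
#'   `tai_count`, `lst_count`, `gi_score`.
#' @examples
#' build <- default_build()
#' prof <- gen_profile(c(loh = 2, tai = 1, lst = 3), build, seed = 1)
#' compute_gi_score(prof, build)
#' @export
compute_gi_score <- function(profile, build, cfg = scar_config()) {
  if (nrow(profile) == 0) {
    stop("insufficient data: profile contains no segments", call. = FALSE)
  }
  loh <- compute_loh_score(profile, build, cfg)
  tai <- compute_tai_score(profile, build, cfg)
  lst <- compute_lst_score(profile, build, cfg)
  tibble::tibble(
    sample = names(loh),
    loh_count = as.integer(loh),
    tai_count = as.integer(tai[names(loh)]),
    lst_count = as.integer(lst[names(loh)]),
    gi_score = .data$loh_count + .data$tai_count + .data$lst_count
  )
}

#' Calibrate the GI-score threshold from a reference score set
#'
#' The deficiency threshold is taken as the fifth percentile (nearest-rank
#' definition: the `ceiling(p/100 * n)`-th order statistic) of GI scores
#' from a reference set of samples carrying deleterious BRCA1/2 variants.
#' Fewer than 20 reference scores make the percentile unstable and raise
#' an error.
#'
#' @param reference_scores Numeric vector of GI scores (>= 20 values).
#' @param percentile Percentile in (0, 100); default 5.
#' @return The threshold (a single number).
#' @examples
#' calibrate_threshold(1:100) # 5
#' @export
calibrate_threshold <- function(reference_scores, percentile = 5) {
  n <- length(reference_scores)
  if (n < 20) {
    stop("need at least 20 reference scores to calibrate a percentile",
      call. = FALSE
    )
  }
  stopifnot(percentile > 0, percentile < 100)
  k <- max(1L, as.integer(ceiling(percentile / 100 * n)))
  sort(reference_scores)[k]
}

#' Call HRD/HRP from GI scores with the BRCA override
#'
#' A sample is HR deficient when its GI score strictly exceeds the
#' threshold (default 42). A sample below the threshold but carrying a
#' pathogenic BRCA1/2 mutation is overridden to HRD with rationale
#' `brca_override`. A score exactly at the threshold is called HRP (the
#' rule is a strict inequality) and flagged with a warning so boundary
#' cases are visible.
#'
#' @param scores Tibble from [compute_gi_score()] (columns `sample`,
#'   `gi_score`, and optionally the components).
#' @param brca_status Either a single status for all samples or a tibble
#'   with columns `sample`, `status` (`mutated`, `wild_type`, `unknown`).
#' @param cfg A [scar_config()]; `cfg$gi_threshold` is the threshold.
#' @return A tibble with one row per sample: the score columns plus
#'   `brca_status`, `label` (`HRD`/`HRP`) and `rationale` (`score` or
#'   `brca_override`).
#' @export
classify_lab1 <- function(scores, brca_status = "unknown", cfg = scar_config()) {
  scores <- tibble::as_tibble(scores)
  if (is.data.frame(brca_status)) {
    status <- brca_status$status[match(scores$sample, brca_status$sample)]
    status[is.na(status)] <- "unknown"
  } else {
    status <- rep_len(as.character(brca_status), nrow(scores))
  }
  if (!all(status %in% c("mutated", "wild_type", "unknown"))) {
    stop("brca_status must be mutated/wild_type/unknown", call. = FALSE)
  }
  at_boundary <- scores$gi_score == cfg$gi_threshold
  if (any(at_boundary)) {
    warning(
      "GI score exactly at threshold (", cfg$gi_threshold, ") for sample(s) ",
      paste(scores$sample[at_boundary], collapse = ", "),
      "; called HRP under the strict > rule",
      call. = FALSE
    )
  }
  by_score <- scores$gi_score > cfg$gi_threshold
  by_brca <- !by_score & status == "mutated"
  dplyr::mutate(
    scores,
    brca_status = status,
    label = ifelse(by_score | by_brca, "HRD", "HRP"),
    rationale = dplyr::case_when(
      by_score ~ "score",
      by_brca ~ "brca_override",
      TRUE ~ "score"
    )
  )
}
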