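# Allele-specific states used by the profile generator. The diploid
# background is (2,1); copy-neutral LOH is (2,0); the allelic-imbalance
# state is (3,1); (4,2) is a balanced, non-LOH buffer used to insulate
# engineered events from each other.
.ST <- list(
  dip = c(2, 1), loh = c(2, 0), ai = c(3, 1), buf = c(4, 2)
)

#' Generate a segment profile with exact scar-score ground truth
#'
#' Constructs a whole-genome allele-specific profile whose LOH, TAI and
#' LST counts are exactly the requested targets. Events are engineered so
#' they never interact: interior copy-neutral LOH runs of 16-30 Mb are
#' flanked by 5 Mb imbalance spacers (too short to form LST flanks);
#' telomere-anchored imbalance runs of 12-25 Mb stop well before the
#' centromere and end in a 5 Mb balanced buffer; each LST is a single
#' engineered junction between a long diploid flank and a 12-15 Mb
#' imbalance segment shielded on the other side by a 5 Mb buffer. All
#' remaining territory is balanced diploid, so the constructed profile
#' has no incidental scars.
#'
#' @param targets Named numeric vector `c(loh =, tai =, lst =)` (or
#'   unnamed length 3 in that order).
#' @param build An `hrd_build`.
#' @param seed Integer seed; the profile is a pure function of
#'   `(targets, build, seed)`.
#' @param sample_id Sample name for the output profile.
#' @return A `segment_profile` tibble covering every chromosome of the
#'   build, with attribute `scar_truth` holding the targets.
#' @examples
#' prof <- gen_profile(c(loh = 3, tai = 2, lst = 4), default_build(), seed = 7)
#' compute_gi_score(prof, default_build())
#' @export
gen_profile <- function(targets, build, seed, sample_id = "S1") {
  if (is.null(names(targets))) names(targets) <- c("loh", "tai", "lst")
  targets <- targets[c("loh", "tai", "lst")]
  stopifnot(all(!is.na(targets)), all(targets >= 0))
  with_seed(seed, {
    arms <- build_arms(build)
    arms$len <- arms$arm_end - arms$arm_start
    arms <- arms[order(-arms$len), ]
    remaining <- as.list(targets)
    pad <- 10e6
    buf <- 5e6
    # blocks per arm, ordered from the telomeric end inward
    arm_blocks <- vector("list", nrow(arms))
    for (i in seq_len(nrow(arms))) {
      space <- arms$len[i]
      blocks <- list()
      if (remaining$tai > 0) {
        tai_len <- sample(121:250, 1) * 1e5
        if (space >= tai_len + buf + pad) {
          blocks <- c(blocks, list(
            list(len = tai_len, st = .ST$ai),
            list(len = buf, st = .ST$buf)
          ))
          space <- space - tai_len - buf
          remaining$tai <- remaining$tai - 1
        }
      }
      repeat {
        placed <- FALSE
        if (remaining$loh > 0) {
          loh_len <- sample(160:300, 1) * 1e5
          need <- pad + buf + loh_len + buf
          if (space >= need + pad) {
            blocks <- c(blocks, list(
              list(len = pad, st = .ST$dip),
              list(len = buf, st = .ST$ai),
              list(len = loh_len, st = .ST$loh),
              list(len = buf, st = .ST$ai)
            ))
            space <- space - need
            remaining$loh <- remaining$loh - 1
            placed <- TRUE
          }
        }
        if (remaining$lst > 0) {
          lst_len <- sample(120:150, 1) * 1e5
          need <- pad + lst_len + buf
          if (space >= need + pad) {
            blocks <- c(blocks, list(
              list(len = pad, st = .ST$dip),
              list(len = lst_len, st = .ST$ai),
              list(len = buf, st = .ST$buf)
            ))
            space <- space - need
            remaining$lst <- remaining$lst - 1
            placed <- TRUE
          }
        }
        if (!placed || (remaining$loh == 0 && remaining$lst == 0)) break
      }
      arm_blocks[[i]] <- blocks
    }
    if (remaining$loh > 0 || remaining$tai > 0 || remaining$lst > 0) {
      stop("targets infeasible for this build: could not place all events",
        call. = FALSE
      )
    }
    segs <- purrr::map(seq_len(nrow(build)), function(ci) {
      ch <- build$chrom[ci]
      len <- build$length[ci]
      rows_p <- arm_rows(arm_blocks, arms, ch, "p", 0, forward = TRUE)
      rows_q <- arm_rows(arm_blocks, arms, ch, "q", len, forward = FALSE)
      p_end <- if (nrow(rows_p) > 0) max(rows_p$end) else 0
      q_start <- if (nrow(rows_q) > 0) min(rows_q$start) else len
      mid <- tibble::tibble(
        start = p_end, end = q_start,
        total_cn = .ST$dip[1], minor_cn = .ST$dip[2]
      )
      dplyr::bind_rows(rows_p, mid, rows_q) |>
        dplyr::filter(.data$end > .data$start) |>
        dplyr::mutate(chrom = ch, .before = 1)
    }) |> purrr::list_rbind()
    out <- dplyr::mutate(segs, sample = sample_id, .before = 1)
    out <- as_segment_profile(out)
    attr(out, "scar_truth") <- targets
    out
  })
}

# materialize one arm's engineered blocks as coordinates; `forward` lays
# them from `origin` rightward (p arm), otherwise leftward from the
# telomere at `origin` (q arm)
arm_rows <- function(arm_blocks, arms, ch, arm, origin, forward) {
  i <- which(arms$chrom == ch & arms$arm == arm)
  blocks <- arm_blocks[[i]]
  if (length(blocks) == 0) {
    return(tibble::tibble(
      start = numeric(), end = numeric(),
      total_cn = numeric(), minor_cn = numeric()
    ))
  }
  lens <- vapply(blocks, function(b) b$len, numeric(1))
  if (forward) {
    ends <- origin + cumsum(lens)
    starts <- ends - lens
  } else {
    # block k sits at [origin - sum(lens[1:k]), origin - sum(lens[1:(k-1)])]
    starts <- origin - cumsum(lens)
    ends <- starts + lens
  }
  tibble::tibble(
    start = starts, end = ends,
    total_cn = vapply(blocks, function(b) b$st[1], numeric(1)),
    minor_cn = vapply(blocks, function(b) b$st[2], numeric(1))
  ) |> dplyr::arrange(.data$start)
}

#' Generate a random (unstructured) segment profile
#'
#' Draws segments with random allele-specific states and random lengths
#' on randomly chosen chromosomes; coordinates are multiples of 0.1 Mb.
#' Unlike [gen_profile()] the scar counts are not controlled — this is
#' the stress-test input for validating the scoring engine against an
#' exhaustive per-base oracle.
#'
#' @param n_segments Total number of segments to draw (the realized count
#'   can be slightly lower when a chromosome fills up).
#' @param build An `hrd_build`.
#' @param seed Integer seed.
#' @param sample_id Sample name.
#' @return A `segment_profile` tibble.
#' @export
gen_random_profile <- function(n_segments, build, seed, sample_id = "S1") {
  states <- list(
    c(1, 0), c(2, 0), c(2, 1), c(3, 0), c(3, 1), c(4, 1), c(4, 2)
  )
  with_seed(seed, {
    chroms <- sample(build$chrom, n_segments, replace = TRUE)
    out <- purrr::map(unique(chroms), function(ch) {
      k <- sum(chroms == ch)
      len <- build_row(build, ch)$length
      pos <- sample(0:floor(len / 1e5), 1) * 1e5
      rows <- list()
      for (i in seq_len(k)) {
        gap <- sample(c(0, 0, 0, sample(0:20, 1) * 1e5), 1)
        seg_len <- sample(5:400, 1) * 1e5
        start <- pos + gap
        end <- min(start + seg_len, floor(len / 1e5) * 1e5)
        if (end <= start) break
        st <- states[[sample(length(states), 1)]]
        rows[[i]] <- tibble::tibble(
          chrom = ch, start = start, end = end,
          total_cn = st[1], minor_cn = st[2]
        )
        pos <- end
      }
      purrr::list_rbind(rows)
    }) |> purrr::list_rbind()
    out <- dplyr::mutate(out, sample = sample_id, .before = 1) |>
      dplyr::arrange(match(.data$chrom, build$chrom), .data$start)
    as_segment_profile(out)
  })
}

#' Simulate shallow-WGS binned coverage over a copy-number profile
#'
#' Per-bin expected counts are proportional to
#' `depth_factor * total_cn / 2`, emulating 0.4-0.8x whole-genome
#' coverage; counts are drawn from a negative binomial whose extra-Poisson
#' dispersion corresponds to a log-scale standard deviation of `sigma`
#' (`sigma = 0` degenerates to Poisson). FFPE shallow WGS is
#' overdispersed, hence the negative binomial default.
#'
#' @param profile A `segment_profile` supplying `total_cn` (regions not
#'   covered by a segment count as diploid).
#' @param build An `hrd_build`; bins tile each chromosome.
#' @param window_kb Bin width in kb.
#' @param depth_factor Sequencing depth in x (0.4-0.8 typical).
#' @param sigma Extra-Poisson log-scale dispersion.
#' @param seed Integer seed.
#' @param reads_per_kb Expected reads per kb per 1x depth for a diploid
#'   bin; default 10 (100 bp reads).
#' @return A `coverage_bins` tibble.
#' @export
gen_coverage <- function(profile, build, window_kb = 5, depth_factor = 0.6,
                         sigma = 0.05, seed = 1L, reads_per_kb = 10) {
  w <- window_kb * 1000
  sample_id <- unique(profile$sample)
  stopifnot(length(sample_id) == 1)
  with_seed(seed, {
    out <- purrr::map(seq_len(nrow(build)), function(ci) {
      ch <- build$chrom[ci]
      nb <- floor(build$length[ci] / w)
      starts <- (seq_len(nb) - 1) * w
      mids <- starts + w / 2
      segs <- profile[profile$chrom == ch, , drop = FALSE]
      cn <- rep(2, nb)
      if (nrow(segs) > 0) {
        segs <- segs[order(segs$start), ]
        idx <- findInterval(mids, segs$start)
        hit <- idx > 0 & mids < segs$end[pmax(idx, 1)]
        cn[hit] <- segs$total_cn[idx[hit]]
      }
      mu <- reads_per_kb * window_kb * depth_factor * cn / 2
      counts <- if (sigma > 0) {
        rnbinom(nb, mu = mu, size = 1 / sigma^2)
      } else {
        rpois(nb, mu)
      }
      tibble::tibble(sample = sample_id, chrom = ch, start = starts, count = counts)
    }) |> purrr::list_rbind()
    as_coverage_bins(out, width = w)
  })
}

#' Generate a total-copy profile with an exact number of LGA junctions
#'
#' Packs alternating long (>= 12 Mb) copy-number-2 and copy-number-3
#' segments into chromosome arms until exactly `n_lga` qualifying
#' junctions exist; each junction has a log2 jump of `log2(3/2) = 0.58`.
#' The remaining genome is diploid. Ground truth for the shallow-WGS
#' recovery properties.
#'
#' @param n_lga Number of ground-truth LGA junctions.
#' @param build An `hrd_build`.
#' @param seed Integer seed (controls per-arm segment-length jitter).
#' @param sample_id Sample name.
#' @return A `segment_profile` with attribute `lga_truth`.
#' @export
gen_lga_profile <- function(n_lga, build, seed, sample_id = "S1") {
  with_seed(seed, {
    arms <- build_arms(build)
    arms$len <- arms$arm_end - arms$arm_start
    arms <- arms[order(-arms$len), ]
    remaining <- n_lga
    rows <- list()
    for (i in seq_len(nrow(arms))) {
      a <- arms[i, ]
      seg <- (120 + sample(0:20, 1)) * 1e5
      j_max <- max(0, floor(a$len / seg) - 1)
      j <- min(remaining, j_max)
      if (j <= 0 || remaining == 0) next
      l0 <- a$len - j * seg
      lens <- c(l0, rep(seg, j))
      cns <- 2 + (seq_len(j + 1) - 1) %% 2
      ends <- a$arm_start + cumsum(lens)
      starts <- ends - lens
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = a$chrom, start = starts, end = ends, total_cn = cns
      )
      remaining <- remaining - j
      if (remaining == 0) break
    }
    if (remaining > 0) {
      stop("n_lga infeasible for this build", call. = FALSE)
    }
    engineered <- purrr::list_rbind(rows)
    # fill everything else with diploid
    full <- purrr::map(seq_len(nrow(build)), function(ci) {
      ch <- build$chrom[ci]
      len <- build$length[ci]
      e <- engineered[engineered$chrom == ch, , drop = FALSE]
      if (nrow(e) == 0) {
        return(tibble::tibble(
          chrom = ch, start = 0, end = len, total_cn = 2
        ))
      }
      e <- e[order(e$start), ]
      gaps_start <- c(0, e$end)
      gaps_end <- c(e$start, len)
      fill <- tibble::tibble(
        chrom = ch, start = gaps_start, end = gaps_end, total_cn = 2
      )
      dplyr::bind_rows(e, fill[fill$end > fill$start, ]) |>
        dplyr::arrange(.data$start)
    }) |> purrr::list_rbind()
    out <- dplyr::mutate(full,
      sample = sample_id, .before = 1
    )
    out$minor_cn <- floor(out$total_cn / 2)
    out <- as_segment_profile(out)
    attr(out, "lga_truth") <- n_lga
    out
  })
}

#' Generate a per-cell immunofluorescence table for one slide
#'
#' Geminin-positive cells are RAD51-positive (five or more foci) with
#' probability `p_rad51` and gammaH2AX-positive with probability
#' `p_gh2ax`; foci counts are drawn so the >= 5 predicate matches the
#' latent positivity. Areas are assigned round-robin. With
#' `exact = TRUE` the number of positives is fixed at `round(p * n)`
#' (positives assigned to a random subset), which pins QC outcomes
#' exactly when a designed failure pattern is required.
#'
#' @param p_rad51 Probability (or with `exact = TRUE`, fraction) of
#'   geminin-positive cells with >= 5 RAD51 foci.
#' @param p_gh2ax Probability/fraction of geminin-positive cells with
#'   gammaH2AX foci.
#' @param n_geminin Number of geminin-positive cells.
#' @param n_areas Number of slide areas.
#' @param seed Integer seed.
#' @param sample_id Sample name.
#' @param n_other Additional geminin-negative cells (ignored by scoring).
#' @param exact Fix positive counts to `round(p * n)` instead of
#'   Bernoulli draws.
#' @return A per-cell tibble in the [read_cell_table()] schema.
#' @export
gen_cells <- function(p_rad51, p_gh2ax, n_geminin, n_areas = 3, seed = 1L,
                      sample_id = "S1", n_other = 20, exact = FALSE) {
  stopifnot(p_rad51 >= 0, p_rad51 <= 1, p_gh2ax >= 0, p_gh2ax <= 1)
  with_seed(seed, {
    draw <- function(p, n) {
      if (exact) {
        pos <- logical(n)
        pos[sample(n, round(p * n))] <- TRUE
        pos
      } else {
        runif(n) < p
      }
    }
    rad_pos <- draw(p_rad51, n_geminin)
    gh_pos <- draw(p_gh2ax, n_geminin)
    foci <- ifelse(rad_pos, 5 + rpois(n_geminin, 4), sample(0:4, n_geminin, TRUE))
    gem <- tibble::tibble(
      sample = sample_id,
      cell_id = sprintf("c%04d", seq_len(n_geminin)),
      geminin_pos = TRUE,
      rad51_foci = as.integer(foci),
      gh2ax_pos = gh_pos,
      area_id = paste0("A", (seq_len(n_geminin) - 1) %% n_areas + 1)
    )
    if (n_other > 0) {
      other <- tibble::tibble(
        sample = sample_id,
        cell_id = sprintf("n%04d", seq_len(n_other)),
        geminin_pos = FALSE,
        rad51_foci = as.integer(rpois(n_other, 1)),
        gh2ax_pos = runif(n_other) < p_gh2ax,
        area_id = paste0("A", (seq_len(n_other) - 1) %% n_areas + 1)
      )
      gem <- dplyr::bind_rows(gem, other)
    }
    gem
  })
}

#' Generate a synthetic trial cohort with designed assay behavior
#'
#' Every sample carries a latent true HRD status; each assay observes it
#' through a designed sensitivity/specificity/missingness filter, so
#' contingency tables between assays can be moment-matched to target
#' margins. Progression times are exponential with the designed hazard
#' ratio between true HRD and HRP strata; censoring is uniform.
#'
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param hrd_frac Prevalence of true HRD.
#' @param hr True progression hazard ratio, HRD vs HRP.
#' @param median_pfs_hrp Median progression-free survival of true-HRP
#'   subjects, months.
#' @param censor_max Uniform censoring horizon, months.
#' @param assays Named list of per-assay designs, each
#'   `list(sens =, spec =, miss =)`.
#' @param p_evaluable Probability a subject is response-evaluable.
#' @param resp_hrd,resp_hrp Response probability by true status.
#' @return A list: `truth` (tibble `sample`, `true_status`), `calls`
#'   (long tibble `sample`, `assay`, `label`), `outcomes` (tibble in the
#'   [read_cohort_table()] schema plus `true_status`).
#' @export
gen_cohort <- function(n = 100, seed = 1L, hrd_frac = 0.56, hr = 0.53,
                       median_pfs_hrp = 18, censor_max = 72,
                       assays = list(
                         myriad = list(sens = 0.97, spec = 0.95, miss = 0.06),
                         lab1 = list(sens = 0.98, spec = 0.88, miss = 0.03),
                         lab2 = list(sens = 0.93, spec = 0.90, miss = 0.03),
                         lab3 = list(sens = 0.80, spec = 0.45, miss = 0.31)
                       ),
                       p_evaluable = 0.64, resp_hrd = 0.82, resp_hrp = 0.60) {
  with_seed(seed, {
    ids <- sprintf("S%03d", seq_len(n))
    hrd <- runif(n) < hrd_frac
    truth <- tibble::tibble(
      sample = ids, true_status = ifelse(hrd, "HRD", "HRP")
    )
    calls <- purrr::imap(assays, function(a, nm) {
      observed <- ifelse(
        hrd, ifelse(runif(n) < a$sens, "HRD", "HRP"),
        ifelse(runif(n) < a$spec, "HRP", "HRD")
      )
      missing <- runif(n) < a$miss
      tibble::tibble(
        sample = ids, assay = nm,
        label = ifelse(missing, "Missing", observed),
        failure_reason = ifelse(missing, "assay_failure", NA_character_)
      )
    }) |> purrr::list_rbind()
    rate_hrp <- log(2) / median_pfs_hrp
    rate <- rate_hrp * ifelse(hrd, hr, 1)
    pfs <- rexp(n, rate)
    cens <- runif(n, 0.1, censor_max)
    evaluable <- runif(n) < p_evaluable
    responder <- runif(n) < ifelse(hrd, resp_hrd, resp_hrp)
    response <- dplyr::case_when(
      !evaluable ~ "not_evaluable",
      responder & runif(n) < 31 / 46 ~ "complete",
      responder ~ "partial",
      runif(n) < 0.6 ~ "stable",
      TRUE ~ "progression"
    )
    outcomes <- tibble::tibble(
      sample = ids,
      time = pmin(pfs, cens),
      event = as.integer(pfs <= cens),
      response = response,
      age_group = ifelse(runif(n) < 0.70, "<65", ">=65"),
      ecog = ifelse(runif(n) < 0.80, "0", "1-2"),
      residual_disease = sample(
        c("none", "<=1cm", ">1cm_or_not_operated"), n,
        replace = TRUE, prob = c(0.36, 0.25, 0.39)
      ),
      figo_stage = ifelse(runif(n) < 0.81, "III", "IV"),
      true_status = truth$true_status
    )
    list(truth = truth, calls = calls, outcomes = outcomes)
  })
}

#' Expected 2x2 contingency table under designed misclassification
#'
#' Moment-matching arithmetic for [gen_cohort()]: given the prevalence of
#' true HRD and two assays' sensitivity/specificity, returns the expected
#' complete-case cell counts for `n` jointly observed samples.
#'
#' @param n Number of complete-case pairs.
#' @param hrd_frac Prevalence of true HRD.
#' @param index,ref Lists with `sens` and `spec`.
#' @return Named numeric vector `c(a, b, c, d)` (index x reference).
#' @export
expected_contingency <- function(n, hrd_frac, index, ref) {
  pi1 <- hrd_frac
  pi0 <- 1 - hrd_frac
  c(
    a = n * (pi1 * index$sens * ref$sens + pi0 * (1 - index$spec) * (1 - ref$spec)),
    b = n * (pi1 * index$sens * (1 - ref$sens) + pi0 * (1 - index$spec) * ref$spec),
    c = n * (pi1 * (1 - index$sens) * ref$sens + pi0 * index$spec * (1 - ref$spec)),
    d = n * (pi1 * (1 - index$sens) * (1 - ref$sens) + pi0 * index$spec * ref$spec)
  )
}

#' Published contingency tables of the three academic assays vs Myriad
#'
#' The fixed complete-case 2x2 tables of the three academic HRD assays
#' cross-tabulated against the Myriad reference on the trial cohort
#' (index assay in rows): LAB1 (53, 6, 1, 32) on 92 samples, LAB2
#' (48, 6, 5, 33) on 92, LAB3 (34, 16, 7, 8) on 65, together with the
#' full printed margins including missing calls. Immutable.
#'
#' @return A list with elements `LAB1`, `LAB2`, `LAB3` (each a
#'   `contingency_2x2`) and `margins` (a tibble of the full 3x3 counts
#'   per assay).
#' @export
fixture_table2 <- function() {
  margins <- tibble::tribble(
    ~assay, ~index_label, ~ref_hrd, ~ref_hrp, ~ref_missing,
    "LAB1", "HRD", 53, 6, 2,
    "LAB1", "HRP", 1, 32, 3,
    "LAB1", "Missing", 1, 1, 1,
    "LAB2", "HRD", 48, 6, 2,
    "LAB2", "HRP", 5, 33, 3,
    "LAB2", "Missing", 2, 0, 1,
    "LAB3", "HRD", 34, 16, 3,
    "LAB3", "HRP", 7, 8, 1,
    "LAB3", "Missing", 14, 15, 2
  )
  list(
    LAB1 = contingency_table(53, 6, 1, 32, n_excluded_missing = 8),
    LAB2 = contingency_table(48, 6, 5, 33, n_excluded_missing = 8),
    LAB3 = contingency_table(34, 16, 7, 8, n_excluded_missing = 35),
    margins = margins
  )
}

#' Reconstruct per-sample call tables matching the published margins
#'
#' Expands the full printed margins (including missing calls) of one
#' assay-vs-reference comparison into two per-sample call tibbles whose
#' cross-tabulation via [build_contingency()] reproduces the published
#' 2x2 table exactly. Sample ids are synthetic.
#'
#' @param assay `"LAB1"`, `"LAB2"` or `"LAB3"`.
#' @return A list of two tibbles, `index` and `ref`, each with columns
#'   `sample`, `assay`, `label`.
#' @export
fixture_calls_table2 <- function(assay = c("LAB1", "LAB2", "LAB3")) {
  assay <- match.arg(assay)
  m <- fixture_table2()$margins
  m <- m[m$assay == assay, ]
  long <- tidyr::pivot_longer(m, c("ref_hrd", "ref_hrp", "ref_missing"),
    names_to = "ref_label", values_to = "n"
  )
  long$ref_label <- dplyr::recode(long$ref_label,
    ref_hrd = "HRD", ref_hrp = "HRP", ref_missing = "Missing"
  )
  idx <- rep(seq_len(nrow(long)), long$n)
  ids <- sprintf("S%03d", seq_along(idx))
  list(
    index = tibble::tibble(
      sample = ids, assay = assay, label = long$index_label[idx]
    ),
    ref = tibble::tibble(
      sample = ids, assay = "Myriad", label = long$ref_label[idx]
    )
  )
}
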