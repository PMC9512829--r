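#' Configuration for shallow-WGS HRD scoring
#'
#' Tunables of the ensemble large-scale genomic alteration (LGA) caller:
#' the ladder of window sizes over which coverage is re-binned and
#' segmented, the LGA predicate (flank length and log2-ratio gap), the
#' per-model HRD cutoff, and the cross-window agreement needed for a
#' consensus call. The six window sizes span 5-1000 kb as a geometric
#' ladder; the cutoff and agreement rule are explicit, recalibratable
#' stand-ins (see [calibrate_lga_cutoff()]).
#'
#' @param window_sizes_kb Exactly six ascending window sizes in kb, all
#'   within 5-1000.
#' @param lga_min_seg Minimum flanking-segment length for an LGA, bp.
#' @param lga_smooth_len Segments shorter than this are smoothed away, bp.
#' @param lga_min_cn_gap Minimum absolute log2-ratio difference across a
#'   junction.
#' @param lga_hrd_cutoff Per-model HRD call when `lga_count >= cutoff`.
#' @param min_agreement Models that must share the majority label for a
#'   consensus (out of six).
#' @param penalty_factor Segmentation penalty per changepoint, in units of
#'   `sigma^2 * log(n)` where `sigma` is the estimated bin noise.
#' @param min_bins Minimum bins per chromosome after re-binning;
#'   shorter chromosomes are skipped with a warning.
#' @param min_coverage_frac Minimum fraction of the genome the bins must
#'   cover for a call; below it the sample fails with reason
#'   `insufficient coverage`.
#' @return A list of class `shallow_config`.
#' @export
shallow_config <- function(window_sizes_kb = c(5, 10, 50, 100, 500, 1000),
                           lga_min_seg = 10e6, lga_smooth_len = 3e6,
                           lga_min_cn_gap = 0.2, lga_hrd_cutoff = 20,
                           min_agreement = 4, penalty_factor = 3,
                           min_bins = 10, min_coverage_frac = 0.8) {
  if (length(window_sizes_kb) != 6 || is.unsorted(window_sizes_kb, strictly = TRUE) ||
    any(window_sizes_kb < 5 | window_sizes_kb > 1000)) {
    stop("window_sizes_kb must be six ascending sizes within [5, 1000] kb",
      call. = FALSE
    )
  }
  structure(
    list(
      window_sizes_kb = window_sizes_kb, lga_min_seg = lga_min_seg,
      lga_smooth_len = lga_smooth_len, lga_min_cn_gap = lga_min_cn_gap,
      lga_hrd_cutoff = lga_hrd_cutoff, min_agreement = min_agreement,
      penalty_factor = penalty_factor, min_bins = min_bins,
      min_coverage_frac = min_coverage_frac
    ),
    class = "shallow_config"
  )
}

#' Re-bin coverage counts into larger windows
#'
#' Counts are summed within non-overlapping windows of the target size,
#' which must be an integer multiple of the source bin width. A trailing
#' window not fully covered by source bins is dropped.
#'
#' @param bins A `coverage_bins` tibble (columns `sample`, `chrom`,
#'   `start`, `count`) with a uniform bin width.
#' @param window_kb Target window size in kb.
#' @return A `coverage_bins` tibble at the new bin width.
#' @export
rebin <- function(bins, window_kb) {
  w0 <- bin_width(bins)
  w <- window_kb * 1000
  if (is.na(w0)) stop("source bin width is undetermined", call. = FALSE)
  if (w %% w0 != 0) {
    stop(
      "target window (", w, " bp) is not a multiple of the source bin width (",
      w0, " bp)",
      call. = FALSE
    )
  }
  k <- w %/% w0
  if (k == 1) {
    return(bins)
  }
  df <- tibble::as_tibble(bins)
  parts <- split(
    df[, c("start", "count")],
    list(sample = df$sample, chrom = df$chrom),
    drop = TRUE, sep = "\r"
  )
  out <- purrr::imap(parts, function(d, key) {
    nm <- strsplit(key, "\r", fixed = TRUE)[[1]]
    o <- order(d$start)
    s <- d$start[o]
    cnt <- d$count[o]
    n <- length(s)
    contiguous <- n > 0 && s[1] %% w == 0 &&
      isTRUE(all(s == s[1] + (seq_len(n) - 1) * w0))
    if (contiguous) {
      # fast path: fold k consecutive bins per window, drop trailing partial
      nk <- (n %/% k) * k
      if (nk == 0) {
        return(NULL)
      }
      counts <- colSums(matrix(cnt[seq_len(nk)], nrow = k))
      starts <- s[seq(1, nk, by = k)]
    } else {
      win <- (s %/% w) * w
      full <- names(which(table(win) == k))
      keep <- win %in% as.numeric(full)
      if (!any(keep)) {
        return(NULL)
      }
      counts <- as.numeric(rowsum(cnt[keep], win[keep]))
      starts <- sort(unique(win[keep]))
    }
    tibble::tibble(sample = nm[1], chrom = nm[2], start = starts, count = counts)
  }) |> purrr::list_rbind()
  as_coverage_bins(out, width = w)
}

#' Segment binned coverage into a piecewise-constant log2-ratio profile
#'
#' Counts are converted to log2 ratios against the sample median (with a
#' 0.5 pseudo-count guarding empty bins) and each chromosome is segmented
#' by exact penalized least-squares changepoint detection (PELT). The
#' per-changepoint penalty is `penalty_factor * sigma^2 * log(n)`, with
#' `sigma` estimated robustly from the median absolute first difference of
#' the log2 ratios. The fit is deterministic for fixed input.
#'
#' @param bins A single-sample `coverage_bins` tibble.
#' @param window_kb Optional window size in kb; when it differs from the
#'   current bin width the bins are passed through [rebin()] first.
#' @param cfg A [shallow_config()].
#' @return A tibble of class `hrd_segmentation`: columns `chrom`, `start`,
#'   `end`, `n_bins`, `mean_log2`, with attributes `window_kb`, `sigma`
#'   and `skipped` (chromosomes with too few bins).
#' @export
segment_bins <- function(bins, window_kb = NULL, cfg = shallow_config()) {
  if (length(unique(bins$sample)) != 1) {
    stop("segment_bins() expects a single-sample bin table", call. = FALSE)
  }
  if (!is.null(window_kb) && window_kb * 1000 != bin_width(bins)) {
    bins <- rebin(bins, window_kb)
  }
  w <- bin_width(bins)
  df <- tibble::as_tibble(bins) |>
    dplyr::arrange(.data$chrom, .data$start)
  med <- stats::median(df$count)
  df$log2r <- log2((df$count + 0.5) / (med + 0.5))
  diffs <- unlist(tapply(df$log2r, df$chrom, diff, simplify = FALSE),
    use.names = FALSE
  )
  sigma <- stats::mad(diffs) / sqrt(2)
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1e-3
  beta <- cfg$penalty_factor * sigma^2 * log(nrow(df))
  chroms <- unique(df$chrom)
  skipped <- character()
  segs <- purrr::map(chroms, function(ch) {
    r <- df$log2r[df$chrom == ch]
    starts <- df$start[df$chrom == ch]
    if (length(r) < cfg$min_bins) {
      skipped <<- c(skipped, ch)
      return(NULL)
    }
    cps <- fpop_mean(r, beta)
    bounds <- c(0L, cps, length(r))
    tibble::tibble(
      chrom = ch,
      start = starts[bounds[-length(bounds)] + 1L],
      end = starts[bounds[-1]] + w,
      n_bins = diff(bounds),
      mean_log2 = vapply(
        seq_len(length(bounds) - 1),
        function(i) mean(r[(bounds[i] + 1):bounds[i + 1]]),
        numeric(1)
      )
    )
  })
  if (length(skipped) > 0) {
    warning(
      "chromosome(s) skipped (fewer than ", cfg$min_bins, " bins): ",
      paste(skipped, collapse = ", "),
      call. = FALSE
    )
  }
  out <- purrr::list_rbind(purrr::compact(segs))
  attr(out, "window_kb") <- w / 1000
  attr(out, "sigma") <- sigma
  attr(out, "skipped") <- skipped
  attr(out, "sample") <- unique(bins$sample)
  class(out) <- unique(c("hrd_segmentation", class(tibble::tibble())))
  out
}

# Smooth a continuous-valued arm profile: merge neighbours whose mean
# log2 ratios differ by less than `gap` (weighted mean), iteratively drop
# sub-smooth_len segments, until stable.
smooth_arm_log2 <- function(d, smooth_len, gap) {
  merge_close <- function(d, max_jump) {
    while (nrow(d) > 1) {
      dif <- abs(diff(d$mean_log2))
      adj <- (d$start[-1] - d$end[-nrow(d)]) < smooth_len
      i <- which(dif < max_jump & adj)
      if (length(i) == 0) break
      i <- i[which.min(dif[i])]
      w1 <- d$bases[i]
      w2 <- d$bases[i + 1]
      d$mean_log2[i] <- (d$mean_log2[i] * w1 + d$mean_log2[i + 1] * w2) / (w1 + w2)
      d$end[i] <- d$end[i + 1]
      d$bases[i] <- w1 + w2
      d <- d[-(i + 1), , drop = FALSE]
    }
    d
  }
  d <- d[order(d$start), , drop = FALSE]
  d$bases <- d$end - d$start
  d <- merge_close(d, gap)
  repeat {
    n0 <- nrow(d)
    d <- d[d$bases >= smooth_len, , drop = FALSE]
    d <- merge_close(d, gap)
    if (nrow(d) == n0) break
  }
  d
}

#' Count large-scale genomic alterations (LGAs) in a segmentation
#'
#' Per chromosome arm, segments shorter than `cfg$lga_smooth_len` are
#' smoothed away (neighbouring segments closer than `cfg$lga_min_cn_gap`
#' in log2 ratio are merged first, so over-segmentation is harmless) and
#' every junction with both flanks at least `cfg$lga_min_seg` long and an
#' absolute log2-ratio jump of at least `cfg$lga_min_cn_gap` is counted.
#'
#' @param seg An `hrd_segmentation` tibble from [segment_bins()].
#' @param build An `hrd_build`.
#' @param cfg A [shallow_config()].
#' @return Integer LGA count.
#' @export
count_lga <- function(seg, build, cfg = shallow_config()) {
  arms <- build_arms(build)
  total <- 0L
  for (i in seq_len(nrow(arms))) {
    a <- arms[i, ]
    d <- seg[seg$chrom == a$chrom & seg$end > a$arm_start & seg$start < a$arm_end, ,
      drop = FALSE
    ]
    if (nrow(d) == 0) next
    d <- tibble::as_tibble(d)
    d$start <- pmax(d$start, a$arm_start)
    d$end <- pmin(d$end, a$arm_end)
    d <- smooth_arm_log2(d, cfg$lga_smooth_len, cfg$lga_min_cn_gap)
    if (nrow(d) <= 1) next
    j <- seq_len(nrow(d) - 1)
    adjacent <- (d$start[j + 1] - d$end[j]) < cfg$lga_smooth_len
    jump <- abs(diff(d$mean_log2)) >= cfg$lga_min_cn_gap
    long_both <- d$bases[j] >= cfg$lga_min_seg & d$bases[j + 1] >= cfg$lga_min_seg
    total <- total + sum(adjacent & jump & long_both)
  }
  as.integer(total)
}

consensus_from_labels <- function(labels, min_agreement) {
  tab <- table(factor(labels, levels = c("HRD", "HRP")))
  top <- names(tab)[which.max(tab)]
  agreement <- max(tab) / length(labels)
  consensus <- if (max(tab) >= min_agreement) top else "Inconclusive"
  list(label = consensus, agreement = agreement)
}

#' Ensemble HRD call from shallow-WGS coverage bins
#'
#' Runs the full per-sample pipeline: for each of the six window sizes,
#' re-bin, segment and count LGAs; call each model HRD when its LGA count
#' reaches `cfg$lga_hrd_cutoff`; take the majority label as consensus when
#' at least `cfg$min_agreement` of the six models share it, otherwise
#' `Inconclusive`. BRCA status is never consulted. Samples whose bins
#' cover less than `cfg$min_coverage_frac` of the genome fail with reason
#' `insufficient coverage`.
#'
#' @param bins A `coverage_bins` tibble; may contain several samples.
#' @param build An `hrd_build`.
#' @param cfg A [shallow_config()].
#' @return A tibble with one row per sample: `sample`, `label` (`HRD`,
#'   `HRP` or `Inconclusive`), `agreement`, `failure_reason`, and a
#'   list-column `models` holding the per-window LGA counts and labels.
#' @export
classify_lab2 <- function(bins, build, cfg = shallow_config()) {
  samples <- unique(bins$sample)
  purrr::map(samples, function(s) {
    b <- bins[bins$sample == s, , drop = FALSE]
    b <- as_coverage_bins(tibble::as_tibble(b), width = bin_width(bins))
    covered <- nrow(b) * bin_width(b)
    if (covered / sum(build$length) < cfg$min_coverage_frac) {
      return(tibble::tibble(
        sample = s, label = "Inconclusive", agreement = NA_real_,
        failure_reason = "insufficient coverage",
        models = list(tibble::tibble(
          window_kb = numeric(), lga_count = integer(), label = character()
        ))
      ))
    }
    models <- purrr::map(cfg$window_sizes_kb, function(wkb) {
      seg <- segment_bins(b, window_kb = wkb, cfg = cfg)
      n <- count_lga(seg, build, cfg)
      tibble::tibble(
        window_kb = wkb, lga_count = n,
        label = if (n >= cfg$lga_hrd_cutoff) "HRD" else "HRP"
      )
    }) |> purrr::list_rbind()
    cons <- consensus_from_labels(models$label, cfg$min_agreement)
    tibble::tibble(
      sample = s, label = cons$label, agreement = cons$agreement,
      failure_reason = NA_character_, models = list(models)
    )
  }) |> purrr::list_rbind()
}

#' Calibrate the per-model LGA cutoff from labeled training counts
#'
#' Scans every integer threshold and returns the one maximizing Youden's
#' J (sensitivity + specificity - 1) for the rule `HRD iff count >=
#' cutoff`; ties are broken toward the higher threshold (higher
#' specificity). Mirrors a development set of known-HRD and known-HRP
#' samples.
#'
#' @param lga_counts Integer vector of per-sample LGA counts.
#' @param labels Character vector (`"HRD"`/`"HRP"`), same length; at least
#'   10 of each.
#' @return A list with `cutoff`, `youden_j`, `sensitivity`, `specificity`.
#' @export
calibrate_lga_cutoff <- function(lga_counts, labels) {
  stopifnot(length(lga_counts) == length(labels))
  hrd <- lga_counts[labels == "HRD"]
  hrp <- lga_counts[labels == "HRP"]
  if (length(hrd) < 10 || length(hrp) < 10) {
    stop("need at least 10 training samples per group", call. = FALSE)
  }
  thresholds <- seq(min(lga_counts), max(lga_counts) + 1L)
  sens <- vapply(thresholds, function(t) mean(hrd >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(hrp < t), numeric(1))
  j <- sens + spec - 1
  best <- max(j)
  cutoff <- max(thresholds[j == best]) # ties -> higher specificity
  if (best <= 0) {
    warning("training groups are not separable (Youden's J <= 0)", call. = FALSE)
  }
  i <- match(cutoff, thresholds)
  list(
    cutoff = as.integer(cutoff), youden_j = best,
    sensitivity = sens[i], specificity = spec[i]
  )
}
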