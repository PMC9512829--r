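# Independent oracles used to validate the engines.
#
# The scar oracle materializes per-base state vectors at 0.1 Mb resolution
# and applies the LOH/TAI/LST definitions literally on those arrays; it
# shares no interval arithmetic with the package implementation.

# a build whose lengths/centromeres sit on the 0.1 Mb oracle grid
grid_build <- function(res = 1e5) {
  b <- hrdkit::default_build()
  hrdkit::genome_build(
    b$chrom,
    floor(b$length / res) * res,
    floor(b$cen_start / res) * res,
    floor(b$cen_end / res) * res
  )
}

rha <- function(x) sign(x) * floor(abs(x) + 0.5) # round half away from zero

# runs of `flag` over per-base bins where NA means uncovered; flagged runs
# separated by a single uncovered stretch shorter than gap_tol merge.
# Returns first_bin/last_bin (span) and bases (flagged bins only).
base_runs <- function(flag, res, gap_tol) {
  cat3 <- ifelse(is.na(flag), 1L, ifelse(flag, 2L, 0L))
  r <- rle(cat3)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- list()
  cur <- NULL
  for (i in seq_along(r$values)) {
    v <- r$values[i]
    if (v == 2L) {
      if (is.null(cur)) {
        cur <- list(first = starts[i], last = ends[i], bases = r$lengths[i])
      } else {
        cur$last <- ends[i]
        cur$bases <- cur$bases + r$lengths[i]
      }
    } else if (v == 1L && !is.null(cur) && r$lengths[i] * res < gap_tol &&
      i < length(r$values) && r$values[i + 1] == 2L) {
      # short uncovered gap between flagged stretches: run continues
    } else {
      if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
      cur <- NULL
    }
  }
  if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
  runs
}

oracle_scar_scores <- function(profile, build, cfg = hrdkit::scar_config(),
                               res = 1e5) {
  stopifnot(length(unique(profile$sample)) == 1)
  loh <- tai <- lst <- 0L
  for (ci in seq_len(nrow(build))) {
    ch <- build$chrom[ci]
    len <- build$length[ci]
    nb <- floor(len / res)
    total <- rep(NA_real_, nb)
    minor <- rep(NA_real_, nb)
    segs <- profile[profile$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(segs))) {
      i0 <- floor(segs$start[i] / res) + 1
      i1 <- min(ceiling(segs$end[i] / res), nb)
      if (i1 >= i0) {
        total[i0:i1] <- rha(segs$total_cn[i])
        minor[i0:i1] <- rha(segs$minor_cn[i])
      }
    }
    minor <- pmin(minor, total - minor)

    # LOH: minor 0, total >= 1; > loh_min_len; not the whole chromosome
    for (run in base_runs(minor == 0 & total >= 1, res, cfg$gap_tol)) {
      if (run$bases * res > cfg$loh_min_len &&
        !(run$first == 1 && run$last == nb)) {
        loh <- loh + 1L
      }
    }

    # TAI: allelic imbalance touching an end, centromere-free, > tai_min_len
    cen0 <- build$cen_start[ci]
    cen1 <- build$cen_end[ci]
    for (run in base_runs(minor != total - minor, res, cfg$gap_tol)) {
      span0 <- (run$first - 1) * res
      span1 <- run$last * res
      touches <- run$first == 1 || run$last == nb
      crosses <- span0 < cen1 && span1 > cen0
      if (touches && !crosses && run$bases * res > cfg$tai_min_len) {
        tai <- tai + 1L
      }
    }

    # LST: per arm, smoothed junction count on the base state vector
    for (arm in list(c(0, cen0), c(cen1, len))) {
      a0 <- floor(arm[1] / res) + 1
      a1 <- floor(arm[2] / res)
      if (a1 < a0) next
      st <- ifelse(is.na(total[a0:a1]), NA,
        paste(total[a0:a1], minor[a0:a1])
      )
      lst <- lst + oracle_arm_lst(st, res, cfg)
    }
  }
  c(loh = loh, tai = tai, lst = lst)
}

oracle_arm_lst <- function(st, res, cfg) {
  r <- rle(st)
  d <- data.frame(
    state = r$values,
    first = cumsum(r$lengths) - r$lengths + 1,
    last = cumsum(r$lengths)
  )
  d <- d[!is.na(d$state), , drop = FALSE]
  if (nrow(d) == 0) {
    return(0L)
  }
  d$bases <- (d$last - d$first + 1) * res
  merge_same <- function(d, max_gap) {
    repeat {
      if (nrow(d) <= 1) {
        return(d)
      }
      gap <- (d$first[-1] - d$last[-nrow(d)] - 1) * res
      i <- which(d$state[-1] == d$state[-nrow(d)] & gap < max_gap)
      if (length(i) == 0) {
        return(d)
      }
      i <- i[1]
      d$last[i] <- d$last[i + 1]
      d$bases[i] <- d$bases[i] + d$bases[i + 1]
      d <- d[-(i + 1), , drop = FALSE]
    }
  }
  d <- merge_same(d, cfg$gap_tol)
  repeat {
    n0 <- nrow(d)
    d <- d[d$bases >= cfg$lst_smooth_len, , drop = FALSE]
    d <- merge_same(d, cfg$lst_smooth_len)
    if (nrow(d) == n0) break
  }
  if (nrow(d) <= 1) {
    return(0L)
  }
  i <- seq_len(nrow(d) - 1)
  gap <- (d$first[i + 1] - d$last[i] - 1) * res
  sum(
    gap < cfg$lst_smooth_len &
      d$state[i + 1] != d$state[i] &
      d$bases[i] >= cfg$lst_min_seg &
      d$bases[i + 1] >= cfg$lst_min_seg
  )
}

# exhaustive O(n^2) optimal partitioning for penalized least-squares
# segmentation (reference for the pruned implementations)
oracle_op_segment <- function(x, beta) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  ss <- cumsum(c(0, x^2))
  F <- c(-beta, rep(Inf, n))
  prev <- integer(n + 1)
  for (t in seq_len(n)) {
    for (s in 0:(t - 1)) {
      d <- cs[t + 1] - cs[s + 1]
      v <- F[s + 1] + (ss[t + 1] - ss[s + 1] - d^2 / (t - s)) + beta
      if (v < F[t + 1]) {
        F[t + 1] <- v
        prev[t + 1] <- s
      }
    }
  }
  cps <- integer(0)
  t <- n
  while (t > 0) {
    if (prev[t + 1] > 0) cps <- c(prev[t + 1], cps)
    t <- prev[t + 1]
  }
  cps
}

# brute-force log-rank chi-square via hypergeometric expectations
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group))
  obs <- exp_ <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    obs <- obs + d1
    exp_ <- exp_ + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (obs - exp_)^2 / v
}
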