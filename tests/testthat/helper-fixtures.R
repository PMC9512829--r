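# Small fixtures built in code.

# two 200 Mb chromosomes with a 10 Mb centromere at 95-105 Mb
toy_build <- function(n_chrom = 2) {
  hrdkit::genome_build(
    paste0("chr", seq_len(n_chrom)),
    rep(200e6, n_chrom),
    rep(95e6, n_chrom),
    rep(105e6, n_chrom)
  )
}

# quick single-sample profile builder: rows are c(chrom, start, end, total, minor)
prof <- function(..., sample = "S1") {
  rows <- list(...)
  tibble::tibble(
    sample = sample,
    chrom = vapply(rows, function(r) as.character(r[[1]]), ""),
    start = vapply(rows, function(r) as.numeric(r[[2]]), 0),
    end = vapply(rows, function(r) as.numeric(r[[3]]), 0),
    total_cn = vapply(rows, function(r) as.numeric(r[[4]]), 0),
    minor_cn = vapply(rows, function(r) as.numeric(r[[5]]), 0)
  )
}

# fill uncovered territory of a single-sample profile with balanced diploid
fill_diploid <- function(p, build) {
  sid <- if (nrow(p) > 0) unique(p$sample) else "S1"
  extra <- list()
  for (ci in seq_len(nrow(build))) {
    ch <- build$chrom[ci]
    len <- build$length[ci]
    segs <- p[p$chrom == ch, , drop = FALSE]
    segs <- segs[order(segs$start), ]
    bounds_start <- c(0, segs$end)
    bounds_end <- c(segs$start, len)
    keep <- bounds_end > bounds_start
    if (any(keep)) {
      extra[[length(extra) + 1]] <- tibble::tibble(
        sample = sid, chrom = ch,
        start = bounds_start[keep], end = bounds_end[keep],
        total_cn = 2, minor_cn = 1
      )
    }
  }
  dplyr::arrange(
    dplyr::bind_rows(p, purrr::list_rbind(extra)),
    chrom, start
  )
}

# per-sample call tibble shorthand
calls_tbl <- function(labels, assay = "A") {
  tibble::tibble(
    sample = sprintf("S%03d", seq_along(labels)),
    assay = assay,
    label = labels
  )
}
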