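#' @import tibble
#' @importFrom rlang .data
#' @importFrom stats median qbeta qchisq qnorm quantile rbinom rexp rnbinom
#'   rpois runif setNames complete.cases mad pchisq sd
#' @importFrom utils head tail
NULL

# Closed vocabulary for variant clinical significance, with common aliases.
CLASSIFICATION_LEVELS <- c(
  "pathogenic", "likely_pathogenic", "vus", "likely_benign", "benign", "passenger"
)

normalize_classification <- function(x) {
  key <- gsub("[ /-]", "_", tolower(trimws(as.character(x))))
  map <- c(
    pathogenic = "pathogenic",
    likely_pathogenic = "likely_pathogenic",
    vus = "vus",
    uncertain_significance = "vus",
    variant_of_unknown_significance = "vus",
    likely_benign = "likely_benign",
    benign = "benign",
    passenger = "passenger"
  )
  out <- unname(map[key])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown classification token(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  out
}

read_tsv_checked <- function(path, required, what) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(
      what, " file ", path, " is missing column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  df
}

#' Read allele-specific copy-number segments (SEG dialect)
#'
#' Reads a tab-separated segment file with header columns `sample`,
#' `chrom`, `start`, `end`, `total_cn`, `minor_cn`. Input coordinates are
#' interpreted as 1-based inclusive (the common SEG convention) and
#' converted to the package's internal 0-based half-open convention, so a
#' segment covering the first megabase reads as `start = 0, end = 1e6`.
#'
#' Malformed rows are rejected, never repaired: `end < start`, unknown
#' chromosomes, negative copy numbers and overlapping segments within a
#' sample all raise an error that names the offending row or interval.
#'
#' @param path Path to the TSV file.
#' @param build An `hrd_build`; chromosome names are normalized against it
#'   and coordinates validated against its lengths.
#' @return A `segment_profile` tibble: columns `sample`, `chrom`, `start`,
#'   `end`, `total_cn`, `minor_cn`, sorted by sample, chromosome, start.
#' @seealso [write_segments()], [gen_profile()]
#' @export
read_segments <- function(path, build) {
  df <- read_tsv_checked(
    path, c("sample", "chrom", "start", "end", "total_cn", "minor_cn"),
    "segment"
  )
  df$.row <- seq_len(nrow(df)) + 1L # header is row 1
  bad <- which(df$end < df$start)
  if (length(bad) > 0) {
    stop("segment end < start at file row ", df$.row[bad[1]], call. = FALSE)
  }
  if (any(df$total_cn < 0 | df$minor_cn < 0)) {
    bad <- which(df$total_cn < 0 | df$minor_cn < 0)[1]
    stop("negative copy number at file row ", df$.row[bad], call. = FALSE)
  }
  df$chrom <- normalize_chrom(df$chrom, build)
  # 1-based inclusive -> 0-based half-open
  df$start <- as.numeric(df$start) - 1
  df$end <- as.numeric(df$end)
  lens <- build$length[match(df$chrom, build$chrom)]
  if (any(df$start < 0 | df$end > lens)) {
    bad <- which(df$start < 0 | df$end > lens)[1]
    stop("segment outside chromosome bounds at file row ", df$.row[bad],
      call. = FALSE
    )
  }
  out <- df |>
    dplyr::select(!".row") |>
    dplyr::arrange(.data$sample, match(.data$chrom, build$chrom), .data$start)
  validate_profile(out)
  as_segment_profile(out)
}

validate_profile <- function(segs) {
  ov <- segs |>
    dplyr::group_by(.data$sample, .data$chrom) |>
    dplyr::filter(dplyr::lag(.data$end, default = -Inf) > .data$start) |>
    dplyr::ungroup()
  if (nrow(ov) > 0) {
    stop(
      "overlapping segments for sample ", ov$sample[1], " on ", ov$chrom[1],
      " at [", ov$start[1], ", ", ov$end[1], ")",
      call. = FALSE
    )
  }
  invisible(segs)
}

as_segment_profile <- function(df) {
  class(df) <- unique(c("segment_profile", class(tibble::as_tibble(df))))
  tibble::as_tibble(df)
}

#' Write segments back to the SEG dialect
#'
#' Inverse of [read_segments()]: internal 0-based half-open coordinates are
#' converted back to 1-based inclusive on write, so write-then-read is the
#' identity.
#'
#' @param segs A segment tibble as returned by [read_segments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segs, path) {
  out <- segs
  out$start <- out$start + 1
  readr::write_tsv(
    out[, c("sample", "chrom", "start", "end", "total_cn", "minor_cn")],
    path, progress = FALSE
  )
  invisible(path)
}

#' Read a somatic variant table (TSV or VCF dialect)
#'
#' Two formats are accepted. A TSV with header `sample`, `gene`, `hgvs`,
#' `classification`, `origin`; or a VCF 4.x file whose INFO field carries
#' `GENE=` and `CLNSIG=` keys (and optionally `HGVS=`), with the sample id
#' taken from the single genotype column. Classification tokens are
#' normalized to the closed vocabulary `pathogenic`, `likely_pathogenic`,
#' `vus`, `likely_benign`, `benign`, `passenger`; any other token is
#' rejected with the token named.
#'
#' @param path Path to the variant file; VCF is detected by the
#'   `##fileformat=VCF` header line.
#' @return A tibble with columns `sample`, `gene`, `hgvs`, `classification`,
#'   `origin`.
#' @export
read_variant_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    return(read_variant_vcf(path))
  }
  df <- read_tsv_checked(
    path, c("sample", "gene", "hgvs", "classification", "origin"), "variant"
  )
  df$classification <- normalize_classification(df$classification)
  origin_ok <- df$origin %in% c("somatic", "germline", "unknown")
  if (!all(origin_ok)) {
    stop("unknown origin token(s): ",
      paste(unique(df$origin[!origin_ok]), collapse = ", "),
      call. = FALSE
    )
  }
  tibble::as_tibble(df[, c("sample", "gene", "hgvs", "classification", "origin")])
}

read_variant_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1) stop("VCF lacks a #CHROM header line", call. = FALSE)
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t")[[1]]
  sample_id <- if (length(cols) >= 10) cols[10] else "sample"
  body <- lines[seq.int(hdr + 1, length(lines))]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(tibble::tibble(
      sample = character(), gene = character(), hgvs = character(),
      classification = character(), origin = character()
    ))
  }
  fields <- strsplit(body, "\t")
  parse_one <- function(f, row) {
    info <- f[8]
    kv <- strsplit(strsplit(info, ";")[[1]], "=")
    keys <- vapply(kv, `[`, "", 1)
    vals <- vapply(kv, function(x) if (length(x) > 1) x[2] else NA_character_, "")
    get <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    gene <- get("GENE")
    clnsig <- get("CLNSIG")
    if (is.na(gene) || is.na(clnsig)) {
      stop("VCF record ", row, " lacks GENE/CLNSIG INFO keys", call. = FALSE)
    }
    hgvs <- get("HGVS")
    if (is.na(hgvs)) hgvs <- paste(f[1], f[2], f[4], f[5], sep = ":")
    origin <- get("ORIGIN")
    if (is.na(origin)) origin <- "unknown"
    tibble::tibble(
      sample = sample_id, gene = gene, hgvs = hgvs,
      classification = clnsig, origin = origin
    )
  }
  out <- purrr::map2(fields, seq_along(fields), parse_one) |> purrr::list_rbind()
  out$classification <- normalize_classification(out$classification)
  out
}

#' Write a variant table as TSV
#'
#' @param variants Tibble as returned by [read_variant_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  readr::write_tsv(
    variants[, c("sample", "gene", "hgvs", "classification", "origin")],
    path, progress = FALSE
  )
  invisible(path)
}

#' Read a per-cell immunofluorescence count table
#'
#' TSV with header `sample`, `cell_id`, `geminin_pos` (0/1), `rad51_foci`
#' (integer, >= 0), `gh2ax_pos` (0/1), `area_id`. Negative foci counts and
#' non-binary marker flags are rejected with the file row named.
#'
#' @param path Path to the TSV file.
#' @return A tibble of per-cell records, one row per cell.
#' @seealso [classify_lab3()], [gen_cells()]
#' @export
read_cell_table <- function(path) {
  df <- read_tsv_checked(
    path,
    c("sample", "cell_id", "geminin_pos", "rad51_foci", "gh2ax_pos", "area_id"),
    "cell"
  )
  bad <- which(df$rad51_foci < 0)
  if (length(bad) > 0) {
    stop("negative RAD51 foci count at file row ", bad[1] + 1L, call. = FALSE)
  }
  bad <- which(!(df$geminin_pos %in% c(0, 1)) | !(df$gh2ax_pos %in% c(0, 1)))
  if (length(bad) > 0) {
    stop("marker flags must be 0/1 at file row ", bad[1] + 1L, call. = FALSE)
  }
  df$geminin_pos <- as.logical(df$geminin_pos)
  df$gh2ax_pos <- as.logical(df$gh2ax_pos)
  tibble::as_tibble(df)
}

#' Write a per-cell count table as TSV
#'
#' @param cells Tibble as returned by [read_cell_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  out <- cells
  out$geminin_pos <- as.integer(out$geminin_pos)
  out$gh2ax_pos <- as.integer(out$gh2ax_pos)
  readr::write_tsv(
    out[, c("sample", "cell_id", "geminin_pos", "rad51_foci", "gh2ax_pos", "area_id")],
    path, progress = FALSE
  )
  invisible(path)
}

#' Read binned coverage counts
#'
#' TSV with header `sample`, `chrom`, `start`, `count`; `start` is the
#' 0-based bin start and the bin width must be uniform within each sample.
#'
#' @param path Path to the TSV file.
#' @param build An `hrd_build` used to normalize chromosome names.
#' @return A `coverage_bins` tibble with columns `sample`, `chrom`, `start`,
#'   `count` and a `bin_width` attribute.
#' @export
read_coverage_bins <- function(path, build) {
  df <- read_tsv_checked(path, c("sample", "chrom", "start", "count"), "bins")
  if (any(df$count < 0)) stop("negative bin counts", call. = FALSE)
  df$chrom <- normalize_chrom(df$chrom, build)
  as_coverage_bins(tibble::as_tibble(df))
}

as_coverage_bins <- function(df, width = NULL) {
  if (is.null(width)) {
    key <- paste(df$sample, df$chrom)
    w <- unique(unlist(
      tapply(df$start, key, function(s) unique(diff(sort(s))), simplify = FALSE)
    ))
    if (length(w) > 1) stop("bin width is not uniform", call. = FALSE)
    width <- if (length(w) == 1) w else NA_real_
  }
  attr(df, "bin_width") <- width
  class(df) <- unique(c("coverage_bins", class(tibble::as_tibble(df))))
  df
}

bin_width <- function(bins) attr(bins, "bin_width")

#' Write binned coverage counts as TSV
#'
#' @param bins A `coverage_bins` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_bins <- function(bins, path) {
  readr::write_tsv(
    as.data.frame(bins)[, c("sample", "chrom", "start", "count")],
    path, progress = FALSE
  )
  invisible(path)
}

#' Read a cohort outcome table
#'
#' TSV with header `sample`, `time` (months, > 0), `event` (0/1),
#' `response`, `age_group`, `ecog`, `residual_disease`, `figo_stage`.
#' Covariate levels are validated against their closed vocabularies.
#'
#' @param path Path to the TSV file.
#' @return A tibble of subject outcomes.
#' @export
read_cohort_table <- function(path) {
  df <- read_tsv_checked(
    path,
    c(
      "sample", "time", "event", "response", "age_group", "ecog",
      "residual_disease", "figo_stage"
    ),
    "cohort"
  )
  if (any(df$time <= 0)) stop("event/censoring times must be > 0", call. = FALSE)
  vocab <- list(
    response = c("complete", "partial", "stable", "progression", "not_evaluable"),
    age_group = c("<65", ">=65"),
    ecog = c("0", "1-2"),
    residual_disease = c("none", "<=1cm", ">1cm_or_not_operated"),
    figo_stage = c("III", "IV")
  )
  for (col in names(vocab)) {
    bad <- setdiff(unique(as.character(df[[col]])), vocab[[col]])
    if (length(bad) > 0) {
      stop("unknown ", col, " level(s): ", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  tibble::as_tibble(df)
}
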